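# internal validation helpers

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  if (strict_lower && x <= lower)
    stop_field(field, sprintf("must be > %g", lower))
  if (!strict_lower && x < lower)
    stop_field(field, sprintf("must be >= %g", lower))
  if (x > upper)
    stop_field(field, sprintf("must be <= %g", upper))
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop_field(field, sprintf("must be an integer >= %d", min))
  invisible(as.integer(x))
}

check_interval <- function(x, field, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)) || x[1] > x[2])
    stop_field(field, "must be a numeric interval c(lo, hi) with lo <= hi")
  if (x[1] < lower)
    stop_field(field, sprintf("lower bound must be >= %g", lower))
  invisible(x)
}

# proportions summing to 1 over a fixed name set
check_proportions <- function(x, field, names_expected, tol = 1e-12) {
  if (!is.numeric(x) || is.null(names(x)))
    stop_field(field, "must be a named numeric vector")
  missing <- setdiff(names_expected, names(x))
  if (length(missing))
    stop_field(field, paste("missing names:", paste(missing, collapse = ", ")))
  x <- x[names_expected]
  if (any(x < 0) || any(x > 1))
    stop_field(field, "entries must lie in [0, 1]")
  if (abs(sum(x) - 1) > tol)
    stop_field(field, sprintf("must sum to 1 (got %.15g)", sum(x)))
  invisible(x)
}

copepod_orders <- c("calanoid", "cyclopoid", "harpacticoid", "poecilostomatoid")
copepod_stages <- c("adult", "copepodite", "nauplius")
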