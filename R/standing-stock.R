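#' Parameters of the global adult-copepod standing-stock chain
#'
#' The global adult copepod standing stock in the top 100 m is obtained
#' from the global mesozooplankton stock by a multiplicative chain:
#' `z0 * (1 + net_correction) * f_copepod * f_adult`.
#'
#' Defaults: a global zooplankton stock of 0.31 GtC in the upper 100 m,
#' inflated by 1/3 because 200 um nets undersample mesozooplankton, 80% of
#' zooplankton biomass being copepods, and 60% of copepods being adults and
#' older copepodites at any time. These defaults give an adult stock of
#' 0.1984 GtC.
#'
#' @param z0_GtC Global mesozooplankton carbon stock, top 100 m, GtC.
#' @param net_correction Additive undersampling correction fraction.
#' @param f_copepod Copepod share of zooplankton biomass.
#' @param f_adult Adult + older-copepodite share of copepods.
#' @return An object of class `stock_params`.
#' @examples
#' adult_stock(stock_params())  # 0.1984
#' @export
stock_params <- function(z0_GtC = 0.31, net_correction = 1 / 3,
                         f_copepod = 0.8, f_adult = 0.6) {
  check_number(z0_GtC, "z0_GtC", lower = 0, upper = 2, strict_lower = TRUE)
  check_number(net_correction, "net_correction", lower = 0, upper = 2)
  check_number(f_copepod, "f_copepod", lower = 0, upper = 2,
               strict_lower = TRUE)
  check_number(f_adult, "f_adult", lower = 0, upper = 2,
               strict_lower = TRUE)
  structure(list(z0_GtC = z0_GtC, net_correction = net_correction,
                 f_copepod = f_copepod, f_adult = f_adult),
            class = "stock_params")
}

#' Global adult copepod standing stock
#'
#' @param params A [stock_params()].
#' @return Adult + older-copepodite copepod carbon stock, GtC, top 100 m.
#' @export
adult_stock <- function(params = stock_params()) {
  stopifnot(inherits(params, "stock_params"))
  params$z0_GtC * (1 + params$net_correction) * params$f_copepod *
    params$f_adult
}

#' Partition the adult copepod stock into calanoids and cyclopoids
#'
#' Applies a realm composition profile to the total adult stock. With
#' `cyclopoid_mode = "merged"` (default) poecilostomatoids count as
#' cyclopoids (`p_cyc_effective`); with `"strict"` only the nominal
#' cyclopoid share is used. The harpacticoid share is dropped, not
#' redistributed, so `B_cal + B_cyc` can be less than `B_adult`.
#'
#' @param B_adult Total adult copepod stock, GtC.
#' @param profile A [composition_profile()] (or [manual_profile()]).
#' @param cyclopoid_mode `"merged"` or `"strict"`.
#' @return An object of class `standing_stock`: list with `realm`,
#'   `B_adult_GtC`, `B_cal_GtC`, `B_cyc_GtC`, `cyclopoid_mode`.
#' @examples
#' coastal <- manual_profile(p_cal = 0.605, p_cyc = 0.285, p_poe = 0.11,
#'                           realm = "coastal")
#' partition_stock(adult_stock(), coastal)
#' @export
partition_stock <- function(B_adult, profile,
                            cyclopoid_mode = c("merged", "strict")) {
  cyclopoid_mode <- match.arg(cyclopoid_mode)
  check_number(B_adult, "B_adult", lower = 0)
  stopifnot(inherits(profile, "composition_profile"))
  p_cyc <- if (cyclopoid_mode == "merged") profile$p_cyc_effective
           else profile$p_cyc
  structure(list(realm = profile$realm,
                 B_adult_GtC = B_adult,
                 B_cal_GtC = B_adult * profile$p_cal,
                 B_cyc_GtC = B_adult * p_cyc,
                 cyclopoid_mode = cyclopoid_mode),
            class = "standing_stock")
}

#' @export
print.standing_stock <- function(x, ...) {
  cat(sprintf(
    "Adult copepod standing stock (%s, cyclopoid mode: %s)\n",
    x$realm, x$cyclopoid_mode))
  cat(sprintf("  total     %.4f GtC\n", x$B_adult_GtC))
  cat(sprintf("  calanoid  %.4f GtC\n", x$B_cal_GtC))
  cat(sprintf("  cyclopoid %.4f GtC\n", x$B_cyc_GtC))
  invisible(x)
}
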