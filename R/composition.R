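#' Filter plankton-abundance records to the budget's target fraction
#'
#' Keeps only the records that inform the calanoid/cyclopoid composition of
#' the surface copepod community: adults and copepodites, collected in the
#' top `max_depth_m` metres with a fine mesh. Coarse (e.g. 200 um) nets
#' undersample small copepods, so only the fine-mesh records are comparable.
#'
#' @param records Data frame of abundance records with at least the columns
#'   `depth_m`, `mesh_um`, `stage` (see [generate_abundance_records()] or
#'   [read_abundance_csv()] for the full schema).
#' @param max_depth_m Maximum sampling depth retained, metres (inclusive).
#' @param mesh_range_um Inclusive interval of accepted mesh sizes, micrometres.
#' @param stages Character vector of accepted life stages.
#' @return The retained rows of `records`, in their original order. An empty
#'   result is legal.
#' @examples
#' recs <- generate_abundance_records(abundance_spec(
#'   realm_label = "coastal", n_records = 200,
#'   true_fractions = c(calanoid = 0.6, cyclopoid = 0.3,
#'                      harpacticoid = 0, poecilostomatoid = 0.1),
#'   seed = 1))
#' nrow(filter_records(recs))
#' @export
filter_records <- function(records, max_depth_m = 100,
                           mesh_range_um = c(100, 116),
                           stages = c("adult", "copepodite")) {
  stopifnot(is.data.frame(records))
  need <- c("depth_m", "mesh_um", "stage")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("records is missing columns: ", paste(missing, collapse = ", "))
  check_interval(mesh_range_um, "mesh_range_um", lower = 0)
  keep <- records$depth_m <= max_depth_m &
    records$mesh_um >= mesh_range_um[1] &
    records$mesh_um <= mesh_range_um[2] &
    records$stage %in% stages
  records[keep, , drop = FALSE]
}

#' Copepod order composition of a set of filtered records
#'
#' Computes the share of each copepod order in a (filtered) abundance table.
#' Poecilostomatoids are traditionally counted with the cyclopoids and the
#' carnivorous genera among them feed like cyclopoids, so an effective
#' cyclopoid share `p_cyc_effective = p_cyc + p_poe` is always reported.
#' The harpacticoid share is reported but never redistributed: downstream
#' stock partitioning simply drops it.
#'
#' @param records Data frame of abundance records, normally the output of
#'   [filter_records()]; must be non-empty.
#' @param realm Realm label ("coastal" or "oceanic"). Taken from a `realm`
#'   column if present and `NULL` here.
#' @param weight `"abundance"` (default) weights each record by its
#'   `abundance` value, matching databases that report densities;
#'   `"records"` counts records equally, for sensitivity analysis.
#' @return An object of class `composition_profile`: a list with `realm`,
#'   the four order proportions `p_cal`, `p_cyc`, `p_har`, `p_poe`,
#'   `p_cyc_effective`, and `n_records_used`.
#' @examples
#' recs <- data.frame(
#'   order = c("calanoid", "cyclopoid", "poecilostomatoid"),
#'   abundance = c(605, 285, 110))
#' composition_profile(recs, realm = "coastal")
#' @export
composition_profile <- function(records, realm = NULL,
                                weight = c("abundance", "records")) {
  weight <- match.arg(weight)
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L)
    stop("cannot compute a composition profile from an empty record set",
         call. = FALSE)
  if (!"order" %in% names(records))
    stop("records is missing column: order")
  if (is.null(realm)) {
    realm <- if ("realm" %in% names(records)) {
      u <- unique(records$realm)
      if (length(u) != 1L)
        stop("records span several realms; pass `realm` explicitly")
      u
    } else NA_character_
  }
  w <- if (weight == "abundance") {
    if (!"abundance" %in% names(records))
      stop("records is missing column: abundance")
    if (any(records$abundance < 0)) stop("abundance must be non-negative")
    records$abundance
  } else rep(1, nrow(records))
  total <- sum(w)
  if (total <= 0) stop("total abundance weight is zero")
  share <- function(ord) sum(w[records$order == ord]) / total
  p <- vapply(copepod_orders, share, numeric(1))
  structure(list(
    realm = realm,
    p_cal = unname(p["calanoid"]),
    p_cyc = unname(p["cyclopoid"]),
    p_har = unname(p["harpacticoid"]),
    p_poe = unname(p["poecilostomatoid"]),
    p_cyc_effective = unname(p["cyclopoid"] + p["poecilostomatoid"]),
    n_records_used = nrow(records),
    weight = weight
  ), class = "composition_profile")
}

#' Build a composition profile from known order shares
#'
#' Convenience constructor when the shares themselves are the input (e.g.
#' published database percentages) rather than raw records.
#'
#' @param p_cal,p_cyc,p_har,p_poe Order proportions in `[0, 1]`; their sum
#'   must not exceed 1.
#' @param realm Realm label.
#' @return A `composition_profile`.
#' @examples
#' manual_profile(p_cal = 0.913, p_cyc = 0.059, p_har = 0.024,
#'                p_poe = 0.004, realm = "oceanic")
#' @export
manual_profile <- function(p_cal, p_cyc, p_har = 0, p_poe = 0, realm = NA) {
  for (nm in c("p_cal", "p_cyc", "p_har", "p_poe"))
    check_number(get(nm), nm, lower = 0, upper = 1)
  if (p_cal + p_cyc + p_har + p_poe > 1 + 1e-9)
    stop("order proportions sum to more than 1")
  structure(list(realm = realm, p_cal = p_cal, p_cyc = p_cyc,
                 p_har = p_har, p_poe = p_poe,
                 p_cyc_effective = p_cyc + p_poe,
                 n_records_used = NA_integer_, weight = "manual"),
            class = "composition_profile")
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("Copepod composition profile (%s, %s-weighted)\n",
              x$realm, x$weight))
  cat(sprintf("  calanoid         %6.1f%%\n", 100 * x$p_cal))
  cat(sprintf("  cyclopoid        %6.1f%%\n", 100 * x$p_cyc))
  cat(sprintf("  harpacticoid     %6.1f%%\n", 100 * x$p_har))
  cat(sprintf("  poecilostomatoid %6.1f%%\n", 100 * x$p_poe))
  cat(sprintf("  cyclopoid (effective, poecilostomatoids merged) %6.1f%%\n",
              100 * x$p_cyc_effective))
  if (!is.na(x$n_records_used))
    cat(sprintf("  records used: %d\n", x$n_records_used))
  invisible(x)
}

#' Read an abundance-record CSV with strict schema checking
#'
#' Expects columns `station_id, realm, depth_m, mesh_um, order, stage,
#' abundance`. Malformed rows (non-numeric depth/mesh/abundance, negative
#' values, unknown order or stage) are reported with their row numbers.
#'
#' @param path Path to a CSV file with a header row.
#' @return A data frame of abundance records.
#' @export
read_abundance_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "realm", "depth_m", "mesh_um", "order", "stage",
            "abundance")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("abundance CSV is missing columns: ",
         paste(missing, collapse = ", "))
  bad <- which(
    !is.finite(df$depth_m) | df$depth_m < 0 |
    !is.finite(df$mesh_um) | df$mesh_um <= 0 |
    !is.finite(df$abundance) | df$abundance < 0 |
    !(df$order %in% c(copepod_orders, "other")) |
    !(df$stage %in% copepod_stages)
  )
  if (length(bad))
    stop("malformed abundance records at rows: ",
         paste(utils::head(bad, 20), collapse = ", "),
         if (length(bad) > 20) sprintf(" (and %d more)", length(bad) - 20))
  df
}
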