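#' Specification for a synthetic plankton-abundance table
#'
#' Describes a synthetic database emulating public plankton-abundance
#' archives: records carry station, depth, mesh size, copepod order, life
#' stage and an abundance value. A fixed 20% of records are decoys that
#' violate exactly one of the composition filters (too deep, coarse mesh, or
#' naupliar stage) so that filtering tests are non-vacuous; the remaining
#' records draw their order from `true_fractions`, the planted ground truth.
#'
#' @param realm_label Realm the table represents ("coastal" or "oceanic").
#' @param n_records Number of records to generate.
#' @param true_fractions Named proportions over the four copepod orders
#'   (`calanoid`, `cyclopoid`, `harpacticoid`, `poecilostomatoid`); must sum
#'   to 1.
#' @param depth_range_m Interval of sampling depths for non-decoy records,
#'   metres.
#' @param mesh_values_um Mesh sizes in use; must include at least one value
#'   inside the fine-mesh window `[100, 116]` um and, for decoys to exist,
#'   at least one outside it.
#' @param stage_mix Named proportions over `adult`, `copepodite`,
#'   `nauplius`; non-decoy records use the adult/copepodite part
#'   (renormalised), decoy stage records are nauplii.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return An object of class `abundance_spec`.
#' @export
abundance_spec <- function(realm_label = "coastal",
                           n_records,
                           true_fractions,
                           depth_range_m = c(0, 100),
                           mesh_values_um = c(100, 110, 116, 200, 333),
                           stage_mix = c(adult = 0.5, copepodite = 0.3,
                                         nauplius = 0.2),
                           seed = 1L) {
  n_records <- check_count(n_records, "n_records", min = 1L)
  true_fractions <- check_proportions(true_fractions, "true_fractions",
                                      copepod_orders)
  check_interval(depth_range_m, "depth_range_m", lower = 0)
  if (!is.numeric(mesh_values_um) || !length(mesh_values_um) ||
      any(mesh_values_um <= 0))
    stop_field("mesh_values_um", "must be positive mesh sizes")
  if (!any(mesh_values_um >= 100 & mesh_values_um <= 116))
    stop_field("mesh_values_um",
               "must include at least one fine mesh in [100, 116] um")
  stage_mix <- check_proportions(stage_mix, "stage_mix", copepod_stages)
  if (stage_mix["adult"] + stage_mix["copepodite"] <= 0)
    stop_field("stage_mix", "adult + copepodite share must be positive")
  structure(list(realm_label = realm_label, n_records = n_records,
                 true_fractions = true_fractions,
                 depth_range_m = depth_range_m,
                 mesh_values_um = mesh_values_um,
                 stage_mix = stage_mix, seed = as.integer(seed)),
            class = "abundance_spec")
}

# decoy rate is fixed by design so filter tests always have both classes
DECOY_RATE <- 0.2

#' Generate a synthetic plankton-abundance table
#'
#' Draws `n_records` abundance records per the spec. Non-decoy records
#' sample depth uniformly in `depth_range_m`, a fine mesh from the in-window
#' mesh values, and an adult or copepodite stage, so that (when
#' `depth_range_m` lies within the filter window) they all pass
#' [filter_records()] and their order shares converge to `true_fractions`.
#' Decoys (a fixed 20%, flagged in the `decoy` column) violate one filter
#' each. Abundances are log-normal, independent of order.
#'
#' @param spec An [abundance_spec()].
#' @return Data frame with columns `station_id, realm, depth_m, mesh_um,
#'   order, stage, abundance, decoy` (the last is planted ground truth).
#' @examples
#' spec <- abundance_spec(n_records = 100,
#'   true_fractions = c(calanoid = 0.605, cyclopoid = 0.285,
#'                      harpacticoid = 0, poecilostomatoid = 0.11),
#'   seed = 42)
#' head(generate_abundance_records(spec))
#' @export
generate_abundance_records <- function(spec) {
  stopifnot(inherits(spec, "abundance_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_records
    n_decoy <- round(DECOY_RATE * n)
    decoy <- rep(FALSE, n)
    if (n_decoy > 0) decoy[sample.int(n, n_decoy)] <- TRUE

    fine_mesh <- spec$mesh_values_um[spec$mesh_values_um >= 100 &
                                     spec$mesh_values_um <= 116]
    coarse_mesh <- spec$mesh_values_um[spec$mesh_values_um < 100 |
                                       spec$mesh_values_um > 116]
    ac <- spec$stage_mix[c("adult", "copepodite")]
    ac <- ac / sum(ac)

    depth <- stats::runif(n, spec$depth_range_m[1], spec$depth_range_m[2])
    mesh <- sample(fine_mesh, n, replace = TRUE)
    stage <- sample(c("adult", "copepodite"), n, replace = TRUE, prob = ac)
    ord <- sample(copepod_orders, n, replace = TRUE,
                  prob = spec$true_fractions)

    # each decoy breaks exactly one filter; coarse-mesh mode needs a coarse
    # mesh size to exist in the spec
    modes <- c("depth", "stage", if (length(coarse_mesh)) "mesh")
    if (n_decoy > 0) {
      dm <- sample(modes, n_decoy, replace = TRUE)
      idx <- which(decoy)
      depth[idx][dm == "depth"] <- stats::runif(sum(dm == "depth"), 101, 500)
      stage[idx][dm == "stage"] <- "nauplius"
      if (length(coarse_mesh))
        mesh[idx][dm == "mesh"] <- sample(coarse_mesh, sum(dm == "mesh"),
                                          replace = TRUE)
    }

    data.frame(
      station_id = sprintf("ST%05d", sample.int(500, n, replace = TRUE)),
      realm = spec$realm_label,
      depth_m = depth,
      mesh_um = mesh,
      order = ord,
      stage = stage,
      abundance = stats::rlnorm(n, meanlog = log(50), sdlog = 1),
      decoy = decoy,
      stringsAsFactors = FALSE
    )
  })
}

#' Specification for synthetic copepod ingestion-rate records
#'
#' Emulates a feeding-study meta-analysis: records of daily carbon ingestion
#' against body mass for one copepod group in one experimental setting,
#' generated from a power-law (allometric) relation
#' `ingestion = intercept * mass^exponent` with log10-normal noise.
#'
#' @param group `"calanoid"` or `"cyclopoid"`.
#' @param setting `"field"` or `"laboratory"`.
#' @param n Number of records (>= 3).
#' @param allometry_intercept Ingestion (ugC/day) at 1 ugC body mass; > 0.
#' @param allometry_exponent Allometric scaling exponent (dimensionless).
#' @param mass_range_ugC Body-mass interval, ugC; lower bound > 0. Masses
#'   are drawn log-uniformly.
#' @param noise_sd_log10 Standard deviation of the log10 noise.
#' @param seed Integer seed.
#' @return An object of class `ingestion_spec`.
#' @export
ingestion_spec <- function(group = c("calanoid", "cyclopoid"),
                           setting = c("field", "laboratory"),
                           n,
                           allometry_intercept,
                           allometry_exponent = 1,
                           mass_range_ugC = c(1, 100),
                           noise_sd_log10 = 0.1,
                           seed = 1L) {
  group <- match.arg(group)
  setting <- match.arg(setting)
  n <- check_count(n, "n", min = 3L)
  check_number(allometry_intercept, "allometry_intercept", lower = 0,
               strict_lower = TRUE)
  check_number(allometry_exponent, "allometry_exponent")
  check_interval(mass_range_ugC, "mass_range_ugC")
  if (mass_range_ugC[1] <= 0)
    stop_field("mass_range_ugC", "lower bound must be > 0")
  check_number(noise_sd_log10, "noise_sd_log10", lower = 0)
  structure(list(group = group, setting = setting, n = n,
                 allometry_intercept = allometry_intercept,
                 allometry_exponent = allometry_exponent,
                 mass_range_ugC = mass_range_ugC,
                 noise_sd_log10 = noise_sd_log10, seed = as.integer(seed)),
            class = "ingestion_spec")
}

#' Generate synthetic ingestion-rate records
#'
#' @param spec An [ingestion_spec()].
#' @return Data frame with columns `group, setting, diet, body_mass_ugC,
#'   ingestion_ugC_per_day`.
#' @examples
#' recs <- generate_ingestion_records(ingestion_spec(
#'   group = "calanoid", setting = "field", n = 10,
#'   allometry_intercept = 0.05, allometry_exponent = 1,
#'   noise_sd_log10 = 0, seed = 7))
#' all.equal(recs$ingestion_ugC_per_day / recs$body_mass_ugC,
#'           rep(0.05, 10))
#' @export
generate_ingestion_records <- function(spec) {
  stopifnot(inherits(spec, "ingestion_spec"))
  withr::with_seed(spec$seed, {
    lmass <- stats::runif(spec$n, log10(spec$mass_range_ugC[1]),
                          log10(spec$mass_range_ugC[2]))
    mass <- 10^lmass
    ling <- log10(spec$allometry_intercept) +
      spec$allometry_exponent * lmass +
      if (spec$noise_sd_log10 > 0)
        stats::rnorm(spec$n, 0, spec$noise_sd_log10) else 0
    data.frame(
      group = spec$group,
      setting = spec$setting,
      diet = sample(c("heterotrophic_dinoflagellate", "ciliate",
                      "metazoan", "mixed"), spec$n, replace = TRUE),
      body_mass_ugC = mass,
      ingestion_ugC_per_day = 10^ling,
      stringsAsFactors = FALSE
    )
  })
}

#' Specification for a synthetic gut-content clone library
#'
#' Emulates a clone-library survey of copepod gut contents: short 16S-like
#' nucleotide fragments, several clones per copepod, drawn from a planted
#' set of prey OTUs. Reference OTU sequences are constructed so that every
#' pair diverges by at least `between_otu_divergence`; clones are copies of
#' their OTU's reference with substitutions at per-site rate
#' `within_otu_divergence` (no indels, so divergence is Hamming distance
#' over length).
#'
#' @param n_copepods Number of copepod specimens.
#' @param n_otus Number of planted prey OTUs.
#' @param seq_length_bp Fragment length, bases (>= 50).
#' @param within_otu_divergence Upper bound on the divergence between any
#'   two clones of one OTU (intra-OTU variable-site fraction); must be
#'   below `between_otu_divergence`.
#' @param between_otu_divergence Minimum pairwise divergence between OTU
#'   references.
#' @param clones_per_copepod Clones sequenced per copepod (default 5).
#' @param incidence_density Probability that a copepod carries each OTU
#'   beyond its first (every copepod carries at least one).
#' @param seed Integer seed.
#' @return An object of class `clone_spec`.
#' @export
clone_spec <- function(n_copepods, n_otus, seq_length_bp = 200,
                       within_otu_divergence = 0,
                       between_otu_divergence = 0.1,
                       clones_per_copepod = 5,
                       incidence_density = 0.2,
                       seed = 1L) {
  n_copepods <- check_count(n_copepods, "n_copepods")
  n_otus <- check_count(n_otus, "n_otus")
  seq_length_bp <- check_count(seq_length_bp, "seq_length_bp", min = 50L)
  check_number(within_otu_divergence, "within_otu_divergence", lower = 0,
               upper = 1)
  check_number(between_otu_divergence, "between_otu_divergence", lower = 0,
               upper = 1)
  if (within_otu_divergence >= between_otu_divergence)
    stop_field("within_otu_divergence",
               "must be below between_otu_divergence")
  clones_per_copepod <- check_count(clones_per_copepod, "clones_per_copepod")
  check_number(incidence_density, "incidence_density", lower = 0, upper = 1)
  d_sites <- ceiling(between_otu_divergence * seq_length_bp)
  if ((n_otus - 1L) * d_sites > seq_length_bp)
    stop("divergence constraints are infeasible: ", n_otus,
         " references with >= ", d_sites,
         " distinct mutated sites each do not fit in ", seq_length_bp,
         " bases", call. = FALSE)
  structure(list(n_copepods = n_copepods, n_otus = n_otus,
                 seq_length_bp = seq_length_bp,
                 within_otu_divergence = within_otu_divergence,
                 between_otu_divergence = between_otu_divergence,
                 clones_per_copepod = clones_per_copepod,
                 incidence_density = incidence_density,
                 seed = as.integer(seed)),
            class = "clone_spec")
}

# mutate `seq` (character vector of bases) at positions `pos`
mutate_sites <- function(seq, pos) {
  bases <- c("A", "C", "G", "T")
  for (p in pos) seq[p] <- sample(setdiff(bases, seq[p]), 1L)
  seq
}

# number of intra-OTU variable sites implied by the within divergence;
# bounding the count (rather than mutating each site independently) caps
# any clone-pair divergence at `within`, which is what a divergence
# threshold clustering rule assumes of intraspecific variation
n_variable_sites <- function(within, L) floor(within * L)

#' Generate a synthetic clone library with planted OTU structure
#'
#' Reference sequences are built from one random backbone by mutating
#' disjoint blocks of `ceiling(between * L)` sites per OTU, which guarantees
#' every pairwise reference divergence is at least `between_otu_divergence`.
#' Each copepod is assigned one OTU uniformly plus each further OTU with
#' probability `incidence_density`; its clones sample uniformly from the
#' assigned OTUs. Intra-OTU variation (intraspecific polymorphism plus
#' polymerase error) is planted at a per-OTU pool of
#' `floor(within_otu_divergence * L)` variable sites, each mutated in a
#' clone with probability 1/2, so any two clones of one OTU diverge by at
#' most `within_otu_divergence` and the planted clustering is recoverable
#' whenever the threshold separates the two divergence scales.
#'
#' @param spec A [clone_spec()].
#' @return A list with `sequences` (a [Biostrings::DNAStringSet] named
#'   `copepodID|cloneN`), `incidence` (planted copepod x OTU clone-count
#'   matrix), `otu_of_clone` (planted OTU id per clone) and `references`
#'   (the OTU reference sequences).
#' @export
generate_clone_library <- function(spec) {
  stopifnot(inherits(spec, "clone_spec"))
  withr::with_seed(spec$seed, {
    L <- spec$seq_length_bp
    k <- spec$n_otus
    bases <- c("A", "C", "G", "T")
    backbone <- sample(bases, L, replace = TRUE)
    d_sites <- ceiling(spec$between_otu_divergence * L)
    refs <- vector("list", k)
    refs[[1]] <- backbone
    if (k > 1) {
      for (i in 2:k) {
        block <- ((i - 2L) * d_sites + 1L):((i - 1L) * d_sites)
        refs[[i]] <- mutate_sites(backbone, block)
      }
    }
    n_var <- n_variable_sites(spec$within_otu_divergence, L)
    variable_sites <- lapply(seq_len(k), function(i)
      if (n_var > 0) sample.int(L, n_var) else integer(0))

    otu_ids <- sprintf("OTU%d", seq_len(k))
    cop_ids <- sprintf("cop%02d", seq_len(spec$n_copepods))
    incidence <- matrix(0L, spec$n_copepods, k,
                        dimnames = list(cop_ids, otu_ids))
    seqs <- character(0)
    seq_names <- character(0)
    otu_of_clone <- character(0)

    for (ci in seq_len(spec$n_copepods)) {
      carried <- unique(c(sample.int(k, 1L),
                          which(stats::runif(k) < spec$incidence_density)))
      for (cl in seq_len(spec$clones_per_copepod)) {
        otu <- if (length(carried) == 1L) carried else sample(carried, 1L)
        s <- refs[[otu]]
        vs <- variable_sites[[otu]]
        if (length(vs)) {
          hit <- vs[stats::runif(length(vs)) < 0.5]
          if (length(hit)) s <- mutate_sites(s, hit)
        }
        seqs <- c(seqs, paste(s, collapse = ""))
        seq_names <- c(seq_names, sprintf("%s|clone%d", cop_ids[ci], cl))
        otu_of_clone <- c(otu_of_clone, otu_ids[otu])
        incidence[ci, otu] <- incidence[ci, otu] + 1L
      }
    }

    dss <- Biostrings::DNAStringSet(seqs)
    names(dss) <- seq_names
    ref_set <- Biostrings::DNAStringSet(
      vapply(refs, paste, character(1), collapse = ""))
    names(ref_set) <- otu_ids
    list(sequences = dss, incidence = incidence,
         otu_of_clone = stats::setNames(otu_of_clone, seq_names),
         references = ref_set)
  })
}
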