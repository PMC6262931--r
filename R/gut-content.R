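#' Pairwise sequence divergence by global alignment
#'
#' Aligns two nucleotide sequences end to end (Needleman-Wunsch; match 1,
#' mismatch -1, gap -2 per gap position by default) and returns
#' `(mismatches + gap columns) / alignment length`. On equal-length,
#' indel-free pairs this equals the Hamming distance over the length. `N`
#' bases count as mismatches against everything, including `N`.
#'
#' @param a,b Nucleotide sequences (single characters strings over
#'   `A,C,G,T,N`, or [Biostrings::DNAString] objects); non-empty.
#' @param match,mismatch Alignment scores.
#' @param gap Score per gap position (negative).
#' @return Divergence in `[0, 1]`; symmetric in its arguments.
#' @examples
#' pairwise_divergence("ACGT", "ACGT")  # 0
#' pairwise_divergence("AAAA", "AAAT")  # 0.25
#' @export
pairwise_divergence <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- as.character(a); b <- as.character(b)
  if (length(a) != 1L || length(b) != 1L || !nzchar(a) || !nzchar(b))
    stop("sequences must be single non-empty strings", call. = FALSE)
  if (gap > 0) stop("gap score must be non-positive", call. = FALSE)
  letters <- c("A", "C", "G", "T", "N")
  submat <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(submat) <- match
  submat["N", "N"] <- mismatch  # N is never a confident match
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = submat,
    gapOpening = 0, gapExtension = -gap)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gaps <- pa == "-" | pb == "-"
  mism <- !gaps & (pa != pb | pa == "N")
  (sum(mism) + sum(gaps)) / length(pa)
}

#' Cluster clone sequences into OTUs at a divergence threshold
#'
#' Implements the clone-library convention that sequences within 1%
#' divergence belong to one operational taxonomic unit, allowing for
#' intra-specific variation and polymerase error. The default linkage is
#' greedy centroid in input order: each clone joins the first OTU whose
#' representative (founding clone) lies strictly below the threshold,
#' otherwise it founds a new OTU. This guarantees every member is within
#' the threshold of its representative and is deterministic for a fixed
#' input order. `linkage = "single"` instead cuts a single-linkage
#' hierarchical tree of all pairwise divergences at the threshold.
#'
#' @param clones A named [Biostrings::DNAStringSet] or named character
#'   vector; names follow `copepodID|cloneN` so the incidence matrix can
#'   be attributed to copepods.
#' @param threshold Divergence threshold (default 0.01, i.e. <1%).
#' @param linkage `"greedy"` (default) or `"single"`.
#' @return An object of class `otu_clustering`: list with
#'   `otu_assignments` (named character vector clone -> OTU id),
#'   `representatives` (named character vector OTU -> sequence),
#'   `threshold`, `linkage`, and `incidence` (copepod x OTU clone-count
#'   matrix; single row "all" if names carry no copepod ids).
#' @examples
#' lib <- generate_clone_library(clone_spec(n_copepods = 3, n_otus = 2,
#'   within_otu_divergence = 0, between_otu_divergence = 0.1, seed = 1))
#' cl <- cluster_otus(lib$sequences)
#' table(cl$otu_assignments)
#' @export
cluster_otus <- function(clones, threshold = 0.01,
                         linkage = c("greedy", "single")) {
  linkage <- match.arg(linkage)
  check_number(threshold, "threshold", lower = 0, upper = 1)
  seqs <- as.character(clones)
  if (!length(seqs)) stop("no clone sequences supplied", call. = FALSE)
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("clone%d", seq_along(seqs))

  n <- length(seqs)
  if (linkage == "greedy") {
    rep_seq <- character(0)
    assign <- integer(n)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (k in seq_along(rep_seq)) {
        # identical strings short-circuit the alignment
        d <- if (seqs[i] == rep_seq[k]) 0
             else pairwise_divergence(seqs[i], rep_seq[k])
        if (d < threshold) { assign[i] <- k; placed <- TRUE; break }
      }
      if (!placed) {
        rep_seq <- c(rep_seq, seqs[[i]])
        assign[i] <- length(rep_seq)
      }
    }
  } else {
    if (n == 1L) {
      assign <- 1L
    } else {
      d <- matrix(0, n, n)
      for (i in seq_len(n - 1)) for (j in (i + 1):n)
        d[i, j] <- d[j, i] <- if (seqs[i] == seqs[j]) 0
                              else pairwise_divergence(seqs[i], seqs[j])
      hc <- stats::hclust(stats::as.dist(d), method = "single")
      assign <- stats::cutree(hc, h = threshold - 1e-12)
      # renumber OTUs by first appearance to match input order
      assign <- match(assign, unique(assign))
    }
    rep_seq <- seqs[!duplicated(assign)]
  }

  otu_ids <- sprintf("OTU%d", seq_along(rep_seq))
  assignments <- stats::setNames(otu_ids[assign], names(seqs))
  representatives <- stats::setNames(unname(rep_seq), otu_ids)

  cop <- sub("\\|.*$", "", names(seqs))
  if (all(cop == names(seqs))) cop <- rep("all", n)
  incidence <- table(factor(cop, levels = unique(cop)),
                     factor(assignments, levels = otu_ids))
  incidence <- matrix(as.integer(incidence), nrow = nrow(incidence),
                      dimnames = dimnames(incidence))

  structure(list(otu_assignments = assignments,
                 representatives = representatives,
                 threshold = threshold, linkage = linkage,
                 incidence = incidence),
            class = "otu_clustering")
}

#' @export
print.otu_clustering <- function(x, ...) {
  cat(sprintf(
    "OTU clustering: %d clones -> %d OTUs (<%g divergence, %s linkage)\n",
    length(x$otu_assignments), length(x$representatives),
    x$threshold, x$linkage))
  invisible(x)
}

#' Summarise diet incidence across oceanographic conditions
#'
#' From a copepod x OTU incidence matrix (clone counts or presences)
#' computes per-condition distinct-OTU counts, per-copepod OTU richness
#' with its range and mean +/- sd per condition, optional per-phylum OTU
#' counts, and a two-sample t test comparing per-copepod richness between
#' the two conditions (Student equal-variance, two-sided, by default; the
#' variant is configurable since small clone-library studies rarely state
#' theirs).
#'
#' @param incidence Copepod x OTU matrix; entries > 0 mean the OTU was
#'   detected in that copepod.
#' @param condition_map Named vector mapping every copepod (row name) to a
#'   condition, e.g. `"downwelling"` / `"upwelling"`.
#' @param taxonomy Optional data frame with columns `otu` and `phylum`.
#' @param var_equal Use the pooled-variance Student t test (default)?
#' @param alternative Sidedness of the t test (`"two.sided"` default).
#' @return An object of class `diet_summary`: list with `n_otus_total`,
#'   `otus_per_condition`, `richness` (per copepod), `richness_stats`
#'   (per condition: n, mean, sd, min, max), `phylum_counts` (or `NULL`),
#'   and `t_test` (an `htest`, `NULL` if fewer than two conditions).
#' @examples
#' fix <- load_gut_incidence()
#' diet_summary(fix$incidence, fix$conditions, fix$taxonomy)
#' @export
diet_summary <- function(incidence, condition_map, taxonomy = NULL,
                         var_equal = TRUE, alternative = "two.sided") {
  incidence <- as.matrix(incidence)
  if (!nrow(incidence) || !ncol(incidence))
    stop("incidence matrix is empty", call. = FALSE)
  cops <- rownames(incidence)
  if (is.null(cops)) stop("incidence must have copepod row names")
  missing <- setdiff(cops, names(condition_map))
  if (length(missing))
    stop("no condition for copepods: ", paste(missing, collapse = ", "),
         call. = FALSE)
  cond <- factor(condition_map[cops])

  detected <- incidence > 0
  richness <- rowSums(detected)
  otus_per_condition <- vapply(
    levels(cond),
    function(lv) sum(colSums(detected[cond == lv, , drop = FALSE]) > 0),
    integer(1))
  richness_stats <- do.call(rbind, lapply(levels(cond), function(lv) {
    r <- richness[cond == lv]
    data.frame(condition = lv, n = length(r), mean = mean(r),
               sd = stats::sd(r), min = min(r), max = max(r),
               stringsAsFactors = FALSE)
  }))

  phylum_counts <- NULL
  if (!is.null(taxonomy)) {
    stopifnot(all(c("otu", "phylum") %in% names(taxonomy)))
    detected_otus <- colnames(incidence)[colSums(detected) > 0]
    ph <- taxonomy$phylum[match(detected_otus, taxonomy$otu)]
    phylum_counts <- table(ph)
  }

  t_test <- NULL
  if (nlevels(cond) == 2L &&
      all(table(cond) >= 2L)) {
    t_test <- stats::t.test(richness ~ cond, var.equal = var_equal,
                            alternative = alternative)
  }

  structure(list(n_otus_total = sum(colSums(detected) > 0),
                 otus_per_condition = otus_per_condition,
                 richness = richness,
                 richness_stats = richness_stats,
                 phylum_counts = phylum_counts,
                 t_test = t_test),
            class = "diet_summary")
}

#' @export
print.diet_summary <- function(x, ...) {
  cat(sprintf("Diet incidence summary: %d OTUs detected\n", x$n_otus_total))
  for (i in seq_len(nrow(x$richness_stats))) {
    r <- x$richness_stats[i, ]
    cat(sprintf(
      "  %-12s n=%d, distinct OTUs %d, richness %.2f +/- %.2f [%d, %d]\n",
      r$condition, r$n, x$otus_per_condition[[r$condition]], r$mean,
      ifelse(is.na(r$sd), 0, r$sd), r$min, r$max))
  }
  if (!is.null(x$phylum_counts)) {
    cat("  phyla: ",
        paste(sprintf("%s %d", names(x$phylum_counts), x$phylum_counts),
              collapse = ", "), "\n")
  }
  if (!is.null(x$t_test))
    cat(sprintf("  richness t test: t = %.3f, p = %.3f\n",
                x$t_test$statistic, x$t_test$p.value))
  invisible(x)
}

#' Load the packaged gut-content incidence fixture
#'
#' A clone-library survey of the digestive tracts of 17 adult female
#' copepod species from a seasonal upwelling system (NW Iberian shelf):
#' 16 metazoan prey OTUs across three phyla, with each copepod sampled
#' under either downwelling or upwelling conditions. Shipped as plain CSV
#' so the diet summaries run without sequence data.
#'
#' @return List with `incidence` (17 x 16 copepod x OTU clone-count
#'   matrix), `conditions` (named vector copepod -> condition),
#'   `copepods` (metadata data frame: species, condition, size class) and
#'   `taxonomy` (data frame: otu, taxon, phylum, closest-match accession).
#' @examples
#' fix <- load_gut_incidence()
#' dim(fix$incidence)
#' @export
load_gut_incidence <- function() {
  path <- function(f) system.file("extdata", f, package = "copelink",
                                  mustWork = TRUE)
  wide <- utils::read.csv(path("gut_incidence.csv"), check.names = FALSE)
  incidence <- as.matrix(wide[, -1, drop = FALSE])
  rownames(incidence) <- wide[[1]]
  storage.mode(incidence) <- "integer"
  copepods <- utils::read.csv(path("gut_copepods.csv"),
                              stringsAsFactors = FALSE)
  taxonomy <- utils::read.csv(path("gut_otus.csv"),
                              stringsAsFactors = FALSE)
  list(incidence = incidence,
       conditions = stats::setNames(copepods$condition,
                                    copepods$copepod_id),
       copepods = copepods,
       taxonomy = taxonomy)
}

#' Write clone sequences to a multi-FASTA file
#'
#' @param sequences A [Biostrings::DNAStringSet] (e.g. from
#'   [generate_clone_library()]); names follow `copepodID|cloneN`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clone_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(sequences, filepath = path)
  invisible(path)
}

#' Read clone sequences from a multi-FASTA file
#'
#' @param path FASTA file; headers follow `copepodID|cloneN`.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_clone_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}
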