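test_that("pairwise divergence handles matches, substitutions and gaps", {
  expect_equal(pairwise_divergence("ACGTACGT", "ACGTACGT"), 0)
  # one substitution in 200 bases
  s <- paste(rep("ACGT", 50), collapse = "")
  s2 <- sub("^A", "T", s)
  expect_equal(pairwise_divergence(s, s2), 1 / 200)
  expect_equal(pairwise_divergence("AAAA", "AAAT"), 0.25)
  # one deletion: 8-column alignment with one gap column
  expect_equal(pairwise_divergence("ACGTACGT", "ACGACGT"), 1 / 8)
  # symmetry
  expect_equal(pairwise_divergence("ACGTTT", "AGGTTA"),
               pairwise_divergence("AGGTTA", "ACGTTT"))
  expect_error(pairwise_divergence("", "ACGT"), "non-empty")
})

test_that("alignment divergence equals Hamming distance on indel-free pairs", {
  withr::with_seed(99, {
    for (rep in 1:10) {
      L <- sample(60:200, 1)
      a <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      b <- a
      k <- sample(0:floor(L / 10), 1)
      if (k > 0) {
        pos <- sample(L, k)
        for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                              a[p]), 1)
      }
      hamming <- sum(a != b) / L  # direct count, the oracle
      expect_equal(pairwise_divergence(paste(a, collapse = ""),
                                       paste(b, collapse = "")),
                   hamming)
    }
  })
})

test_that("greedy clustering recovers a planted library exactly", {
  lib <- generate_clone_library(clone_spec(
    n_copepods = 17, n_otus = 4, within_otu_divergence = 0,
    between_otu_divergence = 0.10, seed = 3))
  cl <- cluster_otus(lib$sequences, threshold = 0.01)
  expect_length(cl$representatives, 4L)
  expect_true(same_partition(cl$otu_assignments,
                             lib$otu_of_clone[names(cl$otu_assignments)]))
  # incidence matches the planted matrix up to OTU relabelling
  map <- vapply(cl$representatives, function(s)
    names(which(as.character(lib$references) == s)), character(1))
  expect_equal(unname(cl$incidence[rownames(lib$incidence),
                                   order(match(map,
                                               colnames(lib$incidence)))]),
               unname(lib$incidence))
  # single linkage agrees on a well-separated library
  sl <- cluster_otus(lib$sequences, threshold = 0.01, linkage = "single")
  expect_true(same_partition(sl$otu_assignments, cl$otu_assignments))
})

test_that("clustering extremes behave as the threshold dictates", {
  clones <- c("a|clone1" = "ACGTACGTAC", "a|clone2" = "ACGTACGTAC",
              "b|clone1" = "ACGTACGTAC")
  expect_length(cluster_otus(clones)$representatives, 1L)

  distinct <- c(x = "AAAAAAAAAA", y = "AAAAATAAAA", z = "TTTTTTTTAA")
  # threshold 0: nothing is < 0 divergent, one OTU per unique sequence
  expect_length(cluster_otus(distinct, threshold = 0)$representatives, 3L)
  # threshold 1: every divergence (< 1) joins the first OTU
  expect_length(cluster_otus(distinct, threshold = 1)$representatives, 1L)

  # OTU count is non-increasing in the threshold
  lib <- generate_clone_library(clone_spec(
    n_copepods = 6, n_otus = 3, within_otu_divergence = 0.01,
    between_otu_divergence = 0.08, seq_length_bp = 150, seed = 5))
  counts <- vapply(c(0.001, 0.01, 0.05, 0.2, 1),
                   function(th) length(cluster_otus(lib$sequences,
                                                    th)$representatives),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("incidence bookkeeping is exact", {
  lib <- generate_clone_library(clone_spec(
    n_copepods = 5, n_otus = 2, within_otu_divergence = 0,
    between_otu_divergence = 0.1, clones_per_copepod = 4, seed = 7))
  cl <- cluster_otus(lib$sequences)
  expect_equal(unname(rowSums(cl$incidence)), rep(4, 5))
  expect_equal(sum(cl$incidence), length(lib$sequences))
  # every clone is assigned to exactly one OTU, within threshold of its rep
  expect_length(cl$otu_assignments, length(lib$sequences))
  for (i in seq_along(cl$otu_assignments)) {
    d <- pairwise_divergence(
      as.character(lib$sequences[[i]]),
      cl$representatives[[cl$otu_assignments[[i]]]])
    expect_lt(d, cl$threshold)
  }
})

test_that("the packaged gut-content fixture yields the published summaries", {
  fix <- load_gut_incidence()
  expect_equal(dim(fix$incidence), c(17L, 16L))
  ds <- diet_summary(fix$incidence, fix$conditions, fix$taxonomy)
  expect_equal(ds$n_otus_total, 16L)
  expect_equal(unname(ds$otus_per_condition["downwelling"]), 7L)
  expect_equal(unname(ds$otus_per_condition["upwelling"]), 12L)
  expect_true(all(ds$richness >= 1 & ds$richness <= 4))
  expect_equal(as.vector(ds$phylum_counts[c("Crustacea", "Mollusca",
                                            "Chordata")]),
               c(13L, 2L, 1L))
  # per-condition richness means and sds as recomputed from the table
  rs <- ds$richness_stats
  expect_equal(rs$mean[rs$condition == "downwelling"], 13 / 7)
  expect_equal(rs$sd[rs$condition == "downwelling"], 0.69,
               tolerance = 0.01)
  expect_equal(rs$mean[rs$condition == "upwelling"], 2)
  expect_equal(rs$sd[rs$condition == "upwelling"], 1.15,
               tolerance = 0.01)
  expect_s3_class(ds$t_test, "htest")
})

test_that("the richness t test degenerates to p = 1 on identical groups", {
  inc <- matrix(0L, 6, 3,
                dimnames = list(paste0("c", 1:6), paste0("OTU", 1:3)))
  inc[1, 1] <- 1; inc[2, 1:2] <- 1; inc[3, 1:3] <- 1  # richness 1,2,3
  inc[4, 1] <- 1; inc[5, 1:2] <- 1; inc[6, 1:3] <- 1  # identical again
  cond <- stats::setNames(rep(c("A", "B"), each = 3), rownames(inc))
  ds <- diet_summary(inc, cond)
  expect_equal(ds$t_test$p.value, 1)

  expect_error(diet_summary(inc, cond[-1]), "c1")
})

test_that("clone FASTA round-trips through disk", {
  lib <- generate_clone_library(clone_spec(
    n_copepods = 2, n_otus = 2, within_otu_divergence = 0,
    between_otu_divergence = 0.1, seed = 2))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_clone_fasta(lib$sequences, f)
  back <- read_clone_fasta(f)
  expect_equal(as.character(back), as.character(lib$sequences))
})
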