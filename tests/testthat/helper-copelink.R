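# shared fixtures: the published database composition profiles
coastal_profile <- function() {
  manual_profile(p_cal = 0.605, p_cyc = 0.285, p_poe = 0.11,
                 realm = "coastal")
}

oceanic_profile <- function() {
  manual_profile(p_cal = 0.913, p_cyc = 0.059, p_har = 0.024,
                 p_poe = 0.004, realm = "oceanic")
}

# two labelled clusterings induce the same partition iff their
# cross-tabulation is a permutation matrix pattern
same_partition <- function(a, b) {
  tab <- table(a, b) > 0
  all(rowSums(tab) == 1) && all(colSums(tab) == 1)
}

# independent closed-form least squares on log10 scale (oracle for the
# allometric WSIR fit; avoids lm on purpose)
ols_log10 <- function(mass, ingestion) {
  x <- log10(mass); y <- log10(ingestion)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  c(intercept = a, slope = b)
}
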