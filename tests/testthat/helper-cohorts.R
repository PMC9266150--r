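# Small in-code fixtures shared across test files.

# A tiny hand-checkable set: 3 samples, 3 wavelengths.
tinySet <- function() {
  SpectraSet(sampleIds = c("s1", "s2", "s3"),
             wavelengths = c(500, 600, 700),
             intensities = rbind(c(1, 2, 3), c(3, 2, 1), c(2, 2, 2)),
             diameters = c(70, 80, 90), ssc = c(12, 13, 14),
             group = c("65-75", "75-85", "85-95"))
}

# Noiseless cohort with SSC-independent constant extinction: the exact
# Beer-Lambert world in which recovery/collapse are closed-form.
noiselessCohort <- function(u = 0.04, nPerGroup = 30L, seed = 11L) {
  generateCohort(syntheticConfig(nPerGroup = nPerGroup, baseExtinction = u,
                                 sscCoupling = 0, noiseSd = 0, seed = seed))
}

# Reference spectrum/diameter from the generator's own law at the medium
# group's mean diameter.
trueReference <- function(cohort) {
  med <- subsetGroup(cohort$set, "75-85")
  dR <- mean(diameters(med))
  list(spectrum = trueSpectrumAt(cohort$truth, dR), dR = dR)
}

# Naive reimplementation of the greedy max-min rule, used as the
# Kennard-Stone oracle (plain loops, recomputing distances on demand).
bruteForceKS <- function(x, nCal) {
  n <- nrow(x)
  d2 <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))
  best <- c(1L, 2L); bestD <- -Inf
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    dij <- d2(i, j)
    if (dij > bestD) { bestD <- dij; best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < nCal) {
    cand <- setdiff(seq_len(n), sel)
    score <- vapply(cand, function(i) min(vapply(sel, d2, 0, i = i)), 0)
    sel <- c(sel, cand[which.max(score)])
  }
  sort(sel)
}
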