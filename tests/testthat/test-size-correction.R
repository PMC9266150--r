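test_that("single-sample extinction quotient matches the closed form", {
  s <- SpectraSet("a", 700, matrix(100), diameters = 70, ssc = 13)
  ref <- Spectrum(700, 100 * exp(-0.5))
  m <- estimateExtinction(s, ref, referenceDiameter = 80)
  expect_equal(extinction(m), 0.05, tolerance = 1e-12)
  expect_identical(m@nUsed, 1L)
})

test_that("equal and opposite log-ratio quotients average to zero extinction", {
  # both samples sit 0.5 log-units below the reference, on opposite sides of
  # d_R: quotients +0.05 and -0.05 cancel
  s <- SpectraSet(c("a", "b"), 700, matrix(rep(100 * exp(-0.5), 2), 2),
                  diameters = c(70, 90), ssc = c(12, 14))
  ref <- Spectrum(700, 100)
  m <- estimateExtinction(s, ref, referenceDiameter = 80)
  expect_equal(extinction(m), 0, tolerance = 1e-12)
})

test_that("noiseless constant-extinction cohort is recovered exactly", {
  ch <- noiselessCohort(u = 0.04)
  ref <- trueReference(ch)
  m <- estimateExtinction(ch$set, ref$spectrum, ref$dR)
  expect_lt(max(abs(extinction(m) - 0.04)), 1e-10)
  expect_identical(m@nUsed + length(m@excludedIds), nSamples(ch$set))
  # every excluded sample really sits within minGap of the reference
  gaps <- abs(ref$dR - diameters(ch$set))
  expect_setequal(m@excludedIds, sampleIds(ch$set)[gaps < 1])
})

test_that("estimation guards its domain", {
  s <- SpectraSet("a", 700, matrix(100), 80, 13)
  ref <- Spectrum(700, 90)
  expect_error(estimateExtinction(s, ref, referenceDiameter = 80.5),
               "diameter gap")
  neg <- SpectraSet("a", 700, matrix(-1), 70, 13)
  expect_error(estimateExtinction(neg, ref, referenceDiameter = 80),
               "non-positive")
  badRef <- Spectrum(700, 0)
  s2 <- SpectraSet("a", 700, matrix(100), 70, 13)
  expect_error(estimateExtinction(s2, badRef, referenceDiameter = 80),
               "reference")
})

test_that("applyCorrection matches the closed form and its identity cases", {
  s <- SpectraSet(c("a", "b"), 700, matrix(c(100, 50), 2),
                  diameters = c(70, 80), ssc = c(12, 13))
  ref <- Spectrum(700, 60)
  m <- new("CorrectionModel", referenceSpectrum = ref, referenceDiameter = 80,
           extinction = 0.05, nUsed = 1L, excludedIds = character(0))
  out <- applyCorrection(s, m)
  expect_equal(intensities(out)[1, 1], 100 * exp(-0.5), tolerance = 1e-12)
  # d_i == d_R: bit-identical
  expect_identical(intensities(out)[2, 1], 50)
  # u_e == 0: bit-identical for every sample
  m0 <- new("CorrectionModel", referenceSpectrum = ref, referenceDiameter = 80,
            extinction = 0, nUsed = 1L, excludedIds = character(0))
  expect_identical(intensities(applyCorrection(s, m0)), intensities(s))
  # metadata untouched
  expect_identical(diameters(out), diameters(s))
  expect_identical(ssc(out), ssc(s))
  # misaligned grid
  s2 <- SpectraSet("a", 710, matrix(100), 70, 12)
  expect_error(applyCorrection(s2, m), "aligned")
})

test_that("correction collapses an exact Beer-Lambert cohort onto the reference", {
  ch <- noiselessCohort(u = 0.04)
  ref <- trueReference(ch)
  m <- estimateExtinction(ch$set, ref$spectrum, ref$dR)
  out <- applyCorrection(ch$set, m)
  refI <- spectrumValues(ref$spectrum)
  rel <- abs(sweep(intensities(out), 2, refI) /
             matrix(refI, nSamples(out), length(refI), byrow = TRUE))
  expect_lt(max(rel), 1e-9)
})

test_that("positive extinction moves small fruit down and large fruit up", {
  ch <- noiselessCohort(u = 0.05, seed = 13)
  ref <- trueReference(ch)
  m <- estimateExtinction(ch$set, ref$spectrum, ref$dR)
  out <- applyCorrection(ch$set, m)
  smaller <- diameters(ch$set) < ref$dR
  larger <- diameters(ch$set) > ref$dR
  expect_true(all(intensities(out)[smaller, ] < intensities(ch$set)[smaller, ]))
  expect_true(all(intensities(out)[larger, ] > intensities(ch$set)[larger, ]))
})

test_that("correction shrinks the small-vs-large group gap on realistic cohorts", {
  ch <- generateCohort(syntheticConfig(nPerGroup = 60, seed = 17))
  m <- estimateExtinction(ch$set, referenceGroup = "75-85")
  out <- applyCorrection(ch$set, m)
  gapBefore <- mean(abs(spectrumValues(meanSpectrum(subsetGroup(ch$set, "65-75"))) -
                        spectrumValues(meanSpectrum(subsetGroup(ch$set, "85-95")))))
  gapAfter <- mean(abs(spectrumValues(meanSpectrum(subsetGroup(out, "65-75"))) -
                       spectrumValues(meanSpectrum(subsetGroup(out, "85-95")))))
  expect_lt(gapAfter, gapBefore)
})

test_that("diameter-attenuation diagnostic recovers slope, intercept and r-squared", {
  d <- seq(60, 100, by = 5)
  I <- 1000 * exp(-0.03 * d)
  s <- SpectraSet(sprintf("s%d", seq_along(d)), c(700, 750),
                  cbind(I, I * 2), d, rep(13, length(d)))
  fit <- diameterAttenuationFit(s, 701)
  expect_equal(fit$slope, -0.03, tolerance = 1e-10)
  expect_equal(fit$intercept, log(1000), tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_identical(fit$wavelength, 700)

  expect_error(diameterAttenuationFit(s[1:2, ], 700), "3 samples")
  flat <- SpectraSet(c("a", "b", "c"), 700, matrix(c(1, 2, 3), 3),
                     rep(80, 3), c(12, 13, 14))
  expect_error(diameterAttenuationFit(flat, 700), "diameter")
})

test_that("attenuation slope on a noisy cohort sits within 3 SE of the truth", {
  cfg <- syntheticConfig(nPerGroup = 60, sscCoupling = 0, seed = 19)
  ch <- generateCohort(cfg)
  wl0 <- 700
  fit <- diameterAttenuationFit(ch$set, wl0)
  j <- which(cfg$wavelengths == wl0)
  lmfit <- lm(log(intensities(ch$set)[, j]) ~ diameters(ch$set))
  se <- summary(lmfit)$coefficients[2, 2]
  expect_lt(abs(fit$slope - (-cfg$baseExtinction[j])), 3 * se)
})

test_that("a correction model survives JSON serialization", {
  ch <- noiselessCohort(nPerGroup = 10, seed = 23)
  m <- estimateExtinction(ch$set, referenceGroup = "75-85")
  path <- withr::local_tempfile(fileext = ".json")
  writeCorrectionModel(m, path)
  m2 <- readCorrectionModel(path)
  expect_equal(extinction(m2), extinction(m), tolerance = 1e-12)
  expect_equal(referenceDiameter(m2), referenceDiameter(m), tolerance = 1e-12)
  expect_equal(spectrumValues(referenceSpectrum(m2)),
               spectrumValues(referenceSpectrum(m)), tolerance = 1e-12)
  expect_identical(m2@nUsed, m@nUsed)
  # the restored model corrects identically
  expect_equal(intensities(applyCorrection(ch$set, m2)),
               intensities(applyCorrection(ch$set, m)), tolerance = 1e-12)
})
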