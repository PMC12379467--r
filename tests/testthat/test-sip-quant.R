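mixedEnvelope <- function(pep, ria1, ria2, share2) {
  comp <- peptideComposition(pep)
  a <- envelopeProbs(isotopeEnvelope(comp, "C", ria = ria1))
  b <- envelopeProbs(isotopeEnvelope(comp, "C", ria = ria2))
  k <- max(length(a), length(b))
  length(a) <- k; length(b) <- k
  a[is.na(a)] <- 0; b[is.na(b)] <- 0
  (1 - share2) * a + share2 * b
}

test_that("noiseless envelopes are recovered within the grid step", {
  pep <- "ELVISLIVESKAAAK"
  for (ria in c(1.07, 5, 10, 25, 50, 75, 95.7, 99)) {
    p <- envelopeProbs(isotopeEnvelope(peptideComposition(pep), "C",
                                       ria = ria))
    w <- mergeWeights(detectWeights(pep, p))
    expect_equal(nrow(w), 1L)
    expect_lt(abs(w$ria - ria), 0.5)
    expect_equal(w$share, 1)
  }
})

test_that("natural-abundance features self-match with share one", {
  p <- envelopeProbs(isotopeEnvelope(peptideComposition("PEPTIDER"), "C"))
  w <- mergeWeights(detectWeights("PEPTIDER", p))
  expect_equal(nrow(w), 1L)
  expect_lt(abs(w$ria - 1.07), 0.5)
  expect_false(classifyLabeled(w))
})

test_that("1:1 natural/labeled mixtures resolve into two equal weights", {
  mix <- mixedEnvelope("ELVISLIVESKAAAK", 1.07, 10.99, 0.5)
  w <- mergeWeights(detectWeights("ELVISLIVESKAAAK", mix))
  expect_equal(nrow(w), 2L)
  expect_equal(w$share, c(0.5, 0.5), tolerance = 0.05)
  expect_true(classifyLabeled(w))
  lr <- labelingRatio(w)
  expect_equal(lr$lrLabeled, 0.5, tolerance = 0.05)
})

test_that("noisy recovery stays within one atom percent in the median", {
  set.seed(21)
  pep <- "ELVISLIVESKAAAK"
  errs <- c()
  for (ria in c(1.07, 5, 10, 25, 50, 75, 95.7, 99)) {
    p <- envelopeProbs(isotopeEnvelope(peptideComposition(pep), "C",
                                       ria = ria))
    for (rep in 1:3) {
      noisy <- p * exp(rnorm(length(p), 0, 0.02))
      w <- mergeWeights(detectWeights(pep, noisy))
      top <- w[which.max(w$share), ]
      errs <- c(errs, abs(top$ria - ria))
    }
  }
  expect_lt(median(errs), 1)
})

test_that("estimated RIA agrees with the centroid-shift oracle", {
  pep <- "PEPTIDERPEPTIDER"
  comp <- peptideComposition(pep)
  nC <- comp[["C"]]
  for (ria in c(10, 40, 80)) {
    env <- isotopeEnvelope(comp, "C", ria = ria)
    w <- mergeWeights(detectWeights(pep, envelopeProbs(env)))
    oracle <- 100 * envelopeCentroid(env) / nC
    expect_lt(abs(w$ria - oracle), 0.5 + 0.2)  # grid step + centroid bias
  }
})

test_that("weight merging uses the isotope-specific window", {
  w <- data.frame(ria = c(48, 51), share = c(0.25, 0.75),
                  correlation = c(0.9, 0.95))
  m <- mergeWeights(w, "C")                       # window +-5.0
  expect_equal(nrow(m), 1L)
  expect_equal(m$ria, 0.25 * 48 + 0.75 * 51)      # share-weighted mean
  expect_equal(m$share, 1)
  expect_equal(m$correlation, 0.95)

  w2 <- data.frame(ria = c(1.07, 50), share = c(0.5, 0.5),
                   correlation = c(0.9, 0.9))
  expect_equal(nrow(mergeWeights(w2, "C")), 2L)   # gap > window

  one <- data.frame(ria = 10, share = 1, correlation = 0.9)
  expect_identical(mergeWeights(one, "C"), one)

  wH <- data.frame(ria = c(1, 3), share = c(0.5, 0.5),
                   correlation = c(0.9, 0.9))
  expect_equal(nrow(mergeWeights(wH, "H")), 2L)   # 2H window is +-1.5
})

test_that("labeled classification keys on the natural window", {
  nat <- data.frame(ria = 1.07, share = 1, correlation = 1)
  expect_false(classifyLabeled(nat, "C"))
  two <- data.frame(ria = c(1.07, 10.9), share = c(0.5, 0.5),
                    correlation = c(1, 1))
  expect_true(classifyLabeled(two, "C"))
  high <- data.frame(ria = 95.7, share = 1, correlation = 1)
  expect_true(classifyLabeled(high, "C"))
  expect_false(classifyLabeled(nat[0, ], "C"))
})

test_that("labeling ratios are the shares of non-natural weights", {
  two <- data.frame(ria = c(1.07, 10.99), share = c(0.5, 0.5),
                    correlation = c(1, 1))
  expect_equal(labelingRatio(two, "C")$lrLabeled, 0.5)
  nat <- data.frame(ria = 1.07, share = 1, correlation = 1)
  expect_equal(labelingRatio(nat, "C")$lrLabeled, 0)
  lab <- data.frame(ria = 50, share = 1, correlation = 1)
  expect_equal(labelingRatio(lab, "C")$lrLabeled, 1)
})

test_that("degenerate features are reported unassigned", {
  expect_equal(nrow(detectWeights("PEPTIDER", c(1, 0))), 0L)     # < 3 peaks
  expect_equal(nrow(detectWeights("PEPTIDER", c(1, 0, 0, 0))), 0L)
  expect_equal(nrow(detectWeights("PEPTIDER", c(0, 0, 0))), 0L)
  expect_no_error(detectWeights("GGGG", c(1, 1, 1), labelElement = "O"))
})

test_that("peptide summaries aggregate labeling across samples", {
  res <- data.frame(
    peptide = c("A", "A", "A", "B", "B"),
    sample = c("s1", "s2", "s3", "s1", "s1"),
    ria = c(94, 96, 97, 50, 1.07),
    share = c(1, 1, 1, 0.6, 0.4),
    correlation = 0.9,
    labeled = c(TRUE, TRUE, TRUE, TRUE, TRUE),
    lrLabeled = 1)
  s <- summarizePeptides(res, "C", minSamples = 2)
  a <- s[s$peptide == "A", ]
  expect_true(a$labeled)
  expect_equal(a$ria, mean(c(94, 96, 97)), tolerance = 1e-9)
  b <- s[s$peptide == "B", ]
  expect_false(b$labeled)            # labeled in one sample only
})

test_that("raw peaks align to charge-scaled shift bins", {
  monoMz <- 500.25
  mz <- monoMz + c(0, 1, 2, 5) * 1.00335 / 2
  out <- alignPeaks(mz, c(10, 8, 3, 1), monoMz, charge = 2)
  expect_equal(out[c(1, 2, 3, 6)], c(10, 8, 3, 1))
  expect_equal(out[c(4, 5)], c(0, 0))
  ## a peak far off every bin is dropped
  out2 <- alignPeaks(c(monoMz + 0.2), c(5), monoMz, charge = 2)
  expect_equal(length(out2), 0L)
})
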