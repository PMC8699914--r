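test_that("discordance is zero for identical panels and counts strata", {
  set.seed(1)
  cl <- matrix(sample(c(0L, 1L), 200, TRUE), 20, 10)
  rep0 <- discordanceReport(cl, cl)
  expect_equal(rep0$overall, 0)
  expect_equal(rep0$imputationAccuracy, 1)
  # 1 discordant cell among 200 compared
  cl2 <- cl
  cl2[3, 4] <- 1L - cl2[3, 4]
  expect_equal(discordanceReport(cl2, cl)$overall, 1 / 200)
})

test_that("stratified rates match hand enumeration on a 4x4 example", {
  imput <- matrix(c(0L, 1L, 1L, 0L,
                    1L, 1L, 0L, 0L,
                    0L, 0L, 1L, 1L,
                    1L, 0L, NA, 0L), 4, 4, byrow = TRUE)
  comp <- matrix(c(0L, 1L, 0L, 0L,
                   1L, 0L, 0L, NA,
                   0L, 0L, 1L, 1L,
                   1L, 1L, 1L, 0L), 4, 4, byrow = TRUE)
  prov <- matrix(c("RAW_CALLED", "RAW_CALLED", "HB_CALLED", "COMPLETED",
                   "RAW_CALLED", "HB_CALLED", "HB_CALLED", "COMPLETED",
                   "RAW_CALLED", "RAW_CALLED", "HB_CALLED", "COMPLETED",
                   "MISSING", "RAW_CALLED", "MISSING", "COMPLETED"),
                 4, 4, byrow = TRUE)
  rep <- discordanceReport(imput, comp, prov)
  # hand count: compared cells exclude (2,4) NA-comp and (4,3) NA-imputed
  # discordant: (1,3) HB, (2,2) HB, (4,2) RAW
  expect_equal(rep$nCells$overall, 14L)
  expect_equal(rep$overall, 3 / 14)
  expect_equal(unname(rep$byClass["RAW_CALLED"]), 1 / 6)
  expect_equal(unname(rep$byClass["HB_CALLED"]), 2 / 4)
  expect_equal(unname(rep$byClass["COMPLETED"]), 0 / 3)
  # allele strata keyed on the comparison call
  expect_equal(unname(rep$byAllele["REF"]), 2 / 8)
  expect_equal(unname(rep$byAllele["ALT"]), 1 / 6)
  # stratum counts recombine to the overall count
  expect_equal(sum(rep$nCells$byClass) + 1L, rep$nCells$overall)  # 1 MISSING-prov cell compared
  # empty stratum is NA, not zero
  rep2 <- discordanceReport(imput, comp,
                            matrix("RAW_CALLED", 4, 4))
  expect_true(is.na(rep2$byClass["COMPLETED"]))
})

test_that("imputation accuracy is a per-marker mean correlation", {
  set.seed(2)
  cl <- matrix(sample(c(0L, 1L), 300, TRUE), 30, 10)
  expect_equal(imputationAccuracy(cl, cl), 1)
  expect_equal(imputationAccuracy(1L - cl, cl), -1)
  # a rare variant imputed to the major allele contributes 0 and drags the
  # mean down disproportionately
  comp <- matrix(0L, 2, 10)
  comp[1, 1] <- 1L          # rare variant, one carrier
  comp[2, 1:5] <- 1L        # common variant
  imput <- comp
  imput[1, 1] <- 0L         # rare carrier imputed to major allele
  expect_equal(imputationAccuracy(imput, comp), mean(c(0, 1)))
  expect_error(imputationAccuracy(matrix(0L, 2, 3), matrix(0L, 2, 3)),
               "polymorphic")
})

test_that("allele-frequency spectra match a brute-force tally", {
  set.seed(3)
  # 7 haplotypes: frequencies are multiples of 1/7 and never coincide with
  # the 0.1-step bin edges, so the oracle is unambiguous
  cl <- matrix(sample(c(0L, 1L), 350, TRUE, prob = c(0.7, 0.3)), 50, 7)
  edges <- seq(0, 1, by = 0.1)
  sp <- afSpectrum(cl, edges)
  freq <- rowMeans(cl == 1L)
  brute <- vapply(seq_len(10), function(b)
    sum(freq >= edges[b] & (freq < edges[b + 1] | (b == 10 & freq <= 1))),
    integer(1))
  expect_equal(sp$counts, brute)
  expect_equal(sp$nonFixed, sum(freq > 0 & freq < 1))
  fixed <- matrix(0L, 5, 4)
  spf <- afSpectrum(fixed, edges)
  expect_equal(spf$counts[1], 5L)
  expect_equal(spf$nonFixed, 0L)
  # 2 haplotypes, calls (REF, ALT) -> frequency 0.5
  expect_equal(afSpectrum(matrix(c(0L, 1L), 1, 2))$freq, 0.5)
})

test_that("CNV detection metrics follow the confusion-matrix definitions", {
  pred <- matrix(FALSE, 2, 5); true <- matrix(FALSE, 2, 5)
  true[1, 1:4] <- TRUE
  pred[1, 2:4] <- TRUE; pred[2, 1:2] <- TRUE
  m <- cnvMetrics(pred, true)
  expect_equal(m$recall, 3 / 4)
  expect_equal(m$falsePositiveShare, 2 / 5)
  same <- cnvMetrics(true, true)
  expect_equal(same$recall, 1)
  expect_equal(same$falsePositiveShare, 0)
  all1 <- matrix(TRUE, 2, 5)
  m2 <- cnvMetrics(all1, true)
  expect_equal(m2$recall, 1)
  expect_equal(m2$falsePositiveShare, 1 - 4 / 10)
  expect_true(is.na(cnvMetrics(pred, matrix(FALSE, 2, 5))$recall))
  expect_true(is.na(cnvMetrics(matrix(FALSE, 2, 5), true)$falsePositiveShare))
})

test_that("the marker scan flags perfect association and is calibrated", {
  set.seed(4)
  n <- 80
  cl <- matrix(sample(c(0L, 1L), 50 * n, TRUE), 50, n)
  cl[7, ] <- sample(c(0L, 1L), n, TRUE)
  y <- as.numeric(cl[7, ])
  p <- singleMarkerScan(cl, y)
  expect_equal(which.min(p), 7L)
  expect_lt(p[7], 1e-20)
  # monomorphic markers get p = 1
  cl[9, ] <- 0L
  expect_equal(singleMarkerScan(cl, y)[9], 1)
  # null p-values are uniform: permuted phenotype
  set.seed(5)
  cl2 <- matrix(sample(c(0L, 1L), 1000 * 100, TRUE), 1000, 100)
  p2 <- singleMarkerScan(cl2, rnorm(100))
  expect_lt(abs(mean(p2 < 0.05) - 0.05), 0.025)
  expect_warning(pz <- singleMarkerScan(cl2, rep(1, 100)), "zero variance")
  expect_true(all(pz == 1))
  # agreement with lm() on a handful of markers
  y3 <- rnorm(n)
  p3 <- singleMarkerScan(cl, y3)
  for (m in c(1, 25, 50)) {
    pl <- summary(lm(y3 ~ cl[m, ]))$coefficients[2, 4]
    expect_equal(p3[m], pl, tolerance = 1e-10)
  }
})

test_that("region chaining and QTL classification match the worked case", {
  pos <- c(1.0e6, 1.8e6, 5.0e6)
  p <- c(1e-8, 1e-8, 1e-8)
  res <- gwasRegionClassification(p, pos, qtlPos = 2.5e6,
                                  params = gwasEvalParams(pThreshold = 1e-5))
  expect_equal(res$nRegions, 2L)
  expect_equal(res$regions$startBp, c(1.0e6, 5.0e6))
  expect_equal(res$regions$endBp, c(1.8e6, 5.0e6))
  expect_equal(res$regions$truePositive, c(TRUE, FALSE))
  expect_equal(res$tpShare, 0.5)
  expect_equal(unname(res$qtlPeakDistance), 1.5e6)  # peak at 1.0 Mb (first min)
  # no significant markers
  none <- gwasRegionClassification(rep(0.5, 3), pos, qtlPos = 2.5e6)
  expect_equal(none$nRegions, 0L)
  expect_true(is.na(none$tpShare))
  # every marker significant on one chromosome -> one region
  dense <- gwasRegionClassification(rep(1e-9, 20), seq(1e5, 2e6, by = 1e5),
                                    qtlPos = 1e6,
                                    params = gwasEvalParams(pThreshold = 1e-5))
  expect_equal(dense$nRegions, 1L)
  expect_equal(unname(dense$qtlPeakDistance), abs(dense$regions$peakBp - 1e6))
  # QTL inside the interval has distance 0 for classification
  expect_true(dense$regions$truePositive)
})

test_that("region chaining equals a brute-force oracle on random scans", {
  for (seed in 1:4) {
    set.seed(seed)
    nM <- sample(100:500, 1)
    pos <- sort(sample.int(5e7, nM))
    p <- runif(nM)^3
    thr <- 0.01
    res <- gwasRegionClassification(p, pos, qtlPos = numeric(0),
                                    params = gwasEvalParams(
                                      pThreshold = thr))
    want <- bruteRegions(p, pos, thr, 1e6)
    if (nrow(want) == 0) {
      expect_equal(res$nRegions, 0L)
    } else {
      expect_equal(res$regions$startBp, want$startBp)
      expect_equal(res$regions$endBp, want$endBp)
    }
  }
})
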