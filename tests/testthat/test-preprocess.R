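spotRow <- function(ch1, ch2, bg1 = c(0, 0, 0), bg2 = c(0, 0, 0),
                    id = "p1") {
  tab <- data.frame(probe_id = id)
  for (r in 1:3) {
    tab[[sprintf("rep%d_ch1", r)]] <- ch1[r]
    tab[[sprintf("rep%d_ch2", r)]] <- ch2[r]
    tab[[sprintf("rep%d_bg1", r)]] <- bg1[r]
    tab[[sprintf("rep%d_bg2", r)]] <- bg2[r]
  }
  tab
}

test_that("spot summarization averages triplicates minus backgrounds", {
  net <- summarizeSpots(spotRow(c(100, 100, 100), c(100, 100, 100),
                                bg1 = c(10, 10, 10)))
  expect_equal(net$net_ch1, 90)
  expect_equal(net$net_ch2, 100)

  net <- summarizeSpots(spotRow(c(90, 100, 110), c(50, 50, 50),
                                bg1 = c(20, 10, 30)))
  expect_equal(net$net_ch1, 80) # 100 - 20
  # intensity equal to background cancels to zero
  net <- summarizeSpots(spotRow(c(5, 5, 5), c(9, 9, 9), bg1 = c(5, 5, 5),
                                bg2 = c(9, 9, 9)))
  expect_equal(net$net_ch1, 0)
  expect_equal(net$net_ch2, 0)

  bad <- spotRow(c(10, 10, 10), c(10, 10, 10))
  bad$rep3_ch1 <- NULL
  expect_error(summarizeSpots(bad), "rep3_ch1")
})

test_that("detectability needs both channels strictly above the threshold", {
  expect_true(flagDetectable(90, 80))
  expect_false(flagDetectable(-5, 80))
  expect_false(flagDetectable(1, 1, minNet = 1))
  expect_equal(flagDetectable(c(2, 0.5), c(2, 2), minNet = 1),
               c(TRUE, FALSE))
})

test_that("within-array normalization centers by an iterative trimmed mean", {
  sym <- c(-2, -1, 0, 1, 2)
  expect_equal(as.numeric(withinArrayNormalize(sym)), sym)
  const <- rep(3.2, 10)
  expect_equal(as.numeric(withinArrayNormalize(const)), rep(0, 10))

  # one wild outlier among a N(0.5, 0.1) bulk is excluded from the center
  set.seed(4)
  bulk <- rnorm(100, 0.5, 0.1)
  x <- c(bulk, 50)
  out <- withinArrayNormalize(x)
  expect_equal(as.numeric(out), trimCenterOracle(x), tolerance = 1e-12)
  expect_lt(abs(mean(out[1:100])), 0.05)
  expect_gt(out[101], 45)

  # shift invariance: adding a constant changes nothing in the output
  shifted <- withinArrayNormalize(x + 7)
  expect_equal(as.numeric(shifted), as.numeric(out), tolerance = 1e-12)

  # the trimmed mean of the output is 0
  expect_lt(abs(attr(withinArrayNormalize(as.numeric(out)), "trimmedMean")),
            1e-12)

  # property: matches the oracle on random contaminated vectors
  for (i in 1:20) {
    set.seed(100 + i)
    v <- c(rnorm(50, runif(1, -1, 1), 0.2), rnorm(3, 0, 10))
    expect_equal(as.numeric(withinArrayNormalize(v)), trimCenterOracle(v),
                 tolerance = 1e-12)
  }

  expect_error(withinArrayNormalize(c(1, 2)), "3 finite")
})

test_that("quantile normalization equalizes column distributions", {
  m <- cbind(a = c(1, 3), b = c(2, 4))
  qn <- quantileNormalize(m)
  expect_equal(unname(qn[, "a"]), c(1.5, 3.5))
  expect_equal(unname(qn[, "b"]), c(1.5, 3.5))

  ident <- cbind(x = c(1, 5, 9), y = c(1, 5, 9))
  expect_equal(quantileNormalize(ident), ident)

  set.seed(8)
  r <- matrix(rnorm(60), 20, 3)
  qr <- quantileNormalize(r)
  # identical multisets across columns
  expect_equal(sort(qr[, 1]), sort(qr[, 2]))
  expect_equal(sort(qr[, 2]), sort(qr[, 3]))
  # idempotent
  expect_equal(quantileNormalize(qr), qr, tolerance = 1e-12)
  # order preserved within a column
  expect_equal(order(r[, 1]), order(qr[, 1]))
  # single column unchanged
  one <- matrix(rnorm(5), ncol = 1)
  expect_identical(quantileNormalize(one), one)
})

test_that("quantile normalization agrees with limma on complete matrices", {
  set.seed(12)
  m <- matrix(rnorm(200), 50, 4)
  expect_equal(unname(quantileNormalize(m)),
               unname(limma::normalizeQuantiles(m)), tolerance = 1e-12)
})

test_that("quantile normalization under missingness stays per-column monotone", {
  set.seed(13)
  m <- matrix(rnorm(70), 10, 7)
  m[sample(70, 12)] <- NA
  qn <- quantileNormalize(m)
  expect_identical(is.na(qn), is.na(m))
  for (j in 1:7) {
    obs <- which(!is.na(m[, j]))
    expect_equal(order(m[obs, j]), order(qn[obs, j]))
  }
  expect_equal(quantileNormalize(qn), qn, tolerance = 1e-12)
})

test_that("presence filter keeps rows observed in enough columns", {
  m <- matrix(1, nrow = 3, ncol = 7,
              dimnames = list(c("keep4", "drop3", "full"), NULL))
  m["keep4", 5:7] <- NA
  m["drop3", 4:7] <- NA
  f <- presenceFilter(m, minPresent = 4)
  expect_identical(rownames(f), c("keep4", "full"))

  full <- matrix(rnorm(21), 3, 7)
  expect_equal(presenceFilter(full), full)

  # brute-force count over random missingness patterns
  set.seed(14)
  for (i in 1:10) {
    mm <- matrix(rnorm(7 * 30), 30, 7)
    mm[runif(210) < 0.4] <- NA
    kept <- nrow(presenceFilter(mm, 4))
    brute <- sum(apply(mm, 1, function(r) sum(!is.na(r)) >= 4))
    expect_equal(kept, brute)
  }
  expect_error(presenceFilter(m, minPresent = 8), "exceeds")
})

test_that("reference-design harmonization is an exact subtraction", {
  d <- generateDesign(tinyParams(nPairs = 2))
  p <- designPairs(d)
  genes <- c("g1", "g2")
  caseM <- matrix(c(1.0, 0.585, 0.2, 0.0), 2, 2,
                  dimnames = list(genes, p$case_id))
  ctrlM <- matrix(c(0.4, 0, 0.2, NA), 2, 2,
                  dimnames = list(genes, p$control_id))
  h <- harmonizeReferenceDesign(caseM, ctrlM, d)
  expect_equal(unname(h["g1", 1]), 0.6)
  expect_equal(unname(h["g2", 1]), 0.585)
  expect_equal(unname(h["g1", 2]), 0) # case = control
  expect_true(is.na(h["g2", 2])) # missing propagates
  expect_identical(colnames(h), pairIds(d))

  # zero-noise simulated channels reconstruct planted ratios exactly
  pp <- tinyParams(noiseSd = 0, naFraction = 0)
  dd <- generateDesign(pp)
  map <- generateTargetMap(pp)
  truth <- generateTruth(pp, map)
  planted <- generateMrnaRatioMatrix(dd, truth, map, pp)
  set.seed(5)
  ctrlVsRef <- matrix(rnorm(nrow(planted) * nPairs(dd)), nrow(planted),
                      dimnames = list(rownames(planted),
                                      designPairs(dd)$control_id))
  caseVsRef <- ctrlVsRef + planted
  colnames(caseVsRef) <- designPairs(dd)$case_id
  h2 <- harmonizeReferenceDesign(caseVsRef, ctrlVsRef, dd)
  expect_equal(unname(h2), unname(planted), tolerance = 1e-12)

  badDesign <- pairedDesign(data.frame(case_id = "missing",
                                       control_id = p$control_id[1],
                                       family_id = "F1"))
  expect_error(harmonizeReferenceDesign(caseM, ctrlM, badDesign), "missing")
})

test_that("the miRNA preprocessing chain recovers noise-free planted effects", {
  p <- tinyParams(noiseSd = 0, triplicateCv = 0, backgroundLevel = 0)
  d <- generateDesign(p)
  truth <- generateTruth(p, generateTargetMap(p))
  spots <- generateMirnaSpotTables(d, truth, p)
  mat <- preprocessMirnaArrays(spots, normalizeWithin = FALSE,
                               quantileAcross = FALSE)
  eff <- deMirnaEffects(truth)
  for (m in names(eff)) {
    expect_equal(unname(mat[m, designPairs(d)$case_id]),
                 rep(unname(eff[m]), 5), tolerance = 1e-12)
    expect_equal(unname(mat[m, designPairs(d)$control_id]), rep(0, 5),
                 tolerance = 1e-12)
  }
})
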