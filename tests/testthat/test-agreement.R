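test_that("Dice handles the canonical exact cases", {
  m <- array(0L, c(1, 4, 4)); m[1, 1:2, 1] <- 1L; m[1, 1, 2] <- 1L  # |A| = 3
  n <- array(0L, c(1, 4, 4)); n[1, 1:2, 1] <- 1L; n[1, 4, 4] <- 1L  # |B| = 3, overlap 2
  expect_equal(diceCoef(m, m), 1.0)
  expect_equal(diceCoef(m, n), 2 * 2 / (3 + 3), tolerance = 1e-15)
  disj <- array(0L, c(1, 4, 4)); disj[1, 4, 4] <- 1L
  expect_equal(diceCoef(m, disj), 0.0)
  # vacuous agreement of two empty masks
  expect_equal(diceCoef(array(0L, c(1, 2, 2)), array(0L, c(1, 2, 2))), 1.0)
  expect_error(diceCoef(array(0L, c(1, 2, 2)), array(0L, c(1, 3, 3))),
               "shapes")
})

test_that("Dice matches exact rational arithmetic on integer masks", {
  set.seed(31)
  for (i in 1:100) {
    a <- matrix(rbinom(400, 1, runif(1, 0.05, 0.5)), 20)
    b <- matrix(rbinom(400, 1, runif(1, 0.05, 0.5)), 20)
    d <- diceCoef(a, b)
    expect_equal(d, oracleDice(a, b), tolerance = 1e-8)
    # 2|AnB| and |A|+|B| are integers: d * (|A|+|B|) must be an even integer
    tot <- sum(a) + sum(b)
    if (tot > 0) expect_equal(d * tot, round(d * tot), tolerance = 1e-9)
  }
})

test_that("ICC matches the brute-force two-way ANOVA oracle", {
  set.seed(37)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    x <- rnorm(n); y <- x + rnorm(n, sd = runif(1, 0.1, 2)) + runif(1, -1, 1)
    expect_equal(iccAgreement(x, y)$icc, oracleICC21(x, y), tolerance = 1e-8)
  }
})

test_that("ICC reproduces independently computed reference values", {
  # toy table frozen against an external two-way mixed-model implementation
  a <- c(0.62, 0.45, 0.71, 0.30, 0.55, 0.48)
  b <- c(0.58, 0.49, 0.68, 0.35, 0.60, 0.44)
  icc <- iccAgreement(a, b)
  expect_equal(icc$icc, 0.948154, tolerance = 1e-5)
  expect_equal(icc$lo, 0.68, tolerance = 0.005)
  expect_equal(icc$hi, 0.99, tolerance = 0.005)
  expect_equal(iccAgreement(a, b, type = "consistency")$icc, 0.939234,
               tolerance = 1e-5)
})

test_that("ICC limiting and degenerate behaviour is correct", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(iccAgreement(x, x)$icc, 1.0)
  # zero total variance: undefined, not 1
  expect_true(is.na(iccAgreement(rep(2, 6), rep(2, 6))$icc))
  # absolute agreement penalizes a constant offset; consistency does not
  shifted <- iccAgreement(x, x + 1)
  expect_lt(shifted$icc, 1.0)
  expect_equal(iccAgreement(x, x + 1, type = "consistency")$icc, 1.0)
  # rater exchange symmetry
  set.seed(5)
  y <- x + rnorm(6)
  expect_equal(iccAgreement(x, y)$icc, iccAgreement(y, x)$icc,
               tolerance = 1e-12)
})

test_that("Pearson r and p match the textbook formula", {
  x <- 1:10
  expect_equal(pearsonCor(x, 2 * x + 1)$r, 1.0)
  set.seed(41)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    a <- rnorm(n); b <- rnorm(n) + 0.5 * a
    got <- pearsonCor(a, b); want <- oraclePearson(a, b)
    expect_equal(got$r, want$r, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
  # affine invariance with positive slope
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(pearsonCor(3 * a + 2, b)$r, pearsonCor(a, b)$r,
               tolerance = 1e-12)
  expect_true(is.na(pearsonCor(rep(1, 10), rnorm(10))$r))
})

test_that("Bland-Altman limits match hand computation and the oracle", {
  ba <- blandAltman(c(1, 2, 3), c(1.2, 1.8, 3.1))
  expect_equal(ba$meanDiff, -1 / 30, tolerance = 1e-9)
  expect_equal(ba$loa, c(-0.441340, 0.374673), tolerance = 1e-5)
  ident <- blandAltman(1:5, 1:5)
  expect_equal(ident$loa, c(0, 0))
  set.seed(43)
  for (i in 1:100) {
    n <- sample(3:30, 1)
    a <- rnorm(n); b <- rnorm(n)
    got <- blandAltman(a, b); want <- oracleBlandAltman(a, b)
    expect_equal(got$meanDiff, unname(want["meanDiff"]), tolerance = 1e-8)
    expect_equal(got$loa, unname(want[c("lo", "hi")]), tolerance = 1e-8)
  }
  # antisymmetry under source swap
  a <- rnorm(8); b <- rnorm(8)
  f <- blandAltman(a, b); r <- blandAltman(b, a)
  expect_equal(f$meanDiff, -r$meanDiff, tolerance = 1e-12)
  expect_equal(f$loa, -rev(r$loa), tolerance = 1e-12)
})

test_that("Dice-area correlation handles degenerate and permuted input", {
  expect_true(is.na(diceAreaCorrelation(rep(0.7, 8), rnorm(8))$r))
  set.seed(47)
  d <- runif(12); a <- runif(12)
  perm <- sample(12)
  expect_equal(diceAreaCorrelation(d, a)$r,
               diceAreaCorrelation(d[perm], a[perm])$r, tolerance = 1e-12)
})

test_that("a self-comparison report is all-perfect with full coverage", {
  set.seed(53)
  vols <- generateTrainingSet(testPhantomSpec(), 5, seed = 3L)
  masks <- lapply(vols, `[[`, "mask")
  names(masks) <- paste0("v", 1:5)
  rep <- runAgreement(masks, masks)
  expect_equal(rep$dice$mean, rep(1, 3))
  expect_equal(nrow(rep$stats), 18L)  # 6 parameters x 3 regions
  expect_setequal(unique(rep$stats$roi),
                  c("full_6x6", "circle_3mm", "circle_1mm"))
  ok <- !is.na(rep$stats$icc)
  expect_true(all(rep$stats$icc[ok] == 1))
  expect_true(all(rep$stats$mean_diff == 0))
  expect_true(all(rep$stats$loa_lo == 0 & rep$stats$loa_hi == 0))
})
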