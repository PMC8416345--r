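test_that("an empty lesion plan yields a pure-background mask", {
  ph <- generateVolume(testPhantomSpec(nHardExudate = 0L, nSmallHrd = 0L,
                                       nNoise = 0L))
  expect_true(all(labels3d(ph$mask) == 0L))
  expect_equal(nrow(ph$lesions), 0L)
  # layered structure still present
  expect_gt(max(voxels(ph$volume)), 0.5)
})

test_that("phantom generation is deterministic in the seed", {
  a <- generateVolume(testPhantomSpec(seed = 5L))
  b <- generateVolume(testPhantomSpec(seed = 5L))
  expect_identical(voxels(a$volume), voxels(b$volume))
  expect_identical(labels3d(a$mask), labels3d(b$mask))
  expect_identical(a$lesions, b$lesions)
  c <- generateVolume(testPhantomSpec(seed = 6L))
  expect_false(identical(labels3d(a$mask), labels3d(c$mask)))
})

test_that("speckle level does not touch the ground-truth mask", {
  lo <- generateVolume(testPhantomSpec(seed = 2L, speckleVar = 0.001))
  hi <- generateVolume(testPhantomSpec(seed = 2L, speckleVar = 0.1))
  expect_identical(labels3d(lo$mask), labels3d(hi$mask))
  expect_false(identical(voxels(lo$volume), voxels(hi$volume)))
})

test_that("every mask component matches its recorded diameter and class", {
  ph <- generateVolume(testPhantomSpec(seed = 9L))
  sp <- spacingUm(ph$mask)
  diag <- sqrt(sp[2]^2 + sp[3]^2)
  inMask <- ph$lesions[ph$lesions$class != "noise", ]
  found <- 0
  for (b in seq_len(dim(ph$mask)[1])) {
    for (comp in extractComponents(labels3d(ph$mask)[b, , ] != 0)) {
      d <- physicalDiameter(comp, sp)
      les <- inMask[inMask$bscan == b &
                      abs(inMask$x_px - mean(comp$pixels[, 2])) < 10, ]
      expect_equal(nrow(les), 1L)
      expect_lt(abs(d - les$diameter_um), diag + 1e-9)
      found <- found + 1
    }
  }
  expect_equal(found, nrow(inMask))
})

test_that("the rule classifier recovers the planned 5 + 10 lesion counts", {
  spec <- PhantomSpec(shape = c(8L, 256L, 256L), nHardExudate = 5L,
                      nSmallHrd = 10L, nNoise = 3L, seed = 21L)
  ph <- generateVolume(spec)
  res <- classifyAll(labels3d(ph$mask) != 0L, ph$volume)
  cls <- table(factor(res$components$class,
                      levels = c("hard_exudate", "small_hrd", "noise")))
  expect_equal(unname(cls[["hard_exudate"]]), 5L)
  expect_equal(unname(cls[["small_hrd"]]), 10L)
})

test_that("a zero-noise rater reproduces the mask exactly", {
  ph <- generateVolume(testPhantomSpec(seed = 3L))
  out <- simulateRater(ph$mask, RaterNoiseSpec(jitterPx = 0, dropProb = 0,
                                               flipProb = 0, seed = 1L))
  expect_identical(labels3d(out), labels3d(ph$mask))
  expect_equal(diceCoef(ph$mask, out), 1.0)
})

test_that("drop probability one empties the mask", {
  ph <- generateVolume(testPhantomSpec(seed = 3L))
  out <- simulateRater(ph$mask, RaterNoiseSpec(jitterPx = 0, dropProb = 1,
                                               flipProb = 0, seed = 1L))
  expect_true(all(labels3d(out) == 0L))
})

test_that("mean Dice degrades monotonically with boundary jitter", {
  ph <- generateVolume(testPhantomSpec(seed = 4L))
  meanDice <- vapply(0:3, function(j) {
    mean(vapply(1:10, function(s) {
      out <- simulateRater(ph$mask, RaterNoiseSpec(jitterPx = j, dropProb = 0,
                                                   flipProb = 0,
                                                   seed = as.integer(s)))
      diceCoef(ph$mask, out)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(meanDice[1], 1.0)
  expect_true(all(diff(meanDice) <= 1e-12))
})

test_that("class flips swap hard exudates and small HRDs", {
  ph <- generateVolume(testPhantomSpec(seed = 3L))
  out <- simulateRater(ph$mask, RaterNoiseSpec(jitterPx = 0, dropProb = 0,
                                               flipProb = 1, seed = 1L))
  expect_identical(labels3d(out) != 0L, labels3d(ph$mask) != 0L)
  orig <- labels3d(ph$mask)[labels3d(ph$mask) > 0L]
  flip <- labels3d(out)[labels3d(out) > 0L]
  expect_true(all(flip == c(2L, 1L)[orig]))
})

test_that("training sets are reproducible and pairwise distinct", {
  s1 <- generateTrainingSet(testPhantomSpec(), 4, seed = 11L)
  s2 <- generateTrainingSet(testPhantomSpec(), 4, seed = 11L)
  for (i in 1:4)
    expect_identical(voxels(s1[[i]]$volume), voxels(s2[[i]]$volume))
  for (i in 1:3) for (j in (i + 1):4)
    expect_false(identical(labels3d(s1[[i]]$mask), labels3d(s1[[j]]$mask)))
})

test_that("an oversubscribed lesion plan fails with a clear message", {
  expect_error(generateVolume(PhantomSpec(shape = c(1L, 256L, 256L),
                                          nHardExudate = 20L, seed = 1L)),
               "infeasible")
})
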