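tinyNet <- function(seed = 1L) buildNetwork(NetConfig(baseChannels = 4L), seed)

test_that("the network maps (H, W) inputs to same-shape probability maps", {
  net <- tinyNet()
  v <- OCTVolume(array(runif(2 * 64 * 64), c(2, 64, 64)), c(47, 2.26, 11.7))
  p <- segmentProbability(net, v)
  expect_equal(dim(p), c(2L, 64L, 64L))
  expect_true(all(p >= 0 & p <= 1))
  # internal padding handles non-divisible shapes transparently
  v2 <- OCTVolume(array(runif(1 * 60 * 52), c(1, 60, 52)), c(47, 2.26, 11.7))
  p2 <- segmentProbability(net, v2)
  expect_equal(dim(p2), c(1L, 60L, 52L))
  expect_true(all(is.finite(p2)))
  # direct forward on a non-divisible shape errors with the constraint named
  x <- array(runif(60 * 52), c(60, 52, 1))
  expect_error(hrdq:::.netForward(net$params, x), "divisible")
})

test_that("degenerate all-zero input still yields valid probabilities", {
  net <- tinyNet()
  v <- OCTVolume(array(0, c(1, 32, 32)), c(47, 2.26, 11.7))
  p <- segmentProbability(net, v)
  expect_true(all(is.finite(p)))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("class probabilities are normalized per pixel", {
  net <- tinyNet()
  x <- array(runif(32 * 32), c(32, 32, 1))
  logits <- hrdq:::.netForward(net$params, x, wantCache = FALSE)$logits
  p <- hrdq:::.softmax2(logits)
  expect_equal(p[, , 1] + p[, , 2], matrix(1, 32, 32), tolerance = 1e-12)
})

test_that("inference is deterministic for fixed weights and input", {
  net <- tinyNet()
  v <- OCTVolume(array(runif(1 * 32 * 32), c(1, 32, 32)), c(47, 2.26, 11.7))
  expect_identical(segmentProbability(net, v), segmentProbability(net, v))
})

test_that("CAM gates stay strictly inside (0, 1)", {
  net <- tinyNet()
  x <- array(runif(16 * 16 * 16, -1, 1), c(16, 16, 16))
  cam <- hrdq:::.camFw(net$params, "cam3", x)
  expect_true(all(cam$s > 0 & cam$s < 1))
  expect_length(cam$s, 16L)
})

test_that("the 3-level MSCM network undercuts a 4-level baseline U-Net", {
  # baseline: standard 4-level U-Net with double 3x3 convolutions per stage,
  # 2x2 transpose-conv upsampling, channels c, 2c, ..., 16c; closed-form
  # parameter count including biases
  baselineParams <- function(c) {
    convP <- function(k, cin, cout) k * k * cin * cout + cout
    enc <- convP(3, 1, c) + convP(3, c, c) +
      convP(3, c, 2 * c) + convP(3, 2 * c, 2 * c) +
      convP(3, 2 * c, 4 * c) + convP(3, 4 * c, 4 * c) +
      convP(3, 4 * c, 8 * c) + convP(3, 8 * c, 8 * c)
    bridge <- convP(3, 8 * c, 16 * c) + convP(3, 16 * c, 16 * c)
    dec <- convP(2, 16 * c, 8 * c) + convP(3, 16 * c, 8 * c) + convP(3, 8 * c, 8 * c) +
      convP(2, 8 * c, 4 * c) + convP(3, 8 * c, 4 * c) + convP(3, 4 * c, 4 * c) +
      convP(2, 4 * c, 2 * c) + convP(3, 4 * c, 2 * c) + convP(3, 2 * c, 2 * c) +
      convP(2, 2 * c, c) + convP(3, 2 * c, c) + convP(3, c, c)
    enc + bridge + dec + convP(1, c, 2)
  }
  for (c in c(8L, 16L)) {
    net <- buildNetwork(NetConfig(baseChannels = c))
    expect_lt(countParams(net), baselineParams(c))
  }
})

test_that("backpropagation matches finite differences through the full net", {
  net <- tinyNet(seed = 3L)
  # give the zero-initialized head small random weights so every path is live
  set.seed(4)
  net$params[["out.W"]] <- matrix(rnorm(8, sd = 0.1), 4, 2)
  x <- array(runif(8 * 8), c(8, 8, 1))
  fg <- matrix(rbinom(64, 1, 0.2), 8, 8)
  lossOf <- function(params) {
    fw <- hrdq:::.netForward(params, x, wantCache = FALSE)
    hrdq:::.segLoss(fw$logits, fg)$loss
  }
  fw <- hrdq:::.netForward(net$params, x)
  ls <- hrdq:::.segLoss(fw$logits, fg)
  grads <- hrdq:::.netBackward(net$params, fw$cache, ls$dlogits)
  eps <- 1e-6
  for (nm in c("enc1.b2.W", "enc2.fuse.W", "cam3.W1", "camb.W2", "bridge.b1.W",
               "up2.W", "dec1.W", "out.W", "enc3.b3.b", "dec3.b")) {
    p <- net$params
    i <- sample(length(p[[nm]]), 1)
    p[[nm]][i] <- p[[nm]][i] + eps
    num <- (lossOf(p) - ls$loss) / eps
    expect_equal(grads[[nm]][i], num, tolerance = 5e-3,
                 label = sprintf("grad %s", nm))
  }
})

test_that("binarize respects thresholds, limits and complement identity", {
  p <- matrix(0.4, 8, 8)
  expect_true(all(binarize(p, 0.5) == 0L))
  expect_true(all(binarize(p, 1e-9) == 1L))
  # complement identity (no boundary ties for continuous random maps)
  set.seed(11)
  q <- matrix(runif(100), 10)
  t <- 0.37
  expect_equal(binarize(1 - q, 1 - t), 1L - binarize(q, t))
  expect_error(binarize(matrix(1.5, 2, 2)), "prob")
})

test_that("augmentation applies 2-4 ops, preserves labels and geometry", {
  ph <- generateVolume(testPhantomSpec(seed = 6L))
  img <- voxels(ph$volume)[1, , ]; msk <- labels3d(ph$mask)[1, , ]
  for (s in 1:20) {
    set.seed(s)
    out <- augmentSample(img, msk)
    expect_identical(dim(out$image), dim(img))
    expect_true(all(out$mask %in% c(0L, 1L, 2L)))
  }
})

test_that("flips are involutions that preserve the mask pixel count", {
  set.seed(1)
  img <- matrix(runif(64 * 64), 64); msk <- matrix(rbinom(64 * 64, 1, 0.1), 64)
  lr <- function(m) m[, ncol(m):1]
  ud <- function(m) m[nrow(m):1, ]
  expect_identical(lr(lr(msk)), msk)
  expect_identical(ud(ud(msk)), msk)
  expect_equal(sum(lr(msk)), sum(msk))
  # right-angle rotation is a permutation too
  expect_equal(sum(t(msk)[, nrow(msk):1]), sum(msk))
})

test_that("small rotations keep masks integral and roughly size-preserving", {
  msk <- matrix(0L, 64, 64); msk[28:36, 28:36] <- 1L
  rot <- hrdq:::.rotate2d(msk, 12, bilinear = FALSE)
  expect_true(all(rot %in% c(0, 1)))
  expect_lt(abs(sum(rot) - sum(msk)) / sum(msk), 0.15)
})

test_that("gaussian noise perturbs the image but never the mask", {
  ph <- generateVolume(testPhantomSpec(seed = 6L))
  img <- voxels(ph$volume)[1, , ]; msk <- labels3d(ph$mask)[1, , ]
  found <- FALSE
  for (s in 1:60) {
    set.seed(s)
    out <- augmentSample(img, msk)
    ops <- attr(out, "ops")
    if (identical(sort(ops), c("gaussian_noise", "lr_flip"))) {
      found <- TRUE
      expect_identical(out$mask, msk[, ncol(msk):1])
      expect_false(identical(out$image, img[, ncol(img):1]))
    }
  }
  expect_true(found)
})

test_that("zero-epoch training returns the network unchanged", {
  net <- tinyNet()
  img <- matrix(runif(16 * 16), 16); msk <- matrix(0L, 16, 16); msk[5, 5] <- 1L
  r <- trainNetwork(net, list(list(image = img, mask = msk)),
                    TrainConfig(epochs = 0L, seed = 1L))
  expect_identical(r$net$params, net$params)
  expect_equal(nrow(r$trace), 0L)
})

test_that("a short training run reduces the loss on a small phantom set", {
  ph <- generateVolume(PhantomSpec(shape = c(2L, 64L, 64L),
                                   hardDiamUm = c(45, 60), nHardExudate = 0L,
                                   nSmallHrd = 2L, nNoise = 0L, seed = 7L))
  pairs <- lapply(1:2, function(b)
    list(image = voxels(ph$volume)[b, , ],
         mask = (labels3d(ph$mask)[b, , ] > 0) * 1L))
  net <- tinyNet()
  r <- trainNetwork(net, pairs, TrainConfig(epochs = 10L, augment = FALSE,
                                            seed = 1L))
  expect_true(all(is.finite(r$trace$loss)))
  expect_lt(r$trace$loss[10], r$trace$loss[1])
})

test_that("fold plans partition the ids with near-equal sizes", {
  plan <- makeFolds(1:20, 4, seed = 1L)
  sizes <- lengths(plan$folds)
  expect_equal(unname(sizes), rep(5L, 4))
  expect_setequal(unlist(plan$folds), 1:20)
  expect_equal(sum(duplicated(unlist(plan$folds))), 0L)
  expect_identical(makeFolds(1:20, 4, seed = 1L), plan)
  for (n in c(9, 13, 21)) {
    p <- makeFolds(seq_len(n), 4, seed = 2L)
    expect_lte(diff(range(lengths(p$folds))), 1L)
    expect_setequal(unlist(p$folds), seq_len(n))
  }
})

test_that("cross-validation evaluates every id exactly once and averages folds", {
  set.seed(9)
  pairs <- lapply(1:8, function(i) {
    msk <- matrix(0L, 16, 16); msk[4:6, 4:6] <- 1L
    list(image = matrix(runif(256), 16) + 0.5 * msk, mask = msk)
  })
  names(pairs) <- paste0("v", 1:8)
  plan <- makeFolds(names(pairs), 4, seed = 1L)
  cv <- crossValidate(pairs, NetConfig(baseChannels = 4L),
                      TrainConfig(epochs = 0L, seed = 1L), plan)
  expect_equal(sort(cv$evaluated), sort(names(pairs)))
  expect_equal(sum(duplicated(cv$evaluated)), 0L)
  expect_equal(cv$mean, mean(cv$perFold$dice), tolerance = 1e-12)
  expect_equal(nrow(cv$perFold), 4L)
  # reduced smoke run with a different fold count keeps the schema
  plan2 <- makeFolds(names(pairs), 2, seed = 1L)
  cv2 <- crossValidate(pairs, NetConfig(baseChannels = 4L),
                       TrainConfig(epochs = 0L, seed = 1L), plan2)
  expect_named(cv2, c("perFold", "mean", "sd", "evaluated"))
  expect_equal(nrow(cv2$perFold), 2L)
})

test_that("threshold segmentation is monotone and respects its band", {
  ph <- generateVolume(testPhantomSpec(seed = 10L, speckleVar = 0.01))
  m1 <- thresholdSegment(ph$volume, 0.3)
  m2 <- thresholdSegment(ph$volume, 0.6)
  expect_true(all(m2 <= m1))
  expect_true(all(thresholdSegment(ph$volume, 1.0) == 0L))
  banded <- thresholdSegment(ph$volume, 0.3, band = c(60, 100))
  expect_true(all(banded[, c(1:59, 101:dim(ph$volume)[2]), ] == 0L))
})
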