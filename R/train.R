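#' Online augmentation of an image/mask pair
#'
#' Applies k distinct operations, k drawn uniformly from {2, 3, 4}, chosen
#' from left-right flip, up-down flip, random rotation (uniform in
#' [-15, 15] degrees, bilinear for the image, nearest-neighbour for the
#' mask so labels stay integral), and additive Gaussian noise (sigma
#' uniform in [0.01, 0.05] of the intensity range, image only). Spatial
#' transforms are applied identically to image and mask. Uses the current
#' RNG state.
#'
#' @param image numeric matrix (z, x).
#' @param mask integer matrix of the same shape.
#' @return list(image, mask).
#' @export
augmentSample <- function(image, mask) {
  stopifnot(identical(dim(image), dim(mask)))
  k <- sample(2:4, 1)
  ops <- sample(c("lr_flip", "ud_flip", "rotation", "gaussian_noise"), k)
  for (op in ops) {
    res <- switch(op,
      lr_flip = list(image = image[, ncol(image):1],
                     mask = mask[, ncol(mask):1]),
      ud_flip = list(image = image[nrow(image):1, ],
                     mask = mask[nrow(mask):1, ]),
      rotation = {
        theta <- stats::runif(1, -15, 15)
        list(image = .rotate2d(image, theta, bilinear = TRUE),
             mask = .rotate2d(mask, theta, bilinear = FALSE))
      },
      gaussian_noise = {
        sigma <- stats::runif(1, 0.01, 0.05)
        list(image = image + matrix(stats::rnorm(length(image), sd = sigma),
                                    nrow(image)),
             mask = mask)
      })
    image <- res$image; mask <- res$mask
  }
  storage.mode(mask) <- "integer"
  structure(list(image = image, mask = mask), ops = ops)
}

# rotate about the image center by `theta` degrees (inverse mapping);
# out-of-field pixels become 0
.rotate2d <- function(m, theta, bilinear = TRUE) {
  H <- nrow(m); W <- ncol(m)
  ci <- (H + 1) / 2; cj <- (W + 1) / 2
  th <- theta * pi / 180
  co <- cos(th); si <- sin(th)
  ii <- rep(seq_len(H), times = W) - ci
  jj <- rep(seq_len(W), each = H) - cj
  si0 <- co * ii - si * jj + ci
  sj0 <- si * ii + co * jj + cj
  out <- numeric(H * W)
  if (bilinear) {
    i0 <- floor(si0); j0 <- floor(sj0)
    fi <- si0 - i0; fj <- sj0 - j0
    val <- function(i, j) {
      ok <- i >= 1 & i <= H & j >= 1 & j <= W
      v <- numeric(length(i))
      v[ok] <- m[cbind(i[ok], j[ok])]
      v
    }
    out <- (1 - fi) * (1 - fj) * val(i0, j0) +
      (1 - fi) * fj * val(i0, j0 + 1) +
      fi * (1 - fj) * val(i0 + 1, j0) +
      fi * fj * val(i0 + 1, j0 + 1)
  } else {
    i0 <- round(si0); j0 <- round(sj0)
    ok <- i0 >= 1 & i0 <= H & j0 >= 1 & j0 <= W
    out[ok] <- m[cbind(i0[ok], j0[ok])]
  }
  matrix(out, H, W)
}

#' Train the segmentation network
#'
#' Stochastic gradient descent with momentum and weight decay over
#' per-b-scan image/mask pairs, with online augmentation (optional) and a
#' combined cross-entropy + soft-Dice loss. Reproducible for a fixed
#' `config@seed`. A non-finite loss aborts with the epoch reported.
#'
#' @param net a network from [buildNetwork()].
#' @param pairs list of `list(image = matrix, mask = matrix)` training
#'   pairs; any non-zero mask value counts as foreground.
#' @param config a \linkS4class{TrainConfig}.
#' @param verbose print per-epoch `epoch,loss,dice` lines to stderr.
#' @return list(net = trained network, trace = data.frame(epoch, loss,
#'   dice)) where dice is the running training foreground Dice of that
#'   epoch's predictions.
#' @export
trainNetwork <- function(net, pairs, config = TrainConfig(), verbose = FALSE) {
  stopifnot(length(pairs) >= 1)
  validObject(config)
  set.seed(config@seed)
  params <- net$params
  vel <- lapply(params, function(p) p * 0)
  trace <- data.frame(epoch = integer(), loss = numeric(), dice = numeric())
  lr <- config@learningRate; mom <- config@momentum; wd <- config@weightDecay
  for (ep in seq_len(config@epochs)) {
    ord <- sample.int(length(pairs))
    epLoss <- 0; nBatch <- 0
    inter <- 0; denom <- 0
    for (bi in seq(1, length(ord), by = config@batchSize)) {
      idx <- ord[bi:min(bi + config@batchSize - 1, length(ord))]
      gacc <- NULL; bloss <- 0
      for (i in idx) {
        img <- pairs[[i]]$image; msk <- pairs[[i]]$mask
        if (config@augment) {
          aug <- augmentSample(img, msk)
          img <- aug$image; msk <- aug$mask
        }
        fg <- (msk > 0) * 1
        x <- array(img, dim = c(nrow(img), ncol(img), 1))
        fw <- .netForward(params, x)
        ls <- .segLoss(fw$logits, fg)
        if (!is.finite(ls$loss))
          stop(sprintf("divergent loss (non-finite) at epoch %d", ep))
        bloss <- bloss + ls$loss
        pb <- ls$p[, , 2] >= 0.5
        inter <- inter + sum(pb & fg > 0)
        denom <- denom + sum(pb) + sum(fg)
        g <- .netBackward(params, fw$cache, ls$dlogits)
        if (is.null(gacc)) gacc <- g
        else for (nm in names(g)) gacc[[nm]] <- gacc[[nm]] + g[[nm]]
      }
      nb <- length(idx)
      # clip the global gradient norm (at 5): guards the first large SGD
      # steps at lr 0.01 / momentum 0.9 against ReLU die-off
      gnorm <- sqrt(sum(vapply(gacc, function(g) sum((g / nb)^2), numeric(1))))
      scale <- if (gnorm > 5) 5 / gnorm else 1
      for (nm in names(params)) {
        grad <- scale * gacc[[nm]] / nb + wd * params[[nm]]
        vel[[nm]] <- mom * vel[[nm]] - lr * grad
        params[[nm]] <- params[[nm]] + vel[[nm]]
      }
      epLoss <- epLoss + bloss / nb
      nBatch <- nBatch + 1
    }
    dice <- if (denom > 0) 2 * inter / denom else 1
    trace <- rbind(trace, data.frame(epoch = ep, loss = epLoss / nBatch,
                                     dice = dice))
    if (verbose)
      message(sprintf("%d,%.5f,%.4f", ep, epLoss / nBatch, dice))
  }
  net$params <- params
  list(net = net, trace = trace)
}

#' Partition volume ids into cross-validation folds
#'
#' Random partition into `nFolds` folds whose sizes differ by at most one;
#' deterministic for a fixed seed.
#'
#' @param ids vector of volume identifiers.
#' @param nFolds number of folds (default 4).
#' @param seed integer seed.
#' @return list(nFolds, folds = named list f1..fn of id vectors).
#' @examples
#' makeFolds(1:20, 4, seed = 1)
#' @export
makeFolds <- function(ids, nFolds = 4L, seed = 1L) {
  stopifnot(length(ids) >= nFolds, nFolds >= 2)
  set.seed(seed)
  shuffled <- sample(ids)
  assign <- rep(seq_len(nFolds), length.out = length(ids))
  folds <- split(shuffled, assign)
  names(folds) <- paste0("f", seq_len(nFolds))
  list(nFolds = as.integer(nFolds), folds = folds)
}

#' k-fold cross-validation of the segmentation network
#'
#' For each fold, trains a fresh network on the remaining folds and
#' evaluates the foreground Dice on the held-out fold only, so every id is
#' test data exactly once. The final output is the mean (and SD) of the
#' per-fold metrics.
#'
#' @param pairsById named list: id -> `list(image, mask)`.
#' @param netConfig a \linkS4class{NetConfig}.
#' @param trainConfig a \linkS4class{TrainConfig}.
#' @param foldPlan from [makeFolds()] over `names(pairsById)`.
#' @return list(perFold = data.frame(fold, dice, n_test), mean, sd,
#'   evaluated = character vector of test ids in evaluation order).
#' @export
crossValidate <- function(pairsById, netConfig, trainConfig, foldPlan) {
  ids <- names(pairsById)
  stopifnot(setequal(unlist(foldPlan$folds), ids))
  perFold <- data.frame(fold = character(), dice = numeric(), n_test = integer())
  evaluated <- character()
  for (fname in names(foldPlan$folds)) {
    testIds <- as.character(foldPlan$folds[[fname]])
    trainIds <- setdiff(ids, testIds)
    net <- buildNetwork(netConfig, seed = trainConfig@seed)
    if (trainConfig@epochs > 0 && length(trainIds) > 0)
      net <- trainNetwork(net, pairsById[trainIds], trainConfig)$net
    inter <- 0; denom <- 0
    for (id in testIds) {
      img <- pairsById[[id]]$image
      fg <- (pairsById[[id]]$mask > 0) * 1
      pd <- .padTo8(img)
      x <- array(pd$m, dim = c(nrow(pd$m), ncol(pd$m), 1))
      p <- .softmax2(.netForward(net$params, x, wantCache = FALSE)$logits)
      pb <- p[seq_len(pd$H), seq_len(pd$W), 2] >= 0.5
      inter <- inter + sum(pb & fg > 0)
      denom <- denom + sum(pb) + sum(fg)
      evaluated <- c(evaluated, id)
    }
    dice <- if (denom > 0) 2 * inter / denom else 1
    perFold <- rbind(perFold, data.frame(fold = fname, dice = dice,
                                         n_test = length(testIds)))
  }
  list(perFold = perFold, mean = mean(perFold$dice),
       sd = stats::sd(perFold$dice), evaluated = evaluated)
}
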