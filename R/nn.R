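## Minimal CNN layer toolkit with explicit backpropagation.
## Tensors are numeric arrays of dim (H, W, C); convolution weights are
## (k*k*Cin x Cout) matrices flattened column-major from (k, k, Cin, Cout),
## matching the C++ im2col layout. All layers here are deterministic at
## inference; randomness enters only through initialization and training.

.heInit <- function(k, cin, cout) {
  sd <- sqrt(2 / (k * k * cin))
  matrix(stats::rnorm(k * k * cin * cout, sd = sd), k * k * cin, cout)
}

.conv <- function(X, W, b, k, dil = 1L) {
  conv2d_fw(X, W, b, as.integer(k), as.integer(dil))
}

.relu <- function(X) {
  X[X < 0] <- 0
  X
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# 2x2 max pooling with argmax routing for the backward pass
.maxpoolFw <- function(X) {
  H <- dim(X)[1]; W <- dim(X)[2]
  io <- seq(1, H, 2); jo <- seq(1, W, 2)
  x11 <- X[io, jo, , drop = FALSE];     x21 <- X[io + 1, jo, , drop = FALSE]
  x12 <- X[io, jo + 1, , drop = FALSE]; x22 <- X[io + 1, jo + 1, , drop = FALSE]
  Y <- pmax(x11, x12, x21, x22)
  list(Y = Y, w11 = x11 == Y, w12 = x12 == Y, w21 = x21 == Y, w22 = x22 == Y)
}

.maxpoolBw <- function(cache, dY, dimX) {
  dX <- array(0, dimX)
  io <- seq(1, dimX[1], 2); jo <- seq(1, dimX[2], 2)
  # ties routed to the first maximal position in (11, 12, 21, 22) order
  w11 <- cache$w11
  w12 <- cache$w12 & !w11
  w21 <- cache$w21 & !(w11 | w12)
  w22 <- cache$w22 & !(w11 | w12 | w21)
  dX[io, jo, ]         <- dY * w11
  dX[io, jo + 1, ]     <- dY * w12
  dX[io + 1, jo, ]     <- dY * w21
  dX[io + 1, jo + 1, ] <- dY * w22
  dX
}

.upsampleFw <- function(X) {
  X[rep(seq_len(dim(X)[1]), each = 2), rep(seq_len(dim(X)[2]), each = 2), ,
    drop = FALSE]
}

.upsampleBw <- function(dY) {
  H2 <- dim(dY)[1]; W2 <- dim(dY)[2]
  io <- seq(1, H2, 2); jo <- seq(1, W2, 2)
  dY[io, jo, , drop = FALSE] + dY[io, jo + 1, , drop = FALSE] +
    dY[io + 1, jo, , drop = FALSE] + dY[io + 1, jo + 1, , drop = FALSE]
}

## MSCM: three parallel 3x3 convolutions at dilations 1/2/3, ReLU each,
## concatenated and fused by a ReLU 1x1 convolution back to the stage width.
.mscmInit <- function(params, name, cin, cout) {
  for (d in 1:3) {
    params[[paste0(name, ".b", d, ".W")]] <- .heInit(3, cin, cout)
    params[[paste0(name, ".b", d, ".b")]] <- numeric(cout)
  }
  params[[paste0(name, ".fuse.W")]] <- .heInit(1, 3 * cout, cout)
  params[[paste0(name, ".fuse.b")]] <- numeric(cout)
  params
}

.mscmFw <- function(params, name, X) {
  br <- lapply(1:3, function(d)
    .relu(.conv(X, params[[paste0(name, ".b", d, ".W")]],
                params[[paste0(name, ".b", d, ".b")]], 3L, d)))
  cat3 <- array(c(br[[1]], br[[2]], br[[3]]),
                dim = c(dim(X)[1], dim(X)[2], 3 * dim(br[[1]])[3]))
  Y <- .relu(.conv(cat3, params[[paste0(name, ".fuse.W")]],
                   params[[paste0(name, ".fuse.b")]], 1L, 1L))
  list(Y = Y, X = X, br = br, cat3 = cat3)
}

.mscmBw <- function(params, name, cache, dY, grads) {
  dY <- dY * (cache$Y > 0)
  bwF <- conv2d_bw(cache$cat3, params[[paste0(name, ".fuse.W")]], dY, 1L, 1L)
  grads[[paste0(name, ".fuse.W")]] <- bwF$dW
  grads[[paste0(name, ".fuse.b")]] <- as.numeric(bwF$db)
  dcat <- bwF$dX
  cout <- dim(cache$br[[1]])[3]
  dX <- 0
  for (d in 1:3) {
    dBr <- dcat[, , ((d - 1) * cout + 1):(d * cout), drop = FALSE]
    dBr <- dBr * (cache$br[[d]] > 0)
    bw <- conv2d_bw(cache$X, params[[paste0(name, ".b", d, ".W")]], dBr, 3L, d)
    grads[[paste0(name, ".b", d, ".W")]] <- bw$dW
    grads[[paste0(name, ".b", d, ".b")]] <- as.numeric(bw$db)
    dX <- dX + bw$dX
  }
  list(dX = dX, grads = grads)
}

## CAM: global average pooling -> fully connected bottleneck (reduction r,
## ReLU) -> expansion with sigmoid gate in (0,1), applied multiplicatively
## per channel.
.camInit <- function(params, name, ch, reduction) {
  mid <- max(1L, ch %/% reduction)
  sd1 <- sqrt(2 / ch); sd2 <- sqrt(2 / mid)
  params[[paste0(name, ".W1")]] <- matrix(stats::rnorm(ch * mid, sd = sd1), ch, mid)
  params[[paste0(name, ".b1")]] <- numeric(mid)
  params[[paste0(name, ".W2")]] <- matrix(stats::rnorm(mid * ch, sd = sd2), mid, ch)
  params[[paste0(name, ".b2")]] <- numeric(ch)
  params
}

.camFw <- function(params, name, X) {
  g <- apply(X, 3, mean)
  h <- pmax(as.numeric(crossprod(params[[paste0(name, ".W1")]], g)) +
              params[[paste0(name, ".b1")]], 0)
  s <- .sigmoid(as.numeric(crossprod(params[[paste0(name, ".W2")]], h)) +
                  params[[paste0(name, ".b2")]])
  Y <- sweep(X, 3, s, `*`)
  list(Y = Y, X = X, g = g, h = h, s = s)
}

.camBw <- function(params, name, cache, dY, grads) {
  X <- cache$X; s <- cache$s; h <- cache$h; g <- cache$g
  npix <- dim(X)[1] * dim(X)[2]
  ds <- apply(dY * X, 3, sum)
  dspre <- ds * s * (1 - s)
  grads[[paste0(name, ".W2")]] <- outer(h, dspre)
  grads[[paste0(name, ".b2")]] <- dspre
  dh <- as.numeric(params[[paste0(name, ".W2")]] %*% dspre) * (h > 0)
  grads[[paste0(name, ".W1")]] <- outer(g, dh)
  grads[[paste0(name, ".b1")]] <- dh
  dg <- as.numeric(params[[paste0(name, ".W1")]] %*% dh)
  dX <- sweep(dY, 3, s, `*`) + sweep(array(1, dim(X)), 3, dg / npix, `*`)
  list(dX = dX, grads = grads)
}

## softmax over the channel dimension (2 classes)
.softmax2 <- function(logits) {
  m <- pmax(logits[, , 1], logits[, , 2])
  e1 <- exp(logits[, , 1] - m); e2 <- exp(logits[, , 2] - m)
  s <- e1 + e2
  array(c(e1 / s, e2 / s), dim = dim(logits))
}

## combined class-balanced cross-entropy + soft-Dice loss on the foreground
## probability; returns loss value and gradient w.r.t. the logits.
## Foreground pixels are upweighted by the background/foreground ratio
## (capped at 100): lesions occupy well under 1% of a b-scan, and an
## unweighted CE lets an all-background prediction saturate and freeze.
.segLoss <- function(logits, fg, eps = 1) {
  p <- .softmax2(logits)
  npix <- length(fg)
  p1 <- p[, , 2]
  nfg <- sum(fg)
  wfg <- min(max((npix - nfg) / max(nfg, 1), 1), 100)
  w <- 1 + (wfg - 1) * fg
  sw <- sum(w)
  ce <- -sum(w * (fg * log(p1 + 1e-12) + (1 - fg) * log(1 - p1 + 1e-12))) / sw
  I <- sum(p1 * fg); S <- sum(p1) + sum(fg)
  diceLoss <- 1 - (2 * I + eps) / (S + eps)
  loss <- ce + diceLoss
  # dL/dp1: CE part and soft-Dice part
  dp1 <- -w * (fg / (p1 + 1e-12) - (1 - fg) / (1 - p1 + 1e-12)) / sw
  dp1 <- dp1 - (2 * fg * (S + eps) - (2 * I + eps)) / (S + eps)^2
  # through the 2-class softmax: dl_c = p_c * (dLdp_c - sum_k p_k dLdp_k)
  dot <- p[, , 2] * dp1
  dlog <- array(0, dim(logits))
  dlog[, , 1] <- p[, , 1] * (-dot)
  dlog[, , 2] <- p[, , 2] * (dp1 - dot)
  list(loss = loss, dlogits = dlog, p = p)
}
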