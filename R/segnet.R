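#' Build the improved U-shaped segmentation network
#'
#' Three down/upsampling steps (the input height and width must be divisible
#' by 8). Every encoder stage is an MSCM (parallel 3x3 convolutions at
#' dilation rates 1, 2, 3, fused by a 1x1 convolution); the two deepest
#' encoder stages (the third encoder and the bridge) additionally carry a
#' channel attention module. The decoder mirrors the encoder with three
#' nearest-neighbour upsampling steps and skip connections, and a final 1x1
#' convolution emits per-pixel class scores for background and HRD
#' foreground.
#'
#' @param config a \linkS4class{NetConfig}.
#' @param seed integer seed for He weight initialization.
#' @return A network object (list with elements `params` and `config`).
#' @examples
#' net <- buildNetwork(NetConfig(baseChannels = 8L))
#' countParams(net)
#' @export
buildNetwork <- function(config = NetConfig(), seed = 1L) {
  validObject(config)
  set.seed(seed)
  c1 <- config@baseChannels; c2 <- 2L * c1; c3 <- 4L * c1; cb <- 8L * c1
  p <- list()
  p <- .mscmInit(p, "enc1", config@inChannels, c1)
  p <- .mscmInit(p, "enc2", c1, c2)
  p <- .mscmInit(p, "enc3", c2, c3)
  p <- .camInit(p, "cam3", c3, config@camReduction)
  p <- .mscmInit(p, "bridge", c3, cb)
  p <- .camInit(p, "camb", cb, config@camReduction)
  for (lv in 3:1) {
    cin <- c(c1, c2, c3, cb)[lv + 1]; cout <- c(c1, c2, c3)[lv]
    p[[sprintf("up%d.W", lv)]] <- .heInit(3, cin, cout)
    p[[sprintf("up%d.b", lv)]] <- numeric(cout)
    p[[sprintf("dec%d.W", lv)]] <- .heInit(3, 2L * cout, cout)
    p[[sprintf("dec%d.b", lv)]] <- numeric(cout)
  }
  # zero-init the output head: training starts from maximal class entropy,
  # which keeps the soft-Dice gradient alive on extremely sparse foreground
  p[["out.W"]] <- matrix(0, c1, config@outChannels)
  p[["out.b"]] <- numeric(config@outChannels)
  structure(list(params = p, config = config), class = "hrdqNet")
}

#' Number of trainable parameters of a network
#'
#' @param net a network from [buildNetwork()].
#' @return Integer parameter count.
#' @export
countParams <- function(net) {
  sum(vapply(net$params, length, integer(1)))
}

.netForward <- function(params, x, wantCache = TRUE) {
  H <- dim(x)[1]; W <- dim(x)[2]
  if (H %% 8 != 0 || W %% 8 != 0)
    stop(sprintf("input %d x %d: height and width must be divisible by 8", H, W))
  e1 <- .mscmFw(params, "enc1", x)
  p1 <- .maxpoolFw(e1$Y)
  e2 <- .mscmFw(params, "enc2", p1$Y)
  p2 <- .maxpoolFw(e2$Y)
  e3 <- .mscmFw(params, "enc3", p2$Y)
  a3 <- .camFw(params, "cam3", e3$Y)
  p3 <- .maxpoolFw(a3$Y)
  bb <- .mscmFw(params, "bridge", p3$Y)
  ab <- .camFw(params, "camb", bb$Y)

  dec <- function(lv, below, skip) {
    up <- .upsampleFw(below)
    u <- .relu(.conv(up, params[[sprintf("up%d.W", lv)]],
                     params[[sprintf("up%d.b", lv)]], 3L, 1L))
    cat2 <- array(c(u, skip), dim = c(dim(u)[1], dim(u)[2],
                                      dim(u)[3] + dim(skip)[3]))
    d <- .relu(.conv(cat2, params[[sprintf("dec%d.W", lv)]],
                     params[[sprintf("dec%d.b", lv)]], 3L, 1L))
    list(d = d, u = u, up = up, cat2 = cat2)
  }
  d3 <- dec(3L, ab$Y, a3$Y)
  d2 <- dec(2L, d3$d, e2$Y)
  d1 <- dec(1L, d2$d, e1$Y)
  logits <- .conv(d1$d, params[["out.W"]], params[["out.b"]], 1L, 1L)
  if (!wantCache) return(list(logits = logits))
  list(logits = logits,
       cache = list(e1 = e1, p1 = p1, e2 = e2, p2 = p2, e3 = e3, a3 = a3,
                    p3 = p3, bb = bb, ab = ab, d3 = d3, d2 = d2, d1 = d1))
}

.netBackward <- function(params, cache, dlogits) {
  grads <- list()
  bwOut <- conv2d_bw(cache$d1$d, params[["out.W"]], dlogits, 1L, 1L)
  grads[["out.W"]] <- bwOut$dW
  grads[["out.b"]] <- as.numeric(bwOut$db)
  dd1 <- bwOut$dX

  decBw <- function(lv, dcur, cc) {
    dcur <- dcur * (cc$d > 0)
    bwD <- conv2d_bw(cc$cat2, params[[sprintf("dec%d.W", lv)]], dcur, 3L, 1L)
    grads[[sprintf("dec%d.W", lv)]] <<- bwD$dW
    grads[[sprintf("dec%d.b", lv)]] <<- as.numeric(bwD$db)
    cu <- dim(cc$u)[3]
    du <- bwD$dX[, , seq_len(cu), drop = FALSE]
    dskip <- bwD$dX[, , (cu + 1):dim(bwD$dX)[3], drop = FALSE]
    du <- du * (cc$u > 0)
    bwU <- conv2d_bw(cc$up, params[[sprintf("up%d.W", lv)]], du, 3L, 1L)
    grads[[sprintf("up%d.W", lv)]] <<- bwU$dW
    grads[[sprintf("up%d.b", lv)]] <<- as.numeric(bwU$db)
    list(dbelow = .upsampleBw(bwU$dX), dskip = dskip)
  }
  r1 <- decBw(1L, dd1, cache$d1)
  r2 <- decBw(2L, r1$dbelow, cache$d2)
  r3 <- decBw(3L, r2$dbelow, cache$d3)

  cb <- .camBw(params, "camb", cache$ab, r3$dbelow, grads); grads <- cb$grads
  mb <- .mscmBw(params, "bridge", cache$bb, cb$dX, grads); grads <- mb$grads
  dp3 <- .maxpoolBw(cache$p3, mb$dX, dim(cache$a3$Y))
  c3 <- .camBw(params, "cam3", cache$a3, dp3 + r3$dskip, grads); grads <- c3$grads
  m3 <- .mscmBw(params, "enc3", cache$e3, c3$dX, grads); grads <- m3$grads
  dp2 <- .maxpoolBw(cache$p2, m3$dX, dim(cache$e2$Y))
  m2 <- .mscmBw(params, "enc2", cache$e2, dp2 + r2$dskip, grads); grads <- m2$grads
  dp1 <- .maxpoolBw(cache$p1, m2$dX, dim(cache$e1$Y))
  m1 <- .mscmBw(params, "enc1", cache$e1, dp1 + r1$dskip, grads); grads <- m1$grads
  grads
}

.padTo8 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  H2 <- ceiling(H / 8) * 8; W2 <- ceiling(W / 8) * 8
  if (H2 == H && W2 == W) return(list(m = m, H = H, W = W))
  out <- matrix(0, H2, W2)
  out[seq_len(H), seq_len(W)] <- m
  list(m = out, H = H, W = W)
}

#' Per-pixel foreground probability maps for a volume
#'
#' Runs every b-scan through the network; inputs whose height/width are not
#' divisible by 8 are zero-padded internally and the output is cropped back,
#' so the returned maps match the input in-plane shape exactly. The two
#' class probabilities sum to 1 per pixel; the foreground channel is
#' returned.
#'
#' @param net a network from [buildNetwork()] or [trainNetwork()].
#' @param volume an \linkS4class{OCTVolume}.
#' @return Numeric array (n_bscans, n_axial, n_lateral) of foreground
#'   probabilities in [0, 1].
#' @export
segmentProbability <- function(net, volume) {
  stopifnot(is(volume, "OCTVolume"))
  d <- dim(volume)
  out <- array(0, d)
  for (b in seq_len(d[1])) {
    pd <- .padTo8(volume@voxels[b, , ])
    x <- array(pd$m, dim = c(nrow(pd$m), ncol(pd$m), 1))
    logits <- .netForward(net$params, x, wantCache = FALSE)$logits
    p <- .softmax2(logits)
    out[b, , ] <- p[seq_len(pd$H), seq_len(pd$W), 2]
  }
  out
}

#' Binarize a probability map
#'
#' A pixel is foreground iff its probability is greater than or equal to the
#' threshold.
#'
#' @param prob numeric array/matrix of probabilities in [0, 1].
#' @param threshold scalar threshold, default 0.5.
#' @return Integer array of the same shape with values in {0, 1}.
#' @export
binarize <- function(prob, threshold = 0.5) {
  stopifnot(all(prob >= 0 & prob <= 1))
  array(as.integer(prob >= threshold), dim = dim(prob))
}

#' Deterministic threshold segmentation (network-free reference path)
#'
#' Marks as foreground every voxel brighter than `threshold` inside the
#' given axial band. On phantoms whose lesions are far brighter than the
#' mid-retina band, this recovers the ground-truth components without any
#' training, which makes the downstream classification and quantification
#' stages testable in isolation.
#'
#' @param volume an \linkS4class{OCTVolume}.
#' @param threshold intensity threshold in (0, 1).
#' @param band integer(2): axial row range (min, max) to consider; defaults
#'   to the whole depth.
#' @return Integer binary array (b, z, x).
#' @export
thresholdSegment <- function(volume, threshold, band = NULL) {
  stopifnot(is(volume, "OCTVolume"), threshold > 0, threshold <= 1)
  d <- dim(volume)
  fg <- volume@voxels > threshold
  if (!is.null(band)) {
    keep <- array(FALSE, d)
    keep[, max(1, band[1]):min(d[2], band[2]), ] <- TRUE
    fg <- fg & keep
  }
  array(as.integer(fg), dim = d)
}
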