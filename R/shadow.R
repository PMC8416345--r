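#' Estimate the RPE depth per lateral column of a b-scan
#'
#' Takes the per-column argmax of intensity in the lower half of the image
#' (the RPE-like band is the brightest deep structure, and a back shadow
#' only attenuates it multiplicatively, so it stays the columnar maximum),
#' then smooths the depth profile laterally with a running median of window
#' 15 px. A flat lower half (no detectable band) falls back to a fixed 0.85
#' fraction of the depth and sets the fallback flag.
#'
#' @param bscan numeric matrix (z, x).
#' @param exclude optional logical matrix of the same shape: pixels to
#'   ignore (e.g. segmented lesion pixels, which would otherwise outshine
#'   an attenuated RPE directly beneath them).
#' @return list(depthPx = integer vector of length ncol(bscan),
#'   fallback = logical).
#' @export
estimateRpeDepth <- function(bscan, exclude = NULL) {
  H <- nrow(bscan); W <- ncol(bscan)
  if (!is.null(exclude)) bscan[exclude] <- 0
  lower <- bscan[(floor(H / 2) + 1):H, , drop = FALSE]
  rng <- range(lower)
  if (!is.finite(rng[1]) || (rng[2] - rng[1]) < 1e-8)
    return(list(depthPx = rep(round(0.85 * H), W), fallback = TRUE))
  depth <- apply(lower, 2, which.max) + floor(H / 2)
  win <- min(15L, if (W %% 2 == 1) W else W - 1L)
  if (win >= 3) depth <- as.integer(round(stats::runmed(depth, win)))
  list(depthPx = depth, fallback = FALSE)
}

#' Test a component for a back shadow
#'
#' Compares the mean intensity of the column band directly beneath the
#' component (from the component bottom to the estimated RPE depth) to the
#' mean of two flanking bands of the same width and depth range, laterally
#' offset by `flankFactor` component widths. Shadow is declared iff
#' beneath/flank < tau. Pixels belonging to any segmented component are
#' excluded from all bands. Windows shorter than `minWindowPx` cannot be
#' tested and return shadow = FALSE with a "window_too_short" flag.
#'
#' @param bscan numeric matrix (z, x).
#' @param component list with element `pixels` (n x 2 matrix of (z, x)
#'   indices), as produced by [extractComponents()].
#' @param params a \linkS4class{ShadowParams}.
#' @param rpeDepth optional precomputed [estimateRpeDepth()] result.
#' @param componentLabels optional integer matrix of per-pixel component
#'   labels (> 0 on any component) used for exclusion.
#' @return list(shadow = logical, ratio = numeric (NA when untestable),
#'   flag = character: "ok", "window_too_short", "no_flank" or
#'   "flat_flank").
#' @export
hasBackShadow <- function(bscan, component, params = ShadowParams(),
                          rpeDepth = NULL, componentLabels = NULL) {
  pix <- component$pixels
  stopifnot(is.matrix(pix), nrow(pix) >= 1)
  H <- nrow(bscan); W <- ncol(bscan)
  if (is.null(rpeDepth)) {
    excl <- if (is.null(componentLabels)) {
      m <- matrix(FALSE, H, W); m[pix] <- TRUE; m
    } else componentLabels > 0L
    rpeDepth <- estimateRpeDepth(bscan, exclude = excl)
  }
  x0 <- min(pix[, 2]); x1 <- max(pix[, 2])
  zb <- max(pix[, 1])
  rpe <- round(stats::median(rpeDepth$depthPx[x0:x1]))
  zTop <- zb + 1L; zBot <- rpe - 1L
  if (zBot - zTop + 1 < params@minWindowPx)
    return(list(shadow = FALSE, ratio = NA_real_, flag = "window_too_short"))
  rows <- zTop:zBot
  w <- x1 - x0 + 1L
  shift <- ceiling(params@flankFactor * w)
  free <- if (is.null(componentLabels)) matrix(TRUE, H, W) else componentLabels == 0L
  bandMean <- function(cols) {
    cols <- cols[cols >= 1 & cols <= W]
    if (!length(cols)) return(NA_real_)
    sel <- free[rows, cols, drop = FALSE]
    if (!any(sel)) return(NA_real_)
    mean(bscan[rows, cols, drop = FALSE][sel])
  }
  beneath <- bandMean(x0:x1)
  flanks <- c(bandMean((x0:x1) - shift - w), bandMean((x0:x1) + shift + w))
  flank <- mean(flanks, na.rm = TRUE)
  if (!is.finite(flank))
    return(list(shadow = FALSE, ratio = NA_real_, flag = "no_flank"))
  if (flank <= 1e-12)
    return(list(shadow = FALSE, ratio = 1, flag = "flat_flank"))
  ratio <- beneath / flank
  list(shadow = ratio < params@tau, ratio = ratio, flag = "ok")
}
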