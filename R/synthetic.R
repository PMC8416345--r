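## Layered-retina OCT phantoms.
##
## A phantom b-scan is a vertical stack of bands: dark vitreous, a bright
## NFL-like band, a dark mid-retina band, a bright RPE-like band (with a
## slight parabolic axial profile so its center is the brightest row), and a
## dim sub-RPE zone. Lesions are physical discs in the (z, x) plane of one
## b-scan: hard exudates at RPE-like reflectivity with an attenuated column
## rendered beneath them, small HRDs at NFL-like reflectivity, and sub-20-um
## noise dots that are visible in the image but absent from the ground-truth
## mask. Speckle is multiplicative gamma noise with mean 1 and never touches
## the mask, which is a pure function of the lesion plan.

.layerProfile <- function(H, layers) {
  prof <- rep(layers[["vitreous"]], H)
  z <- seq_len(H)
  nflTop <- ceiling(layers[["nfl_top"]] * H); nflBot <- floor(layers[["nfl_bot"]] * H)
  rpeTop <- ceiling(layers[["rpe_top"]] * H); rpeBot <- floor(layers[["rpe_bot"]] * H)
  prof[z >= nflTop & z <= nflBot] <- layers[["nfl"]]
  prof[z > nflBot & z < rpeTop] <- layers[["mid"]]
  rpeRows <- z[z >= rpeTop & z <= rpeBot]
  if (length(rpeRows)) {
    ctr <- (rpeTop + rpeBot) / 2
    hw <- max((rpeBot - rpeTop) / 2, 0.5)
    prof[rpeRows] <- layers[["rpe"]] * (1 - 0.3 * ((rpeRows - ctr) / hw)^2)
  }
  prof[z > rpeBot] <- layers[["below"]]
  prof
}

# pixel offsets of a physical disc of diameter `diamUm` at spacing (sz, sx)
.discOffsets <- function(diamUm, sz, sx) {
  r <- diamUm / 2
  mz <- floor(r / sz); mx <- floor(r / sx)
  dz <- rep(-mz:mz, times = 2 * mx + 1)
  dx <- rep(-mx:mx, each = 2 * mz + 1)
  keep <- (dz * sz)^2 + (dx * sx)^2 <= r^2   # always contains (0, 0)
  cbind(dz = dz[keep], dx = dx[keep])
}

.classOfLesion <- function(type) {
  switch(type, hard_exudate = 1L, small_hrd = 2L, noise = 0L)
}

#' Generate a layered-retina OCT phantom with ground-truth annotations
#'
#' Renders the phantom described by `spec`, returning the speckled intensity
#' volume, the noise-free ground-truth label mask (hard exudates = 1, small
#' HRDs = 2; sub-20-um noise dots appear in the image only), and a lesion
#' table. Each lesion record carries the physical Feret diameter measured on
#' the rendered pixel set, so the recorded class is exactly what the rule
#' classifier decides from the mask and rendered shadows.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return A list with elements `volume` (\linkS4class{OCTVolume}), `mask`
#'   (\linkS4class{LabelMask}) and `lesions` (data.frame with columns
#'   bscan, z_px, x_px, diameter_um, class, shadow; pixel coordinates are
#'   1-based).
#' @examples
#' ph <- generateVolume(PhantomSpec(seed = 7L))
#' table(ph$lesions$class)
#' @export
generateVolume <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  set.seed(spec@seed)
  nb <- spec@shape[1]; H <- spec@shape[2]; W <- spec@shape[3]
  sz <- spec@spacingUm[2]; sx <- spec@spacingUm[3]
  layers <- spec@layers
  prof <- .layerProfile(H, layers)

  plan <- data.frame(
    type = rep(c("hard_exudate", "small_hrd", "noise"),
               times = c(spec@nHardExudate, spec@nSmallHrd, spec@nNoise)),
    stringsAsFactors = FALSE)
  nLes <- nrow(plan)

  # lateral geometry: keep lesions clear of borders (flank bands must fit)
  # and of each other (no merged components, uncontaminated flanks)
  wmax <- 2 * ceiling((spec@hardDiamUm[2] / 2) / sx) + 1
  xmargin <- ceiling(wmax * 3) + 3
  minSep <- max(50, ceiling(4.5 * wmax))
  if (2 * xmargin >= W)
    stop("grid too narrow for the requested lesion diameters")
  # fixed lateral slots (jittered by a few px) keep lesions, their shadows
  # and their flank bands disjoint by construction
  slotsX <- seq(xmargin + 1, W - xmargin, by = minSep)
  combos <- expand.grid(b = seq_len(nb), x = slotsX)
  if (nLes > nrow(combos))
    stop(sprintf("lesion plan infeasible: %d lesions exceed the %d slots of a %d x %d x %d grid",
                 nLes, nrow(combos), nb, H, W))

  nflBot <- floor(layers[["nfl_bot"]] * H)
  rpeTop <- ceiling(layers[["rpe_top"]] * H)

  img <- array(0, dim = c(nb, H, W))
  for (b in seq_len(nb)) img[b, , ] <- matrix(prof, H, W)
  mask <- array(0L, dim = c(nb, H, W))

  pick <- sample.int(nrow(combos), nLes)
  lesions <- vector("list", nLes)
  for (li in seq_len(nLes)) {
    type <- plan$type[li]
    b <- combos$b[pick[li]]
    x0 <- combos$x[pick[li]] + sample(-4:4, 1)
    rng <- switch(type, hard_exudate = spec@hardDiamUm,
                  small_hrd = spec@smallDiamUm, noise = spec@noiseDiamUm)
    refl <- switch(type, hard_exudate = layers[["rpe"]],
                   small_hrd = layers[["nfl"]], noise = layers[["nfl"]])
    placed <- FALSE
    for (try in 1:300) {
      d <- runif(1, rng[1], rng[2])
      off <- if (type == "noise") {
        # sub-lateral-pixel scatterer: lights up one column, axial extent
        # capped so the measured Feret diameter stays below the noise cutoff
        m <- min(floor((19 - sqrt(sz^2 + sx^2)) / (2 * sz)),
                 floor((d / 2) / sz))
        m <- max(m, 0L)
        cbind(dz = -m:m, dx = rep(0L, 2 * m + 1))
      } else {
        .discOffsets(d, sz, sx)
      }
      dMeas <- .feretDiameter(cbind(off[, 1], off[, 2]), c(sz, sx))
      # rendered class must be unambiguous under the 20/40 um rules
      ok <- switch(type,
        hard_exudate = dMeas > 42,
        small_hrd = dMeas >= 21 && dMeas <= 39,
        noise = dMeas <= 18.5)
      if (!ok) next
      az <- max(abs(off[, 1])); ax <- max(abs(off[, 2]))
      zmin <- nflBot + az + 4
      zmax <- rpeTop - az - 18
      if (zmax < zmin)
        stop(sprintf("lesion of %.0f um does not fit the axial band of a %d-px deep b-scan",
                     d, H))
      z0 <- round(runif(1, zmin, zmax))
      zz <- z0 + off[, 1]; xx <- x0 + off[, 2]
      idx <- cbind(b, zz, xx)
      img[idx] <- refl
      cls <- .classOfLesion(type)
      if (cls > 0L) mask[idx] <- cls
      if (type == "hard_exudate") {
        # back shadow: attenuate the full column beneath the lesion
        zb <- max(zz)
        cols <- seq(min(xx), max(xx))
        if (zb < H) img[b, (zb + 1):H, cols] <- img[b, (zb + 1):H, cols] * spec@shadowFactor
      }
      lesions[[li]] <- data.frame(
        bscan = b, z_px = z0, x_px = x0, diameter_um = dMeas,
        class = type, shadow = (type == "hard_exudate"))
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf("could not place a %s lesion after 300 tries (grid %d x %d x %d)",
                   type, nb, H, W))
  }
  lesions <- if (nLes) do.call(rbind, lesions)[order(seq_len(nLes)), , drop = FALSE]
             else data.frame(bscan = integer(), z_px = integer(), x_px = integer(),
                             diameter_um = numeric(), class = character(),
                             shadow = logical())
  rownames(lesions) <- NULL

  if (spec@speckleVar > 0) {
    shape <- 1 / spec@speckleVar
    img <- img * array(rgamma(length(img), shape = shape, scale = 1 / shape),
                       dim = dim(img))
  }
  img <- pmin(pmax(img, 0), 1)
  img <- round(img * 65535) / 65535      # 16-bit grid: MetaImage round trips exactly

  list(volume = OCTVolume(img, spacingUm = spec@spacingUm),
       mask = LabelMask(mask, spacingUm = spec@spacingUm),
       lesions = lesions)
}

#' Simulate a second rater by perturbing a label mask
#'
#' Each connected component (per b-scan, 8-connected) is independently
#' dropped with probability `dropProb`, class-flipped (hard exudate <->
#' small HRD) with probability `flipProb`, and dilated or eroded by a radius
#' drawn uniformly from {-jitterPx, ..., jitterPx} (Chebyshev metric). A
#' zero-noise spec reproduces the input exactly.
#'
#' @param mask a \linkS4class{LabelMask}.
#' @param noise a \linkS4class{RaterNoiseSpec}.
#' @return A perturbed \linkS4class{LabelMask}.
#' @export
simulateRater <- function(mask, noise) {
  stopifnot(is(mask, "LabelMask"), is(noise, "RaterNoiseSpec"))
  set.seed(noise@seed)
  d <- dim(mask)
  out <- array(0L, dim = d)
  jmax <- as.integer(round(noise@jitterPx))
  for (b in seq_len(d[1])) {
    sl <- mask@labels[b, , ]
    if (!any(sl > 0L)) next
    lab <- label8(matrix(as.integer(sl > 0L), d[2], d[3]))
    res <- matrix(0L, d[2], d[3])
    for (k in seq_len(max(lab))) {
      pix <- which(lab == k, arr.ind = TRUE)
      cls <- sl[pix[1, 1], pix[1, 2]]
      if (runif(1) < noise@dropProb) next
      if (runif(1) < noise@flipProb) cls <- c(2L, 1L)[cls]
      j <- if (jmax > 0L) sample(seq(-jmax, jmax), 1) else 0L
      pix <- .morphJitter(pix, j, d[2], d[3])
      if (nrow(pix)) res[pix] <- cls
    }
    out[b, , ] <- res
  }
  LabelMask(out, spacingUm = mask@spacingUm)
}

# Chebyshev dilation (j > 0) or erosion (j < 0) of a pixel set
.morphJitter <- function(pix, j, H, W) {
  if (j == 0L || nrow(pix) == 0L) return(pix)
  r <- abs(j)
  offs <- expand.grid(dz = -r:r, dx = -r:r)
  if (j > 0L) {
    zz <- outer(pix[, 1], offs$dz, `+`)
    xx <- outer(pix[, 2], offs$dx, `+`)
    res <- unique(cbind(as.vector(zz), as.vector(xx)))
    res <- res[res[, 1] >= 1 & res[, 1] <= H & res[, 2] >= 1 & res[, 2] <= W, ,
               drop = FALSE]
    return(res)
  }
  inset <- matrix(FALSE, H, W); inset[pix] <- TRUE
  keep <- vapply(seq_len(nrow(pix)), function(i) {
    zz <- pix[i, 1] + offs$dz; xx <- pix[i, 2] + offs$dx
    all(zz >= 1 & zz <= H & xx >= 1 & xx <= W) && all(inset[cbind(zz, xx)])
  }, logical(1))
  pix[keep, , drop = FALSE]
}

#' Generate an independent set of phantom volumes
#'
#' Per-volume seeds are drawn once from the master seed, so the whole set is
#' reproducible bit-for-bit while volumes differ pairwise in lesion
#' placement.
#'
#' @param spec a \linkS4class{PhantomSpec} template (its seed is ignored).
#' @param nVolumes number of phantoms (>= 1).
#' @param seed master random seed.
#' @return A list of `nVolumes` lists as returned by [generateVolume()].
#' @export
generateTrainingSet <- function(spec, nVolumes, seed = 1L) {
  stopifnot(nVolumes >= 1)
  set.seed(seed)
  seeds <- sample.int(2^31 - 2, nVolumes)
  lapply(seeds, function(s) {
    sp <- spec
    sp@seed <- as.integer(s)
    generateVolume(sp)
  })
}

#' Write a lesion ground-truth table as CSV
#'
#' @param lesions data.frame as returned in `generateVolume()$lesions`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeLesionCsv <- function(lesions, path) {
  utils::write.csv(lesions, path, row.names = FALSE)
  invisible(path)
}
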