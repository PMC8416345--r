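#' Extract 8-connected components from a binary b-scan mask
#'
#' Maximal 8-connected foreground regions of one 2-D mask, labelled once
#' each in first-encounter order. Components are never merged across
#' b-scans; callers iterate slices.
#'
#' @param mask integer/logical matrix (z, x); non-zero is foreground.
#' @return list of components, each `list(id, pixels, bbox)` with `pixels`
#'   an n x 2 matrix of (z, x) indices and `bbox = c(z0, z1, x0, x1)`.
#' @examples
#' m <- matrix(0L, 4, 4); m[1, 1] <- 1L; m[2, 2] <- 1L   # diagonal touch
#' length(extractComponents(m))                          # 1 component
#' @export
extractComponents <- function(mask) {
  stopifnot(is.matrix(mask))
  lab <- label8(matrix(as.integer(mask != 0), nrow(mask), ncol(mask)))
  n <- max(lab)
  if (n == 0L) return(list())
  idx <- which(lab > 0L, arr.ind = TRUE)
  byComp <- split(seq_len(nrow(idx)), lab[idx])
  lapply(seq_len(n), function(k) {
    pix <- idx[byComp[[as.character(k)]], , drop = FALSE]
    colnames(pix) <- c("z", "x")
    list(id = k, pixels = pix,
         bbox = c(min(pix[, 1]), max(pix[, 1]), min(pix[, 2]), max(pix[, 2])))
  })
}

# max pairwise physical distance between pixel centers plus one in-plane
# pixel diagonal (so single pixels have a physically meaningful size)
.feretDiameter <- function(pix, spacingZX) {
  pts <- cbind(pix[, 1] * spacingZX[1], pix[, 2] * spacingZX[2])
  diag <- sqrt(sum(spacingZX^2))
  if (nrow(pts) == 1L) return(diag)
  if (nrow(pts) > 40L) {
    hull <- grDevices::chull(pts)
    if (length(hull) >= 2L) pts <- pts[hull, , drop = FALSE]
  }
  max(stats::dist(pts)) + diag
}

#' Physical Feret diameter of a component
#'
#' Maximum pairwise Euclidean distance between pixel centers after scaling
#' z by the axial and x by the lateral spacing, plus one in-plane pixel
#' diagonal to account for pixel extent.
#'
#' @param component list with element `pixels` (n x 2 matrix of (z, x)).
#' @param spacingUm numeric(3) volume spacing (inter-slice, axial, lateral)
#'   in um, or numeric(2) in-plane spacing (axial, lateral).
#' @return Diameter in micrometres.
#' @examples
#' comp <- list(pixels = cbind(5, 5))
#' physicalDiameter(comp, c(46.875, 2.2599, 11.71875))  # one pixel diagonal
#' @export
physicalDiameter <- function(component, spacingUm) {
  sp <- if (length(spacingUm) == 3L) spacingUm[2:3] else spacingUm
  stopifnot(all(sp > 0), nrow(component$pixels) >= 1)
  .feretDiameter(component$pixels, sp)
}

#' Classify one HRD candidate by physical size and back shadow
#'
#' The classification rules: particles smaller than 20 um are noise and are
#' excluded; particles larger than 40 um with back shadowing are hard
#' exudates; everything else (including shadow-less large particles and the
#' exact 20/40 um boundaries) is a small HRD.
#'
#' @param diameterUm physical diameter in micrometres (> 0).
#' @param shadow logical back-shadow flag.
#' @param thresholds numeric(2): the noise and hard-exudate cutoffs,
#'   default c(20, 40) um.
#' @return One of "noise", "small_hrd", "hard_exudate".
#' @examples
#' classifyComponent(50, TRUE)    # hard_exudate
#' classifyComponent(50, FALSE)   # small_hrd
#' classifyComponent(15, TRUE)    # noise
#' @export
classifyComponent <- function(diameterUm, shadow, thresholds = c(20, 40)) {
  if (!is.finite(diameterUm) || diameterUm <= 0)
    stop("diameterUm must be a positive finite value")
  stopifnot(thresholds[1] > 0, thresholds[2] > thresholds[1])
  if (diameterUm < thresholds[1]) return("noise")
  if (diameterUm > thresholds[2] && isTRUE(shadow)) return("hard_exudate")
  "small_hrd"
}

#' Extract, measure, shadow-test and classify all components of a volume
#'
#' Runs per b-scan: 8-connected component extraction on the binary
#' segmentation, physical Feret diameter measurement, the back-shadow test
#' (skipped for sub-noise-threshold components, whose class is already
#' decided), and the three-rule classification. Noise components are
#' removed from the output mask; every remaining foreground pixel is
#' relabelled to its component's class.
#'
#' @param binary integer/logical array (b, z, x): the segmentation.
#' @param volume the matching \linkS4class{OCTVolume} (intensities are
#'   needed for the shadow test).
#' @param params a \linkS4class{ShadowParams}.
#' @param thresholds numeric(2) classification cutoffs in um.
#' @return list(mask = classified \linkS4class{LabelMask}, components =
#'   data.frame(id, bscan, n_pixels, mean_x_px, diameter_um, shadow, ratio,
#'   flag, class) sorted by (bscan, id)).
#' @export
classifyAll <- function(binary, volume, params = ShadowParams(),
                        thresholds = c(20, 40)) {
  stopifnot(is(volume, "OCTVolume"))
  d <- dim(volume)
  stopifnot(identical(dim(binary), d))
  spacing <- volume@spacingUm
  out <- array(0L, d)
  rows <- list()
  for (b in seq_len(d[1])) {
    sl <- matrix(as.integer(binary[b, , ] != 0), d[2], d[3])
    comps <- extractComponents(sl)
    if (!length(comps)) next
    img <- volume@voxels[b, , ]
    lab <- label8(sl)
    rpe <- estimateRpeDepth(img, exclude = lab > 0L)
    slOut <- matrix(0L, d[2], d[3])
    for (comp in comps) {
      dUm <- .feretDiameter(comp$pixels, spacing[2:3])
      if (dUm < thresholds[1]) {
        cls <- "noise"; sh <- list(shadow = FALSE, ratio = NA_real_, flag = "noise")
      } else {
        sh <- hasBackShadow(img, comp, params, rpeDepth = rpe,
                            componentLabels = lab)
        cls <- classifyComponent(dUm, sh$shadow, thresholds)
      }
      if (cls != "noise")
        slOut[comp$pixels] <- if (cls == "hard_exudate") 1L else 2L
      rows[[length(rows) + 1L]] <- data.frame(
        id = comp$id, bscan = b, n_pixels = nrow(comp$pixels),
        mean_x_px = mean(comp$pixels[, 2]), diameter_um = dUm,
        shadow = sh$shadow, ratio = sh$ratio, flag = sh$flag, class = cls)
    }
    out[b, , ] <- slOut
  }
  components <- if (length(rows)) do.call(rbind, rows)
    else data.frame(id = integer(), bscan = integer(), n_pixels = integer(),
                    mean_x_px = numeric(), diameter_um = numeric(),
                    shadow = logical(), ratio = numeric(), flag = character(),
                    class = character())
  components <- components[order(components$bscan, components$id), ]
  rownames(components) <- NULL
  list(mask = LabelMask(out, spacingUm = spacing), components = components)
}

# components of an already-classified mask (classes known, no shadow test);
# used when comparing two annotation sources
.componentsFromClassified <- function(mask) {
  d <- dim(mask)
  rows <- list()
  for (b in seq_len(d[1])) {
    sl <- mask@labels[b, , ]
    if (!any(sl > 0L)) next
    for (comp in extractComponents(sl != 0L)) {
      cls <- sl[comp$pixels[1, 1], comp$pixels[1, 2]]
      rows[[length(rows) + 1L]] <- data.frame(
        id = comp$id, bscan = b, n_pixels = nrow(comp$pixels),
        mean_x_px = mean(comp$pixels[, 2]),
        diameter_um = .feretDiameter(comp$pixels, mask@spacingUm[2:3]),
        shadow = NA, ratio = NA_real_, flag = "from_mask",
        class = c("hard_exudate", "small_hrd")[cls])
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(id = integer(), bscan = integer(), n_pixels = integer(),
                  mean_x_px = numeric(), diameter_um = numeric(),
                  shadow = logical(), ratio = numeric(), flag = character(),
                  class = character())
}
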