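#' En-face physical centroid of a component
#'
#' The slow-axis position is the b-scan center, (b - 0.5) x inter-slice
#' spacing for a 1-based index b; the lateral position is the mean lateral
#' pixel center, (mean(x) - 0.5) x lateral spacing. Both in millimetres.
#'
#' @param bscan 1-based b-scan index.
#' @param meanXPx mean 1-based lateral pixel index of the component.
#' @param spacingUm numeric(3) spacing (inter-slice, axial, lateral) in um.
#' @return numeric(2): (slow-axis mm, lateral mm).
#' @export
enfaceCentroid <- function(bscan, meanXPx, spacingUm) {
  c((bscan - 0.5) * spacingUm[1], (meanXPx - 0.5) * spacingUm[3]) / 1000
}

#' Fovea-centered region-of-interest specification
#'
#' The regions are the full scan and the 3 mm and 1 mm diameter circles
#' centered on the fovea. The fovea defaults to the geometric scan center
#' (macular cubes are acquired fovea-centered); pass `centerMm` to override
#' for decentered scans.
#'
#' @param shape integer(3) grid shape (b, z, x).
#' @param spacingUm numeric(3) spacing in um.
#' @param centerMm optional numeric(2) fovea center (slow, lateral) in mm.
#' @return list(centerMm, regions).
#' @export
roiSpec <- function(shape, spacingUm, centerMm = NULL) {
  if (is.null(centerMm))
    centerMm <- c(shape[1] * spacingUm[1], shape[3] * spacingUm[3]) / 2000
  list(centerMm = centerMm,
       regions = c("full_6x6", "circle_3mm", "circle_1mm"))
}

#' Regions containing an en-face centroid
#'
#' The full scan always; a circle of diameter d iff the Euclidean en-face
#' distance from the fovea center is < d/2, so the membership sets are
#' nested.
#'
#' @param centroidMm numeric(2) en-face position (slow, lateral), mm.
#' @param roi from [roiSpec()].
#' @return Character vector of region names.
#' @export
roiMembership <- function(centroidMm, roi) {
  d <- sqrt(sum((centroidMm - roi$centerMm)^2))
  regions <- "full_6x6"
  if (d < 1.5) regions <- c(regions, "circle_3mm")
  if (d < 0.5) regions <- c(regions, "circle_1mm")
  regions
}

#' Summarize classified components into per-ROI area and count
#'
#' Count is the number of components whose centroid lies in the region; a
#' component contributes its entire area (n_pixels x axial x lateral pixel
#' area, in mm^2) to every region containing its centroid — lesions are
#' never split at circle boundaries. The total row is hard exudates plus
#' small HRDs, identically for area and count.
#'
#' @param components classified component table from [classifyAll()] (noise
#'   rows are ignored; unclassified rows are an error).
#' @param spacingUm numeric(3) spacing in um.
#' @param shape integer(3) grid shape (for the default fovea center).
#' @param foveaMm optional numeric(2) fovea override, mm.
#' @return data.frame(roi, class, area_mm2, count): 3 regions x
#'   {hard_exudate, small_hrd, total_hrd}.
#' @export
summarizeHRD <- function(components, spacingUm, shape, foveaMm = NULL) {
  roi <- roiSpec(shape, spacingUm, foveaMm)
  if (nrow(components) && any(is.na(components$class)))
    stop("unclassified component present")
  keep <- components[components$class %in% c("hard_exudate", "small_hrd"), ,
                     drop = FALSE]
  pxAreaMm2 <- spacingUm[2] * spacingUm[3] * 1e-6
  grid <- expand.grid(roi = roi$regions,
                      class = c("total_hrd", "hard_exudate", "small_hrd"),
                      stringsAsFactors = FALSE)
  grid$area_mm2 <- 0; grid$count <- 0L
  if (nrow(keep)) {
    for (i in seq_len(nrow(keep))) {
      ctr <- enfaceCentroid(keep$bscan[i], keep$mean_x_px[i], spacingUm)
      regions <- roiMembership(ctr, roi)
      area <- keep$n_pixels[i] * pxAreaMm2
      for (rg in regions) {
        for (cl in c(keep$class[i], "total_hrd")) {
          j <- grid$roi == rg & grid$class == cl
          grid$area_mm2[j] <- grid$area_mm2[j] + area
          grid$count[j] <- grid$count[j] + 1L
        }
      }
    }
  }
  grid
}

#' Write a per-volume HRD summary as CSV
#'
#' @param summary data.frame from [summarizeHRD()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSummaryCsv <- function(summary, path) {
  utils::write.csv(summary, path, row.names = FALSE)
  invisible(path)
}
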