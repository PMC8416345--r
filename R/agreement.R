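#' Dice overlap between two label masks
#'
#' 2|A n B| / (|A| + |B|) over pixels of the given class (or any HRD class
#' when `label` is NULL). Two empty sets agree vacuously: the Dice is
#' defined as 1.
#'
#' @param a,b arrays or matrices of identical shape (label masks or the
#'   \linkS4class{LabelMask} objects themselves).
#' @param label class label to compare (1 or 2), or NULL for any-HRD.
#' @return Dice coefficient in [0, 1].
#' @examples
#' m <- matrix(c(1, 1, 0, 0), 2)
#' diceCoef(m, m)   # 1
#' @export
diceCoef <- function(a, b, label = NULL) {
  if (is(a, "LabelMask")) a <- a@labels
  if (is(b, "LabelMask")) b <- b@labels
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  A <- if (is.null(label)) a != 0 else a == label
  B <- if (is.null(label)) b != 0 else b == label
  nA <- sum(A); nB <- sum(B)
  if (nA + nB == 0) return(1)
  2 * sum(A & B) / (nA + nB)
}

# two-way ANOVA mean squares for an n x 2 rating matrix
.iccMeanSquares <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  grand <- mean(Y)
  rowm <- rowMeans(Y); colm <- colMeans(Y)
  MSR <- k * sum((rowm - grand)^2) / (n - 1)
  MSC <- n * sum((colm - grand)^2) / (k - 1)
  resid <- Y - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand
  MSE <- sum(resid^2) / ((n - 1) * (k - 1))
  list(n = n, k = k, MSR = MSR, MSC = MSC, MSE = MSE)
}

#' Intraclass correlation between two measurement methods
#'
#' Default is ICC(2,1): two-way random effects, absolute agreement, single
#' measures, (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n), with the
#' McGraw-Wong F-based 95% confidence interval. The consistency form
#' ICC(3,1) is available via `type = "consistency"`. Zero total variance
#' leaves the ICC undefined (NA), not 1.
#'
#' @param a,b numeric vectors of paired per-volume values (n >= 2; n >= 5
#'   recommended).
#' @param type "agreement" (default) or "consistency".
#' @param conf confidence level, default 0.95.
#' @return list(icc, lo, hi, type).
#' @export
iccAgreement <- function(a, b, type = c("agreement", "consistency"),
                         conf = 0.95) {
  type <- match.arg(type)
  stopifnot(length(a) == length(b), length(a) >= 2,
            all(is.finite(a)), all(is.finite(b)))
  Y <- cbind(a, b)
  if (max(Y) - min(Y) < .Machine$double.eps * 100)
    return(list(icc = NA_real_, lo = NA_real_, hi = NA_real_, type = type))
  ms <- .iccMeanSquares(Y)
  n <- ms$n; k <- ms$k
  alpha <- 1 - conf
  if (type == "consistency") {
    icc <- (ms$MSR - ms$MSE) / (ms$MSR + (k - 1) * ms$MSE)
    if (ms$MSE <= 0) return(list(icc = icc, lo = NA_real_, hi = NA_real_, type = type))
    F0 <- ms$MSR / ms$MSE
    FL <- F0 / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    FU <- F0 * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    return(list(icc = icc, lo = (FL - 1) / (FL + k - 1),
                hi = (FU - 1) / (FU + k - 1), type = type))
  }
  icc <- (ms$MSR - ms$MSE) / (ms$MSR + (k - 1) * ms$MSE +
                                k * (ms$MSC - ms$MSE) / n)
  aa <- (k * icc) / (n * (1 - icc))
  bb <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (aa * ms$MSC + bb * ms$MSE)^2 /
    ((aa * ms$MSC)^2 / (k - 1) + (bb * ms$MSE)^2 / ((n - 1) * (k - 1)))
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (ms$MSR - FL * ms$MSE) /
    (FL * (k * ms$MSC + (k * n - k - n) * ms$MSE) + n * ms$MSR)
  hi <- n * (FU * ms$MSR - ms$MSE) /
    (k * ms$MSC + (k * n - k - n) * ms$MSE + n * FU * ms$MSR)
  list(icc = icc, lo = lo, hi = hi, type = type)
}

#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson correlation; the p-value comes from the t transform with
#' n - 2 degrees of freedom. A zero-variance series leaves r undefined
#' (NA), reported as such.
#'
#' @param a,b numeric vectors of equal length (n >= 3 for a p-value).
#' @return list(r, p).
#' @export
pearsonCor <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r = NA_real_, p = NA_real_))
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Bland-Altman mean difference and 95% limits of agreement
#'
#' Differences are a - b; the limits of agreement are mean +- 1.96 x sample
#' SD (n - 1 denominator), per conventional Bland-Altman practice.
#'
#' @param a,b numeric vectors of equal length (n >= 2).
#' @return list(meanDiff, sdDiff, loa = c(lower, upper)).
#' @export
blandAltman <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  m <- mean(d); s <- stats::sd(d)
  list(meanDiff = m, sdDiff = s, loa = c(m - 1.96 * s, m + 1.96 * s))
}

#' Correlation between per-volume Dice and lesion burden
#'
#' Smaller targets are harder to delineate, so the per-volume Dice tends to
#' rise with the labelled area; this names that report field.
#'
#' @param dice per-volume Dice coefficients.
#' @param areas per-volume total HRD areas (same order).
#' @return list(r, p) from [pearsonCor()].
#' @export
diceAreaCorrelation <- function(dice, areas) {
  pearsonCor(dice, areas)
}

#' Full agreement report between two annotation sources
#'
#' Assembles, for a matched set of volumes: per-class Dice (mean and SD
#' across volumes; classes total HRD, hard exudate, small HRD) and, for
#' each region x parameter (area and count of the three classes), the
#' ICC(2,1) with 95% CI, the Pearson correlation with p, and the
#' Bland-Altman mean difference with 95% limits of agreement.
#'
#' @param masksA,masksB lists of classified \linkS4class{LabelMask}
#'   objects, matched by position.
#' @param summariesA,summariesB lists of [summarizeHRD()] tables for the
#'   same volumes.
#' @return list(dice = data.frame(class, mean, sd, n), stats =
#'   data.frame(roi, parameter, icc, icc_lo, icc_hi, r, p, mean_diff,
#'   loa_lo, loa_hi)).
#' @export
buildAgreementReport <- function(masksA, masksB, summariesA, summariesB) {
  stopifnot(length(masksA) == length(masksB),
            length(summariesA) == length(summariesB),
            length(masksA) == length(summariesA))
  nV <- length(masksA)
  classes <- c(total_hrd = NA, hard_exudate = 1, small_hrd = 2)
  diceTab <- do.call(rbind, lapply(seq_along(classes), function(ci) {
    lbl <- classes[[ci]]
    vals <- vapply(seq_len(nV), function(i)
      diceCoef(masksA[[i]], masksB[[i]], label = if (is.na(lbl)) NULL else lbl),
      numeric(1))
    data.frame(class = names(classes)[ci], mean = mean(vals),
               sd = if (nV > 1) stats::sd(vals) else NA_real_, n = nV)
  }))
  rois <- unique(summariesA[[1]]$roi)
  rows <- list()
  for (rg in rois) {
    for (cl in names(classes)) {
      for (meas in c("area_mm2", "count")) {
        series <- function(summ) vapply(summ, function(s)
          s[[meas]][s$roi == rg & s$class == cl], numeric(1))
        va <- series(summariesA); vb <- series(summariesB)
        icc <- iccAgreement(va, vb)
        pc <- pearsonCor(va, vb)
        ba <- blandAltman(va, vb)
        rows[[length(rows) + 1L]] <- data.frame(
          roi = rg, parameter = paste(cl, meas, sep = "."),
          icc = icc$icc, icc_lo = icc$lo, icc_hi = icc$hi,
          r = pc$r, p = pc$p, mean_diff = ba$meanDiff,
          loa_lo = ba$loa[1], loa_hi = ba$loa[2])
      }
    }
  }
  list(dice = diceTab, stats = do.call(rbind, rows))
}

#' Write an agreement report as JSON and CSV
#'
#' The JSON is nested region -> parameter -> statistic; the CSV is the flat
#' stats table with the Dice rows appended.
#'
#' @param report from [buildAgreementReport()].
#' @param jsonPath,csvPath output paths (either may be NULL to skip).
#' @return Invisibly, the report.
#' @export
writeAgreementReport <- function(report, jsonPath = NULL, csvPath = NULL) {
  if (!is.null(jsonPath)) {
    nested <- list(dice = report$dice)
    for (rg in unique(report$stats$roi)) {
      sub <- report$stats[report$stats$roi == rg, ]
      nested[[rg]] <- lapply(split(sub, sub$parameter), function(r)
        as.list(r[setdiff(names(r), c("roi", "parameter"))]))
    }
    jsonlite::write_json(nested, jsonPath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  if (!is.null(csvPath)) utils::write.csv(report$stats, csvPath, row.names = FALSE)
  invisible(report)
}
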