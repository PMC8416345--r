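#' Run the full HRD quantification pipeline on one volume
#'
#' segment -> shadow test -> classify -> quantify. The segmentation source
#' is one of: a trained network (`method = "network"`), the deterministic
#' threshold reference (`method = "threshold"`), or an externally supplied
#' binary/ground-truth mask (`method = "oracle"`).
#'
#' @param volume an \linkS4class{OCTVolume} or a path to a MetaImage file.
#' @param segmentation list describing the source: `list(method =
#'   "threshold", threshold =, band =)`, `list(method = "network", net =,
#'   threshold = 0.5)`, or `list(method = "oracle", mask = LabelMask or
#'   binary array)`.
#' @param shadowParams a \linkS4class{ShadowParams}.
#' @param thresholds numeric(2) classification cutoffs in um.
#' @param foveaMm optional numeric(2) fovea center override, mm.
#' @param outDir optional output directory: writes the classified mask
#'   (`mask.mha`), component table (`components.csv`), summary
#'   (`summary.csv`) and a run manifest (`manifest.json`).
#' @return list(mask, components, summary).
#' @export
runPipeline <- function(volume, segmentation = list(method = "threshold",
                                                    threshold = 0.35),
                        shadowParams = ShadowParams(),
                        thresholds = c(20, 40), foveaMm = NULL,
                        outDir = NULL) {
  if (is.character(volume)) volume <- readMetaImage(volume)
  stopifnot(is(volume, "OCTVolume"))
  binary <- switch(segmentation$method,
    threshold = thresholdSegment(volume, segmentation$threshold,
                                 segmentation$band),
    network = binarize(segmentProbability(segmentation$net, volume),
                       segmentation$threshold %||% 0.5),
    oracle = {
      m <- segmentation$mask
      if (is(m, "LabelMask")) m <- m@labels
      array(as.integer(m != 0), dim = dim(volume))
    },
    stop(sprintf("unknown segmentation method '%s'", segmentation$method)))
  cls <- classifyAll(binary, volume, shadowParams, thresholds)
  summary <- summarizeHRD(cls$components, volume@spacingUm, dim(volume),
                          foveaMm)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeMetaImage(cls$mask, file.path(outDir, "mask.mha"))
    utils::write.csv(cls$components, file.path(outDir, "components.csv"),
                     row.names = FALSE)
    writeSummaryCsv(summary, file.path(outDir, "summary.csv"))
    .writeManifest(file.path(outDir, "manifest.json"), list(
      stage = "pipeline", segmentation_method = segmentation$method,
      thresholds_um = thresholds, shadow_tau = shadowParams@tau,
      n_components = nrow(cls$components)))
  }
  list(mask = cls$mask, components = cls$components, summary = summary)
}

#' Agreement analysis between two sets of classified masks
#'
#' Summarizes each classified mask per region, then assembles the full
#' agreement report (Dice, ICC, Pearson, Bland-Altman for all six
#' parameters in all three regions).
#'
#' @param masksA,masksB named lists of classified \linkS4class{LabelMask}
#'   objects; names are volume ids and must match.
#' @param foveaMm optional fovea override, mm.
#' @param outDir optional directory for `agreement.json` / `agreement.csv`.
#' @return The report from [buildAgreementReport()].
#' @export
runAgreement <- function(masksA, masksB, foveaMm = NULL, outDir = NULL) {
  idsA <- names(masksA); idsB <- names(masksB)
  if (!setequal(idsA, idsB)) {
    missing <- c(setdiff(idsA, idsB), setdiff(idsB, idsA))
    stop(sprintf("volume ids differ between sources: %s",
                 paste(missing, collapse = ", ")))
  }
  masksB <- masksB[idsA]
  summarize1 <- function(m)
    summarizeHRD(.componentsFromClassified(m), m@spacingUm, dim(m), foveaMm)
  summariesA <- lapply(masksA, summarize1)
  summariesB <- lapply(masksB, summarize1)
  report <- buildAgreementReport(masksA, masksB, summariesA, summariesB)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeAgreementReport(report, file.path(outDir, "agreement.json"),
                         file.path(outDir, "agreement.csv"))
    .writeManifest(file.path(outDir, "manifest.json"),
                   list(stage = "agreement", n_volumes = length(masksA),
                        ids = idsA))
  }
  report
}

#' Generate a phantom dataset on disk
#'
#' Writes `volume_###.mha`, `mask_###.mha` and `lesions_###.csv` per
#' phantom plus a manifest recording the seed and file list.
#'
#' @param spec a \linkS4class{PhantomSpec} template.
#' @param n number of phantoms.
#' @param seed master seed.
#' @param outDir output directory.
#' @return Invisibly, the manifest list.
#' @export
runSimulate <- function(spec, n, seed, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set <- generateTrainingSet(spec, n, seed)
  files <- lapply(seq_along(set), function(i) {
    v <- sprintf("volume_%03d.mha", i)
    m <- sprintf("mask_%03d.mha", i)
    l <- sprintf("lesions_%03d.csv", i)
    writeMetaImage(set[[i]]$volume, file.path(outDir, v))
    writeMetaImage(set[[i]]$mask, file.path(outDir, m))
    writeLesionCsv(set[[i]]$lesions, file.path(outDir, l))
    list(volume = v, mask = m, lesions = l)
  })
  manifest <- list(stage = "simulate", seed = seed, n = n,
                   shape = spec@shape, spacing_um = spec@spacingUm,
                   files = files)
  .writeManifest(file.path(outDir, "manifest.json"), manifest)
  invisible(manifest)
}

.writeManifest <- function(path, fields) {
  fields$package <- "hrdq"
  fields$version <- as.character(utils::packageVersion("hrdq"))
  fields$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(fields, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any of: `geometry` (extent_mm, shape),
#'   `segmentation`, `shadow` (tau, flankFactor, minWindowPx),
#'   `thresholds_um`, `fovea_mm`, `seed`.
#' @return A named list with \linkS4class{ShadowParams} filled in.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  sh <- cfg$shadow %||% list()
  cfg$shadowParams <- ShadowParams(
    tau = sh$tau %||% 0.75,
    flankFactor = sh$flankFactor %||% 2,
    minWindowPx = sh$minWindowPx %||% 10)
  cfg$thresholds_um <- as.numeric(cfg$thresholds_um %||% c(20, 40))
  if (cfg$thresholds_um[1] <= 0 || cfg$thresholds_um[2] <= cfg$thresholds_um[1])
    stop("thresholds_um must be positive and increasing")
  cfg
}
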