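#' Run the end-to-end mapping pipeline on a synthetic pullback
#'
#' Chains phantom generation, preprocessing, segmentation, calcium
#' quantification and evaluation, writing \code{lesions.jsonl} (one JSON
#' line per plaque record plus a final lesion-summary line) and
#' \code{report.json} to \code{out_dir}. In truth mode the ground-truth
#' label map stands in for the network prediction (probabilities are its
#' one-hot encoding), which exercises quantification and evaluation
#' deterministically; otherwise a trained checkpoint is required and the
#' network segments the preprocessed frames. Every output embeds the seed
#' and a hash of the generating configuration.
#'
#' @param phantom_cfg a \linkS4class{PhantomConfig}.
#' @param out_dir output directory (created if needed).
#' @param mode \code{"truth"} or \code{"model"}.
#' @param checkpoint path to a saved network (required for mode "model").
#' @param pre a \linkS4class{PreprocessConfig} (mode "model").
#' @param lesion_mode,interval_mm lesion-length convention (see
#'   \code{\link{lesionLength}}).
#' @return Invisibly, a list with \code{plaques}, \code{summary}
#'   (\linkS4class{LesionSummary}), \code{report}
#'   (\linkS4class{EvalReport}), and the output paths.
#' @export
runPipeline <- function(phantom_cfg, out_dir, mode = c("truth", "model"),
                        checkpoint = NULL, pre = preprocessConfig(),
                        lesion_mode = "every_frame", interval_mm = 1) {
  mode <- match.arg(mode)
  if (mode == "model" && (is.null(checkpoint) || !file.exists(checkpoint)))
    stop("mode 'model' requires an existing checkpoint file")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  pb <- generatePullback(phantom_cfg)
  prov <- list(seed = phantom_cfg@seed,
               config_hash = configHash(list(
                 n_frames = phantom_cfg@nFrames,
                 n_samples = phantom_cfg@nSamples,
                 n_alines = phantom_cfg@nALines,
                 radial_res_mm = phantom_cfg@radialResMm,
                 frame_spacing_mm = phantom_cfg@frameSpacingMm,
                 plaques = phantom_cfg@plaqueSpecs,
                 seed = phantom_cfg@seed)))
  writePullback(pb$image, file.path(out_dir, "pullback.tiff"),
                file.path(out_dir, "meta.json"), provenance = prov)
  writeLabelMap(pb$labels, file.path(out_dir, "truth.tiff"))

  if (mode == "truth") {
    pred <- pb$labels
  } else {
    net <- loadCheckpoint(checkpoint)
    pred <- segmentPullback(net, pb$image, pre)
    writeLabelMap(pred, file.path(out_dir, "pred.tiff"))
  }

  res <- radialRes(pb$image)
  plq <- extractPlaquesStack(pred, res)
  summ <- quantifyCalcium(pred, res, frameSpacing(pb$image),
                          mode = lesion_mode, interval_mm = interval_mm)

  lesions_path <- file.path(out_dir, "lesions.jsonl")
  con <- file(lesions_path, "w")
  if (nrow(plq)) for (i in seq_len(nrow(plq)))
    writeLines(jsonlite::toJSON(c(as.list(plq[i, ]), prov),
                                auto_unbox = TRUE, digits = NA), con)
  writeLines(jsonlite::toJSON(c(list(record = "lesion_summary"),
                                as.list(summ), prov),
                              auto_unbox = TRUE, digits = NA), con)
  close(con)

  # one-hot probabilities from the predicted labels
  probs <- lapply(seq_len(nFrames(pred)), function(k) {
    lf <- getLabelFrame(pred, k)
    p <- array(0, dim = c(dim(lf), 10L))
    for (cl in 0:9) p[, , cl + 1][lf == cl] <- 1
    p
  })
  report <- tryCatch(
    evaluateSegmentation(probs, labelArray(pb$labels)),
    error = function(e) NULL)
  report_path <- file.path(out_dir, "report.json")
  rep_list <- if (is.null(report)) list() else list(
    per_class_auc = as.list(report@perClassAuc),
    youden_threshold = as.list(report@youdenThreshold),
    confusion = if (nrow(report@confusion)) report@confusion else NULL,
    overall_accuracy = if (length(report@overallAccuracy))
      report@overallAccuracy else NULL)
  jsonlite::write_json(c(rep_list, prov), report_path, auto_unbox = TRUE,
                       digits = NA)

  invisible(list(plaques = plq, summary = summ, report = report,
                 paths = c(lesions = lesions_path, report = report_path)))
}
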