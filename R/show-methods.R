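#' @describeIn waveformParams compact display.
#' @param object object to display.
#' @export
setMethod("show", "WaveformParams", function(object) {
  cat(sprintf("WaveformParams: %g bpm, jitter %.2f, ST %+.2f mV, T polarity %+d\n",
              object@heartRate, object@beatJitter, object@stOffset,
              as.integer(object@tPolarity)))
})

setMethod("show", "SheetSpec", function(object) {
  cat(sprintf("SheetSpec: %d x %d px, minor grid %d px (major every %d), %d x %d leads + rhythm\n",
              object@widthPx, object@heightPx, object@minorGridSpacingPx,
              object@majorGridEvery, object@nLeadRows, object@nLeadCols))
})

setMethod("show", "ECGSheet", function(object) {
  cat(sprintf("ECGSheet [%s]: %d x %d px; signal %d px, grid %d px, label %d px\n",
              object@classLabel, ncol(object@image), nrow(object@image),
              sum(object@signalMask), sum(object@gridMask), sum(object@labelMask)))
})

setMethod("show", "PipelineConfig", function(object) {
  cat(sprintf(paste0("PipelineConfig: crop %.4f x %.4f, open %dx%d, area < %g,",
                     " blur %dx%d (sigma %.2f), NLM p%d/d%d h=%.2f*sigma, HE %s\n"),
              object@cropRatioW, object@cropRatioH, object@morphKernel[1],
              object@morphKernel[2], object@contourAreaMax, object@blurKernel[1],
              object@blurKernel[2], object@blurSigma, object@nlmPatchSize,
              object@nlmPatchDistance, object@nlmHFactor,
              if (object@applyHE) "on" else "off"))
})

setMethod("show", "PreprocessResult", function(object) {
  cat(sprintf("PreprocessResult: final %d x %d, Otsu t = %g%s; stages: %s\n",
              ncol(object@final), nrow(object@final), object@otsuThreshold,
              if (object@degenerate) " (degenerate)" else "",
              paste(names(object@intermediates), collapse = ", ")))
})

setMethod("show", "QualityReport", function(object) {
  cat(sprintf("QualityReport: %d image pairs\n", nrow(object@records)))
  cat("  averages:", paste(sprintf("%s=%.4g", names(object@averages),
                                   object@averages), collapse = ", "), "\n")
})

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(paste0("ModelConfig: input %dx%dx%d, %dx%d filters x%d, %s pool, %s,",
                     " head %s, %s, %s lr=%g, batch %d, epochs %d, classes %d,",
                     " RSF %s, stacks %s\n"),
              object@inputSize[1], object@inputSize[2], object@inputChannels,
              object@filterSize, object@filterSize, object@nFilters,
              object@poolType, object@activation, object@headType, object@loss,
              object@optimizer, object@learningRate, object@batchSize,
              object@epochs, object@nClasses,
              if (object@rsfEnabled) sprintf("on (init %g)", object@rsfInit) else "off",
              paste(object@stackCounts, collapse = "/")))
})

setMethod("show", "InResModel", function(object) {
  cl <- countLayers(object)
  cat(sprintf("InResModel: %d conv+pool layers (%s); %d classes; %s\n",
              cl$total, paste(sprintf("%s=%d", names(cl$perBlock), cl$perBlock),
                              collapse = ", "),
              object@config@nClasses,
              if (nrow(object@history)) sprintf("trained %d epochs", nrow(object@history))
              else "untrained"))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (rows = actual, columns = predicted):\n")
  print(object@counts)
})

setMethod("show", "AblationReport", function(object) {
  cat(sprintf("AblationReport: %d studies, %d candidates (delta = %g)\n",
              length(unique(object@rows$study)), nrow(object@rows), object@delta))
  chosen <- object@rows[object@rows$chosen, c("study", "studyName", "candidate",
                                              "accuracy")]
  print(chosen, row.names = FALSE)
})
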