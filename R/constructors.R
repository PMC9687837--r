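#' Construct beat-template parameters
#'
#' `classWaveformParams()` returns the per-class priors used by the dataset
#' generator: NHB is the baseline morphology; AHB adds strong RR-interval
#' jitter; MI adds ST elevation and a deepened Q wave; HMI has a pathological
#' Q wave and an inverted T wave; COVID has an elevated rate and a damped T
#' wave. These are synthetic, class-separable surrogates, not clinical
#' morphologies.
#'
#' @param heartRate beats/min.
#' @param beatJitter fraction of the RR interval, in [0, 0.5).
#' @param gaussComponents 5 x 3 matrix (rows P,Q,R,S,T; columns amplitude
#'   mV, center s, width s).
#' @param stOffset ST offset in mV.
#' @param tPolarity +1 or -1.
#' @param baselineWanderAmp baseline wander amplitude, mV.
#' @param traceNoiseSd additive trace noise sd, mV.
#' @return a [WaveformParams-class] object.
#' @examples
#' wf <- waveformParams()
#' synthBeat(0.30, wf)  # near the R peak
#' @export
waveformParams <- function(heartRate = 72, beatJitter = 0.02,
                           gaussComponents = defaultBeatComponents(),
                           stOffset = 0, tPolarity = 1,
                           baselineWanderAmp = 0.05, traceNoiseSd = 0.01) {
  new("WaveformParams", heartRate = heartRate, beatJitter = beatJitter,
      gaussComponents = gaussComponents, stOffset = stOffset,
      tPolarity = tPolarity, baselineWanderAmp = baselineWanderAmp,
      traceNoiseSd = traceNoiseSd)
}

#' Default beat template (normal-heartbeat morphology)
#'
#' Amplitudes in mV, centres/widths in seconds within the beat.
#' @return 5 x 3 numeric matrix with rows P, Q, R, S, T.
#' @export
defaultBeatComponents <- function() {
  m <- rbind(
    P = c(0.15, 0.15, 0.025),
    Q = c(-0.12, 0.26, 0.012),
    R = c(1.20, 0.30, 0.018),
    S = c(-0.25, 0.34, 0.012),
    T = c(0.35, 0.55, 0.060)
  )
  colnames(m) <- c("amplitude", "center", "width")
  m
}

#' @rdname waveformParams
#' @param classLabel one of NHB, AHB, MI, HMI, COVID.
#' @export
classWaveformParams <- function(classLabel) {
  classLabel <- match.arg(classLabel, ECG_CLASSES)
  g <- defaultBeatComponents()
  switch(classLabel,
    NHB = waveformParams(),
    AHB = waveformParams(heartRate = 88, beatJitter = 0.28),
    MI = {
      g["Q", "amplitude"] <- -0.45
      waveformParams(gaussComponents = g, stOffset = 0.25)
    },
    HMI = {
      g["Q", "amplitude"] <- -0.50
      waveformParams(gaussComponents = g, tPolarity = -1)
    },
    COVID = {
      g["T", "amplitude"] <- 0.12
      waveformParams(heartRate = 110, gaussComponents = g)
    }
  )
}

#' Construct a sheet specification
#'
#' @param widthPx,heightPx page size in px.
#' @param minorGridSpacingPx,majorGridEvery,gridIntensity grid ruling.
#' @param labelBandTopPx,labelBandBottomPx label band heights.
#' @param nLeadRows,nLeadCols lead strip layout.
#' @param contrastScale global contrast in (0, 1].
#' @param pageNoiseSd page noise sd (intensity units).
#' @param seed rendering seed.
#' @return a [SheetSpec-class] object.
#' @export
sheetSpec <- function(widthPx = 2213L, heightPx = 1572L,
                      minorGridSpacingPx = 8L, majorGridEvery = 5L,
                      gridIntensity = 210, labelBandTopPx = 150L,
                      labelBandBottomPx = 150L, nLeadRows = 6L, nLeadCols = 2L,
                      contrastScale = 1, pageNoiseSd = 4, seed = 1L) {
  new("SheetSpec", widthPx = as.integer(widthPx), heightPx = as.integer(heightPx),
      minorGridSpacingPx = as.integer(minorGridSpacingPx),
      majorGridEvery = as.integer(majorGridEvery), gridIntensity = gridIntensity,
      labelBandTopPx = as.integer(labelBandTopPx),
      labelBandBottomPx = as.integer(labelBandBottomPx),
      nLeadRows = as.integer(nLeadRows), nLeadCols = as.integer(nLeadCols),
      contrastScale = contrastScale, pageNoiseSd = pageNoiseSd,
      seed = as.integer(seed))
}

#' Construct a pipeline configuration
#'
#' Defaults follow the published preparation recipe: fixed-ratio crop
#' 2213x1572 -> 2058x1210, 2x2 rectangular opening, component area
#' threshold 50 px (strict), 3x3 Gaussian blur, sigma-seeded non-local
#' means, then histogram equalisation.
#'
#' @param cropRatioW,cropRatioH retained width/height fractions.
#' @param cropVerticalSplit fraction of removed rows taken from the top.
#' @param morphKernel opening kernel size c(rows, cols).
#' @param contourAreaMax strict component-area threshold (px).
#' @param blurKernel,blurSigma Gaussian blur settings.
#' @param nlmPatchSize,nlmPatchDistance,nlmHFactor non-local-means settings.
#' @param applyHE apply histogram equalisation.
#' @return a [PipelineConfig-class] object.
#' @examples
#' cfg <- pipelineConfig()
#' dim(cropLabels(matrix(0, 1572, 2213), cfg))  # 1210 x 2058
#' @export
pipelineConfig <- function(cropRatioW = 2058 / 2213, cropRatioH = 1210 / 1572,
                           cropVerticalSplit = 0.5, morphKernel = c(2L, 2L),
                           contourAreaMax = 50, blurKernel = c(3L, 3L),
                           blurSigma = 0.8, nlmPatchSize = 5L,
                           nlmPatchDistance = 6L, nlmHFactor = 1.15,
                           applyHE = TRUE) {
  new("PipelineConfig", cropRatioW = cropRatioW, cropRatioH = cropRatioH,
      cropVerticalSplit = cropVerticalSplit, morphKernel = as.integer(morphKernel),
      contourAreaMax = contourAreaMax, blurKernel = as.integer(blurKernel),
      blurSigma = blurSigma, nlmPatchSize = as.integer(nlmPatchSize),
      nlmPatchDistance = as.integer(nlmPatchDistance), nlmHFactor = nlmHFactor,
      applyHE = applyHE)
}

#' Construct a model configuration
#'
#' Defaults are the final configuration selected by the ablation protocol.
#' `reduced = TRUE` swaps in a desk-scale preset (stack counts 1/1/1,
#' 8 filters, 64 x 64 input) for small training runs.
#'
#' @param reduced use the desk-scale preset.
#' @param ... slot overrides, e.g. `nClasses = 3L`, `activation = "relu"`.
#' @return a [ModelConfig-class] object.
#' @export
modelConfig <- function(..., reduced = FALSE) {
  base <- list(
    inputSize = c(224L, 224L), inputChannels = 1L, filterSize = 3L,
    nFilters = 64L, poolType = "max", activation = "prelu", preluInit = 0.1,
    headType = "flatten", loss = "categorical_crossentropy",
    optimizer = "adam", learningRate = 0.0007, batchSize = 32L,
    epochs = 160L, nClasses = 5L, rsfEnabled = TRUE, rsfInit = 0.1,
    stackCounts = c(3L, 5L, 3L)
  )
  if (reduced) {
    base$inputSize <- c(64L, 64L); base$nFilters <- 8L
    base$stackCounts <- c(1L, 1L, 1L)
  }
  dots <- list(...)
  base[names(dots)] <- dots
  for (s in c("inputSize", "inputChannels", "filterSize", "nFilters",
              "batchSize", "epochs", "nClasses", "stackCounts"))
    base[[s]] <- as.integer(base[[s]])
  do.call(new, c(list("ModelConfig"), base))
}

#' Construct a confusion matrix
#'
#' Either from a K x K count matrix (rows = actual, columns = predicted) or
#' from paired actual/predicted label vectors.
#'
#' @param counts square count matrix, or NULL when labels are given.
#' @param actual,predicted label vectors (used when `counts` is NULL).
#' @param levels class labels; defaults to the matrix dimnames or the
#'   sorted union of observed labels.
#' @return a [ConfusionMatrix-class] object.
#' @examples
#' cm <- confusionMatrix(matrix(c(50, 10, 5, 35), 2,
#'                              dimnames = list(c("a", "b"), c("a", "b"))))
#' perClassCounts(cm, "a")
#' @export
confusionMatrix <- function(counts = NULL, actual = NULL, predicted = NULL,
                            levels = NULL) {
  if (is.null(counts)) {
    stopifnot(length(actual) == length(predicted))
    if (is.null(levels)) levels <- sort(unique(c(as.character(actual),
                                                 as.character(predicted))))
    bad <- setdiff(unique(c(as.character(actual), as.character(predicted))), levels)
    if (length(bad)) stop("labels outside the class set: ", paste(bad, collapse = ", "))
    counts <- table(factor(actual, levels), factor(predicted, levels))
    counts <- matrix(as.numeric(counts), length(levels), length(levels),
                     dimnames = list(levels, levels))
  } else {
    counts <- as.matrix(counts)
    if (!is.null(levels)) dimnames(counts) <- list(levels, levels)
    if (is.null(rownames(counts)))
      dimnames(counts) <- list(seq_len(nrow(counts)), seq_len(ncol(counts)))
    colnames(counts) <- rownames(counts)
  }
  new("ConfusionMatrix", counts = counts)
}

#' @describeIn confusionMatrix the raw count matrix.
#' @param object a ConfusionMatrix.
#' @export
cmCounts <- function(object) object@counts
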