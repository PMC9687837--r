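#' Classes for synthetic paper-ECG sheets and the processing toolkit
#'
#' @name InResECG-classes
#' @keywords internal
NULL

ECG_CLASSES <- c("NHB", "AHB", "MI", "HMI", "COVID")

#' Beat-template parameters for the synthetic trace generator
#'
#' The single-beat template is a sum of five Gaussian deflections (P, Q, R,
#' S, T) plus an ST-segment offset applied between the S and T centres.
#' Amplitudes are in millivolts, centres and widths in seconds within the
#' beat.
#'
#' @slot heartRate beats per minute (> 0).
#' @slot beatJitter fraction of the RR interval by which individual beat
#'   lengths vary uniformly; in [0, 0.5).
#' @slot gaussComponents 5 x 3 numeric matrix with rows P, Q, R, S, T and
#'   columns amplitude (mV), center (s), width (s).
#' @slot stOffset ST-segment offset in mV, applied between the S and T
#'   centres.
#' @slot tPolarity +1 or -1; sign multiplier on the T-wave amplitude.
#' @slot baselineWanderAmp baseline wander amplitude in mV.
#' @slot traceNoiseSd additive trace noise standard deviation in mV.
#' @export
setClass("WaveformParams", representation(
  heartRate = "numeric", beatJitter = "numeric",
  gaussComponents = "matrix", stOffset = "numeric", tPolarity = "numeric",
  baselineWanderAmp = "numeric", traceNoiseSd = "numeric"
))

setValidity("WaveformParams", function(object) {
  msg <- character()
  if (object@heartRate <= 0) msg <- c(msg, "heartRate must be > 0")
  if (object@beatJitter < 0 || object@beatJitter >= 0.5)
    msg <- c(msg, "beatJitter must be in [0, 0.5)")
  g <- object@gaussComponents
  if (!identical(dim(g), c(5L, 3L)))
    msg <- c(msg, "gaussComponents must be a 5 x 3 matrix (P,Q,R,S,T)")
  else if (any(g[, 3] <= 0)) msg <- c(msg, "component widths must be > 0")
  if (!object@tPolarity %in% c(-1, 1)) msg <- c(msg, "tPolarity must be +1 or -1")
  if (length(msg)) msg else TRUE
})

#' Geometry and rendering parameters of a synthetic ECG sheet
#'
#' Defaults emulate scanned 12-lead thermal-paper pages: a 2213 x 1572 px
#' page with a 1 mm / 5 mm ruling (8 px minor spacing, every 5th line
#' emphasised), header and footer label bands, and a 6 x 2 lead layout plus
#' a full-width rhythm strip.
#'
#' @slot widthPx,heightPx page size in pixels (defaults 2213 x 1572).
#' @slot minorGridSpacingPx minor grid spacing in pixels (default 8).
#' @slot majorGridEvery draw an emphasised line every this many minors.
#' @slot gridIntensity 0--255 intensity of minor grid lines; major lines
#'   double the contrast against the white page.
#' @slot labelBandTopPx,labelBandBottomPx heights of the text bands.
#' @slot nLeadRows,nLeadCols lead strip layout (a rhythm strip row is added).
#' @slot contrastScale global contrast in (0, 1]; 1 = full contrast.
#' @slot pageNoiseSd additive page noise sd in intensity units.
#' @slot seed integer rendering seed.
#' @export
setClass("SheetSpec", representation(
  widthPx = "integer", heightPx = "integer",
  minorGridSpacingPx = "integer", majorGridEvery = "integer",
  gridIntensity = "numeric",
  labelBandTopPx = "integer", labelBandBottomPx = "integer",
  nLeadRows = "integer", nLeadCols = "integer",
  contrastScale = "numeric", pageNoiseSd = "numeric", seed = "integer"
))

setValidity("SheetSpec", function(object) {
  msg <- character()
  if (object@widthPx < 32L || object@heightPx < 32L)
    msg <- c(msg, "page must be at least 32 x 32 px")
  if (object@labelBandTopPx + object@labelBandBottomPx >= object@heightPx)
    msg <- c(msg, "label bands must not overlap the lead area")
  if (object@contrastScale <= 0 || object@contrastScale > 1)
    msg <- c(msg, "contrastScale must be in (0, 1]")
  if (object@minorGridSpacingPx < 2L) msg <- c(msg, "minor grid spacing >= 2 px")
  if (length(msg)) msg else TRUE
})

#' A rendered synthetic ECG sheet with ground-truth masks
#'
#' @slot image height x width intensity matrix on [0, 255], origin top-left.
#' @slot signalMask,gridMask,labelMask logical matrices marking the pixels
#'   drawn for the trace, the background ruling, and the label text. The
#'   masks are mutually exclusive (later-drawn elements claim shared pixels).
#' @slot classLabel one of NHB, AHB, MI, HMI, COVID.
#' @slot waveform the [WaveformParams-class] used.
#' @slot sheet the [SheetSpec-class] used.
#' @export
setClass("ECGSheet", representation(
  image = "matrix", signalMask = "matrix", gridMask = "matrix",
  labelMask = "matrix", classLabel = "character",
  waveform = "WaveformParams", sheet = "SheetSpec"
))

setValidity("ECGSheet", function(object) {
  msg <- character()
  d <- dim(object@image)
  if (!identical(d, c(object@sheet@heightPx, object@sheet@widthPx)))
    msg <- c(msg, "image shape must equal (heightPx, widthPx)")
  for (s in c("signalMask", "gridMask", "labelMask"))
    if (!identical(dim(slot(object, s)), d)) msg <- c(msg, paste(s, "shape mismatch"))
  if (any(object@signalMask & object@gridMask) ||
      any(object@signalMask & object@labelMask) ||
      any(object@gridMask & object@labelMask))
    msg <- c(msg, "masks must be mutually exclusive")
  if (!object@classLabel %in% ECG_CLASSES)
    msg <- c(msg, "classLabel must be one of NHB, AHB, MI, HMI, COVID")
  if (length(msg)) msg else TRUE
})

#' Configuration of the artifact-removal and enhancement pipeline
#'
#' Holds every tunable of the preparation pipeline: the fixed-ratio label
#' crop, the morphological opening kernel, the connected-component area
#' threshold used to pick out gridline fragments, Gaussian blur and
#' non-local-means settings, and the histogram-equalisation switch.
#'
#' @slot cropRatioW,cropRatioH retained width/height fractions
#'   (defaults 2058/2213 and 1210/1572).
#' @slot cropVerticalSplit fraction of removed rows taken from the top.
#' @slot morphKernel rectangular opening kernel size (rows, cols).
#' @slot contourAreaMax strict upper bound on the pixel count of components
#'   treated as gridline fragments (default 50).
#' @slot blurKernel Gaussian kernel size (default c(3, 3)); dims must be odd.
#' @slot blurSigma Gaussian sigma in pixels.
#' @slot nlmPatchSize,nlmPatchDistance non-local-means patch width and
#'   search radius in pixels.
#' @slot nlmHFactor filtering strength as a multiple of the estimated
#'   noise sigma.
#' @slot applyHE apply histogram equalisation as the final stage.
#' @export
setClass("PipelineConfig", representation(
  cropRatioW = "numeric", cropRatioH = "numeric", cropVerticalSplit = "numeric",
  morphKernel = "integer", contourAreaMax = "numeric",
  blurKernel = "integer", blurSigma = "numeric",
  nlmPatchSize = "integer", nlmPatchDistance = "integer", nlmHFactor = "numeric",
  applyHE = "logical"
))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (object@cropRatioW <= 0 || object@cropRatioW > 1 ||
      object@cropRatioH <= 0 || object@cropRatioH > 1)
    msg <- c(msg, "crop ratios must be in (0, 1]")
  if (object@cropVerticalSplit < 0 || object@cropVerticalSplit > 1)
    msg <- c(msg, "cropVerticalSplit must be in [0, 1]")
  if (any(object@blurKernel %% 2L == 0L)) msg <- c(msg, "blur kernel dims must be odd")
  if (object@contourAreaMax <= 0) msg <- c(msg, "contourAreaMax must be > 0")
  if (object@nlmHFactor <= 0) msg <- c(msg, "nlmHFactor must be > 0")
  if (length(msg)) msg else TRUE
})

#' Result of running the preparation pipeline
#'
#' @slot final the final intensity image (equalised, or denoised when
#'   histogram equalisation is disabled).
#' @slot intermediates named list of every stage output: cropped, gray,
#'   otsu_binary, opened, small_contour_mask, line_removed, inverted,
#'   blurred, denoised, equalized.
#' @slot config the [PipelineConfig-class] used.
#' @slot otsuThreshold the selected global threshold.
#' @slot degenerate TRUE when the grayscale input was constant and the
#'   threshold is degenerate.
#' @export
setClass("PreprocessResult", representation(
  final = "matrix", intermediates = "list", config = "PipelineConfig",
  otsuThreshold = "numeric", degenerate = "logical"
))

#' Batch image-fidelity report
#'
#' @slot records data.frame with columns image_id, mse, psnr, ssim, rmse
#'   (MSE/RMSE on the [0,1] intensity scale; PSNR in dB from 8-bit MSE).
#' @slot averages named numeric vector of metric means (PSNR averaged over
#'   finite values).
#' @slot psnrBins data.frame of 1-dB PSNR bins (edges x.01--(x+1).00] with
#'   counts and percentages; identical-image pairs are binned as "Inf".
#' @export
setClass("QualityReport", representation(
  records = "data.frame", averages = "numeric", psnrBins = "data.frame"
))

#' Architecture and training configuration of the hybrid network
#'
#' Defaults are the configuration selected by the ablation protocol:
#' 3 x 3 filters, 64 filters, max pooling, PReLU, batch size 32, flatten
#' head, categorical cross-entropy, Adam with learning rate 0.0007,
#' 160 epochs, 224 x 224 input, residual scaling enabled.
#'
#' @slot inputSize input image size (height, width).
#' @slot inputChannels input channels (1 for grayscale).
#' @slot filterSize convolution kernel width (all conv layers).
#' @slot nFilters number of filters in every conv layer.
#' @slot poolType "max" or "average".
#' @slot activation one of "prelu", "relu", "leakyrelu", "elu", "tanh".
#' @slot preluInit initial learnable negative-side slope (default 0.1).
#' @slot headType "flatten", "global_average" or "global_max".
#' @slot loss one of "categorical_crossentropy", "binary_crossentropy",
#'   "mse", "mae", "msle", "kld".
#' @slot optimizer one of "adam", "nadam", "adamax", "sgd", "rmsprop".
#' @slot learningRate learning rate.
#' @slot batchSize minibatch size.
#' @slot epochs maximum training epochs.
#' @slot nClasses number of output classes.
#' @slot rsfEnabled learnable residual scaling factor on the inception
#'   branch; when FALSE the scale is fixed at 1 and not trainable.
#' @slot rsfInit initial residual scale (default 0.1; selected in
#'   [0.1, 0.3]).
#' @slot stackCounts repeats of the stacked units in Blocks 2--4
#'   (default c(3, 5, 3)).
#' @export
setClass("ModelConfig", representation(
  inputSize = "integer", inputChannels = "integer",
  filterSize = "integer", nFilters = "integer", poolType = "character",
  activation = "character", preluInit = "numeric", headType = "character",
  loss = "character", optimizer = "character", learningRate = "numeric",
  batchSize = "integer", epochs = "integer", nClasses = "integer",
  rsfEnabled = "logical", rsfInit = "numeric", stackCounts = "integer"
))

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (!object@poolType %in% c("max", "average")) msg <- c(msg, "bad poolType")
  if (!object@activation %in% c("prelu", "relu", "leakyrelu", "elu", "tanh"))
    msg <- c(msg, "bad activation")
  if (!object@headType %in% c("flatten", "global_average", "global_max"))
    msg <- c(msg, "bad headType")
  if (!object@loss %in% c("categorical_crossentropy", "binary_crossentropy",
                          "mse", "mae", "msle", "kld"))
    msg <- c(msg, "bad loss")
  if (!object@optimizer %in% c("adam", "nadam", "adamax", "sgd", "rmsprop"))
    msg <- c(msg, "bad optimizer")
  if (object@rsfInit < 0.1 - 1e-12 || object@rsfInit > 0.3 + 1e-12)
    msg <- c(msg, "rsfInit must lie in [0.1, 0.3]")
  if (length(object@stackCounts) != 3L || any(object@stackCounts < 1L))
    msg <- c(msg, "stackCounts must be three positive integers")
  if (object@learningRate < 0) msg <- c(msg, "learningRate must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A built hybrid Inception-ResNet model
#'
#' @slot layers internal layer-stack representation (list of environments).
#' @slot config the [ModelConfig-class] the model was built from.
#' @slot classLevels class labels in output order.
#' @slot history training history data.frame (empty before training).
#' @export
setClass("InResModel", representation(
  layers = "list", config = "ModelConfig", classLevels = "character",
  history = "data.frame"
))

#' A K x K confusion matrix (rows = actual, columns = predicted)
#'
#' @slot counts non-negative integer matrix with identical row/column
#'   dimnames giving the class labels.
#' @export
setClass("ConfusionMatrix", representation(counts = "matrix"))

setValidity("ConfusionMatrix", function(object) {
  m <- object@counts
  if (nrow(m) != ncol(m)) return("counts must be square")
  if (any(m < 0)) return("counts must be non-negative")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    return("counts needs identical row and column class labels")
  TRUE
})

#' Report of the greedy ablation protocol
#'
#' @slot rows data.frame with one row per evaluated candidate: study index
#'   and name, candidate label, accuracy, complexity, finding
#'   (initial/improved/identical/dropped/failed) and whether it was chosen.
#' @slot finalConfig the [ModelConfig-class] reached after the last study.
#' @slot delta accuracy tolerance (points) of the lower-complexity
#'   preference rule.
#' @export
setClass("AblationReport", representation(
  rows = "data.frame", finalConfig = "ModelConfig", delta = "numeric"
))
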