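#' Remove header/footer labels by fixed-ratio cropping
#'
#' The output is an exact sub-window: `floor(W * cropRatioW)` columns and
#' `floor(H * cropRatioH)` rows, with removed columns split symmetrically
#' left/right and removed rows split per `cropVerticalSplit` top/bottom.
#' With the default ratios a 2213 x 1572 page maps to 2058 x 1210.
#'
#' @param img intensity matrix or height x width x channels array.
#' @param cfg a [PipelineConfig-class].
#' @return cropped image, same channel count.
#' @export
cropLabels <- function(img, cfg = pipelineConfig()) {
  validObject(cfg)
  d <- dim(img); H <- d[1]; W <- d[2]
  outW <- floor(W * cfg@cropRatioW); outH <- floor(H * cfg@cropRatioH)
  if (outW < 1 || outH < 1) stop("crop ratios leave no pixels")
  remW <- W - outW; remH <- H - outH
  left <- floor(remW / 2)
  top <- floor(remH * cfg@cropVerticalSplit)
  rows <- (top + 1):(top + outH); cols <- (left + 1):(left + outW)
  if (length(d) == 3L) img[rows, cols, , drop = FALSE] else img[rows, cols, drop = FALSE]
}

#' Convert an RGB image to grayscale luma
#'
#' `round(0.299 R + 0.587 G + 0.114 B)`.
#'
#' @param rgb height x width x 3 array on [0, 255].
#' @return grayscale matrix.
#' @export
toGrayscale <- function(rgb) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop("toGrayscale expects a 3-channel image")
  round(0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3])
}

#' Global Otsu threshold
#'
#' Chooses t in 0..255 maximising the between-class variance of the
#' grayscale histogram. Dark ink is the foreground: pixels <= t map to 255,
#' the rest to 0. A constant image is flagged degenerate and returns an
#' all-background binary with t equal to the constant.
#'
#' @param gray matrix on [0, 255].
#' @return list with `binary` (0/255 matrix), `threshold`, `degenerate`.
#' @export
otsuThreshold <- function(gray) {
  if (length(gray) == 0L) stop("empty image")
  v <- as.integer(round(gray))
  h <- tabulate(v + 1L, nbins = 256L)
  if (sum(h > 0) == 1L) {
    t <- which(h > 0) - 1L
    return(list(binary = matrix(0, nrow(gray), ncol(gray)),
                threshold = as.numeric(t), degenerate = TRUE))
  }
  n <- as.numeric(sum(h))
  lev <- 0:255
  w1 <- as.numeric(cumsum(h))      # class sizes for threshold t = 0..255
  m1 <- cumsum(as.numeric(h) * lev)
  mT <- m1[256]
  w2 <- n - w1
  # between-class variance w1*w2*(mu1-mu2)^2 / n^2; guard empty classes
  num <- (mT * w1 - m1 * n)^2
  den <- as.numeric(w1) * as.numeric(w2)
  bcv <- ifelse(den > 0, num / den, -Inf)
  t <- which.max(bcv) - 1L
  binary <- matrix(0, nrow(gray), ncol(gray))
  binary[gray <= t] <- 255
  list(binary = binary, threshold = as.numeric(t), degenerate = FALSE)
}

# shift a matrix by (di, dj) with edge replication
shiftRep <- function(x, di, dj) {
  H <- nrow(x); W <- ncol(x)
  ri <- pmin(pmax(seq_len(H) + di, 1L), H)
  ci <- pmin(pmax(seq_len(W) + dj, 1L), W)
  x[ri, ci, drop = FALSE]
}

#' Morphological opening with a rectangular element
#'
#' Erosion (anchor at the top-left of the element) followed by the adjoint
#' dilation. Removes foreground structures that cannot contain the element;
#' with the default 2 x 2 element this wipes 1-px-wide gridlines and
#' isolated specks while keeping >= 2-px-thick ink.
#'
#' @param binary 0/255 matrix.
#' @param kernel element size c(rows, cols).
#' @return opened 0/255 matrix.
#' @export
morphOpen <- function(binary, kernel = c(2L, 2L)) {
  if (!all(binary %in% c(0, 255))) stop("morphOpen expects a 0/255 binary image")
  kh <- kernel[1]; kw <- kernel[2]
  ero <- binary
  for (u in 0:(kh - 1)) for (v in 0:(kw - 1))
    if (u > 0 || v > 0) ero <- pmin(ero, shiftRep(binary, u, v))
  dil <- ero
  for (u in 0:(kh - 1)) for (v in 0:(kw - 1))
    if (u > 0 || v > 0) dil <- pmax(dil, shiftRep(ero, -u, -v))
  dil
}

#' Find small connected components (gridline fragments)
#'
#' Labels the foreground with 8-connectivity and returns the mask of
#' components whose pixel count is strictly below `areaMax`. On a prepared
#' sheet these are the residual gridline fragments and noise specks, while
#' the ECG trace forms large components.
#'
#' @param binary 0/255 matrix.
#' @param areaMax strict area threshold in pixels (default 50).
#' @return logical matrix marking the small-component pixels.
#' @export
findSmallComponents <- function(binary, areaMax = 50) {
  lab <- label8_cpp(binary)
  n <- max(lab)
  if (n == 0L) return(matrix(FALSE, nrow(binary), ncol(binary)))
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  small <- which(sizes < areaMax)
  matrix(lab %in% small & lab > 0L, nrow(binary), ncol(binary))
}

#' Remove masked pixels from a binary image
#'
#' @param binary 0/255 matrix.
#' @param mask logical matrix of pixels to clear.
#' @return binary with masked foreground set to background.
#' @export
removeComponents <- function(binary, mask) {
  if (!identical(dim(binary), dim(mask))) stop("shape mismatch")
  binary[mask] <- 0
  binary
}

#' Invert an 8-bit image
#'
#' @param img matrix on [0, 255].
#' @return `255 - img`.
#' @export
invertImage <- function(img) 255 - img

# normalised 1-d Gaussian kernel of odd length k
gaussKernel1d <- function(k, sigma) {
  c0 <- (k + 1) / 2
  g <- exp(-((seq_len(k) - c0)^2) / (2 * sigma^2))
  g / sum(g)
}

#' Gaussian blur
#'
#' Separable convolution with a normalised Gaussian kernel; borders are
#' handled by edge replication.
#'
#' @param img intensity matrix.
#' @param ksize kernel size c(rows, cols); dims must be odd.
#' @param sigma Gaussian sigma in pixels.
#' @return blurred matrix (not re-quantised).
#' @export
gaussianBlur <- function(img, ksize = c(3L, 3L), sigma = 0.8) {
  if (any(ksize %% 2L == 0L)) stop("kernel dims must be odd")
  gv <- gaussKernel1d(ksize[1], sigma)
  gh <- gaussKernel1d(ksize[2], sigma)
  rv <- (ksize[1] - 1L) %/% 2L; rh <- (ksize[2] - 1L) %/% 2L
  out <- matrix(0, nrow(img), ncol(img))
  for (u in seq_len(ksize[1])) out <- out + gv[u] * shiftRep(img, u - rv - 1L, 0L)
  out2 <- matrix(0, nrow(img), ncol(img))
  for (v in seq_len(ksize[2])) out2 <- out2 + gh[v] * shiftRep(out, 0L, v - rh - 1L)
  out2
}

#' Estimate additive noise sigma
#'
#' Robust wavelet-detail estimate: the median absolute deviation of the
#' first-level Haar diagonal-detail coefficients divided by 0.6745. For a
#' flat field with additive Gaussian noise the estimate is unbiased, and it
#' is invariant to constant offsets.
#'
#' @param img intensity matrix, at least 8 x 8.
#' @return estimated noise standard deviation.
#' @export
estimateSigma <- function(img) {
  if (nrow(img) < 8L || ncol(img) < 8L) stop("image too small (need >= 8 x 8)")
  H <- nrow(img) - nrow(img) %% 2L
  W <- ncol(img) - ncol(img) %% 2L
  a <- img[seq(1L, H, 2L), seq(1L, W, 2L)]
  b <- img[seq(1L, H, 2L), seq(2L, W, 2L)]
  d <- img[seq(2L, H, 2L), seq(1L, W, 2L)]
  e <- img[seq(2L, H, 2L), seq(2L, W, 2L)]
  hh <- (a - b - d + e) / 2
  stats::median(abs(hh)) / 0.6745
}

#' Non-local-means denoising
#'
#' Each output pixel is a weight-normalised average over the search window;
#' the weight of neighbour q is `exp(-D(p, q) / h^2)` where D is the mean
#' squared intensity difference over the `patchSize`-wide patches around p
#' and q (edge-replicated padding).
#'
#' @param img intensity matrix.
#' @param patchSize odd patch width (default 5).
#' @param patchDistance search radius in pixels (default 6).
#' @param h filtering strength (> 0); typically a multiple of the estimated
#'   noise sigma.
#' @return denoised matrix.
#' @export
nlmDenoise <- function(img, patchSize = 5L, patchDistance = 6L, h) {
  if (h <= 0) stop("h must be > 0")
  if (patchSize %% 2L == 0L) stop("patchSize must be odd")
  nlm_cpp(img, (patchSize - 1L) %/% 2L, as.integer(patchDistance), h)
}

#' Histogram equalisation
#'
#' Maps input level k to `floor((hmax - hmin) * t_k + hmin + 0.5)` where
#' t_k is the cumulative proportion of pixels at levels <= k, with
#' hmin = 0, hmax = 255; applied as a lookup table.
#'
#' @param gray matrix on [0, 255].
#' @return equalised matrix; attribute `"lut"` carries the 256-entry mapping.
#' @export
histEqualize <- function(gray) {
  v <- as.integer(round(gray))
  h <- tabulate(v + 1L, nbins = 256L)
  t <- cumsum(h) / length(v)
  lut <- floor(255 * t + 0.5)
  out <- matrix(lut[v + 1L], nrow(gray), ncol(gray))
  attr(out, "lut") <- lut
  out
}

#' Run the full preparation pipeline
#'
#' Executes crop -> grayscale -> Otsu -> opening -> small-component
#' extraction -> removal -> inversion -> Gaussian blur -> sigma-seeded
#' non-local means -> histogram equalisation, in order, with the output of
#' each stage feeding the next. All intermediates are retained.
#'
#' @param img input page: grayscale matrix or RGB array on [0, 255].
#' @param cfg a [PipelineConfig-class].
#' @param stopAfter optional stage name ("cropped", "gray", "otsu_binary",
#'   "opened", "small_contour_mask", "line_removed", "inverted", "blurred",
#'   "denoised", "equalized"); the pipeline halts after that stage and
#'   `final` is its output. Useful for measuring the artifact-removal
#'   stages without paying for denoising.
#' @return a [PreprocessResult-class].
#' @export
runPipeline <- function(img, cfg = pipelineConfig(), stopAfter = NULL) {
  validObject(cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s': %s", name, conditionMessage(e)), call. = FALSE))
  }
  im <- list()
  ot <- NULL
  done <- function(name) !is.null(stopAfter) && identical(stopAfter, name)
  finish <- function() {
    last <- im[[length(im)]]
    new("PreprocessResult",
        final = if (is.matrix(last)) last else matrix(last * 1, nrow(last)),
        intermediates = im, config = cfg,
        otsuThreshold = if (is.null(ot)) NA_real_ else ot$threshold,
        degenerate = if (is.null(ot)) FALSE else ot$degenerate)
  }
  im$cropped <- stage("crop_labels", cropLabels(img, cfg))
  if (done("cropped")) return(finish())
  im$gray <- stage("to_grayscale",
                   if (length(dim(im$cropped)) == 3L) toGrayscale(im$cropped)
                   else im$cropped)
  if (done("gray")) return(finish())
  ot <- stage("otsu_threshold", otsuThreshold(im$gray))
  im$otsu_binary <- ot$binary
  if (done("otsu_binary")) return(finish())
  im$opened <- stage("morph_open", morphOpen(im$otsu_binary, cfg@morphKernel))
  if (done("opened")) return(finish())
  im$small_contour_mask <- stage("find_small_components",
                                 findSmallComponents(im$opened, cfg@contourAreaMax))
  if (done("small_contour_mask")) return(finish())
  im$line_removed <- stage("remove_components",
                           removeComponents(im$opened, im$small_contour_mask))
  if (done("line_removed")) return(finish())
  im$inverted <- stage("invert", invertImage(im$line_removed))
  if (done("inverted")) return(finish())
  im$blurred <- stage("gaussian_blur",
                      gaussianBlur(im$inverted, cfg@blurKernel, cfg@blurSigma))
  if (done("blurred")) return(finish())
  sig <- stage("estimate_sigma", estimateSigma(im$blurred))
  im$denoised <- stage("nlm_denoise",
                       nlmDenoise(im$blurred, cfg@nlmPatchSize, cfg@nlmPatchDistance,
                                  h = max(cfg@nlmHFactor * sig, 1e-3)))
  if (done("denoised") || !cfg@applyHE) return(finish())
  im$equalized <- stage("hist_equalize",
                        histEqualize(pmin(pmax(round(im$denoised), 0), 255)))
  finish()
}

#' @describeIn runPipeline the final image of a result.
#' @param x a PreprocessResult.
#' @export
finalImage <- function(x) x@final

#' @describeIn runPipeline a named intermediate stage output.
#' @param name stage name, e.g. "otsu_binary".
#' @export
stageImage <- function(x, name) {
  if (!name %in% names(x@intermediates)) stop("unknown stage: ", name)
  x@intermediates[[name]]
}

#' Gridline-removal efficacy against ground truth
#'
#' Measures, inside the cropped window of a synthetic sheet: the fraction of
#' ground-truth grid pixels with no remaining foreground after component
#' removal (`gridRemoved`), and the fraction of trace foreground from the
#' Otsu binary that survives opening and component removal
#' (`signalRetained`).
#'
#' @param sample an [ECGSheet-class].
#' @param result a [PreprocessResult-class] from the sample's image.
#' @return named numeric vector `c(gridRemoved, signalRetained)`.
#' @export
gridRemovalStats <- function(sample, result) {
  cfg <- result@config
  grid <- cropLabels(sample@gridMask * 1, cfg) > 0
  signal <- cropLabels(sample@signalMask * 1, cfg) > 0
  fgBefore <- stageImage(result, "otsu_binary") > 0
  fgAfter <- stageImage(result, "line_removed") > 0
  gridRemoved <- 1 - sum(fgAfter & grid) / max(sum(grid), 1)
  sigBefore <- sum(fgBefore & signal)
  signalRetained <- if (sigBefore == 0) NA_real_ else sum(fgAfter & signal) / sigBefore
  c(gridRemoved = gridRemoved, signalRetained = signalRetained)
}
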