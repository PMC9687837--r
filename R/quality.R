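#' Image fidelity metrics
#'
#' `mseImage`/`rmseImage` are computed on intensities rescaled to [0, 1];
#' `psnrImage` uses the 8-bit convention 10*log10(255^2 / MSE8) with MSE8 on
#' the raw 0--255 scale (identical images give +Inf); `ssimImage` is the
#' mean local structural-similarity index over sliding uniform windows.
#'
#' @param a,b intensity matrices of identical shape, values on [0, 255].
#' @return a scalar.
#' @examples
#' a <- matrix(0, 4, 4); b <- a; b[1, 1] <- 255
#' mseImage(a, b)   # 1/16
#' psnrImage(a, a)  # Inf
#' @export
mseImage <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  mean(((a - b) / 255)^2)
}

#' @rdname mseImage
#' @export
rmseImage <- function(a, b) sqrt(mseImage(a, b))

#' @rdname mseImage
#' @export
psnrImage <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  mse8 <- mean((a - b)^2)
  if (mse8 == 0) return(Inf)
  10 * log10(255^2 / mse8)
}

# box-filter mean over all complete (w x w) windows via summed-area table
boxMean <- function(x, w) {
  sat <- apply(apply(x, 2, cumsum), 1, cumsum)  # sat[j, i] after transposes
  sat <- t(sat)
  sat <- rbind(0, cbind(0, sat))
  H <- nrow(x); W <- ncol(x)
  oH <- H - w + 1L; oW <- W - w + 1L
  i1 <- (w + 1):(H + 1); i0 <- 1:oH
  j1 <- (w + 1):(W + 1); j0 <- 1:oW
  (sat[i1, j1] - sat[i0, j1] - sat[i1, j0] + sat[i0, j0]) / (w * w)
}

#' @rdname mseImage
#' @param window odd uniform window width (default 7).
#' @param K1,K2 stabilisation constants.
#' @param L dynamic range (255 for 8-bit).
#' @export
ssimImage <- function(a, b, window = 7L, K1 = 0.01, K2 = 0.03, L = 255) {
  if (!identical(dim(a), dim(b))) stop("shape mismatch")
  if (nrow(a) < window || ncol(a) < window) stop("image smaller than window")
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  n <- window * window
  cnorm <- n / (n - 1)  # sample (co)variance
  mua <- boxMean(a, window); mub <- boxMean(b, window)
  va <- (boxMean(a * a, window) - mua^2) * cnorm
  vb <- (boxMean(b * b, window) - mub^2) * cnorm
  cab <- (boxMean(a * b, window) - mua * mub) * cnorm
  s <- ((2 * mua * mub + C1) * (2 * cab + C2)) /
       ((mua^2 + mub^2 + C1) * (va + vb + C2))
  mean(s)
}

# PSNR bin label with edges (x + 0.01, x + 1.00]
psnrBinLabel <- function(p) {
  if (!is.finite(p)) return("Inf")
  r <- round(p, 2)
  hi <- ceiling(r - 1e-9)
  sprintf("%.2f-%.2f", hi - 0.99, hi)
}

#' Batch image-quality report
#'
#' Computes per-pair MSE, PSNR, SSIM and RMSE (record columns in that
#' order), their arithmetic means (PSNR averaged over finite values), and
#' the PSNR distribution over 1-dB bins with edges (x.01, (x+1).00];
#' identical pairs (infinite PSNR) get their own bin.
#'
#' @param originals,processed lists of intensity matrices, pairwise
#'   comparable.
#' @param ids image identifiers.
#' @return a [QualityReport-class].
#' @export
qualityReport <- function(originals, processed,
                          ids = sprintf("Image_%d", seq_along(originals))) {
  stopifnot(length(originals) == length(processed), length(originals) > 0)
  rec <- data.frame(
    image_id = ids,
    mse = mapply(mseImage, originals, processed),
    psnr = mapply(psnrImage, originals, processed),
    ssim = mapply(ssimImage, originals, processed),
    rmse = mapply(rmseImage, originals, processed),
    stringsAsFactors = FALSE
  )
  avg <- c(mse = mean(rec$mse),
           psnr = mean(rec$psnr[is.finite(rec$psnr)]),
           ssim = mean(rec$ssim), rmse = mean(rec$rmse))
  labs <- vapply(rec$psnr, psnrBinLabel, character(1))
  tab <- table(labs)
  bins <- data.frame(bin = names(tab), count = as.integer(tab),
                     percent = 100 * as.integer(tab) / nrow(rec),
                     stringsAsFactors = FALSE)
  bins <- bins[order(bins$bin != "Inf", bins$bin), , drop = FALSE]
  rownames(bins) <- NULL
  new("QualityReport", records = rec, averages = avg, psnrBins = bins)
}

#' @describeIn qualityReport per-image records.
#' @param x a QualityReport.
#' @export
qualityRecords <- function(x) x@records

#' @describeIn qualityReport metric averages.
#' @export
qualityAverages <- function(x) x@averages

#' @describeIn qualityReport PSNR bin table.
#' @export
psnrBins <- function(x) x@psnrBins
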