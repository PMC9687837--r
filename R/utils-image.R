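#' @useDynLib InResECG, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Read an image file as an 8-bit intensity array
#'
#' Reads a PNG and returns intensities on the 0--255 scale: a matrix
#' (height x width, origin top-left) for grayscale input, or a
#' height x width x 3 array for RGB (any alpha channel is dropped).
#'
#' @param path path to a PNG file.
#' @return numeric matrix or 3-d array with values in [0, 255].
#' @export
readImage8 <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] >= 3L) x <- x[, , 1:3, drop = FALSE] else x <- x[, , 1]
  }
  if (length(dim(x)) == 3L && dim(x)[3] == 1L) x <- x[, , 1]
  round(x * 255)
}

#' Write an 8-bit intensity array to a PNG file
#'
#' @param img matrix or height x width x 3 array with values in [0, 255].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeImage8 <- function(img, path) {
  img <- pmin(pmax(img, 0), 255)
  png::writePNG(img / 255, path)
  invisible(path)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Bilinear resize of a 2-d intensity matrix to (outH, outW).
# Pixel centres are mapped with the half-pixel convention.
resizeBilinear <- function(img, outH, outW) {
  H <- nrow(img); W <- ncol(img)
  if (H == outH && W == outW) return(img)
  yi <- (seq_len(outH) - 0.5) * H / outH + 0.5
  xi <- (seq_len(outW) - 0.5) * W / outW + 0.5
  y0 <- pmin(pmax(floor(yi), 1), H); y1 <- pmin(y0 + 1, H)
  x0 <- pmin(pmax(floor(xi), 1), W); x1 <- pmin(x0 + 1, W)
  fy <- pmin(pmax(yi - y0, 0), 1); fx <- pmin(pmax(xi - x0, 0), 1)
  a <- img[y0, x0, drop = FALSE] * (1 - fy) + img[y1, x0, drop = FALSE] * fy
  b <- img[y0, x1, drop = FALSE] * (1 - fy) + img[y1, x1, drop = FALSE] * fy
  sweep(a, 2, 1 - fx, "*") + sweep(b, 2, fx, "*")
}
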