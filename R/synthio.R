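#' Evaluate the single-beat template
#'
#' The beat is a sum of five Gaussian deflections,
#' sum_i a_i * exp(-(t - mu_i)^2 / (2 sigma_i^2)), with the T amplitude
#' multiplied by the T polarity and the ST offset added only between the S
#' and T centres.
#'
#' @param t time in seconds within the beat (scalar or vector).
#' @param params a [WaveformParams-class] object.
#' @return amplitude in mV, same length as `t`.
#' @examples
#' synthBeat(0.2, waveformParams())
#' @export
synthBeat <- function(t, params) {
  g <- params@gaussComponents
  a <- g[, "amplitude"]
  a["T"] <- a["T"] * params@tPolarity
  mu <- g[, "center"]; s <- g[, "width"]
  val <- numeric(length(t))
  for (i in seq_len(nrow(g)))
    val <- val + a[i] * exp(-(t - mu[i])^2 / (2 * s[i]^2))
  st <- t > mu["S"] & t < mu["T"]
  val[st] <- val[st] + params@stOffset
  unname(val)
}

# Draw a polyline trace into img/mask. y is a vector of row positions per
# column; strokes are 3 px tall with 2-px-wide vertical connectors so the
# ink survives a 2x2 opening.
drawTrace <- function(img, mask, y, cols, rowMin, rowMax, intensity) {
  H <- nrow(img)
  y <- pmin(pmax(y, rowMin + 1L), rowMax - 1L)
  n <- length(cols)
  for (k in seq_len(n)) {
    c0 <- cols[k]
    rows <- (y[k] - 1L):(y[k] + 1L)
    img[rows, c0] <- intensity
    mask[rows, c0] <- TRUE
    if (k > 1L && abs(y[k] - y[k - 1L]) > 1L) {
      lo <- min(y[k], y[k - 1L]); hi <- max(y[k], y[k - 1L])
      img[lo:hi, (c0 - 1L):c0] <- intensity
      mask[lo:hi, (c0 - 1L):c0] <- TRUE
    }
  }
  list(img = img, mask = mask)
}

#' Render a synthetic paper-ECG sheet
#'
#' Draws the background ruling, header/footer label text, and 12 lead strips
#' (`nLeadRows x nLeadCols`) plus a full-width rhythm strip, returning the
#' image together with ground-truth signal/grid/label masks. Rendering is a
#' pure function of (`classLabel`, `sheet`, `wf`, `seed`).
#'
#' @param classLabel one of NHB, AHB, MI, HMI, COVID.
#' @param sheet a [SheetSpec-class].
#' @param wf a [WaveformParams-class]; defaults to the class prior.
#' @param seed integer seed; defaults to `sheet@seed`.
#' @return an [ECGSheet-class] object.
#' @examples
#' sp <- sheetSpec(widthPx = 320, heightPx = 240, minorGridSpacingPx = 4,
#'                 labelBandTopPx = 24, labelBandBottomPx = 24)
#' sh <- renderSheet("NHB", sp)
#' dim(sheetImage(sh))
#' @export
renderSheet <- function(classLabel, sheet = sheetSpec(),
                        wf = classWaveformParams(classLabel),
                        seed = sheet@seed) {
  classLabel <- match.arg(classLabel, ECG_CLASSES)
  validObject(sheet); validObject(wf)
  H <- sheet@heightPx; W <- sheet@widthPx
  stripRows <- sheet@nLeadRows + 1L  # + rhythm strip
  leadTop <- sheet@labelBandTopPx + 1L
  leadBottom <- H - sheet@labelBandBottomPx
  stripH <- (leadBottom - leadTop + 1L) %/% stripRows
  if (stripH < 12L)
    stop("layout overflow: lead strips do not fit the page (strip height ",
         stripH, " px)")
  withSeed(seed, {
    img <- matrix(255, H, W)
    gridMask <- matrix(FALSE, H, W)
    labelMask <- matrix(FALSE, H, W)
    signalMask <- matrix(FALSE, H, W)

    # background ruling: 1-px lines, major line every `majorGridEvery`
    # minors at doubled contrast
    s <- sheet@minorGridSpacingPx
    minorInt <- sheet@gridIntensity
    majorInt <- max(0, 255 - 2 * (255 - sheet@gridIntensity))
    vx <- seq(1L, W, by = s); hy <- seq(1L, H, by = s)
    vmaj <- (seq_along(vx) - 1L) %% sheet@majorGridEvery == 0L
    hmaj <- (seq_along(hy) - 1L) %% sheet@majorGridEvery == 0L
    img[, vx[!vmaj]] <- minorInt; img[, vx[vmaj]] <- majorInt
    img[hy[!hmaj], ] <- pmin(img[hy[!hmaj], ], minorInt)
    img[hy[hmaj], ] <- pmin(img[hy[hmaj], ], majorInt)
    gridMask[, vx] <- TRUE; gridMask[hy, ] <- TRUE

    # label text, only inside the bands
    putText <- function(text, bandTop, bandH) {
      scale <- max(1L, bandH %/% 12L)
      r <- rasterText(text, scale)
      if (nrow(r) > bandH) r <- r[seq_len(bandH), , drop = FALSE]
      if (ncol(r) > W - 16L) r <- r[, seq_len(W - 16L), drop = FALSE]
      top <- bandTop + (bandH - nrow(r)) %/% 2L
      left <- 9L
      sel <- which(r, arr.ind = TRUE)
      idx <- cbind(top + sel[, 1] - 1L, left + sel[, 2] - 1L)
      img[idx] <<- 30
      labelMask[idx] <<- TRUE
      gridMask[idx] <<- FALSE
    }
    if (sheet@labelBandTopPx >= 7L)
      putText("ECG RECORD 12 LEAD ID 0001", 1L, sheet@labelBandTopPx)
    if (sheet@labelBandBottomPx >= 7L)
      putText("25MM/S 10MM/MV 150 1 50", leadBottom + 1L, sheet@labelBandBottomPx)

    # lead strips
    pxPerMm <- s
    pxPerS <- 25 * pxPerMm
    pxPerMv <- 10 * pxPerMm
    stripW <- W %/% sheet@nLeadCols
    period0 <- 60 / wf@heartRate
    for (r in seq_len(stripRows)) {
      rhythm <- r == stripRows
      ncols <- if (rhythm) 1L else sheet@nLeadCols
      for (cc in seq_len(ncols)) {
        x0 <- if (rhythm) 1L else (cc - 1L) * stripW + 1L
        x1 <- if (rhythm) W else cc * stripW
        top <- leadTop + (r - 1L) * stripH
        bottom <- top + stripH - 1L
        baseline <- top + round(stripH * 0.55)
        gain <- stats::runif(1, 0.7, 1.3)
        phase <- stats::runif(1, 0, 2 * pi)
        nc <- x1 - x0 + 1L
        tt <- (seq_len(nc) - 0.5) / pxPerS
        dur <- nc / pxPerS
        nb <- ceiling(dur / (period0 * (1 - wf@beatJitter))) + 2L
        periods <- period0 * (1 + stats::runif(nb, -wf@beatJitter, wf@beatJitter))
        onsets <- c(0, cumsum(periods))
        bi <- findInterval(tt, onsets)
        val <- synthBeat(tt - onsets[bi], wf)
        val <- val + wf@baselineWanderAmp * sin(2 * pi * 0.33 * tt + phase)
        val <- val + stats::rnorm(nc, 0, wf@traceNoiseSd)
        y <- as.integer(round(baseline - val * pxPerMv * gain))
        dr <- drawTrace(img, signalMask, y, x0:x1, top, bottom, 30)
        img <- dr$img; signalMask <- dr$mask
      }
    }
    gridMask[signalMask] <- FALSE
    labelMask[signalMask] <- FALSE

    # global contrast compression toward white, then page noise
    img <- 255 - sheet@contrastScale * (255 - img)
    if (sheet@pageNoiseSd > 0)
      img <- img + stats::rnorm(length(img), 0, sheet@pageNoiseSd)
    img <- matrix(pmin(pmax(round(img), 0), 255), H, W)

    new("ECGSheet", image = img, signalMask = signalMask, gridMask = gridMask,
        labelMask = labelMask, classLabel = classLabel, waveform = wf,
        sheet = sheet)
  })
}

#' @describeIn renderSheet the rendered intensity matrix.
#' @param x an ECGSheet.
#' @export
sheetImage <- function(x) x@image

#' @describeIn renderSheet ground-truth masks as a named list.
#' @export
sheetMasks <- function(x) list(signal = x@signalMask, grid = x@gridMask,
                               label = x@labelMask)

#' @describeIn renderSheet the class label.
#' @export
sheetClass <- function(x) x@classLabel

# Per-image prior perturbation (heart rate, gain-like amplitude scaling)
# so images within a class are not identical.
perturbWaveform <- function(wf, seed) {
  withSeed(seed, {
    g <- wf@gaussComponents
    g[, "amplitude"] <- g[, "amplitude"] * stats::runif(1, 0.9, 1.1)
    waveformParams(heartRate = wf@heartRate * stats::runif(1, 0.95, 1.05),
                   beatJitter = wf@beatJitter, gaussComponents = g,
                   stOffset = wf@stOffset, tPolarity = wf@tPolarity,
                   baselineWanderAmp = wf@baselineWanderAmp,
                   traceNoiseSd = wf@traceNoiseSd)
  })
}

#' Generate a synthetic paper-ECG dataset
#'
#' Renders `perClassCounts[c]` sheets per class with class-specific beat
#' priors, writes images (and, optionally, ground-truth masks) as PNG plus a
#' JSON-lines manifest, and returns the manifest. Per-image seeds follow the
#' counter scheme `seed + image index`, so the output is a pure function of
#' (`perClassCounts`, `seed`, `sheet`).
#'
#' @param perClassCounts named integer vector over classes, e.g.
#'   `c(NHB = 859, AHB = 546, MI = 74, HMI = 203, COVID = 250)` (the default).
#' @param outDir output directory (created if needed).
#' @param seed integer top-level seed.
#' @param sheet a [SheetSpec-class] shared by all images.
#' @param writeMasks also write signal/grid/label mask PNGs.
#' @return manifest data.frame (image_id, path, class, seed), invisibly;
#'   written as `manifest.jsonl` in `outDir`.
#' @export
generateDataset <- function(perClassCounts = c(NHB = 859L, AHB = 546L, MI = 74L,
                                               HMI = 203L, COVID = 250L),
                            outDir, seed = 1L, sheet = sheetSpec(),
                            writeMasks = FALSE) {
  stopifnot(all(perClassCounts >= 0), !is.null(names(perClassCounts)))
  bad <- setdiff(names(perClassCounts), ECG_CLASSES)
  if (length(bad)) stop("unknown classes: ", paste(bad, collapse = ", "))
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    stop("cannot create output directory: ", outDir)
  rows <- list(); i <- 0L
  for (cl in intersect(ECG_CLASSES, names(perClassCounts))) {
    wf0 <- classWaveformParams(cl)
    n <- perClassCounts[[cl]]
    for (k in seq_len(n)) {
      i <- i + 1L
      si <- as.integer(seed) + i
      wfi <- perturbWaveform(wf0, si + 1000003L)
      sh <- renderSheet(cl, sheet, wfi, seed = si)
      id <- sprintf("%s_%05d", cl, i)
      path <- file.path(outDir, paste0(id, ".png"))
      writeImage8(sh@image, path)
      if (writeMasks) {
        msk <- sheetMasks(sh)
        for (mn in names(msk))
          writeImage8(msk[[mn]] * 255, file.path(outDir, sprintf("%s_%s.png", id, mn)))
      }
      rows[[i]] <- data.frame(image_id = id, path = path, class = cl, seed = si,
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows)
    else data.frame(image_id = character(), path = character(),
                    class = character(), seed = integer(),
                    stringsAsFactors = FALSE)
  writeManifest(manifest, file.path(outDir, "manifest.jsonl"))
  invisible(manifest)
}
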