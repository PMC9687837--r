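# Block structure of the hybrid network. The stem (Block-1) is
# conv,conv,conv,pool,conv,conv,pool. Blocks 2-4 stack Inception-ResNet
# units: the inception branch is nConv convs followed by one pool and the
# ResNet branch is 3 convs; the unit output is act(r(x) + alpha * i(x))
# with alpha the learnable residual scaling factor. The first unit of each
# block downsamples (the branch pool is 2x2/2 and the first ResNet conv has
# stride 2); later units are shape-preserving (3x3/1 pool, stride-1 convs).
UNIT_INCEP_CONVS <- c(block2 = 6L, block3 = 5L, block4 = 4L)

buildUnit <- function(cfg, nIncepConv, inC, downsample) {
  F <- cfg@nFilters; k <- cfg@filterSize
  mkAct <- function() newAct(cfg@activation, F, cfg@preluInit)
  incep <- list()
  for (i in seq_len(nIncepConv)) {
    incep[[length(incep) + 1L]] <- newConv(k, if (i == 1) inC else F, F)
    incep[[length(incep) + 1L]] <- mkAct()
  }
  incep[[length(incep) + 1L]] <-
    if (downsample) newPool(cfg@poolType, 2L, 2L, 0L)
    else newPool(cfg@poolType, 3L, 1L, 1L)
  res <- list()
  for (i in 1:3) {
    res[[length(res) + 1L]] <- newConv(k, if (i == 1) inC else F, F,
                                       stride = if (i == 1 && downsample) 2L else 1L)
    res[[length(res) + 1L]] <- mkAct()
  }
  newUnit(incep, res, mkAct(),
          alphaInit = if (cfg@rsfEnabled) cfg@rsfInit else 1,
          alphaTrainable = cfg@rsfEnabled)
}

#' Build the hybrid Inception-ResNet model
#'
#' Assembles Block-1 (5 convs + 2 pools), then the stacked Inception-ResNet
#' units of Blocks 2-4 (stack counts 3/5/3 by default), then the configured
#' head and a fully connected softmax output over `nClasses`. Each stacked
#' unit computes `act(r(x) + alpha * i(x))` where `i` is the inception
#' branch, `r` the ResNet branch and `alpha` the learnable residual scaling
#' factor (fixed at 1 when `rsfEnabled` is FALSE). Weight initialisation is
#' seeded.
#'
#' @param cfg a [ModelConfig-class].
#' @param seed integer seed for weight initialisation.
#' @return an [InResModel-class].
#' @examples
#' m <- buildModel(modelConfig(reduced = TRUE), seed = 1)
#' countLayers(m)$perBlock
#' @export
buildModel <- function(cfg = modelConfig(), seed = 1L) {
  validObject(cfg)
  F <- cfg@nFilters; k <- cfg@filterSize
  withSeed(seed, {
    mkAct <- function() newAct(cfg@activation, F, cfg@preluInit)
    stem <- list(newConv(k, cfg@inputChannels, F), mkAct(),
                 newConv(k, F, F), mkAct(), newConv(k, F, F), mkAct(),
                 newPool(cfg@poolType, 2L, 2L, 0L),
                 newConv(k, F, F), mkAct(), newConv(k, F, F), mkAct(),
                 newPool(cfg@poolType, 2L, 2L, 0L))
    blocks <- list(block1 = stem)
    H <- cfg@inputSize[1] %/% 4L; W <- cfg@inputSize[2] %/% 4L
    if (cfg@inputSize[1] %% 4L || cfg@inputSize[2] %% 4L)
      stop("incompatible input size vs pooling depth (need multiples of 4)")
    for (b in 1:3) {
      bn <- paste0("block", b + 1L)
      units <- list()
      for (u in seq_len(cfg@stackCounts[b])) {
        down <- u == 1L
        if (down) {
          if (H %% 2L || W %% 2L || H < 2L || W < 2L)
            stop("incompatible input size vs pooling depth at ", bn)
          H <- H %/% 2L; W <- W %/% 2L
        }
        units[[u]] <- buildUnit(cfg, UNIT_INCEP_CONVS[b], F, down)
      }
      blocks[[bn]] <- units
    }
    head <- newHead(cfg@headType)
    featN <- if (cfg@headType == "flatten") H * W * F else F
    blocks$head <- list(head, newDense(featN, cfg@nClasses))
    new("InResModel", layers = blocks, config = cfg,
        classLevels = if (cfg@nClasses == 5L) ECG_CLASSES
                      else as.character(seq_len(cfg@nClasses)),
        history = data.frame())
  })
}

modelFwd <- function(model, x) {
  for (bn in names(model@layers)) x <- seqFwd(model@layers[[bn]], x)
  softmaxRows(x)
}

modelLayerList <- function(model) unlist(model@layers, recursive = FALSE)

#' Count layers per block
#'
#' Under the default convention a layer is a convolution or a pooling layer
#' (activations and the residual scale are not counted; the head is not a
#' block). Alternative conventions are reported for transparency.
#'
#' @param model an [InResModel-class].
#' @param convention "conv_pool" (default), "conv_only" or
#'   "with_activation".
#' @return list with `perBlock`, `total`, and `allConventions`.
#' @export
countLayers <- function(model, convention = c("conv_pool", "conv_only",
                                              "with_activation")) {
  convention <- match.arg(convention)
  countIn <- function(layers, kinds) {
    n <- 0L
    for (l in layers) {
      if (l$type %in% kinds) n <- n + 1L
      if (l$type == "unit")
        n <- n + countIn(l$incep, kinds) + countIn(l$res, kinds) +
          countIn(list(l$act), kinds)
    }
    n
  }
  kinds <- switch(convention, conv_pool = c("conv", "pool"),
                  conv_only = "conv", with_activation = c("conv", "pool", "act"))
  blocks <- setdiff(names(model@layers), "head")
  perBlock <- vapply(blocks, function(b) countIn(model@layers[[b]], kinds),
                     integer(1))
  all <- lapply(c(conv_pool = "conv_pool", conv_only = "conv_only",
                  with_activation = "with_activation"), function(cv) {
    kk <- switch(cv, conv_pool = c("conv", "pool"), conv_only = "conv",
                 with_activation = c("conv", "pool", "act"))
    sum(vapply(blocks, function(b) countIn(model@layers[[b]], kk), integer(1)))
  })
  list(perBlock = perBlock, total = sum(perBlock), allConventions = all)
}

#' Count multiply-accumulate operations
#'
#' Sum over conv layers of outH*outW*outC*inC*kH*kW plus the fully
#' connected products, for the model's configured input size.
#'
#' @param model an [InResModel-class].
#' @param inputSize input (height, width); defaults to the config.
#' @return list with `total` MACs and `millions`.
#' @export
countMacs <- function(model, inputSize = model@config@inputSize) {
  total <- 0
  walk <- function(layers, H, W) {
    for (l in layers) {
      if (l$type == "conv") {
        oH <- (H + 2 * l$pad - l$k) %/% l$stride + 1L
        oW <- (W + 2 * l$pad - l$k) %/% l$stride + 1L
        total <<- total + as.numeric(oH) * oW * l$outC * l$inC * l$k * l$k
        H <- oH; W <- oW
      } else if (l$type == "pool") {
        H <- (H + 2 * l$pad - l$size) %/% l$stride + 1L
        W <- (W + 2 * l$pad - l$size) %/% l$stride + 1L
      } else if (l$type == "unit") {
        d <- walk(l$incep, H, W)
        walk(l$res, H, W)
        H <- d[1]; W <- d[2]
      } else if (l$type == "dense") {
        total <<- total + as.numeric(l$inN) * l$outN
      }
    }
    c(H, W)
  }
  d <- c(inputSize[1], inputSize[2])
  for (bn in names(model@layers)) d <- walk(model@layers[[bn]], d[1], d[2])
  list(total = total, millions = total / 1e6)
}

oneHot <- function(labels, levels) {
  outer(as.character(labels), levels, "==") * 1
}

#' Predict class probabilities
#'
#' @param model a built [InResModel-class].
#' @param x input array (H, W, C, N) with intensities on [0, 1].
#' @param batchSize forward batch size.
#' @return N x K probability matrix with class column names.
#' @export
predictProbs <- function(model, x, batchSize = 64L) {
  N <- dim(x)[4]
  out <- matrix(NA_real_, N, model@config@nClasses,
                dimnames = list(NULL, model@classLevels))
  i <- 1L
  while (i <= N) {
    j <- min(i + batchSize - 1L, N)
    out[i:j, ] <- modelFwd(model, x[, , , i:j, drop = FALSE])
    i <- j + 1L
  }
  out
}

#' Train the model
#'
#' Minimises the configured loss with the configured optimizer over seeded
#' shuffled minibatches; records per-epoch train/validation accuracy and
#' loss and restores the weights of the best validation epoch at the end
#' (when validation data are given).
#'
#' @param model a built [InResModel-class] (modified in place; also
#'   returned).
#' @param x,y training inputs (H, W, C, N array on [0, 1]) and labels.
#' @param xVal,yVal optional validation data.
#' @param epochs number of epochs; defaults to the config.
#' @param seed seed controlling shuffle order.
#' @param verbose print per-epoch progress.
#' @return the model, with its `history` slot filled; attribute
#'   `"bestEpoch"` on the history marks the checkpointed epoch.
#' @export
trainModel <- function(model, x, y, xVal = NULL, yVal = NULL,
                       epochs = model@config@epochs, seed = 1L,
                       verbose = FALSE) {
  cfg <- model@config
  N <- dim(x)[4]
  if (N == 0L) stop("empty training split")
  Y <- oneHot(y, model@classLevels)
  params <- collectParams(modelLayerList(model))
  bs <- cfg@batchSize
  hist <- vector("list", epochs)
  best <- -Inf; bestEpoch <- NA_integer_; bestW <- NULL
  t <- 0L
  withSeed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      epLoss <- 0; epHit <- 0L
      i <- 1L
      while (i <= N) {
        j <- min(i + bs - 1L, N)
        idx <- ord[i:j]
        xb <- x[, , , idx, drop = FALSE]
        yb <- Y[idx, , drop = FALSE]
        logits <- xb
        for (bn in names(model@layers)) logits <- seqFwd(model@layers[[bn]], logits)
        P <- softmaxRows(logits)
        lg <- lossAndGradP(cfg@loss, P, yb)
        epLoss <- epLoss + lg$value * length(idx)
        epHit <- epHit + sum(max.col(P) == max.col(yb))
        dP <- lg$dP
        dZ <- P * (dP - rowSums(dP * P))
        dout <- dZ
        for (bn in rev(names(model@layers)))
          dout <- seqBwd(model@layers[[bn]], dout)
        t <- t + 1L
        if (cfg@learningRate > 0)
          optimStep(params, cfg@optimizer, cfg@learningRate, t)
        i <- j + 1L
      }
      row <- data.frame(epoch = ep, trainLoss = epLoss / N, trainAcc = epHit / N,
                        valLoss = NA_real_, valAcc = NA_real_)
      if (!is.null(xVal)) {
        Pv <- predictProbs(model, xVal)
        Yv <- oneHot(yVal, model@classLevels)
        row$valLoss <- lossAndGradP(cfg@loss, Pv, Yv)$value
        row$valAcc <- mean(max.col(Pv) == max.col(Yv))
        if (row$valAcc > best) {
          best <- row$valAcc; bestEpoch <- ep
          bestW <- lapply(params, function(pr) get(pr$p, envir = pr$env))
        }
      }
      hist[[ep]] <- row
      if (verbose)
        message(sprintf("epoch %d: loss %.4f acc %.3f val %.3f", ep,
                        row$trainLoss, row$trainAcc, row$valAcc))
    }
  })
  if (!is.null(bestW))
    for (k in seq_along(params))
      assign(params[[k]]$p, bestW[[k]], envir = params[[k]]$env)
  h <- do.call(rbind, hist)
  attr(h, "bestEpoch") <- bestEpoch
  model@history <- h
  model
}

#' Evaluate a trained model
#'
#' @param model a trained [InResModel-class].
#' @param x input array (H, W, C, N).
#' @param y actual labels.
#' @return list with `confusion` (a [ConfusionMatrix-class], rows = actual,
#'   columns = predicted), `scores` (N x K probabilities) and `accuracy`.
#' @export
evaluateModel <- function(model, x, y) {
  bad <- setdiff(unique(as.character(y)), model@classLevels)
  if (length(bad)) stop("labels outside the class set: ", paste(bad, collapse = ", "))
  P <- predictProbs(model, x)
  pred <- model@classLevels[max.col(P)]
  cm <- confusionMatrix(actual = as.character(y), predicted = pred,
                        levels = model@classLevels)
  list(confusion = cm, scores = P, accuracy = mean(pred == as.character(y)))
}

#' Load manifest images as a model input tensor
#'
#' Reads each image, converts to grayscale if needed, optionally runs the
#' preparation pipeline, resizes bilinearly to `inputSize` and scales
#' intensities to [0, 1].
#'
#' @param manifest data.frame with `path` and `class` columns.
#' @param inputSize target (height, width).
#' @param pipeline optional [PipelineConfig-class]; when given, each image
#'   is run through [runPipeline()] first.
#' @param stopAfter passed to [runPipeline()] (e.g. "line_removed" to train
#'   on the artifact-removed binary signal image).
#' @return list with `x` (H, W, 1, N array) and `y` (class labels).
#' @export
loadManifestImages <- function(manifest, inputSize = c(64L, 64L),
                               pipeline = NULL, stopAfter = NULL) {
  N <- nrow(manifest)
  x <- array(0, c(inputSize[1], inputSize[2], 1L, N))
  for (i in seq_len(N)) {
    img <- readImage8(manifest$path[i])
    if (length(dim(img)) == 3L) img <- toGrayscale(img)
    if (!is.null(pipeline))
      img <- finalImage(runPipeline(img, pipeline, stopAfter = stopAfter)) * 1
    x[, , 1L, i] <- resizeBilinear(img, inputSize[1], inputSize[2]) / 255
  }
  list(x = x, y = manifest$class)
}
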