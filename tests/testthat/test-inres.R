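test_that("prelu follows the piecewise-linear form and its limits", {
  expect_equal(prelu(2.0, 0.7), 2.0)
  expect_equal(prelu(-4.0, 0.1), -0.4)
  expect_equal(prelu(0, 0.1), 0)
  x <- seq(-3, 3, by = 0.25)
  expect_equal(prelu(x, 0), pmax(x, 0))   # K = 0 is ReLU
  expect_equal(prelu(x, 1), x)            # K = 1 is the identity
})

test_that("buildModel wires the head and softmax output", {
  m <- buildModel(modelConfig(reduced = TRUE), seed = 2L)
  x <- array(runif(64 * 64 * 1 * 2), c(64, 64, 1, 2))
  p <- predictProbs(m, x)
  expect_identical(dim(p), c(2L, 5L))
  expect_equal(rowSums(p), c(1, 1), tolerance = 1e-12)
  expect_identical(colnames(p), c("NHB", "AHB", "MI", "HMI", "COVID"))

  m3 <- buildModel(modelConfig(reduced = TRUE, nClasses = 3L), seed = 2L)
  expect_identical(dim(predictProbs(m3, x)), c(2L, 3L))

  expect_error(buildModel(modelConfig(inputSize = c(10L, 10L))),
               "pooling depth")
})

test_that("layer counts match the per-block convention", {
  m <- buildModel(modelConfig(), seed = 1L)   # full-size stacks 3/5/3
  cl <- countLayers(m)
  expect_equal(unname(cl$perBlock["block1"]), 7L)   # 5 conv + 2 pool
  expect_equal(unname(cl$perBlock["block2"]), 30L)
  expect_equal(unname(cl$perBlock["block3"]), 45L)
  expect_equal(unname(cl$perBlock["block4"]), 24L)
  expect_equal(cl$total, 106L)
  expect_true(all(c("conv_pool", "conv_only", "with_activation") %in%
                  names(cl$allConventions)))
  expect_lt(cl$allConventions$conv_only, cl$allConventions$conv_pool)

  toy <- buildModel(modelConfig(reduced = TRUE), seed = 1L)
  cl2 <- countLayers(toy)
  # one unit per block: 6+1+3 / 5+1+3 / 4+1+3 plus the 7-layer stem
  expect_equal(unname(cl2$perBlock), c(7L, 10L, 9L, 8L))
})

test_that("countMacs equals the per-layer closed form", {
  cfg <- modelConfig(reduced = TRUE)
  mk <- function(layers, inputSize) {
    new("InResModel", layers = list(block1 = layers),
        config = modelConfig(reduced = TRUE,
                             inputSize = as.integer(inputSize)),
        classLevels = "x", history = data.frame())
  }
  # single 3x3 conv, 1 -> 1 channel, 10x10 same-padded output
  conv1 <- withr::with_seed(1, InResECG:::newConv(3L, 1L, 1L))
  expect_equal(countMacs(mk(list(conv1), c(10, 10)))$total, 900)

  # fully connected 100 -> 5
  d <- withr::with_seed(1, InResECG:::newDense(100L, 5L))
  expect_equal(countMacs(mk(list(d), c(10, 10)))$total, 500)

  # linear in the output-channel count
  c8 <- withr::with_seed(1, InResECG:::newConv(3L, 1L, 8L))
  c16 <- withr::with_seed(1, InResECG:::newConv(3L, 1L, 16L))
  expect_equal(countMacs(mk(list(c16), c(12, 12)))$total,
               2 * countMacs(mk(list(c8), c(12, 12)))$total)

  # deterministic for a fixed graph
  m <- buildModel(cfg, seed = 3L)
  expect_equal(countMacs(m)$total, countMacs(m)$total)
})

test_that("disabling the residual scale fixes alpha at 1 and keeps topology", {
  on <- buildModel(modelConfig(reduced = TRUE), seed = 1L)
  off <- buildModel(modelConfig(reduced = TRUE, rsfEnabled = FALSE), seed = 1L)
  expect_equal(countLayers(on)$perBlock, countLayers(off)$perBlock)
  unitOn <- on@layers$block2[[1]]
  unitOff <- off@layers$block2[[1]]
  expect_equal(unitOn$alpha, 0.1)
  expect_true(unitOn$alphaTrainable)
  expect_equal(unitOff$alpha, 1)
  expect_false(unitOff$alphaTrainable)
  nOn <- length(InResECG:::collectParams(InResECG:::modelLayerList(on)))
  nOff <- length(InResECG:::collectParams(InResECG:::modelLayerList(off)))
  expect_equal(nOn - nOff, 3L)  # one alpha per stacked unit
})

test_that("training reduces the loss on a degenerate batch and respects lr = 0", {
  cfg <- modelConfig(reduced = TRUE, batchSize = 8L)
  m <- buildModel(cfg, seed = 4L)
  withr::with_seed(4, {
    one <- array(runif(64 * 64), c(64, 64, 1, 1))
  })
  x <- one[, , , rep(1, 8), drop = FALSE]
  y <- rep("MI", 8)
  m <- trainModel(m, x, y, epochs = 5, seed = 4L)
  expect_true(all(diff(m@history$trainLoss) < 0))

  cfg0 <- modelConfig(reduced = TRUE, learningRate = 0, batchSize = 8L)
  m0 <- buildModel(cfg0, seed = 4L)
  w0 <- m0@layers$head[[2]]$W
  m0 <- trainModel(m0, x, y, epochs = 3, seed = 4L)
  expect_identical(m0@layers$head[[2]]$W, w0)
  expect_equal(diff(m0@history$trainAcc), c(0, 0))
})

test_that("evaluateModel reports a consistent confusion matrix and scores", {
  m <- buildModel(modelConfig(reduced = TRUE), seed = 5L)
  withr::with_seed(5, {
    x <- array(runif(64 * 64 * 1 * 12), c(64, 64, 1, 12))
    y <- sample(c("NHB", "AHB", "MI", "HMI", "COVID"), 12, TRUE)
  })
  ev <- evaluateModel(m, x, y)
  expect_equal(sum(cmCounts(ev$confusion)), 12)
  expect_equal(rowSums(ev$scores), rep(1, 12), tolerance = 1e-12)
  expect_error(evaluateModel(m, x, rep("unknown", 12)), "class set")
})
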