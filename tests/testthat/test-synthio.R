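test_that("synthBeat evaluates the Gaussian-sum template", {
  g0 <- defaultBeatComponents(); g0[, "amplitude"] <- 0
  wfZero <- waveformParams(gaussComponents = g0, baselineWanderAmp = 0,
                           traceNoiseSd = 0)
  expect_equal(synthBeat(seq(0, 0.8, by = 0.05), wfZero),
               rep(0, 17))

  g1 <- g0; g1["R", ] <- c(1, 0.2, 0.05)
  wf1 <- waveformParams(gaussComponents = g1)
  expect_equal(synthBeat(0.2, wf1), 1.0)

  # default morphology at the R centre: independent term-by-term arithmetic
  wf <- waveformParams()
  g <- defaultBeatComponents()
  tR <- g["R", "center"]
  expected <- 0
  for (i in 1:5) {
    a <- g[i, "amplitude"]
    expected <- expected + a * exp(-(tR - g[i, "center"])^2 / (2 * g[i, "width"]^2))
  }
  expect_equal(synthBeat(tR, wf), expected)

  # ST offset applies strictly between the S and T centres
  wfSt <- waveformParams(gaussComponents = g0, stOffset = 0.3)
  g <- defaultBeatComponents()
  mid <- (g["S", "center"] + g["T", "center"]) / 2
  expect_equal(synthBeat(mid, wfSt), 0.3)
  expect_equal(synthBeat(g["S", "center"] - 0.05, wfSt), 0)

  # T polarity flips only the T deflection
  wfT <- waveformParams(tPolarity = -1)
  tT <- g["T", "center"]
  expect_lt(synthBeat(tT, wfT), 0)
})

test_that("renderSheet is deterministic and honours the layout contract", {
  sp <- testSheetSpec(seed = 3L)
  a <- renderSheet("MI", sp)
  b <- renderSheet("MI", sp)
  expect_identical(sheetImage(a), sheetImage(b))
  expect_identical(sheetMasks(a), sheetMasks(b))

  img <- sheetImage(a)
  expect_identical(dim(img), c(240L, 320L))
  msk <- sheetMasks(a)
  expect_false(any(msk$signal & msk$grid))
  expect_false(any(msk$signal & msk$label))
  expect_false(any(msk$grid & msk$label))
  # label ink only inside the bands
  labRows <- which(apply(msk$label, 1, any))
  expect_true(all(labRows <= 24 | labRows > 240 - 24))
  # trace only inside the lead area
  sigRows <- which(apply(msk$signal, 1, any))
  expect_true(all(sigRows > 24 & sigRows <= 240 - 24))

  # layout overflow is a configuration error
  expect_error(renderSheet("NHB", sheetSpec(widthPx = 300L, heightPx = 120L,
                                            labelBandTopPx = 40L,
                                            labelBandBottomPx = 40L)),
               "overflow")
})

test_that("default sheet geometry matches the scanned-page dimensions", {
  sh <- fullSheet()
  expect_identical(dim(sheetImage(sh)), c(1572L, 2213L))
})

test_that("an invisible (white) grid leaves the rendered page unchanged", {
  spWhite <- testSheetSpec(gridIntensity = 255, seed = 9L)
  spGray <- testSheetSpec(gridIntensity = 210, seed = 9L)
  a <- renderSheet("NHB", spWhite)
  b <- renderSheet("NHB", spGray)
  expect_gt(sum(a@gridMask), 0)
  # the two renders may differ only where the visible grid was drawn
  diff <- sheetImage(a) != sheetImage(b)
  expect_true(all(diff[!b@gridMask] == FALSE))
})

test_that("erasing grid-mask pixels removes the grid's intensity deviation", {
  sp <- testSheetSpec(pageNoiseSd = 0, seed = 21L)
  sh <- renderSheet("AHB", sp)
  ref <- renderSheet("AHB", testSheetSpec(pageNoiseSd = 0, seed = 21L,
                                          gridIntensity = 255))
  img <- sheetImage(sh)
  devBefore <- sum(abs(img - sheetImage(ref)))
  img[sh@gridMask] <- 255
  devAfter <- sum(abs(img - sheetImage(ref)))
  expect_gte(1 - devAfter / devBefore, 0.99)
})

test_that("generateDataset writes a reproducible manifest-backed dataset", {
  d0 <- withr::local_tempdir()
  empty <- generateDataset(c(NHB = 0L), d0, seed = 1L, sheet = testSheetSpec())
  expect_identical(nrow(empty), 0L)
  expect_identical(nrow(readManifest(file.path(d0, "manifest.jsonl"))), 0L)

  counts <- c(NHB = 2L, AHB = 2L, MI = 2L, HMI = 2L, COVID = 2L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- generateDataset(counts, d1, seed = 4L, sheet = testSheetSpec())
  m2 <- generateDataset(counts, d2, seed = 4L, sheet = testSheetSpec())
  expect_identical(nrow(m1), 10L)
  expect_identical(sort(unique(m1$class)), sort(ECG5))
  sums1 <- unname(tools::md5sum(sort(list.files(d1, "png$", full.names = TRUE))))
  sums2 <- unname(tools::md5sum(sort(list.files(d2, "png$", full.names = TRUE))))
  expect_identical(sums1, sums2)
  # round-trip through the manifest
  rm <- readManifest(file.path(d1, "manifest.jsonl"))
  expect_identical(rm$image_id, m1$image_id)
})

test_that("class priors produce separable beat morphology", {
  sp <- morphSheetSpec()
  feats <- list(); labs <- character(); i <- 0
  for (cl in ECG5) for (k in 1:10) {
    i <- i + 1
    wf <- InResECG:::perturbWaveform(classWaveformParams(cl), 1000 + i)
    sh <- renderSheet(cl, sp, wf, seed = 100 + i)
    feats[[i]] <- beatTraceStats(sh, sp)
    labs[i] <- cl
  }
  ok <- !vapply(feats, is.null, logical(1))
  expect_gte(sum(ok), 45)
  df <- data.frame(do.call(rbind, feats[ok]), class = factor(labs[ok]))
  fit <- rpart::rpart(class ~ ., df,
                      control = rpart::rpart.control(maxdepth = 4,
                                                     minsplit = 2, cp = 0))
  acc <- mean(predict(fit, df, type = "class") == df$class)
  expect_equal(acc, 1)
})
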