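test_that("cropLabels removes the label bands by exact sub-windowing", {
  cfg <- pipelineConfig()
  big <- matrix(seq_len(1572L * 2213L), 1572, 2213)
  out <- cropLabels(big, cfg)
  expect_identical(dim(out), c(1210L, 2058L))
  # exact sub-window (no resampling): removed rows split 181/181, cols 77/78
  expect_identical(out, big[182:1391, 78:2135])

  idcfg <- pipelineConfig(cropRatioW = 1, cropRatioH = 1)
  expect_identical(cropLabels(big, idcfg), big)

  sq <- matrix(0, 1000, 1000)
  expect_identical(dim(cropLabels(sq, cfg)),
                   as.integer(c(floor(1000 * 1210 / 1572),
                                floor(1000 * 2058 / 2213))))

  expect_error(pipelineConfig(cropRatioW = 1.2), "ratios")
})

test_that("toGrayscale applies the luma weights", {
  px <- function(r, g, b) array(c(r, g, b), c(1, 1, 3))
  expect_equal(as.numeric(toGrayscale(px(255, 255, 255))), 255)
  expect_equal(as.numeric(toGrayscale(px(0, 0, 0))), 0)
  expect_equal(as.numeric(toGrayscale(px(100, 150, 200))),
               round(0.299 * 100 + 0.587 * 150 + 0.114 * 200))  # 141
  expect_error(toGrayscale(matrix(0, 2, 2)), "3-channel")
})

test_that("otsuThreshold maximises between-class variance (exhaustive oracle)", {
  ex <- matrix(c(10, 12, 11, 200, 205, 199, 10, 201), 2, 4)
  r <- otsuThreshold(ex)
  expect_equal(r$threshold, bruteOtsu(ex))
  expect_false(r$degenerate)
  # dark side is the foreground
  expect_true(all((r$binary == 255) == (ex <= r$threshold)))

  bi <- matrix(rep(c(0, 255), each = 8), 4, 4)
  rb <- otsuThreshold(bi)
  expect_true(all(rb$binary[bi == 0] == 255))
  expect_true(all(rb$binary[bi == 255] == 0))

  rc <- otsuThreshold(matrix(77, 5, 5))
  expect_true(rc$degenerate)
  expect_equal(rc$threshold, 77)
  expect_true(all(rc$binary == 0))

  withr::with_seed(42, {
    for (rep in 1:20) {
      img <- matrix(sample(0:255, 256, TRUE), 16, 16)
      expect_equal(otsuThreshold(img)$threshold, bruteOtsu(img))
    }
  })
})

test_that("morphOpen removes sub-element structures and is a proper opening", {
  z <- matrix(0, 8, 8)
  expect_equal(morphOpen(z), z)

  single <- z; single[4, 4] <- 255
  expect_equal(morphOpen(single), z)

  block <- matrix(0, 14, 14); block[3:12, 3:12] <- 255
  expect_equal(morphOpen(block), block)

  # a 1-px line cannot contain the 2x2 element
  line <- matrix(0, 10, 10); line[5, ] <- 255
  expect_true(all(morphOpen(line) == 0))

  expect_error(morphOpen(matrix(3, 2, 2)), "binary")

  withr::with_seed(7, {
    for (rep in 1:10) {
      x <- randomBinary(20, 20)
      o <- morphOpen(x)
      expect_true(all(o <= x))               # anti-extensive
      expect_equal(morphOpen(o), o)          # idempotent
    }
  })
})

test_that("findSmallComponents uses 8-connectivity and a strict area bound", {
  img <- matrix(0, 30, 40)
  img[2:6, 2:3] <- 255            # size 10
  img[10:19, 10:19] <- 255        # size 100
  m <- findSmallComponents(img, 50)
  expect_equal(sum(m), 10)
  expect_true(all(which(m) %in% which(img == 255 &
                                      row(img) <= 6 & col(img) <= 3)))

  # size exactly 50 is excluded (strict <)
  img50 <- matrix(0, 20, 20); img50[3:7, 3:12] <- 255
  expect_equal(sum(findSmallComponents(img50, 50)), 0)
  expect_equal(sum(findSmallComponents(img50, 51)), 50)

  # diagonal neighbours belong to one component
  diag2 <- matrix(0, 10, 10)
  for (i in 1:6) diag2[i, i] <- 255
  expect_equal(sum(findSmallComponents(diag2, 7)), 6)
  expect_equal(sum(findSmallComponents(diag2, 6)), 0)

  expect_equal(sum(findSmallComponents(matrix(0, 5, 5), 50)), 0)

  # partition property: small-mask and remainder tile the foreground
  withr::with_seed(11, {
    x <- randomBinary(30, 30, 0.4)
    sm <- findSmallComponents(x, 20)
    rest <- removeComponents(x, sm)
    expect_true(all((rest == 255) + sm == (x == 255)))
  })
})

test_that("removeComponents subtracts exactly the masked pixels", {
  x <- randomBinary(10, 10)
  expect_equal(removeComponents(x, matrix(FALSE, 10, 10)), x)
  expect_true(all(removeComponents(x, x == 255) == 0))
  expect_error(removeComponents(x, matrix(FALSE, 5, 5)), "mismatch")
})

test_that("invertImage is the 255-complement involution", {
  x <- matrix(c(0, 100, 255, 40), 2, 2)
  expect_equal(invertImage(invertImage(x)), x)
  expect_equal(invertImage(matrix(0, 2, 2)), matrix(255, 2, 2))
  expect_equal(invertImage(matrix(100, 1, 1))[1, 1], 155)
})

test_that("gaussianBlur matches the normalised kernel on an impulse", {
  const <- matrix(120, 9, 9)
  expect_equal(gaussianBlur(const), const)

  imp <- matrix(0, 11, 11); imp[6, 6] <- 1
  out <- gaussianBlur(imp, c(3L, 3L), sigma = 0.8)
  g <- exp(-((-1:1)^2) / (2 * 0.8^2)); g <- g / sum(g)
  expect_equal(out[5:7, 5:7], outer(g, g), tolerance = 1e-12)
  expect_equal(sum(out), 1, tolerance = 1e-12)

  expect_error(gaussianBlur(imp, c(2L, 2L)), "odd")
})

test_that("estimateSigma recovers additive noise levels", {
  expect_lt(estimateSigma(matrix(128, 16, 16)), 0.5)
  withr::with_seed(13, {
    noisy <- matrix(128 + rnorm(64 * 64, 0, 10), 64, 64)
    s <- estimateSigma(noisy)
    expect_gte(s, 8); expect_lte(s, 12)
    expect_equal(estimateSigma(noisy + 31), s)
  })
  expect_error(estimateSigma(matrix(0, 4, 4)), "small")
})

test_that("nlmDenoise matches the brute-force patch-weight oracle", {
  withr::with_seed(17, {
    img <- matrix(runif(64, 0, 255), 8, 8)
    for (h in c(5, 20)) {
      mine <- nlmDenoise(img, patchSize = 3L, patchDistance = 2L, h = h)
      ref <- bruteNlm(img, 3L, 2L, h)
      expect_lt(max(abs(mine - ref)), 1e-6)
    }
    # default-parameter geometry against the oracle as well
    img2 <- matrix(runif(144, 0, 255), 12, 12)
    expect_lt(max(abs(nlmDenoise(img2, 5L, 6L, 15) - bruteNlm(img2, 5L, 6L, 15))),
              1e-6)
  })
  expect_error(nlmDenoise(matrix(0, 8, 8), h = 0), "h must be")
})

test_that("nlmDenoise reduces noise on a corrupted render", {
  sp <- testSheetSpec(pageNoiseSd = 0, seed = 31L)
  clean <- sheetImage(renderSheet("NHB", sp))[101:180, 101:220]
  withr::with_seed(31, {
    noisy <- clean + rnorm(length(clean), 0, 15)
  })
  den <- nlmDenoise(noisy, 5L, 6L, h = 1.15 * estimateSigma(noisy))
  expect_lt(mean((den - clean)^2), mean((noisy - clean)^2))
})

test_that("histEqualize follows the cumulative-distribution mapping", {
  x <- matrix(c(0, 0, 255, 255), 2, 2)
  out <- histEqualize(x)
  # CDF(0) = 0.5 -> floor(255 * 0.5 + 0.5) = 128; CDF(255) = 1 -> 255
  expect_equal(sort(unique(as.vector(out))), c(128, 255))
  expect_equal(out[x == 0], c(128, 128))

  # exactly uniform input maps almost to the identity
  u <- matrix(0:255, 16, 16)
  lut <- attr(histEqualize(u), "lut")
  expect_true(all(abs(lut - 0:255) <= 1))

  withr::with_seed(19, {
    r <- matrix(sample(0:255, 400, TRUE), 20, 20)
    lutR <- attr(histEqualize(r), "lut")
    expect_true(all(diff(lutR) >= 0))
    expect_true(all(lutR >= 0 & lutR <= 255))
  })
})

test_that("runPipeline chains the stages and retains intermediates", {
  sp <- testSheetSpec(seed = 23L)
  sh <- renderSheet("MI", sp)
  res <- runPipeline(sheetImage(sh))
  expect_s4_class(res, "PreprocessResult")
  expect_setequal(names(res@intermediates),
                  c("cropped", "gray", "otsu_binary", "opened",
                    "small_contour_mask", "line_removed", "inverted",
                    "blurred", "denoised", "equalized"))
  expect_identical(finalImage(res), stageImage(res, "equalized"))

  # deterministic
  res2 <- runPipeline(sheetImage(sh))
  expect_identical(finalImage(res), finalImage(res2))

  # disabling HE stops after denoising
  resNoHe <- runPipeline(sheetImage(sh), pipelineConfig(applyHE = FALSE))
  expect_identical(finalImage(resNoHe), stageImage(res, "denoised"))
  expect_false("equalized" %in% names(resNoHe@intermediates))

  # ground-truth efficacy on the synthetic sheet
  st <- gridRemovalStats(sh, res)
  expect_gte(st["gridRemoved"], 0.95)
  expect_gte(st["signalRetained"], 0.90)
})

test_that("runPipeline stage errors carry the stage name", {
  expect_error(runPipeline(matrix(0, 4, 4)), "estimate_sigma|crop_labels")
})
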