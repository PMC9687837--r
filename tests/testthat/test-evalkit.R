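cm2 <- confusionMatrix(matrix(c(50, 10, 5, 35), 2,
                              dimnames = list(c("a", "b"), c("a", "b"))))

test_that("perClassCounts decomposes one-vs-rest", {
  expect_equal(perClassCounts(cm2, "a"),
               c(TP = 50, TN = 35, FP = 10, FN = 5))
  expect_error(perClassCounts(cm2, "z"), "unknown class")

  diag3 <- confusionMatrix(diag(c(3, 4, 5)), levels = c("x", "y", "z"))
  for (cl in c("x", "y", "z")) {
    ct <- perClassCounts(diag3, cl)
    expect_equal(unname(ct["FP"]), 0)
    expect_equal(unname(ct["FN"]), 0)
    expect_equal(sum(ct), 12)
  }
})

test_that("cmMetrics evaluates the one-vs-rest formulas", {
  met <- cmMetrics(cm2)
  expect_equal(met$perClass["a", "precision"], 50 / 60, tolerance = 1e-12)
  expect_equal(met$perClass["a", "recall"], 50 / 55, tolerance = 1e-12)
  expect_equal(met$perClass["a", "f1"],
               2 * (50 / 60) * (50 / 55) / (50 / 60 + 50 / 55),
               tolerance = 1e-12)
  expect_equal(round(met$perClass["a", c("precision", "recall", "f1")],
                     4),
               data.frame(precision = 0.8333, recall = 0.9091, f1 = 0.8696,
                          row.names = "a"))
  expect_equal(met$accuracy, 85 / 100)

  perf <- cmMetrics(confusionMatrix(diag(c(5, 5)), levels = c("a", "b")))
  expect_true(all(perf$perClass[, c("recall", "specificity", "precision",
                                    "f1")] == 1))
  expect_true(all(perf$perClass[, c("fpr", "fnr", "fdr")] == 0))
})

test_that("complement identities hold exactly on random confusion matrices", {
  withr::with_seed(3, {
    for (rep in 1:25) {
      K <- sample(2:6, 1)
      m <- matrix(rpois(K * K, 8) + (diag(K) * 5), K,
                  dimnames = list(letters[1:K], letters[1:K]))
      met <- suppressWarnings(cmMetrics(confusionMatrix(m)))
      pc <- met$perClass
      okRows <- stats::complete.cases(pc)
      expect_equal(pc$fpr[okRows], 1 - pc$specificity[okRows], tolerance = 1e-12)
      expect_equal(pc$fnr[okRows], 1 - pc$recall[okRows], tolerance = 1e-12)
      expect_equal(pc$fdr[okRows], 1 - pc$precision[okRows], tolerance = 1e-12)
    }
  })
})

test_that("metrics are equivariant under class permutation", {
  m <- matrix(c(20, 3, 1, 2, 30, 4, 5, 2, 25), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  met <- cmMetrics(confusionMatrix(m))
  p <- c(3, 1, 2)
  mp <- m[p, p]
  metP <- cmMetrics(confusionMatrix(mp))
  expect_equal(metP$perClass[rownames(m)[p], ], met$perClass[rownames(m)[p], ])
  expect_equal(metP$macro, met$macro)
  expect_equal(mccScore(confusionMatrix(mp)), mccScore(confusionMatrix(m)))
  expect_equal(kappaScore(confusionMatrix(mp)), kappaScore(confusionMatrix(m)))
})

test_that("maeRmse averages one-hot-vs-score deviations", {
  sc <- matrix(c(1, 0, 0, 0, 0), 1, dimnames = list(NULL, letters[1:5]))
  expect_equal(maeRmse("a", sc), c(mae = 0, rmse = 0))

  uni <- matrix(0.2, 1, 5, dimnames = list(NULL, letters[1:5]))
  r <- maeRmse("a", uni)
  expect_equal(unname(r["mae"]), (0.8 + 4 * 0.2) / 5)  # 0.32
  expect_equal(unname(r["rmse"]), sqrt((0.8^2 + 4 * 0.2^2) / 5))

  withr::with_seed(6, {
    for (rep in 1:10) {
      s <- matrix(runif(20), 4, 5, dimnames = list(NULL, letters[1:5]))
      s <- s / rowSums(s)
      y <- sample(letters[1:5], 4, TRUE)
      rr <- maeRmse(y, s)
      expect_gte(rr["rmse"], rr["mae"])
    }
  })
})

test_that("mcc and kappa agree with their definitions", {
  perf <- confusionMatrix(diag(c(4, 5, 6)), levels = c("a", "b", "c"))
  expect_equal(mccScore(perf), 1)
  expect_equal(kappaScore(perf), 1)

  chance <- confusionMatrix(matrix(25, 2, 2, dimnames = list(c("a", "b"),
                                                             c("a", "b"))))
  expect_equal(kappaScore(chance), 0)

  withr::with_seed(10, {
    for (rep in 1:15) {
      m <- matrix(rpois(9, 6), 3, dimnames = list(letters[1:3], letters[1:3]))
      if (sum(m) == 0) next
      mcc <- mccScore(confusionMatrix(m))
      if (!is.nan(mcc)) expect_equal(mcc, bruteMcc(m), tolerance = 1e-12)
    }
  })

  # kappa = 1 iff no off-diagonal mass
  off <- confusionMatrix(matrix(c(5, 1, 0, 5), 2,
                                dimnames = list(c("a", "b"), c("a", "b"))))
  expect_lt(kappaScore(off), 1)
})

test_that("exact Wilcoxon signed-rank matches sign enumeration", {
  # 9 strictly positive differences: two-sided p = 2 / 2^9
  r9 <- wilcoxonSignedRank(2:10, 1:9)
  expect_true(r9$exact)
  expect_equal(r9$p, 2 / 512)
  expect_equal(round(r9$p, 3), 0.004)

  expect_warning(r0 <- wilcoxonSignedRank(1:5, 1:5), "zero")
  expect_true(is.na(r0$p))

  withr::with_seed(14, {
    for (rep in 1:6) {
      x <- round(rnorm(6, 0, 3), 1)
      y <- round(rnorm(6, 0.5, 3), 1)
      if (all(x == y)) next
      mine <- wilcoxonSignedRank(x, y)
      expect_equal(mine$p, bruteWilcoxP(x, y), tolerance = 1e-12)
      expect_gt(mine$p, 0); expect_lte(mine$p, 1)
    }
  })

  # agreement with the reference implementation when there are no ties
  withr::with_seed(15, {
    x <- rnorm(12); y <- rnorm(12)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(wilcoxonSignedRank(x, y)$p, unname(ref$p.value),
                 tolerance = 1e-12)
  })

  # a longer strictly one-sided series attains a smaller minimum p
  pShort <- wilcoxonSignedRank(2:7, 1:6)$p
  pLong <- wilcoxonSignedRank(2:13, 1:12)$p
  expect_lt(pLong, pShort)
})

test_that("roc/auc equals the normalised Mann-Whitney statistic", {
  lev <- c("a", "b")
  sc <- matrix(c(0.9, 0.8, 0.2, 0.1, 0.1, 0.2, 0.8, 0.9), 4,
               dimnames = list(NULL, lev))
  y <- c("a", "a", "b", "b")
  r <- rocAuc(y, sc)
  expect_equal(r$perClass$a$auc, 1)
  expect_equal(r$macroAuc, 1)

  withr::with_seed(18, {
    # label-independent scores give AUC near 1/2
    n <- 400
    y2 <- sample(lev, n, TRUE)
    s2 <- matrix(runif(2 * n), n, dimnames = list(NULL, lev))
    s2 <- s2 / rowSums(s2)
    expect_lt(abs(rocAuc(y2, s2)$macroAuc - 0.5), 0.05)

    # U-statistic oracle at n <= 50
    for (rep in 1:5) {
      y3 <- sample(lev, 30, TRUE)
      s3 <- matrix(runif(60), 30, dimnames = list(NULL, lev))
      auc <- rocAuc(y3, s3)$perClass$a$auc
      expect_equal(auc, bruteAuc(s3[y3 == "a", "a"], s3[y3 != "a", "a"]),
                   tolerance = 1e-12)
    }
  })

  expect_true(is.na(rocAuc(rep("a", 4), sc)$perClass$a$auc))
})

test_that("kfoldCV drives the trainer over disjoint folds", {
  man <- data.frame(image_id = as.character(1:40),
                    path = as.character(1:40),
                    class = rep(c("a", "b"), each = 20),
                    stringsAsFactors = FALSE)
  constTrainer <- function(tr, ev) mean(ev$class == "a")
  r <- kfoldCV(man, 5, constTrainer, seed = 2L)
  expect_equal(r$foldAccuracy, rep(0.5, 5))
  expect_equal(r$mean, 0.5)
  expect_equal(r$sd, 0)

  # evaluation folds are disjoint and cover the manifest
  seen <- new.env(); assign("ids", character(), seen)
  spyTrainer <- function(tr, ev) {
    assign("ids", c(get("ids", seen), ev$image_id), seen)
    expect_length(intersect(tr$image_id, ev$image_id), 0)
    1
  }
  kfoldCV(man, 4, spyTrainer, seed = 3L)
  expect_setequal(get("ids", seen), man$image_id)
  expect_length(get("ids", seen), 40)
})

test_that("cvSummary reproduces hand-computed fold statistics", {
  accs <- c(98.22, 98.27, 98.29, 98.34, 98.31)
  s <- cvSummary(accs)
  expect_equal(unname(s["mean"]), 98.286)
  # population SD: mean squared deviation 0.001624
  expect_equal(unname(s["sd"]), sqrt(0.001624), tolerance = 1e-12)
  expect_equal(round(unname(s["sd"]), 4), 0.0403)
})
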