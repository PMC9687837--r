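#' The ten-study ablation plan
#'
#' Ordered studies over the model configuration, each with its candidate
#' values: residual scaling factor (with/without), filter size (3x3, 2x2,
#' 5x5), number of filters (16/32/64), pooling type (max/average),
#' activation (PReLU/ReLU/LeakyReLU/Tanh/ELU), batch size (16/32/64/128),
#' head (flatten/global max/global average), loss (six candidates),
#' optimizer (Adam/Nadam/SGD/Adamax/RMSprop) and learning rate
#' (0.01/0.007/0.001/0.0007/0.0001).
#'
#' @return list of studies, each with `name`, `knob`, `values`, `labels`.
#' @export
defaultStudyPlan <- function() {
  list(
    list(name = "rsf", knob = "rsfEnabled",
         values = list(TRUE, FALSE), labels = c("With RSF", "Without RSF")),
    list(name = "filter_size", knob = "filterSize",
         values = list(3L, 2L, 5L), labels = c("3 x 3", "2 x 2", "5 x 5")),
    list(name = "n_filters", knob = "nFilters",
         values = list(16L, 32L, 64L), labels = c("16", "32", "64")),
    list(name = "pooling", knob = "poolType",
         values = list("max", "average"), labels = c("Max", "Average")),
    list(name = "activation", knob = "activation",
         values = list("prelu", "relu", "leakyrelu", "tanh", "elu"),
         labels = c("PReLU", "ReLU", "LeakyReLU", "Tanh", "ELU")),
    list(name = "batch_size", knob = "batchSize",
         values = list(16L, 32L, 64L, 128L), labels = c("16", "32", "64", "128")),
    list(name = "head", knob = "headType",
         values = list("flatten", "global_max", "global_average"),
         labels = c("Flatten", "Global max-pooling", "Global average pooling")),
    list(name = "loss", knob = "loss",
         values = list("binary_crossentropy", "categorical_crossentropy",
                       "mse", "mae", "msle", "kld"),
         labels = c("Binary cross-entropy", "Categorical cross-entropy",
                    "Mean squared error", "Mean absolute error",
                    "Mean squared logarithmic error",
                    "Kullback-Leibler divergence")),
    list(name = "optimizer", knob = "optimizer",
         values = list("adam", "nadam", "sgd", "adamax", "rmsprop"),
         labels = c("Adam", "Nadam", "SGD", "Adamax", "RMSprop")),
    list(name = "learning_rate", knob = "learningRate",
         values = list(0.01, 0.007, 0.001, 0.0007, 0.0001),
         labels = c("0.01", "0.007", "0.001", "0.0007", "0.0001"))
  )
}

#' The base (pre-ablation) model configuration
#'
#' The hybrid base model before the studies: no residual scaling, 32
#' filters, ReLU, global-average head, Adam with learning rate 0.001,
#' batch size 32.
#'
#' @param ... overrides passed to [modelConfig()].
#' @return a [ModelConfig-class].
#' @export
baseModelConfig <- function(...) {
  modelConfig(rsfEnabled = FALSE, nFilters = 32L, activation = "relu",
              headType = "global_average", learningRate = 0.001, ...)
}

applyKnob <- function(cfg, knob, value) {
  intSlots <- c("filterSize", "nFilters", "batchSize", "epochs", "nClasses")
  if (knob %in% intSlots) value <- as.integer(value)
  slot(cfg, knob) <- value
  cfg
}

#' Run the greedy ablation protocol
#'
#' Studies are executed in order. Within a study every candidate is
#' evaluated with all previously adopted values held fixed; the adopted
#' candidate is the accuracy maximiser, except that a lower-complexity
#' candidate within `delta` accuracy points of the maximum is preferred
#' (complexity ties resolve to higher accuracy, then to listing order; with
#' `delta = 0` this is pure argmax). Findings are labelled against the
#' running best accuracy, compared at two decimals: "improved", "identical"
#' or "dropped" ("failed" when the evaluator errors, and the candidate is
#' skipped). The running best is seeded by the first study's incumbent
#' (base-configuration) candidate.
#'
#' @param plan study plan, e.g. [defaultStudyPlan()].
#' @param baseCfg starting [ModelConfig-class].
#' @param evaluator `function(cfg, study, candidate)` returning a list with
#'   `accuracy` (percent), `complexity` and optionally `epochTime`. Real
#'   runs can ignore `study`/`candidate`; table-replay evaluators may use
#'   them for lookup.
#' @param delta accuracy tolerance (points) of the complexity preference
#'   rule (default 0.5).
#' @return an [AblationReport-class].
#' @examples
#' ev <- makeTableEvaluator(ablationReferenceMetrics())
#' rep <- runAblation(defaultStudyPlan(), baseModelConfig(), ev)
#' finalConfig(rep)
#' @export
runAblation <- function(plan, baseCfg, evaluator, delta = 0.5) {
  cfg <- baseCfg
  runningBest <- NA_real_
  rows <- list()
  for (si in seq_along(plan)) {
    st <- plan[[si]]
    evals <- vector("list", length(st$values))
    for (ci in seq_along(st$values)) {
      evals[[ci]] <- tryCatch({
        candCfg <- applyKnob(cfg, st$knob, st$values[[ci]])
        r <- evaluator(candCfg, study = st$name, candidate = st$labels[ci])
        list(ok = TRUE, accuracy = r$accuracy, complexity = r$complexity,
             epochTime = if (is.null(r$epochTime)) NA_real_ else r$epochTime)
      }, error = function(e) list(ok = FALSE, accuracy = NA_real_,
                                  complexity = NA_real_, epochTime = NA_real_))
    }
    ok <- vapply(evals, `[[`, logical(1), "ok")
    if (!any(ok)) stop("every candidate failed in study ", st$name)
    acc <- vapply(evals, `[[`, numeric(1), "accuracy")
    cpx <- vapply(evals, `[[`, numeric(1), "complexity")
    incumbent <- vapply(st$values, identical, logical(1), slot(cfg, st$knob))
    if (is.na(runningBest)) {
      # seed the running best with the incumbent (base-configuration)
      # candidate of the first study, falling back to the first candidate
      seedIdx <- if (any(incumbent & ok)) which(incumbent & ok)[1] else which(ok)[1]
      runningBest <- acc[seedIdx]
    }
    # selection: within delta of the max, prefer lower complexity, then
    # higher accuracy, then listing order
    cand <- which(ok & acc >= max(acc[ok]) - delta)
    chosen <- cand[order(cpx[cand], -acc[cand])][1]
    finding <- character(length(evals))
    for (ci in seq_along(evals)) {
      finding[ci] <- if (!ok[ci]) "failed"
        else if (round(acc[ci], 2) > round(runningBest, 2)) "improved"
        else if (round(acc[ci], 2) == round(runningBest, 2)) "identical"
        else "dropped"
    }
    rows[[si]] <- data.frame(
      study = si, studyName = st$name, candidate = st$labels,
      accuracy = acc, complexity = cpx,
      epochTime = vapply(evals, `[[`, numeric(1), "epochTime"),
      finding = finding, chosen = seq_along(evals) == chosen,
      stringsAsFactors = FALSE)
    cfg <- applyKnob(cfg, st$knob, st$values[[chosen]])
    runningBest <- acc[chosen]
  }
  new("AblationReport", rows = do.call(rbind, rows), finalConfig = cfg,
      delta = delta)
}

#' @describeIn runAblation the configuration adopted after the last study.
#' @param report an AblationReport.
#' @export
finalConfig <- function(report) report@finalConfig

#' Format an ablation report as a table
#'
#' @param report an [AblationReport-class].
#' @param file optional CSV output path.
#' @return the per-candidate data.frame, invisibly when writing.
#' @export
formatReport <- function(report, file = NULL) {
  tab <- report@rows
  if (!is.null(file)) {
    utils::write.csv(tab, file, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Recorded reference ablation metrics
#'
#' The per-candidate test accuracies and time complexities recorded in the
#' original ablation experiments, bundled so the selection protocol can be
#' replayed without any training.
#'
#' @return data.frame with columns study, candidate, accuracy,
#'   complexity_m, epoch_s.
#' @export
ablationReferenceMetrics <- function() {
  utils::read.csv(system.file("extdata", "ablation_reference_metrics.csv",
                              package = "InResECG"),
                  stringsAsFactors = FALSE, check.names = FALSE)
}

#' Build a table-replay evaluator
#'
#' @param tbl data.frame as returned by [ablationReferenceMetrics()].
#' @return an evaluator `function(cfg, study, candidate)` for
#'   [runAblation()].
#' @export
makeTableEvaluator <- function(tbl) {
  function(cfg, study, candidate) {
    row <- tbl[tbl$study == study & tbl$candidate == candidate, , drop = FALSE]
    if (nrow(row) != 1L)
      stop("no recorded metrics for ", study, " / ", candidate)
    list(accuracy = row$accuracy, complexity = row$complexity_m,
         epochTime = row$epoch_s)
  }
}
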