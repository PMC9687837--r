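#' Read / write a JSON-lines manifest
#'
#' One JSON object per line with at least fields image_id, path, class and
#' optionally split, fold, seed.
#'
#' @param path manifest file path.
#' @return data.frame.
#' @export
readManifest <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(image_id = character(), path = character(),
                      class = character(), stringsAsFactors = FALSE))
  rows <- lapply(lines, function(l) as.data.frame(jsonlite::fromJSON(l),
                                                  stringsAsFactors = FALSE))
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) { r[setdiff(cols, names(r))] <- NA; r[cols] })
  do.call(rbind, rows)
}

#' @rdname readManifest
#' @param manifest data.frame to write.
#' @export
writeManifest <- function(manifest, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(manifest))
    for (i in seq_len(nrow(manifest)))
      writeLines(jsonlite::toJSON(as.list(manifest[i, , drop = FALSE]),
                                  auto_unbox = TRUE), con)
  invisible(path)
}

#' Stratified 70:20:10 split
#'
#' Per class with n records: train gets floor(trainRatio * n), validation
#' floor(valRatio * n), and test the remainder; membership within a class
#' is a seeded shuffle. With the class sizes 546/250/203/74/859 this yields
#' the totals 1351/384/197.
#'
#' @param manifest data.frame with a `class` column.
#' @param ratios named ratios summing to 1 (default c(train = 0.7,
#'   val = 0.2, test = 0.1)).
#' @param seed integer seed.
#' @return the manifest with a `split` column.
#' @export
stratifiedSplit <- function(manifest, ratios = c(train = 0.7, val = 0.2, test = 0.1),
                            seed = 1L) {
  stopifnot(abs(sum(ratios) - 1) < 1e-9, all(c("train", "val") %in% names(ratios)))
  if (is.null(manifest$class)) stop("every record needs a class")
  manifest$split <- NA_character_
  withSeed(seed, {
    for (cl in unique(manifest$class)) {
      idx <- which(manifest$class == cl)
      n <- length(idx)
      if (n == 0L) next
      idx <- idx[sample.int(n)]
      nTrain <- floor(ratios[["train"]] * n)
      nVal <- floor(ratios[["val"]] * n)
      manifest$split[idx[seq_len(nTrain)]] <- "train"
      if (nVal > 0) manifest$split[idx[nTrain + seq_len(nVal)]] <- "val"
      if (n > nTrain + nVal)
        manifest$split[idx[(nTrain + nVal + 1):n]] <- "test"
    }
  })
  manifest
}

#' Stratified k-fold partition
#'
#' For k >= 2: per-class seeded shuffle assigned round-robin to folds, so
#' per-class fold sizes differ by at most one. k = 1 is treated as a single
#' seeded holdout repetition: records are split with the standard
#' 70:20:10 ratios and the test records form fold 1 (others get fold NA).
#'
#' @param manifest data.frame with a `class` column.
#' @param k number of folds (>= 1).
#' @param seed integer seed.
#' @return the manifest with a `fold` column.
#' @export
kfoldPartition <- function(manifest, k, seed = 1L) {
  stopifnot(k >= 1)
  if (is.null(manifest$class)) stop("every record needs a class")
  if (k == 1L) {
    m <- stratifiedSplit(manifest, seed = seed)
    manifest$fold <- ifelse(m$split == "test", 1L, NA_integer_)
    return(manifest)
  }
  smallest <- min(table(manifest$class))
  if (k > smallest)
    warning("k exceeds the smallest class size (", smallest,
            "); some folds will miss classes")
  manifest$fold <- NA_integer_
  withSeed(seed, {
    for (cl in unique(manifest$class)) {
      idx <- which(manifest$class == cl)
      idx <- idx[sample.int(length(idx))]
      manifest$fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  manifest
}

#' Per-class and per-split count table
#'
#' @param manifest data.frame with `class` and optionally `split` columns.
#' @return list with `counts` (class x split table, plus a total column)
#'   and `total`.
#' @export
summarizeManifest <- function(manifest) {
  if (nrow(manifest) == 0L)
    return(list(counts = table(character()), total = 0L))
  if (!is.null(manifest$split) && !all(is.na(manifest$split))) {
    tab <- table(class = manifest$class, split = manifest$split)
    tab <- cbind(tab, total = rowSums(tab))
  } else {
    tab <- table(class = manifest$class)
  }
  list(counts = tab, total = nrow(manifest))
}
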