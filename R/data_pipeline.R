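# Labeled-dataset construction: replicate averaging, Loewe-threshold class
# labels, reversed-pair augmentation, and the four grouped five-fold
# cross-validation schemes.

#' Synergy class labels, in fixed order
#' @export
synergyClasses <- function() c("antagonistic", "additive", "synergistic")

#' Average replicate synergy measurements
#'
#' Collapses rows to one record per unique (unordered drug pair, cell line)
#' combination, the score being the arithmetic mean of the replicates. The
#' emitted pair is in lexicographic drug order.
#'
#' @param rows data.frame with columns \code{drug1}, \code{drug2},
#'   \code{cell}, \code{score}.
#' @return data.frame with the same columns, one row per combination.
#' @export
aggregateReplicates <- function(rows) {
  stopifnot(all(c("drug1", "drug2", "cell", "score") %in% names(rows)))
  if (!is.numeric(rows$score)) stop("scores must be numeric")
  a <- pmin(rows$drug1, rows$drug2)
  b <- pmax(rows$drug1, rows$drug2)
  key <- paste(a, b, rows$cell, sep = "\r")
  agg <- tapply(rows$score, key, mean)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  out <- data.frame(drug1 = vapply(parts, `[`, "", 1),
                    drug2 = vapply(parts, `[`, "", 2),
                    cell = vapply(parts, `[`, "", 3),
                    score = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out[order(out$drug1, out$drug2, out$cell), , drop = FALSE]
}

#' Label records by Loewe-score thresholds
#'
#' Scores above 30 are synergistic, below 0 antagonistic, and the closed
#' interval [0, 30] additive, so the three classes partition the real line.
#'
#' @param records data.frame with a numeric \code{score} column.
#' @return the records with an added \code{class} column.
#' @examples
#' assignClassLabels(data.frame(drug1 = "a", drug2 = "b", cell = "c",
#'                              score = c(35, -5, 15)))$class
#' @export
assignClassLabels <- function(records) {
  stopifnot(is.numeric(records$score))
  records$class <- ifelse(records$score > 30, "synergistic",
                          ifelse(records$score < 0, "antagonistic", "additive"))
  records
}

#' Append drug-swapped twins of every record
#'
#' Doubles the dataset: each original row is followed by a copy with
#' \code{drug1} and \code{drug2} exchanged and identical score, class and
#' cell. A \code{reversed} provenance column guards against applying the
#' augmentation twice.
#'
#' @param records deduplicated data.frame of synergy records.
#' @return data.frame with \code{2 * nrow(records)} rows and a
#'   \code{reversed} logical column.
#' @export
augmentReversedPairs <- function(records) {
  if ("reversed" %in% names(records))
    stop("records already carry a 'reversed' column; refusing to augment twice")
  twins <- records
  twins$drug1 <- records$drug2
  twins$drug2 <- records$drug1
  records$reversed <- FALSE
  twins$reversed <- TRUE
  n <- nrow(records)
  out <- rbind(records, twins)[rep(seq_len(n), each = 2) + c(0, n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.group_key <- function(records, scheme) {
  switch(scheme,
         pair = paste(pmin(records$drug1, records$drug2),
                      pmax(records$drug1, records$drug2), sep = "\r"),
         cell = records$cell,
         drug1 = records$drug1,
         drug2 = records$drug2,
         stop("unknown scheme '", scheme, "'"))
}

#' Grouped five-fold assignment
#'
#' Shuffles the scheme's grouping entities (unordered drug pair, cell line,
#' first drug or second drug) with the given seed and deals them round-robin
#' into five folds, so no entity ever spans folds. Under \code{scheme =
#' "pair"} a record and its reversed twin always share a fold because both
#' map to the same unordered pair.
#'
#' @param records data.frame of (augmented) synergy records.
#' @param scheme one of \code{"pair"}, \code{"cell"}, \code{"drug1"},
#'   \code{"drug2"}.
#' @param seed integer shuffle seed.
#' @return a \linkS4class{FoldSplit}.
#' @export
splitFolds <- function(records, scheme = c("pair", "cell", "drug1", "drug2"),
                       seed = 0L) {
  scheme <- match.arg(scheme)
  key <- .group_key(records, scheme)
  entities <- unique(key)
  if (length(entities) < 5)
    stop("scheme '", scheme, "' has only ", length(entities),
         " grouping entities; need at least 5")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  shuffled <- sample(entities)
  fold_of <- structure((seq_along(shuffled) - 1L) %% 5L, names = shuffled)
  new("FoldSplit", scheme = scheme, fold = as.integer(fold_of[key]),
      groups = key, seed = as.integer(seed))
}
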