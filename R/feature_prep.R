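# Descriptor cleaning, landmark-gene selection and bounded tanh
# normalization shared by every feature family (chemical descriptors, graph
# embeddings, interaction features, expression).

#' Clean a chemical-descriptor matrix
#'
#' Drops every column that contains a non-numeric or missing value, then
#' every remaining column whose variance across rows is exactly zero.
#' Column order is otherwise preserved.
#'
#' @param raw data.frame of raw descriptors, rows are drugs.
#' @return data.frame with only finite, varying numeric columns.
#' @examples
#' raw <- data.frame(a = c(1, 2), b = c("x", "y"), c = c(3, 3))
#' cleanDescriptors(raw)   # keeps only column a
#' @export
cleanDescriptors <- function(raw) {
  stopifnot(is.data.frame(raw), nrow(raw) >= 1)
  if (nrow(raw) < 2)
    stop("variance filtering needs at least 2 rows, got ", nrow(raw))
  numeric_ok <- vapply(raw, function(col) {
    is.numeric(col) && all(is.finite(col))
  }, logical(1))
  out <- raw[, numeric_ok, drop = FALSE]
  pop_var <- vapply(out, function(col) mean((col - mean(col))^2), numeric(1))
  out <- out[, pop_var > 0, drop = FALSE]
  if (ncol(out) == 0)
    stop("no descriptor columns survive cleaning (all non-numeric or constant)")
  out
}

#' Fit a tanh normalizer on training rows
#'
#' Estimates per-column mean and population standard deviation for the
#' bounded transform \eqn{z = 0.5(\tanh(c (x - \mu)/\sigma) + 1)}. Columns
#' with zero spread get \eqn{\sigma = 1}. Statistics must come from training
#' rows only; apply the fitted object to any matching matrix.
#'
#' @param train numeric data.frame/matrix of training rows (>= 2 rows).
#' @param scale_c scale constant \code{c} of the transform (default 0.01,
#'   the usual tanh-estimator scaling).
#' @return a \linkS4class{TanhNormalizer}.
#' @export
fitNormalizer <- function(train, scale_c = 0.01) {
  train <- as.data.frame(train)
  stopifnot(nrow(train) >= 2, ncol(train) >= 1)
  mu <- vapply(train, mean, numeric(1))
  sigma <- vapply(train, function(col) sqrt(mean((col - mean(col))^2)), numeric(1))
  sigma[sigma == 0] <- 1
  new("TanhNormalizer", mu = mu, sigma = sigma, scale_c = scale_c,
      columns = colnames(train))
}

#' Apply a fitted tanh normalizer
#'
#' @param x numeric data.frame/matrix whose columns match the fitted ones.
#' @param norm a \linkS4class{TanhNormalizer}.
#' @return numeric matrix with all entries strictly inside (0, 1).
#' @examples
#' nm <- fitNormalizer(data.frame(a = c(0, 2)))
#' applyNormalizer(data.frame(a = 1), nm)   # 0.5 at the mean
#' @export
applyNormalizer <- function(x, norm) {
  stopifnot(is(norm, "TanhNormalizer"))
  x <- as.data.frame(x)
  missing_cols <- setdiff(norm@columns, colnames(x))
  extra <- setdiff(colnames(x), norm@columns)
  if (length(missing_cols) || length(extra))
    stop("column mismatch; missing: [", paste(missing_cols, collapse = ", "),
         "], unexpected: [", paste(extra, collapse = ", "), "]")
  m <- as.matrix(x[, norm@columns, drop = FALSE])
  z <- sweep(sweep(m, 2, norm@mu, "-"), 2, norm@sigma, "/")
  out <- 0.5 * (tanh(norm@scale_c * z) + 1)
  # keep the open-interval contract where tanh saturates in floating point
  pmin(pmax(out, .Machine$double.xmin), 1 - .Machine$double.eps / 2)
}

#' Select the landmark-gene panel from an expression matrix
#'
#' Keeps exactly the genes shared between the expression matrix and the
#' panel, in panel order.
#'
#' @param expr numeric matrix or data.frame, cells x genes (columns named by
#'   gene).
#' @param panel character vector of landmark gene ids.
#' @return the column subset of \code{expr}, with attribute
#'   \code{"panel_overlap"} recording the intersection size.
#' @export
selectGenePanel <- function(expr, panel) {
  stopifnot(length(panel) >= 1, !anyDuplicated(panel))
  shared <- panel[panel %in% colnames(expr)]
  if (!length(shared))
    stop("no overlap between expression genes and the panel")
  out <- expr[, shared, drop = FALSE]
  attr(out, "panel_overlap") <- length(shared)
  out
}

#' Read a one-gene-per-line panel file
#' @param path text file with one gene id per line.
#' @return character vector of gene ids.
#' @export
readGenePanel <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x)]
}
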