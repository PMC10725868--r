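# Reusable network blocks: multi-head dot-product attention with residual
# concatenation, the two-layer cross-stitch subnetwork, and the generic
# fully connected (dense/ReLU/dropout) stack. Each block is a pure
# parameterized function; public wrappers evaluate numerically, internal
# *ForwardNode builders run on the autodiff tape for training.

.he_init <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

adParams <- function(tape, params) {
  out <- list()
  for (nm in names(params)) out[[nm]] <- adParam(tape, params[[nm]], nm)
  out
}

# ---- fully connected subnetwork ----

#' Create a fully connected subnetwork
#'
#' A stack of dense layers with a rectifier after each layer, dropout after
#' all but the last layer (training only), and L2 penalties on both weights
#' and activations accumulated into the training loss.
#'
#' @param input_dim length of the input feature vector.
#' @param widths integer vector of hidden widths.
#' @param dropout dropout rate in [0, 1).
#' @param l2_weights,l2_activity regularization coefficients.
#' @param name parameter-name prefix.
#' @return a block: list of \code{spec} and initialized \code{params}
#'   (initialization draws from the current RNG state).
#' @export
newFCSubnetwork <- function(input_dim, widths, dropout = 0.2,
                            l2_weights = 1e-4, l2_activity = 1e-5,
                            name = "fc") {
  stopifnot(input_dim >= 1, length(widths) >= 1, all(widths >= 1),
            dropout >= 0, dropout < 1)
  params <- list()
  nin <- input_dim
  for (i in seq_along(widths)) {
    params[[sprintf("%s_W%d", name, i)]] <- .he_init(nin, widths[i])
    params[[sprintf("%s_b%d", name, i)]] <- matrix(0, 1, widths[i])
    nin <- widths[i]
  }
  list(spec = list(kind = "fc", name = name, input_dim = as.integer(input_dim),
                   widths = as.integer(widths), dropout = dropout,
                   l2_weights = l2_weights, l2_activity = l2_activity),
       params = params)
}

fcForwardNode <- function(tape, pn, spec, x, training = FALSE) {
  reg <- list()
  h <- x
  L <- length(spec$widths)
  for (i in seq_len(L)) {
    W <- pn[[sprintf("%s_W%d", spec$name, i)]]
    b <- pn[[sprintf("%s_b%d", spec$name, i)]]
    h <- adRelu(tape, adAddBias(tape, adMatmul(tape, h, W), b))
    if (training) {
      if (spec$l2_weights > 0)
        reg[[length(reg) + 1L]] <- adScale(tape, adSumSq(tape, W), spec$l2_weights)
      if (spec$l2_activity > 0)
        reg[[length(reg) + 1L]] <- adScale(tape, adSumSq(tape, h),
                                           spec$l2_activity / nrow(h$value))
    }
    if (i < L) h <- adDropout(tape, h, spec$dropout, training)
  }
  list(out = h, reg = reg)
}

#' Evaluate a fully connected subnetwork
#'
#' @param x numeric vector or matrix (rows are samples).
#' @param net block from \code{\link{newFCSubnetwork}}.
#' @param training apply dropout (draws from the current RNG state).
#' @return numeric matrix of activations of the last layer.
#' @export
fcSubnetwork <- function(x, net, training = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  stopifnot(ncol(x) == net$spec$input_dim)
  tape <- adTape()
  pn <- adParams(tape, net$params)
  fcForwardNode(tape, pn, net$spec, adConst(tape, x), training)$out$value
}

# ---- multi-head attention ----

#' Create a multi-head attention block
#'
#' Flat feature vectors are reshaped into \code{length / token_dim} tokens.
#' Per head, query/key/value tokens pass through rectified dense projections
#' of width \code{token_dim / heads}; softmax over key tokens of the
#' query-key dot products weights the value tokens; head outputs are
#' concatenated so the attended vector matches the query length, and the
#' block returns \code{concat(attended, query input)} (twice the query
#' length).
#'
#' @param input_dim query vector length.
#' @param kv_dim key/value vector length (defaults to \code{input_dim}).
#' @param heads number of heads; must divide \code{token_dim}.
#' @param token_dim token width; must divide \code{input_dim} and
#'   \code{kv_dim}.
#' @param share_qkv use one shared projection for query, key and value.
#' @param scale divide attention scores by sqrt(head width) (off by
#'   default).
#' @param name parameter-name prefix.
#' @return a block: list of \code{spec} and initialized \code{params}.
#' @export
newAttentionBlock <- function(input_dim, kv_dim = input_dim, heads = 4L,
                              token_dim = 16L, share_qkv = FALSE,
                              scale = FALSE, name = "attn") {
  if (token_dim %% heads != 0)
    stop("heads (", heads, ") must divide token_dim (", token_dim, ")")
  if (input_dim %% token_dim != 0)
    stop("token_dim (", token_dim, ") must divide the query length (", input_dim, ")")
  if (kv_dim %% token_dim != 0)
    stop("token_dim (", token_dim, ") must divide the key/value length (", kv_dim, ")")
  dk <- token_dim %/% heads
  params <- list()
  roles <- if (share_qkv) "q" else c("q", "k", "v")
  for (h in seq_len(heads)) {
    for (r in roles) {
      params[[sprintf("%s_W%s%d", name, r, h)]] <- .he_init(token_dim, dk)
      params[[sprintf("%s_b%s%d", name, r, h)]] <- matrix(0, 1, dk)
    }
  }
  list(spec = list(kind = "attention", name = name,
                   input_dim = as.integer(input_dim), kv_dim = as.integer(kv_dim),
                   heads = as.integer(heads), token_dim = as.integer(token_dim),
                   head_dim = as.integer(dk), share_qkv = share_qkv, scale = scale),
       params = params)
}

# B x d matrix node -> (B, T, token_dim) token array node
adToTokens <- function(tape, x, token_dim) {
  B <- nrow(x$value); d <- ncol(x$value)
  Tn <- d %/% token_dim
  adAperm(tape, adReshape(tape, x, c(B, token_dim, Tn)), c(1, 3, 2))
}

adFromTokens <- function(tape, a) {
  d <- dim(a$value)
  adReshape(tape, adAperm(tape, a, c(1, 3, 2)), c(d[1], d[2] * d[3]))
}

.project_tokens <- function(tape, pn, spec, tokens, role, head) {
  r <- if (spec$share_qkv) "q" else role
  W <- pn[[sprintf("%s_W%s%d", spec$name, r, head)]]
  b <- pn[[sprintf("%s_b%s%d", spec$name, r, head)]]
  d <- dim(tokens$value)
  flat <- adReshape(tape, tokens, c(d[1] * d[2], d[3]))
  proj <- adRelu(tape, adAddBias(tape, adMatmul(tape, flat, W), b))
  adReshape(tape, proj, c(d[1], d[2], spec$head_dim))
}

attentionForwardNode <- function(tape, pn, spec, q, k = q, v = k) {
  qt <- adToTokens(tape, q, spec$token_dim)
  kt <- adToTokens(tape, k, spec$token_dim)
  vt <- adToTokens(tape, v, spec$token_dim)
  heads <- list()
  weights <- list()
  for (h in seq_len(spec$heads)) {
    att <- adAttention(tape,
                       .project_tokens(tape, pn, spec, qt, "q", h),
                       .project_tokens(tape, pn, spec, kt, "k", h),
                       .project_tokens(tape, pn, spec, vt, "v", h),
                       scale = spec$scale)
    heads[[h]] <- att
    weights[[h]] <- att$attn_weights
  }
  merged <- if (length(heads) > 1) adConcat3(tape, heads) else heads[[1]]
  out <- adConcatCols(tape, list(adFromTokens(tape, merged), q))
  list(out = out, weights = weights)
}

#' Apply multi-head attention to feature vectors
#'
#' @param query,key,value numeric vectors or matrices (rows are samples);
#'   key and value must share a token count.
#' @param block block from \code{\link{newAttentionBlock}}.
#' @return numeric matrix \code{cbind(attended, query)}; attribute
#'   \code{"weights"} holds the per-head attention weight arrays
#'   (samples x query tokens x key tokens).
#' @export
multiHeadAttention <- function(query, key = query, value = key, block) {
  as_mat <- function(x) if (is.null(dim(x))) matrix(x, nrow = 1) else x
  query <- as_mat(query); key <- as_mat(key); value <- as_mat(value)
  stopifnot(ncol(query) == block$spec$input_dim)
  if (ncol(key) != ncol(value))
    stop("key and value must have the same length (token count)")
  tape <- adTape()
  pn <- adParams(tape, block$params)
  res <- attentionForwardNode(tape, pn, block$spec,
                              adConst(tape, query), adConst(tape, key),
                              adConst(tape, value))
  structure(res$out$value, weights = res$weights)
}

# ---- cross-stitch ----

#' Apply one cross-stitch unit
#'
#' Mixes two task representations elementwise through a learned 2x2 matrix:
#' \code{t1' = r11 t1 + r12 t2}, \code{t2' = r21 t1 + r22 t2}.
#'
#' @param t1,t2 equal-length numeric vectors (or matrices).
#' @param R 2x2 mixing matrix.
#' @return list with elements \code{t1} and \code{t2}.
#' @examples
#' crossStitchUnit(c(1, 0), c(0, 1), diag(2))   # identity
#' @export
crossStitchUnit <- function(t1, t2, R) {
  stopifnot(length(t1) == length(t2), all(dim(R) == c(2, 2)))
  list(t1 = R[1, 1] * t1 + R[1, 2] * t2,
       t2 = R[2, 1] * t1 + R[2, 2] * t2)
}

#' Create a cross-stitch subnetwork
#'
#' Two cross-stitch units around per-task rectified dense layers. Mixing
#' entries start near identity (diagonal 0.9, off-diagonal 0.1) so tasks
#' initially keep their own representation.
#'
#' @param input_dim task representation length.
#' @param width width of the per-task dense layers between the units.
#' @param name parameter-name prefix.
#' @return a block: list of \code{spec} and initialized \code{params}.
#' @export
newCrossStitchSubnetwork <- function(input_dim, width, name = "cs") {
  stopifnot(input_dim >= 1, width >= 1)
  params <- list()
  for (u in 1:2) for (i in 1:2) for (j in 1:2) {
    params[[sprintf("%s_u%d_r%d%d", name, u, i, j)]] <-
      matrix(if (i == j) 0.9 else 0.1, 1, 1)
  }
  for (task in 1:2) {
    params[[sprintf("%s_W%d", name, task)]] <- .he_init(input_dim, width)
    params[[sprintf("%s_b%d", name, task)]] <- matrix(0, 1, width)
  }
  list(spec = list(kind = "cross_stitch", name = name,
                   input_dim = as.integer(input_dim), width = as.integer(width)),
       params = params)
}

csUnitNode <- function(tape, pn, name, u, t1, t2) {
  r <- function(i, j) pn[[sprintf("%s_u%d_r%d%d", name, u, i, j)]]
  list(t1 = adAdd(tape, adSMul(tape, t1, r(1, 1)), adSMul(tape, t2, r(1, 2))),
       t2 = adAdd(tape, adSMul(tape, t1, r(2, 1)), adSMul(tape, t2, r(2, 2))))
}

crossStitchForwardNode <- function(tape, pn, spec, t1, t2) {
  u1 <- csUnitNode(tape, pn, spec$name, 1L, t1, t2)
  dense <- function(task, x) {
    W <- pn[[sprintf("%s_W%d", spec$name, task)]]
    b <- pn[[sprintf("%s_b%d", spec$name, task)]]
    adRelu(tape, adAddBias(tape, adMatmul(tape, x, W), b))
  }
  t11 <- dense(1L, u1$t1)
  t22 <- dense(2L, u1$t2)
  u2 <- csUnitNode(tape, pn, spec$name, 2L, t11, t22)
  list(t1 = adConcatCols(tape, list(u2$t1, t1)),
       t2 = adConcatCols(tape, list(u2$t2, t2)))
}

#' Evaluate the cross-stitch subnetwork
#'
#' Unit, per-task dense, unit, then each task's mixed representation is
#' concatenated with that task's input; output length is
#' \code{width + input length}.
#'
#' @param t1,t2 equal-length numeric vectors or matrices.
#' @param block block from \code{\link{newCrossStitchSubnetwork}}.
#' @return list with matrices \code{t1} and \code{t2}.
#' @export
crossStitchSubnetwork <- function(t1, t2, block) {
  as_mat <- function(x) if (is.null(dim(x))) matrix(x, nrow = 1) else x
  t1 <- as_mat(t1); t2 <- as_mat(t2)
  if (ncol(t1) != ncol(t2)) stop("task representations must have equal length")
  tape <- adTape()
  pn <- adParams(tape, block$params)
  res <- crossStitchForwardNode(tape, pn, block$spec,
                                adConst(tape, t1), adConst(tape, t2))
  list(t1 = res$t1$value, t2 = res$t2$value)
}
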