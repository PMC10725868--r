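# helper: an attention block with identity projections (token_dim 1, one
# head) so the softmax mixture can be checked by hand
identity_attention <- function(n_tokens) {
  blk <- newAttentionBlock(input_dim = n_tokens, heads = 1, token_dim = 1,
                           name = "id")
  blk$params$id_Wq1 <- matrix(1, 1, 1)
  blk$params$id_Wk1 <- matrix(1, 1, 1)
  blk$params$id_Wv1 <- matrix(1, 1, 1)
  blk
}

test_that("hand-computed two-token attention example matches", {
  blk <- identity_attention(2)
  x <- c(1, 2)
  out <- multiHeadAttention(x, block = blk)
  # query token 1: softmax([1,2]) . [1,2]; token 2: softmax([2,4]) . [1,2]
  s1 <- exp(c(1, 2)) / sum(exp(c(1, 2)))
  s2 <- exp(c(2, 4)) / sum(exp(c(2, 4)))
  expect_equal(as.numeric(out), c(sum(s1 * x), sum(s2 * x), 1, 2),
               tolerance = 1e-6)
  expect_equal(as.numeric(out)[1:2], c(1.7311, 1.8808), tolerance = 1e-4)
})

test_that("attention weights are a proper distribution over key tokens", {
  set.seed(20)
  blk <- newAttentionBlock(input_dim = 12, kv_dim = 8, heads = 2,
                           token_dim = 4)
  q <- matrix(runif(5 * 12), 5)
  kv <- matrix(runif(5 * 8), 5)
  out <- multiHeadAttention(q, kv, kv, block = blk)
  for (w in attr(out, "weights")) {
    expect_true(all(w >= 0))
    expect_equal(apply(w, c(1, 2), sum),
                 matrix(1, nrow(q), 3), tolerance = 1e-6)
  }
})

test_that("single-token and all-equal-key degenerate cases", {
  blk1 <- identity_attention(1)
  out <- multiHeadAttention(5, block = blk1)
  expect_equal(as.numeric(out), c(5, 5))   # weight 1 -> projected value

  blk <- identity_attention(3)
  out3 <- multiHeadAttention(c(2, 2, 2), block = blk)
  w <- attr(out3, "weights")[[1]]
  expect_equal(as.numeric(w), rep(1 / 3, 9))
})

test_that("the residual concatenation doubles the length and keeps the input", {
  set.seed(21)
  blk <- newAttentionBlock(input_dim = 16, heads = 4, token_dim = 8)
  x <- matrix(runif(3 * 16), 3)
  out <- multiHeadAttention(x, block = blk)
  expect_equal(dim(out), c(3L, 32L))
  expect_equal(unname(out[, 17:32]), unname(x))
})

test_that("attention rejects inconsistent shapes", {
  expect_error(newAttentionBlock(input_dim = 10, heads = 4, token_dim = 6),
               "divide")
  expect_error(newAttentionBlock(input_dim = 10, heads = 2, token_dim = 4),
               "query length")
  blk <- newAttentionBlock(input_dim = 8, kv_dim = 8, heads = 2, token_dim = 4)
  expect_error(multiHeadAttention(matrix(1, 1, 8), matrix(1, 1, 8),
                                  matrix(1, 1, 4), block = blk),
               "same length")
})

test_that("cross-stitch unit applies the 2x2 mix exactly", {
  t1 <- c(1, 0)
  t2 <- c(0, 1)
  id <- crossStitchUnit(t1, t2, diag(2))
  expect_equal(id$t1, t1)
  expect_equal(id$t2, t2)

  mix <- crossStitchUnit(t1, t2, matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE))
  expect_equal(mix$t1, c(0.9, 0.1))
  expect_equal(mix$t2, c(0.1, 0.9))

  swap <- crossStitchUnit(t1, t2, matrix(c(0, 1, 1, 0), 2))
  expect_equal(swap$t1, t2)
  expect_equal(swap$t2, t1)
})

test_that("cross-stitch subnetwork equals its straight-line composition", {
  set.seed(22)
  blk <- newCrossStitchSubnetwork(input_dim = 6, width = 4)
  t1 <- matrix(runif(2 * 6), 2)
  t2 <- matrix(runif(2 * 6), 2)
  res <- crossStitchSubnetwork(t1, t2, blk)

  p <- blk$params
  r <- function(u, i, j) as.numeric(p[[sprintf("cs_u%d_r%d%d", u, i, j)]])
  # unit 1 -> per-task rectified dense -> unit 2 -> concat with inputs
  a1 <- r(1, 1, 1) * t1 + r(1, 1, 2) * t2
  a2 <- r(1, 2, 1) * t1 + r(1, 2, 2) * t2
  d1 <- pmax(sweep(a1 %*% p$cs_W1, 2, as.numeric(p$cs_b1), "+"), 0)
  d2 <- pmax(sweep(a2 %*% p$cs_W2, 2, as.numeric(p$cs_b2), "+"), 0)
  f1 <- r(2, 1, 1) * d1 + r(2, 1, 2) * d2
  f2 <- r(2, 2, 1) * d1 + r(2, 2, 2) * d2
  expect_equal(res$t1, cbind(f1, t1), tolerance = 1e-12)
  expect_equal(res$t2, cbind(f2, t2), tolerance = 1e-12)
  expect_equal(ncol(res$t1), 4 + 6)
})

test_that("identity-configured cross-stitch subnetwork reproduces its input", {
  blk <- newCrossStitchSubnetwork(input_dim = 3, width = 3)
  for (u in 1:2) for (i in 1:2) for (j in 1:2)
    blk$params[[sprintf("cs_u%d_r%d%d", u, i, j)]] <-
      matrix(as.numeric(i == j), 1, 1)
  blk$params$cs_W1 <- diag(3)
  blk$params$cs_W2 <- diag(3)
  t1 <- matrix(c(1, 2, 3), 1)
  t2 <- matrix(c(4, 5, 6), 1)
  res <- crossStitchSubnetwork(t1, t2, blk)
  expect_equal(res$t1, cbind(t1, t1))
  expect_equal(res$t2, cbind(t2, t2))
})

test_that("gradients flow to the cross-stitch mixing entries", {
  set.seed(23)
  blk <- newCrossStitchSubnetwork(input_dim = 4, width = 3)
  t1 <- matrix(runif(4), 1)
  t2 <- matrix(runif(4), 1)
  lossof <- function(params) {
    b <- blk
    b$params <- params
    r <- crossStitchSubnetwork(t1, t2, b)
    sum(r$t1^2) + sum(r$t2^2)
  }
  # analytic gradient via the tape
  tape <- comboSyn:::adTape()
  pn <- comboSyn:::adParams(tape, blk$params)
  res <- comboSyn:::crossStitchForwardNode(tape, pn, blk$spec,
                                           comboSyn:::adConst(tape, t1),
                                           comboSyn:::adConst(tape, t2))
  loss <- comboSyn:::adAdd(tape, comboSyn:::adSumSq(tape, res$t1),
                           comboSyn:::adSumSq(tape, res$t2))
  comboSyn:::adBackward(tape, loss)
  g <- comboSyn:::adGrads(tape)
  for (nm in grep("_r", names(blk$params), value = TRUE)) {
    eps <- 1e-6
    up <- blk$params; up[[nm]] <- up[[nm]] + eps
    dn <- blk$params; dn[[nm]] <- dn[[nm]] - eps
    fd <- (lossof(up) - lossof(dn)) / (2 * eps)
    expect_equal(as.numeric(g[[nm]]), fd, tolerance = 1e-5)
    expect_true(abs(g[[nm]]) > 0)
  }
})

test_that("fc subnetwork matches straight-line matrix arithmetic", {
  set.seed(24)
  net <- newFCSubnetwork(3, c(4, 2), dropout = 0)
  x <- matrix(runif(5 * 3), 5)
  out <- fcSubnetwork(x, net)
  h <- pmax(sweep(x %*% net$params$fc_W1, 2, as.numeric(net$params$fc_b1), "+"), 0)
  h <- pmax(sweep(h %*% net$params$fc_W2, 2, as.numeric(net$params$fc_b2), "+"), 0)
  expect_equal(out, h, tolerance = 1e-12)
})

test_that("fc subnetwork with zero weights emits the rectified bias", {
  net <- newFCSubnetwork(2, 3, dropout = 0)
  net$params$fc_W1 <- matrix(0, 2, 3)
  net$params$fc_b1 <- matrix(c(-1, 0, 2), 1)
  out <- fcSubnetwork(c(7, 9), net)
  expect_equal(as.numeric(out), c(0, 0, 2))
})

test_that("evaluation mode is deterministic despite a dropout rate", {
  set.seed(25)
  net <- newFCSubnetwork(6, c(8, 4), dropout = 0.5)
  x <- matrix(runif(12), 2)
  expect_identical(fcSubnetwork(x, net), fcSubnetwork(x, net))
  # training mode with dropout is stochastic across RNG states
  set.seed(1); a <- fcSubnetwork(x, net, training = TRUE)
  set.seed(2); b <- fcSubnetwork(x, net, training = TRUE)
  expect_false(identical(a, b))
})
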