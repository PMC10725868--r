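tiny_dims <- list(chem = 10, graph = 12, cell = 8, ddi = 6)
# note: the interaction branch ends in 8 units = two attention key tokens,
# so the query/key projections of the cell attention receive gradient

tiny_feats <- function(n, dims = tiny_dims, seed = 60) {
  set.seed(seed)
  list(chem1 = matrix(runif(n * dims$chem), n),
       graph1 = matrix(runif(n * dims$graph), n),
       chem2 = matrix(runif(n * dims$chem), n),
       graph2 = matrix(runif(n * dims$graph), n),
       cell = matrix(runif(n * dims$cell), n),
       ddi = matrix(runif(n * dims$ddi), n))
}

tiny_cfg <- function(...) {
  tinyModelConfig(drug_widths = c(16L, 8L), cell_widths = c(16L, 8L),
                  ddi_widths = c(8L, 8L), graph_widths = c(8L, 4L),
                  pred_widths = c(8L, 4L), heads = 2L, token_dim = 4L,
                  cross_stitch_width = 8L, dropout = 0.2, ...)
}

test_that("the forward pass equals the composition of the tested blocks", {
  for (rep in 1:10) {
    set.seed(600 + rep)
    cfg <- tiny_cfg()
    m <- assembleSynergyModel(cfg, tiny_dims)
    feats <- tiny_feats(3, seed = 700 + rep)
    pred <- predictSynergy(m, feats)

    # straight-line recomposition from the public block functions
    specs <- m@artifacts$specs
    pick <- function(name) {
      list(spec = specs[[name]],
           params = m@params[grep(paste0("^", name, "_"), names(m@params),
                                  value = TRUE)])
    }
    fc <- function(name, x) fcSubnetwork(x, pick(name))
    att <- function(name, q, k = q, v = k)
      unclass(multiHeadAttention(q, k, v, block = pick(name)))[,, drop = FALSE]
    d1 <- cbind(fc("chem", feats$chem1), fc("graph", feats$graph1))
    d2 <- cbind(fc("chem", feats$chem2), fc("graph", feats$graph2))
    ddi <- fc("ddifc", feats$ddi)
    cell <- att("cellattn", fc("cell", feats$cell), ddi, ddi)
    fused <- cbind(d1, d2, cell)
    t1 <- att("task1attn", fused)
    t2 <- att("task2attn", fused)
    cs <- crossStitchSubnetwork(t1, t2, pick("cs"))
    score <- sweep(fc("head1", cs$t1) %*% m@params$out1_W, 2,
                   as.numeric(m@params$out1_b), "+")
    logits <- sweep(fc("head2", cs$t2) %*% m@params$out2_W, 2,
                    as.numeric(m@params$out2_b), "+")
    expect_equal(pred$score, as.numeric(score), tolerance = 1e-10)
    probs <- exp(logits - apply(logits, 1, max))
    probs <- probs / rowSums(probs)
    expect_equal(unname(pred$probs), unname(probs), tolerance = 1e-10)
  }
})

test_that("predictions are valid distributions and duplicate-consistent", {
  set.seed(61)
  m <- assembleSynergyModel(tiny_cfg(), tiny_dims)
  feats <- tiny_feats(6)
  p <- predictSynergy(m, feats)
  expect_equal(rowSums(p$probs), rep(1, 6), tolerance = 1e-6)
  expect_true(all(p$probs >= 0))
  dup <- lapply(feats, function(x) x[c(1, 1), , drop = FALSE])
  pd <- predictSynergy(m, dup)
  expect_equal(pd$score[1], pd$score[2])
  expect_equal(pd$probs[1, ], pd$probs[2, ])
})

test_that("drug order changes the prediction despite shared branch weights", {
  set.seed(62)
  m <- assembleSynergyModel(tiny_cfg(), tiny_dims)
  feats <- tiny_feats(4)
  swapped <- feats
  swapped$chem1 <- feats$chem2; swapped$chem2 <- feats$chem1
  swapped$graph1 <- feats$graph2; swapped$graph2 <- feats$graph1
  p1 <- predictSynergy(m, feats)
  p2 <- predictSynergy(m, swapped)
  expect_false(isTRUE(all.equal(p1$score, p2$score)))
})

test_that("ablation toggles change the architecture as documented", {
  mk <- function(...) {
    set.seed(63)
    assembleSynergyModel(tiny_cfg(...), tiny_dims)
  }
  full <- mk()
  no_cs <- mk(cross_stitch = FALSE)
  # removing cross-stitch removes exactly the r_ij and inter-unit dense
  # parameters, and shrinks the head input from width + task_dim to task_dim
  gone <- setdiff(names(full@params), names(no_cs@params))
  expect_true(all(grepl("^cs_", gone)))
  expect_equal(sum(grepl("_r[12][12]$", gone)), 8)
  expect_lt(parameterCount(no_cs), parameterCount(full))
  expect_false("cs" %in% names(no_cs@artifacts$specs))

  no_fa <- mk(feature_attention = FALSE)
  expect_true(any(grepl("^task1fc_", names(no_fa@params))))
  expect_false(any(grepl("^task1attn_", names(no_fa@params))))

  no_ia <- mk(interaction_attention = FALSE)
  expect_false(any(grepl("^ddifc_|^cellattn_", names(no_ia@params))))
  # DDI features unused: forward works without a ddi matrix
  feats <- tiny_feats(2)
  feats$ddi <- NULL
  expect_equal(length(predictSynergy(no_ia, feats)$score), 2)

  # dropping view I shrinks the graph input dimension
  dims_noI <- tiny_dims
  dims_noI$graph <- tiny_dims$graph - 4
  no_v1 <- assembleSynergyModel(tiny_cfg(graph_view_I = FALSE), dims_noI)
  expect_lt(parameterCount(no_v1), parameterCount(mk(graph_view_I = FALSE)))
})

test_that("every parameter tensor receives gradient after one step", {
  set.seed(64)
  cfg <- tiny_cfg(dropout = 0)
  m <- assembleSynergyModel(cfg, tiny_dims)
  feats <- tiny_feats(8)
  y <- rnorm(8, sd = 3)
  ycl <- sample(synergyClasses(), 8, replace = TRUE)
  tape <- comboSyn:::adTape()
  pn <- comboSyn:::adParams(tape, m@params)
  fwd <- comboSyn:::synergyForwardNode(tape, pn, m, feats, training = TRUE)
  loss <- comboSyn:::adAdd(tape,
                           comboSyn:::adMSELoss(tape, fwd$score, y),
                           comboSyn:::adCrossEntropyLoss(
                             tape, fwd$logits, match(ycl, synergyClasses())))
  for (r in fwd$reg) loss <- comboSyn:::adAdd(tape, loss, r)
  expect_true(is.finite(loss$value))
  comboSyn:::adBackward(tape, loss)
  g <- comboSyn:::adGrads(tape)
  expect_setequal(names(g), names(m@params))
  dead <- names(g)[!vapply(g, function(x) any(x != 0), logical(1))]
  expect_equal(dead, character(0))
})

test_that("zero-epoch training returns the untrained forward pass", {
  set.seed(65)
  m <- assembleSynergyModel(tiny_cfg(), tiny_dims)
  feats <- tiny_feats(5)
  y <- rnorm(5)
  ycl <- rep("additive", 5)
  before <- predictSynergy(m, feats)
  m0 <- trainSynergyModel(m, feats, y, ycl, seed = 1, epochs = 0)
  expect_false(m0@trained)
  after <- predictSynergy(m0, feats)
  # identical parameters; scores shift only by the stored target scaling
  expect_equal(m0@params, m@params)
  expect_equal(after$probs, before$probs)
})

test_that("training is bitwise reproducible under a fixed seed", {
  set.seed(66)
  m <- assembleSynergyModel(tiny_cfg(), tiny_dims)
  feats <- tiny_feats(16)
  y <- rnorm(16, sd = 4)
  ycl <- sample(synergyClasses(), 16, replace = TRUE)
  m1 <- trainSynergyModel(m, feats, y, ycl, seed = 7, epochs = 4)
  m2 <- trainSynergyModel(m, feats, y, ycl, seed = 7, epochs = 4)
  expect_identical(m1@log, m2@log)
  expect_identical(m1@params, m2@params)
  m3 <- trainSynergyModel(m, feats, y, ycl, seed = 8, epochs = 4)
  expect_false(identical(m1@log, m3@log))
})

test_that("training reduces both task losses on a learnable signal", {
  set.seed(67)
  cfg <- tiny_cfg(dropout = 0)
  m <- assembleSynergyModel(cfg, tiny_dims)
  n <- 60
  feats <- tiny_feats(n, seed = 68)
  beta <- rnorm(tiny_dims$chem, sd = 2)
  y <- 10 + 8 * as.numeric((feats$chem1 + feats$chem2) %*% beta) + rnorm(n)
  ycl <- assignClassLabels(data.frame(score = y))$class
  m1 <- trainSynergyModel(m, feats, y, ycl, seed = 1, epochs = 30)
  expect_lt(tail(m1@log$loss_score, 1), m1@log$loss_score[1])
  expect_lt(tail(m1@log$loss_class, 1), m1@log$loss_class[1])
})
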