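# The assembled two-headed synergy network: per-drug chemical + graph
# branches (shared between the two drugs), a cell branch whose features are
# modulated by drug-interaction features through attention, per-task
# attention over the fused representation, a cross-stitch subnetwork, and
# two prediction heads (synergy score; 3-class synergy label).

#' Construct a model configuration
#'
#' Defaults are the published global settings: drug chemical branch
#' [1024, 512, 256], cell branch [512, 256, 128], interaction branch
#' [1024, 512, 256], graph branch [258, 128], prediction heads [128, 64],
#' dropout 0.2, 4 attention heads, AdamW with lr 1e-5, weight decay 0.025,
#' 1000 epochs, batch 64.
#'
#' @param drug_widths,cell_widths,ddi_widths,graph_widths,pred_widths
#'   integer vectors of hidden widths.
#' @param dropout,heads,token_dim,lr,weight_decay,epochs,batch see
#'   \linkS4class{ModelConfig}.
#' @param loss_w_score,loss_w_class multi-task loss weights (default 1, 1:
#'   unweighted sum).
#' @param l2_weights,l2_activity regularization coefficients.
#' @param share_qkv,scale_attention attention variants (both off by
#'   default).
#' @param cross_stitch_width width of the dense layers between the two
#'   cross-stitch units.
#' @param cross_stitch,feature_attention,interaction_attention,graph_view_I
#'   ablation toggles; TRUE keeps the component.
#' @return a \linkS4class{ModelConfig}.
#' @export
modelConfig <- function(drug_widths = c(1024L, 512L, 256L),
                        cell_widths = c(512L, 256L, 128L),
                        ddi_widths = c(1024L, 512L, 256L),
                        graph_widths = c(258L, 128L),
                        pred_widths = c(128L, 64L),
                        dropout = 0.2, heads = 4L, token_dim = 16L,
                        lr = 1e-5, weight_decay = 0.025,
                        epochs = 1000L, batch = 64L,
                        loss_w_score = 1, loss_w_class = 1,
                        l2_weights = 1e-4, l2_activity = 1e-5,
                        share_qkv = FALSE, scale_attention = FALSE,
                        cross_stitch_width = 512L,
                        cross_stitch = TRUE, feature_attention = TRUE,
                        interaction_attention = TRUE, graph_view_I = TRUE) {
  new("ModelConfig",
      drug_widths = as.integer(drug_widths),
      cell_widths = as.integer(cell_widths),
      ddi_widths = as.integer(ddi_widths),
      graph_widths = as.integer(graph_widths),
      pred_widths = as.integer(pred_widths),
      dropout = dropout, heads = as.integer(heads),
      token_dim = as.integer(token_dim), lr = lr,
      weight_decay = weight_decay, epochs = as.integer(epochs),
      batch = as.integer(batch), loss_w_score = loss_w_score,
      loss_w_class = loss_w_class, l2_weights = l2_weights,
      l2_activity = l2_activity, share_qkv = share_qkv,
      scale_attention = scale_attention,
      cross_stitch_width = as.integer(cross_stitch_width),
      toggles = c(cross_stitch = cross_stitch,
                  feature_attention = feature_attention,
                  interaction_attention = interaction_attention,
                  graph_view_I = graph_view_I))
}

#' A CPU-scale configuration for tests and small synthetic studies
#'
#' Same architecture, every width shrunk, a larger learning rate and fewer
#' epochs so a model trains in seconds to minutes on one CPU.
#'
#' @param ... overrides passed on to \code{\link{modelConfig}}.
#' @return a \linkS4class{ModelConfig}.
#' @export
tinyModelConfig <- function(...) {
  args <- utils::modifyList(
    list(drug_widths = c(32L, 16L), cell_widths = c(32L, 16L),
         ddi_widths = c(16L, 8L), graph_widths = c(16L, 8L),
         pred_widths = c(16L, 8L), heads = 2L, token_dim = 8L,
         lr = 1e-3, epochs = 200L, batch = 32L,
         cross_stitch_width = 16L, weight_decay = 1e-3),
    list(...))
  do.call(modelConfig, args)
}

.fused_dim <- function(config) {
  drug_feat <- config@drug_widths[length(config@drug_widths)] +
    config@graph_widths[length(config@graph_widths)]
  cell_out <- config@cell_widths[length(config@cell_widths)]
  cell_prime <- if (config@toggles[["interaction_attention"]]) 2L * cell_out
                else cell_out
  2L * drug_feat + cell_prime
}

#' Assemble an untrained synergy model
#'
#' Builds every block and initializes parameters (drawing from the current
#' RNG state). Forward contract: per drug,
#' \code{drugFeat = concat(FC_chem(descriptors), FC_graph(embedding))} with
#' parameters shared between the two drugs; the cell branch is
#' \code{attention(query = FC_cell(expr), key = value = FC_ddi(ddiFeat))};
#' the fused vector \code{concat(drugFeat1, drugFeat2, cell')} feeds one
#' attention block per task; the two task vectors pass through the
#' cross-stitch subnetwork; head 1 regresses the synergy score, head 2
#' emits 3-class logits. Ablation toggles replace blocks by pass-through
#' paths: without cross-stitch the task vectors go straight to the heads;
#' without feature attention each task gets a plain rectified dense layer;
#' without interaction attention the DDI branch is absent and the cell
#' features pass through unchanged.
#'
#' @param config a \linkS4class{ModelConfig}.
#' @param dims named list of input feature lengths: \code{chem},
#'   \code{graph}, \code{cell}, and \code{ddi} (required only when the
#'   interaction-attention toggle is on).
#' @return an untrained \linkS4class{SynergyModel}.
#' @export
assembleSynergyModel <- function(config, dims) {
  stopifnot(is(config, "ModelConfig"),
            all(c("chem", "graph", "cell") %in% names(dims)))
  tg <- config@toggles
  params <- list()
  specs <- list()
  add <- function(block) {
    params <<- c(params, block$params)
    specs[[block$spec$name]] <<- block$spec
  }
  add(newFCSubnetwork(dims$chem, config@drug_widths, config@dropout,
                      config@l2_weights, config@l2_activity, name = "chem"))
  add(newFCSubnetwork(dims$graph, config@graph_widths, config@dropout,
                      config@l2_weights, config@l2_activity, name = "graph"))
  add(newFCSubnetwork(dims$cell, config@cell_widths, config@dropout,
                      config@l2_weights, config@l2_activity, name = "cell"))
  cell_out <- config@cell_widths[length(config@cell_widths)]
  if (tg[["interaction_attention"]]) {
    if (is.null(dims$ddi)) stop("dims$ddi required when interaction attention is on")
    add(newFCSubnetwork(dims$ddi, config@ddi_widths, config@dropout,
                        config@l2_weights, config@l2_activity, name = "ddifc"))
    add(newAttentionBlock(cell_out,
                          kv_dim = config@ddi_widths[length(config@ddi_widths)],
                          heads = config@heads, token_dim = config@token_dim,
                          share_qkv = config@share_qkv,
                          scale = config@scale_attention, name = "cellattn"))
  }
  fused <- .fused_dim(config)
  if (tg[["feature_attention"]]) {
    add(newAttentionBlock(fused, heads = config@heads,
                          token_dim = config@token_dim,
                          share_qkv = config@share_qkv,
                          scale = config@scale_attention, name = "task1attn"))
    add(newAttentionBlock(fused, heads = config@heads,
                          token_dim = config@token_dim,
                          share_qkv = config@share_qkv,
                          scale = config@scale_attention, name = "task2attn"))
    task_dim <- 2L * fused
  } else {
    add(newFCSubnetwork(fused, fused, config@dropout, config@l2_weights,
                        config@l2_activity, name = "task1fc"))
    add(newFCSubnetwork(fused, fused, config@dropout, config@l2_weights,
                        config@l2_activity, name = "task2fc"))
    task_dim <- fused
  }
  if (tg[["cross_stitch"]]) {
    add(newCrossStitchSubnetwork(task_dim, config@cross_stitch_width,
                                 name = "cs"))
    head_in <- config@cross_stitch_width + task_dim
  } else {
    head_in <- task_dim
  }
  add(newFCSubnetwork(head_in, config@pred_widths, config@dropout,
                      config@l2_weights, config@l2_activity, name = "head1"))
  add(newFCSubnetwork(head_in, config@pred_widths, config@dropout,
                      config@l2_weights, config@l2_activity, name = "head2"))
  pw <- config@pred_widths[length(config@pred_widths)]
  params$out1_W <- .he_init(pw, 1L)
  params$out1_b <- matrix(0, 1, 1)
  params$out2_W <- .he_init(pw, 3L)
  params$out2_b <- matrix(0, 1, 3)

  new("SynergyModel", config = config, params = params,
      dims = lapply(dims, as.integer),
      artifacts = list(specs = specs), trained = FALSE,
      log = data.frame())
}

#' Total trainable parameter count of a synergy model
#' @param model a \linkS4class{SynergyModel}.
#' @return integer.
#' @export
parameterCount <- function(model) {
  sum(vapply(model@params, length, numeric(1)))
}

# forward pass on the tape; batch is a list of matrices chem1, graph1,
# chem2, graph2, cell, ddi (ddi optional under the ablation)
synergyForwardNode <- function(tape, pn, model, batch, training = FALSE) {
  cfg <- model@config
  specs <- model@artifacts$specs
  tg <- cfg@toggles
  reg <- list()
  run_fc <- function(name, x) {
    r <- fcForwardNode(tape, pn, specs[[name]], x, training)
    reg <<- c(reg, r$reg)
    r$out
  }
  drug_feat <- function(chem, graph) {
    adConcatCols(tape, list(run_fc("chem", chem), run_fc("graph", graph)))
  }
  d1 <- drug_feat(adConst(tape, batch$chem1), adConst(tape, batch$graph1))
  d2 <- drug_feat(adConst(tape, batch$chem2), adConst(tape, batch$graph2))
  cell <- run_fc("cell", adConst(tape, batch$cell))
  if (tg[["interaction_attention"]]) {
    ddi <- run_fc("ddifc", adConst(tape, batch$ddi))
    cell <- attentionForwardNode(tape, pn, specs$cellattn, cell, ddi, ddi)$out
  }
  fused <- adConcatCols(tape, list(d1, d2, cell))
  if (tg[["feature_attention"]]) {
    t1 <- attentionForwardNode(tape, pn, specs$task1attn, fused)$out
    t2 <- attentionForwardNode(tape, pn, specs$task2attn, fused)$out
  } else {
    t1 <- run_fc("task1fc", fused)
    t2 <- run_fc("task2fc", fused)
  }
  if (tg[["cross_stitch"]]) {
    cs <- crossStitchForwardNode(tape, pn, specs$cs, t1, t2)
    u1 <- cs$t1
    u2 <- cs$t2
  } else {
    u1 <- t1
    u2 <- t2
  }
  h1 <- run_fc("head1", u1)
  h2 <- run_fc("head2", u2)
  score <- adAddBias(tape, adMatmul(tape, h1, pn$out1_W), pn$out1_b)
  logits <- adAddBias(tape, adMatmul(tape, h2, pn$out2_W), pn$out2_b)
  list(score = score, logits = logits, reg = reg)
}

#' Train a synergy model
#'
#' Minimizes \code{w_score * MSE(score) + w_class * crossentropy(3-class)}
#' plus the subnetwork regularization penalties with AdamW, shuffling
#' mini-batches with the given seed. Runs are deterministic for a fixed
#' seed.
#'
#' @param model an assembled \linkS4class{SynergyModel}.
#' @param features list of matrices \code{chem1}, \code{graph1},
#'   \code{chem2}, \code{graph2}, \code{cell}, optionally \code{ddi}, one
#'   row per sample.
#' @param y_score numeric vector of observed synergy scores.
#' @param y_class character/factor of 3-class labels
#'   (see \code{\link{synergyClasses}}).
#' @param seed RNG seed for shuffling and dropout.
#' @param epochs,batch,lr optional overrides of the configured values.
#' @return the trained model; slot \code{log} holds one row per epoch with
#'   both task losses.
#' @export
trainSynergyModel <- function(model, features, y_score, y_class, seed = 0L,
                              epochs = NULL, batch = NULL, lr = NULL) {
  cfg <- model@config
  epochs <- if (is.null(epochs)) cfg@epochs else as.integer(epochs)
  batch <- if (is.null(batch)) cfg@batch else as.integer(batch)
  lr <- if (is.null(lr)) cfg@lr else lr
  n <- length(y_score)
  if (n == 0) stop("empty training set")
  ycls <- match(as.character(y_class), synergyClasses())
  if (anyNA(ycls)) stop("unknown class label(s)")
  # regress on the standardized score so both task losses are O(1);
  # predictions are mapped back to the Loewe scale
  y_center <- mean(y_score)
  y_scale <- stats::sd(y_score)
  if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
  yz <- (y_score - y_center) / y_scale
  params <- model@params
  state <- adamWInit(params)
  log <- vector("list", epochs)
  .with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      tot_s <- tot_c <- 0
      nb <- 0
      for (start in seq(1, n, by = batch)) {
        ib <- ord[start:min(start + batch - 1, n)]
        sub <- lapply(features, function(m) {
          m <- m[ib, , drop = FALSE]
          dimnames(m) <- NULL
          m
        })
        tape <- adTape()
        pn <- adParams(tape, params)
        fwd <- synergyForwardNode(tape, pn, model, sub, training = TRUE)
        l_s <- adMSELoss(tape, fwd$score, yz[ib])
        l_c <- adCrossEntropyLoss(tape, fwd$logits, ycls[ib])
        loss <- adAdd(tape, adScale(tape, l_s, cfg@loss_w_score),
                      adScale(tape, l_c, cfg@loss_w_class))
        for (r in fwd$reg) loss <- adAdd(tape, loss, r)
        if (!is.finite(loss$value))
          stop("non-finite loss at epoch ", ep, " (score loss ",
               l_s$value, ", class loss ", l_c$value, ")")
        adBackward(tape, loss)
        upd <- adamWStep(params, adGrads(tape), state, lr, cfg@weight_decay)
        params <- upd$params
        state <- upd$state
        tot_s <- tot_s + as.numeric(l_s$value)
        tot_c <- tot_c + as.numeric(l_c$value)
        nb <- nb + 1
      }
      log[[ep]] <- data.frame(epoch = ep, loss_score = tot_s / nb,
                              loss_class = tot_c / nb)
    }
  })
  model@params <- params
  model@artifacts$y_center <- y_center
  model@artifacts$y_scale <- y_scale
  model@trained <- epochs > 0
  model@log <- if (epochs > 0) do.call(rbind, log) else data.frame()
  model
}

#' Predict synergy scores and class probabilities
#'
#' Deterministic (dropout disabled). The hard class label is the argmax of
#' the probabilities; a binary synergy call is the synergistic class.
#'
#' @param model a \linkS4class{SynergyModel}.
#' @param features list of feature matrices as in
#'   \code{\link{trainSynergyModel}}.
#' @return list with \code{score} (numeric vector), \code{probs} (matrix
#'   with columns \code{\link{synergyClasses}}), and \code{class}
#'   (character vector).
#' @export
predictSynergy <- function(model, features) {
  tape <- adTape()
  pn <- adParams(tape, model@params)
  fwd <- synergyForwardNode(tape, pn, model, features, training = FALSE)
  probs <- softmaxRows(fwd$logits$value)
  colnames(probs) <- synergyClasses()
  center <- if (is.null(model@artifacts$y_center)) 0 else model@artifacts$y_center
  scale_ <- if (is.null(model@artifacts$y_scale)) 1 else model@artifacts$y_scale
  list(score = as.numeric(fwd$score$value) * scale_ + center, probs = probs,
       class = synergyClasses()[max.col(probs, ties.method = "first")])
}
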