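# Drug-drug-interaction classifier: two parallel fully connected branches
# (one per drug) whose concatenated outputs pass through a shared stack and
# a K-way softmax. Its penultimate activations become drug-interaction
# features for the synergy network.

.multiclass_report <- function(y, pred, K) {
  acc <- mean(pred == y)
  per <- vapply(seq_len(K), function(k) {
    tp <- sum(pred == k & y == k)
    fp <- sum(pred == k & y != k)
    fn <- sum(pred != k & y == k)
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
      2 * prec * rec / (prec + rec) else NA_real_
    c(prec, rec, f1)
  }, numeric(3))
  pe <- sum(vapply(seq_len(K), function(k) mean(pred == k) * mean(y == k),
                   numeric(1)))
  list(accuracy = acc,
       precision = mean(per[1, ], na.rm = TRUE),
       recall = mean(per[2, ], na.rm = TRUE),
       kappa = if (pe < 1) (acc - pe) / (1 - pe) else 1,
       f1 = mean(per[3, ], na.rm = TRUE))
}

.ddi_param_blocks <- function(input_dim, branch_widths, post_widths, n_classes,
                              dropout, l2_weights, l2_activity) {
  b1 <- newFCSubnetwork(input_dim, branch_widths, dropout, l2_weights,
                        l2_activity, name = "ddi_b1")
  b2 <- newFCSubnetwork(input_dim, branch_widths, dropout, l2_weights,
                        l2_activity, name = "ddi_b2")
  post <- newFCSubnetwork(2 * branch_widths[length(branch_widths)],
                          post_widths, dropout, l2_weights, l2_activity,
                          name = "ddi_post")
  params <- c(b1$params, b2$params, post$params)
  params$ddi_out_W <- .he_init(post_widths[length(post_widths)], n_classes)
  params$ddi_out_b <- matrix(0, 1, n_classes)
  list(params = params, specs = list(b1 = b1$spec, b2 = b2$spec, post = post$spec))
}

.ddi_forward <- function(tape, pn, specs, x1, x2, training,
                         stop_at = c("logits", "post", "branch")) {
  stop_at <- match.arg(stop_at)
  reg <- list()
  r1 <- fcForwardNode(tape, pn, specs$b1, x1, training)
  r2 <- fcForwardNode(tape, pn, specs$b2, x2, training)
  reg <- c(reg, r1$reg, r2$reg)
  cat12 <- adConcatCols(tape, list(r1$out, r2$out))
  if (stop_at == "branch") return(list(out = cat12, reg = reg))
  rp <- fcForwardNode(tape, pn, specs$post, cat12, training)
  reg <- c(reg, rp$reg)
  if (stop_at == "post") return(list(out = rp$out, reg = reg))
  logits <- adAddBias(tape, adMatmul(tape, rp$out, pn$ddi_out_W), pn$ddi_out_b)
  list(out = logits, reg = reg)
}

#' Train the drug-drug-interaction classifier
#'
#' Splits pairs 9:1 into training and validation, stratified by interaction
#' class (classes too small to stratify trigger a warning and a plain random
#' split), trains with cross-entropy under AdamW, and reports accuracy,
#' macro precision/recall/F1 and Cohen's kappa on the validation split.
#'
#' @param data data.frame with columns \code{drug1}, \code{drug2},
#'   \code{label} (dense integer classes starting at 0).
#' @param descriptors numeric matrix of cleaned, normalized descriptors,
#'   rownames are drug ids; every drug in \code{data} must have a row.
#' @param branch_widths,post_widths hidden widths of the per-drug branches
#'   and the shared stack after concatenation.
#' @param epochs,batch,lr,weight_decay AdamW training settings.
#' @param dropout,l2_weights,l2_activity subnetwork regularization.
#' @param seed RNG seed for the split, initialization and shuffling.
#' @param penultimate which activations \code{\link{extractDDIFeatures}}
#'   returns: \code{"post"} (last shared hidden layer) or \code{"branch"}.
#' @return a trained \linkS4class{DDIModel}; its \code{report} slot carries
#'   the validation metrics, split sizes and seed.
#' @export
trainDDI <- function(data, descriptors, branch_widths = c(1024L, 512L, 256L),
                     post_widths = c(512L, 256L), epochs = 30L, batch = 64L,
                     lr = 1e-3, weight_decay = 0.025, dropout = 0.2,
                     l2_weights = 1e-4, l2_activity = 1e-5, seed = 0L,
                     penultimate = "post") {
  stopifnot(all(c("drug1", "drug2", "label") %in% names(data)), nrow(data) >= 2)
  missing_drugs <- setdiff(unique(c(data$drug1, data$drug2)), rownames(descriptors))
  if (length(missing_drugs))
    stop("no descriptor row for drug(s): ", paste(missing_drugs, collapse = ", "))
  y <- as.integer(data$label) + 1L
  K <- max(y)
  if (!identical(as.integer(sort(unique(y))), seq_len(K)))
    stop("labels must be dense integers 0..K-1")
  X <- as.matrix(descriptors)

  .with_seed(seed, {
    counts <- table(y)
    if (any(counts < 2)) {
      warning("class(es) with fewer than 2 samples; falling back to a random 9:1 split")
      val <- sample(nrow(data), max(1L, round(nrow(data) / 10)))
    } else {
      val <- unlist(lapply(seq_len(K), function(k) {
        ik <- which(y == k)
        sample(ik, max(1L, round(length(ik) / 10)))
      }))
    }
    tr <- setdiff(seq_len(nrow(data)), val)

    blocks <- .ddi_param_blocks(ncol(X), as.integer(branch_widths),
                                as.integer(post_widths), K, dropout,
                                l2_weights, l2_activity)
    params <- blocks$params
    state <- adamWInit(params)
    losses <- numeric(0)
    if (epochs > 0) {
      for (ep in seq_len(epochs)) {
        ord <- sample(tr)
        ep_loss <- 0
        nb <- 0
        for (start in seq(1, length(ord), by = batch)) {
          ib <- ord[start:min(start + batch - 1, length(ord))]
          tape <- adTape()
          pn <- adParams(tape, params)
          x1 <- X[data$drug1[ib], , drop = FALSE]
          x2 <- X[data$drug2[ib], , drop = FALSE]
          dimnames(x1) <- dimnames(x2) <- NULL
          fwd <- .ddi_forward(tape, pn, blocks$specs, adConst(tape, x1),
                              adConst(tape, x2), training = TRUE)
          loss <- adCrossEntropyLoss(tape, fwd$out, y[ib])
          for (r in fwd$reg) loss <- adAdd(tape, loss, r)
          adBackward(tape, loss)
          upd <- adamWStep(params, adGrads(tape), state, lr, weight_decay)
          params <- upd$params
          state <- upd$state
          ep_loss <- ep_loss + as.numeric(loss$value)
          nb <- nb + 1
        }
        losses <- c(losses, ep_loss / nb)
      }
    }

    model <- new("DDIModel", params = params,
                 branch_widths = as.integer(branch_widths),
                 post_widths = as.integer(post_widths),
                 input_dim = ncol(X), n_classes = as.integer(K),
                 penultimate = penultimate, trained = epochs > 0,
                 report = list())
    probs <- .ddi_predict_probs(model, X[data$drug1[val], , drop = FALSE],
                                X[data$drug2[val], , drop = FALSE])
    rep_ <- .multiclass_report(y[val], max.col(probs, ties.method = "first"), K)
    rep_$n_train <- length(tr)
    rep_$n_val <- length(val)
    rep_$seed <- as.integer(seed)
    rep_$epoch_loss <- losses
    model@report <- rep_
    model
  })
}

.ddi_specs <- function(model) {
  spec <- function(name, input_dim, widths) {
    list(kind = "fc", name = name, input_dim = as.integer(input_dim),
         widths = as.integer(widths), dropout = 0,
         l2_weights = 0, l2_activity = 0)
  }
  list(b1 = spec("ddi_b1", model@input_dim, model@branch_widths),
       b2 = spec("ddi_b2", model@input_dim, model@branch_widths),
       post = spec("ddi_post",
                   2L * model@branch_widths[length(model@branch_widths)],
                   model@post_widths))
}

.ddi_predict_probs <- function(model, x1, x2) {
  tape <- adTape()
  pn <- adParams(tape, model@params)
  fwd <- .ddi_forward(tape, pn, .ddi_specs(model),
                      adConst(tape, x1), adConst(tape, x2), training = FALSE)
  softmaxRows(fwd$out$value)
}

#' Extract drug-interaction features from a trained DDI model
#'
#' Returns the penultimate-layer activations for each (drug1, drug2) pair:
#' the last shared hidden layer (default) or the concatenated branch
#' outputs, depending on how the model was configured. The branches are
#' order-sensitive, so (d1, d2) and (d2, d1) generally differ.
#'
#' @param model a \linkS4class{DDIModel}.
#' @param drug1,drug2 descriptor vectors (or matrices, rows are pairs) in
#'   the layout the model was trained on.
#' @param allow_untrained set TRUE to extract from an untrained model (for
#'   tests).
#' @return numeric matrix of interaction features, one row per pair.
#' @export
extractDDIFeatures <- function(model, drug1, drug2, allow_untrained = FALSE) {
  stopifnot(is(model, "DDIModel"))
  if (!model@trained && !allow_untrained)
    stop("DDI model is untrained; pass allow_untrained = TRUE to override")
  as_mat <- function(x) if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  x1 <- as_mat(drug1)
  x2 <- as_mat(drug2)
  if (ncol(x1) != model@input_dim || ncol(x2) != model@input_dim)
    stop("descriptor length ", ncol(x1), "/", ncol(x2),
         " does not match model input ", model@input_dim)
  tape <- adTape()
  pn <- adParams(tape, model@params)
  .ddi_forward(tape, pn, .ddi_specs(model), adConst(tape, x1),
               adConst(tape, x2), training = FALSE,
               stop_at = model@penultimate)$out$value
}

#' Width of the interaction-feature vector a DDI model emits
#' @param model a \linkS4class{DDIModel}.
#' @return integer feature length.
#' @export
ddiFeatureDim <- function(model) {
  if (model@penultimate == "post") model@post_widths[length(model@post_widths)]
  else 2L * model@branch_widths[length(model@branch_widths)]
}
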