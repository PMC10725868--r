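# End-to-end experiment runner: dataset labeling, per-fold feature
# preparation with train-only statistics, model training and evaluation,
# and per-fold aggregation with confidence intervals.

#' Build the labeled synergy dataset
#'
#' Replicate averaging, Loewe-threshold class labels, then reversed-pair
#' augmentation.
#'
#' @param synergy data.frame (drug1, drug2, cell, score), possibly with
#'   replicated rows.
#' @return augmented data.frame with \code{class} and \code{reversed}
#'   columns.
#' @export
prepareSynergyRecords <- function(synergy) {
  augmentReversedPairs(assignClassLabels(aggregateReplicates(synergy)))
}

# Per-fold feature preparation. All statistics (normalizers, view
# vocabularies) are fitted on training rows/entities only; the atom-label
# dictionary and the descriptor column filters are structural properties of
# the drug universe and are derived from the full drug table.
buildFeatureSet <- function(tables, records, train_mask, config,
                            ddi_model = NULL,
                            graph_dims = c(I = 16, II = 32, III = 8, IV = 32),
                            max_edges = 6L, scale_c = 1) {
  smiles <- structure(tables$drugs$smiles, names = tables$drugs$drug_id)
  train_drugs <- unique(c(records$drug1[train_mask], records$drug2[train_mask]))
  train_cells <- unique(records$cell[train_mask])

  graphs <- lapply(smiles, smilesToGraph)
  label_map <- buildAtomLabelMap(graphs)
  tr_graphs <- graphs[train_drugs]
  vocabs <- list(
    II = buildViewVocab(lapply(tr_graphs, viewBondLabelPaths,
                               max_edges = max_edges), graph_dims[["II"]], "II"),
    III = buildViewVocab(lapply(tr_graphs, viewShortestPathLengths),
                         graph_dims[["III"]], "III"),
    IV = buildViewVocab(lapply(tr_graphs, viewAtomLabelPaths,
                               max_edges = max_edges), graph_dims[["IV"]], "IV"))
  graph_emb <- t(vapply(graphs, function(g)
    embedGraph(g, vocabs, label_map, graph_dims, max_edges)$vector,
    numeric(sum(graph_dims))))
  if (!config@toggles[["graph_view_I"]])
    graph_emb <- graph_emb[, -seq_len(graph_dims[["I"]]), drop = FALSE]
  graph_norm <- fitNormalizer(graph_emb[train_drugs, , drop = FALSE], scale_c)
  graph_emb <- applyNormalizer(graph_emb, graph_norm)
  rownames(graph_emb) <- names(smiles)

  desc <- cleanDescriptors(tables$descriptors)
  desc_norm <- fitNormalizer(desc[train_drugs, , drop = FALSE], scale_c)
  desc_mat <- applyNormalizer(desc, desc_norm)
  rownames(desc_mat) <- rownames(desc)

  expr <- selectGenePanel(tables$expression, tables$gene_panel)
  expr_norm <- fitNormalizer(expr[train_cells, , drop = FALSE], scale_c)
  expr_mat <- applyNormalizer(expr, expr_norm)
  rownames(expr_mat) <- rownames(expr)

  feats <- list(chem1 = desc_mat[records$drug1, , drop = FALSE],
                graph1 = graph_emb[records$drug1, , drop = FALSE],
                chem2 = desc_mat[records$drug2, , drop = FALSE],
                graph2 = graph_emb[records$drug2, , drop = FALSE],
                cell = expr_mat[records$cell, , drop = FALSE])
  dims <- list(chem = ncol(desc_mat), graph = ncol(graph_emb),
               cell = ncol(expr_mat))
  artifacts <- list(label_map = label_map, vocabs = vocabs,
                    graph_dims = graph_dims, max_edges = max_edges,
                    normalizers = list(graph = graph_norm, desc = desc_norm,
                                       expr = expr_norm))
  if (config@toggles[["interaction_attention"]]) {
    if (is.null(ddi_model)) stop("interaction attention needs a DDI model")
    raw <- extractDDIFeatures(ddi_model, desc_mat[records$drug1, , drop = FALSE],
                              desc_mat[records$drug2, , drop = FALSE],
                              allow_untrained = TRUE)
    colnames(raw) <- sprintf("ddi_%03d", seq_len(ncol(raw)))
    keepable <- apply(raw[train_mask, , drop = FALSE], 2,
                      function(x) stats::var(x) > 0)
    ddi_norm <- fitNormalizer(raw[train_mask, , drop = FALSE], scale_c)
    feats$ddi <- applyNormalizer(raw, ddi_norm)
    dims$ddi <- ncol(feats$ddi)
    artifacts$normalizers$ddi <- ddi_norm
    artifacts$ddi_constant_features <- sum(!keepable)
  }
  list(features = feats, dims = dims, artifacts = artifacts)
}

.subset_features <- function(feats, idx) {
  lapply(feats, function(m) m[idx, , drop = FALSE])
}

#' Run a grouped cross-validation experiment
#'
#' For each fold: fit every normalizer and vocabulary on the training rows,
#' assemble and train a fresh model, evaluate on the held-out fold, then
#' aggregate the per-fold metrics with Student-t confidence intervals. The
#' interaction classifier is pretrained once on the DDI table (an
#' independent dataset) before the folds run.
#'
#' @param tables input tables as returned by \code{\link{readWorldTables}}
#'   (or a \linkS4class{SyntheticWorld} object).
#' @param config a \linkS4class{ModelConfig}.
#' @param scheme grouped CV scheme (see \code{\link{splitFolds}}).
#' @param seed master seed; fold shuffling, DDI pretraining and per-fold
#'   training seeds derive from it.
#' @param folds integer fold ids to run (default all five).
#' @param graph_dims per-view graph-embedding lengths.
#' @param train_epochs,ddi_epochs training lengths (defaults: the
#'   configured epochs; 20 for the DDI model).
#' @param level confidence level for the aggregate reports.
#' @param out_dir optional directory for artifacts (fold assignment,
#'   per-fold metrics, aggregate report, resolved config).
#' @return list with \code{reports} (named \linkS4class{MetricReport}s),
#'   \code{per_fold} (data.frame), \code{split}, \code{ddi_report},
#'   \code{config}.
#' @export
runCVExperiment <- function(tables, config = tinyModelConfig(),
                            scheme = "pair", seed = 0L, folds = 0:4,
                            graph_dims = c(I = 16, II = 32, III = 8, IV = 32),
                            train_epochs = NULL, ddi_epochs = 20L,
                            level = 0.95, out_dir = NULL) {
  if (is(tables, "SyntheticWorld"))
    tables <- list(drugs = tables@drugs, descriptors = tables@descriptors,
                   expression = tables@expression, gene_panel = tables@gene_panel,
                   ddi = tables@ddi, synergy = tables@synergy)
  records <- prepareSynergyRecords(tables$synergy)
  split <- splitFolds(records, scheme, seed = seed)

  ddi_model <- NULL
  ddi_report <- NULL
  if (config@toggles[["interaction_attention"]]) {
    desc <- cleanDescriptors(tables$descriptors)
    ddi_desc <- applyNormalizer(desc, fitNormalizer(desc, scale_c = 1))
    rownames(ddi_desc) <- rownames(desc)
    ddi_model <- trainDDI(tables$ddi, ddi_desc,
                          branch_widths = config@ddi_widths,
                          post_widths = c(2L * config@ddi_widths[length(config@ddi_widths)],
                                          config@ddi_widths[length(config@ddi_widths)]),
                          epochs = ddi_epochs, batch = config@batch,
                          lr = 1e-3, weight_decay = config@weight_decay,
                          dropout = config@dropout, seed = seed + 1009L)
    ddi_report <- ddi_model@report
  }

  per_fold <- list()
  for (f in folds) {
    tr <- foldAssignment(split) != f
    te <- !tr
    fs <- buildFeatureSet(tables, records, tr, config, ddi_model,
                          graph_dims = graph_dims)
    .with_seed(seed * 131L + f, {
      model <- assembleSynergyModel(config, fs$dims)
    })
    model <- trainSynergyModel(model, .subset_features(fs$features, tr),
                               records$score[tr], records$class[tr],
                               seed = seed * 131L + f,
                               epochs = train_epochs)
    pred <- predictSynergy(model, .subset_features(fs$features, te))
    reg <- regressionMetrics(records$score[te], pred$score)
    cls <- classificationMetrics(records$class[te], pred$probs)
    per_fold[[length(per_fold) + 1L]] <- data.frame(
      fold = f, n_test = sum(te), mse = reg$mse, rmse = reg$rmse,
      pearson = reg$pearson, accuracy = cls$accuracy,
      precision = cls$precision, kappa = cls$kappa,
      roc_auc = cls$roc_auc, pr_auc = cls$pr_auc,
      binary_accuracy = cls$binary_accuracy)
  }
  per_fold <- do.call(rbind, per_fold)

  metrics <- c("mse", "rmse", "pearson", "accuracy", "precision", "kappa",
               "roc_auc", "pr_auc", "binary_accuracy")
  reports <- list()
  if (nrow(per_fold) >= 2) {
    for (mname in metrics) {
      v <- per_fold[[mname]]
      if (all(is.finite(v)))
        reports[[mname]] <- foldAggregateCI(v, level = level, metric = mname)
    }
  }

  out <- list(reports = reports, per_fold = per_fold, split = split,
              ddi_report = ddi_report, config = config, scheme = scheme,
              seed = seed)
  if (!is.null(out_dir)) .write_experiment(out, records, out_dir)
  out
}

.config_as_list <- function(config) {
  nm <- slotNames(config)
  out <- lapply(nm, function(s) slot(config, s))
  names(out) <- nm
  out$toggles <- as.list(config@toggles)
  out
}

.write_experiment <- function(res, records, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cbind(sample_id = seq_along(foldAssignment(res$split)),
                         records[, c("drug1", "drug2", "cell")],
                         fold = foldAssignment(res$split),
                         scheme = res$scheme, seed = res$seed),
                   file.path(out_dir, "fold_assignment.csv"), row.names = FALSE)
  utils::write.csv(res$per_fold, file.path(out_dir, "per_fold_metrics.csv"),
                   row.names = FALSE)
  agg <- do.call(rbind, lapply(res$reports, function(r)
    data.frame(metric = r@metric, mean = r@mean, sd = r@sd,
               ci_lo = r@ci[1], ci_hi = r@ci[2])))
  utils::write.csv(agg, file.path(out_dir, "aggregate_metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(.config_as_list(res$config),
                       file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

# ---- checkpoints ----

.pack_params <- function(params) {
  lapply(params, function(p) list(dim = dim(p), values = as.numeric(p)))
}

.unpack_params <- function(packed) {
  lapply(packed, function(p) array(unlist(p$values), dim = unlist(p$dim)))
}

#' Save / load a DDI model checkpoint (single JSON file)
#' @param model a \linkS4class{DDIModel}.
#' @param path JSON file path.
#' @export
saveDDIModel <- function(model, path) {
  jsonlite::write_json(
    list(params = .pack_params(model@params),
         branch_widths = model@branch_widths, post_widths = model@post_widths,
         input_dim = model@input_dim, n_classes = model@n_classes,
         penultimate = model@penultimate, trained = model@trained,
         report = model@report),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveDDIModel
#' @export
loadDDIModel <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("DDIModel", params = .unpack_params(x$params),
      branch_widths = as.integer(x$branch_widths),
      post_widths = as.integer(x$post_widths),
      input_dim = as.integer(x$input_dim), n_classes = as.integer(x$n_classes),
      penultimate = x$penultimate, trained = x$trained,
      report = as.list(x$report))
}
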