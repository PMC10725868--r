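#' @import methods
NULL

#' Labeled molecular graph
#'
#' An undirected graph parsed from a SMILES string: atoms are nodes labeled
#' with element symbols, chemical bonds are edges labeled
#' \code{"single"}, \code{"double"}, \code{"triple"} or \code{"aromatic"}.
#' Hydrogens are implicit and never appear as nodes. Aromatic bonds keep
#' their own label; rings are not kekulized.
#'
#' @slot atoms character vector of element symbols, one per node, in parse
#'   order (node index = position, 1-based).
#' @slot aromatic logical vector flagging aromatic atoms.
#' @slot bonds data.frame with integer columns \code{from}, \code{to}
#'   (\code{from < to}) and character column \code{label}.
#' @exportClass MolecularGraph
setClass("MolecularGraph",
  representation(atoms = "character", aromatic = "logical", bonds = "data.frame"))

setValidity("MolecularGraph", function(object) {
  n <- length(object@atoms)
  b <- object@bonds
  msgs <- character(0)
  if (length(object@aromatic) != n) msgs <- c(msgs, "aromatic flags must match atom count")
  if (any(!nzchar(object@atoms))) msgs <- c(msgs, "atom labels must be non-empty")
  if (nrow(b)) {
    if (!all(c("from", "to", "label") %in% names(b))) {
      msgs <- c(msgs, "bonds need columns from, to, label")
    } else {
      if (any(b$from < 1 | b$to > n)) msgs <- c(msgs, "bond endpoints out of range")
      if (any(b$from == b$to)) msgs <- c(msgs, "self-loop bonds are not allowed")
      if (any(b$from > b$to)) msgs <- c(msgs, "bonds must be stored with from < to")
      if (any(!nzchar(b$label))) msgs <- c(msgs, "bond labels must be non-empty")
      if (anyDuplicated(paste(b$from, b$to))) msgs <- c(msgs, "duplicate bonds")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Per-column tanh normalizer
#'
#' Holds per-column mean and population standard deviation estimated on
#' training rows plus the scale constant \code{c} of the bounded tanh
#' transform \eqn{z = 0.5(\tanh(c (x - \mu)/\sigma) + 1)}. Columns with zero
#' spread store \eqn{\sigma = 1} so the transform stays defined.
#'
#' @slot mu,sigma named numeric vectors of per-column statistics.
#' @slot scale_c numeric scale constant.
#' @slot columns character vector of column names the normalizer was fitted on.
#' @exportClass TanhNormalizer
setClass("TanhNormalizer",
  representation(mu = "numeric", sigma = "numeric", scale_c = "numeric",
                 columns = "character"))

setValidity("TanhNormalizer", function(object) {
  if (length(object@mu) != length(object@columns) ||
      length(object@sigma) != length(object@columns))
    return("mu/sigma length must match columns")
  if (any(object@sigma <= 0)) return("sigma entries must be positive")
  if (length(object@scale_c) != 1 || object@scale_c <= 0)
    return("scale_c must be a single positive number")
  TRUE
})

#' Model hyperparameter configuration
#'
#' Widths of every subnetwork, attention layout, optimizer settings and the
#' ablation toggles of the two-headed synergy network. Defaults are the
#' published global settings; \code{tinyModelConfig()} shrinks every width
#' for CPU-scale tests.
#'
#' @slot drug_widths,cell_widths,ddi_widths,graph_widths,pred_widths integer
#'   vectors of hidden-layer widths.
#' @slot dropout dropout rate applied after all but the last layer of each
#'   fully connected subnetwork.
#' @slot heads number of attention heads.
#' @slot token_dim attention token width; flat feature vectors are reshaped
#'   into \code{length/token_dim} tokens.
#' @slot lr,weight_decay,epochs,batch AdamW settings.
#' @slot loss_w_score,loss_w_class multi-task loss weights.
#' @slot l2_weights,l2_activity regularization coefficients for layer weights
#'   and activations.
#' @slot share_qkv share one projection across query/key/value per head.
#' @slot scale_attention divide attention scores by sqrt(head width).
#' @slot cross_stitch_width width of the dense layers between the two
#'   cross-stitch units.
#' @slot toggles named logical vector of ablation switches:
#'   \code{cross_stitch}, \code{feature_attention},
#'   \code{interaction_attention}, \code{graph_view_I}.
#' @exportClass ModelConfig
setClass("ModelConfig",
  representation(drug_widths = "integer", cell_widths = "integer",
                 ddi_widths = "integer", graph_widths = "integer",
                 pred_widths = "integer", dropout = "numeric",
                 heads = "integer", token_dim = "integer",
                 lr = "numeric", weight_decay = "numeric",
                 epochs = "integer", batch = "integer",
                 loss_w_score = "numeric", loss_w_class = "numeric",
                 l2_weights = "numeric", l2_activity = "numeric",
                 share_qkv = "logical", scale_attention = "logical",
                 cross_stitch_width = "integer", toggles = "logical"))

setValidity("ModelConfig", function(object) {
  msgs <- character(0)
  for (s in c("drug_widths", "cell_widths", "ddi_widths", "graph_widths", "pred_widths"))
    if (any(slot(object, s) <= 0)) msgs <- c(msgs, paste(s, "must be positive"))
  if (object@dropout < 0 || object@dropout >= 1) msgs <- c(msgs, "dropout must be in [0,1)")
  if (object@heads < 1) msgs <- c(msgs, "heads must be >= 1")
  if (object@token_dim < 1) msgs <- c(msgs, "token_dim must be >= 1")
  if (object@token_dim %% object@heads != 0)
    msgs <- c(msgs, "heads must divide token_dim")
  need <- c("cross_stitch", "feature_attention", "interaction_attention", "graph_view_I")
  if (!all(need %in% names(object@toggles)))
    msgs <- c(msgs, "toggles must name cross_stitch, feature_attention, interaction_attention, graph_view_I")
  if (length(msgs)) msgs else TRUE
})

#' Pretrained drug-drug-interaction classifier
#'
#' Two parallel fully connected branches (one per drug descriptor vector)
#' whose outputs are concatenated and passed through a shared stack ending in
#' a K-way softmax over interaction classes. The penultimate activations are
#' reusable as drug-interaction features.
#'
#' @slot params named list of weight/bias arrays.
#' @slot branch_widths,post_widths integer layer widths.
#' @slot input_dim descriptor length expected for each drug.
#' @slot n_classes number of interaction classes.
#' @slot penultimate \code{"post"} (last shared hidden layer) or
#'   \code{"branch"} (concatenated branch outputs).
#' @slot trained logical flag.
#' @slot report list of validation metrics from training.
#' @exportClass DDIModel
setClass("DDIModel",
  representation(params = "list", branch_widths = "integer",
                 post_widths = "integer", input_dim = "integer",
                 n_classes = "integer", penultimate = "character",
                 trained = "logical", report = "list"))

setValidity("DDIModel", function(object) {
  if (!object@penultimate %in% c("post", "branch"))
    return("penultimate must be 'post' or 'branch'")
  if (object@n_classes < 2) return("need at least 2 interaction classes")
  TRUE
})

#' Assembled two-headed synergy network
#'
#' The full multi-task model: per-drug chemical and graph branches, a cell
#' branch modulated by drug-interaction features through attention, per-task
#' attention over the fused representation, a cross-stitch subnetwork, and
#' two prediction heads (synergy score regression; 3-class synergy label).
#'
#' @slot config a \linkS4class{ModelConfig}.
#' @slot params named list of parameter arrays.
#' @slot dims named list of input dimensions (chem, graph, cell, ddi).
#' @slot artifacts list of fitted preprocessing state (normalizers,
#'   vocabularies, label map, DDI model) carried with the checkpoint.
#' @slot trained logical.
#' @slot log data.frame of per-epoch training losses.
#' @exportClass SynergyModel
setClass("SynergyModel",
  representation(config = "ModelConfig", params = "list", dims = "list",
                 artifacts = "list", trained = "logical", log = "data.frame"))

#' Grouped cross-validation assignment
#'
#' Maps every sample to one of five folds so that the scheme's grouping
#' entity (unordered drug pair, cell line, first drug or second drug) never
#' spans folds.
#'
#' @slot scheme one of \code{"pair"}, \code{"cell"}, \code{"drug1"},
#'   \code{"drug2"}.
#' @slot fold integer fold id in 0..4 per sample.
#' @slot groups character grouping key per sample.
#' @slot seed integer seed used for the shuffle.
#' @exportClass FoldSplit
setClass("FoldSplit",
  representation(scheme = "character", fold = "integer",
                 groups = "character", seed = "integer"))

setValidity("FoldSplit", function(object) {
  msgs <- character(0)
  if (!object@scheme %in% c("pair", "cell", "drug1", "drug2"))
    msgs <- c(msgs, "unknown scheme")
  if (length(object@fold) != length(object@groups))
    msgs <- c(msgs, "fold/groups length mismatch")
  if (length(object@fold) && (min(object@fold) < 0 || max(object@fold) > 4))
    msgs <- c(msgs, "folds must lie in 0..4")
  bad <- tapply(object@fold, object@groups, function(f) length(unique(f)) > 1)
  if (any(unlist(bad))) msgs <- c(msgs, "a grouping entity spans folds")
  if (length(msgs)) msgs else TRUE
})

#' Aggregated per-fold metric with confidence interval
#'
#' Mean, sample standard deviation and Student-t confidence interval of a
#' metric across cross-validation folds.
#'
#' @slot metric metric name.
#' @slot values per-fold values.
#' @slot mean,sd aggregate statistics (sd uses n-1).
#' @slot ci numeric length-2 interval \code{c(lo, hi)}.
#' @slot level confidence level.
#' @exportClass MetricReport
setClass("MetricReport",
  representation(metric = "character", values = "numeric", mean = "numeric",
                 sd = "numeric", ci = "numeric", level = "numeric"))

setValidity("MetricReport", function(object) {
  if (length(object@ci) != 2) return("ci must be c(lo, hi)")
  if (object@ci[1] > object@mean || object@ci[2] < object@mean)
    return("ci must bracket the mean")
  if (object@sd < 0) return("sd must be non-negative")
  TRUE
})

#' Seeded synthetic study world
#'
#' A fully reproducible stand-in for the external inputs of a synergy study:
#' a drug table with valid SMILES, a chemical-descriptor matrix with planted
#' non-numeric and zero-variance columns, a gene-expression matrix with a
#' landmark panel of known overlap, a multi-class drug-drug-interaction pair
#' table, and a replicated synergy table whose scores span the antagonistic,
#' additive and synergistic regimes. All tables are synthetic.
#'
#' @slot seed integer seed the world was generated from.
#' @slot params generator parameters actually used.
#' @slot drugs data.frame (drug_id, smiles).
#' @slot descriptors data.frame of raw per-drug descriptors (pre-cleaning).
#' @slot expression numeric matrix, cells x genes.
#' @slot gene_panel character vector of landmark gene ids.
#' @slot ddi data.frame (drug1, drug2, label).
#' @slot synergy data.frame (drug1, drug2, cell, score) with replicates.
#' @slot effects list of the planted ground-truth effects.
#' @exportClass SyntheticWorld
setClass("SyntheticWorld",
  representation(seed = "integer", params = "list", drugs = "data.frame",
                 descriptors = "data.frame", expression = "matrix",
                 gene_panel = "character", ddi = "data.frame",
                 synergy = "data.frame", effects = "list"))
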