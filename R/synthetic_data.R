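# Seeded generators emulating every external input of a synergy study:
# drug SMILES, chemical descriptors, cell-line expression with a landmark
# panel, a multi-class drug-drug-interaction table, and a replicated synergy
# table with planted additive structure. Everything is synthetic and fully
# reproducible from the seed.

# Curated bank of valid drug-like SMILES (parseable by smilesToGraph and by
# standard toolkits). Random SMILES generation is avoided on purpose: it
# risks chemically invalid strings.
.smiles_bank <- c(
  "CCO", "CC(=O)O", "CC(C)O", "CCN(CC)CC", "CCOCC", "CCC(=O)O",
  "CC(=O)C", "OCCO", "OCC(O)CO", "CC(C)(C)O", "CNC", "CC#N",
  "C#C", "C=CC=C", "CCCCCC", "FC(F)F", "BrCCBr", "CSC",
  "CC(N)C(=O)O", "O=C(O)CCC(=O)O", "CC(C)=CCO", "S=C=S",
  "C1CCCCC1", "C1CCNCC1", "C1CCOC1", "O=C1CCCCC1", "OC1CCCCC1",
  "CN1CCCC1", "C1CC1", "C1CCCC1",
  "c1ccccc1", "c1ccncc1", "c1ccsc1", "c1cc[nH]c1", "Cc1ccccc1C",
  "Clc1ccccc1", "COc1ccccc1", "Nc1ccc(N)cc1", "N#Cc1ccccc1",
  "NC(=O)c1ccccc1", "OC(=O)c1ccccc1O", "Cc1ncccc1",
  "c1ccc2ccccc2c1", "c1ccc(cc1)c1ccccc1",
  "CC(=O)Nc1ccc(O)cc1", "CC(=O)Oc1ccccc1C(=O)O",
  "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "CCOC(=O)c1ccccc1",
  "Cn1cnc2c1c(=O)n(C)c(=O)n2C", "CC1=CC(=O)CC(C)(C)C1")

#' The built-in bank of valid SMILES used by the generator
#' @return named character vector of SMILES.
#' @export
smilesBank <- function() {
  structure(.smiles_bank, names = sprintf("bank%02d", seq_along(.smiles_bank)))
}

.zscore <- function(m) {
  mu <- colMeans(m)
  s <- apply(m, 2, stats::sd)
  s[s == 0 | is.na(s)] <- 1
  sweep(sweep(m, 2, mu, "-"), 2, s, "/")
}

.with_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Default generator parameters
#'
#' The study conditions the synthetic world emulates: 20 drugs, 10 cell
#' lines, a 1200-gene expression matrix against a 1000-gene landmark panel
#' overlapping in 875 genes, 6 interaction classes, and 600 unique synergy
#' combinations of which 30 percent carry a replicate measurement. Synergy
#' scores follow mu + a(drug1) + a(drug2) + b(cell) + interaction + noise,
#' placed so the antagonistic (<0), additive ([0,30]) and synergistic (>30)
#' regimes are all populated.
#'
#' @return named list of parameters.
#' @export
defaultWorldParams <- function() {
  list(n_drugs = 20L, n_cells = 10L, n_genes = 1200L,
       n_panel = 1000L, panel_overlap = 875L,
       n_ddi_classes = 6L, n_synergy = 600L, replicate_frac = 0.3,
       score_mu = 15, drug_effect_sd = 8, cell_effect_sd = 8,
       interaction_sd = 10, noise_sd = 5,
       n_descriptors = 30L)
}

#' Generate a synthetic study world
#'
#' @param params list of generator parameters; missing entries fall back to
#'   \code{\link{defaultWorldParams}}.
#' @param seed integer seed; the world is byte-reproducible from it.
#' @return a \linkS4class{SyntheticWorld}.
#' @examples
#' w <- generateWorld(list(n_drugs = 6, n_cells = 5, n_genes = 50,
#'                         n_panel = 40, panel_overlap = 30,
#'                         n_synergy = 40), seed = 1)
#' w
#' @export
generateWorld <- function(params = list(), seed = 0L) {
  p <- utils::modifyList(defaultWorldParams(), params)
  stopifnot(p$n_drugs >= 2, p$n_cells >= 1, p$n_genes >= 1,
            p$panel_overlap <= p$n_panel, p$panel_overlap <= p$n_genes,
            p$n_drugs <= length(.smiles_bank))
  .with_seed(seed, {
    drug_ids <- sprintf("D%02d", seq_len(p$n_drugs))
    smiles <- sample(.smiles_bank, p$n_drugs)
    drugs <- data.frame(drug_id = drug_ids, smiles = smiles,
                        stringsAsFactors = FALSE)

    # descriptors: graph-derived signal + random projections + planted
    # non-numeric and zero-variance columns the cleaner must remove
    graphs <- lapply(smiles, smilesToGraph)
    base <- cbind(
      n_atoms = vapply(graphs, numAtoms, numeric(1)),
      n_bonds = vapply(graphs, function(g) nrow(bondTable(g)), numeric(1)),
      n_arom = vapply(graphs, function(g) sum(bondTable(g)$label == "aromatic"),
                      numeric(1)),
      n_hetero = vapply(graphs, function(g) sum(atomLabels(g) != "C"), numeric(1)))
    proj <- matrix(stats::rnorm(ncol(base) * (p$n_descriptors - ncol(base))),
                   ncol(base))
    num <- cbind(base, .zscore(base) %*% proj +
                   matrix(stats::rnorm(p$n_drugs * ncol(proj), sd = 0.3),
                          p$n_drugs))
    colnames(num) <- sprintf("desc_%03d", seq_len(ncol(num)))
    descriptors <- data.frame(num, check.names = FALSE)
    descriptors$assay_tag <- sample(c("lcms", "nmr"), p$n_drugs, replace = TRUE)
    descriptors$const_feat <- 1
    rownames(descriptors) <- drug_ids

    # expression and landmark panel with planted overlap
    genes <- sprintf("g%04d", seq_len(p$n_genes))
    cells <- sprintf("CL%02d", seq_len(p$n_cells))
    expr <- matrix(stats::rnorm(p$n_cells * p$n_genes), p$n_cells,
                   dimnames = list(cells, genes))
    panel <- c(sample(genes, p$panel_overlap),
               sprintf("x%04d", seq_len(p$n_panel - p$panel_overlap)))
    panel <- sample(panel)

    # DDI pairs: class decided by a linear rule on concatenated descriptors,
    # so the interaction classifier has learnable structure
    pairs <- expand.grid(i = seq_len(p$n_drugs), j = seq_len(p$n_drugs))
    pairs <- pairs[pairs$i != pairs$j, ]
    X <- .zscore(num)
    Wc <- matrix(stats::rnorm(2 * ncol(num) * p$n_ddi_classes, sd = 1),
                 2 * ncol(num))
    sc <- cbind(X[pairs$i, , drop = FALSE], X[pairs$j, , drop = FALSE]) %*% Wc
    ddi <- data.frame(drug1 = drug_ids[pairs$i], drug2 = drug_ids[pairs$j],
                      label = max.col(sc, ties.method = "first") - 1L,
                      stringsAsFactors = FALSE)

    # synergy scores with planted additive structure
    a <- stats::rnorm(p$n_drugs, sd = p$drug_effect_sd)
    names(a) <- drug_ids
    b <- stats::rnorm(p$n_cells, sd = p$cell_effect_sd)
    names(b) <- cells
    gmat <- matrix(stats::rnorm(p$n_drugs^2, sd = p$interaction_sd), p$n_drugs,
                   dimnames = list(drug_ids, drug_ids))
    gmat <- (gmat + t(gmat)) / 2
    all_combo <- expand.grid(i = seq_len(p$n_drugs), j = seq_len(p$n_drugs),
                             k = seq_len(p$n_cells))
    all_combo <- all_combo[all_combo$i < all_combo$j, ]
    take <- all_combo[sample(nrow(all_combo), min(p$n_synergy, nrow(all_combo))), ]
    mu_row <- p$score_mu + a[take$i] + a[take$j] + b[take$k] +
      gmat[cbind(take$i, take$j)]
    rep_extra <- seq_len(floor(nrow(take) * p$replicate_frac))
    idx <- c(seq_len(nrow(take)), rep_extra)
    synergy <- data.frame(
      drug1 = drug_ids[take$i][idx], drug2 = drug_ids[take$j][idx],
      cell = cells[take$k][idx],
      score = mu_row[idx] + stats::rnorm(length(idx), sd = p$noise_sd),
      stringsAsFactors = FALSE)
    synergy <- synergy[sample(nrow(synergy)), ]
    rownames(synergy) <- NULL

    new("SyntheticWorld", seed = as.integer(seed), params = p, drugs = drugs,
        descriptors = descriptors, expression = expr, gene_panel = panel,
        ddi = ddi, synergy = synergy,
        effects = list(mu = p$score_mu, drug = a, cell = b, interaction = gmat))
  })
}

#' Write a synthetic world to disk
#'
#' Emits the file set the readers expect: \code{drugs.csv},
#' \code{descriptors.csv}, \code{expression.csv}, \code{gene_panel.txt},
#' \code{ddi.csv} and \code{synergy.csv}.
#'
#' @param world a \linkS4class{SyntheticWorld}.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of file paths written.
#' @export
writeWorld <- function(world, dir) {
  stopifnot(is(world, "SyntheticWorld"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("drugs.csv", "descriptors.csv", "expression.csv",
                            "gene_panel.txt", "ddi.csv", "synergy.csv"))
  utils::write.csv(world@drugs, paths[1], row.names = FALSE)
  utils::write.csv(cbind(drug_id = rownames(world@descriptors),
                         world@descriptors), paths[2], row.names = FALSE)
  utils::write.csv(cbind(cell_id = rownames(world@expression),
                         as.data.frame(world@expression)), paths[3],
                   row.names = FALSE)
  writeLines(world@gene_panel, paths[4])
  utils::write.csv(world@ddi, paths[5], row.names = FALSE)
  utils::write.csv(world@synergy, paths[6], row.names = FALSE)
  invisible(paths)
}

#' Read the input tables written by \code{\link{writeWorld}}
#'
#' @param dir directory holding the CSV/TXT file set.
#' @return list with \code{drugs}, \code{descriptors}, \code{expression},
#'   \code{gene_panel}, \code{ddi}, \code{synergy}.
#' @export
readWorldTables <- function(dir) {
  desc <- utils::read.csv(file.path(dir, "descriptors.csv"),
                          stringsAsFactors = FALSE, check.names = FALSE)
  rownames(desc) <- desc$drug_id
  desc$drug_id <- NULL
  expr <- utils::read.csv(file.path(dir, "expression.csv"),
                          stringsAsFactors = FALSE, check.names = FALSE)
  rownames(expr) <- expr$cell_id
  expr$cell_id <- NULL
  list(drugs = utils::read.csv(file.path(dir, "drugs.csv"),
                               stringsAsFactors = FALSE),
       descriptors = desc,
       expression = as.matrix(expr),
       gene_panel = readGenePanel(file.path(dir, "gene_panel.txt")),
       ddi = utils::read.csv(file.path(dir, "ddi.csv"),
                             stringsAsFactors = FALSE),
       synergy = utils::read.csv(file.path(dir, "synergy.csv"),
                                 stringsAsFactors = FALSE))
}
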