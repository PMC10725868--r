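#' @describeIn MolecularGraph number of atoms (nodes)
#' @param x a \linkS4class{MolecularGraph}
#' @export
setGeneric("numAtoms", function(x) standardGeneric("numAtoms"))

#' @describeIn MolecularGraph atom element symbols in node order
#' @export
setGeneric("atomLabels", function(x) standardGeneric("atomLabels"))

#' @describeIn MolecularGraph bond table (from, to, label)
#' @export
setGeneric("bondTable", function(x) standardGeneric("bondTable"))

#' @describeIn MetricReport per-fold values
#' @param x a \linkS4class{MetricReport}
#' @export
setGeneric("foldValues", function(x) standardGeneric("foldValues"))

#' @describeIn MetricReport confidence interval endpoints \code{c(lo, hi)}
#' @export
setGeneric("confInt", function(x) standardGeneric("confInt"))

#' @describeIn FoldSplit integer fold ids (0..4), one per sample
#' @param x a \linkS4class{FoldSplit}
#' @export
setGeneric("foldAssignment", function(x) standardGeneric("foldAssignment"))

setMethod("numAtoms", "MolecularGraph", function(x) length(x@atoms))
setMethod("atomLabels", "MolecularGraph", function(x) x@atoms)
setMethod("bondTable", "MolecularGraph", function(x) x@bonds)
setMethod("foldValues", "MetricReport", function(x) x@values)
setMethod("confInt", "MetricReport", function(x) x@ci)
setMethod("foldAssignment", "FoldSplit", function(x) x@fold)

setMethod("show", "MolecularGraph", function(object) {
  cat(sprintf("MolecularGraph: %d atoms, %d bonds\n",
              length(object@atoms), nrow(object@bonds)))
  cat("  atoms:", paste(object@atoms, collapse = " "), "\n")
  if (nrow(object@bonds)) {
    lab <- table(object@bonds$label)
    cat("  bonds:", paste(sprintf("%s=%d", names(lab), lab), collapse = ", "), "\n")
  }
})

setMethod("show", "TanhNormalizer", function(object) {
  cat(sprintf("TanhNormalizer: %d columns, c = %g\n",
              length(object@columns), object@scale_c))
})

setMethod("show", "ModelConfig", function(object) {
  cat("ModelConfig\n")
  cat("  widths: drug", paste(object@drug_widths, collapse = "/"),
      "| cell", paste(object@cell_widths, collapse = "/"),
      "| ddi", paste(object@ddi_widths, collapse = "/"),
      "| graph", paste(object@graph_widths, collapse = "/"),
      "| pred", paste(object@pred_widths, collapse = "/"), "\n")
  cat(sprintf("  attention: %d heads, token_dim %d | dropout %.2g\n",
              object@heads, object@token_dim, object@dropout))
  cat(sprintf("  AdamW: lr %g, weight_decay %g, epochs %d, batch %d\n",
              object@lr, object@weight_decay, object@epochs, object@batch))
  off <- names(object@toggles)[!object@toggles]
  if (length(off)) cat("  ablated:", paste(off, collapse = ", "), "\n")
})

setMethod("show", "DDIModel", function(object) {
  cat(sprintf("DDIModel: %d classes, branches [%s], shared [%s], penultimate = %s, %s\n",
              object@n_classes, paste(object@branch_widths, collapse = ","),
              paste(object@post_widths, collapse = ","), object@penultimate,
              if (object@trained) "trained" else "untrained"))
  if (length(object@report))
    cat(sprintf("  validation accuracy %.3f, kappa %.3f\n",
                object@report$accuracy, object@report$kappa))
})

setMethod("show", "SynergyModel", function(object) {
  cat(sprintf("SynergyModel (%s): %d parameter tensors, %d parameters\n",
              if (object@trained) "trained" else "untrained",
              length(object@params),
              sum(vapply(object@params, length, numeric(1)))))
})

setMethod("show", "FoldSplit", function(object) {
  cat(sprintf("FoldSplit: scheme '%s', %d samples, %d groups, seed %d\n",
              object@scheme, length(object@fold),
              length(unique(object@groups)), object@seed))
  print(table(fold = object@fold))
})

setMethod("show", "MetricReport", function(object) {
  cat(sprintf("%s: %.4f +/- %.4f  [%0.4f, %0.4f] (%d folds, %g%% CI)\n",
              object@metric, object@mean, object@sd,
              object@ci[1], object@ci[2], length(object@values),
              100 * object@level))
})

setMethod("show", "SyntheticWorld", function(object) {
  cat(sprintf(paste0("SyntheticWorld (seed %d): %d drugs, %d cells, %d genes, ",
                     "%d DDI pairs (%d classes), %d synergy rows\n"),
              object@seed, nrow(object@drugs), nrow(object@expression),
              ncol(object@expression), nrow(object@ddi),
              length(unique(object@ddi$label)), nrow(object@synergy)))
})
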