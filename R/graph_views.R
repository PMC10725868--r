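# Four-view molecular-graph embedding. A molecule's graph is summarized by
# (I) the integer codes of its node labels, (II) counts of bond-label
# sequences along simple paths, (III) a histogram of shortest-path lengths
# over node pairs, and (IV) counts of atom-label sequences along simple
# paths. Views are encoded against corpus-level vocabularies into
# fixed-length zero-filled vectors and concatenated.

.graph_as_igraph <- function(graph) {
  b <- graph@bonds
  igraph::graph_from_data_frame(
    d = if (nrow(b)) b[, c("from", "to")] else data.frame(from = integer(0), to = integer(0)),
    directed = FALSE,
    vertices = data.frame(name = seq_along(graph@atoms)))
}

# lexicographic a <= b for equal-length character vectors
.lex_leq <- function(a, b) {
  d <- which(a != b)
  if (!length(d)) TRUE else a[d[1]] < b[d[1]]
}

.canonical_direction <- function(path, labels) {
  fwd <- labels[path]
  rev_ <- rev(fwd)
  if (identical(fwd, rev_)) return(path[1] <= path[length(path)])
  .lex_leq(fwd, rev_)
}

#' Enumerate canonical simple paths of a molecular graph
#'
#' Returns every simple path (no repeated node) with between 1 and
#' \code{max_edges} edges, one representative per undirected path: the
#' traversal direction whose node-label sequence is lexicographically no
#' greater than its reverse, ties broken by the smaller first node index.
#' Output is ordered deterministically by (length, node sequence).
#'
#' Paths are capped at \code{max_edges} edges because unrestricted path sets
#' are unbounded on cyclic graphs; 0-edge self-paths are excluded.
#'
#' @param graph a \linkS4class{MolecularGraph}.
#' @param max_edges maximum number of edges per path (default 6).
#' @return list of integer node-index vectors.
#' @export
enumerateSimplePaths <- function(graph, max_edges = 6L) {
  stopifnot(max_edges >= 1)
  n <- numAtoms(graph)
  if (n < 2 || nrow(graph@bonds) == 0) return(list())
  ig <- .graph_as_igraph(graph)
  out <- list()
  for (v in seq_len(n)) {
    sp <- igraph::all_simple_paths(ig, from = v, cutoff = max_edges)
    for (p in sp) {
      idx <- as.integer(igraph::as_ids(p))
      if (length(idx) >= 2 && .canonical_direction(idx, graph@atoms))
        out[[length(out) + 1L]] <- idx
    }
  }
  key <- vapply(out, function(p)
    sprintf("%02d|%s", length(p), paste(sprintf("%04d", p), collapse = ",")),
    character(1))
  out[order(key)]
}

#' Integer node-label view (view I)
#'
#' Maps each atom label to its integer code from a corpus-level dictionary,
#' in node-index order.
#'
#' @param graph a \linkS4class{MolecularGraph}.
#' @param label_map named integer vector, atom symbol to positive code.
#' @return integer vector, one code per node.
#' @export
viewNodeLabels <- function(graph, label_map) {
  unseen <- setdiff(unique(graph@atoms), names(label_map))
  if (length(unseen))
    stop("atom label(s) not in vocabulary: ", paste(unseen, collapse = ", "))
  as.integer(label_map[graph@atoms])
}

# canonical sequence key: the lexicographically smaller of seq and rev(seq)
.seq_key <- function(x) {
  r <- rev(x)
  if (.lex_leq(x, r)) paste(x, collapse = "|") else paste(r, collapse = "|")
}

.tabulate_keys <- function(keys) {
  if (!length(keys)) return(integer(0))
  tab <- table(keys)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[order(names(counts))]
}

#' Bond-label path counts (view II)
#'
#' Counts, over all canonical simple paths up to \code{max_edges} edges, how
#' often each sequence of bond labels occurs. Keys are orientation-free
#' (a sequence and its reverse share a key, joined by "|").
#'
#' @inheritParams enumerateSimplePaths
#' @return named integer vector of counts.
#' @export
viewBondLabelPaths <- function(graph, max_edges = 6L) {
  paths <- enumerateSimplePaths(graph, max_edges)
  if (!length(paths)) return(integer(0))
  b <- graph@bonds
  blab <- structure(b$label, names = paste(b$from, b$to))
  keys <- vapply(paths, function(p) {
    e <- vapply(seq_len(length(p) - 1L), function(i) {
      blab[[paste(min(p[i], p[i + 1L]), max(p[i], p[i + 1L]))]]
    }, character(1))
    .seq_key(e)
  }, character(1))
  .tabulate_keys(keys)
}

#' Shortest-path-length histogram (view III)
#'
#' For every unordered pair of nodes in the same connected component, the
#' breadth-first shortest-path edge count; returns how many pairs sit at
#' each distance. Self-pairs are excluded.
#'
#' @param graph a \linkS4class{MolecularGraph}.
#' @return named integer vector, names are distances.
#' @export
viewShortestPathLengths <- function(graph) {
  n <- numAtoms(graph)
  if (n < 2) return(integer(0))
  d <- igraph::distances(.graph_as_igraph(graph))
  up <- d[upper.tri(d)]
  up <- up[is.finite(up) & up > 0]
  .tabulate_keys(as.character(as.integer(up)))
}

#' Atom-label path counts (view IV)
#'
#' Counts, over all canonical simple paths up to \code{max_edges} edges, how
#' often each sequence of atom labels (endpoints included) occurs. Keys are
#' orientation-free.
#'
#' @inheritParams enumerateSimplePaths
#' @return named integer vector of counts.
#' @export
viewAtomLabelPaths <- function(graph, max_edges = 6L) {
  paths <- enumerateSimplePaths(graph, max_edges)
  if (!length(paths)) return(integer(0))
  keys <- vapply(paths, function(p) .seq_key(graph@atoms[p]), character(1))
  .tabulate_keys(keys)
}

#' Build a corpus-level view vocabulary
#'
#' Ranks keys by total count across the corpus (descending, ties broken
#' lexicographically) and keeps the first \code{dim}. The key order fixes
#' each key's position in the encoded view vector, so positions are
#' comparable across molecules.
#'
#' @param corpus list of named integer count vectors from one view.
#' @param dim vector length reserved for the view.
#' @param view_id optional view identifier ("II", "III" or "IV").
#' @return list with \code{view_id}, \code{keys} and \code{dim}.
#' @export
buildViewVocab <- function(corpus, dim, view_id = NA_character_) {
  stopifnot(dim >= 1)
  totals <- list()
  for (cnt in corpus) {
    for (k in names(cnt)) {
      totals[[k]] <- (if (is.null(totals[[k]])) 0 else totals[[k]]) + cnt[[k]]
    }
  }
  keys <- names(totals)
  if (is.null(keys) || !length(keys)) {
    return(list(view_id = view_id, keys = character(0), dim = as.integer(dim)))
  }
  tot <- unlist(totals, use.names = FALSE)
  keys <- keys[order(-tot, keys)]
  list(view_id = view_id, keys = utils::head(keys, dim), dim = as.integer(dim))
}

#' Build the corpus-level atom-label dictionary for view I
#'
#' Assigns consecutive positive integer codes to atom symbols in order of
#' first occurrence across the corpus.
#'
#' @param graphs list of \linkS4class{MolecularGraph} objects.
#' @return named integer vector, symbol to code.
#' @export
buildAtomLabelMap <- function(graphs) {
  syms <- unique(unlist(lapply(graphs, atomLabels)))
  structure(seq_along(syms), names = syms)
}

.encode_counts <- function(counts, vocab) {
  v <- numeric(vocab$dim)
  if (length(vocab$keys)) {
    hit <- intersect(vocab$keys, names(counts))
    v[match(hit, vocab$keys)] <- counts[hit]
  }
  v
}

#' Encode a molecule as a fixed-length multi-view vector
#'
#' View I is the node-label code sequence zero-padded or truncated to
#' \code{dims["I"]}; views II-IV place each vocabulary key's count at its
#' vocabulary position (zeros for absent keys; keys outside the vocabulary
#' are dropped). The four segments are concatenated in order I, II, III, IV.
#'
#' @param graph a \linkS4class{MolecularGraph}.
#' @param vocabs list with elements \code{II}, \code{III}, \code{IV} from
#'   \code{\link{buildViewVocab}}.
#' @param label_map atom-symbol dictionary from
#'   \code{\link{buildAtomLabelMap}}.
#' @param dims named numeric vector of per-view lengths
#'   (names \code{I, II, III, IV}).
#' @param max_edges simple-path cap shared by views II and IV.
#' @return list with \code{segments} (per-view numeric vectors) and
#'   \code{vector} (their concatenation).
#' @export
embedGraph <- function(graph, vocabs, label_map,
                       dims = c(I = 64, II = 128, III = 32, IV = 128),
                       max_edges = 6L) {
  stopifnot(all(c("I", "II", "III", "IV") %in% names(dims)), all(dims >= 1))
  codes <- viewNodeLabels(graph, label_map)
  seg1 <- numeric(dims[["I"]])
  keep <- min(length(codes), dims[["I"]])
  if (keep) seg1[seq_len(keep)] <- codes[seq_len(keep)]
  segs <- list(
    I = seg1,
    II = .encode_counts(viewBondLabelPaths(graph, max_edges), vocabs$II),
    III = .encode_counts(viewShortestPathLengths(graph), vocabs$III),
    IV = .encode_counts(viewAtomLabelPaths(graph, max_edges), vocabs$IV))
  list(segments = segs, vector = unlist(segs, use.names = FALSE))
}

#' Featurize a set of drugs by multi-view graph embedding
#'
#' Parses each SMILES, builds the corpus-level atom dictionary and view
#' vocabularies, and embeds every drug. The returned vocabularies and label
#' map are reusable at prediction time so new molecules are encoded into the
#' same positions.
#'
#' @param smiles named character vector (names are drug ids).
#' @param dims per-view vector lengths.
#' @param max_edges simple-path cap.
#' @return list with \code{embeddings} (drugs x features matrix),
#'   \code{vocabs}, \code{label_map}, \code{dims} and \code{max_edges}.
#' @examples
#' fz <- featurizeDrugs(c(d1 = "CCO", d2 = "C1CC1"), dims = c(I = 4, II = 4, III = 3, IV = 4))
#' dim(fz$embeddings)
#' @export
featurizeDrugs <- function(smiles, dims = c(I = 64, II = 128, III = 32, IV = 128),
                           max_edges = 6L) {
  stopifnot(length(smiles) >= 1, !is.null(names(smiles)))
  graphs <- lapply(smiles, smilesToGraph)
  label_map <- buildAtomLabelMap(graphs)
  c2 <- lapply(graphs, viewBondLabelPaths, max_edges = max_edges)
  c3 <- lapply(graphs, viewShortestPathLengths)
  c4 <- lapply(graphs, viewAtomLabelPaths, max_edges = max_edges)
  vocabs <- list(II = buildViewVocab(c2, dims[["II"]], "II"),
                 III = buildViewVocab(c3, dims[["III"]], "III"),
                 IV = buildViewVocab(c4, dims[["IV"]], "IV"))
  emb <- t(vapply(graphs, function(g)
    embedGraph(g, vocabs, label_map, dims, max_edges)$vector,
    numeric(sum(dims))))
  rownames(emb) <- names(smiles)
  colnames(emb) <- unlist(lapply(c("I", "II", "III", "IV"), function(v)
    sprintf("%s_%03d", v, seq_len(dims[[v]]))))
  list(embeddings = emb, vocabs = vocabs, label_map = label_map,
       dims = dims, max_edges = max_edges)
}
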