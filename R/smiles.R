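# SMILES reader for drug-like organic molecules: organic-subset and bracket
# atoms, branches, ring-bond closures (incl. %nn), explicit bond orders and
# aromatic lowercase notation. Hydrogens stay implicit; aromatic bonds keep
# the label "aromatic" (no kekulization). Stereo marks (/ \ @) are accepted
# and ignored; disconnected structures (".") are rejected.

.bond_symbols <- c("-" = "single", "=" = "double", "#" = "triple", ":" = "aromatic")

.parse_smiles <- function(s) {
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  atoms <- character(0)
  arom <- logical(0)
  bonds <- list()
  prev <- NA_integer_
  stack <- integer(0)
  pending <- NA_character_
  rings <- list()

  add_bond <- function(i, j, label) {
    bonds[[length(bonds) + 1L]] <<- list(from = min(i, j), to = max(i, j), label = label)
  }
  implicit <- logical(0)
  add_atom <- function(symbol, aromatic) {
    atoms <<- c(atoms, symbol)
    arom <<- c(arom, aromatic)
    idx <- length(atoms)
    if (!is.na(prev)) {
      lab <- if (!is.na(pending)) pending
             else if (aromatic && arom[prev]) "aromatic" else "single"
      add_bond(prev, idx, lab)
      implicit[length(bonds)] <<- is.na(pending)
    }
    prev <<- idx
    pending <<- NA_character_
    idx
  }
  close_ring <- function(key) {
    if (is.null(rings[[key]])) {
      rings[[key]] <<- list(atom = prev, bond = pending)
      pending <<- NA_character_
    } else {
      open <- rings[[key]]
      rings[[key]] <<- NULL
      labs <- c(open$bond, pending)
      labs <- labs[!is.na(labs)]
      if (length(unique(labs)) > 1) stop("conflicting ring-bond orders for ring ", key)
      lab <- if (length(labs)) labs[1]
             else if (arom[open$atom] && arom[prev]) "aromatic" else "single"
      add_bond(open$atom, prev, lab)
      implicit[length(bonds)] <<- length(labs) == 0
      pending <<- NA_character_
    }
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed bracket atom")
      inner <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(inner, regexec("^[0-9]*([A-Z][a-z]?|[bcnops])", inner))[[1]]
      if (length(m) < 2) stop("cannot read bracket atom [", inner, "]")
      sym <- m[2]
      aromatic <- sym %in% c("b", "c", "n", "o", "p", "s")
      add_atom(if (aromatic) toupper(sym) else sym, aromatic)
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      add_atom(paste0(ch, chars[i + 1L]), FALSE)
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      add_atom(ch, FALSE)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      add_atom(toupper(ch), TRUE)
      i <- i + 1L
    } else if (ch %in% names(.bond_symbols)) {
      pending <- .bond_symbols[[ch]]
      i <- i + 1L
    } else if (ch %in% c("/", "\\")) {
      pending <- "single"
      i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) stop("branch before any atom")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop("unbalanced parenthesis")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("truncated %nn ring closure")
      close_ring(paste0(chars[i + 1L], chars[i + 2L]))
      i <- i + 3L
    } else if (ch == ".") {
      stop("disconnected SMILES are not supported")
    } else {
      stop("unexpected character '", ch, "'")
    }
  }
  if (length(stack)) stop("unbalanced parenthesis")
  open_rings <- names(rings)[!vapply(rings, is.null, logical(1))]
  if (length(open_rings)) stop("unclosed ring bond(s): ", paste(open_rings, collapse = ","))
  if (!length(atoms)) stop("no atoms")
  bdf <- if (length(bonds)) {
    do.call(rbind, lapply(bonds, function(b)
      data.frame(from = b$from, to = b$to, label = b$label,
                 stringsAsFactors = FALSE)))
  } else {
    data.frame(from = integer(0), to = integer(0), label = character(0),
               stringsAsFactors = FALSE)
  }
  # an implicit bond between two aromatic atoms is aromatic only inside a
  # ring; acyclic links between aromatic systems (e.g. the biphenyl bridge)
  # are single bonds
  cand <- which(bdf$label == "aromatic" & implicit[seq_len(nrow(bdf))])
  if (length(cand)) {
    ig <- igraph::graph_from_data_frame(bdf[, c("from", "to")],
                                        directed = FALSE,
                                        vertices = data.frame(name = seq_along(atoms)))
    br <- as.integer(igraph::bridges(ig))
    bdf$label[intersect(cand, br)] <- "single"
  }
  list(atoms = atoms, aromatic = arom, bonds = bdf)
}

#' Parse a SMILES string into a labeled molecular graph
#'
#' Each heavy atom becomes a node labeled with its element symbol (in parse
#' order) and each chemical bond an edge labeled single/double/triple/
#' aromatic. Implicit hydrogens are not materialized.
#'
#' @param smiles a single non-empty SMILES string.
#' @return a \linkS4class{MolecularGraph}.
#' @examples
#' g <- smilesToGraph("CCO")
#' atomLabels(g)   # "C" "C" "O"
#' bondTable(g)
#' @export
smilesToGraph <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || !nzchar(smiles))
    stop("smiles must be a single non-empty string")
  parsed <- tryCatch(.parse_smiles(smiles), error = function(e)
    stop("cannot parse SMILES '", smiles, "': ", conditionMessage(e), call. = FALSE))
  new("MolecularGraph", atoms = parsed$atoms, aromatic = parsed$aromatic,
      bonds = parsed$bonds)
}
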