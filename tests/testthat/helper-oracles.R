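# Independent oracles used across the suite. These re-derive expected
# values from first principles (naive DFS, hand BFS, straight-line
# arithmetic) and must stay independent of the package implementation.

# -- naive exhaustive DFS enumeration of simple paths ------------------------
# Directed simple paths with 1..max_edges edges from every start node, then
# one representative per undirected path: keep the direction whose
# node-label sequence is lexicographically <= its reverse (ties: smaller
# first node index).
oracle_simple_paths <- function(atoms, edge_df, max_edges) {
  n <- length(atoms)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (r in seq_len(nrow(edge_df))) {
    a <- edge_df$from[r]; b <- edge_df$to[r]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  out <- list()
  walk <- function(path) {
    for (nb in adj[[path[length(path)]]]) {
      if (!(nb %in% path)) {
        np <- c(path, nb)
        out[[length(out) + 1L]] <<- np
        if (length(np) <= max_edges) walk(np)   # edges = length - 1
      }
    }
  }
  for (v in seq_len(n)) walk(v)
  lex_leq <- function(a, b) {
    d <- which(a != b)
    if (!length(d)) TRUE else a[d[1]] < b[d[1]]
  }
  keep <- vapply(out, function(p) {
    fwd <- atoms[p]; bwd <- rev(fwd)
    if (identical(fwd, bwd)) p[1] <= p[length(p)] else lex_leq(fwd, bwd)
  }, logical(1))
  out[keep]
}

# orientation-free key of a label sequence
oracle_seq_key <- function(x) {
  lex_leq <- function(a, b) {
    d <- which(a != b)
    if (!length(d)) TRUE else a[d[1]] < b[d[1]]
  }
  r <- rev(x)
  if (lex_leq(x, r)) paste(x, collapse = "|") else paste(r, collapse = "|")
}

oracle_count_table <- function(keys) {
  if (!length(keys)) return(integer(0))
  tab <- table(keys)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[order(names(counts))]
}

oracle_bond_counts <- function(atoms, edge_df, max_edges) {
  paths <- oracle_simple_paths(atoms, edge_df, max_edges)
  lab <- structure(edge_df$label, names = paste(pmin(edge_df$from, edge_df$to),
                                                pmax(edge_df$from, edge_df$to)))
  keys <- vapply(paths, function(p) {
    e <- vapply(seq_len(length(p) - 1L), function(i)
      lab[[paste(min(p[i], p[i + 1L]), max(p[i], p[i + 1L]))]], character(1))
    oracle_seq_key(e)
  }, character(1))
  oracle_count_table(keys)
}

oracle_atom_counts <- function(atoms, edge_df, max_edges) {
  paths <- oracle_simple_paths(atoms, edge_df, max_edges)
  keys <- vapply(paths, function(p) oracle_seq_key(atoms[p]), character(1))
  oracle_count_table(keys)
}

# hand BFS all-pairs shortest path length histogram
oracle_spl_counts <- function(atoms, edge_df) {
  n <- length(atoms)
  if (n < 2) return(integer(0))
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (r in seq_len(nrow(edge_df))) {
    a <- edge_df$from[r]; b <- edge_df$to[r]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  dists <- c()
  for (s in seq_len(n)) {
    d <- rep(NA_integer_, n)
    d[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (nb in adj[[v]]) {
        if (is.na(d[nb])) { d[nb] <- d[v] + 1L; queue <- c(queue, nb) }
      }
    }
    dists <- c(dists, d[seq_len(n) > s & !is.na(d)])
  }
  oracle_count_table(as.character(dists))
}

# random connected labeled graph with <= max_nodes nodes
random_labeled_graph <- function(max_nodes = 8, atom_pool = c("C", "N", "O", "S"),
                                 bond_pool = c("single", "double", "aromatic")) {
  n <- sample(2:max_nodes, 1)
  atoms <- sample(atom_pool, n, replace = TRUE)
  # random spanning tree + a few extra edges
  edges <- data.frame(from = integer(0), to = integer(0), label = character(0),
                      stringsAsFactors = FALSE)
  for (v in 2:n) {
    u <- sample(v - 1, 1)
    edges <- rbind(edges, data.frame(from = min(u, v), to = max(u, v),
                                     label = sample(bond_pool, 1),
                                     stringsAsFactors = FALSE))
  }
  extra <- sample(0:2, 1)
  for (k in seq_len(extra)) {
    uv <- sort(sample(n, 2))
    if (!any(edges$from == uv[1] & edges$to == uv[2])) {
      edges <- rbind(edges, data.frame(from = uv[1], to = uv[2],
                                       label = sample(bond_pool, 1),
                                       stringsAsFactors = FALSE))
    }
  }
  new("MolecularGraph", atoms = atoms, aromatic = rep(FALSE, n), bonds = edges)
}

# apply a node permutation to a MolecularGraph (perm[i] = new index of old i)
permute_graph <- function(graph, perm) {
  atoms <- character(length(perm))
  atoms[perm] <- atomLabels(graph)
  b <- bondTable(graph)
  nf <- perm[b$from]; nt <- perm[b$to]
  nb <- data.frame(from = pmin(nf, nt), to = pmax(nf, nt), label = b$label,
                   stringsAsFactors = FALSE)
  new("MolecularGraph", atoms = atoms,
      aromatic = rep(FALSE, length(perm)), bonds = nb)
}

# a small synthetic world shared by the slower pipeline tests
small_test_world <- function(seed = 7) {
  generateWorld(list(n_drugs = 10L, n_cells = 6L, n_genes = 80L,
                     n_panel = 60L, panel_overlap = 40L,
                     n_synergy = 120L), seed = seed)
}
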