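test_that("SMILES parsing produces the expected labeled graphs", {
  g <- smilesToGraph("CCO")
  expect_equal(atomLabels(g), c("C", "C", "O"))
  b <- bondTable(g)
  expect_equal(nrow(b), 2)
  expect_equal(b$label, c("single", "single"))
  expect_equal(unname(as.matrix(b[, c("from", "to")])),
               matrix(c(1L, 2L, 2L, 3L), 2))

  g1 <- smilesToGraph("C")
  expect_equal(numAtoms(g1), 1)
  expect_equal(nrow(bondTable(g1)), 0)

  tri <- smilesToGraph("C1CC1")
  expect_equal(atomLabels(tri), c("C", "C", "C"))
  expect_equal(nrow(bondTable(tri)), 3)
  expect_true(all(bondTable(tri)$label == "single"))

  pyr <- smilesToGraph("c1ccncc1")
  expect_equal(sort(atomLabels(pyr)), c("C", "C", "C", "C", "C", "N"))
  expect_true(all(bondTable(pyr)$label == "aromatic"))

  expect_error(smilesToGraph("C1CC"), "C1CC")
  expect_error(smilesToGraph(""), "non-empty")
  expect_error(smilesToGraph("CC.O"), "disconnected")
})

test_that("SMILES parser agrees with a reference cheminformatics parser", {
  script <- "
import sys, json
from rdkit import Chem
out = []
for smi in sys.argv[1:]:
    m = Chem.MolFromSmiles(smi)
    out.append({'atoms': [a.GetSymbol() for a in m.GetAtoms()],
                'bonds': sorted((min(b.GetBeginAtomIdx(), b.GetEndAtomIdx()),
                                 max(b.GetBeginAtomIdx(), b.GetEndAtomIdx()),
                                 str(b.GetBondType()).lower()) for b in m.GetBonds())})
print(json.dumps(out))
"
  bank <- smilesBank()
  res <- system2("python", c("-c", shQuote(script), shQuote(bank)),
                 stdout = TRUE, stderr = FALSE)
  ref <- jsonlite::fromJSON(res, simplifyVector = FALSE)
  for (i in seq_along(bank)) {
    g <- smilesToGraph(bank[[i]])
    expect_equal(atomLabels(g), unlist(ref[[i]]$atoms), info = bank[[i]])
    b <- bondTable(g)
    ours <- sort(sprintf("%d,%d,%s", b$from - 1L, b$to - 1L, b$label))
    theirs <- sort(vapply(ref[[i]]$bonds, function(e)
      sprintf("%d,%d,%s", e[[1]], e[[2]], e[[3]]), character(1)))
    expect_equal(ours, theirs, info = bank[[i]])
  }
})

test_that("simple-path enumeration matches the spec examples", {
  g <- smilesToGraph("CCO")
  p <- enumerateSimplePaths(g, 6)
  expect_equal(p, list(c(1L, 2L), c(2L, 3L), c(1L, 2L, 3L)))
  expect_equal(enumerateSimplePaths(smilesToGraph("C"), 6), list())
  tri <- enumerateSimplePaths(smilesToGraph("C1CC1"), 2)
  expect_equal(length(tri), 6)
  expect_equal(sum(lengths(tri) == 2), 3)
  expect_equal(sum(lengths(tri) == 3), 3)
})

test_that("per-view counts match the worked examples", {
  g <- smilesToGraph("CCO")
  expect_equal(viewNodeLabels(g, c(C = 1L, O = 2L)), c(1L, 1L, 2L))
  expect_equal(viewBondLabelPaths(g),
               c(single = 2L, `single|single` = 1L))
  expect_equal(viewShortestPathLengths(g), c(`1` = 2L, `2` = 1L))
  expect_equal(viewAtomLabelPaths(g),
               c(`C|C` = 1L, `C|C|O` = 1L, `C|O` = 1L))

  single <- smilesToGraph("C")
  expect_equal(viewNodeLabels(single, c(C = 1L)), 1L)
  expect_equal(viewBondLabelPaths(single), integer(0))
  expect_equal(viewShortestPathLengths(single), integer(0))
  expect_equal(viewAtomLabelPaths(single), integer(0))

  tri <- smilesToGraph("C1CC1")
  expect_equal(viewNodeLabels(tri, c(C = 1L)), c(1L, 1L, 1L))
  expect_equal(viewBondLabelPaths(tri, 6),
               c(single = 3L, `single|single` = 3L))
  expect_equal(viewShortestPathLengths(tri), c(`1` = 3L))
  expect_equal(viewAtomLabelPaths(tri, 6), c(`C|C` = 3L, `C|C|C` = 3L))

  expect_error(viewNodeLabels(g, c(C = 1L)), "O")
})

test_that("views II-IV equal the exhaustive DFS oracle on random graphs", {
  set.seed(42)
  for (rep in 1:60) {
    g <- random_labeled_graph()
    me <- sample(2:5, 1)
    expect_equal(viewBondLabelPaths(g, me),
                 oracle_bond_counts(atomLabels(g), bondTable(g), me))
    expect_equal(viewAtomLabelPaths(g, me),
                 oracle_atom_counts(atomLabels(g), bondTable(g), me))
    expect_equal(viewShortestPathLengths(g),
                 oracle_spl_counts(atomLabels(g), bondTable(g)))
  }
})

test_that("views II-IV are invariant under node relabeling; view I permutes", {
  set.seed(43)
  for (rep in 1:12) {
    g <- random_labeled_graph()
    n <- numAtoms(g)
    lm <- structure(seq_along(unique(atomLabels(g))),
                    names = unique(atomLabels(g)))
    for (k in 1:20) {
      perm <- sample(n)
      gp <- permute_graph(g, perm)
      expect_equal(viewBondLabelPaths(gp, 4), viewBondLabelPaths(g, 4))
      expect_equal(viewAtomLabelPaths(gp, 4), viewAtomLabelPaths(g, 4))
      expect_equal(viewShortestPathLengths(gp), viewShortestPathLengths(g))
      expect_equal(viewNodeLabels(gp, lm)[perm], viewNodeLabels(g, lm))
    }
  }
})

test_that("raising the path cap never decreases view II/IV counts", {
  set.seed(44)
  for (rep in 1:15) {
    g <- random_labeled_graph()
    lo2 <- viewBondLabelPaths(g, 2)
    hi2 <- viewBondLabelPaths(g, 5)
    expect_true(all(lo2 <= hi2[names(lo2)]))
    lo4 <- viewAtomLabelPaths(g, 2)
    hi4 <- viewAtomLabelPaths(g, 5)
    expect_true(all(lo4 <= hi4[names(lo4)]))
  }
})

test_that("vocabulary ranking is by total count then lexicographic", {
  v <- buildViewVocab(list(c(a = 3L, b = 1L), c(b = 4L)), dim = 2)
  expect_equal(v$keys, c("b", "a"))
  expect_equal(buildViewVocab(list(), dim = 4)$keys, character(0))
  expect_equal(buildViewVocab(list(c(a = 1L, b = 1L)), dim = 1)$keys, "a")
})

test_that("graph encoding fills vocabulary positions and pads with zeros", {
  g <- smilesToGraph("CCO")
  lm <- buildAtomLabelMap(list(g))
  dims <- c(I = 5, II = 4, III = 3, IV = 4)
  vocabs <- list(
    II = buildViewVocab(list(viewBondLabelPaths(g)), dims["II"], "II"),
    III = buildViewVocab(list(viewShortestPathLengths(g)), dims["III"], "III"),
    IV = buildViewVocab(list(viewAtomLabelPaths(g)), dims["IV"], "IV"))
  emb <- embedGraph(g, vocabs, lm, dims)
  expect_equal(length(emb$vector), sum(dims))
  expect_equal(emb$segments$I, c(1, 1, 2, 0, 0))
  expect_equal(emb$segments$III, c(2, 1, 0))
  expect_true(all(emb$vector >= 0))

  # sum of encoded view-II entries equals total path count when the
  # vocabulary covers all observed keys
  expect_equal(sum(emb$segments$II), sum(viewBondLabelPaths(g)))

  single <- smilesToGraph("C")
  e1 <- embedGraph(single, vocabs, lm, dims)
  expect_equal(e1$segments$I, c(1, 0, 0, 0, 0))
  expect_true(all(unlist(e1$segments[c("II", "III", "IV")]) == 0))
})

test_that("isomorphic molecules share their view II-IV encodings", {
  set.seed(45)
  g <- smilesToGraph("CC(=O)Nc1ccc(O)cc1")
  perm <- sample(numAtoms(g))
  ar <- g@aromatic
  gp <- permute_graph(g, perm)
  gp@aromatic[perm] <- ar
  lm <- buildAtomLabelMap(list(g))
  dims <- c(I = 16, II = 16, III = 8, IV = 16)
  vocabs <- list(
    II = buildViewVocab(list(viewBondLabelPaths(g)), dims["II"], "II"),
    III = buildViewVocab(list(viewShortestPathLengths(g)), dims["III"], "III"),
    IV = buildViewVocab(list(viewAtomLabelPaths(g)), dims["IV"], "IV"))
  e1 <- embedGraph(g, vocabs, lm, dims)
  e2 <- embedGraph(gp, vocabs, lm, dims)
  for (v in c("II", "III", "IV"))
    expect_equal(e1$segments[[v]], e2$segments[[v]])
})

test_that("featurizeDrugs yields one fixed-length row per drug", {
  fz <- featurizeDrugs(c(d1 = "CCO", d2 = "C1CC1", d3 = "c1ccccc1"),
                       dims = c(I = 8, II = 8, III = 4, IV = 8))
  expect_equal(dim(fz$embeddings), c(3L, 28L))
  expect_equal(rownames(fz$embeddings), c("d1", "d2", "d3"))
  expect_true(all(c("C", "O") %in% names(fz$label_map)))
})
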