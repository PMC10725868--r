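---
title: "Multi-task synergy prediction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task synergy prediction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comboSyn)
```

## The problem

High-throughput screens measure how strongly two drugs help or hinder each
other on a cancer cell line, summarized as a Loewe-additivity score:
positive values mean the pair kills cells beyond what dose additivity
predicts, negative values mean antagonism. `comboSyn` predicts both the
continuous score and a discrete synergy call for unseen (drug, drug, cell)
triples with one two-headed network trained on both tasks at once, so that
what the regression head learns about the dose-response surface transfers
to the classifier and vice versa.

## Feature construction

**Chemical descriptors.** Each drug arrives as a vector of precomputed
molecular descriptors. `cleanDescriptors()` drops every column containing a
non-numeric or missing entry and every column with exactly zero population
variance; both filters mirror how descriptor arrays are routinely pruned
before modeling. Cleaning requires at least two rows, because variance is
undefined on one.

**Multi-view graph embedding.** A SMILES string becomes a labeled graph
(atoms are nodes, bonds are edges labeled single/double/triple/aromatic;
hydrogens stay implicit, aromatic systems are not kekulized). Four
complementary summaries are encoded into fixed-length, zero-filled vectors
and concatenated:

* **View I** - the sequence of integer codes of the node labels, padded or
  truncated to its reserved length. Codes come from a corpus-level
  dictionary in first-occurrence order starting at 1, so the same element
  always maps to the same code across molecules.
* **View II** - counts of bond-label sequences along simple paths.
* **View III** - a histogram of breadth-first shortest-path lengths over
  unordered node pairs (self-pairs excluded).
* **View IV** - counts of atom-label sequences along simple paths.

"All paths" is unbounded on cyclic graphs, so views II and IV enumerate
*simple* paths (no repeated node) with at most `max_edges` edges (default
6); the cap is shared with the brute-force enumerator the tests compare
against. Each undirected path is counted once: the canonical traversal is
the direction whose node-label sequence is lexicographically no greater
than its reverse, with ties broken by the smaller first node index, and
path keys are additionally orientation-free (a label sequence and its
reverse share one key), which makes all three counting views invariant
under graph isomorphism. Zero-edge self-paths are excluded: after SMILES
parsing a molecular graph has no self-loop edges, so there is nothing for a
"loop" to traverse. Key-to-position rules are corpus-level vocabularies
ranked by total count (descending, ties lexicographic), so a vector
position means the same path pattern for every molecule; keys outside the
vocabulary are dropped.

The SMILES reader covers the organic subset, bracket atoms, branches, ring
closures (including `%nn`) and aromatic lowercase notation. One subtlety:
an implicit bond between two aromatic atoms is aromatic only inside a ring;
if the bond is a bridge of the molecular graph (as in biphenyl) it is a
single bond. The test suite cross-checks every banked molecule against a
reference cheminformatics parser.

**Cell lines.** Expression vectors are reduced to the genes shared with a
landmark panel (in panel order); the synthetic default plants the
875-of-1000 overlap typical of landmark panels against genome-wide arrays.

**Bounded normalization.** Every feature family passes through
`z = 0.5 * (tanh(c * (x - mu) / sigma) + 1)` with per-column mean and
population standard deviation estimated on training rows only
(`sigma = 1` where a column is constant), mapping features into (0, 1).
The scale constant `c` is configurable: the normalizer's own default is the
classical tanh-estimator value `c = 0.01`, while the experiment pipeline
uses `c = 1`. The reason is numeric, not statistical: with `c = 0.01` a
standardized feature in (-3, 3) lands in (0.485, 0.515) - a dynamic range
of about 0.03 - and a rectifier network initialized for unit-scale inputs
then needs thousands of epochs just to amplify its inputs. `c = 1`
preserves the bounded contract and the monotone shape while keeping
unit-scale variation. Where tanh saturates in floating point the output is
clamped to the largest representable values inside the open interval.

## Network blocks

**Multi-head attention with residual concatenation.** Flat feature vectors
are reshaped into `length / token_dim` tokens (`token_dim` 16 by default;
the attention over a single token is degenerate, so the layout matters).
Per head, query, key and value tokens pass through separate rectified dense
projections of width `token_dim / heads`; scores are plain dot products
(no `1/sqrt(d)` scaling by default - a flag enables it), softmax runs over
key tokens per query token, and the weighted value sums from all heads are
concatenated so the attended vector matches the query length. The block
returns `concat(attended, query input)` - twice the query length - which
both preserves the raw signal and stabilizes training. A `share_qkv` flag
collapses the three projections into one, the literal reading of a shared
projection weight; separate projections are the default because they strictly
generalize the shared form.

**Cross-stitch subnetwork.** Two task vectors are mixed elementwise by a
learned 2x2 matrix, passed through per-task rectified dense layers, mixed
by a second 2x2 unit, and each result is concatenated with that task's
original input. Mixing entries start near identity (diagonal 0.9,
off-diagonal 0.1), the standard initialization for cross-stitch networks:
tasks begin mostly independent and learn how much to share.

**Fully connected subnetworks.** Dense stacks with a rectifier after every
layer, dropout (default rate 0.2) after all but the last layer, and L2
penalties on both weights (1e-4) and activations (1e-5) accumulated into
the training loss. Dropout is inert at evaluation, making prediction a
deterministic pure function of inputs and parameters.

All blocks run on a small reverse-mode automatic-differentiation tape
written in base R; gradients of every operation are verified against
central finite differences in the test suite, and training uses AdamW
(decoupled weight decay).

## The assembled model

Per drug, `drugFeat = concat(FC_chem(descriptors), FC_graph(embedding))`,
with branch parameters shared between the two drugs of a pair - consistent
with the reversed-pair augmentation, which teaches the model symmetry
instead of hard-coding it. The cell branch is
`attention(query = FC_cell(expression), key = value = FC_ddi(ddiFeat))`,
where `ddiFeat` are penultimate-layer activations of a separately
pretrained drug-drug-interaction classifier (two parallel descriptor
branches, concatenated, then a shared stack ending in a K-way softmax;
which layer counts as "penultimate" is configurable between the shared
stack, the default, and the concatenated branch outputs). The fused vector
`concat(drugFeat1, drugFeat2, cell')` feeds one attention block per task;
the two task vectors pass through the cross-stitch subnetwork; the first
output drives the regression head, the second the 3-class head (fixed by
convention, exposed in the code). Each head is a dense stack topped by a
linear layer (1 output; 3 logits).

Default widths follow the published global settings - drugs
[1024, 512, 256], cell [512, 256, 128], interaction [1024, 512, 256], graph
[258, 128], prediction [128, 64], 4 heads, AdamW with learning rate 1e-5,
weight decay 0.025, 1000 epochs, batch 64. `tinyModelConfig()` keeps the
architecture and shrinks every width (with a learning rate of 1e-3 and 200
epochs) so a model trains in minutes on one CPU; it is the configuration
used throughout the tests and the acceptance script.

The training loss is `w_score * MSE + w_class * cross-entropy` plus the
regularization penalties, with both weights defaulting to 1 (an unweighted
sum; nothing in the source material fixes them, so they are configuration).
Internally the regression target is standardized with training-set mean and
standard deviation and predictions are mapped back to the Loewe scale;
this keeps both task losses at comparable magnitude and is recorded in the
checkpoint. Additive-class rows stay in the 3-class training signal but are
excluded from the binary (synergistic vs antagonistic) evaluation metrics.

**Ablation toggles.** Four switches reproduce the architecture variants
used to justify each component: `cross_stitch = FALSE` wires the task
vectors straight into the heads; `feature_attention = FALSE` replaces the
per-task attention with plain rectified dense layers; `interaction_attention
= FALSE` removes the DDI branch and the cell attention entirely (cell
features pass through unchanged); `graph_view_I = FALSE` drops the view-I
segment from the graph embedding. Each toggle changes the parameter set
exactly as described, which the tests assert.

## Dataset rules and cross-validation

Replicated measurements of one (unordered drug pair, cell) combination are
averaged. Scores above 30 are labeled synergistic, below 0 antagonistic,
and the closed interval [0, 30] additive - the boundary values land in the
additive class, since the defining inequalities for the outer classes are
strict. The labeled table is then doubled with drug-swapped twins (guarded
against double application by a provenance column).

Four grouped five-fold schemes are provided: leave-pair-out,
leave-cell-out, leave-first-drug-out and leave-second-drug-out. Grouping
entities are shuffled with the given seed and dealt round-robin, so fold
sizes differ by at most one entity and no entity ever spans folds. Under
the pair scheme a record and its reversed twin share the unordered-pair key
and therefore always share a fold - reversal augmentation cannot leak a
pair across the train/test boundary regardless of whether augmentation or
splitting happens first. The drug1/drug2 schemes group by the column as
given post-augmentation, which is the order-sensitive reading of "unique
first drugs".

Per fold, every fitted statistic - descriptor, expression, graph and
interaction-feature normalizers, and the view vocabularies - is computed on
training rows only. Two fitted objects are deliberately corpus-level rather
than per-fold: the descriptor column filters and the atom-label dictionary.
Both are structural properties of the known drug universe (which columns
are numeric; which elements occur), not statistics of the outcome, and
fitting them per fold would only create spurious unseen-symbol failures.

## Evaluation

Regression: MSE, RMSE and Pearson correlation (flagged undefined when
either side is constant). Classification: accuracy and Cohen's kappa on
3-class argmax labels, precision for the synergistic class, and ROC-AUC
(trapezoidal rule) plus PR-AUC (average-precision step interpolation)
computed from P(synergistic) on the subset whose true class is synergistic
or antagonistic. Which subset published accuracy/kappa figures use is not
stated in the source material; the all-samples choice here is documented
rather than asserted. Per-fold values are aggregated as mean, sample
standard deviation and a Student-t interval
`mean +/- t((1+level)/2, n-1) * sd / sqrt(n)`. The t-based form (rather
than a normal quantile) is used because it exactly regenerates the
published five-fold interval endpoints from their printed mean and standard
deviation, which the acceptance checks recompute.

## The synthetic world

`generateWorld()` emulates every external input so the whole pipeline runs
with no downloads: a drug table drawn from a curated bank of ~50 valid
drug-like SMILES (random SMILES generation is avoided because it risks
invalid chemistry); a descriptor matrix built from graph statistics plus
noisy random projections, with a planted text column and a constant column
for the cleaner to remove; an expression matrix with a landmark panel of
known overlap (875 of 1000 by default); an interaction-pair table whose
class is a linear rule on the concatenated descriptors, so the DDI
classifier has learnable structure; and a synergy table generated as
`mu + a(drug1) + a(drug2) + b(cell) + interaction(drug1, drug2) + noise`.

Default conditions: 20 drugs, 10 cell lines, 1200 genes, 6 interaction
classes, 600 unique synergy combinations of which 30% carry a replicate.
Effect scales (`mu = 15`, drug and cell effects with sd 8, a symmetric
interaction with sd 10, measurement noise with sd 5) were chosen once so
that the combined score distribution populates all three label regimes at
roughly screen-like proportions (about one fifth antagonistic and one
fifth synergistic) while leaving most variance explainable from drug and
cell identity. With noise and interaction switched off the scores are
exactly additive, and the tests verify that an ordinary least-squares
oracle recovers them to numerical precision.

What the world does *not* emulate: real dose-response surfaces, any
correlation between expression and drug response beyond cell identity,
chemically meaningful descriptor-activity relationships, or class imbalance
as extreme as real screens. Passing the learnability checks therefore
demonstrates that the implementation can extract planted signal through
the full feature-model-evaluation chain - not that the architecture would
match published performance on real screens, which would require the
original data and full-scale training.

## Problem sizes and numerical choices

The test suite and the acceptance script run the tiny configuration: the
learnability check trains one leave-pair-out fold for 200 epochs on the
default 600-combination world; the acceptance script trains all five folds
for 150 epochs with batch 64. These sizes are the package's CPU-scale
choices and are stated here so results are interpreted at that scale.
Further numerics: softmax rows are computed with max-subtraction;
cross-entropy uses the log-sum-exp form; He initialization everywhere;
AdamW bias correction enabled; training batches are shuffled with the run
seed and a fixed seed makes runs bit-reproducible (asserted in the tests).
Degenerate inputs - empty graphs, single-token attention, constant
predictions, single-class truth - are either defined results (empty counts,
weight 1) or flagged NA values rather than silent numbers.

## Known limitations

* Training is pure R; it is fast enough for the bundled study sizes but not
  for thousand-epoch runs at the published widths.
* The SMILES reader targets the curated bank's feature set; exotic notation
  (isotopes with charge brackets beyond element extraction, stereo bonds as
  anything but single bonds) is accepted but simplified.
* Attention requires `token_dim` to divide every attended vector length;
  configurations violating this fail fast at assembly with the offending
  junction named.
* With a single key token the attention weights are identically 1 and the
  query/key projections receive no gradient; this is a property of softmax
  attention, and configurations with at least two key tokens avoid it.
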