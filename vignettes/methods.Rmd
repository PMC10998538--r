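---
title: "Predicting piRNA-disease associations: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting piRNA-disease associations: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pdaLink)
```

## The problem

Piwi-interacting RNAs (piRNAs) are 24–35 nt small non-coding RNAs whose
aberrant expression is implicated in cancers and neurodegenerative disease.
Experimentally validated piRNA–disease associations (PDAs) are scarce: the
curated association matrices this method targets are 5–8% dense, and the
unlabelled pairs are not verified negatives — they are simply unexplored.
`pdaLink` treats PDA discovery as positive-unlabelled bipartite link
prediction: score every (piRNA, disease) pair, learning from known
positives and from *reliable negatives* distilled out of the unlabelled
set.

## The model

**Similarity networks.** Let $A \in \{0,1\}^{m \times n}$ be the adjacency
of known associations. piRNA similarity $S_p$ is the mean of (i) normalised
Smith–Waterman local-alignment similarity
$\mathrm{SW}(i,j)/\sqrt{\mathrm{SW}(i,i)\,\mathrm{SW}(j,j)}$ and (ii) the
Gaussian interaction-profile (GIP) kernel
$\exp(-\lambda_p \lVert A_{i\cdot} - A_{j\cdot}\rVert^2)$ with
data-adaptive bandwidth $\lambda_p = 1/\overline{\lVert A_{k\cdot}\rVert^2}$.
Disease similarity $S_d$ is the mean of the GIP kernel on columns of $A$
and a Wang-style ontology semantic similarity: each disease contributes 1
to itself and each ancestor term the decayed maximum
$\theta \cdot$ (best child contribution), $\theta = 0.5$; two diseases are
similar in proportion to the contributions of their shared ancestors.

**Heterogeneous graph convolution.** The blocks assemble into
$A_h = \begin{bmatrix} S_p & A \\ A^\top & S_d \end{bmatrix}$, and node
features propagate through
$H^{l+1} = \mathrm{ReLU}(D^{-1/2} A_h D^{-1/2} H^l W^l)$ for two layers.
$D$ is the degree matrix of $A_h$; because the similarity blocks have unit
diagonals, every node has positive degree and no extra self-loops are
needed. Initial disease features are the rows of $S_d$; initial piRNA
features come from the sequence encoder below, linearly projected to the
same width.

**Sequence encoder.** Each sequence is tokenized into overlapping 3-mers
(`ATTGCAT` → `ATT, TTG, TGC, GCA, CAT`); 3-mers are embedded by a
skip-gram model with negative sampling trained on the whole corpus (each
sequence is a sentence); the token-vector matrix is then encoded by a
convolutional text encoder with kernel sizes 1, 3 and 5 (128 filters each),
ReLU, global max pooling and a linear projection to the 128-dimensional
piRNA embedding. Unlike bag-of-k-mer counts this retains positional
information — reversing a non-palindromic sequence changes its feature.

**Cross-attention decoder.** The final GCN embeddings split into piRNA
rows $H_p$ and disease rows $H_d$. A two-head scaled dot-product attention
encoder attends piRNA queries over disease keys/values (and the mirror
image for diseases), followed by a residual addition and row-wise layer
normalisation. The association score is the inner product of the encoded
piRNA and disease vectors; a logistic map turns scores into probabilities.
The whole stack — text encoder included — is trained end-to-end with
binary cross-entropy and Adam.

**Reliable negatives.** Three selectors operate on pair features
$[S_p(i,\cdot)\,\Vert\,S_d(j,\cdot)]$ with 500-tree random forests:

* *Spy*: hide 5% of the positives among the unlabelled pairs, train
  positives-vs-rest, and keep the unlabelled pairs whose posterior falls
  below the weakest spy.
* *PU bagging*: 30 bootstrap classifiers per round (positives vs an
  equally-sized unlabelled draw), out-of-bag scores averaged over 5
  rounds; the averaged scores are split into three clusters and the middle
  cluster is returned.
* *Two-step*: starting from "all unlabelled pairs are negative", iterate
  five times, promoting pairs that outscore every current positive and
  confirming pairs that score below every current positive; the confirmed
  negatives are returned.

The combined selector is the union of the three.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `kmer_k` | 3 | token length for sequence tokenization |
| `word_dim` | 64 | skip-gram vector dimension |
| `embed_dim` | 128 | piRNA embedding / GCN / attention width |
| `n_heads` | 2 | attention heads (must divide `embed_dim`) |
| `gcn_layers` | 2 | graph-convolution depth |
| `theta` | 0.5 | semantic-similarity decay per ontology level |
| `sw_match/mismatch/gap` | +2 / −1 / −1 | alignment scoring (normalisation makes self-similarity 1 for any positive match) |
| `spy_frac` | 0.05 | fraction of positives planted as spies |
| `rf_estimators` | 500 | trees per random forest |
| `n_bags`, `bag_rounds` | 30, 5 | PU-bagging bootstraps per round, rounds |
| `two_step_iters` | 5 | two-step relabelling iterations |
| `lr`, `epochs` | 1e-3, 200 | Adam step size and training epochs |
| `report_window` | 5 | final epochs averaged when reporting CV metrics |

All are collected in `run_config()` and validated there.

## Evaluation protocol

Positives and unlabelled pairs are each shuffled and split into five folds.
Within a fold, the test positives are zeroed out of the adjacency and
*everything* downstream — both GIP kernels, the fused similarities, the
initial embeddings, reliable-negative selection and the training loss — is
recomputed from that masked adjacency, so no test information reaches
training (this is asserted by recomputation in the test suite). Test pairs
are the held-out positives (label 1) and held-out unlabelled pairs
(label 0). Metrics: ROC AUC (rank statistic), area under the
precision–recall curve (step integration over distinct thresholds, robust
to the extreme class imbalance), and the rank index — the mean normalised
rank of the test positives among all test pairs (lower is better; a random
ranking concentrates near 0.5). Per-fold metrics are averaged over the
final five training epochs, mirroring common reporting practice for
full-batch training, and summarised as mean and variance across folds.

## What the synthetic generator emulates — and what it does not

`gen_study()` produces random 24–35 nt sequences, a random rooted disease
DAG (every non-root term has 1–2 parents among earlier terms), and a
planted low-rank association structure: non-negative factors $U, V$ give
scores $UV^\top$ plus Gaussian noise, the top $q\,mn$ pairs are true
associations, and only a fraction (`reveal`, default 0.7) is observed. The
unrevealed associations are *hidden positives* inside the unlabelled set —
exactly the situation positive-unlabelled learning is meant to handle, and
the basis for measuring whether selectors avoid them. Defaults
($m=200$, $n=15$, $q=0.08$) reproduce the sparsity regime of the curated
benchmark datasets at a size where the full pipeline runs in about two
minutes per replicate on one CPU; the acceptance experiment uses five
replicates (seeds 0–4), where the mean held-out AUC is above 0.9 and the
combined selector picks hidden positives at under half the rate at which
it picks true negatives.

The generator does **not** emulate real piRNA sequence composition (no
repeat structure, no strand or expression biases), real Disease Ontology
topology (which is far deeper), or the long-tailed degree distributions of
curated databases. Passing the recovery experiment therefore shows the
machinery is sound and the signal path works end-to-end; it does not
certify benchmark-level performance on curated data.

## Numerical and design choices

* **Ordering.** Rows/columns are ordered lexicographically by id at
  dataset construction, making repeated loads and seeded runs
  bit-identical.
* **Alignment backend.** Local alignment is delegated to
  `Biostrings::pairwiseAlignment`; scores are clamped at zero (the local
  alignment optimum is never negative by definition). Scoring parameters
  are exposed because no single convention dominates for short DNA reads.
* **Degenerate inputs.** An all-zero profile matrix makes the GIP
  bandwidth undefined and errors; diseases absent from the ontology fall
  back to a delta similarity row with a warning; fewer than three distinct
  bagging scores trigger a flagged lowest-tertile fallback in place of the
  three-cluster split; unlabelled pairs never out-of-bag get the mean
  score, with a warning.
* **Two-step output.** The selector returns the pairs *explicitly
  confirmed* negative (below every current-positive score at the last
  iteration), with posteriors taken from out-of-bag predictions. Returning
  everything still labelled negative would return essentially the whole
  unlabelled set — resubstitution posteriors of forest training points
  saturate at their labels, so no pair can outscore a training positive —
  and the selector would add nothing over "no selection". Out-of-bag
  posteriors restore a meaningful positive score range.
* **Attention dimensioning.** Per-head query/key/value projections are
  stored as column blocks of full `d x d` matrices; the output projection
  follows the concatenation. Residuals are added before layer
  normalisation (post-norm), layer-norm epsilon is `1e-5`.
* **Training.** Loss, optimiser and schedule are not prescribed by the
  architecture, so the package uses logit-stable binary cross-entropy,
  full-batch Adam at `1e-3` for 200 epochs. The ReLU after the final GCN
  layer is kept by default and controllable (`final_relu`).
* **Initial feature reconciliation.** Disease initial features are the
  $n$-dimensional rows of $S_d$; the 128-dimensional sequence features are
  linearly projected to that width so the two blocks share one feature
  space.
* **Word2vec determinism.** Skip-gram training is single-threaded with a
  fixed seed, full-window contexts and a linearly decayed learning rate;
  with a 64-word vocabulary this costs seconds and is bit-reproducible.

## Known limitations

* The model is transductive: scores exist only for the piRNAs and diseases
  present in the training graph.
* Graph convolution over a dense similarity graph smooths near-identical
  piRNAs onto near-identical embeddings; conflicting labels between such
  twins cannot be fitted exactly (training AUC plateaus slightly below 1
  even on consistent plantings). This is a property of the architecture,
  shared with every GCN-over-similarity-graph method.
* Two of the three PU selectors score training points; despite the
  out-of-bag correction their thresholds are noisy for very small positive
  sets (fewer than ~20 positives leaves a single spy).
* Disease-name-to-ontology mapping is the caller's responsibility; terms
  that cannot be mapped only contribute interaction-profile similarity.
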