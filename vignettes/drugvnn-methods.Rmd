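---
title: "DrugVNN: model, training objective and interpretation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DrugVNN: model, training objective and interpretation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DrugVNN)
```

## The problem

Pharmacogenomic screens measure, for many cancer cell lines and many
compounds, the area under the normalized dose-response curve (AUC): 0 means
complete cell killing, 1 means no drug effect. DrugVNN predicts the AUC of a
(cell line, drug) pair from the cell line's multi-omic genotype and the
drug's chemical structure, with a network whose internal units are, by
construction, nameable biological subsystems — so a fitted model can be
interrogated about *which* subsystem drove a prediction, not only *what* it
predicted.

## Model

**Genotype branch (visible neural network).** A biological-process hierarchy
— a rooted DAG of subsystem terms with direct gene annotations — is compiled
into the network skeleton (`loadOntology()`, `layerArchitecture()`). Every
term $t$ becomes a block of $k(t)$ neurons whose input vector $V_i(t)$
concatenates the activation blocks of its child terms with the fused values
of its directly annotated genes, and whose state is

$$O_i(t) = \mathrm{BatchNorm}\big(\tanh(W(t)\, V_i(t) + b(t))\big).$$

Batch normalization is applied after the nonlinearity, following the block
formula literally; it uses batch statistics during training (falling back to
the stored running statistics for single-row batches, whose variance is
undefined) and running statistics at evaluation. Because a term receives
input only from its children and its own genes, a term's state is *exactly*
invariant to genes outside its descendant closure — this structural sparsity
is what makes the network "visible", and the test suite verifies it by
finite differences on random hierarchies. Multi-parent terms feed every
parent (fan-out duplication); child blocks are concatenated in lexicographic
term order and genes in gene-index order, so evaluation is reproducible and
invariant to the particular topological order used.

Each term also carries an auxiliary linear head mapping $O_i(t)$ to a scalar
response estimate; these heads provide per-subsystem supervision during
training and are reused by the interpretation machinery.

**Genotype encoding.** Three channels — binary mutation calls, expression
and copy number — are aligned to a common gene index, imputed per gene with
the cohort mean (`imputeMissing()`), min-max normalized per gene to $[0,1]$
(`minmaxNormalize()`; constant genes map to 0 to stay in range without NaN),
optionally Gray-encoded for the mutation word (`grayEncode()`; off by
default since with one bit per gene the reflected transform mostly mixes
neighboring genes), and fused. The default fusion is the element-wise mean
("superposition without changing dimensions"); a `stack` mode keeps the
three channels side by side, giving each gene an input width of 3. An
entirely missing channel (a cohort lacking, say, copy number) is substituted
by the element-wise mean of the available channels, with a loud message.

**Drug branch.** Drug structures given as SMILES are encoded as 2048-bit
folded circular (Morgan-style) fingerprints of radius 2
(`morganFingerprint()`): atoms start from hashed invariant tuples (atomic
number, heavy degree, implicit hydrogens, charge, ring membership) and are
iteratively re-hashed with their neighbors' identifiers; all identifiers are
folded modulo the bit length. SMILES parsing, kekulization and ring
perception are delegated to ChemmineR/OpenBabel; the hashing is this
package's own and deterministic, so bit positions are comparable within
DrugVNN but, as for any folded fingerprint, not across toolkits. The
fingerprint feeds a conventional three-layer network (affine, tanh, batch
norm per layer; default widths 100-50-6) whose last layer is the drug
embedding.

**Fusion head.** The root term's state (the genotype embedding) and the
drug embedding are concatenated and passed through one tanh+BN hidden layer
(width 6) and a final linear unit to give the predicted AUC. Predictions
are not clipped to $[0,1]$; out-of-range values are reported as they are.

## Training objective

With $N$ pairs in a batch, root $r$, auxiliary predictions
$\hat y_i(t)$ and final predictions $\hat y_i$:

$$\mathcal{L} = \frac1N \sum_i (\hat y_i - y_i)^2
  \;+\; \alpha \sum_{t \ne r} \frac1N \sum_i (\hat y_i(t) - y_i)^2
  \;+\; \lambda \sum_t \lVert W(t) \rVert_2^2.$$

The fusion head is the root predictor; auxiliary heads supervise the other
subsystems ($\alpha = 0.3$ by default — the auxiliary weight is not pinned
down by the protocol, and 0.3 keeps the auxiliary sum, over tens of terms,
from drowning the main term). The L2 penalty covers all subsystem weight
matrices; its factor is chosen by 4-fold cross-validation (`tuneLambda()`,
default grid $10^{-5}, 10^{-4}, 10^{-3}$). Optimization is Adam over
shuffled minibatches (batch size capped at 10,000 pairs and shrunk to the
dataset for smaller cohorts), learning rate from the grid
$10^{-1}\ldots10^{-4}$ (`tuneLearningRate()`; default $10^{-2}$), weights
initialized uniformly in $(-0.01, 0.01)$. Per epoch, a held-out fraction
(10%) of pairs scores the model and the best-validation parameters are
retained. One seed drives initialization, splits and shuffling: identical
seeds give bit-identical histories, parameters and output files.

Training is end-to-end by default: the objective couples both branches, and
it is the only fully specified protocol. A `twoStage` option first trains
the branches separately (the VNN against its root auxiliary head, the drug
branch through a temporary linear head) and then fine-tunes the fusion head,
for the reading in which the two sub-models are trained independently.

Within a minibatch the VNN evaluates each *distinct cell line* once and the
drug branch each *distinct drug* once; batch-norm statistics are computed
over those distinct entities, and the fusion head normalizes over pairs.
This avoids weighting normalization statistics by how often an entity is
repeated in the batch, and is also the natural factorization of the
computation (gradients are summed over the pairs that share an entity — the
algebra is identical to pair-expanded rows everywhere except the BN
statistics).

## Interpretation

**RLIPP.** For a term $t$ with children, two linear (ridge, penalty
$10^{-6}$ — the least-squares limit, kept solvable under collinear neuron
states) predictors of the observed AUC are fitted: one from the parent's
neuron states (Pearson correlation $P_2$) and one from the children's states
($P_1$). The score

$$\mathrm{RLIPP} = \frac{P_2 - P_1}{P_1}$$

is the relative improvement the parent adds over what its children already
know: positive scores mark subsystems where predictive information *emerges*
rather than being passed through. Three methodological choices matter:

* *Child aggregation.* By default $P_1$ comes from a single linear model on
  the concatenated child states. The alternative reading — one model per
  child, predictions averaged before correlating — is available
  (`aggregation = "mean"`) but has a structural artifact: averaging divides
  one informative child's prediction by the child count, so every ancestor
  of an informative term scores roughly (number of children − 1) regardless
  of its own contribution, and the emergence point can never rank first. On
  planted-mechanism simulations the concatenated form localizes the
  mechanism; the averaged form systematically crowns its ancestors.
* *Held-out, grouped fits.* Correlations are computed out-of-fold by
  default (5 folds), with folds assigned by *cell line*, not by pair:
  neuron states are cell-level features and each cell line appears in many
  pairs, so pair-level folds would leak every cell's signal between train
  and test — a handful of free coefficients then chance-correlates with a
  few hundred cells at $r \approx \sqrt{p/n_{\text{cells}}}$, which is far
  from negligible. `heldOut = FALSE` gives the in-sample reading.
* *Significance guard.* The ratio is meaningless when $P_1 \approx 0$:
  sampling noise becomes an unbounded score. Terms whose $P_1$ is not
  significantly positive (one-sided test, level 0.05) are flagged
  `undefined` and sink to the bottom of the ranking instead of dominating
  it. Published subsystem rankings are likewise restricted to significant
  scores. `sigLevel = 0` disables the guard.

Per-drug analyses (`drugFilter =` one id, or several) mirror the practice of
scoring subsystems against a responsive compound; `responsiveDrugs()`
returns the drugs whose response variance across cell lines is above
average, which is where genotype attribution has any power at all.

**Embeddings.** `cellEmbeddings()` and `drugEmbeddings()` project the root
states and drug embeddings onto their first two principal components
(mean-centered, no scaling), with each axis's sign fixed so its
largest-magnitude loading is positive — deterministic up to that rule, with
explained-variance fractions attached. `subsystemStateExport()` writes
per-cell neuron states and auxiliary predictions for downstream plots, and
`rlippFromStates()` re-scores exported tables exactly.

## The synthetic study cohort

`simSpec()` / `simulateCohort()` fabricate everything the pipeline consumes
— ontology, three genotype CSVs, drug table, response triples, index files —
so no download is ever needed. The default cohort is desk-scale: 30 terms
(depth ≤ 6), 100 genes, 200 cell lines, 25 drugs, 2,000 pairs. Mutations
are Bernoulli(0.1); expression and copy number are Uniform(0,1);
fingerprints are random bit vectors averaging 81 set bits. The response is

$$\mathrm{AUC} = \mathrm{clip}\big(c_0 - c_1 \cdot \bar g_{T^*}(\text{cell})
  \cdot \text{bit}_{B^*}(\text{drug}) + \varepsilon,\; 0, 1\big),
  \qquad \varepsilon \sim N(0, \sigma^2),$$

with $\bar g_{T^*}$ the mean fused value of the planted term's descendant
genes, $c_0 = 0.9$, $c_1 = 1$, $\sigma = 0.05$. The multiplicative gene-set
× drug-bit form means *both* branches are necessary to fit it, which is what
makes end-to-end training and RLIPP recovery meaningful tests. Two
identifiability choices are deliberate:

* the planted bit is set in half the drugs (background bits are recalibrated
  so the mean popcount stays 81). At the background rate of 81/2048 the bit
  would appear in about one drug of 25 and the interaction would be
  unlearnable at this scale;
* the planted term is auto-chosen as a term whose children are all leaves
  and whose *own* direct annotations make up roughly half to three quarters
  of its descendant genes. A term with no direct annotations is
  mathematically indistinguishable from the union of its children — there
  is no emergence to detect — while a term whose children carry no signal
  has an undefined denominator. The generator gives leaf-parent terms a few
  direct genes so such candidates exist.

What the generator does **not** emulate: mutation hotspots and co-occurrence
structure, expression covariance, linkage, dose-response curve shapes,
chemical similarity between drugs, or assay noise heteroscedasticity.
Passing the recovery tests therefore shows the machinery is correct and the
analysis protocol is sound at this signal-to-noise ratio — not that
comparable accuracy would be reached on a real screen.

## Numerical choices and degenerate inputs

* Batch-norm $\epsilon = 10^{-5}$, momentum 0.1, biased batch variance.
* Constant genotype columns normalize to 0; fully missing genes are an
  error naming the gene; a fully missing channel is substituted (loudly).
* Ontology ties are broken lexicographically everywhere (topological order,
  child concatenation, ranking ties), so results are order-independent.
* A cycle reports "not a DAG" with an offending edge; multiple roots are
  listed; descendant-gene coverage is enforced at pruning and compilation
  (a freshly loaded ontology may legitimately contain uncovered terms).
* Training batches of one pair fall back to running BN statistics.
* RLIPP with $P_1 = 0$ (or not significantly positive) is `NA` and
  flagged, never infinite.
* Checkpoints embed a hash of the ontology content and refuse to load
  against a different hierarchy.

## Problem sizes used by the test suite

The packaged tests run the default cohort (2,000 pairs) for the recovery
properties — held-out Pearson ≥ 0.8 within 100 epochs, and the planted term
reaching the top 5% of subsystem ranks (percentile over all terms of the
hierarchy, the convention used when quoting "top x%" pathway ranks) in at
least 9 of 10 seeded replicates — and smaller cohorts (tens of cells,
hundreds of pairs) for unit and property tests. These sizes were chosen so
the whole suite runs comfortably on a laptop while keeping every property
statistically meaningful at its scale.

## Known limitations

* The fingerprint implementation is deterministic and well-formed but its
  bit positions are not interchangeable with other toolkits' Morgan bits;
  models and fingerprints must come from the same implementation.
* The L2 term regularizes subsystem weight matrices only (the formula's
  $W(t)$), not the drug branch or fusion head.
* RLIPP compares linear readouts; a subsystem whose contribution is purely
  nonlinear in its children's states can score near zero.
* Training is plain R matrix arithmetic: fine at cohort scales of up to a
  few thousand cells/terms, not engineered for genome-scale ontologies with
  thousands of terms times large minibatches.
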