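---
title: "Benchmark construction and model evaluation for compound-target interaction prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmark construction and model evaluation for compound-target interaction prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctibench)
```

## The problem

Compound-target interaction (CTI) prediction asks whether a small
molecule binds a protein. Reported performance of CTI models depends at
least as much on *how the benchmark is built* — where negatives come
from, whether test compounds or targets were seen in training, how
flexible the compounds are — as on the model itself. `ctibench`
implements the full benchmarking methodology as reusable, testable
components: gold-standard dataset construction, splitting designs,
featurization, reference architectures, and evaluation, all runnable at
desk scale on synthetic fixtures.

## Labels from affinities

Interaction tables carry continuous affinities that are binarized per
measure:

* KiBA score: hit iff score $\le 3$ (lower score = stronger binding
  under this convention);
* dissociation constant $K_d$ in micromolar: hit iff $K_d < 10\,\mu M$,
  non-binder at or above;
* already-binary labels pass through.

Both cut-offs are arguments of `cti_thresholds()`; the defaults are the
values used on the public KiBA and Davis exports. Records are filtered
before modelling: target sequences above 1400 residues and SMILES above
348 characters are excluded (348, not the looser 350 sometimes quoted
for the raw data, because 348 is the height of the one-hot encoder —
every surviving record must be encodable), unparseable SMILES are
dropped, and exact (canonical SMILES, sequence, label) duplicates are
collapsed. `preprocess_records()` is idempotent and reports per-reason
exclusion counts.

## Negative sampling by maximum Tanimoto distance

Interaction databases list binders but rarely non-binders. For a target
$t$ with binder set $C_t = (d_1,\dots,d_m)$ and candidate pool
$C'_t = (d'_1,\dots,d'_n)$, each candidate's distance to the binder set
is

$$ D(d'_i) = \min_{j=1..m}\left[1 - \mathrm{Tanimoto}(d_j, d'_i)\right], $$

and the $k$ candidates with the largest $D$ become label-0 pairs for
$t$: the compounds most dissimilar from everything known to bind. The
selection is required (and tested) to agree exactly with a brute-force
evaluation; ties break lexicographically by compound id so runs are
reproducible. The fingerprint is Morgan radius 2 at 2048 bits by
default and is injectable, which the test suite uses to check the
selection logic against an independent oracle on random bit patterns.
When `k` is not given it defaults to `round(2.5 * m)` per target, which
places the global negative:positive ratio inside the 1.9–3 band typical
of curated CTI benchmarks.

## Splitting designs

* **Warm start** (`warm_split()`): each entity's records are shuffled
  (seeded) and dealt round-robin, so any compound (or target) with at
  least `n_folds` records appears in every fold — the models always see
  the test entities during training.
* **Cold start** (`cold_split()`): entities are sorted by descending
  record count and assigned *as blocks* to folds visited cyclically,
  skipping folds at capacity; no entity ever spans two folds, so test
  entities are genuinely unseen. The capacity defaults to
  `ceiling(N / n_folds) * 1.007`: a fixed cap of 34,000 reported for a
  337,526-record 10-fold benchmark is that equal share plus ~0.7%
  slack, and the ratio generalizes where the constant does not. An
  entity bigger than the capacity is isolated in the emptiest fold and
  flagged rather than silently split.
* **Mutation-aware** (`mutation_split()`): training on wild-type target
  records only, testing on mutant records only. The similarity report
  ranks, per mutant, the most similar wild-type targets by a normalized
  Needleman-Wunsch score — global alignment, identity scoring
  (match 1, mismatch 0, gap 0) normalized by the longer sequence's
  self-score, which is 1 on identity and >0.95 for a single point
  mutation of any realistic-length protein. BLOSUM-style matrices can
  be passed instead; the normalization generalizes unchanged.
* **Label reversal** (`verify_label_reversal()`): validates a designed
  test in which any compound shared between train and test carries
  complementary labels, the probe for compound-memorization bias.

## Compound and target representations

Compounds: a character-level one-hot matrix (348 × 98); a 3239-bit
concatenation Morgan(1024) ⊕ MACCS(167) ⊕ path fingerprint(1024) ⊕
atom pairs(1024); a (3 × 2048) conformer fingerprint matrix; and an
atom graph whose nodes carry 34 features in nine groups (atom type 10,
heavy-atom degree 7, charge flag, hybridization 6, chirality flag,
radical flag, aromatic flag, configuration 2, hydrogen count 5).
Degrees above 6 and hydrogen counts above 4 clamp into the last bin and
are flagged. Everything is computed on the canonical SMILES, so two
spellings of one molecule encode identically.

The 98-character vocabulary is a design choice: only its *size* is
conventional, not its membership. The frozen table is the 94 printable
non-space ASCII characters plus space, tab, CR and LF (raw table
exports occasionally leak whitespace into a SMILES field); characters
outside the table are an error, never remapped, because silent
remapping corrupts one-hot semantics.

The configuration (R/S) bits are set from the tetrahedral parity mark
of the canonical SMILES (`@`/`@@`), not from a full CIP assignment —
an approximation that is deterministic and spelling-invariant, but can
disagree with strict CIP priority order for exotic substituent
patterns.

Conformers are embedded with ETKDG distance geometry at a fixed random
seed (RMS-pruned, so rigid molecules yield a single conformer and the
padding rows stay zero), then hashed by an iterative spherical-shell
scheme: each heavy atom starts from a hash of its element, charge and
aromaticity, then at levels $r = 1.718\,\text{Å} \times \ell$
absorbs the distance-binned identifiers of atoms inside the growing
shell; all identifiers fold into 2048 bits per conformer.

Targets: a (1400 × 20) one-hot matrix; a (1400 × 20) physicochemical
matrix obtained by z-scoring a 20 × P amino-acid property table
(P = 512 by default) and projecting with PCA fitted *on the 20 residue
types* — the representation must be a sequence-independent per-residue
lookup; a residue interaction graph with typed, energy-weighted edges
(disulfide 167, ionic 20, hydrogen 17, π-cation 9.6, π-π 9.4, van der
Waals 6 — weights depend on the type alone); and loaders for
precomputed per-target embeddings validated against their declared
width (UniRep-style 1900, BERT-style 768).

One numerical subtlety: a column-centered 20-row table has rank at most
19, so the 20th principal component is necessarily a null direction
whose scores are ~0 for every residue. The fit tolerates exactly that
one degenerate component (and fixes every component's sign by making
its largest-magnitude loading positive, for full determinism); any
deeper rank deficiency is an error suggesting fewer components.

The shipped property table is **synthetic** (`synthetic_aa_properties()`:
correlated Gaussian traits, seeded) — it has the shape and correlation
structure of a real physicochemical catalogue but no chemical meaning.
Any real 20 × P export drops in unchanged. Passing tests therefore
demonstrate the pipeline's mechanics, not biological validity of the
features.

## Model architectures

All towers end in a 128-dimensional representative vector; a pair model
concatenates a compound tower and a target tower (256) and classifies
through fully-connected layers (default 256 → 64 → 2) with a softmax
over two output neurons, trained with the cross-entropy
$\mathcal{L}(y', y) = -[y \log y' + (1-y)\log(1-y')]$ (predictions
clipped at $\varepsilon = 10^{-7}$) and momentum SGD (defaults lr 0.01,
momentum 0.9, batch 32 — all in `train_config()`, fully seeded).

* **Graph attention v2** (`gatv2_layer()`): scores
  $e(f_i,f_j) = a^\top \mathrm{LeakyReLU}(W[f_i \| f_j])$, softmax over
  each neighbourhood, update
  $f'_i = \sigma(\sum_j \alpha_{ij} W_r f_j)$. Since $W$ acts on the
  concatenation it is $d_{out} \times 2d_{in}$; the update uses its
  neighbour-side block, the standard resolution of that notation.
  $\sigma$ is ELU (configurable), one attention head, isolated nodes
  get self-loops so the softmax is defined, and residue-graph edge
  weights optionally scale the attention logits before the softmax (the
  weighting mechanism is not pinned down by convention; the scaling is
  multiplicative and can be disabled). Two stacked layers with widths
  8 then 4 over 1400 padded residues concatenate to the 5600-d code of
  the structure-based target tower.
* **Convolution–pooling towers** (`conv_pool_tower()`): single-channel
  2D stages following `floor((n - k + 2p)/s) + 1` per axis. The
  physicochemical target tower — conv (603,8) pad 1, pool (201,4)
  stride 1, conv (303,7) pad 1, pool (101,4) stride 1 on a (1400,20)
  input — flattens to exactly 1000; the conformer tower — conv (3,501)
  pad 1 then a (3,5) pool — flattens to 310. The conformer tower's pool
  must be non-overlapping (stride = kernel): with stride 1 the output
  would be 4638-wide, and (1550−5)/5+1 = 310 is the only reading
  consistent with the printed width. The physicochemical tower's pools
  use stride 1, which reproduces its printed intermediate shapes.
* **Fingerprint MLP** (`fp_mlp_tower()`): 3239 → 2048 → 512 → 128,
  ReLU on the hidden layers, affine output.
* **Embedding MLP** (`embedding_mlp_params()`): width → 512 → 128 for
  precomputed protein embeddings.
* **Global-window sequence tower** (`deepconv_target_tower()`): a
  trainable residue embedding table, 1-D convolution filters of several
  window widths over the whole sequence, global max-pooling per filter
  with padded positions masked out of the max. The table initializes
  either uniformly at random (seeded) or from the L2-normalized
  projected physicochemical vectors (`phys_init_embeddings()`), the
  chemistry-informed initialization that remains trainable.

Gradient training (analytic backprop) covers the dense pathways —
fingerprint/embedding towers and the head — which is where trainable
benchmarking happens in this package. The convolutional and
graph-attention towers are exact, seeded forward passes; used inside a
pair model they act as frozen feature extractors with a trainable
read-out. Implementing full backprop through conv/pool/attention in
base R would add much surface for little benchmarking value; it is the
package's main known limitation.

## Evaluation

`compute_metrics()` reports accuracy, F1 and MCC at threshold 0.5 on
the positive-class probability, AUROC by trapezoidal integration and
AUPR by step (average-precision) integration — the integration rule is
fixed because trapezoid-vs-step changes the third decimal. MCC is
defined as 0 whenever a confusion-matrix margin is empty, so constant
or random predictors score 0 instead of NaN. With single-class labels
the ranking metrics are flagged undefined rather than fabricated.
`random_baseline()` draws labels at a given prevalence and uniform
scores: the expected AUPR of an uninformative scorer *is* the
prevalence (≈0.289 at the 97,471/337,526 class balance) and the
expected MCC is 0 — the floor against which model numbers must be read
on imbalanced data. `cross_validate()` trains per fold, flags folds
with single-class test labels, and aggregates mean ± sd.

## The synthetic data generator

`gen_compounds()` assembles SMILES from a closed-ring/chain fragment
grammar (guaranteeing parseability and meaningful fingerprints), with
rotatable-bond counts spanning 0–20 so both sides of the LRB (≤10
rotatable bonds) and RRB (rotatable-bond fraction ≤0.184) filters are
populated. Rotatable bonds follow the strict definition: single,
non-ring bonds between non-terminal heavy atoms, excluding amides and
bonds at triple-bond carbons; the fraction divides by all heavy-atom
bonds, with 0/0 defined as 0 (an atom without bonds is trivially
rigid). `gen_targets()` draws random sequences (default 150–400
residues); mutants are single-point substitutions of generated
wild-types. `gen_interactions()` plants the learnable signal: a pair is
positive iff its compound carries a sulfonamide fragment *and* its
target carries a W/H-rich motif, with optional label noise; affinities
are drawn consistently with the label under the declared measure, so
binarization reproduces the labels. Default prevalence is 0.289, the
class balance of the large aggregated benchmark the random baseline
refers to. `gen_contacts()` emits typed residue contacts with
disulfides only between cysteines.

What the generator does *not* emulate: real binding physics, correlated
assay noise, chemical series structure, or homology families beyond
point mutants. Passing tests on synthetic data demonstrate that the
machinery is correct — splits disjoint, oracles matched, signal
learnable — not that any architecture ranks the same way on real
benchmarks.

## Problem sizes and numerical choices

The test-suite and demonstration configurations are chosen for a
single-CPU desk run: synthetic datasets of 100–300 pairs and 15–40
entities per side, 1000 random instances for the negative-sampling
oracle (fingerprints of 32 bits there — the logic is
length-independent), graphs of ≤6 nodes for the attention oracle
(tolerance 1e-6), exhaustive metric enumeration over all labelings of
10 points, a 100,000-draw random baseline, and learnability training of
the full-width fingerprint MLP on 200 pairs with early stopping at
training MCC 0.95. Degenerate inputs follow documented conventions
rather than NaN: Tanimoto of two empty bit sets is 1 (identical
vectors), RBF 0/0 is 0, degenerate MCC is 0, and the no-signal control
is evaluated on held-out pairs (training loss on shuffled labels keeps
falling below $\ln 2$ by sheer memorization — 200 pairs against a
high-capacity MLP — so the held-out loss is the faithful check that
nothing generalizable was learned).
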