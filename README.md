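# ctibench

Gold-standard benchmarking for compound–target interaction (CTI)
prediction, in R.

Whether a model appears to predict drug–target binding well depends
heavily on how its benchmark was built: where the negative pairs came
from, whether test-set compounds or proteins were already seen in
training, and how conformationally flexible the test compounds are.
`ctibench` implements that benchmarking methodology end to end, for
method developers who want to evaluate CTI models under controlled,
reproducible designs rather than a single convenience split.

## What it provides

**Dataset construction.** Affinity binarization (KiBA score ≤ 3 = hit;
Kd < 10 µM = hit), length/validity/duplicate preprocessing, and
max–min Tanimoto negative sampling: for a target *t* with binders
*C<sub>t</sub>* and candidate pool *C′<sub>t</sub>*, each candidate's
distance to the binder set is

> D(d′ᵢ) = min over binders dⱼ of [ 1 − Tanimoto(dⱼ, d′ᵢ) ]

and the *k* most distant candidates become label-0 pairs — the
compounds least like anything known to bind. Rotatable-bond filters
build the LRB (≤ 10 rotatable bonds) and RRB (rotatable-bond fraction
≤ 0.184) dataset variants.

**Splitting designs.** Warm start (entities shared between folds),
cold start (entity-blocked folds with capacity control — test
compounds/targets never seen in training), mutation-aware
(train on wild-type proteins, test on mutants, with a
Needleman–Wunsch similarity report), and a label-reversal validator
that exposes compound-memorization bias.

**Featurization.** Compounds: SMILES one-hot (348 × 98), a 3239-bit
fingerprint concatenation (Morgan 1024 ⊕ MACCS 167 ⊕ path 1024 ⊕
atom-pair 1024), conformer-based 3D fingerprints (3 × 2048, ETKDG
embedding at a fixed seed), and atom graphs with 34-dimensional node
features. Targets: sequence one-hot (1400 × 20), physicochemical PCA
vectors, residue interaction graphs weighted by dissociation energy
(disulfide 167 … van der Waals 6), and loaders for precomputed
protein embeddings (1900-d UniRep-style, 768-d BERT-style).

**Models and evaluation.** GATv2 graph-attention layers,
convolution/max-pool towers (the physicochemical target tower flattens
to exactly 1000 dimensions; the conformer tower to 310), fingerprint
and embedding MLP towers, a global-window sequence tower with
physicochemistry-initialized embeddings, a seeded momentum-SGD trainer,
and metrics (accuracy, AUROC, AUPR, F1, MCC) with a random-prediction
baseline: an uninformative scorer's AUPR equals the class prevalence,
its MCC is 0.

**Synthetic data.** A fragment-grammar compound generator, motif-bearing
target generator and planted-signal interaction generator make the full
pipeline testable on one CPU with no downloads.

## Worked example

```r
library(ctibench)

ds <- synthetic_dataset(n_compounds = 20, n_targets = 12,
                        n_pairs = 150, seed = 1)
print(ds$records)
#> <cti_records> 150 records | 20 compounds | 12 targets | 150 labelled (43 positive)

prof <- rotatable_bond_profile(ds$compounds[[1]])
sprintf("%d rotatable of %d bonds (RBF %.3f)",
        prof$n_rotatable, prof$n_bonds, prof$rbf)
#> "4 rotatable of 19 bonds (RBF 0.211)"

folds <- cold_split(ds$records, "compound", n_folds = 3)
print(folds)
#> <fold_assignment> COLD_COMPOUND: 150 records in 3 folds (sizes 49, 51, 50)

baseline <- random_baseline(1e5, prevalence = 97471 / 337526, seed = 1)
print(baseline)
#> <eval_report> n=100000 (28957 pos / 71043 neg)
#>   accuracy 0.4968 | AUROC 0.4955 | AUPR 0.2864 | F1 0.3640 | MCC -0.0056
```

The 150 generated records carry a planted signal (a sulfonamide
substructure × a sequence motif) at 29% prevalence. The cold split
assigns each compound's records as a block, so the three folds share no
compounds. The baseline report shows what "no information" looks like
at the class balance of a large aggregated CTI benchmark (97,471
positives among 337,526 records): AUPR ≈ 0.29 (= prevalence) and
MCC ≈ 0 — numbers any real model must beat.

A thin CLI covers the same stages
(`exec/ctibench simulate|negatives|filter-rb|split|eval|run`), and
`run_pipeline()` executes simulate → preprocess → split → featurize →
train with a provenance manifest. See the vignette
(`vignettes/ctibench-methods.Rmd`) for the models, parameter choices
and limitations.

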