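---
title: "Predicting small-molecule regulation of miRNA expression: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting small-molecule regulation of miRNA expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Curated pharmacogenomics databases record experimentally supported
effects of small molecules on miRNA expression, split by direction:
a compound may *up-regulate* or *down-regulate* a given mature miRNA.
`smiReg` treats each direction as a separate binary classification
problem over (molecule, miRNA) pairs:

* a **positive** pair is a curated regulation of that direction;
* a **negative** pair is mined (see below), since "no regulation" is
  never curated;
* the feature vector of a pair is the concatenation of a 277-dimensional
  miRNA sequence descriptor and a 166-key MACCS structural fingerprint —
  443 numeric features, ordering frozen inside every trained bundle.

The model makes two structural assumptions worth stating explicitly.
First, *chemical similarity propagates regulation*: molecules with
similar structures tend to regulate the same miRNAs. This licenses both
the negative-mining score and, implicitly, the classifier's ability to
generalize. Second, *sequence composition carries the miRNA-side
signal*: no secondary structure, precursor context or target information
enters the model, only k-mer statistics of the mature sequence.

## The miRNA descriptor

For a normalized sequence (uppercase, `T` mapped to `U`, any other
non-ACGU symbol a hard error) of length $L \ge 4$:

| block | size | definition |
|---|---|---|
| length | 1 | $L$ in nucleotides |
| mononucleotide ratios | 4 | counts of A, C, G, U over $L$ |
| 2-mer frequencies | 16 | overlapping counts over $L-1$ windows |
| 4-mer frequencies | 256 | overlapping counts over $L-3$ windows |

Two conventions are underdetermined by the method description and are
fixed here by decision: **frequency** means overlapping-window count
divided by the number of windows ($L-k+1$), so each k-block is a
probability vector (testable as an invariant); **ordering** is
lexicographic with $A < C < G < U$ within each block, blocks ordered
length → 1-mer → 2-mer → 4-mer. Sequences shorter than 4 nt are rejected
rather than zero-padded, because the 4-mer block is undefined for them.

## The molecule fingerprint

SMILES strings are parsed and fingerprinted by RDKit, invoked through
the bundled Python helper (`inst/python/maccs_fp.py`); the 167-bit MACCS
convention's unused bit 0 is dropped so exactly the 166 public keys
remain. MACCS SMARTS definitions differ slightly between cheminformatics
toolkits, so *absolute bit patterns are backend-dependent*; the pipeline
logic depends only on fingerprints being fixed-length binary vectors,
and the test suite freezes one RDKit-computed fingerprint (ethanol) as a
fixture to pin the backend's behaviour. Duplicate molecules are detected
by canonical-SMILES equality, not input-string equality. Fingerprints
can also be imported directly from TSV, which is how the synthetic
generator feeds the pipeline without any Python dependency.

Tanimoto similarity is $|A \cap B| / |A \cup B|$ over on-bit sets, with
the all-zero/all-zero case defined as 0 — a conservative choice:
featureless molecules should not count as similar.

## Negative mining

For a candidate pair (molecule $D$, miRNA $m$) in direction $d$, the
regulation score is the arithmetic mean of Tanimoto similarities between
$D$ and every molecule known to regulate $m$ in direction $d$.
Candidates scoring **strictly below 0.1** form the credible-negative
pool; exactly as many negatives as there are positives are drawn
uniformly without replacement under an explicit seed.

Design choices where the method description is silent:

* **Candidate universe** — the Cartesian product of the direction's own
  molecules and miRNAs (matching the reported per-direction entity
  counts), minus its positives. miRNAs with no in-direction regulator
  are excluded rather than scored 0; a 0 would flood the pool with
  unscoreable pairs.
* **Cross-direction exclusion** — a pair curated as a down-regulation
  should not become a "no up-regulation" negative by sampling accident;
  exclusion of opposite-direction positives defaults on and can be
  disabled (`--no-cross-exclude`).
* **Strict inequality** at the threshold, global (not per-miRNA)
  uniform sampling, and a logged seed.

## Training, tuning, calibration

Each balanced dataset is split 50/50, stratified by label (odd class
counts round toward training). On the training half, the single
hyperparameter of each classifier family is tuned by **mean AUC over 5
stratified CV folds**, ties broken toward the smaller value; sensitivity
and specificity are reported at the 0.5 cutoff alongside fold SDs. The
final model is refit on the full training half, evaluated by rank-based
AUC (Mann–Whitney with midranks) on the held-out half, and calibrated:
the **suggestion rate** is the lowest threshold on the 0.00–1.00 grid
(step 0.01) maximizing F1 on the held-out predictions. The original
description does not say which data the F1 sweep used; held-out
predictions were chosen here because calibrating on training data with a
random forest (whose training-set probabilities are optimistic) would
push the threshold toward 1.

The five families, their tuned parameter and backend:

| family | tuned | default grid | backend |
|---|---|---|---|
| glm | elastic-net alpha | 0, 0.25, …, 1 | glmnet (lambda fixed at 1e-3) |
| knn | k | 3, 5, …, 21 | FNN; probability = positive fraction of the k neighbours |
| svm | log2(C) | −2 … 6 | in-package SMO, RBF kernel, gamma = 1/p, Platt-scaled |
| ann | weight decay | 0.1 … 0.9 | in-package 1-hidden-layer (5 units) MLP, BFGS |
| rf | mtry | √p, 100, 149 | in-package forest, 500 trees; probability = vote fraction |

The rf/svm/ann backends are authored inside the package because no R
implementation of these learners is available in the supported
environment; they follow the textbook algorithms (Breiman forest with
Gini/CART and bootstrap per tree; simplified-SMO SVM with a cached
kernel matrix; penalized cross-entropy MLP with analytic gradients) and
are deterministic given (data, seed). Features are standardized with
train-set mean/SD for glm/knn/svm/ann and left raw for rf. Tree count
(500) and hidden-layer size (5) are fixed common defaults. The split is
by *pair*, not by entity, mirroring the original design; this can leak
molecule/miRNA identity between train and test, so held-out AUCs should
be read as optimistic for truly novel entities.

## Prediction semantics

A pair whose predicted probability is **at or above** the bundle's
suggestion rate is called `worth-studying` (the boundary case is
included; the original phrasing "higher than" leaves the tie open).
Rankings sort by probability descending with ties broken by entity id
ascending, so batch output is a deterministic permutation of the
library and always consistent with single-pair prediction.

## What the synthetic world does and does not establish

The generator plants a fully known regulation rule so that every stage
is testable offline:

* each of `n_families` molecule families owns a **disjoint block of
  MACCS keys**; the family prototype sets exactly that block, and
  members flip each of the 166 keys independently with probability
  `fingerprint_noise` (default 0.05). Disjoint blocks keep cross-family
  Tanimoto — and hence cross-family regulation scores — safely below the
  0.1 mining threshold;
* each family owns a unique 4-mer motif, planted at a uniform position
  in the miRNAs it regulates (lengths 18–25, uniform composition).
  Sequences are **rejection-sampled so that no miRNA carries any family
  motif by chance**; without this, roughly 7% of ~22-nt sequences would
  contain a given 4-mer coincidentally and the noise-free world would
  not actually be separable, breaking the recovery oracle;
* every (family member, regulated miRNA) pair is emitted as a positive
  with the family's direction; `label_noise` (default 0.05) flips the
  direction of a random subset, and the uncorrupted rule is written to
  `truth.tsv` for recovery scoring.

Defaults (10 families × 10 molecules, 200 miRNAs half of which are
regulated, noise 0.05/0.05) give ≈1,000 positives per the all-up
configuration — about 2,000 balanced rows, the scale of the smaller
curated direction. A green end-to-end test establishes that the pipeline
recovers a planted family-by-motif interaction under mild noise; it does
**not** establish performance on real corpora, whose similarity
structure is continuous (no disjoint key blocks), whose miRNA signal is
not a single exact motif, and whose curation noise is not independent
Bernoulli. Real-corpus figures require the external databases and are
deliberately out of the acceptance gate.

## Numerical and degenerate-input choices

* AUC uses midranks, so heavy score ties are handled exactly;
  single-class evaluation sets are errors, never NaN.
* F1 at a threshold with zero predicted positives is defined as 0; if no
  grid threshold predicts any positive, selection errors out.
* Grid-AUC ties choose the smaller hyperparameter; F1 ties choose the
  lower threshold (both documented, both tested).
* Zero-variance feature columns standardize to zero (SD clamped to 1).
* All RNG flows through explicitly scoped seeds (`local_seed`), so
  library calls never perturb user-level randomness, and CLI manifests
  omit timestamps so identical manifests reproduce byte-identical
  outputs.

## Known limitations

* No miRNA-side similarity enters negative mining (molecule similarity
  only, as in the original design); target- or sequence-based miRNA
  similarity is a known extension.
* The SMILES path requires an external RDKit; MACCS bit patterns are
  toolkit-dependent, so bundles should only score fingerprints produced
  by the same backend they were trained with.
* Pair-level splitting (see above) and threshold calibration on the same
  held-out half used for AUC reporting are faithful to the original
  design but optimistic; an entity-level split would be the stricter
  protocol.
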