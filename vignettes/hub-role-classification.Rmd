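---
title: "Classifying party and date hubs from biological features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying party and date hubs from biological features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`hubclass` treats the network role of a protein — non-hub (NH),
intermediately connected (IC), party hub (PH), date hub (DH), coded 1–4 —
as a four-class supervised learning problem over feature encodings of the
protein itself. The pipeline is: encode up to seventeen feature sets,
reduce each to three combined features by supervised PCA, optionally fuse
sets greedily, and classify with a Bayes rule whose class-conditional
densities are Gaussian or Gaussian-mixture models, under either the
maximum-posterior or a minimum-expected-cost decision.

The statistical assumptions are modest: class priors are estimated as
training frequencies; class-conditional densities of the *reduced*
(3–15 dimensional) features are assumed approximately Gaussian or
mixture-of-Gaussian; and feature sets are assumed complementary enough
that concatenating their reductions can improve discrimination. Nothing
assumes the interaction network itself is observed.

## Feature encodings and their conventions

All 20- and 400-dimensional encodings index residues alphabetically by
one-letter code (`A, C, D, …, Y`); this fixed order makes vectors
comparable across modules. Residues outside the 20 standard types (B, J,
O, U, X, Z) are retained in sequences but contribute to no numerator
count, while the literal denominators $N$, $N-1$, $N-1-k$ are kept, so a
composition vector of a sequence containing nonstandard letters sums to
slightly less than 1. This preserves the defining formulas exactly:

* amino-acid composition $\mathrm{comp}(i) = R_i / N$;
* dipeptides $\mathrm{dpep}(i) = D_i / (N-1)$;
* gapped pairs $\mathrm{gapped\_dip}_k(i) = E_k(i) / (N-1-k)$, counting
  ordered patterns $A x^k B$; $k = 0$ reduces to dipeptides. Gaps up to
  $k = 4$ are the intended range.

The co-occurrence matrix is the 400-vector reshaped to $20 \times 20$
(rows = first residue). It is directional — ordered pairs are counted and
the matrix is not symmetrised. Twelve Haralick texture statistics are
computed from it with these numerical conventions, fixed here because the
texture-analysis literature varies: logarithms are base 2 with
$0 \log 0 = 0$; correlation is defined as 0 when a marginal has zero
variance; *sum variance* is the dispersion of the sum distribution
$p_{x+y}$ around the sum average (the classical definition centred on the
sum entropy is widely regarded as a typographical accident); and the
*information measure of correlation* is the first measure (IMC1) only,
defined as 0 for a single-cell matrix. By default the Haralick features
are computed on the $k = 1$ co-occurrence matrix (`haralick_k` in
`extract_features()` changes this; no canonical choice exists).

The 48 physicochemical property groups are table-driven. The original
48-group listing is not publicly available, so the shipped default
(`extdata/property_groups48_synthetic.tsv`) is a constructed stand-in
assembled from standard residue classifications (CTD hydrophobicity /
volume / polarity / polarizability / charge / secondary structure /
accessibility classes, Taylor classes, and classical chemical groups);
only the aromatic group (H, F, W, Y) is anchored to the published
description. Any 48-row table can be substituted.

PSSM profiles are stored positions × residues ($L \times 20$), matching
the PSI-BLAST ASCII layout, with columns remapped to the canonical
residue order whatever order the file header uses. PSSM-20 is the
column-wise mean of the weighted-percentage block rescaled to fractions;
when a profile lacks percentages the softmax of the position-averaged
scores is used instead (with a warning), since both estimate the
homologue composition. PSSM-400 aggregates, for each residue type, the
mean of the score rows at positions holding that residue, with absent
types contributing zero blocks, then squashes every value through the
logistic $1/(1+e^{-x})$ — the standard construction of this encoding in
the protein-localisation literature, adopted because no aggregation rule
is canonical.

GO features are binary memberships over per-aspect, per-level term
vocabularies taken from the input tables as given (no graph traversal or
term inference). The two extracted levels are called "level one" and
"level two" per aspect; in yeast these correspond to 19/8/15 and 65/33/60
categories for BP/CC/MF. Disorder features are four scalars computed from
normalised half-open intervals: disordered fraction, region count,
longest and mean region length.

## Reduction

"Supervised PCA" is implemented screen-then-project: features are ranked
by their one-way ANOVA F statistic across the four classes, the top
`screen_fraction` (default 0.5, never fewer than `n_components`) kept,
standardised, and projected on the leading `n_components = 3` principal
components. This is the natural multiclass form of label-informed
screening followed by PCA; with `screen_fraction = 1` it degrades to
ordinary PCA for comparison runs. Determinism is enforced by stable
ranking and by fixing each component's sign so its largest-magnitude
loading is positive. Zero-variance features are dropped; perfectly
separating features (zero within-class variance) rank first.

## Classifiers and decisions

Gaussian class-conditional densities use maximum-likelihood means and
covariances with a ridge of $10^{-6}$ times the mean covariance diagonal
(raised, with a warning, when a class has fewer samples than dimensions).
The mixture-density model fits, per class, Gaussian mixtures by EM —
k-means++ initialisation from the model seed, full covariances with the
same ridge, convergence at a relative log-likelihood change of $10^{-6}$
or 500 iterations, collapsed components pruned — and selects the
per-class component count by 5-fold cross-validated held-out
log-likelihood up to `max_components`. With one component the mixture
model reproduces the Gaussian classifier exactly (identical estimators
and ridge), which the tests assert.

Posteriors are computed in the log domain throughout, so extreme queries
yield well-defined decisions rather than NaN. The KNN baseline uses
Euclidean distance with fully deterministic ties (equal distances rank by
training-row order; vote ties resolve to the lowest class index — the
same tie rule used by every decision function).

Minimum-risk decisions minimise $\sum_i L[i,j]\,P(i\mid x)$ over the
predicted class $j$. The default cost matrix charges 0.9 for predicting a
true hub as NH/IC, 0.1–0.2 otherwise, with a zero diagonal. The matrix is
oriented rows = true class, columns = predicted class; this orientation
is what makes the rule *hub-favouring* (the 0.9 penalties pull mass
toward PH/DH), which matches its purpose of compensating the extreme
class imbalance — the alternative orientation would suppress hub
predictions. Class priors remain training frequencies; imbalance is
handled by the risk term, not by prior reweighting.

## Fusion and the experiment protocol

Experiments split the data 70/30, stratified per class, and use 5-fold
stratified cross-validation *inside the training split* for every
selection decision; the test split influences nothing but the final
report (the tests corrupt held-out records and assert that fitted models
and selected sets are unchanged). Greedy forward fusion ranks the reduced
sets by standalone CV average CCR, seeds the combination with the best,
and accepts a candidate only when both the CV average CCR and the label
correlation *strictly* improve; the search stops when no remaining
candidate is accepted. Requiring both metrics on CV (rather than the test
portion, which the protocol leaves open) avoids selection leakage. Each
accepted combination is the concatenation of 3-dimensional reductions, so
a five-set fusion is 15-dimensional.

The label correlation is the Pearson correlation of the integer codings
1–4 (in the fixed order NH, IC, PH, DH), reported in percent; it is one
defensible reading of an underspecified statistic and reproduces the
qualitative behaviour expected of it. AROC uses the midrank
(Mann–Whitney) formulation, equal to the trapezoidal area with ties at
half credit. One-vs-rest metrics are also reported for the merged PH+DH
super-class (any-hub detection).

## The synthetic generator

`simulate_proteins()` produces the study conditions the pipeline is
tested under: class labels drawn from the yeast-like mix
(81.4/9.8/3.3/5.5% by default), degrees from truncated discrete power
laws consistent with the degree thresholds (so
`assign_roles(degree, avg_pcc)` reproduces the labels exactly), and hub
co-expression from a two-component mixture (party hubs centred at 0.8,
date hubs at 0.2, threshold 0.5). Per protein it draws a log-normal
length (median ≈ 450 residues), residues from a Dirichlet-perturbed
class composition, Poisson domain counts (hubs > non-hubs), adjacent
repeated domains with hub-elevated probability, a class-correlated
cellular compartment, class-dependent disorder content (date hubs most
disordered, consistent with their flexible-binding biology), and a
profile whose log-odds reflect the class composition. All contrasts scale
with one `effect` parameter and vanish at 0; the shipped strong-effects
configuration (`extdata/strong_effects.yaml`, effect 2.5) gives a
residue concentration contrast of about $e^2 \approx 7.4$ between
classes, deliberately above the ~5-fold level at which composition alone
supports clearly-above-chance recovery.

What the generator does *not* emulate: real interactome motif structure,
the GO graph hierarchy, evolutionary features such as protein age,
correlated annotation noise, or the 2009-era annotation snapshots behind
the published yeast results. Passing the synthetic recovery tests
therefore demonstrates that the pipeline's machinery is sound — not that
the headline yeast accuracies are reproducible here, which would require
the original label set, InterPro/GO snapshots and nr-database profiles.

## Problem sizes and numerical checks in the test suite

The suite exercises the formulas against naive brute-force counters (100
random sequences up to length 50), Haralick statistics against direct
summation, decisions against grid-density and pair-ordering oracles, EM
against an independent mixture implementation, and the full pipeline on
synthetic datasets of 2000 proteins over three seeds (strong effects:
average CCR and merged-hub sensitivity well above 60%/70%; zero effects:
chance-level 25 ± 5%). These sizes were chosen as the smallest at which
the class mix leaves dozens of hubs in the held-out split, keeping every
estimate stable while the whole suite runs in about a minute.

## Known limitations

* The 48-group property table is a labelled stand-in, not the original
  grouping.
* The disorder summary features are this package's definition; the
  original feature list behind published disorder results is not stated.
* GO "level one/two" naming is a package convention; sources disagree on
  whether these are the second/third graph levels.
* Mixture-component selection by CV log-likelihood can choose one
  component for genuinely multimodal but overlapping classes at small
  class sizes.
* `read_pssm()` supports the PSI-BLAST ASCII dialect only (no XML).
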