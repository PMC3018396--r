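# hubclass

Predicting the network role of a protein — non-hub (NH), intermediately
connected (IC), party hub (PH) or date hub (DH) — from its biological
features alone, without access to the interaction network.

## The problem

Protein interaction networks (PINs) are scale-free: a few hub proteins
(conventionally more than eight interaction partners) hold the network
together, while most proteins are non-hubs (fewer than three partners).
Hubs split further by gene co-expression with their partners: *party hubs*
are co-expressed with most partners at once and act as local coordinators;
*date hubs* bind different partners at different times or places and act
as global connectors. Because complete, reliable PINs exist for only a few
organisms, a classifier that infers these four roles from protein features
that *are* widely available — sequence, domain architecture, Gene Ontology
annotation, disorder content, evolutionary profiles — is a useful
surrogate, e.g. for prioritising drug targets or studying network
modularity.

## The method

For each protein, up to seventeen feature sets `X_1 .. X_n` are encoded:

* **Compositions** — amino-acid composition `comp(i) = R_i / N` (20 dims),
  dipeptides `dpep(i) = D_i / (N - 1)` (400), and gapped pairs
  `gapped_dip_k(i) = E_k(i) / (N - 1 - k)` (400, patterns `A x^k B`);
* **Co-occurrence texture** — the gapped-pair counts arranged as a 20 x 20
  co-occurrence matrix, summarised by 12 Haralick statistics (energy,
  correlation, inertia, entropy, ...);
* **Physicochemical fractions** (48 residue property groups, plus length);
* **Domain content** — binary membership over a domain vocabulary, and
  repeated domains (two adjacent domains of the same family);
* **GO levels** — binary membership of biological-process, cellular-
  compartment and molecular-function terms at two graph levels;
* **Disorder** — fraction, count, longest and mean disordered region;
* **PSSM-20 / PSSM-400** — homologue composition and residue-conditioned
  mean profile rows (logistic-squashed) from PSI-BLAST profiles.

Each feature set is reduced to **three combined features** by supervised
PCA (ANOVA-F screening, then PCA on the standardised survivors). A Bayes
classifier — Gaussian or mixture-density (EM-fitted) class-conditional
densities — produces posteriors `P(class | x)`; decisions are either
maximum-posterior or **minimum-risk** under the hub-prioritising cost
matrix

```
L = [ 0   0.1  0.2  0.2
      0.1 0    0.2  0.2
      0.9 0.9  0    0.2
      0.9 0.9  0.2  0  ]      (rows = true, cols = predicted)
```

which makes missing a true hub nine times costlier than the converse.
Feature sets are combined by **greedy forward fusion**: candidates are
added in order of standalone cross-validated average CCR and kept only if
both the CV average CCR and the label correlation strictly improve.
Evaluation reports the 4 x 4 confusion matrix, the average correct
classification rate (mean per-class recall), Pearson label correlation,
one-vs-rest sensitivity / specificity / PPV / NPV (including the merged
PH+DH super-class) and per-class AROC.

A synthetic-data module generates complete labelled datasets (sequences,
domains, GO terms, disorder, profiles) with the statistical structure the
classifier assumes, so the whole pipeline is testable end to end.

## Worked example

```r
library(hubclass)

cfg <- synthetic_config(n = 600, mix = c(0.55, 0.2, 0.1, 0.15),
                        with_pssm = FALSE)
ds  <- simulate_proteins(cfg, seed = 1)
ds
#> <hub_dataset> 600 proteins | NH 341 IC 113 PH 63 DH 83

ex <- run_experiment(ds, experiment_config(
  seed = 1, sets = c("aac", "domains", "go_cc_1", "disorder")))
ex
#> <hub_experiment> gauss (min-risk)
#>   sets: aac + disorder
#>   test average CCR 99.0%, correlation 99.1%

ex$fusion$trace
#>    step candidate sets                 cv_ccr cv_corr accepted
#> 1     1 aac       aac                    98.4    98.1 TRUE
#> 2     2 go_cc_1   aac+go_cc_1            95.6    96.1 FALSE
#> 3     3 disorder  aac+disorder           99.7    99.6 TRUE
#> 4     4 go_cc_1   aac+disorder+go_cc_1   97.5    97.9 FALSE
#> 5     5 domains   aac+disorder+domains   98.7    98.5 FALSE
```

The fusion trace reads: amino-acid composition is the strongest standalone
set (CV average CCR 98.4%); adding disorder improves both CV metrics so it
is kept; the remaining candidates improve neither and are rejected. On the
held-out 30% the fused classifier reaches an average CCR of 99.0% — the
synthetic generator's default effects are deliberately strong. `tidy(ex)`
and `glance(ex)` return the per-class metric table and the one-row
summary; `autoplot(ex)` draws the one-vs-rest ROC curves and
`autoplot(ex$report)` the confusion heat map.

A thin command-line front-end over the same functions is installed at
`inst/cli/hubclass.R` (subcommands `simulate` and `run`).

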