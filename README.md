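# stromasig

Methylation-signature deconvolution of tumor and microenvironment signal
in bulk DNA-methylation (beta-value) data.

## The problem

A bulk methylome is a mixture: every CpG beta value averages over
neoplastic cells and the stroma around them — macrophages and
microglia-like cells, lymphocytes, endothelium, fibroblasts. Classifiers
and subtype systems trained on bulk beta values therefore absorb
tumor-microenvironment (TME) signal, and an "immune-enriched" epigenetic
subgroup may be defined as much by its infiltrate as by its tumor cells.
`stromasig` is for computational biologists who want to dissect that
confound: discover methylation signatures from bulk methylomes without
supervision, annotate them as neoplastic (N) or stromal (S), estimate
per-sample signature fractions, ask which probes a random-forest
classifier uses to separate classes and in which methylation direction,
and test whether the inferred immune fraction stratifies survival.

## The model

Beta matrices $V$ (probes × samples, values in $[0,1]$) are factorized as

$$V \approx W H, \qquad 0 \le W \le 1, \quad H \ge 0, \quad \mathbf{1}^{\mathsf T} H = \mathbf{1}^{\mathsf T},$$

so each sample is a convex combination of signature methylomes. Fitting
uses multiplicative updates with corrective rules inside every iteration
(clip $W$ at 1; renormalize the columns of $H$), converging when the
relative change of $\lVert V - WH\rVert_F$ falls below 0.01%. The rank is
chosen by Owen–Perry bicrossvalidation: hold out quadrant $A$, fit NMF on
the complementary quadrant $D$, predict
$\hat A = (B H_D^{+})(W_D^{+} C)$, and minimize the mean held-out
Frobenius error over four quadrant rotations. New methylomes are
deconvolved against the (merged, annotated) signature basis by
non-negative least squares; immune enrichment is the summed fraction of
the immune signatures, stratified at the quartiles (high = top quartile
vs intermediate/low) and tested with a log-rank statistic.

A synthetic-data module generates every input with known ground truth —
reference profiles with planted hyper-/hypomethylated marker blocks,
bulk mixtures $V = \mathrm{clip}(WH + \varepsilon)$ with class-conditional
Dirichlet mixing, two-class matrices for forest introspection, and
exponential survival cohorts whose hazard depends on immune fraction — so
the whole pipeline is testable without access-restricted cohorts.

## Worked example

```r
library(stromasig)

W_true <- makeSignatureBasis(240, 3, seed = 1)          # ground-truth basis
mix <- makeBulkMixtures(W_true, 80, rep(1, 3), noiseSd = 0.02, seed = 101)

bcv <- bicrossvalidate(mix$V, 1:5, seed = 11)
bcv
#> BCVResult over k in {1, 2, 3, 4, 5}
#>   selected k = 3
#>   mean held-out errors:
#>      1      2      3      4      5
#> 9.0200 6.6680 1.4632 1.4680 1.4800

fit <- fitNMF(mix$V, selectedK(bcv), seed = 12)
fit
#> NMFFit: 240 probes x 3 components, 80 samples
#>   204 iterations, converged: TRUE (tol 0.0001)
#>   final ||V - WH||_F = 2.74085

dec <- deconvolveNNLS(mix$V, basisMatrix(fit))
round(t(fractions(dec))[1:3, ], 3)
#>          component_1 component_2 component_3
#> bulk_001       0.632       0.205       0.163
#> bulk_002       0.499       0.202       0.299
#> bulk_003       0.094       0.321       0.585
```

The held-out error collapses between ranks 2 and 3 and is flat beyond —
the planted rank is 3, and the tie-break prefers the smaller rank. The
fractions are the per-sample simplex coordinates of each methylome over
the fitted signatures.

Survival stratification on a synthetic cohort whose immune-low stratum
carries a 3-fold hazard:

```r
coh <- makeSurvivalCohort(400, hazardRatioLowVsHigh = 3,
                          baselineRate = 0.1, censorTime = 20, seed = 5)
st <- quartileStratify(setNames(coh$immune_fraction, coh$sample_id))
logrankTest(coh$time, coh$event, st$dichotomous)
#> Log-rank test: chi-square = 62.9 on 1 df, p = 2.179e-15
#>         observed expected
#> int_low      297   224.53
#> high          86   158.47
```

The immune-high quartile experiences far fewer events than expected under
the null — the direction and magnitude a 3-fold hazard ratio produces at
this cohort size.

## Command line

A thin CLI over the same functions supports running the pipeline from a
shell; see `system.file("scripts", "stromasig.R", package = "stromasig")`:

```sh
alias stromasig='Rscript $(Rscript -e "cat(system.file(\"scripts\",\"stromasig.R\",package=\"stromasig\"))")'
stromasig simulate --preset mixtures --out-dir work --seed 17
stromasig bcv --input work/V.tsv --k-min 1 --k-max 4 --seed 17 --out work/bcv.json
stromasig nmf --input work/V.tsv --k 3 --seed 17 --out-prefix work/fit
stromasig signatures --w work/fit_W.tsv --h work/fit_H.tsv \
  --refs work/refs.tsv --ref-labels work/ref_celltype_labels.csv --out-prefix work/atlas
stromasig deconv --input work/V.tsv --basis work/atlas_W.tsv --out work/fractions.tsv
stromasig stratify --fractions work/fractions.tsv --immune-ids S1,S2 \
  --survival work/survival.csv --out-strata work/strata.csv --out-logrank work/logrank.json
```

Subcommands `panel`, `probe-usage`, `correlate` and `separation` cover
probe-panel construction, forest introspection and class-separation
summaries.

## Scope

No IDAT parsing, array normalization or batch correction; no Cox
regression, concordance or Brier scoring; no reproduction of any
proprietary classifier's probe set or calibrated scores. The methods
vignette (`vignettes/methylome-deconvolution.Rmd`) documents the model,
the numerical choices, the synthetic-data design and its limitations.
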