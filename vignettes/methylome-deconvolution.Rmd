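---
title: "Separating tumor and microenvironment signal in bulk methylomes"
author: "stromasig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating tumor and microenvironment signal in bulk methylomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromasig)
```

## The problem

Bulk DNA-methylation arrays measure a mixture. A tumor biopsy contains
neoplastic cells alongside stroma — macrophages and microglia-like cells,
lymphocytes, endothelium, fibroblasts — and each beta value is a
cell-number-weighted average over all of them. Classifiers trained on bulk
beta values therefore inevitably pick up microenvironment signal: a tumor
subgroup that is "immune enriched" may owe part of its epigenetic identity
to the immune cells in it rather than to its neoplastic compartment. This
package implements the analysis toolkit for dissecting that confound:
unsupervised discovery of methylation signatures from bulk methylomes,
their annotation as neoplastic or stromal, per-sample deconvolution,
probe-panel construction, introspection of random-forest classifiers to
quantify which probes drive class separation and in which methylation
direction, and survival stratification by the inferred immune fraction.

Because real diagnostic methylome cohorts are access-restricted, the
package ships a synthetic-data generator that emulates the essential
structure of the problem — convex mixtures of cell-type profiles with
bounded noise and outcome-linked immune fractions — so every stage is
testable against known ground truth.

## The factor model

A beta-value matrix $V$ (probes $\times$ samples, entries in $[0,1]$) is
modeled as

$$V \approx W H,$$

where the columns of $W$ are methylation *signatures* constrained, like
beta values, to $[0,1]$, and the columns of $H$ are per-sample signature
contributions constrained to the probability simplex (non-negative, summing
to 1). Under this parameterization a sample's profile is literally a convex
combination of signature methylomes, which is what cellular mixing
produces.

Fitting uses Lee–Seung-style multiplicative updates with two corrective
rules applied inside every iteration to keep the factors feasible:

1. $W \leftarrow W \otimes (V H^{\mathsf T}) \oslash (W H H^{\mathsf T})$
2. $W[W > 1] \leftarrow 1$
3. $H \leftarrow H \otimes (W^{\mathsf T} V) \oslash (W^{\mathsf T} W H)$,
   using the clipped $W$
4. normalize each column of $H$ to sum to 1

with $\otimes, \oslash$ elementwise. The H-update consumes the clipped
$W$ — the natural reading of the rule order — and every denominator carries
a guard of $10^{-12}$ so zero rows or columns are absorbed rather than
raised. Convergence is declared when the relative change of
$\lVert V - WH \rVert_F$ between consecutive iterations drops below
`tolRel` (default $10^{-4}$, i.e. 0.01%); the iteration cap defaults to
10,000 and hitting it is reported in the fit object, never thrown. Pure
multiplicative updates decrease the objective monotonically; the clip in
step 2 can in principle break monotonicity for an iteration, so the test
suite asserts monotonicity only on runs where the constraint stays
inactive, and asserts eventual convergence everywhere.

Initialization draws $W$ and $H$ entrywise from $U(0,1)$ and normalizes
the columns of $H$; a single integer seed per call makes every fit
reproducible, and no function touches the global RNG state.

## Choosing the number of signatures

The rank $k$ is selected by Owen–Perry bicrossvalidation. Rows and columns
are randomly permuted once and split in half, carving $V$ into quadrants
$A, B, C, D$. The NMF is fit on $D$ alone, and the held-out quadrant is
predicted through the self-consistency identity

$$\hat A = (B\, H_D^{+})\,(W_D^{+}\, C),$$

with $Z^{+}$ the Moore–Penrose pseudoinverse (SVD-based, default
singular-value cutoff). Each of the four quadrants takes the role of $A$
in turn, giving four genuinely disjoint held-out blocks from one
partition; the rank minimizing the mean of the four Frobenius prediction
errors wins, with ties broken toward the smaller (more parsimonious) rank.
An alternative reading — four independent repartitions instead of four
rotations of one partition — is available behind
`method = "repartition"`; rotation is the default because it is the
reading under which the four held-out blocks are "entirely distinct".
Every candidate rank must be at most half the smaller matrix dimension so
quadrant $D$ can support the fit.

## From components to named signatures

NMF components are often split representations of one underlying cell
population. `mergeComponents()` clusters the columns of $W$ by cosine
distance (average linkage) and cuts the dendrogram at an explicit
threshold, defaulting to 0.2. The merged basis column is the unweighted
element-wise mean of its members — the only simple combination that stays
inside $[0,1]$ — and the merged coefficient rows are member sums, the
unique choice that preserves the column-sum-to-1 constraint. The true
merge height is irreducibly a judgment call on real data, so the merge
heights are kept on the object for inspection instead of pretending the
cut is automatic.

`annotateSignatures()` labels each merged signature neoplastic (N) or
stromal (S) by the class of its most similar reference cell-type profile,
comparing by Pearson correlation over shared probes (cosine similarity
available). Ordinal names (N1…, S1…) follow descending mean contribution
when merged coefficients are present. Deconvolution of new methylomes is
plain non-negative least squares against the signature basis
(Lawson–Hanson, via `pracma::lsqnonneg`), with per-sample fractions
normalized to sum to 1; the raw coefficients are retained as well because
normalization is a reporting choice, not part of the estimator. Samples
whose NNLS solution is identically zero are flagged and reported missing
rather than silently assigned uniform fractions.

Class separation in a feature space (for example, signature fractions per
sample) is quantified by mean pairwise cosine distance within and between
classes; the measure is invariant to positive rescaling of any sample
vector, and the diagonal of the between-class matrix equals the
within-class vector by construction.

## Probe panels

Two selectors feed the combined analysis panel. The one-vs-rest selector
runs a two-sided Welch $t$-test per probe between each cell type's
replicates and all remaining reference samples, then keeps — among probes
with $p < 10^{-5}$, uncorrected, as is conventional for this selection
step — up to 500 probes per direction (hyper- and hypomethylated) ranked
by absolute mean beta difference. Welch rather than pooled-variance is
used because reference sets from different sources have no reason to share
a variance. The variance selector simply keeps the `nTop` highest-variance
probes with deterministic tie-breaking by probe id. `combinePanels()` takes
the set union, tagging probes found by both routes.

## Forest probe usage

To ask *which probes a trained random-forest classifier actually uses to
separate classes, and in which methylation direction*, the package trains
an off-the-shelf `randomForest` (the introspection, not the learner, is
the contribution here) with in-bag counts retained, then routes each
tree's in-bag samples through its nodes. An internal node splitting on
probe $p$ counts toward the class pair $(i, j)$ when both classes are
present at the node and their weighted majorities route to opposite
children — the weakest condition under which the split actually
discriminates the pair. The count is stored signed per class: negative
when that class's majority goes to the low-beta ($\le$ threshold) child,
i.e. the probe is hypomethylated for that class at those splits. The
resulting probes $\times$ classes $\times$ classes array is antisymmetric
in sign and symmetric in magnitude; the one-vs-rest summary is the signed
row sum over the partner classes. Counts are summed over the ensemble
without normalizing by tree count. A companion helper correlates probe
methylation with an external per-sample abundance covariate (such as
marker-positive staining area), since "probes used against class X" and
"probes tracking immune content" can then be compared directly.

## Immune fraction and survival

The immune-enrichment score of a sample is the sum of its fractions over
the immune-annotated signatures. `quartileStratify()` splits scores at the
linear-interpolation quartiles: *high* is strictly above Q3, *low* at or
below Q1, *intermediate* otherwise, and the dichotomous grouping pools
intermediate with low. Ties exactly at Q3 fall on the intermediate/low
side — the convention consistent with reporting Q3 itself as a cutoff.
Group survival differences are tested with a standard log-rank statistic
(observed-minus-expected event counts with hypergeometric variance at each
distinct event time, $\chi^2$ on groups − 1 degrees of freedom), written
in-package and cross-checked in the test suite against
`survival::survdiff` to $10^{-8}$.

## What the generator emulates — and what it does not

The synthetic modules produce: reference cell-type profiles as a shared
uniform baseline with disjoint planted blocks of hyper-/hypomethylated
probes per cell type; replicate reference samples with truncated Gaussian
within-type noise; bulk mixtures $V = \mathrm{clip}(W_{\mathrm{true}}
H_{\mathrm{true}} + \varepsilon, 0, 1)$ with class-conditional Dirichlet
mixing weights (one parameter vector per class, so dominant-signature
structure is reproducible by making one component large); two-class
matrices differing only at planted probes for forest introspection; and
exponential survival with administrative censoring, where the hazard of
the immune-low stratum (at or below Q3) is multiplied by a specified
ratio — the minimal model under which the log-rank test has known
behavior. The pre-clip matrix is kept in the emitted truth so noise-level
checks can be recomputed exactly.

Default study conditions used in the tests and the acceptance script:
rank-3 mixtures of 240 probes × 80 samples at beta-scale noise sd 0.02 for
rank selection, 200 × 60 noiseless mixtures for factor recovery, reference
panels of 2,000 probes with 50 planted markers per direction at
$\Delta\beta = 0.4$ and 20 replicates per type (within-type sd 0.05),
two-class forest data with 2 informative probes at $\Delta\beta = 0.6$
and 50 samples per class, and survival cohorts of 200–400 subjects with
hazard ratio 3, baseline rate 0.1 and censoring at 20 time units. Within-type
replicate variance is not described for real purified reference sets, so
the 0.05 default is a design choice of this package, not a claim about any
cohort.

Gaussian noise clipped to $[0,1]$ was chosen over Beta-distributed noise
deliberately: it is simpler, and the clipping mimics how real beta arrays
saturate at the boundaries.

What the generator does *not* emulate: array chemistry (IDAT
intensities, dye bias, batch), realistic probe annotation or genomic
autocorrelation, heavy-tailed or heteroscedastic probe noise, and
cell-type profiles estimated with error. Passing tests demonstrate that
the algorithms recover planted structure under the stated noise model;
they do not certify performance on real cohort data.

## Numerical choices and degenerate inputs

- Denominator guard $10^{-12}$ in all multiplicative updates; degeneracies
  are absorbed, never raised.
- Missing beta values are rejected at load time — imputation belongs to
  upstream normalization, which is out of scope.
- Identifiability: when true signature profiles share a dominant common
  baseline (as the planted reference profiles do), the factorization is
  identifiable only up to mixing of the shared part, even at zero noise —
  reconstruction error goes to zero while the factors rotate. The
  factor-recovery fixtures therefore use an iid-uniform basis
  (`makeSignatureBasis()`), whose columns are mutually near-orthogonal;
  recovery of baseline-dominated profiles is assessed through
  reconstruction and deconvolution error instead.
- Ties: argmin over candidate ranks breaks toward the smaller rank;
  dominant-signature argmax breaks toward the earlier signature; variance
  ranking breaks by probe id; samples tied exactly at Q3 are not "high".
- NNLS with an all-zero solution flags the sample; fractions are `NA`.
- A forest node where a class's samples split evenly between children has
  no majority and does not count for that pair — the original
  node-eligibility rule is not recoverable from published descriptions, so
  the weakest discriminating condition was chosen and documented.

## Worked example

```{r example}
W_true <- makeSignatureBasis(240, 3, seed = 1)
mix <- makeBulkMixtures(W_true, 80, rep(1, 3), noiseSd = 0.02, seed = 101)

bcv <- bicrossvalidate(mix$V, 1:5, seed = 11)
bcv

fit <- fitNMF(mix$V, selectedK(bcv), seed = 12)
fit

dec <- deconvolveNNLS(mix$V, basisMatrix(fit))
mean(abs(fractions(dec) - mix$truth$H)) # close only up to column order
```

## Limitations

The package deliberately stops at the boundaries of the published
analysis it re-implements: no IDAT parsing or normalization, no
batch correction, no Cox modeling or concordance statistics beyond the
log-rank test, no attempt to reproduce any proprietary classifier's probe
set or calibrated scores. The constrained NMF is a local optimizer; runs
from different seeds can land in different optima, and on strongly
collinear bases the components are not uniquely determined. Rank selection
by bicrossvalidation assumes the noise is roughly homoscedastic across the
quadrants, which random row/column permutation encourages but does not
guarantee.
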