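---
title: "Methods: heuristic descriptor selection and GEP symbolic regression for MMP inhibition QSAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heuristic descriptor selection and GEP symbolic regression for MMP inhibition QSAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gepqsar)
```

## The modelling problem

Gelatinases (the matrix metalloproteinases MMP-2 and MMP-9) are
zinc-dependent proteases central to tumour invasion and angiogenesis, and
pyrrolidine derivatives inhibit them.  A QSAR study of 33 such derivatives
modelled the base-10 logarithm of IC50 (molar) from CODESSA-computed
molecular descriptors, with 21 compounds for training and 12 for testing,
by two routes:

1. the **heuristic method (HM)**: rule-based descriptor pre-filtering
   followed by a heuristic best-subset multiple linear regression, which
   settled on five descriptors — LUMO energy (`LUMO`), the minimum C–O bond
   resonance energy (`MRECO`), the third-order Kier shape index (`KSIND`),
   the ZX shadow / ZX rectangle ratio (`ZX`) and the minimum atomic state
   energy for an oxygen atom (`MASEOAT`);
2. **gene expression programming (GEP)**: symbolic regression over the same
   five descriptors with multigenic Karva-notation chromosomes.

The study's per-compound descriptor table was never published, only the
final models, their coefficient table, the descriptor correlation matrix
and summary statistics.  This package therefore implements the full
pipeline, evaluators for both published models, and a synthetic benchmark
generator that reproduces the *statistical structure* the analysis assumes,
so that every stage is testable.

## Ordinary least squares and its vocabulary

`fit_ols()` fits `y ~ descriptors` with an intercept on raw descriptor
values (the CODESSA convention; any scaling is the caller's job) and
reports classical standard errors with `t = coefficient / error`.
`model_stats()` reports

* `R2 = 1 − SSE/SST`,
* `Rcv2` (`Q2`): leave-one-out `1 − PRESS/SST`, computed with the
  hat-matrix identity `e(i) = e_i / (1 − h_ii)` (tested to equal naive
  n-fold refitting to 1e−8),
* `F = (SSR/k)/(SSE/(n−k−1))`, `s = sqrt(SSE/(n−k−1))` (intercept counted
  in the degrees of freedom), and `RMS = sqrt(SSE/n)`.

For test sets the literature's "R2" is ambiguous, so `prediction_stats()`
reports both conventions under distinct names: the squared Pearson
correlation and `1 − SSE/SST` about the identity line.  A leave-one-out
`Rcv2` "for a test set" under a fixed model has no definition and is not
emulated.

## The heuristic method

`hm_prefilter()` applies the four published exclusion rules in order:
(1) descriptors with missing values; (2) descriptors with too little
variation, operationalised as relative standard deviation (sd/|mean|, or sd
when the mean is near zero) below 1e−6 or fewer than 4 distinct values;
(3) one-parameter regression F below 1.0; (4) one-parameter |t| below a
user-defined threshold, default 1.5 (the method leaves this value open).
`hm_fit()` then searches subsets of survivors under the collinearity
constraint that no two descriptors with |r| ≥ 0.8 enter the same model.

The original software's "rapid screening" is undocumented, so the search
here is a deterministic beam search (default width 10), seeded by the
one-parameter R2 ranking and expanding each beam member by every admissible
survivor; ties in R2 break lexicographically by descriptor name.  On pools
of up to a dozen survivors and subset sizes up to three it provably matches
exhaustive enumeration (tested), and `search = "exhaustive"` is available
for small pools.  Model growth follows the published descriptor-count
standard: accept size k+1 only if the best (k+1)-descriptor model gains at
least 0.02 in R2 and does not lose leave-one-out Q2.

## The GEP engine

Chromosomes carry 5 genes linked by addition.  Each gene is a Karva string:
a head of 8 symbols over functions and terminals, a tail of 9 symbols over
terminals only (tail = head × (max arity − 1) + 1, which guarantees every
gene decodes), and a Dc domain of 9 indices into 10 per-gene random
numerical constants drawn uniformly from [−10, 10] — gene length 26.
Decoding is breadth-first: symbols are read left to right and children are
assigned level by level, trailing symbols staying noncoding; `?`
placeholders consume Dc indices in reading order.  The inner
decode-and-evaluate loop is implemented in C++ (with `R_pow` for exact
agreement with R's `^`); an independent recursive pointer-tree evaluator in
the test suite checks it on a thousand random chromosomes to 1e−12.

The operator suite and rates follow the study's parameter table: point
mutation 0.044 (per symbol; a mutated position resamples a *different*
symbol from its positional alphabet, so the configured rate equals the
expected changed-symbol fraction, which is verified empirically over 1e5
symbols), head-segment inversion 0.1, IS and RIS transposition 0.1, gene
transposition 0.1, one- and two-point recombination 0.3, gene
recombination 0.1, Dc mutation 0.044, Dc inversion 0.1, Dc IS
transposition 0.1 and RNC mutation 0.01.  Selection is roulette-wheel with
single-elite cloning; a try stops after 200 generations without
improvement (or a hard cap, default 2000) and the best of 3 independent
tries is returned.  Transposon lengths are drawn from 1–3; in the
flattened-chromosome recombinations, whole genes beyond a cut swap their
constants with them while a split gene keeps each parent's constants.

Two fitness functions are provided.  The relative-error form sums
`max(0, R − |100 (P − T)/T|)` over fitness cases (maximum R × n; the
per-case floor at zero keeps totals non-negative for roulette selection,
and the traditional name "absolute-error fitness" notwithstanding, the
published formula scores *relative* error and is implemented as printed).
The MSE form is `1000/(1 + MSE)`; the normalisation constant is this
package's documented choice, since the commercial package leaves it
unstated.  Arithmetic is protected in the classic GEP sense: division by
zero, logarithms and square roots of non-positive arguments, and invalid
powers produce IEEE non-finite values that propagate, and any non-finite
chromosome output maps to fitness 0 (alive but unselectable).  The
"maximum complexity" parameter of the commercial package has no defined
semantics here; it is accepted in `gep_config()` and ignored.

## The synthetic benchmark

`make_benchmark()` generates the study conditions: 21 + 12 compounds, five
Gaussian descriptors with the published inter-correlation matrix, activity
from the published regression coefficients plus Gaussian noise with
sd 0.23 (the study's reported model standard error), and decoy descriptors
that trip each pre-filter rule (a missing-value column, a near-constant
column, pure-noise columns) and the collinearity cap (a true descriptor
plus noise at 0.2 of its sd, |r| ≈ 0.97 with its parent).  One root seed
drives derived sub-streams per stage, so a benchmark is reproducible as a
whole.

Two generator choices deserve emphasis.

**The printed correlation matrix is indefinite** (smallest eigenvalue
−0.055, far beyond rounding noise — a genuine correlation matrix of real
descriptor vectors is positive semidefinite by construction, so the
printed table very likely carries a typo; note its two identical entries
0.3261).  `repair_correlation()` clips eigenvalues and rescales to unit
diagonal, iterated to convergence.  The floor default is 0.05 rather than
a token 1e−6: with a near-zero floor the repaired matrix is numerically
singular, every descriptor's conditional variance collapses, and no
descriptor retains unique explanatory power — which would make the
descriptor-count standard meaningless in the benchmark.  The repaired
matrix sits within 0.05 per entry of the printed one.

**Descriptor locations and scales were never published.**  They matter: the
standardised effect of descriptor j is (slope × sd), so the sds decide how
explanatory power distributes.  The defaults were fixed once, by a design
study, to maximise the smallest population-level R2 increment along the
best-model-per-size chain (the quantity the 0.02 stopping standard cuts
on); the optimum is about 0.029.  The means just place the simulated
log(IC50) near −5.  The generator emulates Gaussian descriptors with the
published second-order structure; it does not emulate the physical meaning,
boundedness or skewness of real CODESSA descriptors, so passing recovery
tests demonstrate correctness of the selection machinery, not performance
on real descriptor tables.

## What the published structure makes impossible

A reader should know that one natural expectation fails *by construction*.
One might expect the heuristic search to re-select exactly the five
generating descriptors in nearly every 21-compound replicate.  It cannot:

* The marginal correlation vector of the five descriptors with activity is
  `rho = C beta`, where `C` is the (repaired) published correlation matrix
  and `beta` the standardised slopes, whose *signs* are fixed by the
  published coefficients.  Maximising the weakest `|rho_j|` over all
  admissible scales yields only ≈ 0.36 — `MRECO` in particular acts as a
  suppressor variable whose marginal correlation is structurally near
  zero.  (Even with *independent* descriptors the budget
  `rho' C^{-1} rho ≤ 1` caps five equal marginals at 1/sqrt(5) ≈ 0.45.)
  At n = 21, rule 3 alone (one-parameter F ≥ 1, i.e. |r| ≥ 0.224) then
  excludes at least one true descriptor in most samples, and rule 4 at its
  1.5 default excludes more.
* Independently, the 0.02 increment standard is noisy at n = 21: the
  best achievable population increment (≈ 0.029) is within sampling error
  of the threshold, so growth stops below five descriptors in many
  replicates even with the pre-filter disabled (measured ≈ 14% exact
  recovery across seeds; 0% with the default pre-filter).

Both bottlenecks follow from printed quantities — coefficient signs, the
correlation table, n = 21, the published thresholds — not from
implementation choices, and the corresponding whole-pipeline recovery
expectation in the acceptance suite is deliberately left failing, with
this analysis as its explanation.  The machinery itself is verified by the
oracle-agreement and fixed-seed noiseless-recovery tests, which relax the
one-parameter thresholds to exercise search and stopping logic in
isolation.

## The published models

`predict_mmp_hm()` evaluates the published linear model; both printed
coefficient variants are retained (`"equation"`, the default, and
`"table"`, which differs in the fifth decimal of the MASEOAT slope and is
the pair consistent with the printed standard errors).  `mmp_hm_ttests()`
recomputes every Student t from the printed coefficient/error pairs; four
of six match the printed t values to 4 decimals, the intercept and KSIND
to 1.5e−4 (their printed values carry one more rounding step).
`predict_mmp_gep()` evaluates the published GEP expression with its evolved
constant −7.653931 as printed; non-finite outputs (for example a negative
radicand in the fifth gene for small KSIND) are flagged, not masked.  The
study's headline fit statistics (train R2 0.93/0.94 etc.) are *not*
reproduction targets: they depend on the unpublished per-compound table.
The anomalous printed test-set figures (a test "Rcv2" for a fixed model;
a GEP test s of 3.95 against test R2 0.81, consistent with non-finite or
extreme predictions for some test compounds) are likewise documented but
not emulated.

## Problem sizes and numerical choices

The test and acceptance runs use deliberately modest sizes chosen as
adequate for their purpose: correlation convergence at n = 1e5 (tolerance
0.02), oracle agreement on 1e3 random chromosomes and 1e5 fuzzed genes,
recovery sweeps over 20 seeds, planted-function GEP runs at n = 100 with
tries capped at 200 generations, and mutation calibration over ≈ 1e5
symbols.  Ties in subset search break lexicographically; all randomness
flows from a single integer seed through labelled sub-streams; JSON
artifacts are written without timestamps so reruns are byte-identical.

## Known limitations

* The benchmark's Gaussianity is an assumption, not a published fact.
* The beam search is an oracle-checked approximation of an undocumented
  commercial heuristic; its per-size optima can in principle miss the true
  best subset for sizes above the exhaustively verified range.
* GEP runs are CPU-bound; the defaults (population 100, 2000-generation
  cap, 3 tries) suit a workstation, and planted-function experiments in
  this package cap generations at 200.
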