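---
title: "Bootstrap PLS-DA biomarker selection on fused biofluid blocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrap PLS-DA biomarker selection on fused biofluid blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plsdafuse)
```

## The problem this package addresses

Clinical metabolomics studies frequently profile the same patients in
several biofluids — here serum, urine and exhaled breath condensate (EBC) —
and ask which metabolites discriminate two diagnostic groups (the motivating
design contrasts chronic obstructive pulmonary disease, COPD, with the
obstructive sleep apnea syndrome, OSAS). Univariate screening followed by a
multivariate classifier selects variables outside the model that ultimately
uses them; `plsdafuse` instead performs the selection *inside* the
discriminant model, with a bootstrap wrapped around the whole fit so that
both the selection and the quality estimate carry uncertainty from the
sampling of patients.

The workflow is: low-level fusion of the biofluid blocks (column
concatenation), a balanced model/test partition by the Kennard–Stone
algorithm run per group, bootstrap PLS-DA with per-replicate complexity
selection, variable selection by bootstrap-averaged VIP scores (iterated)
or selectivity ratios (single pass with a DIVA-derived cut-off), and a
final model evaluated on the untouched test set.

## Model and procedure

### PLS-DA

The two classes are coded $y_i \in \{-1, +1\}$ (the larger cohort is coded
$+1$, by convention the positive class for sensitivity). After autoscaling
each variable on the model set, NIPALS PLS1 extracts $A$ latent components:
for component $a$, the weight vector $w_a \propto X_{a-1}' y_{a-1}$
(unit norm), scores $t_a = X_{a-1} w_a$, X-loadings
$p_a = X_{a-1}' t_a / t_a' t_a$ and y-loading
$q_a = y_{a-1}' t_a / t_a' t_a$, followed by deflation of both $X$ and $y$.
The regression vector of the $A$-component model is
$b = W (P' W)^{-1} q$, a new sample is scored as $\hat y = x_s' b$ on the
autoscaled scale, and classified against the cut-off $0$ — the natural
threshold for a *balanced* model set, which is why the model set is forced
to equal group sizes. A score exactly on the cut-off goes to the
negative-coded class (a documented tie rule, relevant only for degenerate
models).

Model complexity $A$ is chosen by leave-one-out cross-validation on the
misclassification rate, with the autoscaling refit inside every fold and
ties broken toward the smaller $A$ (parsimony). The cap is $A_\max = 5$ by
default — beyond that, models of this sample size are dominated by noise.

### Variable importance in projection (VIP)

$$\mathrm{VIP}_j \;=\; \sqrt{\,p \cdot \frac{\sum_a \mathrm{SSY}_a\, w_{ja}^2}
{\sum_a \mathrm{SSY}_a}}\,,$$

where $p$ is the number of variables and $\mathrm{SSY}_a = q_a^2\, t_a' t_a$
is the response sum of squares explained by component $a$ (taken from the
y-deflation step). The mean of the squared VIPs is exactly 1, which anchors
the customary cut-offs: 1 is "influential", 0.8 the laxer default used
here.

### Target projection and the selectivity ratio (SR)

The $A$-component model is collapsed onto its single predictive direction
$w_{TP} = b / \lVert b \rVert$; scores $t_{TP} = X w_{TP}$ and loadings
$p_{TP} = X' t_{TP} / t_{TP}' t_{TP}$ decompose each variable's sum of
squares into an explained part $(t_{TP}' t_{TP})\, p_{TP,j}^2$ and a
residual, and

$$\mathrm{SR}_j = \frac{\text{explained}_j}{\text{residual}_j}.$$

Two design points deserve note. First, the projection is applied to the
raw autoscaled $X$ rather than to the $A$-component reconstruction
$T P'$: the reconstruction has rank $A$, so for a single-component model
its residual after target projection is *identically zero* for every
variable and all ratios blow up — and single-component replicates are
common inside the bootstrap. The raw-$X$ form is the standard selectivity
ratio, is defined at any complexity, and for $A = 1$ coincides with the
explained/residual ratio of the single component. The reconstruction-based
variant remains available via `reconstructed = TRUE` for sensitivity
analyses. Second, a residual below $10^{-12}$ of a variable's total sum of
squares yields `Inf`, which sorts above all finite ratios; such variables
are always retained by SR selection.

### Bootstrap engine

Each of the $B$ replicates (1000 by default; simulations in the test suite
use 100–200) resamples the model set **with replacement within each
group**, so no replicate ever loses a class and the balanced design is
preserved. Autoscaling is refit on each resample (leakage-safe; a
`refit_scaling = FALSE` flag reuses the model-set scaling), the complexity
is re-selected by LOO inside the replicate, and the AUC of the fitted model
is recorded on the **out-of-bag** samples — the model-set samples the
replicate never drew. Replicates whose out-of-bag set would miss a whole
group are redrawn and counted. The spread of the replicate AUCs
$\theta^*_i$ is summarised by

$$\mathrm{se}_b = \sqrt{\frac{\sum_{i=1}^{b}(\theta^*_i - \bar\theta^*)^2}{b-1}},$$

the sample standard deviation of the bootstrap estimates.

Out-of-bag evaluation is the defensible default but is known to be
*pessimistic* for weak signals: the in-bag and out-of-bag chance group
differences are anti-correlated (the group totals are fixed), so under a
label permutation the mean out-of-bag AUC settles slightly below 0.5
(around 0.41–0.45 at the cohort sizes exercised in the tests) rather than
exactly at chance. An in-bag variant (`oob = FALSE`) is available; it is
optimistic in the opposite direction and is not used by default.

### Selection procedures

*VIP selection* runs the bootstrap, averages the VIP profile over
replicates, drops every variable below the cut-off (default 0.8), and
repeats the whole procedure on the survivors — three rounds by default,
since a single pass tends to leave many weakly-contributing variables.
Rounds stop early when nothing is dropped or fewer than two variables
remain; dropping everything raises an error suggesting a lower cut-off.

*SR selection* is a single bootstrap pass retaining variables whose
average SR clears the cut-off. When no cut-off is given it is derived from
the discriminating-variable (DIVA) test: variables are binned into
equal-width intervals of average SR, each variable is used as a univariate
optimal-threshold classifier evaluated over seeded stratified train/test
half-splits, and the mean correct classification rate (MCCR) per interval
is computed. The proposed cut-off is the lower edge of the first interval
whose MCCR exceeds 60% — a threshold mirroring the 60–62% rates that make
such models practically useful — falling back to the best interval's lower
edge when none qualifies (as happens for pure noise). The exact DIVA
evaluation protocol is not standardised in the literature the method comes
from, so it is explicit, seeded and configurable here
(`intervals`, `reps`, `threshold`).

Under pure noise the MCCR profile is flat near 50% only in large cohorts:
SR binning sorts variables by their accidental group difference, so in
small cohorts the top intervals systematically collect the luckiest noise
variables and sit a few points above 50%. The flatness check in the test
suite therefore uses 200 samples per group.

### Splitting

The Kennard–Stone algorithm (max–min Euclidean distance, first pick = the
mutually most distant pair) is applied separately to each group on that
group's autoscaled fused data; `floor(fraction × min(group sizes))`
samples per group form the model set (0.75 of 18 gives 13 in the reference
design: 13+13 model, 15+5 test). Distance ties break toward the lowest row
index so the split is fully deterministic. Whether the autoscaling feeding
the distance matrix should be fit per group or globally is ambiguous in
the source methodology; per group is the default and `scale_scope =
"global"` the alternative.

## The synthetic cohort generator

No real cohort ships with the package, so every stage is exercised against
`synthetic_spec()` / `generate_cohort()`. The generator emulates the
reference study design: 18 vs 28 samples, three blocks of 16 (EBC), 31
(serum) and 27 (urine) metabolites. Concentrations are log-normal —
metabolite levels are positive and right-skewed — with a per-variable
baseline drawn once from a common abundance range, log-scale standard
deviation `noise_sd = 0.5` (a coefficient of variation around 50%,
typical of biological metabolite panels), and within-block equicorrelation
`correlation = 0.3` induced by a shared latent factor per sample and
block (a moderate shared-physiology correlation; the source data report no
correlation estimates, so this is a stated assumption, not a reproduced
fact). Blocks are mutually independent by default. Planted group effects
are added to the second group's log-mean in units of the pooled log-scale
SD, so effect sizes are directly comparable to the autoscaled modelling
scale.

What the generator does **not** emulate: spectral physics (no multiplets
or chemical-shift variation — spectrum fixtures are a fixed peak template
times a per-sample dilution factor times optional point noise), missing
values, batch effects, or realistic inter-block correlation. Passing tests
therefore demonstrate the correctness and calibration of the *procedure*,
not clinical performance on real patients.

`generate_spectra()` produces the dilution fixtures used to test
probabilistic quotient normalization (PQN): PQN first normalizes every
spectrum to a common total integral, takes the pointwise median spectrum
as reference, and divides each spectrum by the median of its pointwise
quotients against that reference (the standard dilution-correction
dialect). Equal-width binning is anchored at the maximum ppm of the axis,
keeps the last partial bin, and conserves the total integral exactly.

## Numerical choices

- Autoscaling uses the $n-1$ standard deviation; a zero-variance variable
  on fit is an error naming the variable. A variable constant within a
  bootstrap or LOO training fold (but not in the full model set) is mapped
  to zero rather than rescaled, which keeps the fit defined without
  inflating its weight.
- NIPALS stops early when the residual covariance vanishes
  ($\lVert X'y \rVert < 10^{-12}$); requesting more components than the
  rank of $X$ is an error at the user level, while internal LOO/bootstrap
  fits simply cap at the attainable rank.
- LOO complexity uses the first minimum of the error curve (smallest $A$).
- All bootstrap and half-split indices are drawn on the R side from the
  user-supplied seed; the compiled core is purely deterministic given
  those indices, so runs are bit-reproducible.

## Problem sizes used by the test suite

The packaged simulations are sized to make their statistical claims
decisive while staying desk-scale: recovery of five planted biomarkers
(1.5 SD) uses 60 + 60 cohorts, their 45 + 45 Kennard–Stone model sets,
$B = 100$ bootstrap replicates and 100 repetitions; null calibration of
the generator uses 500 cohorts; the permutation null uses $B = 200$. The
headline clinical results of the motivating study are not reproducible
targets because its NMR data are not deposited; the suite instead verifies
the in-design combinatorial facts (split sizes 13+13 / 15+5, selection
overlap counts), the analytic identities (mean squared VIP = 1, the
$b-1$ bootstrap standard error, Mann–Whitney AUC, explained + residual
conservation under target projection), and the simulation properties
above.

## Known limitations

- OOB AUC pessimism under weak signal (discussed above); comparisons
  between in-bag and out-of-bag summaries should not mix the two.
- The DIVA/MCCR cut-off depends on the interval count when variables are
  sparse; the implementation reduces the interval count with a message
  rather than failing.
- PLS1 with a single response assumes exactly two classes; no multi-class
  extension, no OPLS, no sparse/kernel PLS.
- Fusion is low-level only (concatenation before a single autoscaling);
  mid- or high-level fusion schemes are out of scope.

## A minimal run

```{r example, eval = FALSE}
spec <- synthetic_spec(planted = c(serum__v5 = 1.5, urine__v7 = 1.5),
                       seed = 42)
report <- run_pipeline(list(spec = spec, criterion = "both",
                            B = 200, seed = 42))
print(report)
```
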