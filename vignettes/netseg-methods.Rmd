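---
title: "netseg: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{netseg: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netseg)
```

## The scientific problem

Large-scale functional brain networks are modular: nodes cluster into
systems (visual, somato-motor, default, frontoparietal, ...) whose
within-system resting-state correlations exceed their between-system
correlations. *Brain system segregation* summarizes this modularity for
one subject as

$$ S \;=\; \frac{\bar{Z}_w - \bar{Z}_b}{\bar{Z}_w}, $$

where $\bar{Z}_w$ is the mean Fisher-z correlation over all
within-system node pairs and $\bar{Z}_b$ the mean over all
between-system pairs. $S = 1$ when every system is disconnected from
every other; $S = 0$ when the two means coincide. Both aging and
dementia severity are associated with lower segregation, but through
dissociable routes: aging weakens *within-system* coupling of
*association* systems, whereas dementia severity (Clinical Dementia
Rating, CDR) strengthens *between-system* coupling and affects systems
of both processing types. `netseg` implements the full analysis chain
needed to measure and test this dissociation, plus a synthetic cohort
generator so the chain is verifiable without access to restricted
clinical data.

## Two readings of the statistic

The global statistic pools node pairs: every within-system pair
contributes equally to $\bar{Z}_w$, so large systems dominate. The
system-type variant (`system_type_segregation()`) instead computes, for
each system $s$ of a type, its mean within-system correlation $W_s$ and
its mean correlation to all other systems $B_s$, and takes *grand means
across systems*: $(\bar{W_s} - \bar{B_s}) / \bar{W_s}$. For unequal
system sizes the two readings differ; both appear in the field's usage
and both are implemented as separate, separately tested code paths.
`mean_interactions()` returns the grand means themselves — the outcome
pair used in the interaction-type analysis. $B_s$ for a system includes
pairs to systems of the *other* type as well, by definition.

Systems typed `"unassigned"` are excluded from every pool. Undefined
blocks (one-node systems) propagate as `NA`, never as zero.

## The denoising chain

The chain runs in a fixed order, enforced by a stage marker on the
time-series object: (1) per-node demean/detrend; (2) multiple regression
on the nuisance set — global signal, white-matter and ventricle
surrogates, their backward differences, and the Friston-24 motion set
(6 rigid-body parameters, their differences, and both squared);
(3) scrubbing: frames with framewise displacement FD > 0.3 mm are
censored and linearly interpolated from flanking clean frames;
(4) zero-phase 0.009–0.08 Hz bandpass; (5) removal of the interpolated
frames. Subjects with fewer than 100 clean frames are excluded (a
verdict, not an error); survivors contribute exactly their first 100
clean frames, controlling for variable scan lengths.

Numerical choices:

* **FD** is the Power-style sum of absolute backward differences, with
  rotations converted at a 50 mm head radius. The source analysis names
  the threshold but not the formula; this is the field's standard.
* **Regression timing.** The printed step order puts regression before
  scrubbing, but high-motion frames should not drive nuisance fits:
  coefficients are estimated on non-censored frames only and residuals
  computed for all frames, so interpolated frames stay consistent
  through filtering.
* **Interpolation** is linear (the source says "interpolating" without a
  method; spectral interpolation is a known alternative and out of
  scope).
* **Filter.** Second-order Butterworth high- and low-pass biquads
  (bilinear transform, $Q = 1/\sqrt2$), each applied forward-backward
  for zero phase with 24-sample odd-reflection padding. The cascaded
  amplitude response is ≥ 0.9 inside the band and ≤ 0.1 one octave
  outside; both bounds are asserted by tests against sinusoidal probes.
  No installed package provides an IIR filter design, so the ~40-line
  implementation is local and oracle-tested.
* Degenerate nuisance columns (zero variance, duplicates — e.g. the 24
  motion terms of a motionless subject) are dropped with a warning
  rather than failing.

## Network construction

Node time series (averaged from member signals where applicable) are
pairwise Pearson-correlated, Fisher z-transformed with $r$ clipped to
$|r| \le 1 - 10^{-7}$ (keeps duplicated signals finite), negatives set
to zero (global signal regression induces spurious negative
correlations), and the diagonal held out structurally as `NA` so no
averaging step can touch self-correlations. No edge-density
thresholding is applied — the segregation statistic does not need a
sparse graph.

## The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` draws covariates matching the target population:
age truncated-normal 74.70 ± 8.11 on 55–96 years, CDR ∈ {0, 0.5, 1, 2}
with probabilities 0.5424 / 0.3661 / 0.0732 / 0.0183 (the observed
group sizes; the published table pools CDR 1–2, so the 4:1 split within
that pool is our choice), 53.24% female, education 16.5 ± 2.45 years,
and optional pulse/respiration channels. One master seed spawns an
independent stream per subject, so growing a cohort never reshuffles
earlier subjects.

Each subject's generating correlation matrix is block-constant on a
configurable partition (default: 120 nodes, 10 unequal systems — 6
association, 4 sensory-motor), built on the Fisher-z scale and mapped
through `tanh`:

* within-system z: baseline 0.6, lowered by age (−0.004/yr, association
  systems only, centred at age 74.7) and by CDR (−0.03/unit, both
  types);
* between-system z: baseline 0.15, raised by CDR (+0.04/unit).

Effects are injected *linearly on the z scale* — the simplest structure
compatible with the linear models downstream. The source reports effect
directions and standardized sizes, not z-scale slopes; these defaults
are chosen once for detectability at n ≈ 300 and are not estimates of
the published coefficients. If modulation ever made the matrix
indefinite it is repaired by eigenvalue clipping at zero with
renormalized unit diagonal (block-constant matrices with injected
effects can go slightly indefinite; at the defaults the repair is a
no-op).

Signals are zero-mean multivariate normal draws from the generating
matrix plus i.i.d. sensor noise (SD 0.5), which attenuates observed
correlations uniformly. Motion is Gaussian parameter jitter tuned to a
baseline mean FD ≈ 0.15 mm plus spike contamination: with per-frame
probability 0.03 + 0.08·CDR, a 1 mm translation excursion (FD ≫ 0.3 on
the spike frame *and* the return frame, so one spike censors about two
frames) and a shared additive artifact across all nodes. At these
rates a CDR-2 subject loses ≈ 34% of a 140-frame run and about half of
the CDR-2 group fails the 100-clean-frame rule — reproducing,
qualitatively, the observation that QC exclusion tracks dementia
severity. The jitter SD is an explicit parameter so the fully still
subject (FD ≡ 0) remains expressible.

What the generator does **not** emulate: spatial structure within
nodes (no image synthesis — simulation starts at node signals),
heteroscedastic or autocorrelated BOLD noise, physiological
oscillations, scanner drift beyond a linear trend, real atlas geometry,
and any amyloid/APOE biology. A green test therefore establishes that
the *pipeline machinery* is correct and that the *inferential layer*
recovers known injected effects — not that the published coefficient
values are reproduced, which would require the restricted cohort.

## Inference

`fit_ols()` mirrors the primary models: outcome on age and CDR
(continuous, raw values — a categorical variant via `cdr_category()`
collapses 1 and 2), controlling gender, post-scrubbing mean FD and
education; partial $r = t/\sqrt{t^2 + \mathrm{df}}$. The within-subject
contrasts (system type; interaction type) use `lme4` random-intercept
models with the staged scheme: a three-way age × CDR × condition model,
then two two-way models each controlling the other focal variable.
With two condition rows per subject a random slope is not identifiable
separately from the residual, hence intercept-only. p-values use
containment (between-within) degrees of freedom — Satterthwaite
machinery is deliberately not a dependency — and marginal/conditional
R² follow the variance-partition formulas
$R^2_m = \sigma^2_f / (\sigma^2_f + \sigma^2_u + \sigma^2_e)$,
$R^2_c = (\sigma^2_f + \sigma^2_u) / (\sigma^2_f + \sigma^2_u + \sigma^2_e)$.

The block tests regress each system-by-system block mean on CDR with
all covariates, and assess significance by permutation (N = 1000 in the
reference setting). The source says labels were shuffled "controlling
for all covariates" without naming a scheme; we use **Freedman–Lane**
residual permutation — residualize the outcome on covariates, permute
those residuals, refit the full model — the standard way to honor
covariates under the null. The two-sided p uses the +1 correction, so
its floor is $1/(N+1)$. Flags are reported at p < 0.05 uncorrected and
after Benjamini–Hochberg FDR across the tested family, which we take to
be all $S(S+1)/2$ unique blocks of one focal variable's scan (the
family is not stated in the source; it is configurable by subsetting
the block table).

## Validation strategy and scaling

Every operation is tested against independent brute-force oracles
(explicit pair enumeration for the segregation family; normal-equations
solves for the regressions; sinusoid probes for the filter). Two
replicate studies validate the whole stack statistically:

* **Calibration** — 500 null cohorts (all slopes and spike rates zero,
  n = 150), permutation test with 200 permutations on all 55 blocks:
  the pooled uncorrected rejection rate must sit at 5% ± 2%, and
  $P(p \le \alpha) \le \alpha + 0.02$ for $\alpha \in \{0.01, 0.05\}$.
* **Dissociation recovery** — 50 cohorts of n = 300 at the default
  slopes: negative and significant age effect on association-system
  segregation, non-significant age effect on sensory-motor segregation,
  positive and significant CDR effect on mean between-system
  interactions, in ≥ 90% of replicates; the age × system-type
  interaction is likewise detected in ≥ 90%.

Both studies generate each subject's connectivity through
`simulate_connectivity()` — multivariate-normal frames from the
generating matrix, then the standard matrix construction — rather than
the full motion chain: under the calibration null the spike rates are
zero so denoising is an expensive identity, and the recovery study
measures effect transmission, which motion handling (tested end-to-end
elsewhere, including a deliberately contaminated pipeline run) does not
alter. This keeps the suite inside a single-CPU budget.

One behaviour worth knowing: global signal regression in the full chain
lowers between-system correlations relative to the generating matrix
(its textbook effect), so pipeline segregation values exceed the
noise-free oracle of the generating matrix. More consequentially, the
generator injects the CDR between-system effect as a *near-uniform*
elevation of all between-block correlations — which is essentially a
global component, exactly what GSR removes. Through the full chain the
CDR → between-system effect is therefore strongly attenuated, while
the age → association-within effect (block-specific, not global)
passes through intact. Real cohorts show the CDR effect despite GSR
because empirical between-system elevation is spatially structured
rather than uniform; reproducing that would need within-block
heterogeneity in the generator. Oracle-equivalence and effect-recovery
checks are accordingly asserted on the no-GSR path, and the full chain
is checked for the age dissociation and for machinery correctness.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(n_subjects = 60, seed = 7, n_perm = 200,
                       write_intermediate = FALSE)
report <- run_pipeline(cfg, out_dir = "netseg_out")
print(report)
```

## Known limitations

* Block-constant generating matrices are an idealization; real
  connectomes have within-block heterogeneity and hubs.
* Containment df are approximate (exact for balanced two-level
  designs, which is the case here, but not in general).
* The permutation test assumes exchangeable covariate-adjusted
  residuals; heavy heteroscedasticity across CDR groups would erode its
  exactness.
* Linear interpolation of censored frames slightly damps high-frequency
  content next to spikes; spectral interpolation would be the upgrade
  path.
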