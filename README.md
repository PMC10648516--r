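# netseg

Resting-state functional connectivity analysis of **brain system
segregation** in aging and dementia cohorts, as a tested, reusable R
pipeline: BOLD denoising and motion scrubbing, Fisher-z connectivity
matrices, the segregation statistic with system-type and block
decompositions, and a covariate-controlled inferential layer (multiple
regression with partial *r*, random-intercept mixed models,
Freedman–Lane block permutation tests, FDR/Bonferroni corrections). A
synthetic cohort generator with block-structured covariance and
CDR-linked motion-spike contamination stands in for restricted-access
clinical data, so every stage is verifiable end to end on one machine.

## The statistic

For one subject, with node pairs labelled within- or between-system by
a partition of nodes into functional systems,

    S = (Z̄w − Z̄b) / Z̄w

where `Z̄w` is the mean Fisher-z correlation over all within-system
node pairs and `Z̄b` over all between-system pairs. `S = 1` for fully
disconnected systems, `0` for no modular differentiation. A system-type
variant uses grand means of per-system means (association vs
sensory-motor systems), and `S × S` block matrices carry the
system-pair resolution used by the permutation tests. The scientific
target phenomenon is a dissociation: age lowers within-system coupling
of association systems, while dementia severity (CDR) raises
between-system coupling across system types.

## Worked example

```r
library(netseg)
cfg <- pipeline_config(n_subjects = 60, seed = 7, n_perm = 200,
                       write_intermediate = FALSE)
report <- run_pipeline(cfg, out_dir = "netseg_out")
print(report)
#> netseg run report (seed 7 )
#>   subjects: 60 simulated, 0 excluded by QC, 60 analyzed
#>   age -> association segregation:    beta -0.00130 (p 0.000129)
#>   age -> sensory-motor segregation:  beta +0.00021 (p 0.497)
#>   cdr -> mean between-system z:      beta +0.00022 (p 0.827)
```

Reading the report: association-system segregation declines with age
(negative beta, significant) while sensory-motor segregation shows no
age effect — the injected age dissociation, recovered through the full
simulate → denoise → network → segregate → analyze chain. The CDR
effect on between-system connectivity is absorbed here by global
signal regression: the generator injects it as a near-uniform
elevation, which is exactly the component GSR removes (see the methods
vignette); the replicate studies recover it on the no-GSR path.
`netseg_out/` holds the plain-TSV/JSON artifacts of every stage
(`covariates.tsv`, `qc_report.tsv`, `segregation.tsv`, `blocks.tsv`,
`run_report.json`).

A thin command-line front end with `simulate`, `denoise`, `netbuild`,
`segregate` and `run` subcommands is installed at
`inst/cli/netseg.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch with the installed package, the analytic
acceptance quantity: the global segregation of a fully disconnected
modular network (a 12-node, 3-system block-diagonal connectivity
matrix), built through the package's own constructors and statistic,
and writes it as JSON.

## Package layout

- `R/partition.R`, `R/synthetic.R` — system partitions; cohort,
  covariance and time-series generators with ground truth.
- `R/denoise.R` — FD, nuisance design (GSR + Friston-24), ordered
  detrend/regress/scrub/bandpass/trim/QC chain.
- `R/netbuild.R`, `R/segmetrics.R` — connectivity matrices; global,
  system-type, interaction-mean and block-level segregation.
- `R/stats.R`, `R/replicate.R` — OLS with partial *r*, mixed
  interaction models, Freedman–Lane block permutation, corrections;
  calibration and power replicate studies.
- `R/pipeline.R` — configuration, orchestration, machine-readable run
  reports.
- `vignettes/netseg-methods.Rmd` — models, assumptions, parameter
  defaults and design choices.
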