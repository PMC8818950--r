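# mrpipe

Two-sample Mendelian randomization (MR) from GWAS summary statistics, as a
single reusable R package.

## The problem

Observational associations between an exposure (say, a genetic predisposition
to a cancer) and an outcome (say, severe COVID-19) are confounded. MR treats
genetic variants as instrumental variables: a SNP robustly associated with the
exposure, independent of confounders, and affecting the outcome only through
the exposure supports a causal-effect estimate. In the *two-sample* design the
SNP–exposure and SNP–outcome associations come from different GWAS cohorts and
are combined purely at the summary-statistic level.

For harmonized instruments *j* with exposure effects &beta;&#x302;<sub>Xj</sub>
(se &sigma;<sub>Xj</sub>) and outcome effects &beta;&#x302;<sub>Yj</sub>
(se &sigma;<sub>Yj</sub>), the package computes:

- per-SNP **Wald ratios** &beta;&#x302;<sub>Yj</sub>/&beta;&#x302;<sub>Xj</sub>
  with first-order variance &sigma;<sub>Yj</sub>²/&beta;&#x302;<sub>Xj</sub>²;
- the pooled fixed-effect **IVW** estimate
  &theta;&#x302; = &Sigma;<sub>j</sub> &beta;&#x302;<sub>Yj</sub>&beta;&#x302;<sub>Xj</sub>&sigma;<sub>Yj</sub>⁻² / &Sigma;<sub>j</sub> &beta;&#x302;<sub>Xj</sub>²&sigma;<sub>Yj</sub>⁻²,
  se(&theta;&#x302;) = (&Sigma;<sub>j</sub> &beta;&#x302;<sub>Xj</sub>²&sigma;<sub>Yj</sub>⁻²)<sup>−1/2</sup>
  (a multiplicative random-effects variant is available);
- **MR-Egger** (weighted regression with a free intercept estimating average
  directional pleiotropy), the **weighted median**, and the **simple and
  weighted mode** estimators;
- diagnostics: Cochran's Q (IVW and Egger forms), the Egger intercept test,
  leave-one-out refits, funnel-plot coordinates with a weighted-correlation
  asymmetry statistic, per-SNP F-statistics, and a Bonferroni threshold over
  the methods;
- the **E-value** `RR + sqrt(RR*(RR-1))` (inverting RR < 1 first): the minimum
  confounder strength that could explain away an observed risk ratio;
- upstream plumbing: dialect-mapped TSV/CSV readers with row validation,
  strict `p < 5e-8` instrument selection, greedy LD clumping (lowest p wins,
  default r² 0.01 within 10,000 kb), LD proxy lookup (default r² ≥ 0.8), and
  allele harmonization that infers strand for palindromic SNPs from allele
  frequency and discards non-inferable ones (minor-allele frequency above
  0.42);
- a seeded **synthetic generator** of paired exposure/outcome tables with a
  known causal effect, pleiotropy, LD blocks and harmonization corruptions —
  the test bed for everything above.

## Worked example

```r
library(mrpipe)

# a synthetic world with true causal effect theta = 0.5 and outcome-table
# corruptions that harmonization must undo
sc  <- mr_scenario(nsnp = 40, theta = 0.5, beta_x_sd = 0.15, n_exp = 5e5,
                   frac_allele_swapped = 0.2, frac_strand_flipped = 0.1,
                   seed = 42)
sim <- generate_pair(sc)
write_summary_stats(sim$exposure, "exposure.tsv")
write_summary_stats(sim$outcome,  "outcome.tsv")

cfg <- mr_config(exposure = "exposure.tsv", outcome = "outcome.tsv",
                 n_boot = 1000, seed = 42)
rep <- run_mr(cfg)
rep
```

```
MR run: 34 instruments; discarded=3 selected=34
ivw: beta = 0.5109 (se 0.0129), OR = 1.667 [1.625, 1.709], p = 0, nsnp = 34
egger: beta = 0.5408 (se 0.0211), OR = 1.717 [1.648, 1.790], p = 6.62e-23, nsnp = 34
weighted_median: beta = 0.5134 (se 0.0197), OR = 1.671 [1.608, 1.737], p = 2.14e-150, nsnp = 34
simple_mode: beta = 0.5000 (se 0.0291), OR = 1.649 [1.557, 1.745], p = 2.39e-66, nsnp = 34
weighted_mode: beta = 0.5043 (se 0.0190), OR = 1.656 [1.595, 1.719], p = 2.78e-155, nsnp = 34
Cochran's Q = 28.47 (df 33, p = 0.692)
```

Of the 40 simulated SNPs, 37 reached `p < 5e-8` in the exposure GWAS and 3
palindromic SNPs were discarded as non-inferable (MAF > 0.42), leaving 34
instruments. All five estimators recover the true log-odds effect 0.5 within
their confidence intervals; Q shows no heterogeneity (as generated). The
IVW odds ratio 1.667 would need a confounder of strength

```r
evalue_from_rr(rep$estimates$ivw$or_value)$evalue   # 2.72
```

on the risk-ratio scale with both exposure and outcome to be explained away.
`format_table2(rep)` renders the publication-style long table with Bonferroni
stars; `write_report(rep, "out/")` emits `estimates.tsv`, `sensitivity.json`,
`provenance.tsv`, `leave_one_out.tsv`, `funnel.tsv` and `run.log`.

## Command line

```sh
Rscript inst/scripts/mrpipe simulate --nsnp 50 --theta 0.5 --seed 7 --out-dir sim/
Rscript inst/scripts/mrpipe run --exposure sim/exposure.tsv --outcome sim/outcome.tsv \
    --ld sim/ld.tsv --seed 7 --out-dir out/
Rscript inst/scripts/mrpipe evalue 2.93 0.5
```

Exit codes: 0 success, 2 configuration error, 3 degenerate data.

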