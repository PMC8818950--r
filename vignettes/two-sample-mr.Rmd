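---
title: "Two-sample Mendelian randomization with mrpipe: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

## The model

Two-sample Mendelian randomization estimates the causal effect $\theta$ of an
exposure on an outcome using $J$ genetic instruments whose associations come
from two independent GWAS. For instrument $j$ we observe
$\hat\beta_{Xj} \sim N(\beta_{Xj}, \sigma_{Xj}^2)$ and
$\hat\beta_{Yj} \sim N(\theta\,\beta_{Xj} + \alpha_j, \sigma_{Yj}^2)$,
where $\alpha_j$ is a direct (horizontally pleiotropic) effect. The three core
instrumental-variable assumptions are relevance ($\beta_{Xj} \neq 0$),
independence from confounders, and exclusion ($\alpha_j = 0$). The estimators
differ in how much of the third assumption they relax:

* **IVW** assumes $\alpha_j = 0$ for all $j$ and pools Wald ratios
  $\hat\beta_{Yj}/\hat\beta_{Xj}$ with weights $\sigma_{Yj}^{-2}$ on the
  ratio-variance scale; algebraically this is weighted least squares of
  $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ through the origin. The default is the
  fixed-effect form; `variant = "multiplicative"` inflates the standard error
  by the residual standard deviation floored at 1, the random-effects
  convention of widely used MR software. Both are exposed because published
  analyses rarely state which one produced their tables.
* **MR-Egger** frees the intercept: under the InSIDE condition (instrument
  strength independent of direct effects) the slope remains a consistent
  estimate of $\theta$ while the intercept estimates the average directional
  pleiotropy. Each SNP is first oriented so $\hat\beta_{Xj} \ge 0$, making the
  regression invariant to the arbitrary sign of reported effect alleles.
  P-values use $t_{J-2}$.
* **Weighted median**: valid if instruments carrying $\ge 50\%$ of the weight
  are valid. With ratios sorted ascending and cumulative standardized weight
  $p_j = (S_j - w_j/2)/\sum w$, the estimate interpolates the ratio at
  $p = 0.5$.
* **Simple/weighted mode**: the ratio value maximizing a weighted
  normal-kernel density with bandwidth
  $h = \varphi \cdot 0.9\,\min(\mathrm{sd}, \mathrm{IQR}/1.349)\,J^{-1/5}$
  (normal-reference rule, $\varphi = 1$ by default); valid when the largest
  cluster of instruments is valid. If the spread term is zero (all ratios
  identical) the common value is returned rather than an error.

Median and mode standard errors come from a parametric bootstrap: betas are
resampled from $N(\hat\beta, \mathrm{se}^2)$, the point statistic is
recomputed `n_boot` times (default 1000) under the run seed, and the standard
deviation is taken. Their p-values use the normal approximation; IVW uses the
normal too. None of these distributional choices are dictated by the source
analyses, which never state them; they match the field's common defaults.

## Upstream processing

**Reading and validation.** Tables are TSV/CSV with a header; a `column_map()`
translates dialects (e.g. GWAS Catalog or COVID-19 HGI headers). Rows failing
the record invariants — single-nucleotide biallelic alleles, $se > 0$,
$0 < \mathrm{eaf} < 1$, $p \in [0,1]$, unique rsIDs — are dropped and tallied
per reason. Duplicated rsIDs are rejected entirely rather than silently
deduplicated: the sources give no resolution rule, and keeping an arbitrary
row would be unverifiable. Missing allele frequency is tolerated at parse
time; it only becomes fatal for palindromic SNPs at harmonization.

**Instrument selection.** Genome-wide significance is a strict inequality
$p < 5\times10^{-8}$. Clumping is the standard greedy procedure: sort by
ascending p (ties by rsID for determinism), take the best remaining SNP as an
index, and drop every remaining SNP on the same chromosome within the window
whose $r^2$ with the index exceeds the threshold (defaults $r^2 = 0.01$,
window 10{,}000 kb). The distance is $|pos_i - pos_c| \le$ window, 1-based
positions — the sources leave the distance semantics undefined, so the
simplest symmetric rule is used. LD is an *input* (long or square TSV); SNP
pairs absent from the matrix are treated as unlinked, but a pair present with
a missing entry raises an error rather than silently assuming independence.
Proxies for instruments missing from the outcome table take the available SNP
with maximal $r^2 \ge 0.8$ (a conventional value; the sources never state
theirs, so it is a flag), ties broken by lower p then rsID. The proxy's own
alleles and frequency are used downstream; no allele translation between
target and proxy is attempted, a documented limitation.

**Harmonization.** Effects must refer to the same allele. Identical allele
pairs are aligned or flipped (negate $\hat\beta_Y$, $\mathrm{eaf} \to
1-\mathrm{eaf}$); non-palindromic pairs matching only after complementation
are strand-corrected first. Palindromic SNPs (A/T, G/C) cannot reveal strand
from alleles, so orientation is inferred from frequency: both sides on the
same side of 0.5 means aligned, opposite sides means flipped. When either
side's minor-allele frequency exceeds 0.42 the frequencies are too close to
0.5 to trust and the SNP is discarded; exactly 0.42 is kept (the discard rule
is "above 0.42"). The threshold is tested on *both* studies — the sources do
not say which side they tested, and both is the conservative reading.
Equality with 0.5 cannot occur in kept SNPs since MAF 0.5 > 0.42.

## Diagnostics

Cochran's $Q = \sum_j w_j (\hat\beta_j - \hat\theta)^2$ on the ratio scale
with first-order weights (matching the estimators' weighting; the sources
give no formula), $\chi^2_{J-1}$ against the IVW estimate and $\chi^2_{J-2}$
against the oriented Egger fit. The documented ordering $Q_{IVW} \ge
Q_{Egger}$ can fail once sign orientation enters, so only $Q \ge 0$ is
asserted. Funnel "symmetry" is operationalized as the weighted correlation
between ratio and precision so that it is a number a test can check; visual
judgment is out of scope. Leave-one-out defaults to IVW and flags sign or
nominal-significance changes. Instrument strength uses the single-SNP
approximation $F = (\hat\beta_X/\mathrm{se}_X)^2$. The Bonferroni threshold
is $\alpha/m$ with $m = 5$ methods by default, i.e. $0.05/5 = 0.01$.

## The synthetic world

`mr_scenario()` states the generative model the tests live in: true exposure
effects $N(0, 0.08^2)$ (typical log-odds for common-variant cancer GWAS hits),
exposure and outcome sample sizes $10^5$ and $2\times10^4$ (a large exposure
meta-analysis against a smaller outcome study) driving standard errors through
$1/\sqrt{2nf(1-f)}$, allele frequencies uniform on $(0.1, 0.9)$, 20% of SNPs
palindromic with a quarter of those forced into the non-inferable MAF band,
and block-diagonal LD. Corruptions (allele swaps, strand complements) touch
only the emitted outcome table, and the truth record keeps every latent value,
so harmonization can be checked for *exact* recovery.

Simplifications, hence what a green test does not establish: noise on
$\hat\beta_X$ and $\hat\beta_Y$ is independent normal with sd equal to the
emitted se — no winner's curse from selecting significant SNPs, no sample
overlap between the two studies, no liability-scale conversion for binary
traits, and exposure/outcome frequencies are identical (real studies differ
by cohort). Directional-pleiotropy power simulations construct positive
exposure effects directly, because with symmetric effect signs Egger's
internal orientation converts a constant pleiotropic shift into a balanced
one — a real phenomenon, worth knowing when interpreting Egger intercepts.

Calibration facts the test suite recomputes: under the null (no pleiotropy,
$\theta = 0$, 20 SNPs) Q is $\chi^2_{19}$ to Kolmogorov–Smirnov accuracy over
1000 replicates; the Egger intercept test holds its 5% size under balanced
pleiotropy; IVW at $\theta = 0.5$ with 50 SNPs has |bias| < 0.02 and 95% CI
coverage within [0.92, 0.98] over 200 replicates.

## Numerical and design notes

* Ratio variances use the first-order delta method
  $\sigma_{Yj}^2/\hat\beta_{Xj}^2$; the second-order exposure term is behind
  `second_order = TRUE`. An exposure beta of exactly 0 is a degenerate
  instrument and errors by name.
* The weighted-median interpolation clamps to the extreme ratios when 0.5
  falls outside $[p_1, p_J]$ (possible with very skewed weights).
* All randomness (bootstraps, the generator) is seeded and restores the
  caller's RNG state; identical config + seed reproduce reports bit-for-bit.
* The published E-values this package's E-value calculator mirrors depend on
  risk ratios from external observational studies that are not printed
  anywhere reproducible, so the calculator is validated by its closed form:
  $E = RR + \sqrt{RR(RR-1)}$ after inverting $RR < 1$, symmetric under
  $RR \to 1/RR$, strictly increasing, $E \ge RR_{\mathrm{eff}} \ge 1$.
* Reproducing the reference analysis's instrument-level numbers (e.g. an IVW
  beta of 1.074 for the lung-adenocarcinoma/severity pair) requires its
  supplementary per-SNP tables, which cannot be bundled or downloaded here;
  the corresponding acceptance test states this and fails honestly rather
  than asserting values the package never computed.

## A small end-to-end run

```{r example}
sc  <- mr_scenario(nsnp = 30, theta = 0.5, beta_x_sd = 0.15, n_exp = 5e5,
                   frac_allele_swapped = 0.2, seed = 7)
sim <- generate_pair(sc)
h   <- harmonize_all(sim$exposure, sim$outcome)
est <- mr_estimate_all(h$instruments, n_boot = 200, seed = 7)
estimates_table(est)
cochran_q(h$instruments)
```
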