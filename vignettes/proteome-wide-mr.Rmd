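---
title: "Proteome-wide two-sample Mendelian randomization with pwmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteome-wide two-sample Mendelian randomization with pwmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwmr)
```

# The problem

Circulating proteins are attractive biomarkers and drug targets for
childhood obesity, but direct proteomic studies in children are small,
confounded and open to reverse causation.  Two-sample Mendelian
randomization (MR) sidesteps these problems by using genetic variants as
instruments: SNP effects on a protein are taken from one GWAS (here, adult
proteomic GWAS of up to N &asymp; 35,559), SNP effects on childhood body
mass index (BMI) from another (N = 39,620 children), and their ratio
estimates the causal effect of the protein on BMI in SD/SD units.

`pwmr` implements the full analysis pipeline at proteome scale —
instrument selection, harmonization, estimation, multiple-testing control,
colocalization, confounder screening, mediation, reverse MR and power —
together with a summary-statistic simulator with known causal truth, so
that every stage can be validated end to end without access to the
original GWAS downloads.

# The model and its assumptions

An instrument must satisfy the three MR assumptions: it is robustly
associated with the exposure (relevance), independent of confounders of
the exposure-outcome relationship, and affects the outcome only through
the exposure (exclusion restriction).  `pwmr` operationalizes these as:

* **cis-pQTL instruments** (`select_cis_instruments()`): variants within
  1 Mb of the protein-coding gene's transcription start site, with
  association p &le; 5e-8 and single-SNP F-statistic
  $(\beta/\mathrm{se})^2 > 10$.  Restricting to cis variants minimizes
  the scope for horizontal pleiotropy.  Where an LD matrix is available,
  instruments are greedily clumped in ascending p-value order at
  $r^2 \le 0.001$ (the conventional strict default; the parameter is
  exposed because source GWAS rarely report the value they used).
* **Harmonization** (`harmonize()`): exposure and outcome effects are
  aligned to a shared effect allele; swapped or strand-complementary
  representations are flipped (negating the outcome beta and
  complementing its allele frequency).  Palindromic (A/T, C/G) SNPs carry
  no strand information in their labels; those with minor allele
  frequency above 0.42 in either study are excluded as irresolvable,
  while those below are oriented by allele-frequency concordance (flip
  iff $|f_x - f_y| > |f_x - (1-f_y)|$).  The source method statement
  specifies the 0.42 exclusion but not the sub-threshold resolution;
  frequency concordance is the standard practice in two-sample MR tools
  and is applied symmetrically to both studies, which also sidesteps the
  open question of which study's frequencies act as reference.
* **Estimation** (`wald_ratio()`, `mr_ivw()`, `mr_egger()`,
  `mr_weighted_median()`, `mr_weighted_mode()`): a single instrument
  gives the Wald ratio $\beta_Y/\beta_X$ with first-order (delta) SE
  $\mathrm{se}_Y/|\beta_X|$ by default; the second-order form adding the
  exposure-uncertainty term is available by flag.  Multiple instruments
  are combined by IVW — weighted regression through the origin with
  weights $1/\mathrm{se}_Y^2$ — using a fixed-effect SE below 4 SNPs and
  multiplicative random effects otherwise, with the dispersion floor
  $\max(1,\hat\phi)$ so heterogeneity can never shrink the SE.  The
  pleiotropy-robust estimators follow the standard constructions:
  MR-Egger (weighted regression with intercept after orienting exposure
  effects positive; the intercept is the pleiotropy test), the
  weight-interpolated median of per-SNP ratios, and the mode of an
  inverse-variance-weighted normal-kernel density of ratios with a
  MAD-based default bandwidth.  Median and mode SEs come from a
  parametric bootstrap with a mandatory, defaulted seed (1234).
  All p-values are two-sided normal; at GWAS sample sizes the normal/t
  distinction is negligible and the choice keeps results exactly
  reproducible.
* **FDR** (`bh_fdr()`): Benjamini-Hochberg step-up across all
  successfully tested proteins, significance at adjusted p &le; 0.05.
  The equivalent raw-scale cutoff is dataset-dependent and is reported,
  never hard-coded.

# Colocalization

A significant MR hit can still be an LD artifact: the pQTL may merely be
correlated with a distinct causal variant for BMI.  `coloc_sumstats()`
evaluates the five standard hypotheses (H0 no association, H1/H2 one
trait only, H3 two distinct causal variants, H4 one shared causal
variant) under the single-causal-variant assumption, using per-SNP
Wakefield approximate Bayes factors

$$\log\mathrm{ABF} = \tfrac12\log\frac{V}{V+W} +
  \tfrac12 z^2 \frac{W}{V+W}, \qquad V = \mathrm{se}^2,\; z = \beta/\mathrm{se},$$

with priors $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ and prior effect
variance $W = 0.15^2$ per trait (the quantitative-trait default; the
source analysis states only that default priors were used, so this value
is pinned here and recorded).  Variants with MAF &lt; 0.01 are excluded.
Accumulation is entirely in log space via log-sum-exp, so z-scores of any
magnitude cannot overflow, and the H3 term uses
$\log(1-e^{d})$ with $d = \ell_{12}-\ell_1-\ell_2 \le 0$ rather than a
subtraction of exponentials.  One-SNP regions give PP.H3 = 0 exactly and
$p_{12}=0$ gives PP.H4 = 0 exactly.  PP.H4 &gt; 0.75 is called
"colocalized", PP.H3 &gt; 0.75 "distinct", anything else "underpowered".
The implementation is tested against brute-force enumeration of all
$(M+1)^2$ single-causal configurations to $10^{-10}$.

# Mediation, reverse MR and power

Because BMI reflects both fat and lean mass, an effect of a protein on
BMI may be mediated by adiposity.  `two_step_mediation()` combines an MR
estimate $a$ of protein &rarr; body-fat-percentage with an estimate $b$
of body-fat-percentage &rarr; BMI into the indirect effect $ab$, with the
first-order Sobel SE $\sqrt{a^2\mathrm{se}_b^2 + b^2\mathrm{se}_a^2}$
(the exact-variance variant adding
$\mathrm{se}_a^2\mathrm{se}_b^2$ is available by flag).  The proportion
mediated is only reported when the total effect exceeds its own SE, to
avoid unstable ratios.

`reverse_mr()` runs IVW, MR-Egger, weighted median and weighted mode on
outcome-trait instruments (e.g. 16 clumped genome-wide-significant BMI
SNPs) against a protein GWAS, to detect reverse causation; proxy
instruments at $r^2 \ge 0.8$ (`find_proxy()`) substitute for missing
variants, and proxies are always re-harmonized on their own alleles.

`mr_power()` is the normal-approximation power for a continuous outcome:
$\mathrm{NCP} = n\,r^2\,\beta^2$ and
$\mathrm{power} = 1-\Phi(z_{1-\alpha/2}-\sqrt{\mathrm{NCP}}) +
\Phi(-z_{1-\alpha/2}-\sqrt{\mathrm{NCP}})$.  At $\beta = 0$ it returns
$\alpha$ exactly.  The chi-square and two-tailed-normal formulations
agree to &lt; 1e-4 at the non-centralities arising here, so the simpler
normal composition is used and validated against Monte-Carlo simulation.

# The synthetic-data generator

`simulate_sumstats()` draws regional summary statistics directly on the
z-score scale: with AR(1) LD $R_{ij} = \rho^{|i-j|}$ (default
$\rho = 0.9$ over 200 SNPs spanning ~1 Mb), marginal standardized effects
are the LD-propagated joint effects $R\,b$, per-allele effects scale by
$\sqrt{2f(1-f)}$, standard errors are $1/\sqrt{2f(1-f)\,n}$, and a single
MVN$(0, R)$ noise draw per trait puts LD into the noise exactly as in
real regional statistics.  This is distributionally equivalent to an
individual-level simulation under the standard linear-model
approximation; genotype-level generation, reference LD maps and realistic
frequency spectra are deliberately out of scope, so passing tests
demonstrate correctness of the statistical machinery, not robustness to
real-data pathologies (strand errors beyond palindromes, imputation
noise, sample overlap).

Defaults mirror the study setting: exposure N = 35,559, outcome
N = 39,620, one causal cis variant explaining 2% of protein variance,
protein-on-BMI effects in the -0.07 to -0.33 SD/SD range.  The presets
`paper_scale_eng` (variance explained 0.085, effect -0.07) and
`paper_scale_fabp4` (0.0034, -0.33) are calibrated so that the outcome
z-score at the causal variant matches the z implied by the corresponding
published estimate and p-value; `paper_scale_h4` (0.02, -0.26) is the
intermediate positive control used in end-to-end tests;
`paper_scale_h3` places distinct causal variants with z &asymp; 8 per
trait; `null_535` is an instrumented protein with no outcome effect.
Simulated variants use non-palindromic allele pairs so that no simulated
instrument is lost to strand ambiguity (palindrome handling is exercised
by dedicated fixtures instead).  `simulate_panel()` assembles many
independent regions (one per chromosome) against a single pooled outcome
GWAS, which is the shape the pipeline consumes.

# A worked run

```{r}
panel <- simulate_panel(10, n_signal = 1, seed = 42)
res <- run_pwmr(panel$proteins, panel$outcome, panel$annotations,
                ld = panel$lds, config = pwmr_config(do_reverse = FALSE))
res
subset(res$results, significant,
       select = c(protein, beta, ci_low, ci_high, pval, pp_h4, power))
```

The signal protein (P001) is recovered with an estimate near its
generative truth of -0.26, survives FDR across the 10 proteins, and
colocalizes (PP.H4 &gt; 0.75); the nine nulls do not.

# Numerical and design choices

* Positions are 1-based; alleles are upper-cased on ingest; indels are
  harmonized by exact string match and never enter palindrome logic.
* Non-palindromic variants with missing frequencies proceed through
  harmonization; palindromic ones are excluded (neither rule can apply).
* Rows violating basic range constraints are dropped at ingest with a
  logged count; p-values grossly inconsistent (&gt;10% on the z scale)
  with beta/se warn but are kept, since published rounding can exceed
  that bound.
* A single instrument that is absent from the outcome GWAS is replaced
  by its best LD proxy at $r^2 \ge 0.8$; proteins with no usable
  instrument are reported "not testable" rather than failing the run.
* Instrument selection order (ascending p, ties by rsid) and all
  bootstrap seeds are deterministic, so identical configurations yield
  byte-identical reports.
* The F-statistic uses the single-SNP approximation
  $(\beta/\mathrm{se})^2$ rather than the $R^2$-based form, since
  per-study variance explained is not generally published; the two agree
  asymptotically.
* Test problem sizes (e.g. 100-replicate panels of 10 proteins by 200
  SNPs, 1,000-5,000 replicate calibration loops) were chosen as the
  smallest sizes at which the binomial/Monte-Carlo error of each check is
  comfortably below the asserted margin.

# Known limitations

* Single-causal-variant colocalization only; no SuSiE-style multi-causal
  decomposition or conditional analysis.
* No MR-PRESSO, Steiger filtering, contamination mixture or multivariable
  MR; the robust-estimator set is IVW/Egger/median/mode.
* No genome-build liftover, multi-allelic splitting or binary-outcome
  power.
* The confounder screen counts associations in a user-supplied local
  table; it does not query any external PheWAS service.
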