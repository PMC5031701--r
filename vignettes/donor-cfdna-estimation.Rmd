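---
title: "Estimating donor-derived cfDNA by constrained mixture modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating donor-derived cfDNA by constrained mixture modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(donormix)
```

## The measurement model

Plasma cfDNA from a transplant recipient is a two-contributor DNA mixture:
a major contributor (the recipient) and a minor one (the graft donor) at
unknown fraction $x$. At a biallelic SNP where the recipient is homozygous,
reads carrying the other panel allele can only come from the donor or from
sequencing error. With an *unrelated* donor and allele frequencies near
0.5, the donor's genotype at a recipient-homozygous locus shares both
alleles with probability ¼ (minor-allele signal = the error rate $e$), one
allele with probability ½ (signal $\approx x/2$), and neither with
probability ¼ (signal $\approx x$).

The per-locus minor-allele fractions $y_1, \dots, y_n$ at the selected loci
are therefore modeled as a three-component Gaussian mixture

$$ y_i \sim \tfrac14\, \mathcal N(\mu_{err}, \sigma_{err}^2)
 + \tfrac12\, \mathcal N(\mu_{OSA}, \sigma_{OSA}^2)
 + \tfrac14\, \mathcal N(\mu_{NSA}, \sigma_{NSA}^2), $$

with three biologically motivated constraints that are imposed *exactly*,
not used as initializations:

* mixing weights fixed at $(\tfrac14, \tfrac12, \tfrac14)$;
* $\mu_{NSA} = 2\,\mu_{OSA}$;
* $\sigma_{NSA} = 2\,\sigma_{OSA}$.

The donor estimate from one fit is $\max(0,\; \mu_{NSA} - \mu_{err})$.

The mean constraint is an idealization: physically
$\mu_{OSA} \approx x/2 + e$ and $\mu_{NSA} \approx x + e$, which satisfy
the exact 1:2 ratio only when $e \ll x$. At the Q30 error scale
($e \approx 10^{-3}$) the discrepancy is a few times $10^{-4}$ in fraction
units, negligible against donor fractions of 0.5% and above; at or below
the error scale the estimate is dominated by noise anyway and is reported
as not detectable.

### EM with tied parameters

The free parameters are $(\mu_{err}, \mu_{OSA}, \sigma_{err},
\sigma_{OSA})$. The E-step computes responsibilities in log space. In the
M-step, the error component updates are the usual weighted moments, while
the tied pair is the responsibility-weighted least-squares solution of
$y_i \approx c_k \mu_{OSA}$ with class loadings $c = (1, 2)$ and variances
$(\sigma_{OSA}^2, 4\sigma_{OSA}^2)$:

$$ \hat\mu_{OSA} = \frac{\sum_i r_{i2} y_i + \tfrac12 \sum_i r_{i3} y_i}
                        {\sum_i r_{i2} + \sum_i r_{i3}}, \qquad
   \hat\sigma_{OSA}^2 = \frac{\sum_i r_{i2} (y_i-\hat\mu_{OSA})^2
                        + \tfrac14 \sum_i r_{i3} (y_i-2\hat\mu_{OSA})^2}
                        {\sum_i r_{i2} + \sum_i r_{i3}}. $$

Both updates maximize the expected complete-data log-likelihood subject to
the ties, so the observed log-likelihood is non-decreasing every iteration
— a property the test suite asserts on every fit, alongside a brute-force
grid-search oracle that the EM optimum must match or beat.

### Why replicated fits

With ~40–50 loci the likelihood surface has local structure, and a single
EM run depends on its starting point. `estimate_donor_fraction()` therefore
aggregates many restarts: per replicate, $\mu_{err}$ starts at
$0.001 \cdot \mathrm{LogUnif}(0.5, 2)$ (around the Q30 theoretical rate),
$\mu_{OSA}$ at $\mathrm{LogUnif}(0.25, 4) \cdot \mathrm{median}(y)/2$, and
each SD at half its mean. One master seed drives all draws, so a run is
exactly replayable. The reported donor percentage is the mean of the
per-replicate clamped estimates and its SD is the reproducibility measure.
An alternative bootstrap mode (`estimate_config(bootstrap = TRUE)`)
additionally resamples loci with replacement, which widens the SD into a
sampling-uncertainty measure rather than a pure restart-stability one; it
is not the default because the replicate SD is meant to characterize the
model's run-to-run consistency on fixed data.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_base_quality` | 30 | Phred | Q30 caps the base-error floor at 0.001 |
| `homozygosity_threshold` | 0.86 | fraction | major allele must *exceed* this share of all qualified reads; sets the <14% validity bound |
| `max_ambiguous_fraction` | 0.05 | fraction | loci with *more* than 5% N/off-panel calls are excluded as locally unreliable |
| `min_depth` | 100 | reads | below ~100x a single read moves the minor fraction by ≥1%, too coarse for the mixture |
| `n_replicates` | 10000 | — | replicate mean stabilizes well before this; a few hundred suffice in practice |
| `tol` / `max_iter` | 1e-8 / 500 | loglik / — | standard EM stopping practice |
| `variance_floor` | 1e-5 | fraction | prevents degenerate zero-variance spikes on near-constant data |
| `error_floor` | 0.001 | fraction | Q30 theoretical error; the detectability noise floor |

Denominator conventions, chosen once: the homozygosity and ambiguity rules
divide by *all* quality-passing calls (including ambiguous ones — the
conservative reading), while the donor-signal fraction divides by
panel-allele reads only, because the three mixture classes are defined over
the two panel alleles. Counts keep mutually exclusive buckets: a
quality-passing call of a non-panel base counts as ambiguous, never as a
third allele.

### Detectability

The estimate is flagged `detectable` when the mean percentage exceeds the
noise floor: the largest of the mean fitted $\mu_{err}$, the pooled
across-chip error rate (when supplied), and the 0.001 Q30 floor. The fitted
error component alone is not a sufficient floor: on clean data it converges
near $e/3$ (only a third of substitution errors land on the other panel
allele) or to zero at null, which would flag error-scale estimates as
signal. Error rates from samples co-sequenced on one chip can be combined
with `pool_error_rate()` (locus-count-weighted mean); by default the pooled
value is reported alongside the per-sample subtraction rather than
replacing it (`estimate_config(subtract_pooled = TRUE)` switches).

## What the simulator emulates — and what it does not

`simulate_genotypes()` draws two *independent* contributors under
Hardy–Weinberg at a common allele frequency (default 0.5, as for forensic
identity panels); `simulate_counts()` draws negative-binomial depths
(mean 1500, dispersion 5 — amplicon panels overdisperse relative to
Poisson), splits reads binomially between contributors, and miscalls each
read to a uniformly chosen other base with probability $e$. So an expected
$e/3$ of errors lands on the other panel allele and $2e/3$ becomes
ambiguous. The default panel size of 90 autosomal loci makes the expected
selected count ≈ 45, close to the ~42 informative loci typical of a
124-SNP identity panel — a convention, not a measured value.

`run_titration()` reproduces an in-vitro genomic-DNA titration: one
contributor pair drawn once per series (as when two cell-line DNAs are
mixed at increasing concentrations), six mixtures at 0–8% donor in
triplicate, each pushed through the full selection + estimation pipeline,
summarized by the zero-intercept $R^2$ of estimated on expected percent.
At the defaults this exceeds 0.97 (typically 0.998+); the EM replicate
count for titrations defaults to 200, where the series-level $R^2$ is
already stable.

Features of real plasma data the simulator deliberately omits: amplicon
bias and PCR duplicates, related donor–recipient pairs, locus-specific
error profiles (homopolymer indel error on semiconductor platforms),
contaminating genomic DNA from leukocyte lysis, and allele frequencies
below 0.5 (which only reduce the informative locus count). Passing the
titration and recovery tests therefore demonstrates correctness of the
*estimator* under its stated model, not robustness to every artifact of
real libraries.

```{r titration, eval = FALSE}
tab <- run_titration(seed = 1)
attr(tab, "r2")
aggregate(estimated_percent ~ expected_percent, tab, mean)
```

## Numerical and degenerate-input choices

* **Variance floor.** SDs are clamped at $10^{-5}$ after each M-step; the
  clamped value still maximizes the expected complete-data log-likelihood
  over the constrained region, so monotonicity survives flooring. On
  all-identical data the fit collapses onto the floor and the estimate
  lands at the error scale.
* **Empty responsibilities.** If a component's responsibility mass
  underflows, its parameters are frozen at their previous values for that
  iteration rather than dividing by zero.
* **Clamping.** Per-replicate estimates are clamped at zero *before*
  aggregation: a mixture of fractions cannot be negative, and the
  detectability flag (not a negative number) communicates "no signal".
* **Non-convergence.** Replicates that fail to converge within `max_iter`
  are excluded and counted; if none converge the estimator raises an
  error with diagnostics instead of returning a value.
* **Strictness at thresholds.** The homozygosity rule is strictly greater
  (exactly 86% is not homozygous); the ambiguity rule excludes strictly
  greater (exactly 5% is retained).
* **Fewer than six loci** refuse to fit: three components with four free
  parameters on fewer points is unidentifiable.

## Validity bound and limitations

At a no-shared-allele locus the recipient allele's expected read share is
$1 - x$ (error-free), so the >86% homozygosity call fails in expectation
once $x \ge 0.14$: the method is restricted to donor fractions below 14%,
which covers rejection surveillance in stable recipients but not, for
example, early post-transplant liver monitoring. The 1:2:1 class structure
assumes unrelated contributors; related pairs share more alleles, deflate
the informative classes, and bias the estimate downward. Loci are treated
as independent and identically informative; panel-specific error hotspots
should be handled upstream by excluding the loci or supplying a pooled
error rate measured on reference samples.
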