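---
title: "Founder-cell estimation from allelic epigenetic variance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Founder-cell estimation from allelic epigenetic variance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epifounder)
```

## The clonal-sampling model

Every score this package handles is, at bottom, the answer to a binary
question asked of many DNA molecules: *is this CpG methylated?* For a
tissue founded by $N$ progenitor cells whose epiallele states were fixed
independently with probability $p$ — $p = 0.5$ for which X chromosome is
inactivated, $p \approx 0.1$ for maternal methylation at the IGF2/H19 DMR —
the tissue-level score is the founder fraction

$$ S = \frac{k}{N}, \qquad k \sim \mathrm{Binomial}(N, p), $$

because the descendants of each founder inherit its state and contribute
equally to the bulk signal. Hence

$$ \mathbb{E}[S] = p, \qquad \mathrm{Var}(S) = \frac{p(1-p)}{N}. $$

Small founder populations leave a fingerprint of *large variance* in the
score distribution across tissue samples, and the variance can be inverted
to estimate $N$. The model's assumptions are worth stating plainly:

* founder states are independent Bernoulli($p$) draws — no clonal
  selection, no spatial correlation between founders;
* every tissue sample is an independent realisation of the same
  founder-sampling process (see *Pooling*, below);
* densitometry reads the true founder fraction, up to optional Gaussian
  noise.

## The two estimators

**Moment estimator** (`moment_n()`): $\hat N = p(1-p)/\widehat{\mathrm{Var}}$,
reported unrounded. It is the default because it is closed-form,
assumption-light, and applying it to a summary table's dispersion column
reproduces reported stem-cell counts directly (for example
$0.25 / 0.1637^2 = 9.33$ from a placental X-inactivation SD).

**Distribution fit** (`fit_n_distribution()`): searches integer candidates
$N \in [1, 100]$ for the one whose exact $k/N$ distribution
(`binomial_score_pmf()`) is closest to the empirical score distribution.
The default distance is a Pearson chi-square on 10 equal-width bins over
$[0, 1]$ (scores equal to 1 fall in the last bin; candidates placing zero
mass in an occupied bin are excluded); a Kolmogorov–Smirnov distance is
available, evaluated on the union of the empirical and candidate jump
points since both CDFs are step functions. Ties break toward the smaller
$N$. An optional Gaussian convolution (`noise_sd`) accommodates
measurement noise; its default is 0 because the pure clonal-sampling model
has none. Two numerical edge cases are handled explicitly: a zero-variance
score set implies an unbounded founder count, so the fit returns the top
of the search grid flagged as degenerate rather than a spurious interior
optimum; and scores outside $[0, 1]$ (possible for methylation ratios when
the designated low-methylation allele is locally the stronger band) are
excluded from the fit with a warning but retained in the moment estimate,
whose variance remains well defined.

On clean simulated data the two estimators agree to within one founder
cell at a few thousand samples, which is the package's internal
consistency check.

### Choice of p

$p = 0.5$ is fixed by X-inactivation biology. For the DMR flavour the
default is $p = 0.1$, the approximate population probability that a
maternal DMR molecule is methylated; it can instead be taken from each
group's observed mean score (`p_from_mean = TRUE`), which is typically
close (group means near 0.08–0.10).

### Pooling

`estimate_founders()` pools all five placenta sections across all
individuals of a group as independent draws (default
`pool = "sections"`), mirroring the group-level variance treatment that
the $pq/N$ arithmetic implies. A `pool = "individual_means"` alternative
averages within individual first; it is offered for sensitivity analysis,
not used by default, and necessarily shrinks the variance (means of
sections are less dispersed than sections), so its $N$ estimates are
larger and not comparable with the default.

### Variance flavour

`sample_variance()` uses denominator $n - 1$ (`ddof = 1`) by default. At
the sample sizes involved (hundreds of pooled sections) the distinction
from $n$ is far below the precision of the estimator, but `ddof` is
exposed as a parameter so the choice is explicit rather than buried.

## Allelic scores

`compute_ratios()` maps band intensities to scores. Parental origin is not
observed (parental DNA is typically unavailable), so the package adopts
the standard assumption for these loci: the less methylated allele is
maternal at IGF2/H19 and paternal at IGF2R. The designation is made *once
per individual and locus*, from the allele label whose mean intensity
share across that individual's samples is smaller; individual samples may
then legitimately exceed a ratio of 1, and such values are preserved, not
clipped — only `predicted_total_methylation()` restricts its input to
$[0, 1]$, because the biallelic-methylation model behind it
($\mathrm{total} = (1 + m)/2$) is undefined outside that range. The
X-inactivation score is oriented by the input's `allele_a_label` ("upper"
gel allele) with no automatic re-orientation: the score's distribution is
symmetric about 0.5, so orientation does not affect variance-based
inference. One measurement per sample is taken as given; if replicate gel
quantifications exist they should be combined upstream.

The 3:1 loss-of-imprinting rule (`classify_loi()`) uses a strict
inequality: an allelic expression ratio of exactly 3:1 is *not* called
biallelic, matching the usual phrasing of the threshold ("less than
3:1").

## Group comparisons

* Location: Wilcoxon rank-sum, exact by full enumeration of rank
  assignments for combined $n \le 20$ (the null rank-sum distribution is
  symmetric, so the two-sided p is the probability of a rank sum at least
  as far from its expectation as observed), otherwise the tie-corrected
  normal approximation with continuity correction.
* Variance equality: the test behind reported "variance p-values" in this
  assay family is typically unnamed; the package defaults to the
  Brown–Forsythe (median-centred Levene) test for robustness to the
  strongly skewed ratio distributions, with the classical F test as an
  alternative. Neither is privileged by the package's acceptance checks.
* Expression: ΔΔCt with per-sample $\Delta C_t$ values and a Welch
  two-sample t-test on them. Welch is used because the equal-variance
  assumption of the classical t-test is not defensible for Ct data across
  conception groups; with balanced, similar-variance groups the two
  coincide. No multiple-testing correction is applied — each table cell is
  reported at raw $\alpha = 0.05$, matching the conventions of the tables
  this output mirrors.

## The synthetic cohort generator

`simulate_cohort()` emulates the study design the analysis assumes: two
conception groups (45 in vitro, 56 in vivo informative individuals by
default), seven tissue samples each (cord blood, cord, five placenta
sections), founder counts 8 vs 10, $p_{\mathrm{DMR}} = 0.1$,
$p_{XI} = 0.5$ with X-inactivation scored only in females (sex assigned
Bernoulli(0.5) per individual), and a separate expression cohort (98 vs
160 individuals, the size of the largest placental qPCR comparison) whose
Ct values carry gene- and tissue-specific fold effects on the $\Delta C_t$
scale — by default the reported placental IGF2 (0.52) and H19 (0.72) and
cord-blood IGF2R (0.61) reductions plus near-null effects elsewhere.

Key generator choices:

* **Each tissue sample is an independent binomial draw.** This is the
  model under which the pooled-variance arithmetic is exact, and it is
  what the acceptance-level recovery checks use.
* **Ct baselines are arbitrary constants** (25 for targets, 20 for the
  GAPDH housekeeping gene): only differences enter ΔΔCt. Technical noise
  is `ct_sd = 0.1` cycles per measurement, a typical qPCR replicate SD;
  no between-individual biological expression variance is simulated, so
  simulated p-values are far smaller than real ones at the same fold
  change — the generator is built for effect-size recovery, not p-value
  realism.
* **Densitometry noise defaults to 0** (no published noise magnitude to
  emulate); when enabled, noisy scores are truncated to $[0, 1]$ rather
  than redrawn, with the truncation count reported.
* A single integer seed fully determines both output tables.

What passing simulation-based tests does *not* show: real placental
sections are spatially correlated and share an individual's founder pool,
real densitometry has heteroscedastic noise and gel saturation, and real
expression varies over an order of magnitude between individuals. The
generator establishes that the estimators recover the truth *under the
model they assume*; it cannot validate the model itself against tissue
biology.

## Problem sizes used in the checks

The parameter-recovery checks run 100 replicates of 10,000 scores for
each founder count in $\{5, 10, 20\}$ crossed with $p \in \{0.1, 0.5\}$
(moment estimate within 10% and exact fit recovery in at least 90% of
replicates), 100 replicates at the study's own scale (45/56 individuals
× 5 sections) for the between-group ordering of estimates, 1,000 null
replicates for the variance-test calibration, and full enumeration
against an independent exact implementation for every two-group split of
up to 10 values. These sizes make the Monte-Carlo error comfortably
smaller than the tolerances being checked while keeping the default test
run fast.

## Known limitations

* Point estimates only: no confidence intervals on $N$ beyond
  seeded-replicate spread. The estimator is honest but imprecise; its
  value lies in concordant estimates from independent loci and assays.
* The moment estimator inherits any extra-binomial variance (measurement
  noise, section correlation) as a *downward* bias on $N$.
* When nearly complete imprint loss pushes many scores toward 1 (as at
  IGF2R in placenta), the binomial founder model no longer describes the
  score distribution and founder estimation is not attempted by default
  for that assay.
* The pipeline assumes net (background-subtracted) intensities; no gel
  image processing is provided.
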