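# epifounder

Estimating founder stem-cell numbers from allele-specific epigenetic
variation.

## The problem

Imprinted loci carry parent-of-origin-specific DNA methylation: the
IGF2/H19 differentially methylated region (DMR) is normally methylated
only on the paternal allele, the IGF2R DMR only on the maternal allele,
and in females one of the two X chromosomes is silenced by methylation at
random. Methylation-sensitive restriction assays read these states out as
band-intensity ratios: the **M/P ratio** (maternal over paternal
methylation signal at IGF2/H19; 0 = paternal-only, 1 = equal biallelic
methylation), the analogous **P/M ratio** at IGF2R, and the
**X-inactivation skew score** (upper allele over total at the androgen
receptor locus; 0.5 = balanced).

Tissues are clonal mosaics. If a tissue descends from *N* founder cells
whose epiallele states are independent Bernoulli(*p*) trials, a tissue
sample's score is the founder fraction *k/N* with *k* ~ Binomial(*N*, *p*),
so across samples

```
Var(score) = p(1 - p) / N        =>        N = p(1 - p) / Var
```

The fewer the founder cells, the larger the variance. `epifounder`
implements this variance-based founder estimator (with *p* = 0.5 for
X-inactivation and *p* ≈ 0.1 for maternal IGF2/H19 DMR methylation), an
independent estimator that fits the discrete *k/N* score distribution
directly, and the surrounding comparison machinery used in studies of
assisted-reproduction (in vitro) versus naturally conceived (in vivo)
cohorts: Wilcoxon rank-sum location tests, Levene/Brown–Forsythe
variance-equality tests, ΔΔCt fold-change estimation from qPCR Ct tables
(fold = 2^−ΔΔCt, ΔCt = Ct(target) − Ct(housekeeping)), and a 3:1
loss-of-imprinting call on allelic expression ratios. A seeded cohort
simulator generates ratio and Ct tables with the same clonal-mosaicism
structure, so the whole pipeline is testable without access to raw
densitometry data.

It is aimed at epigenomics researchers analysing allele-specific
methylation or X-inactivation data from tabular band-intensity exports.

## Worked example

Simulate a cohort under the default study design (45 in vitro vs 56
in vivo newborns, seven tissue samples each, founder counts 8 vs 10,
p = 0.1 at the DMR) and estimate the founder numbers from the five pooled
placenta sections:

```r
library(epifounder)

cfg <- cohort_config(seed = 42)
sim <- simulate_cohort(cfg)

fit <- estimate_founders(sim$ratios, assay = "MP")
tidy(fit)
#> # A tibble: 2 × 10
#>   assay group        p n_samples   mean variance n_moment n_fit fit_metric  fit_value
#>   <chr> <chr>    <dbl>     <int>  <dbl>    <dbl>    <dbl> <int> <chr>           <dbl>
#> 1 MP    in_vitro   0.1       225 0.0867  0.00906     9.94     8 chi2_binned      4.18
#> 2 MP    in_vivo    0.1       280 0.0946  0.00811    11.1     10 chi2_binned      4.39
```

`n_moment` is the continuous moment estimate `p(1-p)/Var` from each
group's pooled placental score variance; `n_fit` is the integer founder
count whose binomial score distribution best matches the empirical score
histogram (here it recovers the true generating values 8 and 10;
`autoplot(fit)` draws the histograms with the fitted distribution
overlaid). Applying the moment formula to a reported placental
X-inactivation score SD reproduces a published stem-cell count directly:

```r
moment_n(0.5, 0.1637^2)
#> [1] 9.33
```

Expression differences between the groups come from the Ct table via the
ΔΔCt method. The simulator injected a placental IGF2 fold change of 0.52,
which is recovered:

```r
ddct(sim$ct, "IGF2", tissues = paste0("placenta_", 1:5))
#> # A tibble: 1 × 6
#>   gene  tissue   n_in_vitro n_in_vivo fold_change   p_value
#>   <chr> <chr>         <int>     <int>       <dbl>     <dbl>
#> 1 IGF2  placenta         98       160       0.520 9.49e-125
```

`summarize_groups()` builds the per-tissue mean/variance comparison table
(rank-sum p-values for means, Levene for variances), `compute_ratios()`
turns raw band-intensity tables into scores, and `run_pipeline()` chains
all stages on CSV inputs, writing each result table plus a JSON run
manifest. A thin command-line wrapper with the same stages lives at
`inst/cli/epifounder.R`.

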