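# psiprior

Bayesian quantification of exon-skipping splicing in single-cell RNA-seq,
with an informative prior learned from sequence features.

## The problem

Single-cell RNA-seq coverage is too low and too noisy for bulk splicing
quantifiers: for a typical exon-skipping event a cell yields a handful of
reads, and many expressed events yield none at all (drop-outs). `psiprior`
estimates the exon inclusion ratio ψ (percent spliced-in) of each
exon-skipping event in each cell by combining:

* a **mixture-of-isoforms likelihood**. For event *i* with reads
  *R*<sub>*i*,1:*N*</sub>,

  P(R | ψ) = ∏<sub>n</sub> Σ<sub>I∈{inc,exc}</sub> P(R<sub>n</sub> | I) P(I | ψ),

  where P(R | I) = 1/ℓ<sub>I</sub> for a read compatible with isoform *I*
  (ℓ<sub>I</sub> the effective length) and the mixing weight is
  length-adjusted: w(ψ) = ψℓ<sub>inc</sub> / (ψℓ<sub>inc</sub> + (1−ψ)ℓ<sub>exc</sub>);

* an **informative prior** on y = logit(ψ): y = **W**ᵀ**x** + ε,
  ε ~ N(0, σ²), with a ridge prior **W** ~ N(0, (λI)⁻¹) on weights shared by
  all events (and optionally all cells). The regressors **x** are 735
  sequence-derived features per event: 8 length features, 4 splice-site PWM
  strengths, 7 mean conservation scores and 716 k-mer frequencies.

Inference alternates adaptive Metropolis–Hastings updates of each event's
logit-ψ with collapsed point updates of (**W**, σ)
(W = (XᵀX + σ²λI)⁻¹XᵀY, σ = std(Y − XW)), monitored by Geweke Z scores.
Well-covered events are driven by their reads; zero-read events fall back to
the prior, which is how drop-outs are imputed. Differential splicing between
cells (or pooled groups) is scored by a relaxed Savage–Dickey Bayes factor on
δ = ψ<sub>A</sub> − ψ<sub>B</sub>:

BF = P(−ε < δ < ε | H₁) / P(−ε < δ < ε | D, H₁),  ε = 0.05,

estimated by resampling prior and posterior draws; BF ≥ 10 calls an event
differential.

A first-class simulator reproduces the benchmark designs (coverage at fixed
reads-per-kilobase, mirrored-ψ differential design, Bernoulli drop-outs), so
the whole pipeline runs and is tested without any external data.

## Worked example

Simulate 2,000 events at very low coverage (RPK 25) with 10% forced
drop-outs, fit the model, and compare against the simulation truth:

```r
library(psiprior)
library(dplyr)

sim <- simulate_coverage_benchmark(n_events = 2000, rpk = 25,
                                   dropout_frac = 0.1, seed = 7)
fit <- quant_psi(sim$evidence, sim$features, config = sampler_config(seed = 8))

tidy(fit) |> select(event_id, n_reads, prior_mu, post_mean, ci_low, ci_high) |> head(5)
#> # A tibble: 5 × 6
#>   event_id n_reads prior_mu post_mean   ci_low ci_high
#>   <chr>      <int>    <dbl>     <dbl>    <dbl>   <dbl>
#> 1 sim00001       7   -3.25     0.0342 0.000619   0.185
#> 2 sim00002       0    0.787    0.647  0.0774     0.987
#> 3 sim00003      27    0.427    0.906  0.695      0.995
#> 4 sim00004      16    0.280    0.278  0.0614     0.646
#> 5 sim00005       7    3.92     0.961  0.743      1.000

glance(fit)
#> # A tibble: 1 × 8
#>   n_units n_dropout sigma lambda mean_accept frac_converged n_iter burn_in
#>     <int>     <int> <dbl>  <dbl>       <dbl>          <dbl>  <int>   <int>
#> 1    2000       200  1.77    0.1       0.461          0.640   3000    1000

expressed <- !sim$truth$dropout
cor(tidy(fit)$post_mean[expressed],  sim$truth$psi_true[expressed])   # 0.93
cor(tidy(fit)$post_mean[!expressed], sim$truth$psi_true[!expressed])  # 0.78
```

Event `sim00002` has zero reads: its posterior is its sequence-informed
prior, i.e. the imputed ψ. Even at RPK 25 the posterior means correlate 0.93
with truth for expressed events, and drop-outs are imputed at R ≈ 0.78 from
the prior alone. `autoplot(fit, "sim00003")` draws the prior curve over the
posterior histogram with the mean and 95% credible interval marked;
`plot_truth_scatter(fit, sim$truth)` gives the estimate-vs-truth scatter.

Differential splicing between two fitted cells:

```r
res <- diff_splicing(fit_a, fit_b, epsilon = 0.05, bf_threshold = 10, seed = 1)
res |> filter(called) |> arrange(desc(bf))
```

Real data enter through the same surfaces: `read_gtf_exons()` +
`extract_skipping_events()` + `filter_skipping_events()` for the event
annotation, `event_features()` (with `train_splice_pwms()` and an optional
conservation track) for the regressors, and `read_alignments()` +
`evidence_from_alignments()` for per-cell read evidence from SAM/BAM. A thin
command-line front end is installed at `inst/cli/psiprior`
(`psiprior sim|quant|diff`).

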