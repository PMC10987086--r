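# numchan

Detecting numerosity-tuned sensorimotor channels from individual
differences in reproduction precision.

## What it does

When people press a key a target number of times without counting, their
precision follows Weber's law: the Weber fraction Wf = SD(responses) /
mean(responses) is roughly constant across targets. If several
numerosity-tuned *channels* translate numbers into action sequences — each
with Gaussian tuning on the log axis, responding to numerosity *n* around a
preferred value *p* with weight

    w(n) = exp( -(log2(n / p))^2 / (2 sigma^2) ),   sigma = FWHM / (2 sqrt(2 ln 2))

then participants who are unusually precise at one target should also be
precise at *neighbouring* targets handled by the same channel. The package
implements the resulting inter-individual covariance analysis end to end:

* a generative simulator of channel-structured observer cohorts and
  trial-level tapping data (`channel_config()`, `simulate_cohort()`,
  `simulate_cohort_trials()`);
* preprocessing from raw trial tables to Weber-fraction matrices with
  z-score outlier removal (`remove_outliers()`, `reproduction_stats()`,
  `build_wf_matrix()`);
* inter-participant correlation matrices, their dependence on numerical
  distance `|log10(a/b)|` (six-bin curve and unbinned slope), and a
  within-participant permutation null (`wf_correlation_matrix()`,
  `binned_correlation_curve()`, `distance_slope()`, `shuffle_null()`);
* simulation-based fitting of 1/2/4-channel architectures by R² grid search
  with common random numbers (`predict_corr_matrix()`, `matrix_r2()`,
  `fit_channel_model()`);
* hierarchical clustering of targets (Euclidean/Ward) with an
  inconsistency-coefficient cut and a cluster-contiguity null, plus
  principal components with promax rotation and log-Gaussian tuning fits
  (`hierarchical_clusters()`, `contiguity_null()`, `factor_solution()`,
  `loggaussian_fit()`);
* the duration-matching control analysis (`derive_duration_targets()`,
  `compare_task_precision()`), with the reference duration-target table
  packaged;
* `run_pipeline()` to execute everything on a CSV trial table or a pure
  simulation, writing CSV/JSON artifacts and a manifest.

Results are tibbles or small S3 objects with `tidy()`/`glance()` methods and
`autoplot()` figures throughout.

## Worked example

Simulate a 30-observer fast-tapping cohort from a two-channel model (peaks 8
and 32, full bandwidth 1.45 octaves), then run the covariance analysis:

```r
library(numchan)

cfg    <- channel_config(2, fwhm_octaves = 1.45)
trials <- simulate_cohort_trials(cfg, n_observers = 30, seed = 42,
                                 condition = "fast")
cleaned <- remove_outliers(trials)
wfm  <- build_wf_matrix(reproduction_stats(cleaned), condition = "fast")
corr <- wf_correlation_matrix(wfm)
binned_correlation_curve(corr)
#> # A tibble: 6 × 5
#>   bin          lo     hi mean_r n_pairs
#>   <chr>     <dbl>  <dbl>  <dbl>   <int>
#> 1 <0.08      0      0.08 0.792        9
#> 2 0.08-0.14  0.08   0.14 0.741       10
#> 3 0.14-0.21  0.14   0.21 0.583        9
#> 4 0.21-0.29  0.21   0.29 0.452        9
#> 5 0.29-0.39  0.29   0.39 0.233        9
#> 6 >0.39      0.39 Inf    0.0902       9
```

Correlations between nearby targets are high (~0.8) and fall off with
numerical distance — the signature of tuned channels. The unbinned slope of
r against distance is reliably negative, and the target clustering and
factor structure recover the two generating channels:

```r
hierarchical_clusters(wfm)
#> <channel_clusters: 2 clusters over 11 targets (cutoff 2.015)>
#>   cluster 1: 8, 10, 11, 13, 14, 16
#>   cluster 2: 19, 21, 24, 28, 32
#>   contiguous: TRUE

fs <- factor_solution(wfm)   # promax-rotated components, eigenvalue > 1
glance(fs)
#> # A tibble: 1 × 4
#>   n_components total_variance rotation largest_eigenvalue
#>          <int>          <dbl> <chr>                 <dbl>
#> 1            2          0.857 promax                 5.97

glance(loggaussian_fit(fs$loadings[, 1], wf_targets(wfm)))
#> # A tibble: 1 × 5
#>    peak width amplitude    r2 converged
#>   <dbl> <dbl>     <dbl> <dbl> <lgl>
#> 1  10.4 0.159      1.07 0.909 TRUE
```

Two components emerge (85.7% of the variance in this cohort), one tuned to
the low numbers and one to the high — their fitted log-Gaussian peaks (10.4
and 25.8 here) sit inside the generating peaks 8 and 32, an inward bias of
the method discussed in the vignette. A flat (1-channel) configuration run
through the same pipeline shows no distance falloff and a single component.

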