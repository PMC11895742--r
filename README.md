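# stratpulse

Quantitative analysis of extinction dynamics across a bedded stratigraphic
section, for paleobiologists working with occurrence databases and
geochemical proxy records at bed/sub-bed resolution (the motivating setting
is the Permian–Triassic boundary section at Meishan, South China).

The package answers three questions:

1. **Was the extinction pulsed or continuous, and where?** Observed last
   appearances (LADs) underestimate true extinction horizons when sampling is
   incomplete (the Signor–Lipps effect). stratpulse models per-bed sampling
   with recovery probabilities `p_b` and scores a `k`-pulse model by the
   missed-sampling likelihood

   ```
   L = prod_taxa  p_L(t) * prod_{L(t) < b <= P(t)} (1 - p_b)
   ```

   (taxon last seen in bed `L`, assigned to pulse bed `P >= L`), against an
   explicit continuous-interval alternative (extinction heights uniform over
   a run of beds). Positions are found by exhaustive scan over candidate
   horizons; the pulse count by BIC confirmed with a parametric-bootstrap
   likelihood-ratio test. Stratigraphic range confidence intervals use the
   classical uniform-recovery extension `r((1-C)^(-1/(H-1)) - 1)`.

2. **Which proxies shifted state, and when?** Continuous piecewise-linear
   (segmented) regression of each proxy against height, with the breakpoint
   count selected by BIC, doubles as the state-shift detector and as the
   imputation curve for beds without measurements. Spike-type tracers are
   screened for anomalies against the segmented trend (3 robust scales).

3. **Do proxies explain diversity and composition?** A correlation screen,
   VIF-based collinearity reduction, paired Poisson GLMs of per-bed species
   richness (two models when two focal proxies are mutually collinear), and
   partial distance-based RDA of Jaccard assemblage distances with
   permutation tests, plus a proxy-variance versus extinction-rate check.

A synthetic-data module generates occurrence tables (per-bed Bernoulli
sampling of taxa dying in pulses or an interval), piecewise-linear proxy
series, and Poisson-linked richness, so the whole pipeline is testable with
no external data; `fixture_mini_meishan()` bundles a deterministic toy
section used throughout the docs.

## Worked example

```r
library(stratpulse)

fx <- fixture_mini_meishan()          # synthetic 12-bed, 40-taxon section
cfg <- analysis_config(
  column = fx$column, occurrences = fx$occurrences, proxies = fx$proxies,
  window = c("2", "11"), n_perm = 199, n_boot = 99, seed = 11
)
report <- run_full_analysis(cfg)
report$pulses
#> Extinction pulse model: k = 2 pulse(s) at bed(s) 6, 10 (-0.500, 4.500 m)
#>   taxa: 35   logLik: -11.320   BIC: 29.750
#>   95% bootstrap CIs (m):
#>         low high
#> pulse1 -0.5 -0.5
#> pulse2  4.5  4.5
report$proxies$d13C_carb$fit
#> Segmented regression: 1 breakpoint(s) at -0.5877
#>   SSE: 0.83687   BIC: -214.168   converged: TRUE
#> intercept     slope    delta1
#>   2.05896   0.00939  -1.49939
```

The pooled model recovers the fixture's two extinction pulses (beds 6 and
10; heights are meters relative to the column datum) from LADs thinned at
recovery 0.9, with zero-width bootstrap CIs because the LAD clusters are
unambiguous at this sampling rate. The carbon-isotope proxy's single state
shift lands at the first pulse (truth: breakpoint -0.5 m, slopes 0 then
-1.5, intercept 2). `run_full_analysis(..., out_dir =)` additionally
writes `fig2_pulses.tsv`, `fig3_breakpoints.tsv`, `table1_glm.tsv`,
`fig4_scores.csv`, `variance_rate.tsv` and a run log.

Individual stages are plain functions: `vet_occurrences()`,
`compute_ranges()`, `range_ci()`, `select_pulse_count()`,
`select_segmented()`, `impute_missing()`, `fit_poisson_glm()`,
`partial_dbrda()`, … — see the vignette
(`vignettes/extinction-pulse-analysis.Rmd`) for the models, assumptions and
tuning parameters.

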