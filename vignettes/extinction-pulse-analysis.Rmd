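---
title: "Quantifying extinction dynamics across a stratigraphic section"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying extinction dynamics across a stratigraphic section}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratpulse)
```

## The problem

At a bedded marine section such as Meishan (South China), the Permian–Triassic
mass extinction is recorded as a pile-up of last appearance datums (LADs) of
fossil species, and the environmental upheaval as shifts and spikes in
geochemical proxy series (carbon, oxygen, cadmium and calcium isotopes, iron
speciation, and others). Two inference problems stand between the raw data and
any statement about extinction dynamics:

1. **The Signor–Lipps effect.** Sampling is incomplete, so observed LADs fall
   below true extinction horizons. An abrupt extinction is smeared downward
   into an apparently gradual one; counting LAD clusters naively overstates
   gradualism and misplaces pulses.
2. **Resolution mismatch.** Proxies are measured at arbitrary heights by
   different studies, on the outcrop and on a core with different bed
   thicknesses, while fossils are resolved to beds and sub-beds. Linking the
   two requires height standardization, bed-level aggregation, and imputation
   of unsampled beds.

stratpulse implements the full chain: occurrence vetting and range
construction, pulse-count inference under a missed-sampling model, segmented
regression of proxies, and association models (Poisson GLMs of richness,
partial distance-based RDA of assemblage composition).

## The extinction-pulse model

Work on a window of `B` beds, indexed in stratigraphic order. Each bed `b` has
a *recovery probability* `p_b`: the chance that a taxon alive in bed `b` is
actually sampled there. The default estimator is occupancy among range-through
taxa,

```
p_b = (# taxa with an occurrence in b) / (# taxa whose range spans b),
```

floored at `eps = 1/(2 n_taxa)`. The same floor is applied to the miss
probability `1 - p_b`: an estimated `p_b = 1` comes from a finite denominator
and must not make a miss infinitely improbable, otherwise a single
completely-sampled bed buys spurious extra pulses with effectively infinite
log-likelihood differences.

**k-pulse model.** True extinctions happen at `k` discrete horizons. A taxon
assigned to pulse bed `P` but last seen in bed `L <= P` was sampled at `L` and
missed in every bed of `(L, P]`:

```
L_taxon = p_L * prod_{L < b <= P} (1 - p_b).
```

Given candidate pulse positions (the observed LAD beds), the optimal
assignment maps each taxon to the nearest pulse at or above its LAD, so the
profile likelihood over placements can be scanned exhaustively; the topmost
pulse must sit at the topmost LAD bed. Ties prefer fewer pulses, then lower
horizons (parsimony and reproducibility).

**Interval model (`k = 0`).** True extinction heights are uniform over a
contiguous run of beds `[low, high]`; the observation model is unchanged and
the likelihood marginalizes over the unknown extinction bed. Bounds are
scanned over all bed pairs.

**Model count selection** is the two-step procedure: positions given `k`
(above), then `k` itself by BIC over `{interval, 1, ..., K_max}` with
`k` parameters per pulse model and 2 for the interval. Because BIC can buy an
extra pulse to absorb a handful of stragglers, every adjacent decision between
pulse counts (`k` vs `k - 1`, `k >= 2`) is confirmed by a parametric-bootstrap
likelihood-ratio test at `alpha = 0.05`: datasets are simulated from the
smaller fitted model (each taxon dies at its assigned pulse; its LAD is
redrawn from the conditional missed-sampling distribution), both models are
refitted, and the observed LR is compared to the bootstrap distribution. A
bootstrap dataset on which the larger model is unidentifiable (fewer distinct
LAD beds than `k`) contributes `LR = 0`. Singletons (taxa known from one
horizon) are excluded throughout: their extinction timing is uninformative.

Uncertainty on pulse positions comes from a taxon bootstrap (resample taxa
with replacement, refit positions at fixed `k`, percentile intervals).
Per-clade analyses refuse to fit clades with fewer than `min_richness = 10`
non-singleton species — with less data the placement likelihood is almost
flat — and report them as `"insufficient"`.

## Stratigraphic conventions

- Heights are meters, positive up, relative to the column datum (for Meishan,
  the base of bed 27c, the biostratigraphic Permian/Triassic boundary).
- Beds are half-open `[base, top)`; a sample exactly at a bed top belongs to
  the bed above. Bed labels sort by numeric part, then letter suffix
  (`24a < 24e < 25`).
- FAD/LAD heights sit at the midpoint of their bed: sub-bed thickness is the
  data's resolution, and midpoints avoid zero-length artifacts between
  adjacent sub-beds.
- The range confidence interval is the classical uniform-recovery extension
  `r ((1 - C)^(-1/(H-1)) - 1)` (observed range `r`, `H` fossiliferous
  horizons). The confidence level is configurable and defaults to `C = 0.95`.
- Richness is counted range-through by default (sampled-in-bin is an option);
  the per-bed extinction rate is `LADs / range-through richness` with
  `0/0 = 0` and no edge correction.

## Segmented regression

Proxy state shifts and the imputation curve use continuous piecewise-linear
least squares, `y = b0 + b1 x + sum_j d_j (x - psi_j)_+`. Breakpoints are
estimated by iterative linearization (gap-covariate update), restarted from
10 deterministic quantile-spaced configurations, and additionally guarded by
an exhaustive scan over placements at observed `x`-values (thinned to at most
a few thousand combinations); the best SSE wins. This keeps the optimizer at
or below the data-restricted grid optimum on every instance. Constraints: at
least 3 points per segment and breakpoints strictly inside the span. The
breakpoint count is chosen by BIC with two effective parameters per
breakpoint (position + slope change); a sequential-testing alternative is out
of scope. Breakpoint precision is inherently cube-root-limited: around the
optimum the SSE profile grows like `|psi - psi0|^3`, so with noise at 10% of
the signal range and `n = 100` over a 10 m span the estimator's spread is a
few decimeters no matter the optimizer — tests and acceptance checks use a
±0.5 m tolerance, about five times the median sample spacing of that design.

Transient spikes (volcanism-type tracers such as Hg/TOC) are *anomalies*, not
state shifts: a sample is flagged when its absolute residual from the
segmented trend exceeds 3 MAD-based robust scales of all residuals.

## Proxy handling

One dataset per proxy (mixing studies over the same beds is refused unless
explicitly allowed). Bed-referenced samples are placed at bed midpoints;
core heights are mapped to the outcrop scale through monotone tie points by
piecewise-linear interpolation, extrapolating terminal segments with a
warning. Bed-level values are arithmetic means over the half-open bed
interval; beds without samples are imputed from the segmented curve at the
bed midpoint and tagged `imputed` — observed means are never altered.

## Association models

The bed-by-proxy design matrix (observed or imputed, over the analysis
window) feeds:

- a Pearson/Spearman correlation screen (per pair, plus richness);
- VIF-based reduction: `VIF_j = 1/(1 - R²_j)`, iteratively dropping the
  worst column above 10, after any forced drops (e.g. a proxy measured at
  too coarse a resolution), with a full audit trail;
- paired Poisson GLMs when two focal proxies are too collinear to share a
  model (each model excludes one of them; AICs are compared);
- partial dbRDA: Jaccard distances between bed assemblages (binary,
  sampled incidence), embedded by principal coordinates and regressed on
  constraints after partialling out conditions, through `vegan::capscale`.
  Eigenvalues are rescaled to the classical PCoA scale so that the
  unconstrained analysis matches `cmdscale` exactly. Negative eigenvalues
  are reported, not corrected; a square-root transform of the distances is
  available as an option (it makes Jaccard distances Euclidean-embeddable),
  since published analyses often do not state this choice.
  Permutation tests (overall and marginal per term) use
  `p = (1 + #[F* >= F]) / (1 + n_perm)` with residual permutation under
  conditioning;
- a proxy-variance versus extinction-rate Spearman screen (within-bed sample
  variances, pairwise complete, `NA` when fewer than 4 beds or degenerate);
- an order-2 polynomial trend helper for scatter overlays.

Significance is read at `alpha = 0.05` wherever a decision is binary, and
**no multiple-testing correction is applied anywhere** — the screens are
descriptive, and the permutation and GLM p-values are reported per term for
the reader to judge. The GLM response is range-through richness per bed
(sampled-in-bin is available); observed proxy values are preferred to imputed
ones wherever both exist.

## The synthetic generators and what they do (not) show

`simulate_occurrences()` draws, per taxon, a true extinction bed (its pulse,
or uniform in the interval), an origination bed uniform at or below it, and
Bernoulli samples with per-bed recovery in every lived-through bed; taxa with
no hits are dropped and counted, as in a real database. `simulate_proxy()`
draws a piecewise-linear trend plus Gaussian noise; `simulate_linked_richness()`
draws Poisson counts through a log-linear link. All generators are pure
functions of their configuration (seed mandatory).

Default study conditions used by the tests and the acceptance script: a
20-bed column of 1 m beds; 60–80 taxa; recovery 0.7–0.8; pulses 8 beds
apart; intervals spanning 15 beds; proxy noise at 10% of the signal range
with `n = 100` samples; 200 replicates per recovery-rate estimate, 1000 null
simulations with 199 permutations for the dbRDA level check, and 10,000 taxa
for CI coverage. These sizes make each check stable to a few percent while
keeping a full run in minutes on one CPU.

What the generators deliberately do not emulate: lithology-dependent
preservation, sequence-stratigraphic truncation of ranges, autocorrelated
proxy noise, and taxonomic error beyond a flat synonym map. Passing tests
therefore demonstrate the estimators' correctness under the stated sampling
model, not robustness to facies-controlled preservation — on real sections
those effects are confounded with the extinction signal itself (a lithological
boundary inside the extinction interval shifts LADs for non-biological
reasons).

The bundled `fixture_mini_meishan()` is a deterministic 12-bed, 40-taxon,
4-proxy dataset with a known two-pulse extinction (beds 6 and 10, recovery
0.9) and one proxy breaking at the first pulse; it is fully synthetic and
used throughout the documentation and tests.

## Numerical choices and degenerate inputs

- Likelihood floors: `eps = 1/(2 n_taxa)` on both `p_b` and `1 - p_b`.
- Segmented fits: convergence when breakpoint updates fall below `1e-8`
  of the x-range, 50 iterations, steps damped to the span; degenerate `x`
  and too-short series are errors, as are pulse fits with fewer distinct LAD
  beds than pulses, intervals from a single LAD bed, and saturated dbRDA
  constraint sets.
- Two all-empty bed assemblages are at Jaccard distance 0 by convention
  (with a warning); empty vs non-empty is 1.
- Zero-variance columns yield `NA` correlations and infinite VIFs are
  reported as `Inf` and dropped first.
- Everything stochastic (selection bootstrap, CIs, permutations, simulators)
  takes an explicit seed and restores the caller's RNG state.

## Design choices that were genuinely open

- The published two-step pulse algorithm family specifies positions-then-count
  but not one concrete observation model; this package fixes the per-bed
  Bernoulli missed-sampling likelihood above, BIC + bootstrap-LRT selection,
  and LAD-bed candidate horizons, and validates the combination by simulation
  (brute-force equality on small instances; recovery rates at study scale).
  The explicit `k = 0` interval model is part of the model space because a
  continuous extinction interval is a scientifically distinct conclusion
  from any pulse count.
- Breakpoint-count selection uses BIC rather than sequential hypothesis
  testing: deterministic, simple, and validated by the same recovery
  simulations.
- FAD/LAD at bed midpoints, half-open beds, and label ordering
  `(number, suffix)` were chosen once for internal consistency and are
  documented rather than configurable.

## Limitations

Pulse positions are restricted to observed LAD beds (a pulse in a bed where
nothing was last-seen is indistinguishable under the likelihood); the
recovery profile is treated as known when passed in, and as a plug-in
estimate otherwise — its uncertainty is not propagated; the interval model
assumes a single contiguous interval; and the association models are
correlational by construction (collinear proxies are dropped, not causally
disentangled).

## A worked run

```{r, eval = FALSE}
fx <- fixture_mini_meishan()
cfg <- analysis_config(
  column = fx$column, occurrences = fx$occurrences, proxies = fx$proxies,
  window = c("2", "11"), n_perm = 199, n_boot = 199, seed = 1
)
report <- run_full_analysis(cfg, out_dir = "report")
report$pulses          # pooled extinction model (k, beds, bootstrap CIs)
report$glm$model_a     # Poisson GLM excluding the first focal proxy
report$ordination$permutation
```
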