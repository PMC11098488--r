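# popcoding

Population-coding analysis of hippocampal spike patterns from head-fixed
virtual-track recordings, for electrophysiologists comparing network-level
activity statistics across brain regions or experimental groups (e.g. dorsal
vs ventral CA1, disease-model vs control animals).

The package implements, as tested reusable functions:

- **Spatial coding** — occupancy-normalised rate maps on a 111-bin / 190 cm
  track, Skaggs spatial information
  `I = Σ_x p_x (λ_x/λ) log2(λ_x/λ)` (bits/spike), circular-shuffle null
  distributions, split-half stability.
- **Functional structure** — Pearson correlations of z-scored 10 ms
  firing-rate traces, 250-pair session means, thresholded graphs (r > 0.06)
  with relative degree and global transitivity on 16-unit subsamples.
- **Pattern statistics** — 10 ms binary patterns, plug-in Shannon entropy
  `H = −Σ_k p_k log2 p_k` with explicit normalisation modes, coactivity
  distributions, rate-matched subsample pairing.
- **Pairwise maximum-entropy (Ising) models** —
  `P(σ) = Z⁻¹ exp(Σ h_i σ_i + ½ Σ_{i≠j} J_ij σ_i σ_j)` fitted by exact
  2^n enumeration (moment residuals ≤ 1e−6), Kullback–Leibler divergence on
  the empirical support, and a coactivity-resolved prediction-error
  decomposition.
- **Sharp-wave/ripples** — 150–250 Hz zero-phase band power detection
  (2 SD threshold, 15 ms minimum duration, 1 s refractory, locomotion
  exclusion), peri-SWR time histograms, circular-shuffle modulation indices,
  and SWR vs non-SWR epoch correlations.
- **Coding space** — per-subsample (mean correlation, entropy, KLD) feature
  triplets, a 5-NN group/region decoder with shuffled-label nulls, and a
  10,000-resample bootstrap variance-ratio test.
- **Synthetic sessions** — seeded generators for behaviour (immobility/run
  bouts, lap teleports), place-field Poisson or Ising-coupled spiking
  (compiled Gibbs sampler), and multichannel LFP with ground-truth ripple
  bursts and positively/negatively modulated units.

## Worked example

```r
library(popcoding)

beh <- simulate_behavior(600, mean_run_speed = 5, run_fraction = 0.1, seed = 1)
gt  <- ground_truth(
  unit_rates   = runif(18, 2, 8),
  place_fields = data.frame(unit = 1, center_bin = 55,
                            width_bins = 4, peak_gain = 10),
  seed = 2)
ses <- simulate_session(gt, beh, seed = 3,
                        metadata = list(group = "control", region = "dorsal",
                                        session_id = "demo"))
ses
#> <session_recording> 18 units, 600.0 s [control/dorsal], no LFP

res <- circular_shuffle_null(ses$units[[1]]$spike_times, ses$duration, beh,
                             n_shuffles = 100, seed = 4)
sprintf("unit 1 spatial information: %.3f bits/spike (null mean %.3f)",
        res$info, mean(res$null_infos))
#> "unit 1 spatial information: 0.586 bits/spike (null mean 0.128)"

raster <- binarize(ses)                                   # units x 10 ms bins
sub <- draw_subsamples(raster, k = 16, n_subsamples = 1, seed = 5)
d   <- pattern_distribution(sub$rasters[[1]])
ent <- normalized_entropy(d, mean_population_rate = raster_mean_rate(sub$rasters[[1]]))
fit <- fit_pairwise_maxent(d)
fit
#> <maxent_model> 16 units (16 fitted), logZ = 0.7297, residual 2.6e-09
kld <- kld_on_support(d, model_distribution(fit))
sprintf("entropy %.1f bits/s; maxent KLD %.4f bits", ent$entropy_rate, kld)
#> "entropy 414.0 bits/s; maxent KLD 0.0225 bits"
```

The place-field unit carries 0.586 bits of position information per spike —
far above its 0.128-bit shuffle null (rank above all 100 shuffles), so its
spatial tuning is significant. The 16-unit subsample visits patterns at an
entropy rate of 414 bits/s, and the pairwise maximum-entropy model fitted to
its single-unit and pairwise moments leaves only 0.0225 bits of divergence
on the observed patterns: for this (uncoupled, Poisson) synthetic population,
pairwise structure explains the pattern distribution almost completely.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the pipeline end-to-end on a seeded synthetic cohort — two
groups × two regions, 600 s sessions — running spatial information with
nulls, correlation/graph metrics, entropy and maximum-entropy fits per
16-unit subsample, SWR detection/modulation/epoch correlations against
ground truth, the 4-way coding-space decoder, and the bootstrap variance
test, then writes its JSON report to `--out`. Progress and summary
statistics are logged to stderr.

## Layout

- `R/`, `src/` — implementation (R with one Rcpp Gibbs sampler).
- `tests/testthat/` — unit, property and acceptance suites; all fixtures
  are generated in code.
- `vignettes/population-coding.Rmd` — methods: models, assumptions,
  parameter choices, synthetic-world design, limitations.
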