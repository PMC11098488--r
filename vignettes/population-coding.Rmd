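---
title: "Population coding analysis of hippocampal spike patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population coding analysis of hippocampal spike patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popcoding)
```

## Scope

`popcoding` analyses population spiking from head-fixed rodents running a
1.9 m virtual linear track, of the kind recorded with silicon probes from
dorsal and ventral hippocampal CA1. The pipeline covers single-unit spatial
coding (Skaggs information, shuffle nulls, split-half stability), pairwise
functional structure (correlation matrices, thresholded graphs), population
state statistics (10 ms binary pattern entropy, pairwise maximum-entropy
models with divergence diagnostics), sharp-wave/ripple (SWR) detection with
peri-event modulation statistics, and a k-nearest-neighbour decoder operating
on a three-dimensional "coding space" of per-subsample summary features. A
seeded synthetic-session generator supplies ground truth for every stage, so
the whole pipeline is testable without access to any particular recording.

## The pattern-entropy and maximum-entropy core

Spiking is binarised into 10 ms bins: unit $i$ contributes $\sigma_i = 1$ in
a bin containing at least one spike, else 0. The column vector
$(\sigma_1,\dots,\sigma_n)$ over a subpopulation is a *pattern*; a population
of $n$ units has $2^n$ possible patterns ($1024$ for $n=10$, $65{,}536$ for
$n=16$). The diversity of observed patterns is the Shannon entropy of the
empirical pattern distribution,

$$H = -\sum_k p_k \log_2 p_k,$$

estimated by the plug-in rule over the observed support. Three scalings are
always computed together: raw bits per bin, bits/s (raw divided by the bin
width), and a rate-normalised variant (raw divided by the population mean
firing rate). The reporting mode is an explicit, recorded argument because
the field mixes these units freely and no single normalisation can be
inferred from a number's magnitude alone; the package default is bits/s.
The plug-in estimator is negatively biased at finite samples (the tests
verify convergence to enumeration truth from below); no bias correction is
applied, matching common practice, and this is a known limitation.

The least-structured distribution consistent with each unit's activation
probability and each pair's coactivation probability is the pairwise
maximum-entropy (Ising) model

$$P(\sigma_1,\dots,\sigma_n) = \frac{1}{Z}\exp\Big(\sum_i h_i \sigma_i +
\tfrac{1}{2}\sum_{i \ne j} J_{ij} \sigma_i \sigma_j\Big).$$

`fit_pairwise_maxent()` maximises the average log-likelihood with BFGS using
exact gradients — empirical minus model moments — computed by enumerating all
$2^n$ patterns, which is feasible and error-free for the $n \le 16$
subsamples this pipeline uses (hard limit $n \le 20$). Convergence is
declared when the largest absolute moment residual is at most $10^{-6}$
(configurable); non-convergence raises a classed error carrying the residual
rather than returning a silently bad model. Units that never fire (or always
fire) inside a subsample have no finite field term; they are excluded from
the fit and re-inserted as deterministic bits in the predicted distribution.
Log-probabilities are handled in natural log with log-sum-exp stabilisation
and converted to bits only at reporting.

Model fit is quantified on the empirical support only: the Kullback–Leibler
divergence $\sum_k p^{emp}_k \log_2 (p^{emp}_k / p^{pred}_k)$, and a
coactivity-resolved error decomposition. Each observed pattern's relative
error $|p^{pred}_k - p^{emp}_k| / p^{emp}_k$ is summed within its coactivity
category (the number of simultaneously active units) to give a total
prediction error per category, and divided by the category's support count
for the mean per-pattern error; empty categories report a zero total and an
undefined mean. Two analytic anchors pin the implementation down: any
full-support 2-unit distribution is fitted exactly (three parameters, three
degrees of freedom), and the uniform distribution on the even-parity
patterns of three units — whose pairwise moments exactly match independence —
yields a uniform fitted model and a KLD of exactly 1 bit.

## Spatial coding

The track is divided into 111 bins (~1.7 cm). Only samples with velocity
strictly above 5 cm/s contribute, to occupancy and spike assignment alike.
Per-bin rate is spike count over occupancy time, smoothed with a 5-bin
square wave; at the track ends the window is truncated and renormalised
rather than wrapped, because the track teleports to the start rather than
looping. Bins never visited at running speed are excluded and the occupancy
distribution renormalised. Spatial information is the Skaggs bits-per-spike
form

$$I = \sum_x p_x \frac{\lambda_x}{\lambda} \log_2 \frac{\lambda_x}{\lambda},$$

with $p_x$ the occupancy probability, $\lambda_x$ the smoothed rate in bin
$x$ and $\lambda$ the occupancy-weighted mean rate. This form is invariant
to a global rescaling of the rates and never increases under coarsening of
the spatial bins — both properties are tested. Smoothing is applied to the
rate vector (after dividing counts by occupancy); the alternative order is
not distinguishable from published descriptions, and this choice keeps the
occupancy normalisation exact.

The null distribution comes from circular shuffling: all spikes of a unit
are shifted by one uniform random offset and wrapped modulo the session
duration, preserving the spike count and the inter-spike interval structure
exactly while destroying the spike–position relationship; 100 shuffles per
unit by default. Significance uses the count-based rank rule — more than 95
of 100 null values below the empirical value — whose false-positive rate
under exchangeability is exactly $5/101 \approx 4.95\%$; R's interpolated
quantile would make the rate drift above 5% and is not used. Split-half
stability is the Pearson correlation between the smoothed rate maps of the
two session halves, undefined when either half has no rate variance.

## Correlation matrices and functional graphs

Firing-rate traces are spike counts in a sliding 10 ms window (step equal to
the window by default; the step is configurable because published
descriptions leave it open), z-scored per unit over the whole session.
Zero-variance units are flagged and excluded from pairs — Pearson
correlation is undefined for them — rather than assigned a zero. The mean
pairwise correlation of a session is computed on a random subsample of 250
unit pairs (all pairs when fewer exist), which prevents sessions with many
units from dominating pooled comparisons.

Graphs are built on 16-unit subsamples by thresholding the signed
correlation at $r > 0.06$ (strict; negative correlations never create
edges). Relative degree is edges over $\binom{16}{2}$. The clustering
coefficient is the global transitivity — closed connected triples over all
connected triples, with a triangle contributing three connected triples —
delegated to igraph and cross-checked in the tests against an exhaustive
triplet enumerator on every graph of up to six nodes. A triplet-free graph
is assigned clustering 0 so the metric stays total across sparse subsamples.

## Sharp-wave/ripple analysis

Each LFP channel is band-pass filtered at 150–250 Hz with a zero-phase FFT
filter (purely real gain, hence no phase distortion of onset timing),
squared, summed across channels, and smoothed with a Gaussian kernel of
4 ms standard deviation and 32 ms width. Epochs where this trace exceeds the
mean plus 2 SD are candidate events; candidates shorter than 15 ms, those
overlapping locomotion (any behaviour sample above 5 cm/s), and those
starting within 1 s of the previous kept event's end (the earlier event is
kept) are eliminated. The threshold is expressed in SD units, so detection
is invariant to a global LFP gain. Full-session statistics set the
threshold; restricting to immobility changes it only marginally at the
~10% running fractions typical of these sessions. Two behaviours of this
detector are worth knowing. First, its false-positive floor on pure noise
is not zero (~0.25 events/s on the generator's noise): a 2 SD threshold on
a smoothed power trace with ~10 ms correlation time is crossed for ≥15 ms
stretches at that rate. In ripple-bearing sessions the events themselves
inflate the power SD, raising the threshold, and spurious detections vanish
in practice. Second, onset timing is accurate to ~1 ms in the median but
has an early tail: under a strong burst, in-band noise riding on the
kernel-smeared leading edge can pull the threshold crossing several
milliseconds early, bounded by the kernel's 16 ms half-width. This is a
property of the smoothing-plus-threshold definition, not of the
implementation.

The peri-SWR time histogram (pSWR-TH) spans ±500 ms around event onset in
10 ms bins (the bin width is not fixed by published descriptions; 10 ms
matches the pipeline's pattern scale and is configurable). The modulation
index is the summed squared difference between the empirical pSWR-TH and
the mean of 500 circularly shuffled pSWR-THs inside the 0–200 ms window
after onset; a unit is modulated when its index exceeds the 95th percentile
of the per-shuffle indices. The shuffle shifts the unit's whole spike train
modulo the session duration — the same circular shuffle used for spatial
nulls; an alternative reading (shuffling within each peri-event window
only) is possible from published wording, but the whole-train shift is the
conservative choice consistent with the rest of the pipeline. The sign of
the extremal deviation in the window gives the modulation class, and the
lag is the time of the pSWR-TH extremum. SWR versus non-SWR correlations
concatenate the 500 ms after each onset into one spike set and an equal
number of randomly placed SWR-free 500 ms intervals into another
(non-overlapping by construction; an error reports the deficit when the
recording lacks enough SWR-free time), then apply the identical correlation
machinery to both.

## Coding space, decoder, and variance test

Each 16-unit subsample is summarised by three numbers: mean pairwise
correlation, pattern entropy (mode-tagged), and the KLD of its fitted
maximum-entropy model. The decoder assigns each held-out point the majority
label of its five nearest training neighbours (Euclidean distance), with
ties broken by the nearest neighbour carrying a tied label — a deterministic
rule, unlike the random tie-breaks of common kNN implementations. Splits
are 80/20, stratified by class to avoid empty-class training sets, and
repeated 100 times; the null repeats the procedure with shuffled training
labels. Features are z-scored with training-set statistics before distances
are computed (toggleable): without standardisation the KLD's small numeric
scale would be invisible next to entropy in bits/s. Subsamples from one
session can land in both train and test sets, which makes accuracies
optimistic with respect to session-level generalisation; a session-grouped
split is not implemented and this caveat should accompany any reported
accuracy.

The firing-rate heterogeneity test uses the variance ratio
$\sigma^2_A/\sigma^2_B$ as its statistic: both groups are resampled with
replacement 10,000 times, the p-value is the proportion of bootstrap ratios
exceeding 1, and the null of equal variances is rejected at the two-sided
5% level when $p < 0.025$ or $p > 0.975$. Bootstrap draws where group B has
zero variance are redrawn and counted.

## The synthetic world

`simulate_behavior()` alternates immobility and running bouts with
gamma-distributed durations (mean running bout 2 s; immobility scaled to hit
the requested running fraction), emulating head-fixed sessions in which
animals run ~10% of the time at 5–6 cm/s; position integrates velocity and
teleports to zero at the 190 cm lap end. The locomotion flag is fixed at
velocity > 5 cm/s to match the analysis threshold. Per-bout running speed is
drawn 5–35% above the nominal speed so flagged samples genuinely exceed the
threshold.

Sessions are generated in one of two modes. Independent mode: each unit is
an inhomogeneous Poisson process at its ground-truth rate, multiplied during
locomotion by a Gaussian place-field gain profile and renormalised so the
session-mean rate still matches the ground truth. Coupled mode: 10 ms
patterns are Gibbs-sampled (compiled sampler, 100 burn-in sweeps, 5 sweeps
between retained bins) from a ground-truth Ising model and one spike is
placed uniformly inside each active bin; in this mode the ground-truth rates
are defined as the model's exact-enumeration rates, so the rate contract
holds in both modes. Waveform trough-to-peak times are drawn from a 2:1
broad/narrow bimodal mixture unless supplied.

Synthetic LFP is Gaussian 1/f background noise (spectral exponent 1) —
chosen because only threshold crossings relative to the noise matter to the
detector — with ripple bursts as 150–250 Hz sinusoids of 30–100 ms under a
Tukey envelope: Hann-shaped 8 ms on/off ramps around a sustained plateau.
The cosine ramps keep onsets free of filter ringing while rising fast
enough that threshold detection recovers onsets at millisecond precision; a
full-Hann envelope was rejected because its slow rise delays the threshold
crossing by an amplitude-invariant 8–16 ms (the bursts themselves set the
power SD), destroying onset-timing validation. The default burst amplitude
(4, against a unit-SD broadband background) corresponds to 15–20 times the
in-band noise SD — a strong but physiological ripple; far larger amplitudes
push the detector into a regime where kernel smearing biases onsets early.
Bursts are placed only during immobility with at least 1.2 s separation,
and modulated units multiply (positive) or divide (negative) their rate by
the ground-truth gain inside the 200 ms window after each onset. Reward
licking and theta/gamma oscillations are deliberately not modelled; a green
test therefore establishes correctness of the analysis machinery on
pattern-structured Poisson/Ising spiking, not fidelity to every feature of
real CA1 data.

## Numerical and policy choices

- Binning uses half-open intervals $[t_0 + b\Delta, t_0 + (b+1)\Delta)$;
  a spike exactly on a boundary belongs to the later bin.
- The excitatory/inhibitory waveform split is at 0.5 ms trough-to-peak;
  exactly 0.5 ms is assigned inhibitory (the two published strict
  inequalities leave the point undefined; any fixed choice suffices).
- Sessions must have strictly more than 16 units to be subsampled at
  $k = 16$; subsamples may share units across draws.
- Rate-trace z-scoring uses the full session, not running periods only.
- Every generator and resampling routine takes a `seed` argument,
  evaluated under a temporarily-set RNG state that is restored afterwards,
  so seeded calls are pure functions of their seed and never perturb the
  caller's random stream.
- The rate-matched control pairs subsamples across groups at ±0.1 Hz mean
  rate; unmatched entries are dropped and reported, and a zero-match
  outcome is an explicit failure report rather than a silent empty result.

## Limitations

Plug-in entropy and KLD estimates are biased at small bin counts; the
package reports what the estimator computes and leaves corrections to the
caller. The decoder's train/test splits are not session-grouped. The exact
enumeration strategy caps maximum-entropy fits at 20 units; larger
populations would require MCMC fitting, which is out of scope. SWR onset
timing inherits the several-millisecond early tail discussed above.
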