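---
title: "Models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippotools)
```

This vignette is the package's own account of the science it implements:
the models behind each analysis, the parameters that matter, the numerical
conventions, and the places where a genuinely open design question had to
be decided. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Spatial coding

### Rate maps

A square open-field arena (default 50 cm side) is discretized into a
15 × 15 grid, so each bin covers (50/15)² ≈ 11.1 cm². Bin intervals are
half-open `[low, high)` with the last bin closed; a position exactly on an
interior edge belongs to the higher-index bin. Running speed is estimated
by centered finite differences, boxcar-smoothed over 0.1 s, and both the
occupancy map and the spike counts are restricted to samples faster than
3 cm/s — place fields are poorly expressed during immobility, and the speed
filter removes those epochs. Spike positions are linearly interpolated from
the tracking at spike times. The raw rate map is spike count divided by
dwell time per bin; bins never visited above the speed threshold are
*undefined* (`NA`), never zero-filled, and are excluded from every
downstream sum.

Smoothing uses a Gaussian kernel with a standard deviation of 1 bin,
truncated at 3 SD and renormalized over visited bins, so unvisited bins
contribute no weight and remain undefined in the output. For large unit
populations `session_si_table()` applies the identical smoothing through a
precomputed linear operator; a unit test pins the two code paths to 1e-12.

### Spatial information

The default (`mode = "skaggs"`) is the standard occupancy-weighted form

$$\mathrm{SI} \;=\; \sum_x p_x \frac{\lambda_x}{\bar\lambda}
  \log_2 \frac{\lambda_x}{\bar\lambda},
  \qquad \bar\lambda = \sum_x p_x \lambda_x,$$

with $p_x$ the dwell-time proportion of bin $x$ and $0\log 0 \equiv 0$.
A second mode (`"literal"`) implements the formula as it is sometimes
printed, without the per-bin occupancy weight inside the sum:
$\mathrm{SI} = \tfrac{1}{n}\sum_x (\lambda_x/\bar\lambda)\log_2(\lambda_x/\bar\lambda)$
over the $n$ visited bins. In literal mode $\bar\lambda$ is the unweighted
mean rate over visited bins — the only reading under which the quantity is
guaranteed non-negative (by Jensen's inequality, since the unweighted mean
of $\lambda_x/\bar\lambda$ is then exactly 1) and zero exactly on uniform
maps. Both modes are tested against a brute-force direct-sum oracle; the
mode is a visible argument so the (small) discrepancy between the two
conventions is measurable rather than hidden. SI is undefined — returned as
`NA`, never 0 — when the mean rate is zero.

### Quadrants

An odd grid cannot split into four equal quadrants, so bins whose centers
lie exactly on an arena midline (the 8th row and column of the 15 × 15
grid) are excluded, leaving four 7 × 7 quadrants; this is symmetric and
convention-free. Per-quadrant SI renormalizes both the occupancy
proportions and the mean rate within the quadrant (`local_mean = TRUE`,
the default): each quadrant is treated as its own small environment, which
is the natural reading of "the SI was calculated separately for each
quadrant". The alternative — keeping the whole-map mean rate as the
reference — is available as a switch but is *not* the default because the
quadrant terms can then go negative (a below-average quadrant contributes
$t\log_2 t < 0$ for $t<1$) and localized tuning loss no longer moves all
units in the same direction, which destroys the power of the
inside-versus-outside comparison (we measured a collapse from 100% to 20%
detection at the default effect size when we evaluated both conventions).

### Unit inclusion

Units enter the spatial analysis when their whole-session mean rate lies in
[0.2, 5] Hz (bounds inclusive) — the putative-pyramidal band — and their
rate is at least 0.2 Hz in both the first and last 15 minutes, which
removes units lost or gained mid-session. These rates are computed from
unfiltered spike counts: the speed filter is part of map construction, not
of unit selection; a switch is provided.

### Session comparison

For the three-session protocol (S1 baseline, S2 inhibition confined to one
quadrant, S3 recovery), `compare_sessions()` computes per-unit changes in
quadrant SI from S1 and compares the target-quadrant deltas against the
deltas of the three non-target quadrants with a two-sided Mann–Whitney
test (exact null when $n_1 n_2 \le 400$ without ties, otherwise the normal
approximation with continuity and tie correction, via
`stats::wilcox.test`). Two deliberate choices:

* **Outside deltas are not averaged within unit for the test.** Under no
  manipulation every per-quadrant delta is identically distributed, so
  comparing 1 inside value against 3 outside values per unit keeps the
  test's size nominal. Averaging the three outside quadrants first shrinks
  their dispersion by about √3 and makes the comparison anti-conservative.
  The per-unit mean-of-three is still reported in the `deltas` table, where
  it is the natural per-unit summary.
* **The within-region comparisons are also reported** (`p_inside`,
  `p_outside`): the S2−S1 deltas tested against the S3−S1 deltas inside
  the target quadrant and outside it. An acute, reversible effect appears
  as a very strong within-target difference with, at most, a weak outside
  one.

In the simulation wrapper `simulate_inhibition_experiment()`, one
exploration path is reused for all three sessions by default (spiking is
independent per session). Finite-session SI estimates carry an
occupancy-dependent sampling bias; with a fresh path per session that bias
is shared by all simultaneously recorded units and differs between
sessions, which violates the independence assumption of the rank-sum test
across units and inflates its false-positive rate. Reusing the path models
a manipulation that leaves occupancy and running speed unchanged — the
regime the protocol is designed for — and makes session-to-session SI
changes reflect only the manipulation and spiking noise. With this
protocol the d = 0 rejection rate of both session tests is at its nominal
5 % (measured over 100 replicates); `shared_trajectory = FALSE` restores
fully independent paths.

## 2. Synthetic spatial data

The trajectory is an Ornstein–Uhlenbeck velocity process (relaxation time
1 s) with the driving noise scaled so the stationary speed distribution is
Rayleigh with the requested mean (default 8 cm/s), integrated at the
25-ms tracking interval and folded into the arena (reflecting walls). This
produces realistic speed distributions including the sub-3 cm/s epochs the
speed filter must remove. Spiking is inhomogeneous Poisson against the
per-sample rate

$$\lambda(t) = b + (p - b)\,
  e^{-\lVert x(t) - c\rVert^2 / 2\sigma^2}$$

(defaults: peak $p$ = 6 Hz, baseline $b$ = 0.3 Hz, field width $\sigma$ =
8 cm), piecewise constant over the 25-ms sample — adequate for rates up to
tens of Hz. Inhibition is modelled as *tuning flattening*: inside the
target quadrant during S2 the rate is mixed toward the cell's own
session-mean rate, $(1-d)\lambda(t) + d\bar\lambda$. This preserves the
mean firing rate while destroying spatial selectivity, matching the
observation that SI is lost with only minimal change in average rate;
silencing would confound the two. The degradation model is a stand-in for
an unknown mechanism, not an inference about it.

## 3. Punctum colocalization

### The measurement

Masks are intensities strictly above a threshold — either an explicit
number (standing in for the original manual adjustment, and recorded in
every result) or Otsu's between-class-variance criterion for unattended
runs (when the histogram valley is empty the optimal split is a plateau;
we take its middle). Connected components smaller than 0.1 µm² are
discarded; at 40-nm pixels that cutoff equals 62.5 px, so ≤ 62-px
components are removed and ≥ 63-px retained — an exact, testable boundary.
Connectivity is 8-neighbor by default (switchable to 4); the labelling is
a two-pass union-find implementation, cross-checked against
`EBImage::bwlabel` in the tests. The overlap mask is the pixel-wise
conjunction of the two *already filtered* channel masks, area-filtered
again (filtering the conjunction of unfiltered masks is the other
defensible order; post-filter inputs are the default here). Densities are
mask pixels over image pixels; the reference-normalized overlap
(`relative_to_b`) estimates the fraction of the reference channel's
terminal area that is double-labelled. Centroid colocalization uses
one-to-one mutual-nearest-neighbor matching with a 2-µm cap; a greedy
distance-sorted alternative is provided since the original tool's rule is
not public.

### The generator

Puncta are isotropic 2-D Gaussians (σ = 200 nm, peak 1000 intensity units)
rendered at 40-nm pixels on a 512² field, with centers kept 2σ from the
borders. At the default half-peak threshold a punctum mask has radius
σ√(2 ln 2) ≈ 5.9 px and area ≈ 109 px, comfortably above the 62.5-px area
cutoff — punctum size was chosen so the 0.1 µm² filter passes real puncta
and removes noise specks, as it does in practice. A colocalized A punctum
*is* a double-labelled terminal, so each one is assigned its own B punctum
(hosts drawn without replacement) and displaced by U(0, 40 nm) at a random
angle; exactly `round(coloc_fraction * N_A)` A puncta are colocalized.
Non-colocalized A puncta are rejected within `coloc_radius + 2σ` of any B
center — wider than the pairing radius alone — so chance overlaps cannot
survive the second area filter and blur the ground-truth labels. Densities
default to 0.3/µm². Two features of real data the generator does *not*
emulate: empirical PSF shape (real STED puncta are neither Gaussian nor
identical) and structured background; recovery results on synthetic images
therefore validate the measurement chain, not the thresholding of real
tissue. At high densities neighboring puncta merge into single mask
components (their intensities add), which biases component *counts* down
while leaving area-based densities nearly unbiased — the count-recovery
test runs on sparse fields for exactly this reason.

## 4. EPSC kinetics

Each stimulus evokes $A\,g(t)$ with the unit-peak biexponential
$g(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r}$, shifted by the synaptic
latency; pulses scale by `depression_ratio`$^{k-1}$ and sum linearly.
Defaults describe a slow, strongly depressing synapse: τ_rise 2 ms,
τ_decay 50 ms, amplitude −100 pA, latency 4 ms, depression ratio 0.05,
20 kHz sampling, 5 pulses at 10 Hz.

Measurement conventions (each is a parameter, and each is recorded):

* **Peak**: extremum in (stimulus, next stimulus or +250 ms]; "no
  response" below 3 baseline SDs.
* **Onset latency**: first crossing of 5 % of peak, linearly interpolated.
  The crossing must be *sustained* for 1 ms — a single noisy sample above
  the criterion does not count — because at realistic noise the first
  transient crossing is biased several hundred µs early. Heavy
  pre-smoothing is the wrong tool here: a centered boxcar raises the
  convex onset region and shifts the measured crossing earlier even on
  noiseless data (we measured ≈ 0.6 ms at a 2-ms window), so the default
  is no smoothing with the sustain rule, and 0.25 ms smoothing for noisy
  traces. A 3-SD-of-baseline criterion is available as the alternative.
* **20–80 % rise time**: interpolated between first crossings on the
  rising phase; on a saturating-exponential rise it equals τ ln 4 exactly,
  which the tests pin to 1 %.
* **Decay constant**: Levenberg–Marquardt fit of a single exponential
  (`minpack.lm::nlsLM`, log-linear initialization) from 90 % of peak on
  the falling phase to the earlier of the next stimulus or 95 % recovery.
  The fit additionally starts no earlier than three rise time constants
  (estimated from the 20–80 % time) past the peak: when τ_rise is within a
  factor of ~5 of τ_decay the 90 % point still carries rise-component
  contamination that inflates τ by up to 20 %.
* **Half-width**: interpolated width at 50 % of peak; undefined (flagged)
  when the falling crossing is truncated by the next stimulus. Equals
  τ ln 2 for an instantaneous-rise exponential.
* **Paired-pulse ratio**: second/first amplitude. Because these synapses
  decay slowly relative to the 100-ms interval, the first response's tail
  still carries ~15 % of its peak at the second stimulus; the fitted decay
  is extrapolated from its own fit window (anchored at the fitted
  amplitude, not the raw peak — the biexponential's pure-decay asymptote
  is above the peak value) and subtracted before measuring the second
  pulse. A plain peak measurement is switchable and demonstrably biased in
  the tests.

At SNR 10 (noise SD one-tenth of amplitude) amplitude, latency and decay
constant are recovered within 10 % across a 3 × 3 × 3 grid of
(τ_rise, τ_decay, amplitude); the acceptance script reports the worst-case
error.

## 5. Home-cage learning

Events are 24-h days anchored at the injection (day 0): session A spans
days −5…−1, the novel rotations B/C/D days 0–2, 3–5, 6–8, and the return
A\* days 9–13, so day 8 is the last novel day and day 9 the first return
day. The printed definition of the error rate (assigned pokes over total)
literally defines a success rate; since learning must *lower* an "error
rate", the package computes non-assigned/total by default and offers the
literal reading as a switch. Exclusion keeps animals strictly below 0.70
error on day −1 (the last initial-learning day); animals with no pokes
that day are excluded with a logged reason. Chance level with 8 ports is
7/8 = 0.875, which the tests verify by simulation.

The cohort generator gives each animal a saturating-exponential learning
curve in each session, $p(t) = p_\infty - (p_\infty - p_0)
e^{-t/\tau_{\mathrm{eff}}}$ (defaults $p_0$ = 1/8 — chance — $p_\infty$ =
0.6, τ = 1 day, ~100 Poisson pokes/day). The per-animal ablation covariate
slows learning in novel sessions (τ_eff = τ(1 + 6·ablation)) and acts
asymmetrically on the return session: the A\* curve starts from a
retention mixture of the previously learned performance, with retention
increasing in ablation — the animal that cannot learn the new port also
cannot forget the old one. This coupling reproduces the qualitative
dissociation the analysis must detect: error rate on the last novel day
correlates *negatively* with surviving-terminal density, error on the
first return day non-negatively. It is a phenomenological model chosen for
monotonicity, not a mechanistic claim.

`spearman_rank()` uses average ranks for ties and an exact permutation
p-value for n ≤ 10, enumerating all n! pairings (streamed over leading
elements so n = 10 stays in memory); `cor.test` cannot be exact under ties,
so it serves as the tie-free cross-check in the tests instead of the
implementation. Beyond n = 10 the usual t approximation applies. One-sided
tails are explicit: surviving density against novel-day error is tested
with the negative tail, against return-day error with the positive tail.

## 6. Problem sizes and reproducibility

All generators are pure functions of their parameters and one integer
seed; sub-streams derive from the seed with a counter-based splitter
(`split_seed`), so every sub-result is independently reproducible. The
test suite and acceptance script run at the study's native configuration —
30-min sessions, 100 units and 20 replicates for the inhibition
experiment; 512² images over five planted fractions; a 27-point EPSC grid
at 5 noise seeds; 8-animal cohorts over 20 replicates — chosen to estimate
each rate with single-digit-percent Monte-Carlo error. The two
20-replicate rate criteria are themselves binomial draws: with a perfectly
calibrated 5 %-level test, a ≥ 18/20 restoration criterion still fails
about 8 % of runs by seed luck alone.

## 7. Known limitations

* Spike trains are Poisson: no burstiness, theta modulation, phase
  precession or overdispersion; real SI sampling noise is somewhat larger
  at matched rates.
* The flattening model of photoinhibition is one of many rate models
  consistent with an SI decrease at constant mean rate.
* Synthetic puncta have ideal Gaussian profiles and flat background;
  automatic thresholds that recover them exactly may still disagree with
  an expert's manual threshold on tissue.
* The EPSC model is a linear sum of identical biexponentials; receptor
  saturation, asynchronous release and NMDA components are out of scope.
* The home-cage model draws pokes independently within a day; real
  nosepoke streams are bursty, which widens day-level confidence intervals
  relative to the simulation.
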