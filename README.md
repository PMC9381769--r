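# hippotools

Analysis tools for studies of the deep entorhinal (layer-6b / subplate)
projection to the hippocampus, covering the four quantitative arms such a
study needs:

1. **Place-cell spatial coding** — speed-filtered occupancy and firing-rate
   maps on a 15 × 15 grid, Gaussian smoothing, Skaggs spatial information
   (whole map and per quadrant), unit inclusion rules, and the three-session
   comparison used to quantify quadrant-confined optogenetic inhibition.
2. **Super-resolution punctum colocalization** — channel masks by manual or
   automatic threshold, the 0.1 µm² surface-area filter, signal and overlap
   densities, reference-normalized overlap (e.g. CPLX3⁺ fraction of the
   VGluT1 terminal area), and centroid-distance matching at 2 µm.
3. **EPSC kinetics** — peak amplitude, onset latency, 20–80 % rise time,
   monoexponential decay constant, duration at half maximum, and the
   paired-pulse ratio at 100 ms interstimulus interval, with
   overlap-corrected second-pulse amplitudes for slow synapses.
4. **Home-cage spatial learning** — session labelling over the
   A / B / C / D / A\* port schedule, daily error rates, the 70 % exclusion
   rule, group learning curves, and one-tailed Spearman correlations between
   terminal ablation and behavioral performance.

A synthetic-data module generates every input the pipeline consumes — arena
trajectories, place-field-tuned Poisson spike trains with quadrant-confined
tuning degradation, two-channel punctum images at 40-nm pixels with known
colocalized fractions, biexponential EPSC trains with short-term depression,
and multi-animal nosepoke logs with ablation-coupled learning curves — so
every analysis is testable end to end against known ground truth.

## The core statistic

Spatial information (bits per spike) of a rate map with per-bin rates
λ<sub>x</sub>, occupancy proportions p<sub>x</sub> and mean rate
λ̄ = Σ p<sub>x</sub> λ<sub>x</sub>:

    SI = Σ_x p_x (λ_x / λ̄) log2(λ_x / λ̄)

computed over visited bins only, with 0·log 0 ≡ 0. A `"literal"` mode with
the per-bin occupancy weight outside the sum is provided as well (see the
methods vignette for why both exist). Under quadrant-confined inhibition the
per-unit change in quadrant SI between sessions is compared inside versus
outside the target quadrant with a two-sided Mann–Whitney test.

## Worked example

```r
library(hippotools)

# three 30-min sessions, 30 place cells, 80% tuning degradation confined to
# quadrant 2 during S2
cells <- lapply(1:30, function(i) { set.seed(i); place_cell_params(runif(2, 5, 45)) })
eff   <- inhibition_effect(target_quadrant = 2, degradation = 0.8)
sim   <- simulate_inhibition_experiment(cells, eff, seed = 42)
tabs  <- lapply(names(sim), function(s)
  session_si_table(sim[[s]]$spikes, sim[[s]]$trajectory, session_label = s))
cmp   <- compare_sessions(tabs[[1]], tabs[[2]], tabs[[3]], target_quadrant = 2)
```

This prints (seed 42):

    median dSI(S2-S1) inside: -0.112  outside: -0.003
    inside vs outside: p(S2) = 1.94e-09, p(S3) = 0.85

The in-quadrant spatial information drops during the inhibition session
(S2) while the rest of the arena is untouched, and the difference vanishes
in the recovery session (S3).

```r
# punctum densitometry on a synthetic image pair with 15% planted overlap
pair <- generate_punctum_image_pair(punctum_field_params(coloc_fraction = 0.15), seed = 1)
coloc_densitometry(pair$image_A, pair$image_B, pixel_size_nm = 40,
                   threshold_a = 500, threshold_b = 500)
#> Two-channel densitometry
#>   density A: 0.0548  density B: 0.0552  overlap: 0.0075
#>   overlap / A: 0.1362  overlap / B: 0.1353
#>   thresholds: A 500, B 500

# EPSC metrics of a noiseless 10-Hz train (tau_rise 2 ms, tau_decay 50 ms,
# latency 4 ms, depression ratio 0.05)
tr <- baseline_correct(generate_epsc_train(epsc_params(noise_sd_pA = 0)))
epsc_metrics(tr)
#>   peak_amplitude_pA latency_ms rise_20_80_ms tau_decay_ms halfwidth_ms  ppr
#> 1               100       4.09          2.17           50         42.2 0.05
```

The recovered overlap fraction (0.135 of the reference channel) matches the
planted 0.15 within the pipeline's stated tolerance, and every EPSC metric
matches its analytic value (the 4.09-ms latency is the 4-ms synaptic delay
plus the analytic time to 5 % of peak).

## Vignette

`vignettes/methods.Rmd` documents the models behind the generators, every
tunable parameter with its default and unit, the numerical conventions
(bin edges, smoothing renormalization, area-filter boundary, fit windows),
and what passing the synthetic-data tests does and does not establish about
real recordings.
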