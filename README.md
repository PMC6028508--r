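# cfsedilution

Quantifying rare, slowly cycling (label-retaining) cells from CFSE
dye-dilution flow cytometry.

In a dye-dilution assay, cells are covalently labeled with CFSE and
cultured through a chase period; every division halves a cell's dye, so
the chase-time fluorescence histogram encodes the population's division
history. Cells that stay bright — label-retaining cells (LRCs) — have
divided rarely and are candidates for a quiescent-like compartment, e.g.
in tumor spheroid cultures. This package fits a mechanistic
two-population model to such histograms and reports the fraction of
founder cells in the slow compartment, together with the cycling kinetics
of both compartments. It is aimed at quantitative cell biologists and
modelers who have day-0 and chase-time event data (CSV; one intensity per
event) and want more than a hand-drawn CFSE-high gate.

## The model

Each population's division time follows a location-shifted gamma law with
a hard minimum cycle time *t_b*:

    K(t) = 0                                            for t <  t_b
    K(t) = ((t-t_b)/σ)^(λ-1) e^(-(t-t_b)/σ) / (σ Γ(λ))  for t >= t_b

Successive divisions form a renewal process: the density of the *n*-th
division time satisfies L_n = K * L_{n-1} (convolution), H_n(t) = ∫ L_n
is the probability of having divided at least *n* times, and the expected
cells observed in generation *n* per founder are

    N_n(t) = 2^n N_0 [H_n(t) − H_{n+1}(t)].

Generation-*n* cells carry I_0/2^n of their initial dye, so in
log-intensity the chase histogram is a mixture of copies of the day-0
density shifted by −n·log 2, weighted by N_n. The population is a
two-component mixture — rapidly cycling bulk plus a rare slow component —
with α the *founder* fraction of slow cells (the observed mixture weight
is expansion-adjusted). The seven parameters
(t_b, σ, λ for each population, plus α) are estimated by multi-start
Nelder–Mead least squares between observed and predicted histograms on a
variance-stabilized (square-root density) scale. A seeded agent-based
simulator generates ground-truth experiments for validation and power
analysis. Details and the reasoning behind every numerical choice are in
`vignettes/dye-dilution-model.Rmd`.

## Worked example

Simulate a 6-day labeling experiment under the default study conditions
(10^5 founders; bulk mean cycle 23 h; slow mean cycle 80 h; true slow
fraction α = 0.015; 15% measurement CV), then fit it blind:

```r
library(cfsedilution)

cfg <- simulation_config(n_cells = 1e5, seed = 1)
ex  <- simulate_dye_dilution(cfg)
smp <- sample_cells(ex)                      # cell-level events
d0  <- smp$measured_intensity[smp$chase_time == 0]
d6  <- smp$measured_intensity[smp$chase_time == 144]

bins <- default_bins(d0)
fit <- fit_dye_dilution(build_histogram(d6, bins),
                        initial_intensity_model(d0),
                        chase_time = 144,
                        config = fit_config(n_starts = 2,
                                            max_iterations = 1500,
                                            tolerance = 1e-7, seed = 1))
fit
```

```
Two-population dye-dilution model fit
  chase time: 144 h; 256 bins; 2 starts
  slow (label-retaining) fraction alpha: 0.0115
  bulk mean cycle: 23.01 h   slow mean cycle: 75.1 h
  objective: 0.0325879 (single-population: 0.0358944, improvement 9.2%)
  converged: TRUE; two populations supported: TRUE
```

The fit recovers the bulk kinetics (23.0 h vs the true 23 h), the slow
kinetics (75 h vs 80 h), and a slow fraction of 1.15% against the true
1.5% — α is informed by only a few hundred high-intensity events, so
expect relative errors of tens of percent at this sample size. The
two-population model beats the nested single-population fit by 9.2%,
above the default 5% support threshold. A model-derived sorting gate then
partitions the events:

```r
gate_high_retainers(d6, gate_value = lrc_gate(fit))
```

```
CFSE gate at intensity 697.1: 569 high (0.569%), 99431 bulk
```

`plot(fit)` overlays the observed histogram with the fitted mixture and
its per-population components; `summary(fit)`, `coef(fit)`,
`predict(fit)`, `residuals(fit)` and `simulate(fit)` behave as for any
fitted model object.

A command-line surface wraps the same functions
(`exec/cfse-dilution simulate|fit|gate|report`), reading YAML configs and
writing manifests sufficient to reproduce any run.

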