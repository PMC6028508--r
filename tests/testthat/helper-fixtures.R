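## Shared fixtures, all generated in code.

## small simulated experiment with default (study-condition) parameters
small_experiment <- local({
  cache <- NULL
  function(n_cells = 2e4, seed = 101, ...) {
    if (is.null(cache)) {
      cfg <- simulation_config(n_cells = n_cells, seed = seed, ...)
      cache <<- simulate_dye_dilution(cfg)
    }
    cache
  }
})

## day-0 / chase intensity vectors from a cell-level sample
experiment_samples <- function(ex) {
  smp <- sample_cells(ex)
  list(d0 = smp$measured_intensity[smp$chase_time == 0],
       chase = smp$measured_intensity[smp$chase_time == max(smp$chase_time)],
       records = smp,
       chase_time = max(smp$chase_time))
}

## quick total-variation between a named generation-fraction vector and a
## model fraction vector, padding the shorter with zeros
tv_fracs <- function(a, b) {
  n <- max(length(a), length(b))
  pad <- function(v) { out <- numeric(n); out[seq_along(v)] <- v; out }
  0.5 * sum(abs(pad(a) - pad(b)))
}

## per-founder mixture generation fractions from two filled
## generation_distributions at end of chase
mixture_generation_fractions <- function(gd_bulk, gd_slow, alpha) {
  nb <- gd_bulk$N[, ncol(gd_bulk$N)]
  ns <- gd_slow$N[, ncol(gd_slow$N)]
  n <- max(length(nb), length(ns))
  pad <- function(v) { out <- numeric(n); out[seq_along(v)] <- v; out }
  tot <- (1 - alpha) * pad(nb) + alpha * pad(ns)
  tot / sum(tot)
}
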