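## Parameter vector layout used by the optimizer (and coef.dd_fit):
## (bulk_t, bulk_sigma, bulk_lambda, slow_t, slow_sigma, slow_lambda, alpha)
param_names <- c("bulk_t", "bulk_sigma", "bulk_lambda",
                 "slow_t", "slow_sigma", "slow_lambda", "alpha")

#' Default admissible parameter ranges
#'
#' Cycle-time offsets 2--100 h and scales 0.1--50 h span mammalian
#' cell-cycle biology; the slow fraction is capped at 0.5 so the slow/bulk
#' ordering stays meaningful.
#'
#' @return A 2-row matrix (\code{lower}, \code{upper}) with one column per
#'   parameter.
#' @export
default_bounds <- function() {
  b <- rbind(lower = c(2, 0.1, 0.2, 2, 0.1, 0.2, 1e-4),
             upper = c(100, 50, 20, 100, 50, 20, 0.5))
  colnames(b) <- param_names
  b
}

#' Fitting configuration
#'
#' @param n_starts Number of Nelder-Mead starts (>= 1); the mixture
#'   objective is multi-modal, so several jittered starts are run and the
#'   best kept. Default 8.
#' @param max_iterations Iteration cap per start.
#' @param tolerance Relative objective-change convergence tolerance.
#' @param seed Integer seed for the start-point jitter.
#' @param bounds Admissible ranges as from [default_bounds()]; enforced by
#'   a finite penalty in transformed space.
#' @param fixed Optional named numeric vector of parameters (see
#'   [default_bounds()] column names) held constant during the fit.
#' @param step Renewal grid step in hours used for every objective
#'   evaluation (a fixed step keeps the objective continuous in the
#'   parameters); default 0.25 h.
#' @param loss Residual scale: \code{"hellinger"} (default; squared
#'   residuals on square-root densities, which variance-stabilizes the
#'   histogram noise so that the rare high-intensity shoulder carries
#'   weight comparable to the bulk peak) or \code{"density"} (squared
#'   residuals on the raw densities).
#' @param improvement_threshold Relative objective improvement of the
#'   two-population fit over the single-population fit above which the
#'   second population is called supported. Default 0.05.
#' @return A list of class \code{"fit_config"}.
#' @export
fit_config <- function(n_starts = 8L, max_iterations = 5000L,
                       tolerance = 1e-8, seed = 1L,
                       bounds = default_bounds(), fixed = NULL,
                       step = 0.25, loss = c("hellinger", "density"),
                       improvement_threshold = 0.05) {
  loss <- match.arg(loss)
  if (n_starts < 1) stop("'n_starts' must be >= 1", call. = FALSE)
  stopifnot(is.matrix(bounds), nrow(bounds) == 2L,
            ncol(bounds) == 7L, all(is.finite(bounds)),
            all(bounds[1L, ] < bounds[2L, ]))
  if (!is.null(fixed)) {
    if (is.null(names(fixed)) || !all(names(fixed) %in% param_names))
      stop("'fixed' must be named after the model parameters",
           call. = FALSE)
  }
  structure(list(n_starts = as.integer(n_starts),
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, seed = as.integer(seed),
                 bounds = bounds, fixed = fixed, step = step,
                 loss = loss,
                 improvement_threshold = improvement_threshold),
            class = "fit_config")
}

## search space: log for the positive parameters, logit for alpha
bound_penalty <- function(v, bounds) {
  lo <- bounds[1L, ]; hi <- bounds[2L, ]
  excess <- pmax(lo - v, 0) / (hi - lo) + pmax(v - hi, 0) / (hi - lo)
  if (any(excess > 0)) 10 * (1 + sum(excess)^2) else 0
}

clamp_to_bounds <- function(v, bounds) {
  pmin(pmax(v, bounds[1L, ]), bounds[2L, ])
}

## Square-root-scale residuals use the Anscombe offset of 3/8 count per
## bin when the event count behind the histogram is known: with sparse
## bins (the label-retaining shoulder holds ~10^2 events over ~10^1 bins)
## E[sqrt(X)] << sqrt(E[X]) and plain square-root residuals would shrink
## the fitted shoulder mass; sqrt(X + 3/8) removes most of that bias.
## The objective is divided by the count scale so its magnitude stays on
## the squared-density scale regardless of sample size.
loss_value <- function(observed, pred_density, loss) {
  o <- observed$density
  if (loss == "density") return(sum((o - pred_density)^2))
  s <- observed$total_events * observed$bins$dlog
  if (is.na(s) || !is.finite(s) || s <= 0)
    return(sum((sqrt(o) - sqrt(pred_density))^2))
  sum((sqrt(o * s + 0.375) - sqrt(pred_density * s + 0.375))^2) / s
}

#' Least-squares objective of the dye-dilution model
#'
#' Sum over bins of squared differences between the observed and the
#' predicted (forward-model) density at the chase time, on the square-root
#' density scale by default (see [fit_config()]). When \code{bounds} is
#' supplied and a parameter lies outside it, a large finite penalized
#' value is returned instead of a prediction.
#'
#' @param params A [mixture_params()].
#' @param observed Observed \code{intensity_histogram} (normalized).
#' @param init An [initial_intensity_model()].
#' @param chase_time Chase duration in hours.
#' @param step Renewal grid step; see [forward_model()].
#' @param loss \code{"hellinger"} or \code{"density"}; see [fit_config()].
#' @param bounds Optional bounds matrix as from [default_bounds()].
#' @return Non-negative scalar.
#' @export
dilution_objective <- function(params, observed, init, chase_time,
                               step = NULL,
                               loss = c("hellinger", "density"),
                               bounds = NULL) {
  loss <- match.arg(loss)
  v <- params_to_vector(params)
  if (!is.null(bounds)) {
    pen <- bound_penalty(v, bounds)
    if (pen > 0) return(pen)
  }
  pred <- suppressWarnings(
    forward_model(params, init, chase_time, observed$bins, step = step))
  loss_value(observed, pred$density, loss)
}

## Start points in transformed space, jittered around anchor points: the
## bulk block anchors in the faster-cycling part of its range and the slow
## block in the slower part (the ordering convention makes this the
## relevant region), the fraction near the geometric middle of its range.
make_starts <- function(n_starts, bounds, free) {
  tlo <- c(log(bounds[1L, 1:6]), stats::qlogis(bounds[1L, 7]))
  thi <- c(log(bounds[2L, 1:6]), stats::qlogis(bounds[2L, 7]))
  frac <- c(0.4, 0.4, 0.4, 0.75, 0.75, 0.75, 0.5)
  mid <- tlo + frac * (thi - tlo)
  hw <- (thi - tlo) / 2
  starts <- matrix(rep(mid, n_starts), nrow = n_starts, byrow = TRUE)
  if (n_starts > 1L) {
    for (i in 2:n_starts)
      starts[i, ] <- mid + stats::rnorm(7L, 0, 0.3) * hw
  }
  colnames(starts) <- param_names
  starts[, free, drop = FALSE]
}

run_starts <- function(starts, obj, config) {
  lapply(seq_len(nrow(starts)), function(i) {
    ans <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                        control = list(maxit = config$max_iterations,
                                       reltol = config$tolerance))
    list(start = i, par = ans$par, objective = ans$value,
         converged = ans$convergence == 0L)
  })
}

## Nelder-Mead restarts from the incumbent: a fresh simplex escapes the
## collapsed one, which matters in 7 dimensions
polish_best <- function(best, obj, config, restarts = 3L) {
  for (r in seq_len(restarts)) {
    ans <- stats::optim(best$par, obj, method = "Nelder-Mead",
                        control = list(maxit = config$max_iterations,
                                       reltol = config$tolerance))
    gain <- best$objective - ans$value
    if (ans$value < best$objective) {
      best$par <- ans$par
      best$objective <- ans$value
      best$converged <- best$converged || ans$convergence == 0L
    }
    if (gain <= max(1e-12, config$tolerance * abs(best$objective))) break
  }
  best
}

#' Fit the two-population dye-dilution model to a chase histogram
#'
#' Estimates the seven model parameters (bulk and slow division-time
#' models plus the slow mixing fraction) by least squares on normalized
#' log-bin densities, using multi-start Nelder-Mead simplex search in
#' transformed parameter space (log for times and shapes, logit for the
#' fraction; bounds enforced by a finite penalty). The nested
#' single-population submodel (\eqn{\alpha = 0}) is fitted alongside for
#' model comparison, and the slow/bulk ordering convention (slow has the
#' larger mean cycle time) is applied to the result.
#'
#' @param observed Observed chase-time \code{intensity_histogram}; a
#'   warning is issued when built from fewer than 10^4 events.
#' @param init An [initial_intensity_model()], typically fitted to the
#'   day-0 sample.
#' @param chase_time Chase duration in hours (> 0).
#' @param config A [fit_config()].
#' @return An object of class \code{"dd_fit"}; see [slow_fraction()],
#'   [coef.dd_fit()], [predict.dd_fit()], [plot.dd_fit()].
#' @examples
#' \donttest{
#' cfg <- simulation_config(n_cells = 2e4, seed = 7)
#' ex <- simulate_dye_dilution(cfg)
#' d0 <- ex$cells[ex$cells$chase_time == 0, "measured_intensity"]
#' d6 <- ex$cells[ex$cells$chase_time == 144, "measured_intensity"]
#' bins <- default_bins(d0)
#' fit <- fit_dye_dilution(build_histogram(d6, bins),
#'                         initial_intensity_model(d0),
#'                         chase_time = 144,
#'                         config = fit_config(n_starts = 2))
#' fit
#' }
#' @export
fit_dye_dilution <- function(observed, init, chase_time,
                             config = fit_config()) {
  if (!inherits(observed, "intensity_histogram"))
    stop("'observed' must be an intensity_histogram", call. = FALSE)
  if (!inherits(init, "initial_intensity_model"))
    stop("'init' must be an initial_intensity_model", call. = FALSE)
  if (!inherits(config, "fit_config"))
    stop("'config' must be a fit_config", call. = FALSE)
  if (!is.finite(chase_time) || chase_time <= 0)
    stop("'chase_time' must be > 0", call. = FALSE)
  if (!is.na(observed$total_events) && observed$total_events < 1e4)
    warning("observed histogram built from fewer than 10^4 events; ",
            "the fit may be noisy", call. = FALSE)

  bounds <- config$bounds
  fixed <- config$fixed
  fixed_idx <- match(names(fixed), param_names)
  free <- setdiff(seq_len(7L), fixed_idx)

  assemble <- function(z_free) {
    v <- numeric(7L)
    if (length(fixed_idx)) v[fixed_idx] <- as.numeric(fixed)
    v[free] <- from_transformed_at(z_free, free)
    v
  }
  from_transformed_at <- function(z, idx) {
    ifelse(idx == 7L, stats::plogis(z), exp(z))
  }
  obj_vec <- function(v) {
    pen <- bound_penalty(v, bounds)
    vc <- clamp_to_bounds(v, bounds)
    p <- vector_to_params(vc)
    pred <- suppressWarnings(
      forward_model(p, init, chase_time, observed$bins,
                    step = config$step))
    loss_value(observed, pred$density, config$loss) + pen
  }
  obj_free <- function(z_free) obj_vec(assemble(z_free))

  set.seed(config$seed)

  tlo <- c(log(bounds[1L, 1:6]), stats::qlogis(bounds[1L, 7]))
  thi <- c(log(bounds[2L, 1:6]), stats::qlogis(bounds[2L, 7]))
  hw <- (thi - tlo) / 2
  jitter_around <- function(center, n, idx, sd = 0.3) {
    out <- matrix(rep(center, n), nrow = n, byrow = TRUE)
    if (n > 1L)
      for (i in 2:n)
        out[i, ] <- center + stats::rnorm(length(idx), 0, sd) * hw[idx]
    colnames(out) <- param_names[idx]
    out
  }

  ## data-driven anchor: the mean log-intensity drop over the chase gives
  ## the mean division number, hence a mean-cycle-time estimate
  mlog0 <- if (init$kind == "lognormal") init$log_mean
           else mean_log_intensity(init$empirical)
  nbar <- max((mlog0 - mean_log_intensity(observed)) / log(2), 0.5)
  cycle_hat <- min(max(chase_time / nbar, 1.2 * bounds[1L, 1]), 90)
  anchor_v <- clamp_to_bounds(
    c(0.65 * cycle_hat, 0.175 * cycle_hat, 2,
      2 * cycle_hat, 0.35 * cycle_hat, 2, 0.01), bounds)
  t_anchor <- c(log(anchor_v[1:6]), stats::qlogis(anchor_v[7]))

  ## nested single-population submodel first: alpha = 0, bulk free; its
  ## solution then seeds an informed two-population start
  sp_free <- setdiff(1:3, fixed_idx)
  sp_obj <- function(z) {
    v <- numeric(7L)
    if (length(fixed_idx)) v[fixed_idx] <- as.numeric(fixed)
    v[sp_free] <- exp(z)
    v[4:6] <- clamp_to_bounds(v, bounds)[1:3]  # slow unused at alpha = 0
    v[7] <- 0
    pen <- bound_penalty(v[1:3], bounds[, 1:3, drop = FALSE])
    vc <- clamp_to_bounds(v, bounds)
    vc[7] <- 0
    p <- vector_to_params(vc)
    pred <- suppressWarnings(
      forward_model(p, init, chase_time, observed$bins,
                    step = config$step))
    loss_value(observed, pred$density, config$loss) + pen
  }
  sp_starts <- jitter_around(t_anchor[sp_free], config$n_starts, sp_free)
  sp_runs <- run_starts(sp_starts, sp_obj, config)
  sp_best <- sp_runs[[which.min(vapply(sp_runs, `[[`, numeric(1),
                                       "objective"))]]
  sp_best <- polish_best(sp_best, sp_obj, config)

  sp_v7 <- numeric(7L)
  if (length(fixed_idx)) sp_v7[fixed_idx] <- as.numeric(fixed)
  sp_v7[sp_free] <- exp(sp_best$par)
  sp_v7[1:3] <- clamp_to_bounds(sp_v7, bounds)[1:3]
  ## informed start: fitted bulk, a 3x-slower copy as the slow component,
  ## a rare slow fraction
  sp_v7[4] <- min(3 * sp_v7[1], bounds[2L, 4])
  sp_v7[5] <- min(2 * sp_v7[2], bounds[2L, 5])
  sp_v7[6] <- sp_v7[3]
  sp_v7[7] <- 0.01
  informed <- c(log(sp_v7[1:6]), stats::qlogis(sp_v7[7]))[free]
  ## jittered cloud around the informed start, plus one broad anchor for
  ## diversity
  starts <- rbind(jitter_around(informed, config$n_starts, free),
                  make_starts(1L, bounds, free))

  runs <- run_starts(starts, obj_free, config)
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "objective"))]]
  best <- polish_best(best, obj_free, config)
  v_best <- clamp_to_bounds(assemble(best$par), bounds)
  params <- vector_to_params(v_best, order = TRUE)

  sp_v <- numeric(3L)
  sp_full <- numeric(7L)
  if (length(fixed_idx)) sp_full[fixed_idx] <- as.numeric(fixed)
  sp_full[sp_free] <- exp(sp_best$par)
  sp_v <- clamp_to_bounds(sp_full, bounds)[1:3]
  sp_params <- division_time_model(sp_v[1], sp_v[3], sp_v[2])

  per_start <- do.call(rbind, lapply(runs, function(r) {
    v <- clamp_to_bounds(assemble(r$par), bounds)
    data.frame(start = r$start, objective = r$objective,
               converged = r$converged,
               t(stats::setNames(v, param_names)))
  }))

  improvement <- (sp_best$objective - best$objective) /
    max(sp_best$objective, .Machine$double.eps)

  structure(list(
    params = params,
    objective = best$objective,
    converged = any(vapply(runs, `[[`, logical(1), "converged")),
    per_start = per_start,
    single_population = list(model = sp_params,
                             objective = sp_best$objective,
                             converged = sp_best$converged),
    improvement = improvement,
    observed = observed, init = init, chase_time = chase_time,
    config = config, call = match.call()
  ), class = "dd_fit")
}

#' Fitted slow (label-retaining) population fraction
#'
#' Returns the mixing fraction \eqn{\alpha} under the slow/bulk ordering
#' convention. For a non-converged fit, or a degenerate fit in which the
#' two components have essentially identical mean cycle times (the mixture
#' is then non-identifiable and \eqn{\alpha} meaningless), \code{NA} is
#' returned with a warning.
#'
#' @param x A \code{dd_fit} or \code{mixture_params}.
#' @param ... Unused.
#' @export
slow_fraction <- function(x, ...) UseMethod("slow_fraction")

#' @rdname slow_fraction
#' @export
slow_fraction.mixture_params <- function(x, ...) {
  if (abs(mean(x$slow) - mean(x$bulk)) < 0.02 * mean(x$bulk)) {
    warning("bulk and slow components are essentially identical; ",
            "the mixture fraction is not identifiable", call. = FALSE)
    return(NA_real_)
  }
  x$slow_fraction
}

#' @rdname slow_fraction
#' @export
slow_fraction.dd_fit <- function(x, ...) {
  if (!x$converged) {
    warning("fit did not converge; slow fraction unavailable",
            call. = FALSE)
    return(NA_real_)
  }
  slow_fraction(x$params)
}

#' @export
print.dd_fit <- function(x, digits = 4, ...) {
  cat("Two-population dye-dilution model fit\n")
  cat(sprintf("  chase time: %g h; %d bins; %s starts\n", x$chase_time,
              x$observed$bins$n_bins, x$config$n_starts))
  a <- suppressWarnings(slow_fraction(x))
  cat(sprintf("  slow (label-retaining) fraction alpha: %s\n",
              ifelse(is.na(a), "not identifiable",
                     format(a, digits = digits))))
  cat(sprintf("  bulk mean cycle: %.4g h   slow mean cycle: %.4g h\n",
              mean(x$params$bulk), mean(x$params$slow)))
  cat(sprintf("  objective: %.6g (single-population: %.6g, improvement %.1f%%)\n",
              x$objective, x$single_population$objective,
              100 * x$improvement))
  cat(sprintf("  converged: %s; two populations supported: %s\n",
              x$converged, two_population_support(x)))
  invisible(x)
}

#' Is the second (slow) population supported by the fit?
#'
#' Compares the relative objective improvement of the two-population model
#' over the nested single-population model against the configured
#' threshold.
#'
#' @param fit A \code{dd_fit}.
#' @param threshold Relative improvement threshold; default from the fit's
#'   configuration.
#' @export
two_population_support <- function(fit,
                                   threshold =
                                     fit$config$improvement_threshold) {
  fit$improvement >= threshold
}

#' @export
coef.dd_fit <- function(object, ...) {
  stats::setNames(params_to_vector(object$params), param_names)
}

#' @export
summary.dd_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.dd_fit")
}

#' @export
print.summary.dd_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients:\n")
  print(coef(x$fit))
  cat("\nPer-start results (best kept):\n")
  print(x$fit$per_start, row.names = FALSE, digits = 4)
  sp <- x$fit$single_population
  cat(sprintf("\nSingle-population submodel: t_b=%.4g, sigma=%.4g, lambda=%.4g, objective %.6g\n",
              sp$model$min_cycle_time, sp$model$scale, sp$model$shape,
              sp$objective))
  invisible(x)
}

#' Predicted intensity histogram of a fitted model
#'
#' @param object A \code{dd_fit}.
#' @param chase_time Chase time in hours; defaults to the fitted one.
#' @param component \code{"mixture"} (default), \code{"bulk"} or
#'   \code{"slow"} population prediction.
#' @param ... Unused.
#' @return An \code{intensity_histogram} on the observed axis.
#' @export
predict.dd_fit <- function(object, chase_time = object$chase_time,
                           component = c("mixture", "bulk", "slow"), ...) {
  component <- match.arg(component)
  p <- object$params
  if (component == "bulk")
    p <- structure(list(bulk = p$bulk, slow = p$slow, slow_fraction = 0),
                   class = "mixture_params")
  if (component == "slow")
    p <- structure(list(bulk = p$bulk, slow = p$slow, slow_fraction = 1),
                   class = "mixture_params")
  suppressWarnings(
    forward_model(p, object$init, chase_time, object$observed$bins,
                  step = object$config$step))
}

#' @export
residuals.dd_fit <- function(object, ...) {
  object$observed$density - predict(object)$density
}

#' Overlay of observed and fitted intensity distributions
#'
#' Observed chase histogram with the fitted mixture and the weighted
#' bulk/slow component contributions.
#'
#' @param x A \code{dd_fit}.
#' @param ... Passed to [plot.intensity_histogram()].
#' @export
plot.dd_fit <- function(x, ...) {
  mixture <- predict(x)
  a <- x$params$slow_fraction
  bulk <- predict(x, component = "bulk")
  slow <- predict(x, component = "slow")
  xs <- exp(x$observed$bins$log_centers)
  plot(x$observed, main = "CFSE dilution: observed vs fitted", ...)
  graphics::lines(xs, mixture$density, col = 2, lwd = 2)
  graphics::lines(xs, (1 - a) * bulk$density, col = 3, lty = 2)
  graphics::lines(xs, a * slow$density, col = 4, lty = 2)
  graphics::legend("topleft", bty = "n",
                   legend = c("observed", "fitted mixture",
                              "(1-a) bulk", "a slow"),
                   col = 1:4, lty = c(1, 1, 2, 2))
  invisible(x)
}

#' Simulate dye-dilution experiments from a fitted model
#'
#' Parametric simulation: runs the agent-based generator at the fitted
#' parameter values, with the initial-intensity model taken from the fit.
#'
#' @param object A \code{dd_fit} (lognormal initial-intensity model
#'   required).
#' @param nsim Number of experiments.
#' @param seed Integer seed of the first experiment (subsequent ones
#'   increment it).
#' @param n_cells Founder lineages per experiment.
#' @param measurement_cv Measurement noise CV.
#' @param ... Unused.
#' @return A \code{dd_experiment} (or a list of them when
#'   \code{nsim > 1}).
#' @export
simulate.dd_fit <- function(object, nsim = 1, seed = 1L, n_cells = 1e4,
                            measurement_cv = 0.15, ...) {
  if (object$init$kind != "lognormal")
    stop("simulation from a fit requires a lognormal initial model",
         call. = FALSE)
  one <- function(s) {
    cfg <- simulation_config(
      n_cells = n_cells, params = object$params,
      chase_times = c(0, object$chase_time),
      init_log_mean = object$init$log_mean,
      init_log_sd = object$init$log_sd,
      autofluorescence_floor = object$observed$bins$floor,
      measurement_cv = measurement_cv, seed = s)
    simulate_dye_dilution(cfg)
  }
  if (nsim == 1) one(seed)
  else lapply(seq_len(nsim) - 1L + as.integer(seed), one)
}

#' Partition events into label-retaining (CFSE-high) and bulk sets
#'
#' Deterministically splits events at an intensity gate: events at or
#' above the gate are called CFSE-high (label-retaining candidates), the
#' rest CFSE-bulk. The gate is given either as a quantile of the events
#' (ties broken toward the high set: with \code{n} events and quantile
#' \code{q}, the threshold is the \code{ceiling((1-q)*n)}-th largest
#' event) or as an absolute intensity.
#'
#' @param events Event intensities (or an [event_table()]); non-empty.
#' @param gate_quantile Quantile in \code{[0, 1]} defining the gate
#'   (e.g. 0.995); \code{1} yields an empty high set.
#' @param gate_value Absolute intensity threshold (alternative to
#'   \code{gate_quantile}).
#' @return A list of class \code{"dd_gate"}: \code{threshold},
#'   logical \code{is_high}, and the \code{high} and \code{bulk}
#'   intensity vectors.
#' @examples
#' g <- gate_high_retainers(1:1000, gate_quantile = 0.99)
#' g$threshold; length(g$high)  # exactly 10 events high
#' @export
gate_high_retainers <- function(events, gate_quantile = NULL,
                                gate_value = NULL) {
  if (inherits(events, "event_table")) events <- events$intensities
  if (length(events) == 0L) stop("no events to gate", call. = FALSE)
  if (is.null(gate_quantile) == is.null(gate_value))
    stop("give exactly one of 'gate_quantile' or 'gate_value'",
         call. = FALSE)
  if (!is.null(gate_quantile)) {
    if (gate_quantile < 0 || gate_quantile > 1)
      stop("'gate_quantile' must lie in [0, 1]", call. = FALSE)
    n <- length(events)
    k <- ceiling((1 - gate_quantile) * n - 1e-9)  # guard fp fuzz
    threshold <- if (k == 0L) Inf else sort(events, decreasing = TRUE)[k]
  } else {
    threshold <- gate_value
  }
  is_high <- events >= threshold
  structure(list(threshold = threshold, is_high = is_high,
                 high = events[is_high], bulk = events[!is_high]),
            class = "dd_gate")
}

#' @export
print.dd_gate <- function(x, ...) {
  n <- length(x$is_high)
  cat(sprintf("CFSE gate at intensity %.4g: %d high (%.3g%%), %d bulk\n",
              x$threshold, length(x$high), 100 * length(x$high) / n,
              length(x$bulk)))
  invisible(x)
}

#' Model-derived label-retaining-cell gate
#'
#' Intensity threshold at the given quantile of the fitted *bulk-only*
#' predicted distribution at the chase time: events brighter than
#' essentially all bulk cells are label-retaining candidates. This gives a
#' principled gate when no manual one is set.
#'
#' @param fit A \code{dd_fit}.
#' @param quantile Upper quantile of the bulk prediction; default 0.995.
#' @return Intensity threshold.
#' @export
lrc_gate <- function(fit, quantile = 0.995) {
  h <- predict(fit, component = "bulk")
  cum <- cumsum(h$density * h$bins$dlog)
  cum <- cum / cum[length(cum)]
  j <- which(cum >= quantile)[1L]
  exp(h$bins$log_edges[j + 1L])
}
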