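## Histograms are carried as densities over natural-log intensity on a
## log-spaced bin axis: per-division dye halving is then an exact shift by
## -log 2, the operation at the heart of the forward model.

#' Log-spaced intensity bin axis
#'
#' @param floor Lower intensity limit (autofluorescence floor, > 0). Mass
#'   predicted or measured below it is accumulated into the first bin.
#' @param ceiling Upper intensity limit (> floor).
#' @param n_bins Number of bins (>= 32); default 256, cytometry convention.
#' @return An object of class \code{"intensity_bins"} with intensity-space
#'   \code{edges}, log-space edges/centers, and the constant log-bin width
#'   \code{dlog}.
#' @export
intensity_bins <- function(floor, ceiling, n_bins = 256L) {
  stopifnot(length(floor) == 1L, length(ceiling) == 1L)
  if (!is.finite(floor) || floor <= 0) stop("'floor' must be > 0",
                                            call. = FALSE)
  if (!is.finite(ceiling) || ceiling <= floor)
    stop("'ceiling' must exceed 'floor'", call. = FALSE)
  if (n_bins < 32L) stop("'n_bins' must be >= 32", call. = FALSE)
  log_edges <- seq(log(floor), log(ceiling), length.out = n_bins + 1L)
  structure(list(edges = exp(log_edges), log_edges = log_edges,
                 log_centers = (log_edges[-1L] + log_edges[-(n_bins + 1L)]) / 2,
                 dlog = diff(log_edges[1:2]), n_bins = as.integer(n_bins),
                 floor = floor, ceiling = ceiling),
            class = "intensity_bins")
}

same_axis <- function(a, b) {
  a$n_bins == b$n_bins &&
    isTRUE(all.equal(a$log_edges, b$log_edges, tolerance = 1e-10))
}

new_intensity_histogram <- function(bins, density, total_events = NA_real_) {
  density[density < 0] <- 0
  z <- sum(density * bins$dlog)
  if (z <= 0) stop("histogram has no mass", call. = FALSE)
  structure(list(bins = bins, density = density / z,
                 total_events = total_events),
            class = "intensity_histogram")
}

#' Build a normalized log-intensity histogram from events
#'
#' Events below the bin floor are clamped into the first bin; events above
#' the ceiling into the last. The density is per unit log-intensity and
#' integrates to 1.
#'
#' @param intensities Positive event intensities (an [event_table()] is
#'   also accepted).
#' @param bins An [intensity_bins()] axis.
#' @param weights Optional non-negative per-event weights (e.g.
#'   \code{2^divisions} to convert lineage-representative simulator
#'   records to cell numbers).
#' @return An \code{"intensity_histogram"} with \code{total_events} set.
#' @export
build_histogram <- function(intensities, bins, weights = NULL) {
  if (inherits(intensities, "event_table")) intensities <- intensities$intensities
  if (!inherits(bins, "intensity_bins"))
    stop("'bins' must be an intensity_bins axis", call. = FALSE)
  if (length(intensities) < 1L) stop("no events", call. = FALSE)
  if (any(!is.finite(intensities) | intensities <= 0))
    stop("intensities must be finite and > 0", call. = FALSE)
  if (all(intensities <= bins$floor))
    stop("degenerate input: every event lies at or below the ",
         "autofluorescence floor", call. = FALSE)
  x <- pmin(pmax(log(intensities), bins$log_edges[1L]),
            bins$log_edges[bins$n_bins + 1L])
  idx <- findInterval(x, bins$log_edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- if (is.null(weights)) {
    tabulate(idx, nbins = bins$n_bins)
  } else {
    stopifnot(length(weights) == length(intensities), all(weights >= 0))
    as.numeric(tapply(weights, factor(idx, levels = seq_len(bins$n_bins)),
                      sum, default = 0))
  }
  new_intensity_histogram(bins, counts / (sum(counts) * bins$dlog),
                          total_events = length(intensities))
}

#' @export
print.intensity_histogram <- function(x, ...) {
  cat("Intensity histogram:", x$bins$n_bins, "log bins on [",
      format(x$bins$floor, digits = 3), ",",
      format(x$bins$ceiling, digits = 3), "]")
  if (!is.na(x$total_events)) cat(";", x$total_events, "events")
  cat("\n  mean log-intensity:", format(mean_log_intensity(x), digits = 4),
      "\n")
  invisible(x)
}

#' Mean log-intensity of a histogram
#' @param h An \code{intensity_histogram}.
#' @export
mean_log_intensity <- function(h) {
  sum(h$bins$log_centers * h$density * h$bins$dlog)
}

#' Total-variation distance between two intensity histograms
#'
#' Half the L1 distance between the two densities; requires identical bin
#' axes.
#'
#' @param a,b \code{intensity_histogram}s on the same axis.
#' @export
tv_distance <- function(a, b) {
  if (!same_axis(a$bins, b$bins)) stop("histograms on different axes",
                                       call. = FALSE)
  0.5 * sum(abs(a$density - b$density)) * a$bins$dlog
}

#' Initial (day-0) staining intensity model
#'
#' Either a lognormal fitted by moment matching on log-intensity (the
#' default; day-0 CFSE staining is approximately lognormal), or an
#' empirical smoothed histogram for non-lognormal staining.
#'
#' @param events Day-0 intensities (or an [event_table()]); used to fit the
#'   chosen form. Omit to give \code{log_mean}/\code{log_sd} directly.
#' @param kind \code{"lognormal"} or \code{"empirical"}.
#' @param log_mean,log_sd Natural-log intensity mean and standard deviation
#'   (lognormal case, when \code{events} is missing).
#' @param bins Axis used to build the empirical histogram (empirical case).
#' @return An object of class \code{"initial_intensity_model"}.
#' @export
initial_intensity_model <- function(events = NULL,
                                    kind = c("lognormal", "empirical"),
                                    log_mean = NULL, log_sd = NULL,
                                    bins = NULL) {
  kind <- match.arg(kind)
  if (inherits(events, "event_table")) events <- events$intensities
  if (kind == "lognormal") {
    if (!is.null(events)) {
      lx <- log(events)
      log_mean <- mean(lx)
      log_sd <- stats::sd(lx)
    }
    if (is.null(log_mean) || is.null(log_sd) || log_sd <= 0)
      stop("lognormal model needs events or log_mean and log_sd > 0",
           call. = FALSE)
    out <- list(kind = kind, log_mean = log_mean, log_sd = log_sd,
                empirical = NULL)
  } else {
    if (is.null(events) || is.null(bins))
      stop("empirical model needs 'events' and 'bins'", call. = FALSE)
    out <- list(kind = kind, log_mean = NULL, log_sd = NULL,
                empirical = build_histogram(events, bins))
  }
  structure(out, class = "initial_intensity_model")
}

#' @export
print.initial_intensity_model <- function(x, ...) {
  if (x$kind == "lognormal")
    cat(sprintf("Initial intensity: lognormal, log-mean %.4g, log-sd %.4g\n",
                x$log_mean, x$log_sd))
  else
    cat("Initial intensity: empirical histogram,",
        x$empirical$bins$n_bins, "bins\n")
  invisible(x)
}

## P(log I_0 <= x), vectorized over x
init_log_cdf <- function(init, x) {
  if (init$kind == "lognormal") {
    stats::pnorm(x, mean = init$log_mean, sd = init$log_sd)
  } else {
    h <- init$empirical
    cum <- c(0, cumsum(h$density * h$bins$dlog))
    f <- stats::approxfun(h$bins$log_edges, cum, rule = 2)
    f(x)
  }
}

#' Predicted intensity histogram from generation occupancy
#'
#' Cells that have completed \eqn{n} divisions carry \eqn{I_0 / 2^n} of
#' their initial dye, so in log-intensity space each generation contributes
#' the initial density translated by \eqn{-n \log 2}, weighted by its cell
#' fraction \eqn{N_n / \sum_m N_m}. Undivided cells (generation 0) retain
#' their full initial intensity — these are the label-retaining cells. Mass
#' falling below the axis floor (autofluorescence) is accumulated into the
#' floor bin, and the result is normalized to integrate to 1.
#'
#' @param gd A filled [generation_distribution()].
#' @param init An [initial_intensity_model()].
#' @param bins An [intensity_bins()] axis.
#' @param t Chase time at which to take the generation occupancy; defaults
#'   to the end of the distribution's grid.
#' @return An \code{intensity_histogram}.
#' @export
predict_intensity <- function(gd, init, bins, t = NULL) {
  w <- generation_fractions(gd, t)
  predict_intensity_weights(w, init, bins)
}

## shared by predict_intensity and the chase_time = 0 special case
predict_intensity_weights <- function(w, init, bins) {
  top_gap <- 1 - init_log_cdf(init, bins$log_edges[bins$n_bins + 1L])
  if (top_gap > 1e-3)
    warning(sprintf(paste0("bin axis ceiling truncates %.2g of the initial",
                           " intensity mass"), top_gap), call. = FALSE)
  mass <- numeric(bins$n_bins)
  for (i in seq_along(w)) {
    if (w[i] <= 0) next
    shift <- (i - 1L) * log(2)
    cdf_edges <- init_log_cdf(init, bins$log_edges + shift)
    m <- diff(cdf_edges)
    m[1L] <- m[1L] + cdf_edges[1L]                     # below-floor mass
    m[bins$n_bins] <- m[bins$n_bins] +
      (1 - cdf_edges[bins$n_bins + 1L])                # above-ceiling mass
    mass <- mass + w[i] * m
  }
  new_intensity_histogram(bins, mass / bins$dlog)
}

#' Mixture of bulk and slow population predictions
#'
#' Bin-wise weighted mixture \eqn{(1-\alpha)\,\mathrm{bulk} +
#' \alpha\,\mathrm{slow}} of two predicted histograms on the same axis.
#'
#' @param bulk_pred,slow_pred \code{intensity_histogram}s on identical
#'   axes.
#' @param slow_fraction Mixing fraction \eqn{\alpha} of the slow
#'   population, in \code{[0, 1]}.
#' @export
mix_intensities <- function(bulk_pred, slow_pred, slow_fraction) {
  if (!same_axis(bulk_pred$bins, slow_pred$bins))
    stop("bulk and slow predictions on different bin axes", call. = FALSE)
  if (!is.finite(slow_fraction) || slow_fraction < 0 || slow_fraction > 1)
    stop("'slow_fraction' must lie in [0, 1]", call. = FALSE)
  new_intensity_histogram(
    bulk_pred$bins,
    (1 - slow_fraction) * bulk_pred$density +
      slow_fraction * slow_pred$density
  )
}

#' Two-population mixture parameters
#'
#' The full seven-parameter vector of the model: a bulk and a slow
#' [division_time_model()] plus the slow mixing fraction \eqn{\alpha}. The
#' identifiability convention labels as "slow" the component with the
#' larger mean cycle time \eqn{t_b + \lambda\sigma}; if the arguments
#' violate it the components are swapped (and \eqn{\alpha} complemented)
#' with a warning.
#'
#' @param bulk,slow [division_time_model()]s.
#' @param slow_fraction Mixing fraction \eqn{\alpha} in \code{[0, 1]}.
#' @return An object of class \code{"mixture_params"}.
#' @export
mixture_params <- function(bulk, slow, slow_fraction) {
  stop_if_not_dtm(bulk); stop_if_not_dtm(slow)
  if (!is.finite(slow_fraction) || slow_fraction < 0 || slow_fraction > 1)
    stop("'slow_fraction' must lie in [0, 1]", call. = FALSE)
  if (mean(slow) < mean(bulk)) {
    warning("components swapped to satisfy the slow/bulk ordering ",
            "convention (slow has the larger mean cycle time)",
            call. = FALSE)
    tmp <- bulk; bulk <- slow; slow <- tmp
    slow_fraction <- 1 - slow_fraction
  }
  structure(list(bulk = bulk, slow = slow,
                 slow_fraction = as.numeric(slow_fraction)),
            class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, ...) {
  cat("Two-population mixture\n")
  cat(sprintf("  slow fraction alpha: %.4g\n", x$slow_fraction))
  cat(sprintf("  bulk: t_b=%.3g h, lambda=%.3g, sigma=%.3g h (mean %.3g h)\n",
              x$bulk$min_cycle_time, x$bulk$shape, x$bulk$scale,
              mean(x$bulk)))
  cat(sprintf("  slow: t_b=%.3g h, lambda=%.3g, sigma=%.3g h (mean %.3g h)\n",
              x$slow$min_cycle_time, x$slow$shape, x$slow$scale,
              mean(x$slow)))
  invisible(x)
}

## flatten / rebuild for the optimizer
params_to_vector <- function(p) {
  c(p$bulk$min_cycle_time, p$bulk$scale, p$bulk$shape,
    p$slow$min_cycle_time, p$slow$scale, p$slow$shape,
    p$slow_fraction)
}

vector_to_params <- function(v, order = FALSE) {
  bulk <- division_time_model(v[1], v[3], v[2])
  slow <- division_time_model(v[4], v[6], v[5])
  if (order && mean(slow) < mean(bulk)) {
    tmp <- bulk; bulk <- slow; slow <- tmp
    v[7] <- 1 - v[7]
  }
  structure(list(bulk = bulk, slow = slow, slow_fraction = v[7]),
            class = "mixture_params")
}

#' Forward model: predicted mixture histogram at a chase time
#'
#' Deterministic composition of the whole model: per-population renewal
#' convolution of generation occupancy, dye-halving intensity prediction,
#' and the bulk/slow mixture. At \code{chase_time = 0} the prediction is
#' the initial intensity distribution projected on the bin axis.
#'
#' The mixing fraction \eqn{\alpha} is the fraction of *founder* cells in
#' the slow population. By the chase time the two populations have
#' expanded unequally (per-founder expansion \eqn{S = \sum_n N_n(T)}), so
#' the observed cell mixture carries the effective weight
#' \deqn{\alpha_{\mathrm{eff}} = \frac{\alpha S_{\mathrm{slow}}}
#'   {(1-\alpha) S_{\mathrm{bulk}} + \alpha S_{\mathrm{slow}}},}
#' which is what the per-population normalized predictions are mixed
#' with. (At \eqn{t = 0}, \eqn{\alpha_{\mathrm{eff}} = \alpha}.)
#'
#' @param params A [mixture_params()].
#' @param init An [initial_intensity_model()].
#' @param chase_time Chase duration in hours (>= 0).
#' @param bins An [intensity_bins()] axis.
#' @param step Renewal grid step in hours; default
#'   \code{min(min(scale)/50, 0.1)} over the two populations.
#' @param initial Initial-condition convention, see
#'   [generation_densities()].
#' @param tail_tol Generation-truncation tolerance, see
#'   [generation_distribution()].
#' @return An \code{intensity_histogram}.
#' @export
forward_model <- function(params, init, chase_time, bins, step = NULL,
                          initial = c("point", "uniform"),
                          tail_tol = 1e-6) {
  if (!inherits(params, "mixture_params"))
    stop("'params' must be mixture_params", call. = FALSE)
  initial <- match.arg(initial)
  if (chase_time < 0) stop("'chase_time' must be >= 0", call. = FALSE)
  if (chase_time == 0) {
    return(predict_intensity_weights(1, init, bins))
  }
  if (is.null(step))
    step <- default_grid_step(min(params$bulk$scale, params$slow$scale))
  one <- function(m) {
    gd <- generation_distribution(m, stop = chase_time, step = step,
                                  initial = initial, tail_tol = tail_tol)
    list(pred = predict_intensity(gd, init, bins),
         expansion = sum(gd$N[, ncol(gd$N)]))
  }
  a <- params$slow_fraction
  bulk <- one(params$bulk)
  if (a == 0) return(bulk$pred)
  slow <- one(params$slow)
  if (a == 1) return(slow$pred)
  a_eff <- a * slow$expansion /
    ((1 - a) * bulk$expansion + a * slow$expansion)
  mix_intensities(bulk$pred, slow$pred, a_eff)
}

#' Write / read a histogram as two-column delimited text
#'
#' Plain-text interchange: one row per bin with the geometric bin center
#' (intensity units) and the density per unit log-intensity.
#'
#' @param h An \code{intensity_histogram}.
#' @param path Output (input) file path.
#' @export
write_histogram <- function(h, path) {
  utils::write.table(
    data.frame(bin_center = exp(h$bins$log_centers), density = h$density),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_histogram
#' @param total_events Event count to record on the re-read histogram.
#' @export
read_histogram <- function(path, total_events = NA_real_) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("bin_center", "density") %in% names(d)))
    stop("histogram file needs 'bin_center' and 'density' columns",
         call. = FALSE)
  lc <- log(d$bin_center)
  dlog <- diff(lc[1:2])
  if (max(abs(diff(lc) - dlog)) > 1e-8 * dlog)
    stop("bin centers are not uniformly log-spaced", call. = FALSE)
  bins <- intensity_bins(exp(lc[1L] - dlog / 2),
                         exp(lc[length(lc)] + dlog / 2),
                         n_bins = length(lc))
  new_intensity_histogram(bins, d$density, total_events)
}

#' Plot an intensity histogram (optionally with overlays)
#'
#' @param x An \code{intensity_histogram}.
#' @param overlay Optional named list of further histograms to overlay.
#' @param main,... Passed to [graphics::plot()].
#' @export
plot.intensity_histogram <- function(x, overlay = NULL,
                                     main = "CFSE intensity", ...) {
  xs <- exp(x$bins$log_centers)
  ymax <- max(x$density,
              vapply(overlay, function(h) max(h$density), numeric(1)))
  graphics::plot(xs, x$density, type = "s", log = "x",
                 xlab = "intensity (a.u.)",
                 ylab = "density per log-intensity",
                 ylim = c(0, 1.05 * ymax), main = main, ...)
  if (length(overlay)) {
    for (i in seq_along(overlay))
      graphics::lines(exp(overlay[[i]]$bins$log_centers),
                      overlay[[i]]$density, type = "s", col = i + 1L)
    graphics::legend("topleft", bty = "n",
                     legend = c("observed", names(overlay)),
                     col = seq_len(length(overlay) + 1L), lty = 1)
  }
  invisible(x)
}
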