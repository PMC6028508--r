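#' Intrinsic division-time distribution of one cell population
#'
#' Constructs the distribution of the time a cell takes to complete one
#' division: a gamma density location-shifted by a hard minimum cycle time.
#' Below the minimum cycle time the density is exactly zero; above it the
#' waiting time beyond the minimum follows a gamma distribution with the
#' given shape and scale, so the density is
#' \deqn{K(t) = \frac{1}{\sigma\Gamma(\lambda)}
#'   \left(\frac{t - t_b}{\sigma}\right)^{\lambda-1}
#'   e^{-(t - t_b)/\sigma}, \quad t \ge t_b,}
#' and 0 otherwise. The shape and scale control the broadness of the tail
#' and hence the propensity for long cycle times.
#'
#' @param min_cycle_time Minimum cycle time \eqn{t_b} in hours
#'   (non-negative).
#' @param shape Dimensionless shape parameter \eqn{\lambda} (positive).
#' @param scale Scale parameter \eqn{\sigma} in hours (positive).
#' @return An object of class \code{"division_time_model"}.
#' @examples
#' m <- division_time_model(min_cycle_time = 15, shape = 2, scale = 4)
#' division_pdf(m, c(10, 20, 30))
#' mean(m)  # t_b + lambda * sigma
#' @seealso [division_pdf()], [division_cdf()], [generation_distribution()]
#' @export
division_time_model <- function(min_cycle_time, shape, scale) {
  stopifnot(length(min_cycle_time) == 1L, length(shape) == 1L,
            length(scale) == 1L)
  if (!is.finite(min_cycle_time) || min_cycle_time < 0)
    stop("'min_cycle_time' must be finite and >= 0", call. = FALSE)
  if (!is.finite(shape) || shape <= 0)
    stop("'shape' must be finite and > 0", call. = FALSE)
  if (!is.finite(scale) || scale <= 0)
    stop("'scale' must be finite and > 0", call. = FALSE)
  structure(
    list(min_cycle_time = as.numeric(min_cycle_time),
         shape = as.numeric(shape),
         scale = as.numeric(scale)),
    class = "division_time_model"
  )
}

#' @export
print.division_time_model <- function(x, ...) {
  cat("Division-time model (shifted gamma)\n")
  cat(sprintf("  minimum cycle time t_b: %.3g h\n", x$min_cycle_time))
  cat(sprintf("  shape lambda:           %.3g\n", x$shape))
  cat(sprintf("  scale sigma:            %.3g h\n", x$scale))
  cat(sprintf("  mean cycle time:        %.3g h\n", mean(x)))
  invisible(x)
}

#' @describeIn division_time_model Mean cycle time
#'   \eqn{t_b + \lambda\sigma} in hours.
#' @param x A \code{division_time_model}.
#' @param ... Ignored.
#' @export
mean.division_time_model <- function(x, ...) {
  x$min_cycle_time + x$shape * x$scale
}

stop_if_not_dtm <- function(model) {
  if (!inherits(model, "division_time_model"))
    stop("'model' must be a division_time_model", call. = FALSE)
  invisible(model)
}

#' Density of the division-time distribution
#'
#' @param model A [division_time_model()].
#' @param t Times in hours (vectorized); must be finite.
#' @return Density per hour; exactly 0 for \code{t < min_cycle_time}.
#'   For \code{shape < 1} the density diverges as \code{t} approaches the
#'   minimum cycle time from above and \code{Inf} is returned at that point.
#' @export
division_pdf <- function(model, t) {
  stop_if_not_dtm(model)
  if (any(!is.finite(t))) stop("'t' must be finite", call. = FALSE)
  stats::dgamma(t - model$min_cycle_time, shape = model$shape,
                scale = model$scale)
}

#' Cumulative distribution of the division time
#'
#' @inheritParams division_pdf
#' @return Probability that a division is completed by time \code{t};
#'   0 at and below the minimum cycle time, approaching 1 as
#'   \code{t} grows.
#' @export
division_cdf <- function(model, t) {
  stop_if_not_dtm(model)
  if (any(!is.finite(t))) stop("'t' must be finite", call. = FALSE)
  stats::pgamma(t - model$min_cycle_time, shape = model$shape,
                scale = model$scale)
}

#' Quantile function of the division time
#'
#' Inverse of [division_cdf()]; used for inverse-transform sampling of
#' inter-division times in the simulator.
#'
#' @inheritParams division_pdf
#' @param p Probabilities in \code{[0, 1]}.
#' @export
division_quantile <- function(model, p) {
  stop_if_not_dtm(model)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("'p' must lie in [0, 1]", call. = FALSE)
  model$min_cycle_time + stats::qgamma(p, shape = model$shape,
                                       scale = model$scale)
}
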