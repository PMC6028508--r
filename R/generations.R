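#' Uniform time grid for the renewal computation
#'
#' The chase period \code{[0, stop]} is discretized on a uniform grid with
#' both endpoints included; time 0 is the labeling instant.
#'
#' @param stop End of the chase period in hours (> 0).
#' @param step Grid spacing in hours (> 0).
#' @return A list of class \code{"time_grid"} with elements \code{times},
#'   \code{step} and \code{stop}.
#' @export
time_grid <- function(stop, step) {
  stopifnot(length(stop) == 1L, length(step) == 1L)
  if (!is.finite(step) || step <= 0) stop("'step' must be > 0", call. = FALSE)
  if (!is.finite(stop) || stop <= 0) stop("'stop' must be > 0", call. = FALSE)
  n <- ceiling(stop / step - 1e-9)
  if (n + 1 > 5e5)
    stop("time grid would have more than 5e5 points; increase 'step'",
         call. = FALSE)
  times <- seq(0, by = step, length.out = n + 1)
  structure(list(times = times, step = step, stop = times[n + 1]),
            class = "time_grid")
}

default_grid_step <- function(scale) min(scale / 50, 0.1)

## trapezoidal quadrature on a uniform grid
trapz_uniform <- function(y, step) {
  g <- length(y)
  step * (sum(y) - (y[1L] + y[g]) / 2)
}

cumtrapz_uniform <- function(y, step) {
  g <- length(y)
  c(0, cumsum((y[-1L] + y[-g]) / 2)) * step
}

## Division-time density sampled on the grid. Pointwise evaluation except
## where the density is singular (shape < 1 at t = t_b): there the value is
## replaced by the cell-averaged density from CDF differences, which keeps
## the trapezoidal quadrature finite and mass-preserving.
grid_kernel <- function(model, grid) {
  k <- division_pdf(model, grid$times)
  bad <- !is.finite(k)
  if (any(bad)) {
    h <- grid$step
    t_bad <- grid$times[bad]
    k[bad] <- (division_cdf(model, t_bad + h / 2) -
               division_cdf(model, pmax(t_bad - h / 2, 0))) / h
  }
  k
}

## Trapezoidal convolution of two densities sampled on the same uniform
## grid, returned on that grid. The discrete sums are evaluated by FFT;
## the result equals the direct O(G^2) sum to floating-point accuracy.
trapz_convolve <- function(a, b, step) {
  make_kernel_convolver(a, step)(b)
}

## Pre-transforms the kernel once so the per-generation convolution costs
## two FFTs instead of three.
make_kernel_convolver <- function(k, step) {
  g <- length(k)
  m <- stats::nextn(2L * g)
  fk <- stats::fft(c(k, numeric(m - g)))
  k1 <- k[1]
  function(b) {
    s <- Re(stats::fft(fk * stats::fft(c(b, numeric(m - g))),
                       inverse = TRUE))[seq_len(g)] / m
    out <- step * s - (step / 2) * (k * b[1] + b * k1)
    out[out < 0] <- 0
    out
  }
}

#' Per-generation division densities by renewal convolution
#'
#' Computes the densities \eqn{L_n(t)} of the time of the \eqn{n}-th
#' division through the renewal recursion
#' \deqn{L_n(t) = \int_0^t K(t-\tau)\, L_{n-1}(\tau)\, d\tau,}
#' discretized by trapezoidal quadrature on a uniform grid, where \eqn{K}
#' is the division-time density. With the default initial condition — all
#' cells start a fresh cycle at the labeling instant (a point mass at
#' \eqn{t = 0}) — the first-division density equals \eqn{K} itself. The
#' alternative \code{initial = "uniform"} spreads the first division
#' uniformly over one mean cycle time \eqn{[0, t_b + \lambda\sigma]},
#' emulating cells labeled at random cell-cycle phase.
#'
#' One extra generation beyond \code{n_max} is computed and stored so that
#' [generation_counts()] can form its difference term.
#'
#' @param model A [division_time_model()].
#' @param grid A [time_grid()]; the step should be well below the model's
#'   scale (and minimum cycle time, when positive) or a resolution warning
#'   is issued.
#' @param n_max Largest generation (completed-division count) to represent;
#'   at least 1.
#' @param initial \code{"point"} (default) or \code{"uniform"}; see
#'   Details.
#' @return An object of class \code{"generation_distribution"} holding the
#'   grid and the matrix \code{L} of division densities (rows are
#'   generations \code{1 .. n_max + 1}). Cumulative probabilities and cell
#'   counts are filled in by [cumulative_division_probs()] and
#'   [generation_counts()].
#' @seealso [generation_distribution()] for the one-call wrapper with
#'   adaptive generation truncation.
#' @export
generation_densities <- function(model, grid, n_max,
                                 initial = c("point", "uniform")) {
  stop_if_not_dtm(model)
  if (!inherits(grid, "time_grid")) stop("'grid' must be a time_grid",
                                         call. = FALSE)
  initial <- match.arg(initial)
  if (!is.numeric(n_max) || length(n_max) != 1L || n_max < 1)
    stop("'n_max' must be an integer >= 1", call. = FALSE)
  n_max <- as.integer(n_max)
  if (grid$step > model$scale / 10 ||
      (model$min_cycle_time > 0 && grid$step > model$min_cycle_time / 10))
    warning("time grid step is coarse relative to the division-time scale; ",
            "densities may be poorly resolved", call. = FALSE)

  k <- grid_kernel(model, grid)
  g <- length(grid$times)
  L <- matrix(0, nrow = n_max + 1L, ncol = g)
  L[1L, ] <- if (initial == "point") {
    k
  } else {
    span <- model$min_cycle_time + model$shape * model$scale
    as.numeric(grid$times <= span) / span
  }
  conv <- make_kernel_convolver(k, grid$step)
  for (n in seq_len(n_max)) {
    L[n + 1L, ] <- conv(L[n, ])
  }
  rownames(L) <- paste0("n", seq_len(n_max + 1L))
  structure(list(model = model, grid = grid, n_max = n_max,
                 initial = initial, L = L, H = NULL, N = NULL,
                 founders = NULL),
            class = "generation_distribution")
}

#' Cumulative probabilities of having divided at least n times
#'
#' Fills \eqn{H_n(t) = \int_0^t L_n(\tau)\, d\tau}, the probability that a
#' lineage has completed at least \eqn{n} divisions by time \eqn{t}, by
#' cumulative trapezoidal integration. \eqn{H_0 \equiv 1} (every cell has
#' divided at least zero times).
#'
#' @param gd A \code{generation_distribution} from [generation_densities()].
#' @return The same object with the matrix \code{H} filled (rows are
#'   generations \code{0 .. n_max + 1}).
#' @export
cumulative_division_probs <- function(gd) {
  if (!inherits(gd, "generation_distribution") || is.null(gd$L))
    stop("'gd' must carry division densities", call. = FALSE)
  g <- ncol(gd$L)
  H <- matrix(0, nrow = nrow(gd$L) + 1L, ncol = g)
  H[1L, ] <- 1
  for (i in seq_len(nrow(gd$L))) {
    H[i + 1L, ] <- pmin(cumtrapz_uniform(gd$L[i, ], gd$grid$step), 1)
  }
  rownames(H) <- paste0("n", seq_len(nrow(H)) - 1L)
  gd$H <- H
  gd
}

#' Cell numbers per generation
#'
#' Fills the expected number of cells observed in generation \eqn{n},
#' accounting for cells lost to the next generation:
#' \deqn{N_n(t) = 2^n N_0 \left[H_n(t) - H_{n+1}(t)\right].}
#' The factor \eqn{2^n} encodes the doubling at each division;
#' \eqn{\sum_n N_n(t)/2^n = N_0} by telescoping (lineage conservation), up
#' to the truncated tail beyond \code{n_max}.
#'
#' @param gd A \code{generation_distribution} with cumulative probabilities
#'   filled (see [cumulative_division_probs()]).
#' @param founders Number of founder cells \eqn{N_0} (> 0).
#' @return The same object with the matrix \code{N} filled (rows are
#'   generations \code{0 .. n_max}) and \code{founders} recorded.
#' @export
generation_counts <- function(gd, founders) {
  if (!inherits(gd, "generation_distribution"))
    stop("'gd' must be a generation_distribution", call. = FALSE)
  if (is.null(gd$H))
    stop("cumulative probabilities missing; call cumulative_division_probs()",
         call. = FALSE)
  if (nrow(gd$H) < gd$n_max + 2L)
    stop("internal consistency error: H must extend to generation n_max + 1",
         call. = FALSE)
  if (!is.finite(founders) || founders <= 0)
    stop("'founders' must be > 0", call. = FALSE)
  n_rows <- gd$n_max + 1L
  N <- matrix(0, nrow = n_rows, ncol = ncol(gd$H))
  for (i in seq_len(n_rows)) {
    n <- i - 1L
    N[i, ] <- pmax(2^n * founders * (gd$H[i, ] - gd$H[i + 1L, ]), 0)
  }
  rownames(N) <- paste0("n", seq_len(n_rows) - 1L)
  gd$N <- N
  gd$founders <- founders
  gd
}

#' Generation occupancy of one population over a chase period
#'
#' One-call wrapper around [generation_densities()],
#' [cumulative_division_probs()] and [generation_counts()]. When
#' \code{n_max} is \code{NULL} the generation range is truncated
#' adaptively: generations are added until the probability of having
#' divided beyond the last one by the end of the chase drops below
#' \code{tail_tol} (hard cap 25 — the factor \eqn{2^n} makes deeper tails
#' numerically explosive, and 25 halvings exceed any cytometer's dynamic
#' range).
#'
#' @inheritParams generation_densities
#' @param stop Chase duration in hours.
#' @param step Grid step in hours; default \code{min(scale/50, 0.1)}.
#' @param n_max Largest generation, or \code{NULL} for adaptive truncation.
#' @param founders Founder cell number \eqn{N_0}.
#' @param tail_tol Tail mass threshold for adaptive truncation.
#' @return A fully filled \code{generation_distribution}.
#' @examples
#' m <- division_time_model(15, 2, 4)
#' gd <- generation_distribution(m, stop = 144)
#' generation_fractions(gd)
#' @export
generation_distribution <- function(model, stop, step = NULL, n_max = NULL,
                                    founders = 1,
                                    initial = c("point", "uniform"),
                                    tail_tol = 1e-6) {
  stop_if_not_dtm(model)
  initial <- match.arg(initial)
  if (is.null(step)) step <- default_grid_step(model$scale)
  grid <- time_grid(stop, step)
  if (is.null(n_max)) {
    cap <- 25L
    k <- grid_kernel(model, grid)
    g <- length(grid$times)
    span <- model$min_cycle_time + model$shape * model$scale
    L1 <- if (initial == "point") k else as.numeric(grid$times <= span) / span
    L <- list(L1)
    H_end <- trapz_uniform(L1, grid$step)
    n <- 1L
    conv <- make_kernel_convolver(k, grid$step)
    ## grow until the (n_max + 1)-th generation is negligible at the end of
    ## the chase, keeping one extra generation for the counts difference
    while (H_end >= tail_tol && n < cap + 1L) {
      n <- n + 1L
      L[[n]] <- conv(L[[n - 1L]])
      H_end <- trapz_uniform(L[[n]], grid$step)
    }
    n_max <- max(1L, n - 1L)
    while (length(L) < n_max + 1L)  # counts need one generation beyond n_max
      L[[length(L) + 1L]] <- conv(L[[length(L)]])
    Lm <- do.call(rbind, L)
    rownames(Lm) <- paste0("n", seq_len(nrow(Lm)))
    gd <- structure(list(model = model, grid = grid, n_max = n_max,
                         initial = initial, L = Lm, H = NULL, N = NULL,
                         founders = NULL),
                    class = "generation_distribution")
  } else {
    gd <- generation_densities(model, grid, n_max, initial)
  }
  gd <- cumulative_division_probs(gd)
  generation_counts(gd, founders)
}

#' @export
print.generation_distribution <- function(x, ...) {
  cat("Generation distribution\n")
  cat(sprintf("  chase: [0, %.4g] h, step %.4g h (%d points)\n",
              x$grid$stop, x$grid$step, length(x$grid$times)))
  cat(sprintf("  generations represented: 0 .. %d\n", x$n_max))
  if (!is.null(x$N)) {
    fr <- generation_fractions(x)
    cat("  cell fractions at end of chase:\n")
    print(round(fr, 4))
  }
  invisible(x)
}

#' Generation cell-number fractions at a given time
#'
#' @param gd A filled \code{generation_distribution}.
#' @param t Time in hours; defaults to the end of the chase. Snapped to
#'   the nearest grid point.
#' @return Named vector of \eqn{N_n(t)/\sum_m N_m(t)} over generations
#'   \code{0 .. n_max}.
#' @export
generation_fractions <- function(gd, t = NULL) {
  if (is.null(gd$N)) stop("counts not filled", call. = FALSE)
  j <- if (is.null(t)) ncol(gd$N)
       else which.min(abs(gd$grid$times - t))
  v <- gd$N[, j]
  s <- sum(v)
  if (!is.finite(s) || s <= 0) {
    ## every represented generation exhausted (extremely fast cycling):
    ## all cells sit beyond the truncation, i.e. in the deepest generation
    v <- numeric(length(v))
    v[length(v)] <- 1
    return(stats::setNames(v, rownames(gd$N)))
  }
  v / s
}

#' Lineage-conservation defect of a generation distribution
#'
#' Computes \eqn{\max_t |\sum_n N_n(t)/2^n - N_0| / N_0}. By telescoping
#' this equals the truncated tail mass beyond the represented generations,
#' so it is a direct check of the truncation (and of internal consistency).
#'
#' @param gd A filled \code{generation_distribution}.
#' @return Maximum relative conservation defect over the grid.
#' @export
lineage_conservation_error <- function(gd) {
  if (is.null(gd$N)) stop("counts not filled", call. = FALSE)
  w <- 2^(-(seq_len(nrow(gd$N)) - 1L))
  tot <- colSums(gd$N * w)
  max(abs(tot - gd$founders)) / gd$founders
}
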