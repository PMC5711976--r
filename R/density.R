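#' Kernel density machinery
#'
#' A `cs_density` is the Gaussian-kernel density estimate of a set of
#' chemical-shift observations: d(delta) = (1/n) sum_l G(delta - delta_l),
#' where G is a unit-mass Gaussian of width `bandwidth`, evaluated on a
#' uniform ppm grid.  The grid extends five bandwidths beyond the sample
#' range with step bandwidth/4, which bounds the trapezoidal normalisation
#' error below 1e-6.
#'
#' @name cs_density
NULL

# trapezoidal integral over a uniform (or general) grid
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Silverman rule-of-thumb bandwidth with a scale floor (ppm).
silverman_bw <- function(x, floor = 0.05) {
  n <- length(x)
  s <- if (n > 1L) stats::sd(x) else 0
  iqr <- if (n > 1L) diff(stats::quantile(x, c(0.25, 0.75), names = FALSE)) else 0
  spread <- min(s, iqr / 1.34)
  if (!is.finite(spread) || spread <= 0) spread <- s
  bw <- 0.9 * spread * n^(-1 / 5)
  if (!is.finite(bw) || bw < floor) bw <- floor
  bw
}

#' Construct a density object directly from grid values
#'
#' Used for analytic densities in tests and for deserialisation; normalises
#' the supplied values to unit trapezoidal mass.
#'
#' @param grid uniform ascending ppm grid.
#' @param density non-negative values on `grid`.
#' @param n_obs sample count the density represents.
#' @param bandwidth kernel width in ppm.
#' @return a `cs_density` object.
#' @export
cs_density <- function(grid, density, n_obs, bandwidth) {
  stopifnot(length(grid) == length(density), all(density >= 0),
            n_obs >= 1, bandwidth > 0)
  mass <- trapz(grid, density)
  if (mass <= 0) stop("density has zero mass", call. = FALSE)
  structure(list(grid = grid, density = density / mass,
                 n_obs = as.integer(n_obs), bandwidth = bandwidth),
            class = "cs_density")
}

#' Gaussian-kernel density of a shift sample
#'
#' @param shifts numeric vector of observed shifts (ppm), length >= 1.
#' @param bandwidth kernel width in ppm; `NULL` (default) applies the
#'   Silverman rule-of-thumb floored at `floor`.
#' @param floor minimum bandwidth in ppm (0.02 for 1H, 0.05 for 13C/15N
#'   is used by the trainers).
#' @return a `cs_density`: list with `grid`, `density`, `n_obs`,
#'   `bandwidth`; integrates to 1 within 1e-6.
#' @export
#' @examples
#' d <- build_density(c(4.0, 4.2, 3.9), bandwidth = 0.1)
#' trapz <- function(x, y) sum((y[-1] + y[-length(y)]) * diff(x)) / 2
#' abs(trapz(d$grid, d$density) - 1) < 1e-6
build_density <- function(shifts, bandwidth = NULL, floor = 0.05) {
  if (length(shifts) < 1L) stop("empty shift sample", call. = FALSE)
  if (!all(is.finite(shifts))) stop("non-finite shift values", call. = FALSE)
  bw <- if (is.null(bandwidth)) silverman_bw(shifts, floor) else bandwidth
  if (bw <= 0) stop("bandwidth must be positive", call. = FALSE)
  lo <- min(shifts) - 5 * bw
  hi <- max(shifts) + 5 * bw
  step <- bw / 4
  grid <- seq(lo, hi, by = step)
  if (grid[length(grid)] < hi) grid <- c(grid, grid[length(grid)] + step)
  n <- length(shifts)
  dens <- rowSums(stats::dnorm(outer(grid, shifts, "-"), sd = bw)) / n
  structure(list(grid = grid, density = dens, n_obs = n, bandwidth = bw),
            class = "cs_density")
}

#' Expectation value of a shift density
#'
#' For richly populated categories (`n_obs >= n_min_mean`) the expectation
#' is the density-weighted mean, integral of delta * d(delta); for sparse
#' categories the mode (grid point of highest probability) is more robust.
#' Ties at the mode break toward lower ppm.
#'
#' @param density a `cs_density`.
#' @param n_min_mean sample-count threshold switching mode -> mean
#'   (default 50).
#' @return expected shift in ppm.
#' @export
expected_shift <- function(density, n_min_mean = 50) {
  stopifnot(inherits(density, "cs_density"))
  if (density$n_obs >= n_min_mean) {
    trapz(density$grid, density$grid * density$density) /
      trapz(density$grid, density$density)
  } else {
    density$grid[which.max(density$density)]
  }
}

# Resample a density onto an arbitrary grid (zero outside support).
resample_density <- function(d, grid) {
  y <- stats::approx(d$grid, d$density, xout = grid,
                     yleft = 0, yright = 0)$y
  mass <- trapz(grid, y)
  if (mass > 0) y / mass else y
}

#' Overlap-based correction weight
#'
#' The weight of a pairwise correction term is the negative overlap between
#' the primary and pair-conditioned densities:
#' w = 1 - integral min(d_i, d_ij).  Identical densities give w = 0
#' (the neighbour carries no information); disjoint supports give w = 1.
#' Densities are resampled onto a common uniform grid (union of ranges,
#' finer of the two steps) by linear interpolation and renormalised before
#' the overlap integral, so that w(d, d) is exactly 0.
#'
#' @param d_primary,d_pair `cs_density` objects.
#' @return weight in [0, 1].
#' @export
correction_weight <- function(d_primary, d_pair) {
  stopifnot(inherits(d_primary, "cs_density"), inherits(d_pair, "cs_density"))
  step <- min(d_primary$grid[2] - d_primary$grid[1],
              d_pair$grid[2] - d_pair$grid[1])
  lo <- min(d_primary$grid[1], d_pair$grid[1])
  hi <- max(d_primary$grid[length(d_primary$grid)],
            d_pair$grid[length(d_pair$grid)])
  grid <- seq(lo, hi, by = step)
  y1 <- resample_density(d_primary, grid)
  y2 <- resample_density(d_pair, grid)
  w <- 1 - trapz(grid, pmin(y1, y2))
  min(max(w, 0), 1)
}

#' @export
print.cs_density <- function(x, ...) {
  cat(sprintf(
    "<cs_density> n = %d, bandwidth = %.4g ppm, grid [%.3f, %.3f] (%d pts)\n",
    x$n_obs, x$bandwidth, x$grid[1], x$grid[length(x$grid)], length(x$grid)))
  invisible(x)
}
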