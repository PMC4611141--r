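#' Firing-rate profile of an external input
#'
#' External inputs are experimenter-controlled spiking units whose firing
#' rate over time follows a prescribed curve (they are deterministic, not
#' Poisson). Two kinds are used: a transient Gaussian rate bump (default
#' peak 400 Hz at 25 ms, sd 80 ms) and a sustained constant rate
#' (default 400 Hz).
#'
#' @param kind `"gaussian"` or `"sustained"`.
#' @param peak_rate Maximum firing rate (Hz).
#' @param center Gaussian peak time (ms); ignored for sustained.
#' @param sd Gaussian temporal sd (ms); ignored for sustained.
#' @return An object of class `rate_profile`.
#' @examples
#' rate_profile("gaussian")
#' rate_profile("sustained", peak_rate = 400)
#' @export
rate_profile <- function(kind = c("gaussian", "sustained"),
                         peak_rate = 400, center = 25, sd = 80) {
  kind <- match.arg(kind)
  if (!is.finite(peak_rate) || peak_rate < 0)
    stop("peak_rate must be a non-negative finite number")
  if (kind == "gaussian" && (!is.finite(center) || !is.finite(sd) || sd <= 0))
    stop("gaussian profile needs finite center and positive sd")
  structure(list(kind = kind, peak_rate = peak_rate,
                 center = center, sd = sd),
            class = "rate_profile")
}

#' Evaluate a rate profile (Hz) at times t (ms)
#' @param profile A [rate_profile()].
#' @param t Times in ms.
#' @return Rates in Hz, within `[0, peak_rate]`.
#' @export
rate_at <- function(profile, t) {
  stopifnot(inherits(profile, "rate_profile"))
  switch(profile$kind,
         sustained = rep(profile$peak_rate, length(t)),
         gaussian = profile$peak_rate *
           exp(-(t - profile$center)^2 / (2 * profile$sd^2)))
}

#' Deterministic spike train from a rate profile
#'
#' Integrates the rate curve on the simulation clock and emits a spike at
#' the first step where the running integral crosses each successive
#' integer. No randomness is involved, so a sustained 400 Hz profile over
#' 200 ms yields exactly 80 spikes at 2.5 ms spacing.
#'
#' @param profile A [rate_profile()].
#' @param duration Train duration (ms).
#' @param dt Integration step (ms); use the simulation clock.
#' @return Ordered spike times in ms (each the end of the step in which the
#'   integral crossed an integer).
#' @examples
#' length(rate_to_spike_train(rate_profile("sustained"), 200, 0.01))
#' @export
rate_to_spike_train <- function(profile, duration, dt) {
  stopifnot(inherits(profile, "rate_profile"))
  if (duration <= 0 || dt <= 0) stop("duration and dt must be positive")
  n <- as.integer(round(duration / dt))
  mid <- (seq_len(n) - 0.5) * dt
  r <- rate_at(profile, mid)
  if (any(r < 0)) stop("rate profile is negative")
  cum <- cumsum(r * dt / 1000)           # Hz * ms -> spikes
  n_spk <- floor(cum[n] + 1e-9)
  if (n_spk < 1) return(numeric(0))
  steps <- findInterval(seq_len(n_spk) - 1e-9, cum) + 1L
  steps * dt
}

#' Stimulus specification: mask + gain + rate profile
#'
#' Couples a spatial connection mask (per-cell weights in `[0, 1]`) to an
#' input unit firing along `profile`. Each input spike increments the
#' excitatory conductance of every mask cell by `alpha_s * w`.
#'
#' @param mask A data frame with columns `x`, `y` (0-based cell
#'   coordinates) and `w` (weights in `[0, 1]`), as produced by the mask
#'   constructors.
#' @param alpha_s Input gain.
#' @param profile A [rate_profile()].
#' @return An object of class `stimulus`.
#' @seealso [line_mask()], [square_mask()], [circle_mask()],
#'   [point_pair_stimuli()]
#' @export
stimulus <- function(mask, alpha_s = 4000, profile = rate_profile("gaussian")) {
  stopifnot(is.data.frame(mask), all(c("x", "y", "w") %in% names(mask)))
  if (any(mask$w < 0 | mask$w > 1)) stop("mask weights must lie in [0, 1]")
  if (!is.finite(alpha_s) || alpha_s < 0) stop("alpha_s must be non-negative")
  structure(list(mask = mask, alpha_s = alpha_s, profile = profile),
            class = "stimulus")
}

check_on_grid <- function(mask, grid) {
  if (any(mask$x < 0 | mask$x >= grid[1] | mask$y < 0 | mask$y >= grid[2]))
    stop("stimulus mask extends off the grid")
  mask
}

#' Vertical line stimulus mask
#'
#' A `width`-cell-wide vertical segment at column `x = 50`, vertically
#' centered at `y = 50` (0-based coordinates on the default 100 x 100
#' grid), with unit weights. Lengths above half the Y extent are outside
#' the study protocol and trigger a warning.
#'
#' @param length Number of cells along Y (even, 2..42 in the protocol).
#' @param grid Lattice size.
#' @param x0 Column of the line; defaults to the central column
#'   (`x = 50` on the standard grid).
#' @param width Line width in cells (columns `x0, x0+1, ...`).
#' @return Mask data frame (`x`, `y`, `w`).
#' @examples
#' nrow(line_mask(10))
#' @export
line_mask <- function(length, grid = c(100, 100), x0 = NULL, width = 1) {
  if (is.null(x0)) x0 <- floor(grid[1] / 2)
  if (length < 1) stop("length must be positive")
  if (length > grid[2] / 2)
    warning("line length exceeds half the Y extent; outside the study protocol")
  y <- seq(floor(grid[2] / 2) - length %/% 2,
           length.out = length)
  xs <- x0 + seq_len(width) - 1L
  check_on_grid(data.frame(x = rep(xs, each = length),
                           y = rep(y, times = width), w = 1),
                grid)
}

#' Filled square stimulus mask
#'
#' A filled `side x side` square centered on the grid center (for even
#' sides, on the half-cell point between the four central cells).
#'
#' @param side Side length in cells.
#' @param grid Lattice size.
#' @return Mask data frame.
#' @export
square_mask <- function(side, grid = c(100, 100)) {
  if (side < 1) stop("side must be positive")
  cx <- floor(grid[1] / 2)
  cy <- floor(grid[2] / 2)
  x <- seq(cx - side %/% 2, length.out = side)
  y <- seq(cy - side %/% 2, length.out = side)
  check_on_grid(expand.grid(x = x, y = y, w = 1), grid)
}

#' Filled rasterized disk stimulus mask
#'
#' Contains exactly the cells whose center lies within `diameter / 2` of
#' the stimulus center. For even diameters the center sits on the half-cell
#' point, so the disk is a subset of the same-size square.
#'
#' @param diameter Disk diameter in cells.
#' @param grid Lattice size.
#' @return Mask data frame.
#' @export
circle_mask <- function(diameter, grid = c(100, 100)) {
  if (diameter < 1) stop("diameter must be positive")
  cx <- floor(grid[1] / 2) - if (diameter %% 2 == 0) 0.5 else 0
  cy <- floor(grid[2] / 2) - if (diameter %% 2 == 0) 0.5 else 0
  r <- ceiling(diameter / 2) + 1
  g <- expand.grid(x = seq(floor(cx) - r, floor(cx) + r),
                   y = seq(floor(cy) - r, floor(cy) + r))
  keep <- (g$x - cx)^2 + (g$y - cy)^2 <= (diameter / 2)^2
  check_on_grid(data.frame(x = g$x[keep], y = g$y[keep], w = 1), grid)
}

#' Two competing point stimuli A and B
#'
#' A is a fixed 2 x 2 block anchored at `(31, 51)`; B is the same block
#' displaced by `+distance` along the X axis. Both share the default
#' transient Gaussian rate profile; their gains are set independently so
#' relative stimulus strength can be varied.
#'
#' @param distance Center-to-center separation along X (cells, 2..40 even
#'   in the protocol).
#' @param weight_a,weight_b Input gains for A and B.
#' @param grid Lattice size.
#' @param profile Shared [rate_profile()].
#' @return List with elements `A` and `B`, each a [stimulus()], plus
#'   `a_center` and `b_center` (x, y).
#' @examples
#' point_pair_stimuli(20)$b_center
#' @export
point_pair_stimuli <- function(distance, weight_a = 4000, weight_b = 4000,
                               grid = c(100, 100),
                               profile = rate_profile("gaussian")) {
  if (distance < 1) stop("distance must be positive")
  block <- function(x0, y0) expand.grid(x = x0 + 0:1, y = y0 + 0:1, w = 1)
  a <- block(31, 51)
  b <- block(31 + distance, 51)
  if (any(b$x >= grid[1]))
    stop("stimulus B falls off the grid at distance ", distance)
  list(A = stimulus(check_on_grid(a, grid), alpha_s = weight_a, profile = profile),
       B = stimulus(check_on_grid(b, grid), alpha_s = weight_b, profile = profile),
       a_center = c(31.5, 51.5), b_center = c(31.5 + distance, 51.5))
}

#' @export
print.stimulus <- function(x, ...) {
  cat(sprintf("Stimulus: %d cells, alpha_s = %g, %s profile (peak %g Hz)\n",
              nrow(x$mask), x$alpha_s, x$profile$kind, x$profile$peak_rate))
  invisible(x)
}

#' @export
print.rate_profile <- function(x, ...) {
  if (x$kind == "sustained")
    cat(sprintf("Sustained rate profile: %g Hz\n", x$peak_rate))
  else
    cat(sprintf("Gaussian rate profile: peak %g Hz at %g ms, sd %g ms\n",
                x$peak_rate, x$center, x$sd))
  invisible(x)
}
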