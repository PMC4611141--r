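#' Mexican-hat (difference-of-Gaussians) lateral connectivity
#'
#' The lateral weight between two cells at offset (x, y) is the difference
#' of two concentric Gaussians,
#' \deqn{f(x, y) = (1+\beta)\,e^{-x^2/2\sigma_x^2 - y^2/2\sigma_y^2}
#'              - \beta\, e^{-x^2/2K^2\sigma_x^2 - y^2/2K^2\sigma_y^2},}
#' short-range excitation surrounded by a moderately wider inhibitory
#' annulus. The first (positive) term is the excitatory weight field
#' \eqn{w_e}, the second the inhibitory field \eqn{w_i}; both are kept raw
#' (maxima \eqn{1+\beta} and \eqn{\beta}) and scaled by the gains
#' \eqn{\alpha_e}, \eqn{\alpha_i} when spikes are propagated, so the net
#' kernel \eqn{\alpha_e w_e - \alpha_i w_i} peaks at \eqn{\alpha_e} at the
#' origin.
#'
#' @param sigma_x,sigma_y Gaussian standard deviations in cells.
#' @param K Inhibition/excitation extent ratio (dimensionless, >= 1 for a
#'   Mexican hat).
#' @param beta Depth of inhibition (dimensionless).
#' @param alpha_e,alpha_i Excitatory / inhibitory gains applied to the raw
#'   fields when spikes are delivered.
#' @param mu_x,mu_y Center offset in cells (0 for self-centered kernels).
#' @return An object of class `kernel_spec`.
#' @seealso [kernel_preset()], [build_kernel()], [kernel_minimum()]
#' @examples
#' kernel_spec(sigma_x = 5, K = 1.2, beta = 6)
#' @export
kernel_spec <- function(sigma_x, sigma_y = sigma_x, K, beta,
                        alpha_e = 200, alpha_i = 200, mu_x = 0, mu_y = 0) {
  vals <- list(sigma_x = sigma_x, sigma_y = sigma_y, K = K, beta = beta,
               alpha_e = alpha_e, alpha_i = alpha_i, mu_x = mu_x, mu_y = mu_y)
  for (nm in names(vals)) {
    if (!is.numeric(vals[[nm]]) || length(vals[[nm]]) != 1L || !is.finite(vals[[nm]]))
      stop("kernel parameter '", nm, "' must be a finite scalar")
  }
  if (sigma_x <= 0 || sigma_y <= 0) stop("sigma_x and sigma_y must be positive")
  if (K < 1) stop("K must be >= 1 (inhibition at least as wide as excitation)")
  if (beta < 0 || alpha_e < 0 || alpha_i < 0)
    stop("beta, alpha_e and alpha_i must be non-negative")
  structure(vals, class = "kernel_spec")
}

#' Named kernel presets
#'
#' Three Mexican-hat variants: the reference hat `s1` (K = 1.2, beta = 6),
#' a wider-inhibition hat `s2` (K = 2.0, beta = 1.43, chosen so that the
#' depth of its inhibitory minimum matches s1), and a deeper-inhibition hat
#' `s3` (K = 1.2, beta = 8). All use alpha_e = alpha_i = 200.
#'
#' @param name One of `"s1"`, `"s2"`, `"s3"`.
#' @param sigma Gaussian sd in cells (5 for the single-stimulus protocols,
#'   8.5 for the two-stimulus protocols).
#' @return A [kernel_spec()].
#' @examples
#' kernel_preset("s2", sigma = 5)
#' @export
kernel_preset <- function(name = c("s1", "s2", "s3"), sigma = 5) {
  name <- match.arg(name)
  kb <- switch(name,
               s1 = c(K = 1.2, beta = 6.0),
               s2 = c(K = 2.0, beta = 1.43),
               s3 = c(K = 1.2, beta = 8.0))
  kernel_spec(sigma_x = sigma, sigma_y = sigma, K = kb[["K"]], beta = kb[["beta"]])
}

#' Continuous net kernel profile along a ray
#'
#' Evaluates \eqn{\alpha_e w_e(d) - \alpha_i w_i(d)} at radial distance `d`
#' (cells) for an isotropic, centered spec.
#'
#' @param spec A [kernel_spec()].
#' @param d Radial distance(s) in cells.
#' @return Net weight value(s).
#' @export
kernel_net_profile <- function(spec, d) {
  s2 <- spec$sigma_x^2
  spec$alpha_e * (1 + spec$beta) * exp(-d^2 / (2 * s2)) -
    spec$alpha_i * spec$beta * exp(-d^2 / (2 * spec$K^2 * s2))
}

#' Build the discrete lateral weight fields
#'
#' Evaluates the two Gaussian terms on all integer cell offsets within
#' `support_radius` of the center. By default the support covers the full
#' grid (no truncation); `cutoff = TRUE` trims offsets where the net weight
#' has fallen below `1e-4` of its central value, which speeds up spike
#' propagation with negligible effect on the dynamics.
#'
#' Two conventions are supported for splitting the hat into the excitatory
#' and inhibitory weight fields. Under `"net"` (the default, used by all
#' protocol drivers) the difference of Gaussians is computed first and
#' split by sign: `w_e` is its positive central lobe (maximum exactly 1 at
#' the origin) and `w_i` the magnitude of its negative surround annulus,
#' so with equal gains of 200 the excitatory weight peaks at 200 and the
#' inhibitory at about 113 -- excitation purely local, inhibition purely
#' annular, and the excitation peak roughly twice the inhibition depth.
#' Under `"terms"` the two raw Gaussian terms are used directly (`w_e`
#' peaks at `1 + beta`, `w_i` at `beta`), so every spike deposits large,
#' nearly cancelling increments on both conductances at every offset.
#' The net lateral weight `alpha_e * w_e - alpha_i * w_i` is identical
#' under both conventions; the dynamics are not, because the two
#' conductances see different reversal potentials and decay times.
#'
#' @param spec A [kernel_spec()].
#' @param grid Lattice size `c(nx, ny)`; determines the default support.
#' @param support_radius Optional explicit support radius in cells.
#' @param cutoff If `TRUE`, truncate the support where
#'   `|net| < 1e-4 * net(0)`.
#' @param convention `"net"` (sign-split net hat) or `"terms"` (raw
#'   Gaussian terms); see Details.
#' @return An object of class `kernel_field`: list with weight matrices
#'   `w_e` and `w_i` (dimension `(2R+1) x (2R+1)`, center at `R + 1`,
#'   before gain scaling), the `support_radius` `R`, the scaled `net`
#'   matrix `alpha_e * w_e - alpha_i * w_i`, the `convention`, and the
#'   `spec`.
#' @examples
#' kf <- build_kernel(kernel_preset("s1"), grid = c(21, 21), convention = "terms")
#' kf$w_e[11, 11]  # 1 + beta at the origin under the terms convention
#' @export
build_kernel <- function(spec, grid = c(100, 100), support_radius = NULL,
                         cutoff = FALSE, convention = c("net", "terms")) {
  convention <- match.arg(convention)
  stopifnot(inherits(spec, "kernel_spec"))
  grid <- as.integer(grid)
  if (is.null(support_radius)) support_radius <- max(grid) - 1L
  R <- as.integer(support_radius)
  if (cutoff) {
    net0 <- kernel_net_profile(spec, 0)
    d <- seq(0, R, by = 0.5)
    keep <- abs(kernel_net_profile(spec, d)) >= 1e-4 * net0
    R <- min(R, as.integer(ceiling(max(d[keep]))))
  }
  off <- seq(-R, R)
  gx <- exp(-(off - spec$mu_x)^2 / (2 * spec$sigma_x^2))
  gy <- exp(-(off - spec$mu_y)^2 / (2 * spec$sigma_y^2))
  hx <- exp(-(off - spec$mu_x)^2 / (2 * spec$K^2 * spec$sigma_x^2))
  hy <- exp(-(off - spec$mu_y)^2 / (2 * spec$K^2 * spec$sigma_y^2))
  term_e <- (1 + spec$beta) * outer(gx, gy)
  term_i <- spec$beta * outer(hx, hy)
  if (convention == "net") {
    f <- term_e - term_i          # difference-of-Gaussians, range (-beta, 1]
    w_e <- pmax(f, 0)
    w_i <- pmax(-f, 0)
  } else {
    w_e <- term_e
    w_i <- term_i
  }
  structure(list(w_e = w_e, w_i = w_i,
                 net = spec$alpha_e * w_e - spec$alpha_i * w_i,
                 support_radius = R, convention = convention, spec = spec),
            class = "kernel_field")
}

#' Depth and radius of the inhibitory minimum of the net kernel
#'
#' Minimizes the continuous net profile
#' \eqn{\alpha_e(1+\beta)e^{-d^2/2\sigma^2} - \alpha_i\beta
#' e^{-d^2/2K^2\sigma^2}} over radial distance. Requires `K > 1`; for
#' `K <= 1` the net kernel has no negative lobe.
#'
#' @param spec A [kernel_spec()].
#' @return List with `depth` (most negative net weight) and `radius`
#'   (cells).
#' @examples
#' kernel_minimum(kernel_preset("s1"))
#' @export
kernel_minimum <- function(spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (spec$K <= 1)
    stop("net kernel has no negative lobe for K <= 1")
  opt <- stats::optimize(function(d) kernel_net_profile(spec, d),
                         interval = c(0, 6 * spec$K * spec$sigma_x),
                         tol = 1e-10)
  list(depth = opt$objective, radius = opt$minimum)
}

#' Radial zero crossing of the net kernel
#'
#' The distance at which lateral influence changes sign from excitatory to
#' inhibitory.
#'
#' @param spec A [kernel_spec()] with `K > 1`.
#' @return Radius in cells.
#' @export
kernel_zero_crossing <- function(spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (spec$K <= 1) stop("net kernel does not change sign for K <= 1")
  mn <- kernel_minimum(spec)
  stats::uniroot(function(d) kernel_net_profile(spec, d),
                 interval = c(0, mn$radius), tol = 1e-10)$root
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("Mexican-hat kernel spec: sigma = (%g, %g) cells, K = %g, beta = %g\n",
              x$sigma_x, x$sigma_y, x$K, x$beta))
  cat(sprintf("  gains alpha_e = %g, alpha_i = %g; center offset (%g, %g)\n",
              x$alpha_e, x$alpha_i, x$mu_x, x$mu_y))
  invisible(x)
}

#' @export
print.kernel_field <- function(x, ...) {
  cat(sprintf("Discrete Mexican-hat kernel field, support radius %d cells\n",
              x$support_radius))
  cat(sprintf("  net weight: %g at origin, minimum %g\n",
              x$net[x$support_radius + 1, x$support_radius + 1], min(x$net)))
  invisible(x)
}

#' Export a kernel field as plain-text arrays
#'
#' Writes `w_e` and `w_i` as CSV matrices plus a JSON metadata file holding
#' the spec parameters and support radius.
#'
#' @param field A [build_kernel()] result.
#' @param dir Output directory (created if needed).
#' @param name Base name for the files.
#' @return Invisibly, the paths written.
#' @export
write_kernel <- function(field, dir, name = "kernel") {
  stopifnot(inherits(field, "kernel_field"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pe <- file.path(dir, paste0(name, "_we.csv"))
  pi_ <- file.path(dir, paste0(name, "_wi.csv"))
  pm <- file.path(dir, paste0(name, "_meta.json"))
  utils::write.table(field$w_e, pe, sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(field$w_i, pi_, sep = ",", row.names = FALSE, col.names = FALSE)
  meta <- c(unclass(field$spec), list(support_radius = field$support_radius))
  writeLines(paste0("{", paste(sprintf('"%s": %g', names(meta), unlist(meta)),
                               collapse = ", "), "}"), pm)
  invisible(c(pe, pi_, pm))
}
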