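# terminal detection window used to separate self-maintained clusters
# from residual input-locked firing
persist_window <- function(config, len = 50) {
  c(max(0, config$duration - len), config$duration)
}

classify_run <- function(n_clusters) {
  if (n_clusters == 0) "suppressed"
  else if (n_clusters == 1) "single"
  else if (n_clusters == 2) "double"
  else "multiple"
}

sweep_meta <- function(result, seed = NULL) {
  attr(result, "engine_version") <- as.character(utils::packageVersion("spikefield"))
  attr(result, "seed") <- seed
  attr(result, "timestamp") <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  result
}

#' Size sweep of a single line stimulus
#'
#' Runs the full single-stimulus protocol for one kernel variant: a
#' vertical line stimulus of each requested length, driven by the
#' transient Gaussian rate profile (or a sustained 400 Hz profile), on the
#' 100 x 100 field with sigma = 5 and input gain 4000. Each run is
#' summarized by its cluster count and classification (`single`,
#' `suppressed`, `double`, `multiple`), total spikes, relative activity
#' with respect to the smallest size, first-spike latency, initial
#' (0-6 ms) and late (30-90 ms) membrane rise speeds on the probe column,
#' and the steady firing rate of the largest cluster.
#'
#' @param variant Kernel preset: `"s1"`, `"s2"` or `"s3"`.
#' @param sizes Line lengths in cells.
#' @param profile `"gaussian"` (transient) or `"sustained"`.
#' @param sigma Kernel sd in cells.
#' @param alpha_s Input gain.
#' @param line_width Stimulus line width in cells.
#' @param config A [sim_config()].
#' @param rate_min Minimum terminal-window firing rate (Hz) for a cell to
#'   count as part of a self-maintained cluster (see [detect_clusters()]).
#' @param keep_sims If `TRUE`, attach the full `field_sim` objects as the
#'   `sims` attribute.
#' @return A data frame of class `field_sweep`, one row per size.
#' @export
run_size_sweep <- function(variant = c("s1", "s2", "s3"),
                           sizes = seq(2, 42, by = 2),
                           profile = c("gaussian", "sustained"),
                           sigma = 5, alpha_s = 4000, line_width = 1,
                           config = sim_config(), rate_min = 150,
                           keep_sims = FALSE) {
  variant <- match.arg(variant)
  profile <- match.arg(profile)
  sizes <- as.numeric(sizes)
  kf <- build_kernel(kernel_preset(variant, sigma = sigma), grid = config$grid)
  prof <- if (profile == "gaussian") rate_profile("gaussian")
          else rate_profile("sustained")
  sims <- vector("list", length(sizes))
  rows <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    stim <- stimulus(line_mask(sizes[i], grid = config$grid, width = line_width),
                     alpha_s = alpha_s, profile = prof)
    sim <- simulate_field(kf, list(stim), config)
    # under sustained drive the rate filter cannot separate input-locked
    # mask firing from self-maintained clusters; lateral recruitment can
    rep <- detect_clusters(sim, window = persist_window(config),
                           rate_min = rate_min, off_mask = stim$mask,
                           require_off_mask = profile == "sustained")
    rows[[i]] <- data.frame(
      variant = variant, size = sizes[i], profile = profile,
      n_clusters = nrow(rep), classification = classify_run(nrow(rep)),
      total_spikes = nrow(sim$spikes),
      latency = first_spike_latency(sim),
      cluster_latency = if (nrow(rep) > 0) min(rep$recruited_at) else NA_real_,
      rise_initial = if (config$duration >= 6)
        rise_speed(sim, c(0, 6)) else NA_real_,
      rise_late = if (config$duration >= 90)
        rise_speed(sim, c(30, 90)) else NA_real_,
      steady_rate = if (nrow(rep) > 0) max(rep$steady_rate) else NA_real_)
    if (keep_sims) sims[[i]] <- sim
  }
  res <- do.call(rbind, rows)
  ref <- res$total_spikes[1]
  res$relative_activity <- if (ref > 0) res$total_spikes / ref else NA_real_
  res <- structure(res, class = c("field_sweep", "data.frame"),
                   protocol = paste0("size_sweep_", variant,
                                     if (profile == "sustained") "_sustained" else ""))
  if (keep_sims) attr(res, "sims") <- sims
  sweep_meta(res)
}

#' Size sweep of 2D stimulus shapes
#'
#' Same protocol as [run_size_sweep()] but with filled squares or
#' rasterized disks centered on the map, using the reference kernel (s1).
#'
#' @param shape `"square"` or `"circle"`.
#' @param sizes Side lengths / diameters in cells.
#' @inheritParams run_size_sweep
#' @return A `field_sweep` data frame, one row per size.
#' @export
run_shape_sweep <- function(shape = c("square", "circle"),
                            sizes = seq(2, 30, by = 2),
                            sigma = 5, alpha_s = 4000,
                            config = sim_config(), rate_min = 150,
                            keep_sims = FALSE) {
  shape <- match.arg(shape)
  sizes <- as.numeric(sizes)
  kf <- build_kernel(kernel_preset("s1", sigma = sigma), grid = config$grid)
  maskfun <- if (shape == "square") square_mask else circle_mask
  sims <- vector("list", length(sizes))
  rows <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    stim <- stimulus(maskfun(sizes[i], grid = config$grid), alpha_s = alpha_s)
    sim <- simulate_field(kf, list(stim), config)
    rep <- detect_clusters(sim, window = persist_window(config),
                           rate_min = rate_min, off_mask = stim$mask)
    rows[[i]] <- data.frame(
      shape = shape, size = sizes[i],
      n_clusters = nrow(rep), classification = classify_run(nrow(rep)),
      total_spikes = nrow(sim$spikes),
      latency = first_spike_latency(sim),
      cluster_latency = if (nrow(rep) > 0) min(rep$recruited_at) else NA_real_)
    if (keep_sims) sims[[i]] <- sim
  }
  res <- do.call(rbind, rows)
  ref <- res$total_spikes[1]
  res$relative_activity <- if (ref > 0) res$total_spikes / ref else NA_real_
  res <- structure(res, class = c("field_sweep", "data.frame"),
                   protocol = paste0("shape_sweep_", shape))
  if (keep_sims) attr(res, "sims") <- sims
  sweep_meta(res)
}

#' Distance sweep of two competing point stimuli
#'
#' Stimulus A (2 x 2 block at x = 31, y = 51) competes with an
#' equal-geometry stimulus B displaced along X by each tested distance,
#' both driven by the transient Gaussian profile, on a wider kernel
#' (sigma = 8.5, reference hat). For each distance the cluster nearest B
#' is located and its signed X deviation from B reported (negative =
#' attracted toward A, positive = repulsed away). Optionally a control
#' with B alone at every tested location verifies that cluster positions
#' are not border artifacts.
#'
#' @param weight_a Input gain of stimulus A (B's gain is `weight_b`).
#' @param weight_b Input gain of stimulus B.
#' @param distances Center separations in cells.
#' @param noise_sd Membrane noise sd in mV (0 = deterministic).
#' @param sigma Kernel sd in cells.
#' @param control If `TRUE`, also run B alone at each location and report
#'   the solitary cluster's deviation (`control_dev_x`).
#' @param config A [sim_config()]; its `noise_sd` is overridden.
#' @param keep_sims Attach full simulations as an attribute.
#' @return A data frame of class `field_sweep`, one row per distance:
#'   `distance`, `deviation_x`, `n_clusters`, `suppressed`, `winner_x`,
#'   `winner_y` (and control columns if requested).
#' @export
run_two_stimulus_sweep <- function(weight_a = 4000, weight_b = 4000,
                                   distances = seq(2, 40, by = 2),
                                   noise_sd = 0, sigma = 8.5,
                                   control = FALSE,
                                   config = sim_config(), rate_min = 150,
                                   keep_sims = FALSE) {
  config$noise_sd <- noise_sd
  distances <- as.numeric(distances)
  kf <- build_kernel(kernel_preset("s1", sigma = sigma), grid = config$grid)
  sims <- vector("list", length(distances))
  rows <- vector("list", length(distances))
  for (i in seq_along(distances)) {
    pp <- point_pair_stimuli(distances[i], weight_a = weight_a,
                             weight_b = weight_b, grid = config$grid)
    sim <- simulate_field(kf, list(pp$A, pp$B), config)
    dev <- deviation_from_b(
      detect_clusters(sim, window = persist_window(config),
                      rate_min = rate_min),
      pp$b_center, pp$a_center)
    row <- cbind(data.frame(distance = distances[i],
                            weight_a = weight_a, weight_b = weight_b),
                 dev)
    if (control) {
      csim <- simulate_field(kf, list(pp$B), config)
      cdev <- deviation_from_b(
        detect_clusters(csim, window = persist_window(config),
                        rate_min = rate_min),
        pp$b_center, pp$a_center)
      row$control_dev_x <- cdev$deviation_x
      row$control_n_clusters <- cdev$n_clusters
    }
    rows[[i]] <- row
    if (keep_sims) sims[[i]] <- sim
  }
  res <- structure(do.call(rbind, rows),
                   class = c("field_sweep", "data.frame"),
                   protocol = sprintf("two_stimulus_%g_vs_%g%s", weight_a,
                                      weight_b,
                                      if (noise_sd > 0) "_noise" else ""))
  if (keep_sims) attr(res, "sims") <- sims
  sweep_meta(res, seed = config$seed)
}

#' @export
print.field_sweep <- function(x, ...) {
  cat(sprintf("Field sweep '%s' (%d conditions, engine %s)\n",
              attr(x, "protocol"), nrow(x), attr(x, "engine_version")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write a sweep summary table to CSV
#'
#' Prepends provenance comment lines (protocol, engine version, seed).
#'
#' @param sweep A `field_sweep`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_sweep <- function(sweep, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# protocol: %s", attr(sweep, "protocol")), con)
  writeLines(sprintf("# engine: spikefield %s", attr(sweep, "engine_version")), con)
  if (!is.null(attr(sweep, "seed")))
    writeLines(sprintf("# seed: %s", attr(sweep, "seed")), con)
  utils::write.csv(as.data.frame(sweep), con, row.names = FALSE)
  invisible(path)
}

#' Run a protocol described by a YAML configuration file
#'
#' The file names one of the three protocols and its parameters, e.g.
#' \preformatted{
#' protocol: size_sweep        # size_sweep | shape_sweep | two_stimulus
#' variant: s1                 # kernel preset for size_sweep
#' profile: gaussian
#' sizes: [2, 10, 20]
#' }
#'
#' @param path Path to the YAML file.
#' @param out Optional CSV path for the summary table.
#' @return The `field_sweep` result.
#' @export
run_config <- function(path, out = NULL) {
  cfg <- yaml::read_yaml(path)
  proto <- match.arg(cfg$protocol, c("size_sweep", "shape_sweep", "two_stimulus"))
  base <- sim_config(
    grid = cfg$grid %||% c(100, 100),
    duration = cfg$duration %||% 200,
    noise_sd = cfg$noise_sd %||% 0,
    seed = cfg$seed)
  res <- switch(proto,
    size_sweep = run_size_sweep(
      variant = cfg$variant %||% "s1",
      sizes = cfg$sizes %||% seq(2, 42, 2),
      profile = cfg$profile %||% "gaussian",
      sigma = cfg$sigma %||% 5,
      alpha_s = cfg$alpha_s %||% 4000,
      line_width = cfg$line_width %||% 1,
      config = base),
    shape_sweep = run_shape_sweep(
      shape = cfg$shape %||% "square",
      sizes = cfg$sizes %||% seq(2, 30, 2),
      sigma = cfg$sigma %||% 5,
      alpha_s = cfg$alpha_s %||% 4000,
      config = base),
    two_stimulus = run_two_stimulus_sweep(
      weight_a = cfg$weight_a %||% 4000,
      weight_b = cfg$weight_b %||% 4000,
      distances = cfg$distances %||% seq(2, 40, 2),
      noise_sd = cfg$noise_sd %||% 0,
      sigma = cfg$sigma %||% 8.5,
      control = isTRUE(cfg$control),
      config = base))
  if (!is.null(out)) write_sweep(res, out)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
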