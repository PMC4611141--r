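#' Simulate the spiking neural field
#'
#' Integrates the conductance-based integrate-and-fire lattice under the
#' given lateral kernel and external stimuli. The membrane potential of
#' each cell relaxes toward a conductance-weighted balance of the resting,
#' excitatory and inhibitory reversal potentials; cells crossing threshold
#' spike, reset, become refractory for 1.5 ms and deposit
#' `alpha_e * w_e` / `alpha_i * w_i` increments onto their neighbours'
#' conductances, effective from the next step. Gains are specified in mV
#' (the units of the standard parameter table); the dimensionless
#' conductance increment per spike is the gain expressed in volts, i.e.
#' `alpha * w / 1000`. The membrane equation is advanced with exponential
#' Euler (exact for conductances frozen over one step), which remains
#' stable at arbitrarily high conductance; conductances decay exactly.
#'
#' Without noise the run is fully deterministic and independent of `seed`.
#'
#' @param kernel A [build_kernel()] result (or a [kernel_spec()], which is
#'   built on the config grid).
#' @param stimuli A list of [stimulus()] objects (possibly empty).
#' @param config A [sim_config()].
#' @param params A [neuron_params()].
#' @param probe Cells whose membrane potential and conductances are
#'   recorded on the recording clock: either a two-column matrix/data frame
#'   of 0-based (x, y) coordinates, or `"column"` for the default probe
#'   line (the full column at `probe_x`, parallel to the line stimuli).
#' @param probe_x Column used when `probe = "column"`.
#' @param v_init Optional initial membrane potential (mV): a scalar or an
#'   `nx x ny` matrix. Defaults to the resting potential.
#' @return An object of class `field_sim` with elements `spikes` (data
#'   frame `x`, `y`, `t`; 0-based cells, ms), `trace` (list: `cells`,
#'   `times`, matrices `v`, `g_e`, `g_i` with one row per probe cell),
#'   `config`, `params`, `kernel_spec`, and `elapsed` (seconds).
#' @examples
#' kf <- build_kernel(kernel_preset("s1"), grid = c(30, 30))
#' cfg <- sim_config(grid = c(30, 30), duration = 20)
#' quiet <- simulate_field(kf, list(), cfg)
#' nrow(quiet$spikes)  # 0: the field is quiescent without input
#' @export
simulate_field <- function(kernel, stimuli = list(), config = sim_config(),
                           params = neuron_params(), probe = "column",
                           probe_x = 52, v_init = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(params, "neuron_params"))
  if (inherits(kernel, "kernel_spec"))
    kernel <- build_kernel(kernel, grid = config$grid)
  stopifnot(inherits(kernel, "kernel_field"))
  if (inherits(stimuli, "stimulus")) stimuli <- list(stimuli)
  stopifnot(all(vapply(stimuli, inherits, logical(1), "stimulus")))

  nx <- config$grid[1]; ny <- config$grid[2]
  dt <- config$dt
  n_steps <- as.integer(round(config$duration / dt))
  record_every <- as.integer(round(config$record_dt / dt))

  stim_cells <- list(); stim_inc <- list(); stim_steps <- list()
  for (s in stimuli) {
    m <- check_on_grid(s$mask, config$grid)
    stim_cells[[length(stim_cells) + 1L]] <-
      cbind(as.integer(m$x), as.integer(m$y))
    stim_inc[[length(stim_inc) + 1L]] <- s$alpha_s * m$w / 1000
    tt <- rate_to_spike_train(s$profile, config$duration, dt)
    stim_steps[[length(stim_steps) + 1L]] <-
      as.integer(round(tt / dt)) - 1L
  }

  if (identical(probe, "column")) {
    px <- min(probe_x, nx - 1L)
    probe_cells <- cbind(rep(as.integer(px), ny), seq_len(ny) - 1L)
  } else {
    probe_cells <- as.matrix(probe)
    storage.mode(probe_cells) <- "integer"
  }

  # per-step draw calibrated so the stationary membrane fluctuation under
  # tau_m has sd = noise_sd (an Ornstein-Uhlenbeck balance): noise_sd is
  # the amplitude of the noise ON the potential, not per unit time
  noise_step_sd <- if (config$noise_sd > 0)
    config$noise_sd * sqrt(2 * dt / params$tau_m) else 0
  if (noise_step_sd > 0 && !is.null(config$seed)) set.seed(config$seed)

  v0 <- if (is.null(v_init)) numeric(0) else {
    v <- if (length(v_init) == 1L) matrix(v_init, nx, ny) else as.matrix(v_init)
    stopifnot(all(dim(v) == c(nx, ny)))
    as.numeric(v)
  }

  spec <- kernel$spec
  t0 <- proc.time()[["elapsed"]]
  out <- sim_field_cpp(nx, ny, dt, n_steps, record_every,
                       c(params$tau_m, params$tau_e, params$tau_i,
                         params$v_thresh, params$v_reset, params$v_rest,
                         params$v_exc, params$v_inh, params$refractory),
                       spec$alpha_e * kernel$w_e / 1000,
                       spec$alpha_i * kernel$w_i / 1000,
                       kernel$support_radius,
                       stim_cells, stim_inc, stim_steps,
                       noise_step_sd, probe_cells, v0)
  elapsed <- proc.time()[["elapsed"]] - t0

  structure(list(
    spikes = data.frame(x = out$spike_x, y = out$spike_y, t = out$spike_t),
    trace = list(cells = data.frame(x = probe_cells[, 1], y = probe_cells[, 2]),
                 times = out$trace_times,
                 v = out$trace_v, g_e = out$trace_ge, g_i = out$trace_gi),
    config = config, params = params, kernel_spec = spec,
    elapsed = elapsed),
    class = "field_sim")
}

#' Brute-force reference simulator
#'
#' A deliberately naive per-cell-pair event simulator used as an
#' independent check of the lattice engine: every spike is propagated by an
#' explicit double loop over source-target cell pairs, and every cell's
#' membrane update is computed individually in R. Identical update
#' equations and ordering as [simulate_field()], so on small grids the two
#' must produce identical spike sets. Only practical for grids up to about
#' 15 x 15 and short durations.
#'
#' @inheritParams simulate_field
#' @return A `field_sim` object (without traces).
#' @export
simulate_field_bruteforce <- function(kernel, stimuli = list(),
                                      config = sim_config(),
                                      params = neuron_params(),
                                      v_init = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(kernel, "kernel_spec"))
    kernel <- build_kernel(kernel, grid = config$grid)
  if (inherits(stimuli, "stimulus")) stimuli <- list(stimuli)
  nx <- config$grid[1]; ny <- config$grid[2]
  dt <- config$dt
  n_steps <- as.integer(round(config$duration / dt))
  spec <- kernel$spec
  R <- kernel$support_radius
  AeWe <- spec$alpha_e * kernel$w_e / 1000
  AiWi <- spec$alpha_i * kernel$w_i / 1000

  cells <- expand.grid(x = 0:(nx - 1), y = 0:(ny - 1))
  n_cells <- nrow(cells)
  V <- rep(params$v_rest, n_cells)
  if (!is.null(v_init)) V <- rep_len(as.numeric(v_init), n_cells)
  ge <- gi <- inc_e <- inc_i <- numeric(n_cells)
  refrac <- integer(n_cells)
  refrac_steps <- as.integer(round(params$refractory / dt))
  de <- exp(-dt / params$tau_e); di <- exp(-dt / params$tau_i)

  # same relaxation-factor evaluation as the compiled engine (degree-6
  # Taylor tail below 1/64, exp above, 0 beyond 30) so spike sets match
  # bit for bit
  relax_exp <- function(a) {
    if (a > 30) return(0)
    if (a < 0.015625) {
      s <- 1 - a / 6
      s <- 1 - a * s / 5
      s <- 1 - a * s / 4
      s <- 1 - a * s / 3
      s <- 1 - a * s / 2
      return(1 - a * s)
    }
    exp(-a)
  }

  stim_events <- lapply(stimuli, function(s) {
    tt <- rate_to_spike_train(s$profile, config$duration, dt)
    list(steps = as.integer(round(tt / dt)) - 1L,
         cells = s$mask$x + nx * s$mask$y + 1L,
         inc = s$alpha_s * s$mask$w / 1000)
  })

  sx <- integer(0); sy <- integer(0); st <- numeric(0)
  for (step in 0:(n_steps - 1)) {
    for (c in seq_len(n_cells)) {
      ge[c] <- ge[c] * de + inc_e[c]
      gi[c] <- gi[c] * di + inc_i[c]
      inc_e[c] <- 0; inc_i[c] <- 0
    }
    for (ev in stim_events) {
      if (step %in% ev$steps)
        for (k in seq_along(ev$cells))
          ge[ev$cells[k]] <- ge[ev$cells[k]] + ev$inc[k]
    }
    for (c in seq_len(n_cells)) {
      if (refrac[c] > 0) {
        refrac[c] <- refrac[c] - 1L
        V[c] <- params$v_reset
      } else {
        gtot <- 1 + ge[c] + gi[c]
        vinf <- (params$v_rest + ge[c] * params$v_exc + gi[c] * params$v_inh) / gtot
        a <- dt * gtot / params$tau_m
        V[c] <- vinf + (V[c] - vinf) * relax_exp(a)
      }
    }
    spiked <- which(refrac == 0 & V > params$v_thresh)
    for (c in spiked) {
      cx <- (c - 1) %% nx; cy <- (c - 1) %/% nx
      V[c] <- params$v_reset
      refrac[c] <- refrac_steps
      sx <- c(sx, cx); sy <- c(sy, cy); st <- c(st, (step + 1) * dt)
      # explicit pair loop: every target cell looks up its offset weight
      for (tc in seq_len(n_cells)) {
        tx <- (tc - 1) %% nx; ty <- (tc - 1) %/% nx
        dx <- tx - cx; dy <- ty - cy
        if (abs(dx) <= R && abs(dy) <= R) {
          inc_e[tc] <- inc_e[tc] + AeWe[dx + R + 1, dy + R + 1]
          inc_i[tc] <- inc_i[tc] + AiWi[dx + R + 1, dy + R + 1]
        }
      }
    }
  }
  structure(list(spikes = data.frame(x = sx, y = sy, t = st),
                 trace = NULL, config = config, params = params,
                 kernel_spec = spec, elapsed = NA_real_),
            class = "field_sim")
}

#' @export
print.field_sim <- function(x, ...) {
  cat(sprintf("Spiking neural field simulation: %d x %d cells, %g ms\n",
              x$config$grid[1], x$config$grid[2], x$config$duration))
  cat(sprintf("  %d spikes from %d distinct cells\n",
              nrow(x$spikes), nrow(unique(x$spikes[c("x", "y")]))))
  invisible(x)
}

#' @export
summary.field_sim <- function(object, ...) {
  rep <- detect_clusters(object)
  cat(sprintf("Spiking neural field simulation (%g ms, %d x %d cells)\n",
              object$config$duration, object$config$grid[1], object$config$grid[2]))
  cat(sprintf("  total spikes: %d; first-spike latency: %s ms\n",
              nrow(object$spikes),
              format(first_spike_latency(object))))
  cat(sprintf("  spiking clusters (>= %d cells, 8-connected): %d\n",
              attr(rep, "min_size"), nrow(rep)))
  if (nrow(rep) > 0) print(rep, digits = 4)
  invisible(rep)
}

#' Plot the spike-count map of a simulation
#'
#' @param x A `field_sim`.
#' @param window Time window `[t0, t1]` in ms (defaults to the full run).
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the count matrix.
#' @export
plot.field_sim <- function(x, window = NULL, ...) {
  m <- spike_count_map(x, window)
  nx <- nrow(m); ny <- ncol(m)
  graphics::image(0:(nx - 1), 0:(ny - 1), m,
                  xlab = "x (cells)", ylab = "y (cells)",
                  col = grDevices::hcl.colors(64, "inferno"),
                  useRaster = TRUE, ...)
  invisible(m)
}
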