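#' Neuron parameters for the conductance-based integrate-and-fire field
#'
#' Scalar constants of the membrane equation. The defaults are the values
#' used throughout the reference protocols: a 10 ms membrane time constant,
#' faster excitatory than inhibitory synaptic decay (3 ms vs 10 ms), and a
#' 1.5 ms absolute refractory period which caps the firing rate at about
#' 600 Hz.
#'
#' @param tau_m Membrane time constant (ms).
#' @param tau_e Excitatory synaptic decay time constant (ms).
#' @param tau_i Inhibitory synaptic decay time constant (ms).
#' @param v_thresh Spike threshold (mV).
#' @param v_reset Post-spike reset potential (mV).
#' @param v_rest Resting potential (mV).
#' @param v_exc Excitatory reversal potential (mV).
#' @param v_inh Inhibitory reversal potential (mV).
#' @param refractory Absolute refractory period (ms). While refractory a
#'   cell is clamped to `v_reset` and exempt from all drive; its
#'   conductances keep decaying and accumulating.
#' @return An object of class `neuron_params`.
#' @examples
#' neuron_params()
#' @export
neuron_params <- function(tau_m = 10, tau_e = 3, tau_i = 10,
                          v_thresh = -50, v_reset = -80, v_rest = -70,
                          v_exc = 0, v_inh = -80, refractory = 1.5) {
  p <- list(tau_m = tau_m, tau_e = tau_e, tau_i = tau_i,
            v_thresh = v_thresh, v_reset = v_reset, v_rest = v_rest,
            v_exc = v_exc, v_inh = v_inh, refractory = refractory)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("neuron parameter '", nm, "' must be a finite scalar")
  }
  if (tau_m <= 0 || tau_e <= 0 || tau_i <= 0 || refractory < 0)
    stop("time constants must be positive and refractory non-negative")
  if (!(v_reset <= v_inh && v_inh <= v_rest && v_rest < v_thresh && v_thresh < v_exc))
    stop("potentials must satisfy v_reset <= v_inh <= v_rest < v_thresh < v_exc")
  structure(p, class = "neuron_params")
}

#' Simulation configuration (grid, clocks, duration, noise)
#'
#' @param grid Lattice size as `c(nx, ny)` in cells.
#' @param dt Simulation clock step (ms).
#' @param record_dt Recording clock step (ms); must be a multiple of `dt`.
#' @param duration Total simulated time (ms); a multiple of `record_dt`.
#' @param noise_sd Standard deviation (mV) of the membrane-potential
#'   noise; 0 disables noise. Implemented as independent per-step draws
#'   scaled by `sqrt(2 dt / tau_m)` so that the stationary fluctuation of
#'   the potential around its drift (an Ornstein-Uhlenbeck balance under
#'   the membrane time constant) has the stated sd.
#' @param seed Optional integer seed used when `noise_sd > 0`.
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(duration = 50)
#' @export
sim_config <- function(grid = c(100, 100), dt = 0.01, record_dt = 1,
                       duration = 200, noise_sd = 0, seed = NULL) {
  grid <- as.integer(grid)
  if (length(grid) != 2L || any(grid < 1L))
    stop("grid must be two positive integers")
  if (dt <= 0 || record_dt <= 0 || duration <= 0)
    stop("dt, record_dt and duration must be positive")
  ratio <- record_dt / dt
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("dt must divide record_dt")
  nrec <- duration / record_dt
  if (abs(nrec - round(nrec)) > 1e-9)
    stop("duration must be a multiple of record_dt")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(grid = grid, dt = dt, record_dt = record_dt,
                 duration = duration, noise_sd = noise_sd, seed = seed),
            class = "sim_config")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("Conductance-based integrate-and-fire neuron parameters\n")
  cat(sprintf("  tau_m = %g ms, tau_e = %g ms, tau_i = %g ms\n",
              x$tau_m, x$tau_e, x$tau_i))
  cat(sprintf("  V: rest %g, threshold %g, reset %g, reversal E %g / I %g (mV)\n",
              x$v_rest, x$v_thresh, x$v_reset, x$v_exc, x$v_inh))
  cat(sprintf("  refractory period %g ms\n", x$refractory))
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Field simulation config: %d x %d cells, dt = %g ms, record_dt = %g ms, %g ms\n",
              x$grid[1], x$grid[2], x$dt, x$record_dt, x$duration))
  if (x$noise_sd > 0)
    cat(sprintf("  membrane noise sd %g mV (seed %s)\n", x$noise_sd,
                if (is.null(x$seed)) "unset" else format(x$seed)))
  invisible(x)
}
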