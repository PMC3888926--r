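#' Excitatory output function
#'
#' Piecewise-linear sigmoid of the membrane potential: 0 below the adaptive
#' threshold `phi`, slope 1 between `phi` and `phi + 1`, clipped to 1 above.
#' Represents the cluster's average firing rate in `[0, 1]`.
#'
#' @param V Membrane potential(s).
#' @param phi Output threshold(s) (`phi = alpha * omega`, recycled).
#' @return Output rate(s) in `[0, 1]`.
#' @examples
#' excitatory_output(c(0.3, 0.7, 9), phi = 0.3)
#' @export
excitatory_output <- function(V, phi) {
  pmin(pmax(V - phi, 0), 1)
}

#' Inhibitory output function
#'
#' Rectified-linear output: 0 for negative potentials, the potential itself
#' otherwise (not clipped above).
#'
#' @param V Membrane potential(s).
#' @return Output rate(s) >= 0.
#' @examples
#' inhibitory_output(c(-0.3, 0, 0.7))
#' @export
inhibitory_output <- function(V) {
  pmax(V, 0)
}

#' One Euler step of the membrane equation
#'
#' Integrates `tau * dV/dt = -V + k1 * (V_in + k2 * eta)` with step
#' `params$dt`.  `V_in` is the summed net input (EPSPs positive, IPSPs
#' negative, plus the baseline `Vb` and minus any global-inhibition term).
#'
#' @param V Current membrane potential(s).
#' @param V_in Net input per cell (must be finite).
#' @param params A [dynamics_params()].
#' @param eta Noise sample(s) in `[-0.5, 0.5]`; defaults to 0 (no noise).
#' @return Updated potential(s).
#' @examples
#' integrate_membrane_step(1, 0, dynamics_params(tau = 2.5, dt = 0.5))
#' @export
integrate_membrane_step <- function(V, V_in, params, eta = 0) {
  params <- as_dynamics_params(params)
  bad <- which(!is.finite(V_in))
  if (length(bad) > 0) {
    stop("non-finite net input at cell(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  V + (params$dt / params$tau) *
    (-V + params$k1 * (V_in + params$k2 * eta))
}

#' One Euler step of the adaptation average
#'
#' Integrates `tauA * d(omega)/dt = -omega + O` for excitatory cells; the
#' output threshold used at the next step is `phi = alpha * omega`.
#'
#' @param omega Current output time-average(s) (`omega(x, 0) = 0`).
#' @param O Current output(s).
#' @param params A [dynamics_params()].
#' @return Updated `omega`.
#' @export
update_adaptation <- function(omega, O, params) {
  params <- as_dynamics_params(params)
  omega + (params$dt / params$tauA) * (-omega + O)
}

#' One Euler step of the area-global activity average
#'
#' Integrates `tauS * d(omegaS)/dt = -omegaS + sum(O)` where the sum runs
#' over all excitatory outputs of one area; `kS * omegaS` is subtracted from
#' each of that area's excitatory inputs at the next step.
#'
#' @param omegaS Current area average(s).
#' @param total_O Summed excitatory output(s) of the area(s).
#' @param params A [dynamics_params()].
#' @return Updated `omegaS`.
#' @export
update_global_inhibition <- function(omegaS, total_O, params) {
  params <- as_dynamics_params(params)
  omegaS + (params$dt / params$tauS) * (-omegaS + total_O)
}

#' Initialise network state at rest
#'
#' All membrane potentials, adaptation averages and outputs start at zero.
#'
#' @param net A `ca_network`.
#' @return An object of class `ca_state`.
#' @export
init_state <- function(net) {
  stopifnot(inherits(net, "ca_network"))
  structure(
    list(
      V_e = numeric(net$n_e), V_i = numeric(net$n_e),
      omega = numeric(net$n_e), omegaS = numeric(net$n_areas),
      O_e = numeric(net$n_e), O_i = numeric(net$n_e)
    ),
    class = "ca_state"
  )
}

#' @export
print.ca_state <- function(x, ...) {
  cat(sprintf("<ca_state> %d excitatory cells; mean V_e = %.4f; mean omega = %.4f\n",
              length(x$V_e), mean(x$V_e), mean(x$omega)))
  invisible(x)
}

copy_state <- function(state) {
  structure(lapply(state, function(v) v + 0), class = "ca_state")
}

#' Run the network for a block of steps
#'
#' Advances the network with the compiled engine.  Per step, and
#' synchronously across cells: all outputs are computed from the current
#' state; net inputs are assembled (recurrent and between-area excitation,
#' local inhibitory feedback, area-global inhibition, baseline, optional
#' stimulus); the Hebbian rule is applied to every excitatory-to-excitatory
#' weight (if plasticity is enabled) using the current outputs and
#' postsynaptic potentials; then membrane potentials, adaptation averages and
#' the area-global averages take one Euler step.  Per-cell noise is drawn
#' uniformly from `[-0.5, 0.5]` from R's RNG stream (all excitatory cells in
#' index order, then all inhibitory cells), so trajectories are reproducible
#' under `set.seed()`.
#'
#' @param net A `ca_network`.
#' @param state A `ca_state` (see [init_state()]).
#' @param dynamics A [dynamics_params()].
#' @param n_steps Number of Euler steps.
#' @param stim_cells Global excitatory cell indices receiving the stimulus
#'   (may be empty).
#' @param stim_amp Additive input drive to the stimulated cells.
#' @param stim_window Integer `c(from, to)` step window (1-based, inclusive)
#'   during which the stimulus is applied; default covers all steps.
#' @param plasticity A [plasticity_params()] or `NULL` (frozen weights).
#' @param record If `TRUE`, return the excitatory output time series.
#'
#' @return A list with elements `state` (updated `ca_state`), `net` (with
#'   updated weights if plasticity was enabled) and, if requested,
#'   `recording`: a `ca_recording` matrix of `n_steps` rows (step) by
#'   `net$n_e` columns (cell) holding the outputs used at each step.
#' @examples
#' net <- build_network("serial", grid = c(5, 5), seed = 1)
#' set.seed(1)
#' out <- simulate_network(net, init_state(net), dynamics_params(), 20)
#' @export
simulate_network <- function(net, state, dynamics, n_steps,
                             stim_cells = integer(0), stim_amp = 0,
                             stim_window = c(1L, n_steps),
                             plasticity = NULL, record = TRUE) {
  stopifnot(inherits(net, "ca_network"), inherits(state, "ca_state"),
            n_steps >= 1)
  dynamics <- as_dynamics_params(dynamics)
  plast <- if (is.null(plasticity)) {
    plasticity_params(enabled = FALSE)
  } else {
    as_plasticity_params(plasticity)
  }
  st <- copy_state(state)
  W <- net$W_ee
  if (plast$enabled) W@x <- W@x + 0  # private copy; engine mutates in place

  res <- cpp_simulate(
    W, net$W_ei,
    st$V_e, st$V_i, st$omega, st$omegaS, st$O_e, st$O_i,
    unclass(dynamics), unclass(plast),
    as.integer(n_steps),
    as.integer(stim_cells) - 1L, stim_amp,
    as.integer(stim_window[1]), as.integer(stim_window[2]),
    record,
    net$n_cells, net$n_areas, net$grid[1]
  )
  if (plast$enabled) net$W_ee <- W
  out <- list(state = st, net = net)
  if (record) {
    out$recording <- new_ca_recording(res$recording, net)
  }
  out
}

new_ca_recording <- function(mat, net) {
  structure(mat,
            areas = net$areas,
            n_cells = net$n_cells,
            class = c("ca_recording", "matrix", "array"))
}

#' @export
print.ca_recording <- function(x, ...) {
  cat(sprintf("<ca_recording> %d steps x %d excitatory cells (6 areas)\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Pure-R reference stepper (one step)
#'
#' A direct, unoptimised transcription of the synchronous update used by the
#' compiled engine, for cross-validation on small networks.  Draws noise in
#' the same order as the engine, so trajectories agree bit-for-bit under the
#' same RNG state.
#'
#' @param net A `ca_network`.
#' @param state A `ca_state`.
#' @param dynamics A [dynamics_params()].
#' @param stim_cells,stim_amp Optional additive stimulus.
#' @return List with the updated `state` and the outputs `O_e`, `O_i` used
#'   during the step.
#' @keywords internal
#' @export
step_reference <- function(net, state, dynamics,
                           stim_cells = integer(0), stim_amp = 0) {
  p <- as_dynamics_params(dynamics)
  area <- cell_area(net)
  O_e <- excitatory_output(state$V_e, p$alpha * state$omega)
  O_i <- inhibitory_output(state$V_i)
  area_O <- tapply(O_e, area, sum)

  V_in_e <- as.numeric(Matrix::crossprod(net$W_ee, O_e)) -
    p$g_inh * O_i - p$kS * state$omegaS[area] + p$Vb
  if (length(stim_cells) > 0) V_in_e[stim_cells] <- V_in_e[stim_cells] + stim_amp
  V_in_i <- as.numeric(Matrix::crossprod(net$W_ei, O_e)) +
    if (p$inh_baseline) p$Vb else 0

  eta_e <- runif(net$n_e) - 0.5
  eta_i <- runif(net$n_e) - 0.5
  st <- state
  st$V_e <- integrate_membrane_step(state$V_e, V_in_e, p, eta_e)
  st$V_i <- integrate_membrane_step(state$V_i, V_in_i, p, eta_i)
  st$omega <- update_adaptation(state$omega, O_e, p)
  st$omegaS <- update_global_inhibition(state$omegaS, as.numeric(area_O), p)
  st$O_e <- excitatory_output(st$V_e, p$alpha * st$omega)
  st$O_i <- inhibitory_output(st$V_i)
  list(state = st, O_e = O_e, O_i = O_i)
}
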