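#' Cell and area dynamics parameters
#'
#' Parameters of the graded-response leaky-integrator cells: membrane time
#' constant, input/noise scaling, baseline drive, output-threshold adaptation,
#' area-global inhibition and the Euler step.  The shipped defaults are the
#' calibrated values used throughout the package: they produce a quiet
#' resting state in an untrained network while leaving trained cell
#' assemblies bistable (ignitable by noise, self-terminating through
#' adaptation and global inhibition).
#'
#' @param tau Membrane time constant (arbitrary time units, > 0).
#' @param k1 Input scaling constant (> 0).
#' @param k2 Noise scaling constant (>= 0); the per-cell, per-step noise is
#'   `k2 * eta` with `eta` uniform on `[-0.5, 0.5]`.  Set to 0 to silence
#'   spontaneous firing.
#' @param Vb Constant baseline input term added to every cell's net input.
#' @param alpha Adaptation strength: an excitatory cell's output threshold is
#'   `phi = alpha * omega`, with `omega` the running average of its output.
#' @param tauA Adaptation time constant (> 0).
#' @param kS Gain of the area-global inhibition term subtracted from each
#'   excitatory cell's input (>= 0).
#' @param tauS Time constant of the area-global activity average (> 0).
#' @param dt Euler integration step (> 0 and <= `tau` for stability).
#'   The model is integrated with `dt = 0.5`.
#' @param g_inh Gain of the local inhibitory feedback: each excitatory cell
#'   receives `-g_inh * O_i` from its underlying inhibitory cell.
#' @param inh_baseline Whether inhibitory cells also receive the baseline
#'   term `Vb` (the membrane equation is stated for every cell, so the
#'   default is `TRUE`).
#'
#' @return An object of class `dynamics_params` (a named list).
#' @examples
#' p <- dynamics_params()
#' p$dt
#' @export
dynamics_params <- function(tau = 2.5,
                            k1 = 3,
                            k2 = 0.85,
                            Vb = 0,
                            alpha = 5,
                            tauA = 10,
                            kS = 0.2,
                            tauS = 7.5,
                            dt = 0.5,
                            g_inh = 0.4,
                            inh_baseline = TRUE) {
  stopifnot(
    is.numeric(tau), tau > 0,
    is.numeric(tauA), tauA > 0,
    is.numeric(tauS), tauS > 0,
    is.numeric(dt), dt > 0, dt <= tau,
    is.numeric(k1), k1 > 0,
    is.numeric(k2), k2 >= 0,
    is.numeric(kS), kS >= 0,
    is.numeric(alpha), alpha >= 0,
    is.numeric(g_inh), g_inh >= 0,
    is.logical(inh_baseline), length(inh_baseline) == 1
  )
  structure(
    list(
      tau = tau, k1 = k1, k2 = k2, Vb = Vb, alpha = alpha,
      tauA = tauA, kS = kS, tauS = tauS, dt = dt,
      g_inh = g_inh, inh_baseline = inh_baseline
    ),
    class = "dynamics_params"
  )
}

#' Hebbian plasticity parameters
#'
#' Parameters of the discretised Artola-Broecher-Singer LTP/LTD rule applied
#' to every excitatory-to-excitatory link.  A link from cell `x` to cell `y`
#' is potentiated by `delta_w` when the presynaptic output `O(x)` is at least
#' `theta_pre` and the postsynaptic potential `V(y)` is at least
#' `theta_plus`; it is depressed by `delta_w` when either the presynaptic
#' cell is active but `V(y)` lies in `[theta_minus, theta_plus)`
#' (homosynaptic LTD) or the presynaptic cell is inactive while
#' `V(y) >= theta_plus` (heterosynaptic LTD); otherwise it is unchanged.
#' Weights are clipped to `[0, w_max]`.
#'
#' @param delta_w Fixed weight step (0 < `delta_w` << `w_max`).
#' @param theta_pre Minimum presynaptic output for a link to count as
#'   active, in `]0, 1]`.
#' @param theta_plus Postsynaptic potential threshold for LTP.
#' @param theta_minus Postsynaptic potential threshold for homosynaptic LTD
#'   (must be < `theta_plus`).
#' @param w_max Weight ceiling (> 0).
#' @param enabled Master switch; when `FALSE` weights are left untouched.
#'
#' @return An object of class `plasticity_params` (a named list).
#' @examples
#' plasticity_params(enabled = FALSE)
#' @export
plasticity_params <- function(delta_w = 0.002,
                              theta_pre = 0.15,
                              theta_plus = 0.5,
                              theta_minus = 0.2,
                              w_max = 0.25,
                              enabled = TRUE) {
  stopifnot(
    is.numeric(delta_w), delta_w > 0,
    is.numeric(theta_pre), theta_pre > 0, theta_pre <= 1,
    is.numeric(theta_plus), is.numeric(theta_minus),
    theta_minus < theta_plus,
    is.numeric(w_max), w_max > 0, delta_w < w_max,
    is.logical(enabled), length(enabled) == 1
  )
  structure(
    list(
      delta_w = delta_w, theta_pre = theta_pre, theta_plus = theta_plus,
      theta_minus = theta_minus, w_max = w_max, enabled = enabled
    ),
    class = "plasticity_params"
  )
}

#' @export
print.dynamics_params <- function(x, ...) {
  cat("<dynamics_params>\n")
  for (nm in names(x)) cat(sprintf("  %-12s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' @export
print.plasticity_params <- function(x, ...) {
  cat("<plasticity_params>\n")
  for (nm in names(x)) cat(sprintf("  %-12s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

as_dynamics_params <- function(x) {
  if (inherits(x, "dynamics_params")) return(x)
  do.call(dynamics_params, as.list(x))
}

as_plasticity_params <- function(x) {
  if (inherits(x, "plasticity_params")) return(x)
  do.call(plasticity_params, as.list(x))
}
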