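#' Apply the discretised Artola-Broecher-Singer rule to a weight
#'
#' Vectorised single-step weight update.  A presynaptic link is active when
#' `O_pre >= theta_pre`.  The update is
#' `+delta_w` (LTP) for active links onto strongly depolarised cells
#' (`V_post >= theta_plus`); `-delta_w` (LTD) for active links onto
#' moderately depolarised cells (`theta_minus <= V_post < theta_plus`,
#' homosynaptic LTD) and for inactive links onto strongly depolarised cells
#' (heterosynaptic LTD); no change otherwise.  Results are clipped to
#' `[0, w_max]`.  This is the rule the compiled engine applies to every
#' excitatory-to-excitatory link at every training step.
#'
#' @param w Current weight(s), >= 0.
#' @param O_pre Presynaptic output(s) in `[0, 1]`.
#' @param V_post Postsynaptic membrane potential(s).
#' @param params A [plasticity_params()].
#' @return Updated weight(s).
#' @examples
#' p <- plasticity_params()
#' hebbian_update(0.05, O_pre = 1, V_post = 1, p)   # LTP
#' hebbian_update(0.05, O_pre = 1, V_post = 0.1, p) # homosynaptic LTD
#' @export
hebbian_update <- function(w, O_pre, V_post, params) {
  params <- as_plasticity_params(params)
  if (!params$enabled) return(w)
  pre <- O_pre >= params$theta_pre
  hi <- V_post >= params$theta_plus
  mid <- V_post >= params$theta_minus & V_post < params$theta_plus
  dw <- ifelse(pre & hi, params$delta_w,
               ifelse((pre & mid) | (!pre & hi), -params$delta_w, 0))
  pmin(pmax(w + dw, 0), params$w_max)
}

#' Apply the Hebbian rule across all excitatory links
#'
#' Updates every excitatory-to-excitatory weight of the network from the
#' given outputs and postsynaptic potentials (one plasticity step).
#' Inhibitory wiring is untouched.  This R-level implementation mirrors what
#' the compiled engine does inline during training and is mainly useful for
#' testing and for custom protocols.
#'
#' @param net A `ca_network`.
#' @param state A `ca_state` (uses `O_e` as presynaptic outputs and `V_e`
#'   as postsynaptic potentials).
#' @param params A [plasticity_params()].
#' @return The network with updated `W_ee`.
#' @export
apply_plasticity <- function(net, state, params) {
  stopifnot(inherits(net, "ca_network"), inherits(state, "ca_state"))
  params <- as_plasticity_params(params)
  if (!params$enabled) return(net)
  W <- net$W_ee
  # update the x slot in CSC order so pruned (zero) links keep their slot
  # and can re-potentiate later, exactly as in the compiled engine
  pre <- W@i + 1L
  post <- rep(seq_len(ncol(W)), diff(W@p))
  W@x <- hebbian_update(W@x, state$O_e[pre], state$V_e[post], params)
  net$W_ee <- W
  net
}
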