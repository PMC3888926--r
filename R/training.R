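#' Build a training schedule
#'
#' One row per presentation: patterns are presented in random order without
#' blocking (each pattern appears exactly `presentations_per_pattern` times),
#' each presentation driving the pattern's P1 and M1 cells for
#' `stimulus_steps` steps and followed by an inter-stimulus interval drawn
#' uniformly from `isi_range`.
#'
#' @param n_patterns Number of patterns in the set.
#' @param presentations_per_pattern Presentations of each pattern
#'   (default 15000 at reference scale).
#' @param stimulus_steps Steps the stimulus is applied (default 16).
#' @param isi_range Integer `c(min, max)` of the ISI in steps (default
#'   `c(30, 80)`).
#' @param seed Optional integer seed.
#' @return A tibble of class `ca_schedule` with columns `presentation`,
#'   `pattern`, `isi`; `stimulus_steps` is kept as an attribute.
#' @examples
#' training_schedule(2, 5, seed = 1)
#' @export
training_schedule <- function(n_patterns, presentations_per_pattern = 15000,
                              stimulus_steps = 16, isi_range = c(30, 80),
                              seed = NULL) {
  stopifnot(n_patterns >= 1, presentations_per_pattern >= 1,
            stimulus_steps >= 1, length(isi_range) == 2,
            isi_range[1] >= 1, isi_range[2] >= isi_range[1])
  if (!is.null(seed)) set.seed(seed)
  n <- n_patterns * presentations_per_pattern
  order <- sample(rep(seq_len(n_patterns), presentations_per_pattern))
  isi <- sample(seq(isi_range[1], isi_range[2]), n, replace = TRUE)
  out <- tibble::tibble(presentation = seq_len(n), pattern = order,
                        isi = as.integer(isi))
  class(out) <- c("ca_schedule", class(out))
  attr(out, "stimulus_steps") <- as.integer(stimulus_steps)
  out
}

#' Train the network on the pattern set
#'
#' Runs the full Hebbian training protocol on a fresh ("tabula rasa")
#' network: for each scheduled presentation the pattern's P1 and M1 cells
#' receive a strong additive drive for the stimulus period, followed by the
#' drawn ISI during which activation spreads and decays; the
#' Artola-Broecher-Singer rule is applied to every
#' excitatory-to-excitatory weight at every step.  Over many presentations
#' this grows pattern-specific distributed sensorimotor cell assemblies.
#'
#' @param net A fresh `ca_network`.
#' @param patterns A `ca_patterns` tibble (see [generate_pattern_pairs()]).
#' @param schedule A `ca_schedule` (see [training_schedule()]).
#' @param dynamics A [dynamics_params()].
#' @param plasticity A [plasticity_params()].
#' @param stim_amp Additive drive to stimulated cells; the default saturates
#'   the driven cells' output within 2-3 steps.
#' @param state Optional starting `ca_state` (default: rest).
#'
#' @return A list with `net` (trained weights), `state` (final state) and
#'   `log`: the schedule tibble extended with `act_stim`, `act_isi` (summed
#'   excitatory output during the stimulus/ISI blocks) and `mean_w` (mean
#'   excitatory weight after the presentation).
#' @examples
#' \donttest{
#' net <- build_network("full", grid = c(8, 8), seed = 1)
#' pats <- generate_pattern_pairs(2, 6, 0, grid = c(8, 8), seed = 1)
#' sch <- training_schedule(2, 20, isi_range = c(5, 10), seed = 1)
#' tr <- run_training(net, pats, sch, dynamics_params(), plasticity_params())
#' }
#' @export
run_training <- function(net, patterns, schedule, dynamics, plasticity,
                         stim_amp = 10, state = NULL) {
  stopifnot(inherits(net, "ca_network"))
  dynamics <- as_dynamics_params(dynamics)
  plasticity <- as_plasticity_params(plasticity)
  if (is.null(state)) state <- init_state(net)
  st <- copy_state(state)
  W <- net$W_ee
  W@x <- W@x + 0  # private copy; the engine updates weights in place

  pat_cells <- pattern_global_cells(net, patterns)
  res <- cpp_train(
    W, net$W_ei,
    st$V_e, st$V_i, st$omega, st$omegaS, st$O_e, st$O_i,
    unclass(dynamics), unclass(plasticity),
    lapply(pat_cells, function(v) as.integer(v) - 1L),
    as.integer(schedule$pattern), as.integer(schedule$isi),
    attr(schedule, "stimulus_steps"), stim_amp,
    net$n_cells, net$n_areas, net$grid[1]
  )
  net$W_ee <- W
  log <- dplyr::mutate(tibble::as_tibble(schedule),
                       act_stim = res$act_stim,
                       act_isi = res$act_isi,
                       mean_w = res$mean_w)
  list(net = net, state = st, log = log)
}

#' Probe the trained network with each pattern
#'
#' With plasticity frozen and the network reset to rest (plus a brief
#' noise-driven settling period) before each probe, each pattern is presented
#' and every excitatory cell's output is averaged over the
#' `window_len` steps following stimulus onset (the window starts at
#' onset + 1), then averaged over `n_reps` repetitions.  The resulting
#' per-cell, per-pattern response profile defines cell-assembly membership
#' (see [identify_ca_cells()]).
#'
#' @param net A trained `ca_network`.
#' @param patterns A `ca_patterns` tibble.
#' @param dynamics A [dynamics_params()]; probes run with the same noise
#'   level as the spontaneous phase.
#' @param n_reps Probe repetitions averaged per pattern (default 12).
#' @param stim_steps Stimulus duration in steps (default 16).
#' @param stim_amp Stimulus drive (default as in training).
#' @param window_offset Steps after onset at which the averaging window
#'   starts (default 1).
#' @param window_len Length of the averaging window (default 15).
#' @param settle_steps Noise-only steps run before each probe.
#'   Initialising at zero triggers one rebound ignition (every adaptation
#'   threshold starts at zero); with the default, probes arrive in a
#'   recent-activity context comparable to training, where each stimulus
#'   follows earlier network activity within a few tens of steps.  The
#'   residual adaptation and global inhibition at that point set the gain
#'   of the probe: short settles give high-coverage responses across the
#'   assembly's areas, long settles (past full recovery) let the whole
#'   coupled assembly system co-ignite.  Membership thresholds are relative
#'   per pattern and area, so they adapt to the probe gain.
#'
#' @return An object of class `ca_profile`: a matrix of `net$n_e` rows
#'   (cells) by `n_patterns` columns of time-averaged outputs in `[0, 1]`,
#'   with the area table attached.
#' @export
probe_responses <- function(net, patterns, dynamics, n_reps = 12,
                            stim_steps = 16, stim_amp = 10,
                            window_offset = 1, window_len = 15,
                            settle_steps = 20) {
  stopifnot(inherits(net, "ca_network"), n_reps >= 1)
  dynamics <- as_dynamics_params(dynamics)
  pat_cells <- pattern_global_cells(net, patterns)
  n_pat <- length(pat_cells)
  n_steps <- max(stim_steps, window_offset + window_len)
  win <- window_offset + seq_len(window_len)
  prof <- matrix(0, nrow = net$n_e, ncol = n_pat)
  for (k in seq_len(n_pat)) {
    for (r in seq_len(n_reps)) {
      st <- init_state(net)
      if (settle_steps > 0) {
        st <- simulate_network(net, st, dynamics, settle_steps,
                               record = FALSE)$state
      }
      out <- simulate_network(net, st, dynamics, n_steps,
                              stim_cells = pat_cells[[k]],
                              stim_amp = stim_amp,
                              stim_window = c(1L, stim_steps),
                              record = TRUE)
      prof[, k] <- prof[, k] + colMeans(out$recording[win, , drop = FALSE])
    }
  }
  prof <- prof / n_reps
  structure(prof,
            areas = net$areas, n_cells = net$n_cells,
            class = c("ca_profile", "matrix", "array"))
}

#' @export
print.ca_profile <- function(x, ...) {
  cat(sprintf("<ca_profile> %d cells x %d patterns; max response %.3f\n",
              nrow(x), ncol(x), max(x)))
  invisible(x)
}
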