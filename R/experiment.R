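#' Configure a spontaneous-ignition experiment
#'
#' Bundles every parameter of the end-to-end pipeline (architecture,
#' patterns, training, probing, spontaneous recording, analysis) for one of
#' the three experiment variants:
#' * `"full"` — the complete architecture with jumping links;
#' * `"no_jumping"` — the serial architecture (jumping links removed);
#' * `"no_noise"` — the full architecture, trained with noise, but with the
#'   noise gain `k2` set to 0 during the spontaneous phase only.
#'
#' Two scale presets are provided.  `"full"` is the reference scale
#' (25 x 25 areas, 12 patterns of 20 cells, 15000 presentations per pattern,
#' 20000 recorded steps).  `"reduced"` (the default) preserves the
#' architecture, degree ratios and qualitative dynamics at a size that runs
#' in minutes on one CPU: 12 x 12 areas with proportionally scaled
#' neighbourhoods, 6 patterns of 10 cells (overlap 2), 1000 presentations
#' per pattern with ISIs of 10-25 steps, and a 4000-step spontaneous
#' recording.
#'
#' @param variant `"full"`, `"no_jumping"` or `"no_noise"`.
#' @param scale `"reduced"` or `"full"`.
#' @param seed Integer master seed for the whole pipeline.
#' @param dynamics,plasticity Parameter objects (defaults are the calibrated
#'   package defaults).
#' @param network A [network_config()].
#' @param ... Named overrides of individual preset fields (`grid`,
#'   `n_patterns`, `cells_per_pattern`, `overlap_cells`,
#'   `presentations_per_pattern`, `stimulus_steps`, `isi_range`, `stim_amp`,
#'   `n_probe_reps`, `recording_steps`, `gamma`, `asi_pre`, `asi_len`,
#'   `critical_window`).
#'
#' @return A named list of class `ca_config`.
#' @examples
#' cfg <- experiment_config("full", seed = 1, recording_steps = 500)
#' @export
experiment_config <- function(variant = c("full", "no_jumping", "no_noise"),
                              scale = c("reduced", "full"),
                              seed = 1,
                              dynamics = dynamics_params(),
                              plasticity = plasticity_params(),
                              network = NULL,
                              ...) {
  variant <- match.arg(variant)
  scale <- match.arg(scale)
  preset <- if (scale == "reduced") {
    list(grid = c(12, 12), n_patterns = 6, cells_per_pattern = 10,
         overlap_cells = 2, presentations_per_pattern = 1000,
         stimulus_steps = 16, isi_range = c(10, 25),
         recording_steps = 4000,
         network = network_config(n_within = 7, n_between = 13,
                                  p0_within = 0.5, p0_between = 0.7))
  } else {
    list(grid = c(25, 25), n_patterns = 12, cells_per_pattern = 20,
         overlap_cells = 4, presentations_per_pattern = 15000,
         stimulus_steps = 16, isi_range = c(30, 80),
         recording_steps = 20000,
         network = network_config())
  }
  if (!is.null(network)) preset$network <- network
  cfg <- c(preset, list(
    variant = variant, scale = scale, seed = as.integer(seed),
    dynamics = as_dynamics_params(dynamics),
    plasticity = as_plasticity_params(plasticity),
    stim_amp = 10, n_probe_reps = 12, gamma = 0.5,
    asi_pre = 10, asi_len = 40, critical_window = 6
  ))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) stop("unknown config fields: ",
                                paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "ca_config")
}

#' @export
print.ca_config <- function(x, ...) {
  cat(sprintf("<ca_config> variant %s, scale %s, seed %d\n",
              x$variant, x$scale, x$seed))
  cat(sprintf("  %d x %d areas, %d patterns of %d cells, %d presentations/pattern\n",
              x$grid[1], x$grid[2], x$n_patterns, x$cells_per_pattern,
              x$presentations_per_pattern))
  invisible(x)
}

#' Run one spontaneous-ignition experiment end to end
#'
#' Executes the full pipeline: build the (full or serial) network, generate
#' the pattern pairs, train with Hebbian plasticity, probe the trained
#' network to define CA membership, record stimulus-free spontaneous
#' activity (noise on, or off for the `no_noise` variant), detect ignition
#' events, build (normalised) ASI traces, align the critical window at the
#' last all-baseline step and run the per-step repeated-measures ANOVA with
#' planned comparisons.  Every stage draws from the single RNG stream seeded
#' with `config$seed`, so identical configs reproduce identical event tables
#' and statistics.
#'
#' @param config A [experiment_config()].
#' @param keep_recording Keep the (possibly large) raw recording matrix in
#'   the result (default `TRUE`).
#' @return An object of class `ca_run`: a list with elements `config`,
#'   `audit`, `patterns`, `log` (training log), `profile`, `membership`,
#'   `ca_sizes`, `events`, `asi`, `window`, `anova`, `onsets` and optionally
#'   `recording`.  For runs with no usable ignition events the analysis
#'   elements from `asi` onwards are `NULL`.
#' @export
run_experiment <- function(config, keep_recording = TRUE) {
  stopifnot(inherits(config, "ca_config"))
  set.seed(config$seed)
  net_variant <- if (config$variant == "no_jumping") "serial" else "full"
  net <- build_network(net_variant, grid = config$grid,
                       config = config$network)
  patterns <- generate_pattern_pairs(config$n_patterns,
                                     config$cells_per_pattern,
                                     config$overlap_cells,
                                     grid = config$grid)
  schedule <- training_schedule(config$n_patterns,
                                config$presentations_per_pattern,
                                config$stimulus_steps, config$isi_range)
  trained <- run_training(net, patterns, schedule, config$dynamics,
                          config$plasticity, stim_amp = config$stim_amp)
  profile <- probe_responses(trained$net, patterns, config$dynamics,
                             n_reps = config$n_probe_reps,
                             stim_steps = config$stimulus_steps,
                             stim_amp = config$stim_amp)
  membership <- identify_ca_cells(profile, config$gamma)
  sizes <- ca_size_table(profile)

  spont_dyn <- config$dynamics
  if (config$variant == "no_noise") spont_dyn$k2 <- 0
  rec <- simulate_network(trained$net, init_state(trained$net), spont_dyn,
                          config$recording_steps, record = TRUE)$recording
  events <- detect_ignitions(rec, membership)

  out <- list(config = config, audit = audit_graph(net),
              patterns = patterns, log = trained$log, net = trained$net,
              profile = profile, membership = membership,
              ca_sizes = sizes, events = events,
              asi = NULL, window = NULL, anova = NULL, onsets = NULL)
  if (keep_recording) out$recording <- rec

  if (nrow(events) > 0) {
    asi <- extract_asi(rec, events, membership,
                       pre = config$asi_pre, len = config$asi_len)
    out$asi <- asi
    if (length(unique(asi$pattern)) >= 2) {
      win <- try(align_baseline(asi, window = config$critical_window),
                 silent = TRUE)
      if (!inherits(win, "try-error")) {
        out$window <- win
        out$anova <- rm_anova(win)
        out$onsets <- activation_onset_summary(out$anova)
      }
    }
  }
  class(out) <- "ca_run"
  out
}

#' @export
print.ca_run <- function(x, ...) {
  cat(sprintf("<ca_run> variant %s (%s scale), seed %d\n",
              x$config$variant, x$config$scale, x$config$seed))
  cat(sprintf("  ignition events: %d over %d CAs\n",
              nrow(x$events), length(unique(x$events$pattern))))
  if (!is.null(x$onsets)) {
    on <- x$onsets
    cat(sprintf("  first significant step: central %s, secondary %s, primary %s\n",
                format(on$first_step[1]), format(on$first_step[2]),
                format(on$first_step[3])))
  }
  invisible(x)
}

#' Summarise a run
#'
#' @param object A `ca_run`.
#' @param ... Unused.
#' @return A one-row tibble: seed, variant, number of events, number of
#'   igniting CAs and the first significant steps per centrality level.
#' @export
summary.ca_run <- function(object, ...) {
  on <- object$onsets
  tibble::tibble(
    variant = object$config$variant,
    seed = object$config$seed,
    n_events = nrow(object$events),
    n_cas_ignited = length(unique(object$events$pattern)),
    first_step_central = if (is.null(on)) NA_integer_ else on$first_step[on$level == "central"],
    first_step_secondary = if (is.null(on)) NA_integer_ else on$first_step[on$level == "secondary"],
    first_step_primary = if (is.null(on)) NA_integer_ else on$first_step[on$level == "primary"]
  )
}
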