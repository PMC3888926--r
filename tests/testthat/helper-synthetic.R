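# Small synthetic fixtures shared across tests.  Everything is generated in
# code; nothing is read from disk.

tiny_net <- function(variant = "full", grid = c(6, 6), seed = 1,
                     config = network_config()) {
  build_network(variant, grid = grid, config = config, seed = seed)
}

# A recording matrix with prescribed active cells: `active` is a list, one
# element per step, of global cell indices set to `level` (others 0).
synthetic_recording <- function(net, active, level = 1) {
  rec <- matrix(0, nrow = length(active), ncol = net$n_e)
  for (t in seq_along(active)) {
    if (length(active[[t]]) > 0) rec[t, active[[t]]] <- level
  }
  hebbca:::new_ca_recording(rec, net)
}

# A membership object built directly from a member table (one threshold per
# pattern/area as in identify_ca_cells()).
synthetic_membership <- function(net, members, theta = 0.5) {
  # members: tibble(pattern, area, cell)
  members$response <- 1
  members$theta <- theta
  thr <- tidyr::expand_grid(pattern = unique(members$pattern),
                            area = net$areas$area)
  thr$theta <- theta
  structure(members,
            thresholds = thr, gamma = NA_real_,
            areas = net$areas, n_cells = net$n_cells,
            class = c("ca_membership", class(tibble::tibble())))
}

# Literal per-step, per-CA brute-force ignition detector used as an
# independent oracle for detect_ignitions().
oracle_detect <- function(recording, membership) {
  m <- hebbca:::membership_global(membership)
  out <- list()
  for (w in sort(unique(m$pattern))) {
    mw <- m[m$pattern == w, ]
    active <- logical(nrow(recording))
    for (t in seq_len(nrow(recording))) {
      n_on <- 0
      for (r in seq_len(nrow(mw))) {
        if (recording[t, mw$global[r]] >= mw$theta[r]) n_on <- n_on + 1
      }
      active[t] <- n_on >= 0.5 * nrow(mw)
    }
    t <- 1
    while (t <= length(active)) {
      if (active[t]) {
        s <- t
        while (t < length(active) && active[t + 1]) t <- t + 1
        out[[length(out) + 1]] <- tibble::tibble(pattern = w, onset = s,
                                                 offset = t)
        t <- t + 1
      } else t <- t + 1
    }
  }
  dplyr::bind_rows(out)
}

# Independent RM-ANOVA oracle built on stats::aov with an Error() stratum,
# plus one-sample / paired t-tests for the planned comparisons.
oracle_rm_anova <- function(ds) {
  ds$subject <- factor(ds$pattern)
  ds$C <- factor(ds$centrality, levels = c("primary", "secondary", "central"))
  ds$Fr <- factor(ds$frontality, levels = c("posterior", "anterior"))
  fit <- stats::aov(value ~ C * Fr + Error(subject / (C * Fr)), data = ds)
  s <- summary(fit)
  pick <- function(stratum, row) {
    tab <- s[[stratum]][[1]]
    idx <- grep(row, rownames(tab))
    c(F = tab[idx, "F value"], p = tab[idx, "Pr(>F)"])
  }
  list(
    centrality = pick("Error: subject:C", "^C"),
    frontality = pick("Error: subject:Fr", "^Fr"),
    interaction = pick("Error: subject:C:Fr", "C:Fr")
  )
}
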