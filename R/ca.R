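#' Identify cell-assembly membership from a probe profile
#'
#' For each pattern `w` and area `A`, the area- and pattern-specific
#' threshold is `theta_w(A) = gamma * max` over `A` of the average response
#' to `w`; a cell belongs to the CA for `w` in `A` iff its average response
#' is at least `theta_w(A)`.  The analysis default is `gamma = 0.5`.
#'
#' @param profile A `ca_profile` from [probe_responses()].
#' @param gamma Fraction of the per-area maximal response in `[0, 1]`.
#' @return An object of class `ca_membership`: a tibble with columns
#'   `pattern`, `area`, `cell` (within-area index), `response` and `theta`;
#'   the full per-pattern, per-area threshold table is attached as attribute
#'   `thresholds`.  Patterns whose profile is all zero in an area yield an
#'   empty membership there (flagged via a zero threshold).
#' @examples
#' \donttest{
#' # membership <- identify_ca_cells(profile, gamma = 0.5)
#' }
#' @export
identify_ca_cells <- function(profile, gamma = 0.5) {
  stopifnot(inherits(profile, "ca_profile"), gamma >= 0, gamma <= 1)
  areas <- attr(profile, "areas")
  n_cells <- attr(profile, "n_cells")
  n_pat <- ncol(profile)
  rows <- list()
  thr <- list()
  for (w in seq_len(n_pat)) {
    for (a in seq_len(nrow(areas))) {
      idx <- (a - 1L) * n_cells + seq_len(n_cells)
      resp <- profile[idx, w]
      mx <- max(resp)
      theta <- gamma * mx
      if (mx <= 0) {
        warning(sprintf("pattern %d has an all-zero profile in area %s: empty CA",
                        w, areas$area[a]))
        members <- integer(0)
      } else {
        members <- which(resp >= theta)
      }
      thr[[length(thr) + 1]] <- tibble::tibble(
        pattern = w, area = areas$area[a], theta = theta
      )
      if (length(members) > 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          pattern = w, area = areas$area[a],
          cell = as.integer(members),
          response = resp[members], theta = theta
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(pattern = integer(0), area = character(0),
                          cell = integer(0), response = numeric(0),
                          theta = numeric(0))
  }
  structure(out,
            thresholds = dplyr::bind_rows(thr),
            gamma = gamma, areas = areas, n_cells = n_cells,
            class = c("ca_membership", class(tibble::tibble())))
}

#' Per-area mean CA size across gamma values
#'
#' Mean number of member cells per area, averaged over patterns, for each
#' membership fraction `gamma` — used to control for scaling effects of
#' unequal CA-cell counts across areas.
#'
#' @param profile A `ca_profile`.
#' @param gammas Gamma values (default the analysis grid
#'   `c(.01, .02, .04, .05, .1, .2, .4, .5)`).
#' @return A tibble with columns `gamma`, `area`, `centrality`, `mean_size`.
#' @export
ca_size_table <- function(profile,
                          gammas = c(0.01, 0.02, 0.04, 0.05, 0.1, 0.2, 0.4, 0.5)) {
  stopifnot(inherits(profile, "ca_profile"))
  areas <- attr(profile, "areas")
  purrr::map_dfr(gammas, function(g) {
    m <- suppressWarnings(identify_ca_cells(profile, g))
    counts <- dplyr::count(tibble::as_tibble(m), .data$pattern, .data$area)
    full <- tidyr::complete(counts,
                            pattern = seq_len(ncol(profile)),
                            area = areas$area,
                            fill = list(n = 0L))
    sizes <- dplyr::summarise(dplyr::group_by(full, .data$area),
                              mean_size = mean(.data$n), .groups = "drop")
    sizes$gamma <- g
    sizes
  }) |>
    dplyr::left_join(areas[, c("area", "centrality")], by = "area") |>
    dplyr::arrange(.data$gamma, match(.data$area, AREA_NAMES)) |>
    dplyr::select("gamma", "area", "centrality", "mean_size")
}

membership_global <- function(membership) {
  areas <- attr(membership, "areas")
  n_cells <- attr(membership, "n_cells")
  m <- tibble::as_tibble(membership)
  m$global <- (match(m$area, areas$area) - 1L) * n_cells + m$cell
  m
}

#' Detect spontaneous ignition events
#'
#' A CA is active at a step iff at least half of its member cells (union
#' over all six areas) have output at or above their area- and
#' pattern-specific threshold `theta_w(A)`.  Events are maximal runs of
#' active steps; runs separated by at most `min_gap` inactive steps are
#' merged.
#'
#' @param recording A `ca_recording` (steps x cells output matrix) from a
#'   stimulus-free, noise-driven run.
#' @param membership A `ca_membership`.
#' @param min_gap Merge gap in steps (default 0: strict maximal runs).
#' @return A tibble of class `ca_events` with columns `pattern`, `onset`,
#'   `offset` (step indices, inclusive) and `peak_fraction`.
#' @export
detect_ignitions <- function(recording, membership, min_gap = 0) {
  stopifnot(inherits(recording, "ca_recording"), min_gap >= 0)
  m <- membership_global(membership)
  pats <- sort(unique(m$pattern))
  out <- purrr::map_dfr(pats, function(w) {
    mw <- m[m$pattern == w, ]
    if (nrow(mw) == 0) return(NULL)
    sub <- recording[, mw$global, drop = FALSE]
    frac <- rowMeans(sweep(sub, 2, mw$theta, ">=") * 1)
    active <- frac >= 0.5
    ev <- runs_from_logical(active, min_gap)
    if (nrow(ev) == 0) return(NULL)
    ev$peak_fraction <- vapply(seq_len(nrow(ev)), function(i) {
      max(frac[ev$onset[i]:ev$offset[i]])
    }, numeric(1))
    ev$pattern <- w
    ev[, c("pattern", "onset", "offset", "peak_fraction")]
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(pattern = integer(0), onset = integer(0),
                          offset = integer(0), peak_fraction = numeric(0))
  }
  structure(out, class = c("ca_events", class(tibble::tibble())))
}

# maximal runs of TRUE, merging runs separated by <= min_gap FALSE steps
runs_from_logical <- function(active, min_gap = 0) {
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  if (length(on) == 0) {
    return(tibble::tibble(onset = integer(0), offset = integer(0)))
  }
  onset <- starts[on]
  offset <- ends[on]
  if (min_gap > 0 && length(onset) > 1) {
    keep_on <- onset[1]; res_on <- integer(0); res_off <- integer(0)
    cur_off <- offset[1]
    for (i in seq_along(onset)[-1]) {
      if (onset[i] - cur_off - 1L <= min_gap) {
        cur_off <- offset[i]
      } else {
        res_on <- c(res_on, keep_on); res_off <- c(res_off, cur_off)
        keep_on <- onset[i]; cur_off <- offset[i]
      }
    }
    res_on <- c(res_on, keep_on); res_off <- c(res_off, cur_off)
    onset <- res_on; offset <- res_off
  }
  tibble::tibble(onset = as.integer(onset), offset = as.integer(offset))
}

#' Extract average spontaneous ignition (ASI) traces
#'
#' For each CA and area, averages over all its detected ignition events
#' ("trials") the per-step count of member cells with output at or above the
#' area threshold, in a window of `len` steps starting `pre` steps before
#' event onset.  Events whose window does not fit inside the recording are
#' dropped; CAs with no usable trial are excluded.  The normalised trace
#' divides each count by the CA's size in that area, giving the fraction of
#' active CA cells in `[0, 1]`.
#'
#' @param recording A `ca_recording`.
#' @param events A `ca_events` table from [detect_ignitions()].
#' @param membership A `ca_membership`.
#' @param pre Steps before onset (default 10).
#' @param len Trial length in steps (default 40).
#' @return A tibble of class `ca_asi` with columns `pattern`, `area`,
#'   `step` (relative to onset: `-pre` .. `len - pre - 1`), `count`, `norm`
#'   and `n_trials`.
#' @export
extract_asi <- function(recording, events, membership, pre = 10, len = 40) {
  stopifnot(inherits(recording, "ca_recording"), len > pre)
  m <- membership_global(membership)
  areas <- attr(membership, "areas")
  out <- purrr::map_dfr(sort(unique(events$pattern)), function(w) {
    ev <- events[events$pattern == w, ]
    ok <- ev$onset - pre >= 1 & ev$onset + (len - pre - 1) <= nrow(recording)
    ev <- ev[ok, ]
    if (nrow(ev) == 0) return(NULL)
    mw <- m[m$pattern == w, ]
    purrr::map_dfr(areas$area, function(a) {
      ma <- mw[mw$area == a, ]
      size <- nrow(ma)
      counts <- matrix(0, nrow = nrow(ev), ncol = len)
      if (size > 0) {
        above <- sweep(recording[, ma$global, drop = FALSE], 2, ma$theta, ">=")
        for (i in seq_len(nrow(ev))) {
          win <- (ev$onset[i] - pre):(ev$onset[i] + len - pre - 1)
          counts[i, ] <- rowSums(above[win, , drop = FALSE])
        }
      }
      mean_count <- colMeans(counts)
      tibble::tibble(
        pattern = w, area = a, step = seq_len(len) - pre - 1L,
        count = mean_count,
        norm = if (size > 0) mean_count / size else 0,
        n_trials = nrow(ev)
      )
    })
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(pattern = integer(0), area = character(0),
                          step = integer(0), count = numeric(0),
                          norm = numeric(0), n_trials = integer(0))
  }
  structure(out, pre = as.integer(pre), len = as.integer(len),
            areas = areas,
            class = c("ca_asi", class(tibble::tibble())))
}

#' Align ASI traces at the pre-ignition baseline
#'
#' Sets the critical-window origin (time 0) to the last pre-onset step at
#' which the average number of active CA cells is still zero in all areas
#' (for every CA), and returns the following `window` steps of the
#' normalised traces for the per-time-step ANOVA.
#'
#' @param asi A `ca_asi` tibble from [extract_asi()].
#' @param window Critical-window length in steps (default 6).
#' @param tol Counts at or below `tol` count as baseline (default 0).
#' @return A tibble of class `ca_window` with columns `pattern`, `area`,
#'   `centrality`, `frontality`, `step` (0-based within the window) and
#'   `value` (normalised ASI); the origin (in onset-relative steps) is kept
#'   as attribute `origin`.
#' @export
align_baseline <- function(asi, window = 6, tol = 0) {
  stopifnot(inherits(asi, "ca_asi"))
  pre <- attr(asi, "pre")
  areas <- attr(asi, "areas")
  pre_steps <- sort(unique(asi$step[asi$step < 0]))
  zero_at <- vapply(pre_steps, function(s) {
    all(asi$count[asi$step == s] <= tol)
  }, logical(1))
  if (!any(zero_at)) {
    stop("no all-baseline step found in the pre-onset segment; ",
         "cannot place the critical-window origin")
  }
  origin <- max(pre_steps[zero_at])
  steps <- origin + seq_len(window) - 1L  # origin is step 0
  out <- asi[asi$step %in% steps, c("pattern", "area", "step", "norm")]
  out$step <- out$step - origin
  names(out)[names(out) == "norm"] <- "value"
  out <- dplyr::left_join(out, areas[, c("area", "centrality", "frontality")],
                          by = "area")
  out <- out[, c("pattern", "area", "centrality", "frontality", "step", "value")]
  structure(out, origin = origin, window = as.integer(window),
            class = c("ca_window", class(tibble::tibble())))
}
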