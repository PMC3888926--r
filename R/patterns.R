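#' Generate the sensorimotor pattern pairs
#'
#' Builds the to-be-learnt pattern set: each pattern pair identifies
#' `cells_per_pattern` cells in the primary perceptual area (P1) and the same
#' number in the primary motor area (M1).  Patterns overlap to a degree:
#' each pattern shares exactly `overlap_cells` cells (per area) with its
#' ring-neighbouring pattern and none with any other, mirroring the partial
#' overlap between motor and perceptual features of real action schemata.
#' At the reference scale (12 patterns of 20 cells on a 25 x 25 grid) one
#' pattern covers 3.2% of an area.
#'
#' @param n_patterns Number of pattern pairs (default 12).
#' @param cells_per_pattern Cells per pattern and area (default 20).
#' @param overlap_cells Cells shared (per area) with the ring-neighbouring
#'   pattern; must satisfy `2 * overlap_cells <= cells_per_pattern`.
#' @param grid Per-area grid `c(rows, cols)`.
#' @param layout `"clustered"` (default): each pattern is a compact blob of
#'   cells around its own tile centre, with the shared cells sitting on the
#'   boundary between ring-neighbouring blobs — this preserves the
#'   topographic separation of patterns on small grids.  `"random"`: cells
#'   are drawn uniformly over the grid.
#' @param seed Optional integer seed.
#'
#' @return A tibble of class `ca_patterns` with columns `pattern` (1-based
#'   id), `area` (`"P1"` or `"M1"`) and `cell` (within-area index).
#' @examples
#' pats <- generate_pattern_pairs(4, 10, overlap_cells = 2, grid = c(12, 12),
#'                                seed = 1)
#' table(pats$pattern, pats$area)
#' @export
generate_pattern_pairs <- function(n_patterns = 12, cells_per_pattern = 20,
                                   overlap_cells = 4, grid = c(25, 25),
                                   layout = c("clustered", "random"),
                                   seed = NULL) {
  stopifnot(n_patterns >= 1, cells_per_pattern >= 1, overlap_cells >= 0)
  layout <- match.arg(layout)
  if (!is.null(seed)) set.seed(seed)
  N <- grid[1] * grid[2]
  v <- overlap_cells
  c_ <- cells_per_pattern
  if (n_patterns == 1 || v == 0) {
    needed <- n_patterns * c_
  } else if (n_patterns == 2) {
    needed <- 2L * c_ - v
  } else {
    if (2 * v > c_) stop("overlap_cells too large: each pattern shares ",
                         "cells with two ring neighbours")
    needed <- n_patterns * (c_ - v)
  }
  if (needed > N) {
    stop(sprintf("infeasible: %d patterns of %d cells (overlap %d) need %d of %d cells",
                 n_patterns, c_, v, needed, N))
  }

  clustered_area <- function() {
    rows <- grid[1]; cols <- grid[2]
    # near-square tiling of the grid, tiles visited in snake order so that
    # ring-neighbouring patterns sit in adjacent tiles
    best <- NULL
    for (tr in seq_len(n_patterns)) {
      tc <- ceiling(n_patterns / tr)
      score <- c(tr * tc - n_patterns, abs(tr / tc - rows / cols))
      if (is.null(best) || score[1] < best$score[1] ||
          (score[1] == best$score[1] && score[2] < best$score[2])) {
        best <- list(tr = tr, tc = tc, score = score)
      }
    }
    rc <- (seq_len(best$tr) - 0.5) * rows / best$tr
    cc <- (seq_len(best$tc) - 0.5) * cols / best$tc
    centers <- list()
    for (j in seq_len(best$tc)) {
      rs <- if (j %% 2 == 1) seq_len(best$tr) else rev(seq_len(best$tr))
      for (i in rs) centers[[length(centers) + 1]] <- c(rc[i], cc[j])
    }
    centers <- centers[seq_len(n_patterns)]
    cell_r <- rep(seq_len(rows), times = cols)
    cell_c <- rep(seq_len(cols), each = rows)
    taken <- logical(N)
    jitter <- runif(N) * 1e-3  # random tie-breaks, deterministic under seed
    grab <- function(pt, m) {
      d <- (cell_r - pt[1])^2 + (cell_c - pt[2])^2 + jitter
      d[taken] <- Inf
      idx <- order(d)[seq_len(m)]
      taken[idx] <<- TRUE
      idx
    }
    if (n_patterns == 1 || v == 0) {
      lapply(centers, grab, m = c_)
    } else if (n_patterns == 2) {
      u <- lapply(centers, grab, m = c_ - v)
      s <- grab((centers[[1]] + centers[[2]]) / 2, v)
      list(c(u[[1]], s), c(u[[2]], s))
    } else {
      # unique blob per pattern plus shared blocks on the tile boundaries
      u <- lapply(centers, grab, m = c_ - 2L * v)
      s <- lapply(seq_len(n_patterns), function(k) {
        nxt <- if (k == n_patterns) 1L else k + 1L
        grab((centers[[k]] + centers[[nxt]]) / 2, v)
      })
      lapply(seq_len(n_patterns), function(k) {
        prev <- if (k == 1L) n_patterns else k - 1L
        c(u[[k]], s[[prev]], s[[k]])
      })
    }
  }

  one_area <- function() {
    if (layout == "clustered") return(clustered_area())
    pool <- sample.int(N, needed)
    if (n_patterns == 1 || v == 0) {
      split(pool, rep(seq_len(n_patterns), each = c_))
    } else if (n_patterns == 2) {
      shared <- pool[seq_len(v)]
      rest <- pool[-seq_len(v)]
      u <- c_ - v
      list(c(shared, rest[seq_len(u)]), c(shared, rest[u + seq_len(u)]))
    } else {
      # shared blocks S_k (between pattern k and k+1, ring) and unique blocks
      shared <- split(pool[seq_len(n_patterns * v)],
                      rep(seq_len(n_patterns), each = v))
      uniq <- split(pool[-seq_len(n_patterns * v)],
                    rep(seq_len(n_patterns), each = c_ - 2 * v))
      lapply(seq_len(n_patterns), function(k) {
        prev <- if (k == 1) n_patterns else k - 1
        c(uniq[[k]], shared[[prev]], shared[[k]])
      })
    }
  }

  p1 <- one_area()
  m1 <- one_area()
  one_tbl <- function(sets, area) {
    purrr::map_dfr(seq_along(sets), function(k) {
      tibble::tibble(pattern = k, area = area,
                     cell = as.integer(sort(sets[[k]])))
    })
  }
  out <- dplyr::bind_rows(one_tbl(p1, "P1"), one_tbl(m1, "M1"))
  out <- dplyr::arrange(out, .data$pattern, dplyr::desc(.data$area), .data$cell)
  class(out) <- c("ca_patterns", class(out))
  attr(out, "grid") <- as.integer(grid)
  attr(out, "n_patterns") <- as.integer(n_patterns)
  out
}

#' Global stimulus indices of each pattern
#'
#' @param net A `ca_network`.
#' @param patterns A `ca_patterns` tibble.
#' @return List (one per pattern id) of global excitatory cell indices.
#' @keywords internal
pattern_global_cells <- function(net, patterns) {
  n_pat <- attr(patterns, "n_patterns") %||% max(patterns$pattern)
  lapply(seq_len(n_pat), function(k) {
    rows <- patterns[patterns$pattern == k, ]
    unname(unlist(lapply(unique(rows$area), function(a) {
      global_cells(net, a, rows$cell[rows$area == a])
    })))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
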