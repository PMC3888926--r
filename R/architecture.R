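#' Specification table of the six model areas
#'
#' Returns one row per area with its centrality level (`primary` = P1, M1;
#' `secondary` = HP, PM; `central` = PA, PF), frontality level (`posterior` =
#' P1, HP, PA; `anterior` = M1, PM, PF) and grid size.
#'
#' @param grid Integer vector `c(rows, cols)` of the per-area excitatory (and
#'   inhibitory) cell grid; default `c(25, 25)`.
#' @return A tibble with columns `area`, `centrality`, `frontality`, `rows`,
#'   `cols`, `n_cells`.
#' @examples
#' area_specs()
#' @export
area_specs <- function(grid = c(25, 25)) {
  stopifnot(length(grid) == 2, all(grid >= 1))
  tibble::tibble(
    area = AREA_NAMES,
    centrality = unname(CENTRALITY[AREA_NAMES]),
    frontality = unname(FRONTALITY[AREA_NAMES]),
    rows = as.integer(grid[1]),
    cols = as.integer(grid[2]),
    n_cells = as.integer(grid[1] * grid[2])
  )
}

#' Between-area adjacency of the six-area architecture
#'
#' The `full` variant links next neighbours along the chain
#' P1-HP-PA-PF-PM-M1 and adds the four "jumping" links between second-next
#' neighbours (P1-PA, HP-PF, PA-PM, PF-M1), giving between-area partner
#' counts of 4 (central), 3 (secondary) and 2 (primary).  The `serial`
#' variant keeps only the chain (2:2:1).  All links are reciprocal.
#'
#' @param variant `"full"` or `"serial"`.
#' @return A tibble of undirected edges with columns `from`, `to`,
#'   `jumping` (logical).
#' @examples
#' network_adjacency("serial")
#' @export
network_adjacency <- function(variant = c("full", "serial")) {
  variant <- match.arg(variant)
  chain <- tibble::tibble(
    from = c("P1", "HP", "PA", "PF", "PM"),
    to   = c("HP", "PA", "PF", "PM", "M1"),
    jumping = FALSE
  )
  jump <- tibble::tibble(
    from = c("P1", "HP", "PA", "PF"),
    to   = c("PA", "PF", "PM", "M1"),
    jumping = TRUE
  )
  if (variant == "full") dplyr::bind_rows(chain, jump) else chain
}

#' Sample one sparse topographic projection
#'
#' Draws a random, sparse, patchy, topographic projection between two
#' equally sized cell grids.  A source cell at grid position (r, c) maps to
#' the target position (r, c); a candidate edge to any target cell within the
#' square `n x n` neighbourhood centred there is created independently with
#' probability `p0 * exp(-d^2 / (2 * sigma^2))`, where `d` is the Euclidean
#' grid distance.  The probability is exactly zero outside the
#' neighbourhood.  Neighbourhoods are clipped (not wrapped) at grid borders.
#' Realised weights are drawn uniformly from `]0, 0.1]`.
#'
#' @param grid `c(rows, cols)` of both grids.
#' @param n Odd neighbourhood side length (19 for excitatory, 5 for
#'   inhibitory projections).
#' @param sigma Gaussian fall-off scale in cell units (> 0).
#' @param p0 Peak (distance-0) connection probability in `]0, 1]`.
#' @param exclude_self Drop the distance-0 self pair (used for within-area
#'   excitatory projections, where source and target are the same layer).
#'
#' @return A tibble with columns `src`, `tgt` (within-grid cell indices,
#'   column-major) and `w` (initial weight).
#' @examples
#' set.seed(1)
#' pr <- make_projection(grid = c(8, 8), n = 5, sigma = 1.25, p0 = 0.5)
#' @export
make_projection <- function(grid, n, sigma, p0, exclude_self = FALSE) {
  stopifnot(length(grid) == 2, n >= 1, n %% 2 == 1, sigma > 0,
            p0 > 0, p0 <= 1)
  rows <- grid[1]; cols <- grid[2]
  h <- (n - 1L) %/% 2L
  rr <- rep(seq_len(rows), times = cols)
  cc <- rep(seq_len(cols), each = rows)
  src_all <- seq_len(rows * cols)

  out_src <- integer(0); out_tgt <- integer(0); out_w <- numeric(0)
  # deterministic offset order so edge lists are reproducible under a seed
  for (dr in -h:h) {
    for (dc in -h:h) {
      if (exclude_self && dr == 0L && dc == 0L) next
      tr <- rr + dr; tc <- cc + dc
      ok <- tr >= 1L & tr <= rows & tc >= 1L & tc <= cols
      if (!any(ok)) next
      p <- p0 * exp(-(dr^2 + dc^2) / (2 * sigma^2))
      src <- src_all[ok]
      keep <- runif(length(src)) < p
      m <- sum(keep)
      if (m == 0L) next
      src <- src[keep]
      tgt <- (tc[ok][keep] - 1L) * rows + tr[ok][keep]
      out_src <- c(out_src, src)
      out_tgt <- c(out_tgt, tgt)
      out_w <- c(out_w, 0.1 * (1 - runif(m)))  # uniform on ]0, 0.1]
    }
  }
  tibble::tibble(src = out_src, tgt = out_tgt, w = out_w)
}

#' Default structural configuration of the network
#'
#' Connection-probability and neighbourhood parameters of the sparse
#' topographic wiring.  Excitatory projections use a 19 x 19 neighbourhood,
#' projections onto inhibitory cells a 5 x 5 neighbourhood; the Gaussian
#' fall-off scale defaults to a quarter of the neighbourhood side.
#'
#' @param n_within,n_between,n_inh Neighbourhood side lengths (odd) of
#'   within-area excitatory, between-area excitatory and excitatory ->
#'   inhibitory projections.
#' @param sigma_within,sigma_between,sigma_inh Gaussian fall-off scales
#'   (cell units); default a quarter of the neighbourhood side.
#' @param p0_within Peak probability of within-area excitatory links.
#' @param p0_between Peak probability of between-area excitatory links.
#' @param p0_inh Peak probability of excitatory -> inhibitory links.
#' @return A named list of class `network_config`.
#' @export
network_config <- function(n_within = 19, n_between = 19, n_inh = 5,
                           sigma_within = n_within / 4,
                           sigma_between = n_between / 4,
                           sigma_inh = n_inh / 4,
                           p0_within = 0.3, p0_between = 0.3,
                           p0_inh = 0.6) {
  stopifnot(n_within %% 2 == 1, n_between %% 2 == 1, n_inh %% 2 == 1,
            sigma_within > 0, sigma_between > 0, sigma_inh > 0,
            p0_within > 0, p0_within <= 1,
            p0_between > 0, p0_between <= 1,
            p0_inh > 0, p0_inh <= 1)
  structure(
    list(n_within = as.integer(n_within), n_between = as.integer(n_between),
         n_inh = as.integer(n_inh),
         sigma_within = sigma_within, sigma_between = sigma_between,
         sigma_inh = sigma_inh,
         p0_within = p0_within, p0_between = p0_between, p0_inh = p0_inh),
    class = "network_config"
  )
}

#' Build the six-area network
#'
#' Constructs the full set of sparse projections: within each area,
#' excitatory-to-excitatory links in a 19 x 19 neighbourhood; each
#' excitatory cell drives the inhibitory cell layer within a 5 x 5
#' neighbourhood, and every inhibitory cell feeds back negatively onto the
#' excitatory cell at its own grid position (gain `g_inh` of
#' [dynamics_params()]); between-area excitatory links follow the
#' [network_adjacency()] of the chosen variant and are topographic.  All
#' sparsity draws are independent per direction.
#'
#' @param variant `"full"` (chain plus jumping links) or `"serial"` (chain
#'   only).
#' @param grid Per-area grid size `c(rows, cols)`.
#' @param config A [network_config()].
#' @param seed Optional integer seed (set before sampling); if `NULL` the
#'   current RNG state is used.
#'
#' @return An object of class `ca_network`: a list with the area table,
#'   variant, sparse weight matrices `W_ee` (excitatory -> excitatory,
#'   rows = presynaptic, columns = postsynaptic, over all
#'   `6 * rows * cols` excitatory cells) and `W_ei` (excitatory ->
#'   inhibitory), and the structural config.
#' @examples
#' net <- build_network("full", grid = c(6, 6), seed = 1)
#' net$areas
#' @export
build_network <- function(variant = c("full", "serial"),
                          grid = c(25, 25),
                          config = network_config(),
                          seed = NULL) {
  variant <- match.arg(variant)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(config, "network_config"))
  areas <- area_specs(grid)
  n_cells <- areas$n_cells[1]
  n_areas <- nrow(areas)
  n_e <- n_cells * n_areas

  src <- integer(0); tgt <- integer(0); w <- numeric(0)
  # within-area excitatory recurrence
  for (a in seq_len(n_areas)) {
    pr <- make_projection(grid, config$n_within, config$sigma_within,
                          config$p0_within, exclude_self = TRUE)
    off <- (a - 1L) * n_cells
    src <- c(src, pr$src + off); tgt <- c(tgt, pr$tgt + off); w <- c(w, pr$w)
  }
  # between-area links, sampled independently per direction
  adj <- network_adjacency(variant)
  aidx <- setNames(seq_len(n_areas), areas$area)
  for (k in seq_len(nrow(adj))) {
    for (dir in 1:2) {
      from <- if (dir == 1) adj$from[k] else adj$to[k]
      to <- if (dir == 1) adj$to[k] else adj$from[k]
      pr <- make_projection(grid, config$n_between, config$sigma_between,
                            config$p0_between, exclude_self = FALSE)
      src <- c(src, pr$src + (aidx[[from]] - 1L) * n_cells)
      tgt <- c(tgt, pr$tgt + (aidx[[to]] - 1L) * n_cells)
      w <- c(w, pr$w)
    }
  }
  W_ee <- Matrix::sparseMatrix(i = src, j = tgt, x = w, dims = c(n_e, n_e))

  # excitatory -> inhibitory input (5 x 5), same cell indexing in the
  # inhibitory layer
  src <- integer(0); tgt <- integer(0); w <- numeric(0)
  for (a in seq_len(n_areas)) {
    pr <- make_projection(grid, config$n_inh, config$sigma_inh,
                          config$p0_inh, exclude_self = FALSE)
    off <- (a - 1L) * n_cells
    src <- c(src, pr$src + off); tgt <- c(tgt, pr$tgt + off); w <- c(w, pr$w)
  }
  W_ei <- Matrix::sparseMatrix(i = src, j = tgt, x = w, dims = c(n_e, n_e))

  structure(
    list(areas = areas, variant = variant, grid = as.integer(grid),
         n_cells = n_cells, n_areas = n_areas, n_e = n_e,
         W_ee = W_ee, W_ei = W_ei, config = config),
    class = "ca_network"
  )
}

#' @export
print.ca_network <- function(x, ...) {
  cat(sprintf(
    "<ca_network> %s variant, %d areas of %d x %d cells (%d excitatory)\n",
    x$variant, x$n_areas, x$grid[1], x$grid[2], x$n_e
  ))
  cat(sprintf("  exc->exc links: %d; exc->inh links: %d\n",
              length(x$W_ee@x), length(x$W_ei@x)))
  invisible(x)
}

#' Map cells to areas
#'
#' @param net A `ca_network`.
#' @return Integer vector: area index (1..6) of each global excitatory cell.
#' @keywords internal
cell_area <- function(net) {
  rep(seq_len(net$n_areas), each = net$n_cells)
}

#' Global cell indices of a set of within-area cells
#'
#' @param net A `ca_network`.
#' @param area Area name (e.g. `"P1"`).
#' @param cells Within-area (column-major) cell indices.
#' @return Global excitatory-cell indices.
#' @export
global_cells <- function(net, area, cells) {
  a <- match(area, net$areas$area)
  if (is.na(a)) stop("unknown area: ", area)
  stopifnot(all(cells >= 1), all(cells <= net$n_cells))
  (a - 1L) * net$n_cells + as.integer(cells)
}

#' Audit the between-area wiring of a network
#'
#' Summarises, per area, the number of between-area partner areas and the
#' per-cell mean in/out between-area link counts.  In the full variant the
#' partner counts are 4:3:2 for central:secondary:primary areas; in the
#' serial variant 2:2:1.
#'
#' @param net A `ca_network`.
#' @return A tibble with one row per area: `area`, `centrality`,
#'   `frontality`, `n_partners`, `between_in`, `between_out`,
#'   `mean_in_per_cell`, `mean_out_per_cell`.
#' @examples
#' audit_graph(build_network("serial", grid = c(5, 5), seed = 1))
#' @export
audit_graph <- function(net) {
  stopifnot(inherits(net, "ca_network"))
  W <- net$W_ee
  tr <- Matrix::summary(W)
  a_src <- (tr$i - 1L) %/% net$n_cells + 1L
  a_tgt <- (tr$j - 1L) %/% net$n_cells + 1L
  between <- a_src != a_tgt
  partners <- lapply(seq_len(net$n_areas), function(a) {
    union(unique(a_tgt[between & a_src == a]), unique(a_src[between & a_tgt == a]))
  })
  tibble::tibble(
    area = net$areas$area,
    centrality = net$areas$centrality,
    frontality = net$areas$frontality,
    n_partners = vapply(partners, length, integer(1)),
    between_in = vapply(seq_len(net$n_areas),
                        function(a) sum(between & a_tgt == a), integer(1)),
    between_out = vapply(seq_len(net$n_areas),
                         function(a) sum(between & a_src == a), integer(1)),
    mean_in_per_cell = between_in / net$n_cells,
    mean_out_per_cell = between_out / net$n_cells
  )
}
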