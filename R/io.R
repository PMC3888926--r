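#' Export the excitatory edge list as TSV
#'
#' Columns: source area, source row/col, target area, target row/col,
#' weight.
#'
#' @param net A `ca_network`.
#' @param path Output file.
#' @return The exported tibble, invisibly.
#' @export
write_edge_list <- function(net, path) {
  tr <- Matrix::summary(net$W_ee)
  rows <- net$grid[1]
  coord <- function(g) {
    within <- (g - 1L) %% net$n_cells
    list(area = net$areas$area[(g - 1L) %/% net$n_cells + 1L],
         row = within %% rows + 1L, col = within %/% rows + 1L)
  }
  s <- coord(tr$i); t <- coord(tr$j)
  d <- tibble::tibble(
    source_area = s$area, source_row = s$row, source_col = s$col,
    target_area = t$area, target_row = t$row, target_col = t$col,
    weight = tr$x
  )
  readr::write_tsv(d, path)
  invisible(d)
}

#' Export ignition events as CSV
#'
#' @param events A `ca_events` tibble.
#' @param path Output file.
#' @export
write_events_csv <- function(events, path) {
  readr::write_csv(tibble::as_tibble(events), path)
  invisible(events)
}

#' Write / read pattern pairs as JSON
#'
#' Patterns are serialised as a list of `{pattern, area, cells}` records.
#'
#' @param patterns A `ca_patterns` tibble.
#' @param path File path.
#' @export
write_patterns_json <- function(patterns, path) {
  recs <- dplyr::group_by(tibble::as_tibble(patterns),
                          .data$pattern, .data$area)
  recs <- dplyr::summarise(recs, cells = list(.data$cell), .groups = "drop")
  jsonlite::write_json(
    list(grid = attr(patterns, "grid"), patterns = recs),
    path, auto_unbox = TRUE
  )
  invisible(patterns)
}

#' @rdname write_patterns_json
#' @export
read_patterns_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- tidyr::unnest(tibble::as_tibble(x$patterns), "cells")
  out <- tibble::tibble(pattern = as.integer(d$pattern), area = d$area,
                        cell = as.integer(d$cells))
  class(out) <- c("ca_patterns", class(out))
  attr(out, "grid") <- as.integer(x$grid)
  attr(out, "n_patterns") <- max(out$pattern)
  out
}

#' Write / read an experiment configuration as YAML
#'
#' @param config A [experiment_config()].
#' @param path File path.
#' @export
write_config_yaml <- function(config, path) {
  plain <- lapply(unclass(config), function(x) {
    if (is.list(x)) unclass(x) else x
  })
  yaml::write_yaml(plain, path)
  invisible(config)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  args <- x[setdiff(names(x), c("dynamics", "plasticity", "network",
                                "variant", "scale", "seed"))]
  do.call(experiment_config, c(
    list(variant = x$variant, scale = x$scale, seed = x$seed,
         dynamics = do.call(dynamics_params, x$dynamics),
         plasticity = do.call(plasticity_params, x$plasticity),
         network = do.call(network_config, x$network)),
    args
  ))
}
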