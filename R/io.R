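# CSV readers/writers with strict, line-numbered schema validation, JSON
# config handling, and GraphML export. All tables carry units in their
# column names (x_um, u_map_mmol_gdw_h, ...).

check_numeric_col <- function(df, col, path) {
  v <- df[[col]]
  if (is.character(v)) v <- suppressWarnings(as.numeric(v))
  bad <- which(!is.finite(v))
  if (length(bad)) {
    stop(sprintf("%s: column '%s' is not numeric/finite at data row %d",
                 path, col, bad[1]))
  }
  v
}

read_frame_table <- function(path, required, params, kind) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  for (col in intersect(required, c("frame_index", "time_min", "x_um", "y_um",
                                    "pH", "sigma"))) {
    df[[col]] <- check_numeric_col(df, col, path)
  }
  L <- params$frame_size_um
  oob <- which(df$x_um < 0 | df$x_um > L | df$y_um < 0 | df$y_um > L)
  if (length(oob)) {
    stop(sprintf("%s: position outside [0, %g] um frame at data row %d",
                 path, L, oob[1]))
  }
  if (kind == "probes") {
    bad <- which(df$sigma <= 0)
    if (length(bad)) {
      stop(sprintf("%s: sigma must be > 0 (data row %d)", path, bad[1]))
    }
    bad <- which(df$pH < 3 | df$pH > 11)
    if (length(bad)) {
      stop(sprintf("%s: pH outside plausible range [3, 11] (data row %d)",
                   path, bad[1]))
    }
  }
  if (kind == "cells") {
    for (fi in unique(df$frame_index)) {
      ids <- df$cell_id[df$frame_index == fi]
      if (anyDuplicated(ids)) {
        stop(sprintf("%s: duplicated cell_id '%s' in frame %s", path,
                     ids[duplicated(ids)][1], fi))
      }
    }
  }
  # frames sorted by time
  frame_time <- tapply(df$time_min, df$frame_index, `[`, 1)
  ord <- names(sort(frame_time))
  if (!identical(ord, as.character(sort(unique(df$frame_index)))) ||
      is.unsorted(df$time_min[!duplicated(df$frame_index)])) {
    message(path, ": frames supplied out of time order; returning sorted")
  }
  df <- df[order(df$time_min, df$frame_index), ]
  rownames(df) <- NULL
  df
}

#' Read a cell-position table
#'
#' CSV with header `frame_index,time_min,cell_id,x_um,y_um[,cell_type]`.
#' Validation (with row-numbered errors): numeric finite coordinates
#' within the frame, unique cell ids per frame. Frames are returned sorted
#' by time (with a message if the input was out of order).
#'
#' @param path CSV file path.
#' @param params A [physical_params()] object (frame bounds).
#' @return Validated data frame.
#' @export
read_cell_table <- function(path, params = physical_params()) {
  read_frame_table(path, c("frame_index", "time_min", "cell_id", "x_um", "y_um"),
                   params, "cells")
}

#' Read a probe table
#'
#' CSV with header `frame_index,time_min,probe_id,x_um,y_um,pH,sigma`.
#' Enforces sigma > 0 and pH within the plausible physical range 3-11,
#' with row-numbered errors.
#'
#' @inheritParams read_cell_table
#' @return Validated data frame.
#' @export
read_probe_table <- function(path, params = physical_params()) {
  read_frame_table(path, c("frame_index", "time_min", "probe_id", "x_um",
                           "y_um", "pH", "sigma"),
                   params, "probes")
}

#' Read a bulk series
#'
#' CSV with header `time_min,bulk_pH` (and optionally
#' `bulk_u_mmol_gdw_h`, `bulk_concentration`).
#'
#' @param path CSV file path.
#' @return Data frame sorted by time.
#' @export
read_bulk_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"time_min" %in% names(df)) stop(path, ": missing column 'time_min'")
  if (!any(c("bulk_pH", "bulk_u_mmol_gdw_h", "bulk_concentration") %in% names(df))) {
    stop(path, ": need 'bulk_pH', 'bulk_concentration' or 'bulk_u_mmol_gdw_h'")
  }
  df <- df[order(df$time_min), ]
  rownames(df) <- NULL
  df
}

#' Write a synthetic experiment to the pipeline input formats
#'
#' Writes `cells.csv`, `probes.csv`, `truth.csv` and (if a bulk series is
#' given) `bulk.csv` in the exact formats the inference consumes.
#'
#' @param experiment A [generate_experiment()] result.
#' @param dir Output directory (created if needed).
#' @param bulk Optional [make_bulk_series()] result.
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir, bulk = NULL) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(experiment$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  utils::write.csv(experiment$probes, file.path(dir, "probes.csv"), row.names = FALSE)
  utils::write.csv(experiment$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  if (!is.null(bulk)) {
    utils::write.csv(as.data.frame(bulk), file.path(dir, "bulk.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Write a flux solution to CSV/JSON outputs
#'
#' Writes `fluxes.csv`, `boundary.csv`, `residuals.csv` and
#' `diagnostics.json` under `dir`.
#'
#' @param solution A [infer_fluxes()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_flux_solution <- function(solution, dir) {
  stopifnot(inherits(solution, "flux_solution"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(solution$fluxes, file.path(dir, "fluxes.csv"), row.names = FALSE)
  utils::write.csv(solution$boundary, file.path(dir, "boundary.csv"), row.names = FALSE)
  utils::write.csv(solution$residuals, file.path(dir, "residuals.csv"), row.names = FALSE)
  di <- solution$diagnostics
  di$chi2_trace <- as.numeric(di$chi2_trace)
  jsonlite::write_json(di, file.path(dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Write exchange-network outputs
#'
#' Writes `edges.csv` (all frames), `summary.csv`, and one GraphML file
#' per frame under `dir/graphml/`.
#'
#' @param graphs List of `exchange_graph`s (e.g. [exchange_graphs()]).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_network_outputs <- function(graphs, dir) {
  dir.create(file.path(dir, "graphml"), showWarnings = FALSE, recursive = TRUE)
  edge_rows <- lapply(graphs, function(g) {
    if (nrow(g$edges) == 0L) return(NULL)
    data.frame(frame_index = g$frame_index, donor_id = g$edges$donor,
               acceptor_id = g$edges$acceptor,
               F_mmol_gdw_h = g$edges$weight)
  })
  edges <- do.call(rbind, edge_rows)
  if (is.null(edges)) {
    edges <- data.frame(frame_index = integer(), donor_id = character(),
                        acceptor_id = character(), F_mmol_gdw_h = numeric())
  }
  utils::write.csv(edges, file.path(dir, "edges.csv"), row.names = FALSE)
  utils::write.csv(summarise_graphs(graphs), file.path(dir, "summary.csv"),
                   row.names = FALSE)
  for (g in graphs) {
    ig <- as_igraph(g)
    if (nrow(g$edges)) igraph::E(ig)$weight <- g$edges$weight
    igraph::write_graph(ig,
                        file.path(dir, "graphml",
                                  sprintf("frame_%03d.graphml",
                                          as.integer(g$frame_index))),
                        format = "graphml")
  }
  invisible(dir)
}

#' Default run configuration
#'
#' Nested list with blocks `physical`, `hyper`, `network`, `run`,
#' serializable to/from JSON. Any field can be overridden in a config
#' file; unresolved hyperparameters are written as null.
#'
#' @return Named list.
#' @export
default_config <- function() {
  p <- physical_params()
  h <- hyper_params()
  list(
    physical = unclass(p),
    hyper = unclass(h),
    network = list(threshold = 0.5, dist_exponent = 1),
    run = list(seed = 1L, level = 0.68, log_level = "INFO")
  )
}

#' Read a JSON run configuration
#'
#' Merges the file over [default_config()] (missing fields keep their
#' defaults) and rebuilds the parameter objects.
#'
#' @param path JSON file, or `NULL` for pure defaults.
#' @return List with `physical` ([physical_params()]), `hyper`
#'   ([hyper_params()]), `network`, `run`, and `raw` (the merged list).
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (blk in intersect(names(user), names(cfg))) {
      for (k in names(user[[blk]])) cfg[[blk]][[k]] <- user[[blk]][[k]]
    }
  }
  nul2na <- function(x) if (is.null(x)) NA_real_ else x
  phys <- do.call(physical_params, cfg$physical[
    intersect(names(cfg$physical), names(formals(physical_params)))])
  hy_args <- cfg$hyper[intersect(names(cfg$hyper), names(formals(hyper_params)))]
  hy_args[c("lambda1", "lambda2", "lambda3")] <-
    lapply(hy_args[c("lambda1", "lambda2", "lambda3")], nul2na)
  hyper <- do.call(hyper_params, hy_args)
  list(physical = phys, hyper = hyper, network = cfg$network, run = cfg$run,
       raw = cfg)
}

write_effective_config <- function(config, solution, path) {
  cfg <- config$raw
  cfg$hyper$lambda1 <- solution$diagnostics$lambda1
  cfg$hyper$lambda2 <- solution$diagnostics$lambda2
  cfg$hyper$lambda3 <- solution$diagnostics$lambda3
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
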