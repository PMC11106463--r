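# Interchange formats: all tabular artifacts are CSV keyed by region_id,
# grid series are long CSV, geometries are GeoJSON, configs are YAML.

read_keyed_csv <- function(path, key = "region_id") {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!key %in% names(x)) {
    stop("file ", path, " lacks required key column '", key, "'", call. = FALSE)
  }
  dup <- x[[key]][duplicated(x[[key]])]
  if (length(dup) > 0) {
    stop("duplicated ", key, " in ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  x
}

#' Read and write region-keyed tables
#'
#' CSV interchange for the pipeline's tabular artifacts. All tables carry
#' a `region_id` key column; duplicated keys are rejected on read.
#' Round-tripping preserves identifiers exactly and numeric values to
#' full double precision.
#'
#' @param x Tibble with a `region_id` column.
#' @param path File path.
#' @return `read_feature_table()` and `read_smr_table()` return tibbles;
#'   the writers return `path` invisibly.
#' @export
write_feature_table <- function(x, path) {
  stopifnot("region_id" %in% names(x))
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) read_keyed_csv(path)

#' @rdname write_feature_table
#' @export
write_smr_table <- function(x, path) {
  stopifnot(all(c("region_id", "observed", "expected", "smr", "outlier") %in% names(x)))
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_smr_table <- function(path) {
  x <- read_keyed_csv(path)
  stopifnot(all(c("observed", "expected", "smr", "outlier") %in% names(x)))
  x
}

#' Read and write block assignments
#'
#' @param assignment A [cluster_regions()] result (or its `labels` tibble).
#' @param path File path.
#' @return `read_blocks()` returns a `region_id`/`block` tibble.
#' @export
write_blocks <- function(assignment, path) {
  labs <- if (inherits(assignment, "block_assignment")) assignment$labels else assignment
  stopifnot(all(c("region_id", "block") %in% names(labs)))
  readr::write_csv(labs, path)
  invisible(path)
}

#' @rdname write_blocks
#' @export
read_blocks <- function(path) read_keyed_csv(path)

#' Read and write gridded exposure series as long CSV
#'
#' Columns: `cell_id`, `x`, `y`, `region_id`, `pollutant`, `t`, `value`;
#' one row per cell, pollutant and time step.
#'
#' @param grid A [grid_fields()] object.
#' @param path File path.
#' @return `read_grid_series()` returns a `grid_fields` object.
#' @export
write_grid_series <- function(grid, path) {
  stopifnot(inherits(grid, "grid_fields"))
  long <- purrr::imap_dfr(grid$series, function(mat, pol) {
    tibble::tibble(
      cell_id = rep(grid$cells$cell_id, times = ncol(mat)),
      x = rep(grid$cells$x, times = ncol(mat)),
      y = rep(grid$cells$y, times = ncol(mat)),
      region_id = rep(grid$cells$region_id, times = ncol(mat)),
      pollutant = pol,
      t = rep(seq_len(ncol(mat)), each = nrow(mat)),
      value = as.vector(mat)
    )
  })
  readr::write_csv(long, path)
  invisible(path)
}

#' @rdname write_grid_series
#' @export
read_grid_series <- function(path) {
  long <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("cell_id", "x", "y", "region_id", "pollutant", "t", "value")
  missing <- setdiff(need, names(long))
  if (length(missing) > 0) {
    stop("grid series file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cells <- long |>
    dplyr::distinct(.data$cell_id, .data$x, .data$y, .data$region_id) |>
    dplyr::arrange(.data$cell_id)
  series <- lapply(split(long, long$pollutant), function(df) {
    df <- df[order(df$t, df$cell_id), ]
    matrix(df$value, nrow = nrow(cells))
  })
  grid_fields(cells, series)
}

#' Read and write region geometries as GeoJSON
#'
#' `write_regions_geojson()` writes region centroids as a Point
#' FeatureCollection with a `region_id` property. `read_regions_geojson()`
#' reads Point features into a centroid tibble, or Polygon features into a
#' named list of vertex matrices suitable for [assign_cells()].
#'
#' @param regions Tibble: `region_id`, `x`, `y` (centroids).
#' @param path File path.
#' @return `read_regions_geojson()` returns a tibble (points) or a named
#'   list of matrices (polygons).
#' @export
write_regions_geojson <- function(regions, path) {
  stopifnot(all(c("region_id", "x", "y") %in% names(regions)))
  features <- purrr::pmap(regions[, c("region_id", "x", "y")], function(region_id, x, y) {
    list(
      type = "Feature",
      properties = list(region_id = region_id),
      geometry = list(type = "Point", coordinates = c(x, y))
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_regions_geojson
#' @export
read_regions_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  stopifnot(identical(gj$type, "FeatureCollection"))
  feats <- gj$features
  for (f in feats) {
    rid <- f$properties$region_id
    if (is.null(f$geometry) || is.null(f$geometry$type)) {
      stop("region ", if (is.null(rid)) "<unnamed>" else rid,
           " lacks a geometry", call. = FALSE)
    }
  }
  types <- unique(vapply(feats, function(f) f$geometry$type, character(1)))
  if (identical(types, "Point")) {
    purrr::map_dfr(feats, function(f) {
      tibble::tibble(
        region_id = f$properties$region_id,
        x = f$geometry$coordinates[[1]],
        y = f$geometry$coordinates[[2]]
      )
    })
  } else if (identical(types, "Polygon")) {
    polys <- lapply(feats, function(f) {
      ring <- f$geometry$coordinates[[1]]
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    })
    names(polys) <- vapply(feats, function(f) as.character(f$properties$region_id),
                           character(1))
    polys
  } else {
    stop("unsupported or mixed geometry types: ", paste(types, collapse = ", "),
         call. = FALSE)
  }
}

#' Read and write synthetic-world configurations as YAML
#'
#' @param config A [synthetic_config()].
#' @param path File path.
#' @return `read_config()` returns a validated `synthetic_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "synthetic_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(synthetic_config, yaml::read_yaml(path))
}
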