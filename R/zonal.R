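# Zonal aggregation of gridded exposure series into region-level features.
# The order of operations is fixed: temporal statistics per cell first, then
# the spatial (zonal) average of those per-cell maps within each region.

#' Bundle cell metadata and exposure series into a grid field set
#'
#' @param cells Tibble with `cell_id`, `x`, `y`, `region_id` (one row per
#'   cell; membership must be total).
#' @param series Named list of numeric matrices (cells x timesteps), one
#'   per pollutant, all with the same dimensions and row order as `cells`.
#'
#' @return A list of class `grid_fields`.
#' @export
grid_fields <- function(cells, series) {
  stopifnot(is.list(series), length(series) >= 1, !is.null(names(series)))
  if (any(is.na(cells$region_id))) {
    stop("membership must be total: cells without a region_id", call. = FALSE)
  }
  nt <- unique(vapply(series, ncol, integer(1)))
  if (length(nt) != 1) {
    stop("all pollutant series must share the same timestep axis", call. = FALSE)
  }
  for (p in names(series)) {
    if (nrow(series[[p]]) != nrow(cells)) {
      stop("series '", p, "' has ", nrow(series[[p]]), " rows but there are ",
           nrow(cells), " cells", call. = FALSE)
    }
  }
  structure(list(cells = cells, series = series), class = "grid_fields")
}

#' Per-cell temporal mean and standard deviation
#'
#' Computes, for each grid cell, the mean and standard deviation of its
#' exposure time series. The population convention (divide by `n`) is the
#' default so a single time step has a well-defined zero standard
#' deviation; the sample convention (divide by `n - 1`) is available.
#'
#' @param series Numeric matrix, cells x timesteps.
#' @param std Either `"population"` (default) or `"sample"`.
#'
#' @return Tibble: `cell_id` (row index), `mean`, `std`.
#' @export
#' @examples
#' temporal_stats(rbind(c(1, 2, 3), c(5, 5, 5)))
temporal_stats <- function(series, std = c("population", "sample")) {
  std <- match.arg(std)
  series <- as.matrix(series)
  if (any(!is.finite(series))) {
    bad <- which(!is.finite(series), arr.ind = TRUE)[1, ]
    stop("non-finite value in series at cell ", bad[1], ", timestep ", bad[2],
         call. = FALSE)
  }
  n <- ncol(series)
  m <- rowMeans(series)
  ss <- rowSums((series - m)^2)
  s <- switch(std,
    population = sqrt(ss / n),
    sample = if (n > 1) sqrt(ss / (n - 1)) else rep(0, nrow(series))
  )
  tibble::tibble(cell_id = seq_len(nrow(series)), mean = m, std = s)
}

#' Unweighted zonal mean of a per-cell map
#'
#' Averages a per-cell value within each region (plain arithmetic mean over
#' member cells, no area weighting).
#'
#' @param values Numeric vector, one value per cell.
#' @param membership Region id per cell, same length as `values`.
#'
#' @return Tibble: `region_id`, `value`, sorted by region id.
#' @export
#' @examples
#' zonal_mean(c(1, 3, 10), membership = c("a", "a", "b"))
zonal_mean <- function(values, membership) {
  stopifnot(length(values) == length(membership))
  if (any(is.na(membership))) {
    stop("membership must be total: cell(s) without a region", call. = FALSE)
  }
  tibble::tibble(region_id = membership, value = as.numeric(values)) |>
    dplyr::group_by(.data$region_id) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    dplyr::arrange(.data$region_id)
}

#' Region-level exposure features from gridded series
#'
#' For each pollutant, computes the per-cell temporal mean and standard
#' deviation, then the zonal (within-region) average of each map, yielding
#' features `mean <pollutant>` and `std <pollutant>`. Temporal aggregation
#' always precedes spatial aggregation.
#'
#' @param grid A [grid_fields()] object.
#' @inheritParams temporal_stats
#'
#' @return Tibble: `region_id` plus two feature columns per pollutant.
#' @export
build_exposure_features <- function(grid, std = c("population", "sample")) {
  stopifnot(inherits(grid, "grid_fields"))
  std <- match.arg(std)
  memb <- grid$cells$region_id
  out <- NULL
  for (p in names(grid$series)) {
    ts <- temporal_stats(grid$series[[p]], std = std)
    zm <- zonal_mean(ts$mean, memb)
    zs <- zonal_mean(ts$std, memb)
    cols <- tibble::tibble(zm$value, zs$value)
    names(cols) <- paste(c("mean", "std"), p)
    block <- dplyr::bind_cols(tibble::tibble(region_id = zm$region_id), cols)
    out <- if (is.null(out)) block else dplyr::left_join(out, block, by = "region_id")
  }
  out
}

#' Assign grid cells to regions by polygon containment
#'
#' Assigns each cell to the polygon containing its center (cell-center
#' convention, no fractional overlap). Cells falling outside all polygons
#' are dropped, with a message reporting the count.
#'
#' @param cell_coords Data frame with columns `x` and `y` (cell centers).
#' @param region_polygons Named list of polygons, one per region; each a
#'   two-column matrix of vertex coordinates (closed or open ring).
#'   Polygons are assumed non-overlapping.
#'
#' @return Tibble: `cell_id` (row index into `cell_coords`), `x`, `y`,
#'   `region_id`; only cells inside some polygon are retained.
#' @export
assign_cells <- function(cell_coords, region_polygons) {
  stopifnot(is.list(region_polygons), !is.null(names(region_polygons)))
  pts <- as.matrix(cell_coords[, c("x", "y")])
  memb <- rep(NA_character_, nrow(pts))
  for (rid in names(region_polygons)) {
    poly <- as.matrix(region_polygons[[rid]])
    inside <- mgcv::in.out(poly, pts)
    memb[is.na(memb) & inside] <- rid
  }
  empty <- setdiff(names(region_polygons), unique(memb))
  if (length(empty) > 0) {
    stop("region(s) with zero cells after assignment: ",
         paste(empty, collapse = ", "),
         " (region too small for the grid resolution)", call. = FALSE)
  }
  dropped <- sum(is.na(memb))
  if (dropped > 0) {
    message(dropped, " cell(s) outside all polygons dropped")
  }
  keep <- !is.na(memb)
  tibble::tibble(
    cell_id = which(keep),
    x = pts[keep, 1], y = pts[keep, 2],
    region_id = memb[keep]
  )
}
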