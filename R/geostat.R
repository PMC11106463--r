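# Empirical semivariogram of a regionalized variable (here the SMR over
# region centroids) and automated detection of the range — the lag at which
# the semivariance reaches its plateau — which sets the spatial-blocking
# scale for cross-validation.

#' Pairwise distances between region centroids
#'
#' @param coords Data frame of point coordinates. For `metric =
#'   "euclidean"`, columns `x` and `y` in planar units; for `metric =
#'   "haversine"`, columns `lon` and `lat` in decimal degrees (great-circle
#'   distance on a sphere of radius 6371 km, returned in km).
#' @param metric `"euclidean"` or `"haversine"`.
#'
#' @return Symmetric distance matrix with zero diagonal; row/column names
#'   are taken from a `region_id` column when present.
#' @export
#' @examples
#' pairwise_distances(data.frame(x = c(0, 3), y = c(0, 4)))  # 5
pairwise_distances <- function(coords, metric = c("euclidean", "haversine")) {
  metric <- match.arg(metric)
  if (metric == "euclidean") {
    stopifnot(all(c("x", "y") %in% names(coords)))
    d <- as.matrix(stats::dist(as.matrix(coords[, c("x", "y")])))
  } else {
    stopifnot(all(c("lon", "lat") %in% names(coords)))
    if (any(coords$lat < -90 | coords$lat > 90)) {
      stop("latitude outside [-90, 90] under haversine metric", call. = FALSE)
    }
    pts <- as.matrix(coords[, c("lon", "lat")])
    d <- geosphere::distm(pts, fun = function(p1, p2) {
      geosphere::distHaversine(p1, p2, r = 6371)
    })
  }
  ids <- if ("region_id" %in% names(coords)) as.character(coords$region_id) else NULL
  dimnames(d) <- list(ids, ids)
  d
}

#' Empirical semivariogram (Matheron estimator)
#'
#' For each lag bin, computes half the average squared difference between
#' the values of all point pairs whose separation falls in the bin:
#' `gamma(h) = 1 / (2 N(h)) * sum (z_i - z_j)^2`. Empty bins carry `NA`
#' semivariance and a zero pair count.
#'
#' @param values Numeric vector, one value per point.
#' @param distmat Symmetric pairwise distance matrix for the same points.
#' @param bin_edges Strictly increasing numeric vector of bin boundaries
#'   starting at >= 0. Pairs fall in bin `b` when `edges[b] < d <=
#'   edges[b+1]` (the first bin also includes `d = edges[1]`). Default: 15
#'   equal-width bins from 0 to half the maximum pairwise distance.
#' @param n_bins Number of equal-width bins used when `bin_edges` is NULL.
#'
#' @return An object of class `semivariogram`: a list with `bins` (tibble:
#'   `bin_lo`, `bin_hi`, `bin_center`, `gamma`, `n_pairs`), `values_var`
#'   (sample variance of the input values), and placeholders for
#'   `sill_estimate`, `range_estimate`, `converged` filled by
#'   [estimate_range()].
#' @export
empirical_semivariogram <- function(values, distmat, bin_edges = NULL, n_bins = 15) {
  n <- length(values)
  stopifnot(n >= 2, nrow(distmat) == n, ncol(distmat) == n)
  if (is.null(bin_edges)) {
    dmax <- max(distmat)
    bin_edges <- seq(0, dmax / 2, length.out = n_bins + 1)
  }
  if (any(diff(bin_edges) <= 0) || bin_edges[1] < 0) {
    stop("bin_edges must be strictly increasing and start at >= 0", call. = FALSE)
  }
  iu <- which(upper.tri(distmat), arr.ind = TRUE)
  d <- distmat[iu]
  sq <- (values[iu[, 1]] - values[iu[, 2]])^2
  bin <- findInterval(d, bin_edges, left.open = TRUE, rightmost.closed = FALSE)
  bin[d == bin_edges[1]] <- 1L  # include the lower boundary in the first bin
  keep <- bin >= 1L & bin <= length(bin_edges) - 1L
  nb <- length(bin_edges) - 1L
  counts <- tabulate(bin[keep], nbins = nb)
  sums <- vapply(seq_len(nb), function(b) sum(sq[keep][bin[keep] == b]), numeric(1))
  gamma <- ifelse(counts > 0, sums / (2 * counts), NA_real_)
  if (all(counts == 0)) {
    stop("all semivariogram bins are empty; widen the bins", call. = FALSE)
  }
  structure(
    list(
      bins = tibble::tibble(
        bin_lo = bin_edges[-length(bin_edges)],
        bin_hi = bin_edges[-1],
        bin_center = (bin_edges[-length(bin_edges)] + bin_edges[-1]) / 2,
        gamma = gamma,
        n_pairs = counts
      ),
      values_var = var(values),
      sill_estimate = NA_real_,
      range_estimate = NA_real_,
      converged = NA
    ),
    class = "semivariogram"
  )
}

#' Estimate the semivariogram range (plateau onset)
#'
#' Automates the visual plateau identification: the sill is estimated by
#' the sample variance of the values, and the range is the center of the
#' first bin whose (optionally moving-average smoothed) semivariance
#' reaches `threshold * sill`. If no bin reaches it, the last non-empty bin
#' center is returned and the `converged` flag is set to `FALSE`.
#'
#' @param sv A [empirical_semivariogram()] object with >= 3 non-empty bins.
#' @param threshold Fraction of the sill defining the plateau; default 0.95.
#' @param smooth_window Moving-average window (bins) applied to the
#'   semivariance before scanning; default 3; use 1 for no smoothing.
#'
#' @return The input object with `sill_estimate`, `range_estimate` and
#'   `converged` filled in.
#' @export
estimate_range <- function(sv, threshold = 0.95, smooth_window = 3) {
  stopifnot(inherits(sv, "semivariogram"), threshold > 0, smooth_window >= 1)
  ok <- sv$bins$n_pairs > 0
  if (sum(ok) < 3) {
    stop("need at least 3 non-empty bins to estimate a range", call. = FALSE)
  }
  g <- sv$bins$gamma[ok]
  centers <- sv$bins$bin_center[ok]
  if (smooth_window > 1) {
    half <- floor(smooth_window / 2)
    g <- vapply(seq_along(g), function(i) {
      lo <- max(1, i - half); hi <- min(length(g), i + half)
      mean(g[lo:hi])
    }, numeric(1))
  }
  sill <- sv$values_var
  hit <- which(g >= threshold * sill)
  if (length(hit) > 0) {
    sv$range_estimate <- centers[hit[1]]
    sv$converged <- TRUE
  } else {
    sv$range_estimate <- centers[length(centers)]
    sv$converged <- FALSE
  }
  sv$sill_estimate <- sill
  sv
}

#' @export
print.semivariogram <- function(x, ...) {
  cat("<semivariogram>\n")
  cat("  bins:", nrow(x$bins), " pairs:", sum(x$bins$n_pairs), "\n")
  if (!is.na(x$range_estimate)) {
    cat("  sill:", signif(x$sill_estimate, 4),
        " range:", signif(x$range_estimate, 4),
        if (isFALSE(x$converged)) " (plateau not reached)" else "", "\n")
  }
  invisible(x)
}

#' @rdname empirical_semivariogram
#' @param x A `semivariogram` object.
#' @param ... Unused.
#' @export
tidy.semivariogram <- function(x, ...) x$bins

#' @rdname empirical_semivariogram
#' @export
glance.semivariogram <- function(x, ...) {
  tibble::tibble(
    sill = x$sill_estimate,
    range = x$range_estimate,
    converged = x$converged,
    n_bins = nrow(x$bins),
    n_pairs = sum(x$bins$n_pairs)
  )
}

#' @rdname empirical_semivariogram
#' @param object A `semivariogram` object.
#' @export
autoplot.semivariogram <- function(object, ...) {
  df <- object$bins[object$bins$n_pairs > 0, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_center, y = .data$gamma)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.8) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "lag distance", y = "semivariance",
                  size = "pairs") +
    ggplot2::theme_minimal()
  if (!is.na(object$sill_estimate)) {
    p <- p +
      ggplot2::geom_hline(yintercept = object$sill_estimate, linetype = 2) +
      ggplot2::geom_vline(xintercept = object$range_estimate, linetype = 3)
  }
  p
}
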