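# Spatially coherent cross-validation blocks: hierarchical clustering of
# the inter-region distance matrix, cut at the semivariogram range so that
# regions closer than the spatial correlation scale share a block.

#' Cluster regions into spatial blocks
#'
#' Agglomerative hierarchical clustering of the pairwise distance matrix,
#' with flat block labels obtained by cutting the dendrogram at
#' `cut_distance`. With complete linkage (the default) every block's
#' internal diameter — its maximum intra-block pairwise distance — is
#' bounded by the cut, which is what makes cutting at the semivariogram
#' range meaningful: no two regions within the correlation range end up in
#' different folds.
#'
#' @param distmat Symmetric distance matrix with zero diagonal; row names,
#'   if present, are used as region ids.
#' @param cut_distance Dendrogram cut height; > 0. Cutting at the
#'   semivariogram range yields blocks wider than the spatial correlation.
#' @param linkage `"complete"` (default), `"average"` or `"single"`.
#'
#' @return An object of class `block_assignment`: a list with `labels`
#'   (tibble: `region_id`, `block` with blocks numbered 1..n_blocks),
#'   `cut_distance`, `linkage`, `n_blocks`.
#' @export
#' @examples
#' d <- pairwise_distances(data.frame(x = c(0, 1, 10), y = 0))
#' cluster_regions(d, cut_distance = 5)
cluster_regions <- function(distmat, cut_distance,
                            linkage = c("complete", "average", "single")) {
  linkage <- match.arg(linkage)
  stopifnot(cut_distance > 0, nrow(distmat) == ncol(distmat))
  if (max(abs(distmat - t(distmat))) > 1e-8 || any(diag(distmat) != 0)) {
    stop("distmat must be symmetric with a zero diagonal", call. = FALSE)
  }
  ids <- rownames(distmat)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(distmat)))
  hc <- stats::hclust(stats::as.dist(distmat), method = linkage)
  raw <- stats::cutree(hc, h = cut_distance)
  # relabel blocks in order of first appearance so labels are stable in the
  # region order, not in dendrogram order
  labels <- as.integer(factor(raw, levels = unique(raw)))
  n_blocks <- max(labels)
  if (n_blocks < 2) {
    stop("cut_distance ", cut_distance, " yields a single block; ",
         "choose a smaller cut so cross-validation is possible", call. = FALSE)
  }
  structure(
    list(
      labels = tibble::tibble(region_id = ids, block = labels),
      cut_distance = cut_distance,
      linkage = linkage,
      n_blocks = n_blocks
    ),
    class = "block_assignment"
  )
}

#' Per-block diagnostics
#'
#' @param assignment A [cluster_regions()] result.
#' @param distmat The distance matrix the assignment was built from.
#'
#' @return Tibble: `block`, `size`, `diameter` (maximum intra-block
#'   pairwise distance; 0 for singletons), `singleton` flag.
#' @export
block_summary <- function(assignment, distmat) {
  stopifnot(inherits(assignment, "block_assignment"))
  labs <- assignment$labels$block
  purrr::map_dfr(sort(unique(labs)), function(b) {
    idx <- which(labs == b)
    diam <- if (length(idx) > 1) max(distmat[idx, idx]) else 0
    tibble::tibble(block = b, size = length(idx), diameter = diam,
                   singleton = length(idx) == 1)
  })
}

#' @export
print.block_assignment <- function(x, ...) {
  cat("<block_assignment> ", x$n_blocks, " blocks (", x$linkage,
      " linkage, cut = ", signif(x$cut_distance, 4), ")\n", sep = "")
  print(table(block = x$labels$block))
  invisible(x)
}

#' @rdname cluster_regions
#' @param x A `block_assignment` object.
#' @param ... Unused.
#' @export
tidy.block_assignment <- function(x, ...) x$labels

#' @rdname cluster_regions
#' @export
glance.block_assignment <- function(x, ...) {
  tibble::tibble(
    n_blocks = x$n_blocks,
    cut_distance = x$cut_distance,
    linkage = x$linkage,
    min_size = min(table(x$labels$block)),
    max_size = max(table(x$labels$block))
  )
}
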