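# Independent brute-force oracles and small fixture builders shared across
# the test files. Oracles deliberately use naive double loops, not the
# package's vectorized paths.

# Semivariogram by an explicit all-pairs double loop.
oracle_semivariogram <- function(values, distmat, bin_edges) {
  nb <- length(bin_edges) - 1
  gamma <- rep(NA_real_, nb)
  counts <- integer(nb)
  n <- length(values)
  for (b in seq_len(nb)) {
    tot <- 0
    cnt <- 0L
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d <- distmat[i, j]
        in_bin <- if (b == 1) d >= bin_edges[1] && d <= bin_edges[2]
                  else d > bin_edges[b] && d <= bin_edges[b + 1]
        if (in_bin) {
          tot <- tot + (values[i] - values[j])^2
          cnt <- cnt + 1L
        }
      }
    }
    counts[b] <- cnt
    if (cnt > 0) gamma[b] <- tot / (2 * cnt)
  }
  list(gamma = gamma, counts = counts)
}

# Zonal mean by split + explicit mean.
oracle_zonal_mean <- function(values, membership) {
  groups <- split(values, membership)
  out <- vapply(groups, mean, numeric(1))
  out[order(names(out))]
}

# Connectivity of each region's cell set under 4-neighbour adjacency,
# checked by flood fill.
oracle_regions_connected <- function(cells, grid_side) {
  for (rid in unique(cells$region_id)) {
    sub <- cells[cells$region_id == rid, ]
    key <- paste(sub$x, sub$y)
    seen <- key[1]
    frontier <- key[1]
    coords <- setNames(split(sub[, c("x", "y")], seq_len(nrow(sub))), key)
    while (length(frontier) > 0) {
      cur <- frontier[1]
      frontier <- frontier[-1]
      xy <- as.numeric(strsplit(cur, " ")[[1]])
      nbs <- paste(xy[1] + c(-1, 1, 0, 0), xy[2] + c(0, 0, -1, 1))
      new <- setdiff(intersect(nbs, key), seen)
      seen <- c(seen, new)
      frontier <- c(frontier, new)
    }
    if (length(seen) != nrow(sub)) return(FALSE)
  }
  TRUE
}

# Tiny world used by several files: fast to build, all invariants hold.
tiny_world <- function(seed = 1L) {
  build_world(synthetic_config(
    grid_side = 10, n_regions = 12, n_timesteps = 30,
    n_pollutants = 2, n_features = 8, grf_range = 5, seed = seed
  ))
}

# Random age-structured population / deaths tables for identity checks.
random_mortality_table <- function(n_regions, n_ages, seed) {
  withr::with_seed(seed, {
    pop <- tidyr::expand_grid(
      region_id = seq_len(n_regions),
      age_class = paste0("a", seq_len(n_ages))
    )
    pop$population <- round(runif(nrow(pop), 100, 5000))
    pop$deaths_age <- rpois(nrow(pop), pop$population * runif(nrow(pop), 1e-3, 2e-2))
    pop
  })
}
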