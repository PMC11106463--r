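# Indirect standardization: expected deaths from reference age-specific
# rates applied to each region's age structure, the SMR = O/E ratio, and
# Tukey-fence outlier flagging of the SMR distribution.

#' Expected deaths by indirect standardization
#'
#' Applies reference (e.g. national) age-specific mortality rates to each
#' region's age structure: `E_i = sum_a pop_{i,a} * rate_a`.
#'
#' @param population Long tibble: `region_id`, `age_class`, `population`
#'   (person counts, >= 0). The age-class axis must be identical across
#'   regions.
#' @param rates Tibble: `age_class`, `rate` (deaths per person-year).
#'
#' @return Tibble: `region_id`, `expected`, sorted by region id.
#' @export
#' @examples
#' pop <- tibble::tibble(region_id = "A", age_class = c("young", "old"),
#'                       population = c(1000, 500))
#' rates <- tibble::tibble(age_class = c("young", "old"), rate = c(0.01, 0.10))
#' expected_deaths(pop, rates)  # 10 + 50 = 60
expected_deaths <- function(population, rates) {
  stopifnot(all(c("region_id", "age_class", "population") %in% names(population)),
            all(c("age_class", "rate") %in% names(rates)))
  if (any(population$population < 0)) {
    stop("invalid input: negative population counts", call. = FALSE)
  }
  ages_pop <- sort(unique(population$age_class))
  ages_rate <- sort(unique(rates$age_class))
  if (!identical(ages_pop, ages_rate)) {
    stop("age-class axes of population and rates do not match", call. = FALSE)
  }
  per_region_ages <- population |>
    dplyr::count(.data$region_id) |>
    dplyr::pull(.data$n)
  if (length(unique(per_region_ages)) != 1) {
    stop("age-class axis must be identical across regions", call. = FALSE)
  }
  population |>
    dplyr::left_join(rates, by = "age_class") |>
    dplyr::group_by(.data$region_id) |>
    dplyr::summarise(expected = sum(.data$population * .data$rate),
                     .groups = "drop") |>
    dplyr::arrange(.data$region_id)
}

#' Standardized mortality ratio
#'
#' The ratio of observed to expected deaths. Vectorized; zero observed
#' deaths give an SMR of zero.
#'
#' @param observed Observed death counts (>= 0).
#' @param expected Expected death counts; must be strictly positive.
#'
#' @return Numeric vector of dimensionless ratios.
#' @export
#' @examples
#' smr(observed = 33, expected = 30)  # 1.1
smr <- function(observed, expected) {
  if (any(expected <= 0)) {
    bad <- which(expected <= 0)
    stop("expected deaths must be > 0 (violated at position ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  }
  as.numeric(observed) / as.numeric(expected)
}

#' Flag outliers by Tukey fences
#'
#' Flags values outside `[Q1 - k * IQR, Q3 + k * IQR]`, with quartiles by
#' linear interpolation (the default quantile definition).
#'
#' @param x Numeric vector, length >= 4 (quartiles are unstable below).
#' @param k Fence multiplier; default 1.5.
#'
#' @return Logical vector, `TRUE` where `x` is an outlier.
#' @export
#' @examples
#' flag_outliers(c(0.9, 1.0, 1.0, 1.1, 3.0))
flag_outliers <- function(x, k = 1.5) {
  if (length(x) < 4) {
    stop("need at least 4 values to flag outliers (quartiles unstable)",
         call. = FALSE)
  }
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  x < q[1] - k * iqr | x > q[2] + k * iqr
}

#' SMR table with outlier flags
#'
#' Combines indirect standardization, the SMR ratio, and Tukey-fence
#' outlier flagging into the per-region summary table used by the
#' downstream modelling stages. Outlier regions are flagged, not removed,
#' so any exclusion is auditable.
#'
#' @param observed Tibble: `region_id`, `deaths` (integer counts).
#' @param population Long tibble: `region_id`, `age_class`, `population`.
#' @param rates Tibble: `age_class`, `rate`.
#' @param k Tukey fence multiplier passed to [flag_outliers()]; set to
#'   `NULL` to skip flagging (all flags `FALSE`).
#'
#' @return Tibble: `region_id`, `observed`, `expected`, `smr`, `outlier`.
#' @export
smr_table <- function(observed, population, rates, k = 1.5) {
  stopifnot(all(c("region_id", "deaths") %in% names(observed)))
  if (any(observed$deaths < 0)) {
    stop("invalid input: negative death counts", call. = FALSE)
  }
  exp_tbl <- expected_deaths(population, rates)
  missing <- setdiff(exp_tbl$region_id, observed$region_id)
  if (length(missing) > 0) {
    stop("no observed deaths for region(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- exp_tbl |>
    dplyr::left_join(observed, by = "region_id") |>
    dplyr::mutate(
      observed = as.integer(.data$deaths),
      smr = smr(.data$deaths, .data$expected)
    ) |>
    dplyr::select("region_id", "observed", "expected", "smr")
  out$outlier <- if (is.null(k)) rep(FALSE, nrow(out)) else flag_outliers(out$smr, k = k)
  out
}
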