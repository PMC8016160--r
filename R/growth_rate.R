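# Peak-to-trough replication-rate estimation from binned genome coverage.
#
# Actively replicating bacteria initiate genome copies at a fixed origin, so
# a population snapshot shows higher sequencing coverage near the origin
# than near the terminus; the peak-to-trough ratio (PTR) of smoothed binned
# coverage therefore scores replication activity (1 = static, higher =
# faster). The estimator here is the package's own: equal re-binning,
# circular moving-median smoothing, max/min scoring, and three quality
# gates -- the trough must sit near the antipode of the peak, the
# log2-coverage profile must be well explained by a symmetric piecewise-
# linear peak-to-trough fit (fit R^2), and mean depth must be adequate.
# Strain heterogeneity is proxied by the fraction of bins deviating more
# than two-fold from that fit.

#' Read a binned coverage track
#'
#' A TSV (or BED-like 4-column file) with columns `genome_id`, `start`,
#' `end`, `depth`; 0-based half-open bins must tile the genome without
#' overlap. The genome is treated as circular.
#'
#' @param path Path to the track file.
#' @param genome_length Genome length in bp; defaults to the largest `end`.
#' @return A coverage-track tibble.
#' @export
read_coverage_track <- function(path, genome_length = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    genome_id = "c", start = "d", end = "d", depth = "d"
  ), progress = FALSE)
  require_columns(df, c("genome_id", "start", "end", "depth"),
                  sprintf("coverage track '%s'", path))
  validate_track(df, genome_length %||% max(df$end))
  df
}

validate_track <- function(track, genome_length = max(track$end)) {
  tr <- track[order(track$start), , drop = FALSE]
  if (nrow(tr) == 0) {
    stop_validation("empty coverage track")
  }
  if (tr$start[1] != 0 || abs(tr$end[nrow(tr)] - genome_length) > 1e-6 ||
      (nrow(tr) > 1 && any(abs(tr$end[-nrow(tr)] - tr$start[-1]) > 1e-6))) {
    stop_validation("bins must tile [0, genome_length) without gaps/overlap")
  }
  if (any(!is.finite(tr$depth)) || any(tr$depth < 0)) {
    stop_validation("depths must be finite and >= 0")
  }
  invisible(tr)
}

#' Estimate a peak-to-trough replication score
#'
#' Re-bins the track into `n_bins` equal windows, applies a circular moving
#' median of width `smooth_window`, and scores
#' `max(smoothed) / min(smoothed)`. The estimate passes QC (`qc_pass`) only
#' when (i) the trough lies within `max_antipode_offset` of the genome
#' length from the point opposite the peak, (ii) mean depth reaches
#' `min_mean_depth`, (iii) the minimum smoothed depth is positive, and
#' (iv) the symmetric piecewise-linear fit of log2 depth (peak to antipodal
#' trough and back) attains `min_fit_r2` -- a flat noisy track has no
#' replication signal and must not be scored as growth. Strain heterogeneity
#' is the fraction of bins whose depth deviates from the fitted profile by
#' more than a factor of two (|log2 ratio| > 1).
#'
#' @param track A coverage-track tibble (`genome_id`, `start`, `end`,
#'   `depth`), circular coordinates.
#' @param n_bins Number of equal re-binning windows (default 100, >= 10).
#' @param smooth_window Odd width of the circular moving median (default 5).
#' @param min_mean_depth Minimum mean fold-coverage for a trustworthy
#'   estimate (default 0.2).
#' @param max_antipode_offset Allowed circular offset of the trough from the
#'   peak's antipode, as a fraction of genome length (default 0.25).
#' @param min_fit_r2 Minimum R^2 of the peak-to-trough log2 fit
#'   (default 0.5).
#' @param sample_id Optional sample id carried into the output.
#' @return A one-row tibble: `genome_id`, `sample_id`, `score`,
#'   `heterogeneity`, `mean_depth`, `fit_r2`, `qc_pass`, `peak_bin`,
#'   `trough_bin`, `n_bins`. `score` is `NA` when the smoothed minimum is 0.
#' @export
estimate_ptr <- function(track, n_bins = 100, smooth_window = 5,
                         min_mean_depth = 0.2, max_antipode_offset = 0.25,
                         min_fit_r2 = 0.5, sample_id = NA_character_) {
  stopifnot(n_bins >= 10, smooth_window %% 2 == 1)
  L <- max(track$end)
  tr <- validate_track(track, L)
  depth <- rebin_track(tr, L, n_bins)
  sm <- circular_median(depth, smooth_window)
  mean_depth <- mean(depth)

  peak <- which.max(sm)
  trough <- which.min(sm)
  degenerate <- max(sm) == min(sm)
  score <- if (min(sm) == 0) NA_real_ else max(sm) / min(sm)

  antipode <- ((peak - 1 + n_bins / 2) %% n_bins) + 1
  offset <- circ_bin_dist(trough, antipode, n_bins) / n_bins
  antipode_ok <- offset <= max_antipode_offset

  fit <- peak_trough_fit(depth, peak, n_bins)
  heterogeneity <- if (degenerate) 0 else fit$heterogeneity
  qc_pass <- !degenerate && antipode_ok && mean_depth >= min_mean_depth &&
    min(sm) > 0 && is.finite(fit$r2) && fit$r2 >= min_fit_r2
  if (degenerate) {
    score <- 1
  }

  tibble::tibble(
    genome_id = tr$genome_id[1], sample_id = sample_id, score = score,
    heterogeneity = heterogeneity, mean_depth = mean_depth, fit_r2 = fit$r2,
    qc_pass = qc_pass, peak_bin = peak, trough_bin = trough, n_bins = n_bins
  )
}

# Length-weighted mean depth over n equal windows, via the cumulative
# integral of the piecewise-constant depth function.
rebin_track <- function(tr, L, n_bins) {
  cum <- c(0, cumsum(tr$depth * (tr$end - tr$start)))
  edges <- seq(0, L, length.out = n_bins + 1)
  ci <- stats::approx(c(tr$start, L), cum, xout = edges, rule = 2)$y
  diff(ci) / (L / n_bins)
}

circular_median <- function(x, w) {
  n <- length(x)
  h <- (w - 1) / 2
  idx <- outer(seq_len(n) - 1, -h:h, `+`) %% n + 1
  apply(matrix(x[idx], nrow = n), 1, median)
}

circ_bin_dist <- function(i, j, n) {
  d <- abs(i - j)
  min(d, n - d)
}

# Symmetric two-segment piecewise-linear fit of log2 depth against circular
# distance from the peak (0 at peak, 1 at the antipode): log-coverage
# descends linearly to the trough and ascends back.
peak_trough_fit <- function(depth, peak, n_bins) {
  j <- seq_len(n_bins)
  d <- pmin(abs(j - peak), n_bins - abs(j - peak)) / (n_bins / 2)
  y <- log2(depth)
  ok <- is.finite(y)
  if (sum(ok) < 3 || var(d[ok]) == 0) {
    return(list(r2 = NA_real_, heterogeneity = mean(!ok)))
  }
  b <- stats::cov(d[ok], y[ok]) / var(d[ok])
  a <- mean(y[ok]) - b * mean(d[ok])
  fitted <- a + b * d
  resid <- y - fitted            # -Inf for zero-depth bins: discordant
  ss_tot <- sum((y[ok] - mean(y[ok]))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum((y[ok] - fitted[ok])^2) / ss_tot
  list(r2 = r2, heterogeneity = mean(!ok | abs(resid) > 1))
}

#' Drop unreliable growth estimates
#'
#' Keeps estimates that passed QC and whose strain-heterogeneity proxy does
#' not exceed `max_het` (estimates above 0.5 are likely distorted by
#' co-occurring strains).
#'
#' @param estimates A tibble of rows from [estimate_ptr()].
#' @param max_het Maximum tolerated heterogeneity, inclusive (default 0.5).
#' @return The retained rows.
#' @export
filter_heterogeneity <- function(estimates, max_het = 0.5) {
  require_columns(estimates, c("heterogeneity", "qc_pass"), "estimates")
  dplyr::filter(estimates, .data$qc_pass, .data$heterogeneity <= max_het)
}

#' Call actively growing species per study group
#'
#' Groups the (filtered) replication-score estimates by species, ISO group
#' and category, and tests each group with at least two estimates by a
#' one-sample, one-sided t-test of H1: mean score > 1. A species is called
#' growing when any of its groups is significant at `alpha`; a species with
#' no testable group is reported untestable. No multiple-testing correction
#' is applied.
#'
#' @param estimates Rows from [estimate_ptr()] (after
#'   [filter_heterogeneity()]), with `sample_id` and a `species` column
#'   (falling back to `genome_id`).
#' @param design A design tibble mapping `sample_id` to `iso_group` and
#'   `category`.
#' @param alpha Significance level (default 0.05).
#' @return A tibble of class `pp_growth_calls`: one row per tested
#'   (species, iso_group, category) with `n`, `mean_score`, `statistic`,
#'   `p.value`, `significant`; species-level calls via [growing_species()].
#' @export
call_growing_species <- function(estimates, design, alpha = 0.05) {
  est <- tibble::as_tibble(estimates)
  if (!"species" %in% names(est)) {
    est$species <- est$genome_id
  }
  require_columns(est, c("species", "sample_id", "score"), "estimates")
  validate_design(design)
  est <- dplyr::left_join(est, design[c("sample_id", "iso_group", "category")],
                          by = "sample_id")
  all_species <- unique(est$species)

  groups <- est |>
    dplyr::filter(is.finite(.data$score)) |>
    dplyr::group_by(.data$species, .data$iso_group, .data$category) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_score = mean(.data$score),
      statistic = one_sided_t(.data$score)$t,
      p.value = one_sided_t(.data$score)$p,
      .groups = "drop"
    ) |>
    dplyr::mutate(significant = .data$p.value < alpha)

  out <- groups
  attr(out, "alpha") <- alpha
  attr(out, "untestable") <- setdiff(all_species, groups$species)
  class(out) <- unique(c("pp_growth_calls", class(out)))
  out
}

# One-sample one-sided t vs mu = 1, with conventions for constant groups:
# constant at 1 -> (t = 0, p = 0.5); constant above 1 -> p = 0; below -> 1.
one_sided_t <- function(x, mu = 1) {
  if (sd(x) == 0) {
    delta <- mean(x) - mu
    t <- if (delta == 0) 0 else sign(delta) * Inf
    p <- if (delta == 0) 0.5 else if (delta > 0) 0 else 1
    return(list(t = t, p = p))
  }
  tt <- stats::t.test(x, mu = mu, alternative = "greater")
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Species-level growth calls
#'
#' @param calls A `pp_growth_calls` table from [call_growing_species()].
#' @return A tibble `species`, `n_groups`, `min_p`, `growing`, `untestable`
#'   (untestable species have no group with n >= 2 and `growing = NA`).
#' @export
growing_species <- function(calls) {
  alpha <- attr(calls, "alpha") %||% 0.05
  tested <- tibble::as_tibble(calls) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(n_groups = dplyr::n(), min_p = min(.data$p.value),
                     growing = any(.data$p.value < alpha), .groups = "drop") |>
    dplyr::mutate(untestable = FALSE)
  un <- attr(calls, "untestable") %||% character(0)
  if (length(un) > 0) {
    tested <- dplyr::bind_rows(
      tested,
      tibble::tibble(species = un, n_groups = 0L, min_p = NA_real_,
                     growing = NA, untestable = TRUE)
    )
  }
  dplyr::arrange(tested, .data$species)
}
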