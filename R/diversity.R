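# Alpha/beta diversity, prevalence, core-taxon overlap, rarefaction and
# QC-diversity correlations on filtered study tables.
#
# Diversity is always computed after taxonomic filtering, so "presence"
# below means a post-filter surviving assignment.

#' Expected species richness at a fixed read depth (analytic rarefaction)
#'
#' Exact expectation of the number of distinct taxa observed when `depth`
#' reads are drawn without replacement from the sample:
#' `E[S] = sum_t (1 - choose(N - n_t, d) / choose(N, d))`, with `N` the
#' total reads, `n_t` the reads of taxon t and `d` the depth. This removes
#' sequencing depth as a confounder of richness and, being deterministic,
#' replaces the single random subsample that "rarefying" often implies.
#'
#' @param profile A profile/study tibble (one sample) with `reads`; only rows
#'   at `rank` are used when a `rank` column is present.
#' @param depth Rarefaction depth in reads (default 1000).
#' @param rank Rank considered (default `"species"`).
#' @return Expected richness, or `NA` (with a warning) when the sample has
#'   fewer than `depth` reads -- such samples are excluded from group
#'   comparisons.
#' @export
rarefied_richness <- function(profile, depth = 1000, rank = "species") {
  stopifnot(depth >= 1)
  n <- profile_counts(profile, rank)
  rarefy_counts(n, depth)
}

profile_counts <- function(profile, rank = "species") {
  recs <- tibble::as_tibble(profile)
  require_columns(recs, "reads", "profile")
  if ("rank" %in% names(recs)) {
    recs <- recs[recs$rank == rank, , drop = FALSE]
  }
  if ("sample_id" %in% names(recs) &&
      length(unique(recs$sample_id)) > 1) {
    stop_analysis("expected a single-sample profile; got %d samples",
                  length(unique(recs$sample_id)))
  }
  n <- recs$reads
  n[n > 0]
}

rarefy_counts <- function(n, depth) {
  N <- sum(n)
  if (N == 0) {
    stop_analysis("rarefied richness is undefined for an empty profile")
  }
  if (N < depth) {
    warn(sprintf("sample has %d < %d reads; rarefied richness is NA", N, depth))
    return(NA_real_)
  }
  # log-space hypergeometric tail; lchoose(N - n, d) = -Inf when N - n < d
  sum(1 - exp(lchoose(N - n, depth) - lchoose(N, depth)))
}

#' Shannon entropy of species abundance (nats)
#'
#' `H = -sum p_t log(p_t)` over the relative read abundances of the sample's
#' species-rank taxa, in nats.
#'
#' @inheritParams rarefied_richness
#' @return Entropy in nats; errors on an empty profile.
#' @export
shannon_entropy <- function(profile, rank = "species") {
  n <- profile_counts(profile, rank)
  if (length(n) == 0) {
    stop_analysis("Shannon entropy is undefined for an empty profile")
  }
  p <- n / sum(n)
  -sum(p * log(p))
}

#' Per-sample alpha-diversity summary
#'
#' @param study A (filtered) study tibble.
#' @param depth Rarefaction depth (default 1000).
#' @param rank Rank considered (default `"species"`).
#' @return A tibble with one row per sample: `sample_id`, `n_reads`,
#'   `richness_obs`, `richness_rarefied` (NA when under-sequenced),
#'   `shannon`, plus design columns when available.
#' @export
diversity_summary <- function(study, depth = 1000, rank = "species") {
  recs <- tibble::as_tibble(study)
  recs <- recs[recs$rank == rank & recs$reads > 0, , drop = FALSE]
  out <- recs |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(
      n_reads = sum(.data$reads),
      richness_obs = dplyr::n(),
      richness_rarefied = suppressWarnings(rarefy_counts(.data$reads, depth)),
      shannon = {
        p <- .data$reads / sum(.data$reads)
        -sum(p * log(p))
      },
      .groups = "drop"
    )
  d <- tryCatch(study_design(study), error = function(e) NULL)
  if (!is.null(d)) {
    out <- dplyr::left_join(out, d, by = "sample_id")
  }
  out
}

#' Jaccard distance matrix on presence/absence profiles
#'
#' `d(i, j) = 1 - |A_i intersect A_j| / |A_i union A_j|` on the post-filter
#' presence sets of each pair of samples. Pairs of empty samples get distance
#' 0 with a warning.
#'
#' @param study A study tibble.
#' @param rank Rank considered (default `"species"`).
#' @return A symmetric distance matrix with zero diagonal.
#' @export
jaccard_matrix <- function(study, rank = "species") {
  pres <- study_matrix(study, value = "reads", rank = rank) > 0
  if (nrow(pres) < 2) {
    stop_analysis("need at least 2 samples for a distance matrix")
  }
  d <- as.matrix(vegan::vegdist(pres * 1, method = "jaccard", binary = TRUE))
  if (any(is.nan(d))) {
    warn("distance between empty samples set to 0")
    d[is.nan(d)] <- 0
  }
  diag(d) <- 0
  d
}

#' Two-dimensional ordination of a distance matrix
#'
#' Deterministic classical multidimensional scaling (`"mds"`, default) or
#' seeded non-metric MDS (`"nmds"`, via [vegan::monoMDS()]) of a sample
#' distance matrix. The deterministic default makes ordinations assertable;
#' stochastic embeddings of the UMAP family can be applied externally to the
#' exported distance matrix when a familiar visual is wanted.
#'
#' @param dist A symmetric distance matrix (or `dist`).
#' @param method `"mds"` or `"nmds"`.
#' @param seed Seed used for `"nmds"` (default 1).
#' @return A tibble `sample_id`, `axis1`, `axis2` of class `pp_ordination`.
#' @export
embed_2d <- function(dist, method = c("mds", "nmds"), seed = 1) {
  method <- match.arg(method)
  m <- as.matrix(dist)
  if (max(abs(m - t(m))) > 1e-8) {
    stop_validation("distance matrix is not symmetric")
  }
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  k <- min(2L, nrow(m) - 1L)
  pts <- if (method == "mds") {
    suppressWarnings(cmdscale(stats::as.dist(m), k = k))
  } else {
    withr::with_seed(seed, vegan::monoMDS(stats::as.dist(m), k = k)$points)
  }
  pts <- as.matrix(pts)
  while (ncol(pts) < 2) {
    pts <- cbind(pts, 0)
  }
  out <- tibble::tibble(sample_id = ids, axis1 = pts[, 1], axis2 = pts[, 2])
  attr(out, "method") <- method
  class(out) <- unique(c("pp_ordination", class(out)))
  out
}

#' Rarefaction curves by group
#'
#' Two complementary curves: `type = "samples"` gives the sample-accumulation
#' curve (expected number of unique taxa against the number of samples,
#' averaged over `n_perm` seeded random sample orderings); `type = "reads"`
#' gives the within-sample read-rarefaction curve (mean analytic
#' [rarefied_richness()] across the group's samples over a depth grid).
#'
#' @param study A study tibble with design columns.
#' @param group_vars Design columns defining the groups (default
#'   `"iso_group"`).
#' @param type `"samples"` or `"reads"`.
#' @param n_perm Random orderings for the accumulation curve (default 100).
#' @param depths Depth grid for `type = "reads"`; defaults to a log-spaced
#'   grid up to the largest sample.
#' @param seed Seed for the random orderings.
#' @param rank Rank considered.
#' @return A long tibble: group columns, `x` (samples or depth), `mean`,
#'   `sd`, `n`.
#' @export
rarefaction_curves <- function(study, group_vars = "iso_group",
                               type = c("samples", "reads"), n_perm = 100,
                               depths = NULL, seed = 1, rank = "species") {
  type <- match.arg(type)
  recs <- tibble::as_tibble(study)
  require_columns(recs, c(group_vars, "sample_id", "reads", "rank"),
                  "study table")
  recs <- recs[recs$rank == rank & recs$reads > 0, , drop = FALSE]
  groups <- dplyr::distinct(recs, dplyr::across(dplyr::all_of(group_vars)))
  if (nrow(groups) == 0) {
    stop_analysis("no non-empty groups to rarefy")
  }
  seeds <- split_seed(seed, nrow(groups))
  purrr::map_dfr(seq_len(nrow(groups)), function(g) {
    sub <- dplyr::semi_join(recs, groups[g, , drop = FALSE], by = group_vars)
    curve <- if (type == "samples") {
      accumulation_curve(sub, n_perm = n_perm, seed = seeds[g])
    } else {
      depth_curve(sub, depths = depths)
    }
    dplyr::bind_cols(groups[rep(g, nrow(curve)), , drop = FALSE], curve)
  })
}

accumulation_curve <- function(recs, n_perm, seed) {
  present <- split(recs$taxon_id, recs$sample_id)
  ns <- length(present)
  acc <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      ord <- sample.int(ns)
      seen <- integer(0)
      vapply(ord, function(j) {
        seen <<- union(seen, present[[j]])
        length(seen)
      }, numeric(1))
    }, numeric(ns))
  })
  acc <- matrix(acc, nrow = ns)
  tibble::tibble(x = seq_len(ns), mean = rowMeans(acc),
                 sd = apply(acc, 1, sd), n = ns)
}

depth_curve <- function(recs, depths = NULL) {
  counts <- split(recs$reads, recs$sample_id)
  if (is.null(depths)) {
    maxN <- max(vapply(counts, sum, numeric(1)))
    depths <- unique(round(10^seq(1, log10(maxN), length.out = 12)))
  }
  purrr::map_dfr(depths, function(d) {
    vals <- suppressWarnings(
      vapply(counts, function(n) rarefy_counts(n, d), numeric(1))
    )
    vals <- vals[!is.na(vals)]
    tibble::tibble(x = d,
                   mean = if (length(vals) > 0) mean(vals) else NA_real_,
                   sd = if (length(vals) > 1) sd(vals) else NA_real_,
                   n = length(vals))
  })
}

#' Per-taxon prevalence
#'
#' Fraction of the table's samples in which each taxon is detected
#' (post-filter presence). Filter the study table first to restrict to a
#' group, e.g. `study |> dplyr::filter(iso_group == "ISO-5") |> prevalence()`.
#'
#' @param study A study tibble (possibly pre-filtered to a group).
#' @param rank Rank considered.
#' @return A tibble `taxon_id`, `name`, `n_present`, `n_samples`,
#'   `prevalence`.
#' @export
prevalence <- function(study, rank = "species") {
  recs <- tibble::as_tibble(study)
  recs <- recs[recs$rank == rank & recs$reads > 0, , drop = FALSE]
  n_samples <- length(unique(recs$sample_id))
  if (n_samples == 0) {
    stop_analysis("prevalence is undefined for an empty group")
  }
  recs |>
    dplyr::group_by(.data$taxon_id, .data$name) |>
    dplyr::summarise(n_present = dplyr::n_distinct(.data$sample_id),
                     .groups = "drop") |>
    dplyr::mutate(n_samples = n_samples,
                  prevalence = .data$n_present / n_samples)
}

#' Taxa in the core of two groups
#'
#' Taxa whose prevalence reaches `min_prev` (inclusive) in **both** groups;
#' the operation is symmetric in its two arguments.
#'
#' @param study_a,study_b Study tibbles pre-filtered to the two groups.
#' @param min_prev Minimum prevalence in each group (default 0.9).
#' @param rank Rank considered.
#' @return A tibble `taxon_id`, `name`, `prevalence_a`, `prevalence_b`.
#' @export
shared_core_taxa <- function(study_a, study_b, min_prev = 0.9,
                             rank = "species") {
  pa <- prevalence(study_a, rank = rank)
  pb <- prevalence(study_b, rank = rank)
  dplyr::inner_join(
    dplyr::select(pa, "taxon_id", "name", prevalence_a = "prevalence"),
    dplyr::select(pb, "taxon_id", prevalence_b = "prevalence"),
    by = "taxon_id"
  ) |>
    dplyr::filter(.data$prevalence_a >= min_prev,
                  .data$prevalence_b >= min_prev) |>
    dplyr::arrange(.data$taxon_id)
}

#' Welch two-sample test on a diversity metric
#'
#' Two-sided Welch (unequal-variance) t-test comparing a per-sample metric
#' between two groups of samples. When both groups are constant with equal
#' means the statistic is 0 and p = 1 by convention.
#'
#' @param values_a,values_b Numeric vectors (each of length >= 2).
#' @return A one-row tibble: `mean_a`, `mean_b`, `statistic`, `p.value`,
#'   `direction` (sign of `mean_a - mean_b`).
#' @export
group_diversity_test <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop_analysis("each group needs at least 2 values")
  }
  if (sd(values_a) == 0 && sd(values_b) == 0) {
    delta <- mean(values_a) - mean(values_b)
    stat <- if (delta == 0) 0 else sign(delta) * Inf
    p <- if (delta == 0) 1 else 0
  } else {
    tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
    stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  tibble::tibble(
    mean_a = mean(values_a), mean_b = mean(values_b),
    statistic = stat, p.value = p,
    direction = sign(mean(values_a) - mean(values_b))
  )
}

#' Correlation between a QC metric and a diversity metric
#'
#' Pearson product-moment correlation across samples, used to check that
#' sequence-level QC statistics (k-mer entropy, singleton fraction, read
#' count) track post-filter taxonomic diversity.
#'
#' @param x,y Paired per-sample metrics (length >= 3, finite).
#' @return A one-row tibble `rho`, `n`, `statistic`, `p.value`; `rho` is NA
#'   with a warning when either input has zero variance.
#' @export
qc_diversity_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop_analysis("need >= 3 paired finite values")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop_analysis("inputs must be finite")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warn("zero variance: correlation undefined")
    return(tibble::tibble(rho = NA_real_, n = length(x),
                          statistic = NA_real_, p.value = NA_real_))
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(rho = unname(ct$estimate), n = length(x),
                 statistic = unname(ct$statistic), p.value = ct$p.value)
}
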