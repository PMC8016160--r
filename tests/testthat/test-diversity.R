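species_profile <- function(reads, sample_id = "s1") {
  tibble::tibble(
    sample_id = sample_id,
    taxon_id = seq_along(reads) + 10L,
    name = sprintf("Taxon sp%02d", seq_along(reads)),
    rank = "species",
    reads = as.integer(reads),
    unique_kmers = as.integer(reads) * 3L,
    marker_coverage = 0.01, dup = 1.2,
    rel_abundance = reads / sum(reads)
  )
}

presence_study <- function(sets) {
  design <- tibble::tibble(sample_id = names(sets), category = 1L,
                           iso_group = "ISO-6-8.5", is_control = FALSE)
  recs <- purrr::imap_dfr(sets, function(taxa, id) {
    if (length(taxa) == 0) return(tibble::tibble())
    tibble::tibble(sample_id = id, taxon_id = as.integer(taxa),
                   name = sprintf("t%d", taxa), rank = "species",
                   reads = 1000L, unique_kmers = 3000L,
                   marker_coverage = 0.01, dup = 1.2,
                   rel_abundance = 1 / length(taxa))
  })
  st <- dplyr::left_join(recs, design, by = "sample_id")
  attr(st, "design") <- design
  class(st) <- unique(c("pp_study", class(st)))
  st
}

test_that("analytic rarefaction honours its exact special cases", {
  expect_equal(rarefied_richness(species_profile(5000), depth = 1000), 1)
  prof <- species_profile(c(500, 300, 200))
  # drawing the whole sample recovers observed richness exactly
  expect_equal(rarefied_richness(prof, depth = 1000), 3, tolerance = 1e-12)
  expect_warning(v <- rarefied_richness(prof, depth = 1001), "NA")
  expect_true(is.na(v))
  expect_error(rarefied_richness(species_profile(integer(0))),
               class = "cleanroomr_analysis_error")
})

test_that("analytic rarefaction agrees with vegan and with Monte Carlo", {
  for (seed in 1:10) {
    prof <- random_profile(seed, total = 5000)
    analytic <- rarefied_richness(prof, depth = 1000)
    # independent closed-form implementation in vegan
    expect_equal(analytic,
                 suppressWarnings(
                   unname(vegan::rarefy(matrix(prof$reads, 1), 1000)[1])),
                 tolerance = 1e-8)
  }
  # Monte-Carlo oracle at reduced draw count (the full 10,000-draw check
  # runs in the acceptance suite)
  prof <- species_profile(c(3000, 1200, 500, 200, 60, 20, 12, 5, 2, 1))
  analytic <- rarefied_richness(prof, depth = 1000)
  draws <- withr::with_seed(99, {
    pool <- rep.int(seq_along(prof$reads), prof$reads)
    vapply(1:2000, function(i) {
      length(unique(pool[sample.int(length(pool), 1000)]))
    }, numeric(1))
  })
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(analytic - mean(draws)), 3 * se)
})

test_that("Shannon entropy matches hand-computed values in nats", {
  expect_equal(shannon_entropy(species_profile(rep(25, 4))), log(4),
               tolerance = 1e-12)
  expect_equal(shannon_entropy(species_profile(100)), 0)
  expect_equal(shannon_entropy(species_profile(c(50, 30, 20))),
               -(0.5 * log(0.5) + 0.3 * log(0.3) + 0.2 * log(0.2)),
               tolerance = 1e-12)
  expect_error(shannon_entropy(species_profile(integer(0))),
               class = "cleanroomr_analysis_error")
})

test_that("entropy never exceeds log richness on random profiles", {
  for (seed in 1:20) {
    prof <- random_profile(seed)
    H <- shannon_entropy(prof)
    expect_gte(H, 0)
    expect_lte(H, log(nrow(prof)) + 1e-12)
  }
})

test_that("Jaccard distances reproduce set arithmetic", {
  st <- presence_study(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(1, 2, 3),
                            d = c(7, 8)))
  d <- jaccard_matrix(st)
  expect_equal(d["a", "b"], 0.5)    # share 2 of 4
  expect_equal(d["a", "c"], 0)      # identical
  expect_equal(d["a", "d"], 1)      # disjoint
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 4))
})

test_that("Jaccard satisfies metric axioms on random binary tables", {
  for (seed in 1:20) {
    sets <- withr::with_seed(seed, {
      n <- sample(3:6, 1)
      setNames(lapply(seq_len(n), function(i) {
        which(runif(12) < 0.5)
      }), sprintf("s%d", seq_len(n)))
    })
    sets <- sets[vapply(sets, length, integer(1)) > 0]
    if (length(sets) < 3) next
    d <- jaccard_matrix(presence_study(sets))
    expect_equal(d, t(d))
    n <- nrow(d)
    for (i in 1:n) for (j in 1:n) for (k in 1:n) {
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
    }
  }
})

test_that("classical MDS preserves simple geometric structure", {
  # three equidistant samples embed as an equilateral triangle
  d <- matrix(1, 3, 3) - diag(3)
  rownames(d) <- colnames(d) <- c("a", "b", "c")
  xy <- embed_2d(d)
  seg <- as.matrix(stats::dist(cbind(xy$axis1, xy$axis2)))
  expect_equal(sd(seg[upper.tri(seg)]), 0, tolerance = 1e-9)

  # a duplicated sample lands on its twin
  st <- presence_study(list(a = 1:3, b = 1:3, c = 5:9))
  xy2 <- embed_2d(jaccard_matrix(st))
  pa <- unlist(xy2[xy2$sample_id == "a", c("axis1", "axis2")])
  pb <- unlist(xy2[xy2$sample_id == "b", c("axis1", "axis2")])
  expect_lt(sqrt(sum((pa - pb)^2)), 1e-6)

  asym <- d; asym[1, 2] <- 0.5
  expect_error(embed_2d(asym), class = "cleanroomr_validation_error")
})

test_that("a two-cluster design separates with positive silhouette", {
  sets <- c(
    setNames(lapply(1:5, function(i) c(1:8, 20 + i)), sprintf("u%d", 1:5)),
    setNames(lapply(1:5, function(i) c(101:108, 40 + i)), sprintf("v%d", 1:5))
  )
  st <- presence_study(sets)
  xy <- embed_2d(jaccard_matrix(st))
  lab <- rep(c(1, 2), each = 5)
  pts <- cbind(xy$axis1, xy$axis2)
  dd <- as.matrix(stats::dist(pts))
  sil <- vapply(1:10, function(i) {
    a <- mean(dd[i, lab == lab[i]][-which(which(lab == lab[i]) == i)])
    b <- mean(dd[i, lab != lab[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)
})

test_that("accumulation curves are monotone and saturate at the truth", {
  # every sample observes every taxon of a 15-taxon community eventually
  sets <- setNames(lapply(1:8, function(i) {
    withr::with_seed(i, which(runif(15) < 0.8))
  }), sprintf("s%d", 1:8))
  st <- presence_study(sets)
  cur <- rarefaction_curves(st, group_vars = "iso_group", type = "samples",
                            n_perm = 50, seed = 7)
  expect_true(all(diff(cur$mean) >= -1e-9))
  expect_lt(abs(tail(cur$mean, 1) - length(unique(unlist(sets)))), 0.75)

  one <- presence_study(list(solo = 1:5))
  cur1 <- rarefaction_curves(one, type = "samples", n_perm = 5, seed = 1)
  expect_equal(cur1$mean, 5)
})

test_that("read-rarefaction curves rise with depth toward observed richness", {
  design <- tibble::tibble(sample_id = "s1", category = 1L,
                           iso_group = "ISO-5", is_control = FALSE)
  prof <- species_profile(c(4000, 2000, 1000, 500, 250, 150, 100))
  st <- dplyr::left_join(prof, design, by = "sample_id")
  cur <- rarefaction_curves(st, group_vars = "iso_group", type = "reads",
                            depths = c(10, 100, 1000, 8000))
  expect_true(all(diff(cur$mean) > 0))
  expect_equal(tail(cur$mean, 1), 7, tolerance = 1e-9)
})

test_that("prevalence and core-taxon overlap follow their definitions", {
  st <- presence_study(list(a = c(1, 2), b = c(1, 2, 3), c = c(1, 3, 4),
                            d = c(1, 2, 3)))
  pr <- prevalence(st)
  expect_equal(pr$prevalence[pr$taxon_id == 1], 1)
  expect_equal(pr$prevalence[pr$taxon_id == 2], 0.75)
  expect_false(99 %in% pr$taxon_id)
  empty_group <- dplyr::filter(tibble::as_tibble(st), sample_id == "none")
  expect_error(prevalence(empty_group),
               class = "cleanroomr_analysis_error")

  ga <- presence_study(list(a1 = c(1, 2), a2 = c(1, 2), a3 = c(1, 2),
                            a4 = c(1, 2), a5 = c(1, 2), a6 = c(1, 2),
                            a7 = c(1, 2), a8 = c(1, 2), a9 = c(1, 2),
                            a10 = c(1, 3)))
  gb <- presence_study(list(b1 = c(1, 2), b2 = c(1, 2)))
  core <- shared_core_taxa(ga, gb, min_prev = 0.9)
  # taxon 1: prevalence (1.0, 1.0); taxon 2: (0.9, 1.0) boundary inclusive
  expect_setequal(core$taxon_id, c(1L, 2L))
  core_strict <- shared_core_taxa(ga, gb, min_prev = 0.91)
  expect_setequal(core_strict$taxon_id, 1L)
  # symmetry
  rev <- shared_core_taxa(gb, ga, min_prev = 0.9)
  expect_setequal(rev$taxon_id, core$taxon_id)
})

test_that("the Welch test matches a by-hand computation", {
  expect_equal(group_diversity_test(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  expect_equal(group_diversity_test(c(2, 2), c(2, 2))$statistic, 0)

  a <- c(19.8, 20.4, 19.6, 17.8, 18.5, 18.9, 18.3, 18.9, 19.5, 22.0)
  b <- c(28.2, 26.6, 20.1, 23.3, 25.2, 22.1, 17.7, 27.6, 20.6, 13.7)
  res <- group_diversity_test(a, b)
  # Welch statistic and df computed from first principles
  se <- sqrt(var(a) / 10 + var(b) / 10)
  tstat <- (mean(a) - mean(b)) / se
  df <- se^4 / ((var(a) / 10)^2 / 9 + (var(b) / 10)^2 / 9)
  expect_equal(res$statistic, tstat, tolerance = 1e-12)
  expect_equal(res$p.value, 2 * pt(abs(tstat), df, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$direction, -1)
})

test_that("a 2-sigma shift is detected with high power", {
  rejections <- vapply(1:200, function(seed) {
    withr::with_seed(seed, {
      a <- stats::rnorm(15, 0, 1)
      b <- stats::rnorm(15, 2, 1)
      group_diversity_test(a, b)$p.value < 0.05
    })
  }, logical(1))
  expect_gt(mean(rejections), 0.9)
})

test_that("QC-diversity correlation matches the product-moment formula", {
  expect_equal(qc_diversity_correlation(1:5, 2 * (1:5))$rho, 1)
  expect_equal(qc_diversity_correlation(1:5, -(1:5))$rho, -1)
  x <- c(1.2, 3.4, 2.2, 5.0, 4.1)
  y <- c(0.8, 2.9, 2.5, 4.2, 4.4)
  rho_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(qc_diversity_correlation(x, y)$rho, rho_hand,
               tolerance = 1e-12)
  expect_warning(res <- qc_diversity_correlation(c(1, 1, 1), 1:3),
                 "zero variance")
  expect_true(is.na(res$rho))
  expect_error(qc_diversity_correlation(1:2, 1:2),
               class = "cleanroomr_analysis_error")
})

test_that("the per-sample diversity summary is internally consistent", {
  st <- random_small_study(17)
  div <- diversity_summary(st, depth = 100)
  expect_equal(nrow(div), length(unique(tibble::as_tibble(st)$sample_id)))
  expect_true(all(div$richness_rarefied <= div$richness_obs + 1e-9,
                  na.rm = TRUE))
  expect_true(all(div$shannon >= 0))
  expect_true(all(c("iso_group", "is_control") %in% names(div)))
})
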