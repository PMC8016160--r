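# Helper: a study table from explicit per-sample (reads, kmers) triples.
study_from_rows <- function(rows, design) {
  recs <- rows |>
    dplyr::mutate(name = sprintf("Taxon sp%02d", .data$taxon_id),
                  rank = "species",
                  marker_coverage = pmin(1, .data$unique_kmers / 1e6),
                  dup = 1.5) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(rel_abundance = .data$reads / sum(.data$reads)) |>
    dplyr::ungroup() |>
    dplyr::left_join(design, by = "sample_id")
  attr(recs, "design") <- design
  class(recs) <- unique(c("pp_study", class(recs)))
  recs
}

two_group_design <- function(n_cases = 3, n_ctrl = 1) {
  tibble::tibble(
    sample_id = c(sprintf("case%d", seq_len(n_cases)),
                  sprintf("ctrl%d", seq_len(n_ctrl))),
    category = 1L,
    iso_group = c(rep("ISO-6-8.5", n_cases), rep("control", n_ctrl)),
    is_control = c(rep(FALSE, n_cases), rep(TRUE, n_ctrl))
  )
}

test_that("evidence thresholds classify the boundary cases exactly", {
  design <- two_group_design(8, 1)
  cases <- tibble::tribble(
    ~reads, ~unique_kmers, ~kept,
    256L,   1024L,         TRUE,   # ratio 4.0, both minima met
    255L,   4096L,         FALSE,  # reads one short
    256L,   1023L,         FALSE,  # k-mers one short
    1000L,  2000L,         FALSE,  # ratio 2.0 < 2.5
    1000L,  2500L,         TRUE,   # ratio exactly 2.5
    256L,   640L,          FALSE,  # ratio 2.5 but k-mers below 1024
    410L,   1024L,         FALSE,  # 1024/410 = 2.4976 just under 2.5
    100000L, 250000L,      TRUE    # large assignment, ratio 2.5
  )
  rows <- dplyr::bind_rows(purrr::map(seq_len(nrow(cases)), function(i) {
    tibble::tibble(sample_id = sprintf("case%d", i), taxon_id = 50L + i,
                   reads = cases$reads[i],
                   unique_kmers = cases$unique_kmers[i])
  }))
  st <- study_from_rows(rows, design)
  out <- apply_thresholds(st)
  surviving <- unique(tibble::as_tibble(out)$taxon_id)
  expect_setequal(surviving, 50L + which(cases$kept))
  expect_equal(nrow(filter_report(out)$removed_by_threshold),
               sum(!cases$kept))
})

test_that("thresholds are idempotent, monotone, and only remove content", {
  st <- random_small_study(42, max_taxa = 10, max_samples = 6)
  once <- apply_thresholds(st, filter_params(min_reads = 100,
                                             min_kmers = 50,
                                             min_kmer_per_read = 1))
  twice <- apply_thresholds(once, filter_params(min_reads = 100,
                                                min_kmers = 50,
                                                min_kmer_per_read = 1))
  expect_equal(plain_records(twice), plain_records(once))
  expect_true(all(tibble::as_tibble(once)$taxon_id %in%
                    tibble::as_tibble(st)$taxon_id))

  stricter <- apply_thresholds(st, filter_params(min_reads = 500,
                                                 min_kmers = 50,
                                                 min_kmer_per_read = 1))
  loose_keys <- with(tibble::as_tibble(once), paste(sample_id, taxon_id))
  strict_keys <- with(tibble::as_tibble(stricter), paste(sample_id, taxon_id))
  expect_true(all(strict_keys %in% loose_keys))
})

test_that("a record with k-mers but zero reads is rejected as inconsistent", {
  design <- two_group_design(1, 1)
  rows <- tibble::tibble(sample_id = "case1", taxon_id = 1L,
                         reads = 0L, unique_kmers = 10L)
  recs <- rows |>
    dplyr::mutate(name = "x", rank = "species", marker_coverage = 0,
                  dup = 1.5, rel_abundance = 0) |>
    dplyr::left_join(design, by = "sample_id")
  expect_error(apply_thresholds(recs),
               class = "cleanroomr_validation_error")
})

test_that("the 5x/2x control rule keeps and removes as specified", {
  design <- two_group_design(3, 2)
  base <- tibble::tibble(
    sample_id = c("ctrl1", "ctrl2", "case1", "case2", "case3"),
    taxon_id = 7L,
    reads = c(300L, 250L, 600L, 600L, 100L),
    unique_kmers = c(100L, 80L, 500L, 500L, 50L)
  )
  st <- study_from_rows(base, design)
  out <- control_contamination_filter(st, filter_params())
  # two case samples meet >= 5 x 100 markers and >= 2 x 300 reads exactly
  expect_true(7L %in% filter_report(out)$retained_despite_control)
  expect_true(7L %in% tibble::as_tibble(out)$taxon_id)

  weaker <- base
  weaker$unique_kmers[4] <- 499L  # second supporting sample drops out
  out2 <- control_contamination_filter(study_from_rows(weaker, design))
  expect_true(7L %in% filter_report(out2)$removed_as_contaminant)
  # removal applies everywhere, controls included
  expect_false(7L %in% tibble::as_tibble(out2)$taxon_id)
})

test_that("taxa never seen in a control are untouched", {
  design <- two_group_design(2, 1)
  rows <- tibble::tibble(
    sample_id = c("ctrl1", "case1", "case2"),
    taxon_id = c(1L, 1L, 2L),
    reads = c(500L, 100L, 800L),
    unique_kmers = c(1000L, 100L, 2000L)
  )
  out <- control_contamination_filter(study_from_rows(rows, design))
  kept <- tibble::as_tibble(out)
  expect_true(2L %in% kept$taxon_id)           # never in a control
  expect_false(1L %in% kept$taxon_id)          # no qualifying case support
  expect_error(
    control_contamination_filter(
      study_from_rows(rows[2:3, ], two_group_design(2, 0))),
    class = "cleanroomr_validation_error"
  )
})

test_that("control-rule decisions equal the brute-force oracle", {
  for (seed in 1:30) {
    st <- random_small_study(seed)
    out <- control_contamination_filter(st)
    rep <- filter_report(out)
    oracle <- oracle_control_filter(st)
    for (tid in names(oracle)) {
      if (oracle[[tid]]) {
        expect_true(as.integer(tid) %in% rep$retained_despite_control)
      } else {
        expect_true(as.integer(tid) %in% rep$removed_as_contaminant)
      }
    }
    # idempotence: a second pass removes nothing further
    again <- control_contamination_filter(out)
    expect_equal(plain_records(again), plain_records(out))
  }
})

test_that("replicate concordance behaves on identical and disjoint profiles", {
  design <- tibble::tibble(
    sample_id = sprintf("rep%d", 1:3), category = 5L,
    iso_group = "ISO-6-8.5", is_control = FALSE
  )
  a <- tibble::tibble(sample_id = "rep1", taxon_id = 1:4 * 10L,
                      reads = c(400L, 300L, 200L, 100L),
                      unique_kmers = c(1200L, 900L, 600L, 300L))
  b <- a; b$sample_id <- "rep2"
  c <- tibble::tibble(sample_id = "rep3", taxon_id = 1:4 * 10L + 1L,
                      reads = a$reads, unique_kmers = a$unique_kmers)
  st <- study_from_rows(dplyr::bind_rows(a, b, c), design)
  cc <- replicate_concordance(st, c("rep1", "rep2", "rep3"))
  expect_equal(cc$jaccard[cc$sample_a == "rep1" & cc$sample_b == "rep2"], 1)
  expect_equal(
    cc$pearson_log_abund[cc$sample_a == "rep1" & cc$sample_b == "rep2"], 1)
  expect_equal(cc$jaccard[cc$sample_a == "rep1" & cc$sample_b == "rep3"], 0)

  expect_warning(
    cc2 <- replicate_concordance(st, c("rep1", "rep2", "ghost")),
    "no surviving taxa")
  expect_equal(attr(cc2, "excluded"), "ghost")
  expect_error(
    suppressWarnings(replicate_concordance(st, c("rep1", "ghost"))),
    class = "cleanroomr_analysis_error")
})

test_that("replicates from one community stay concordant under noise", {
  design <- tibble::tibble(
    sample_id = sprintf("rep%d", 1:4), category = 5L,
    iso_group = "ISO-6-8.5", is_control = FALSE
  )
  base_p <- c(0.4, 0.25, 0.15, 0.1, 0.05, 0.05)
  profiles <- purrr::map(1:4, function(i) {
    r <- withr::with_seed(100 + i,
                          as.integer(rmultinom(1, 5000, base_p)))
    tibble::tibble(sample_id = sprintf("rep%d", i),
                   taxon_id = seq_along(base_p) * 10L,
                   reads = r, unique_kmers = r * 3L)
  })
  st <- study_from_rows(dplyr::bind_rows(profiles), design)
  cc <- replicate_concordance(st, design$sample_id)
  # all taxa are comfortably sampled at this depth, so profiles agree
  expect_gt(mean(cc$jaccard), 0.95)
  expect_gt(mean(cc$pearson_log_abund), 0.95)
})
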