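# Shared fixture builders. Everything is generated in code under fixed
# seeds; no binary fixtures exist.

# Record columns only, stripped of carried attributes, for equality checks.
plain_records <- function(st) {
  x <- as.data.frame(tibble::as_tibble(st))
  attr(x, "design") <- NULL
  attr(x, "filter_report") <- NULL
  rownames(x) <- NULL
  x
}

random_profile <- function(seed, sample_id = sprintf("P%03d", seed),
                           n_taxa = NULL, total = NULL) {
  withr::with_seed(seed, {
    if (is.null(n_taxa)) n_taxa <- sample(3:30, 1)
    if (is.null(total)) total <- sample(2000:8000, 1)
    reads <- as.integer(rmultinom(1, total, stats::rexp(n_taxa) + 0.05))
    keep <- reads > 0
    reads <- reads[keep]
    n <- length(reads)
    u <- pmax(1L, as.integer(round(reads * runif(n, 1, 4))))
    tibble::tibble(
      sample_id = sample_id,
      taxon_id = seq_len(n) + 100L,
      name = sprintf("Taxon sp%03d", seq_len(n)),
      rank = "species",
      reads = reads,
      unique_kmers = u,
      marker_coverage = pmin(1, u / 1e5),
      dup = pmax(1, runif(n, 1, 3)),
      rel_abundance = reads / sum(reads)
    )
  })
}

# A small random study table with controls, for oracle comparisons.
random_small_study <- function(seed, max_taxa = 10, max_samples = 6) {
  withr::with_seed(seed, {
    n_taxa <- sample(2:max_taxa, 1)
    n_samples <- sample(3:max_samples, 1)
    n_ctrl <- sample(1:(n_samples - 1), 1)
    design <- tibble::tibble(
      sample_id = sprintf("X%02d", seq_len(n_samples)),
      category = 1L,
      iso_group = c(rep("control", n_ctrl),
                    rep("ISO-6-8.5", n_samples - n_ctrl)),
      is_control = c(rep(TRUE, n_ctrl), rep(FALSE, n_samples - n_ctrl))
    )
    recs <- tidyr::expand_grid(sample_id = design$sample_id,
                               taxon_id = seq_len(n_taxa) + 10L) |>
      dplyr::mutate(
        name = sprintf("Taxon sp%02d", .data$taxon_id),
        rank = "species",
        reads = sample(0:2000, dplyr::n(), replace = TRUE),
        unique_kmers = as.integer(.data$reads *
                                    runif(dplyr::n(), 0.5, 6))
      ) |>
      dplyr::filter(.data$reads > 0) |>
      dplyr::mutate(marker_coverage = pmin(1, .data$unique_kmers / 1e5),
                    dup = 1.5) |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::mutate(rel_abundance = .data$reads / sum(.data$reads)) |>
      dplyr::ungroup() |>
      dplyr::left_join(design, by = "sample_id")
    st <- recs
    attr(st, "design") <- design
    class(st) <- unique(c("pp_study", class(st)))
    st
  })
}

# Independent brute-force oracle for the control-contamination rule:
# enumerates every (taxon, case sample) pair explicitly.
oracle_control_filter <- function(study, params = filter_params()) {
  recs <- as.data.frame(study)
  sp <- recs[recs$rank == "species", ]
  ctrl_ids <- unique(sp$sample_id[sp$is_control])
  case_ids <- setdiff(unique(recs$sample_id), ctrl_ids)
  decisions <- list()
  for (tid in sort(unique(sp$taxon_id[sp$sample_id %in% ctrl_ids]))) {
    U <- 0; R <- 0
    for (s in ctrl_ids) {
      row <- sp[sp$sample_id == s & sp$taxon_id == tid, ]
      if (nrow(row) == 1) {
        U <- max(U, row$unique_kmers)
        R <- max(R, row$reads)
      }
    }
    n_support <- 0
    for (s in case_ids) {
      row <- sp[sp$sample_id == s & sp$taxon_id == tid, ]
      if (nrow(row) == 1 &&
          row$unique_kmers >= params$marker_fold * U &&
          row$reads >= params$read_fold * R) {
        n_support <- n_support + 1
      }
    }
    decisions[[as.character(tid)]] <-
      n_support >= params$min_supporting_samples
  }
  decisions
}

# Brute-force canonical k-mer counter used as the oracle for count_kmers:
# per-read loop, Biostrings reverse complement, table() counting.
oracle_count_kmers <- function(seqs, k) {
  all <- character(0)
  for (s in seqs) {
    L <- nchar(s)
    if (L < k) next
    for (i in seq_len(L - k + 1)) {
      km <- substr(s, i, i + k - 1)
      if (grepl("[^ACGT]", km)) next
      rc <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(km)))
      all <- c(all, min(km, rc))
    }
  }
  if (length(all) == 0) return(integer(0))
  tab <- table(all)
  setNames(as.integer(tab), names(tab))
}

write_fastq <- function(path, seqs) {
  lines <- as.vector(rbind(sprintf("@r%d", seq_along(seqs)), seqs, "+",
                           vapply(seqs, function(s) strrep("I", nchar(s)),
                                  character(1), USE.NAMES = FALSE)))
  writeLines(lines, path)
  path
}

random_reads <- function(seed, n, len = 150, n_frac = 0) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      b <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      if (n_frac > 0) {
        b[runif(len) < n_frac] <- "N"
      }
      paste(b, collapse = "")
    }, character(1))
  })
}
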