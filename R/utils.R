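# Internal validators and small helpers shared across modules.

RANK_LEVELS <- c("species", "genus", "other")
ISO_LEVELS <- c("ISO-5", "ISO-6-8.5", "control")

PROFILE_COLS <- c(
  "sample_id", "taxon_id", "name", "rank", "reads", "unique_kmers",
  "marker_coverage", "dup", "rel_abundance"
)

stop_format <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "cleanroomr_format_error")
}

stop_validation <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "cleanroomr_validation_error")
}

stop_analysis <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "cleanroomr_analysis_error")
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_format("%s is missing mandatory column(s): %s", what,
                paste(missing, collapse = ", "))
  }
  invisible(df)
}

#' Validate a per-sample taxonomic profile table
#'
#' Checks the invariants of a profile tibble: non-negative read and k-mer
#' counts, marker coverage in \[0, 1\], mean marker copy number (`dup`) at
#' least 1 whenever marker k-mers were observed, unique taxon ids within each
#' sample, and species-level relative abundances summing to at most 1 per
#' sample.
#'
#' @param profile A tibble with columns `sample_id`, `taxon_id`, `name`,
#'   `rank`, `reads`, `unique_kmers`, `marker_coverage`, `dup`,
#'   `rel_abundance`.
#' @return The input, invisibly, if valid; otherwise an error is raised.
#' @export
validate_profile <- function(profile) {
  require_columns(profile, PROFILE_COLS, "profile table")
  if (nrow(profile) == 0) {
    return(invisible(profile))
  }
  if (any(profile$reads < 0, na.rm = TRUE) ||
      any(profile$unique_kmers < 0, na.rm = TRUE)) {
    stop_validation("negative read or unique k-mer counts are not allowed")
  }
  if (any(profile$marker_coverage < 0 | profile$marker_coverage > 1,
          na.rm = TRUE)) {
    stop_validation("marker_coverage must lie in [0, 1]")
  }
  bad_dup <- profile$unique_kmers > 0 & !is.na(profile$dup) &
    profile$dup < 1 - 1e-9
  if (any(bad_dup)) {
    stop_validation("dup must be >= 1 whenever unique_kmers > 0")
  }
  if (!all(profile$rank %in% RANK_LEVELS)) {
    stop_validation("rank must be one of: %s", paste(RANK_LEVELS, collapse = ", "))
  }
  dup_tax <- profile |>
    dplyr::count(.data$sample_id, .data$taxon_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup_tax) > 0) {
    stop_validation("duplicated taxon_id within sample(s): %s",
                    paste(unique(dup_tax$sample_id), collapse = ", "))
  }
  ra <- profile |>
    dplyr::filter(.data$rank == "species") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(s = sum(.data$rel_abundance, na.rm = TRUE),
                     .groups = "drop")
  if (any(ra$s > 1 + 1e-6)) {
    stop_validation("species-level rel_abundance sums above 1 in a sample")
  }
  invisible(profile)
}

#' Validate a study design table
#'
#' A design maps each sample to a sampling category (1--5), an ISO cleanroom
#' group (`ISO-5`, `ISO-6-8.5`, or `control`) and a negative-control flag.
#' Sample ids must be unique and the `control` ISO group must coincide with
#' `is_control`.
#'
#' @param design A tibble with columns `sample_id`, `category`, `iso_group`,
#'   `is_control`.
#' @return The input, invisibly, if valid.
#' @export
validate_design <- function(design) {
  require_columns(design, c("sample_id", "category", "iso_group", "is_control"),
                  "design table")
  if (anyDuplicated(design$sample_id) > 0) {
    dup <- design$sample_id[duplicated(design$sample_id)]
    stop_validation("duplicated sample_id in design: %s",
                    paste(unique(dup), collapse = ", "))
  }
  if (nrow(design) > 0) {
    if (!all(design$category %in% 1:5)) {
      stop_validation("category must be an integer in 1..5")
    }
    if (!all(design$iso_group %in% ISO_LEVELS)) {
      bad <- setdiff(unique(design$iso_group), ISO_LEVELS)
      stop_validation("unknown iso_group label(s): %s",
                      paste(bad, collapse = ", "))
    }
    if (!is.logical(design$is_control)) {
      stop_validation("is_control must be logical")
    }
    if (any(xor(design$is_control, design$iso_group == "control"))) {
      stop_validation("iso_group == 'control' must match is_control")
    }
  }
  invisible(design)
}

# Recompute species-level relative abundance per sample; other ranks get NA.
recompute_rel_abundance <- function(records) {
  records |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(
      rel_abundance = dplyr::if_else(
        .data$rank == "species",
        .data$reads / sum(.data$reads[.data$rank == "species"]),
        NA_real_
      )
    ) |>
    dplyr::ungroup()
}

# Reverse complement for plain character DNA (ACGT alphabet).
revcomp_chr <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgt", "TGCAtgca", x))
}

# Derive a stream of child seeds from one parent seed, staying within the
# 32-bit integer range so seeds remain portable.
split_seed <- function(seed, n) {
  (as.numeric(seed) * 7919 + 104729 * seq_len(n)) %% 2147483647
}
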