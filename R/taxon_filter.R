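# Two-stage taxon retention: per-assignment evidence thresholds, then the
# case-versus-control contamination decision rule.
#
# Stage 1 keeps a (sample, taxon) assignment only with >= 256 reads, >= 1024
# unique marker k-mers and >= 2.5 unique marker k-mers per read. Stage 2
# considers every taxon detected in at least one negative control: it is kept
# only if, in at least two case samples, it shows 5x the unique markers AND
# 2x the reads of the strongest control detection; otherwise it is discarded
# from every sample. Taxa never seen in a control are untouched. No
# abundance-based removal is performed.

#' Retention-filter parameters
#'
#' @param min_reads Minimum reads per assignment (default 256).
#' @param min_kmers Minimum unique marker k-mers per assignment (default 1024).
#' @param min_kmer_per_read Minimum unique-k-mers-to-reads ratio (default 2.5);
#'   ratios near 1 are a hallmark of false-positive assignments.
#' @param marker_fold Fold over the control maximum of unique markers required
#'   to rescue a control-detected taxon (default 5).
#' @param read_fold Fold over the control maximum of reads (default 2).
#' @param min_supporting_samples Number of case samples that must meet both
#'   folds simultaneously (default 2).
#' @return A `pp_filter_params` list.
#' @export
filter_params <- function(min_reads = 256, min_kmers = 1024,
                          min_kmer_per_read = 2.5, marker_fold = 5,
                          read_fold = 2, min_supporting_samples = 2) {
  p <- list(min_reads = min_reads, min_kmers = min_kmers,
            min_kmer_per_read = min_kmer_per_read, marker_fold = marker_fold,
            read_fold = read_fold,
            min_supporting_samples = min_supporting_samples)
  if (any(unlist(p) <= 0)) {
    stop_validation("all filter parameters must be strictly positive")
  }
  structure(p, class = "pp_filter_params")
}

new_filter_report <- function(removed_by_threshold = NULL,
                              control_taxa_seen = integer(0),
                              removed_as_contaminant = integer(0),
                              retained_despite_control = integer(0)) {
  structure(
    list(
      removed_by_threshold = removed_by_threshold %||%
        tibble::tibble(sample_id = character(0), taxon_id = integer(0),
                       reads = integer(0), unique_kmers = integer(0)),
      control_taxa_seen = control_taxa_seen,
      removed_as_contaminant = removed_as_contaminant,
      retained_despite_control = retained_despite_control
    ),
    class = "pp_filter_report"
  )
}

#' Extract the filter report attached by a filtering step
#'
#' @param study A study tibble returned by [apply_thresholds()] or
#'   [control_contamination_filter()].
#' @return A `pp_filter_report` (see [tidy.pp_filter_report()]), or `NULL`.
#' @export
filter_report <- function(study) {
  attr(study, "filter_report")
}

#' Apply per-assignment evidence thresholds
#'
#' A (sample, taxon) assignment at the target rank is kept iff
#' `reads >= min_reads` and `unique_kmers >= min_kmers` and
#' `unique_kmers / reads >= min_kmer_per_read`. Failing assignments are
#' dropped (equivalent to zeroing them in the dense view); rows of other
#' ranks pass through untouched. Species-level relative abundances are
#' recomputed over the survivors.
#'
#' @param study A study tibble from [merge_profiles()].
#' @param params A [filter_params()] object.
#' @param rank Rank at which the filter operates (default `"species"`).
#' @return The filtered study tibble, with a `pp_filter_report` in
#'   `attr(, "filter_report")`.
#' @export
apply_thresholds <- function(study, params = filter_params(),
                             rank = "species") {
  recs <- tibble::as_tibble(study)
  require_columns(recs, c("sample_id", "taxon_id", "rank", "reads",
                          "unique_kmers"), "study table")
  inconsistent <- recs$rank == rank & recs$reads == 0 & recs$unique_kmers > 0
  if (any(inconsistent)) {
    stop_validation("inconsistent record(s): unique_kmers > 0 with 0 reads")
  }
  target <- recs$rank == rank
  keep <- !target |
    (recs$reads >= params$min_reads &
       recs$unique_kmers >= params$min_kmers &
       recs$unique_kmers >= params$min_kmer_per_read * recs$reads)
  removed <- recs[target & !keep, c("sample_id", "taxon_id", "reads",
                                    "unique_kmers")]
  out <- recs[keep, , drop = FALSE] |> recompute_rel_abundance()
  out <- new_study(out, attr(study, "design"))
  attr(out, "filter_report") <- new_filter_report(
    removed_by_threshold = removed
  )
  out
}

#' Negative-control contamination rule
#'
#' For every taxon detected (post-threshold) in at least one control sample,
#' let `U*` and `R*` be the maximum unique-marker count and maximum read
#' count over all controls. The taxon is retained only if at least
#' `min_supporting_samples` case samples each show
#' `unique_kmers >= marker_fold * U*` **and** `reads >= read_fold * R*`
#' (both folds in the same sample, read inclusively). Otherwise the taxon is
#' removed from every sample, controls included. Taxa absent from all
#' controls are untouched.
#'
#' @param study A study tibble with design columns (from [merge_profiles()]),
#'   thresholds already applied.
#' @param params A [filter_params()] object.
#' @param rank Rank at which the rule operates (default `"species"`).
#' @param support Which samples may count as supporting: `"cases"` (default)
#'   or `"all"` (controls included).
#' @return The filtered study tibble with a `pp_filter_report` attribute.
#' @export
control_contamination_filter <- function(study, params = filter_params(),
                                         rank = "species",
                                         support = c("cases", "all")) {
  support <- match.arg(support)
  recs <- tibble::as_tibble(study)
  require_columns(recs, c("sample_id", "taxon_id", "rank", "reads",
                          "unique_kmers", "is_control"), "study table")
  design <- study_design(study)
  if (!any(design$is_control)) {
    stop_validation("contamination rule needs at least one control sample")
  }
  if (all(design$is_control)) {
    stop_validation("contamination rule needs at least one case sample")
  }

  sp <- recs[recs$rank == rank, , drop = FALSE]
  ctrl <- sp[sp$is_control, , drop = FALSE]
  control_taxa <- sort(unique(ctrl$taxon_id))

  decide <- function(tid) {
    U <- max(ctrl$unique_kmers[ctrl$taxon_id == tid])
    R <- max(ctrl$reads[ctrl$taxon_id == tid])
    cand <- sp[sp$taxon_id == tid, , drop = FALSE]
    if (support == "cases") {
      cand <- cand[!cand$is_control, , drop = FALSE]
    }
    ok <- cand$unique_kmers >= params$marker_fold * U &
      cand$reads >= params$read_fold * R
    length(unique(cand$sample_id[ok])) >= params$min_supporting_samples
  }
  retained <- control_taxa[purrr::map_lgl(control_taxa, decide)]
  removed <- setdiff(control_taxa, retained)

  keep <- !(recs$rank == rank & recs$taxon_id %in% removed)
  out <- recs[keep, , drop = FALSE] |> recompute_rel_abundance()
  out <- new_study(out, attr(study, "design"))
  attr(out, "filter_report") <- new_filter_report(
    control_taxa_seen = control_taxa,
    removed_as_contaminant = removed,
    retained_despite_control = retained
  )
  out
}

#' Concordance between technical replicates
#'
#' Compares the post-filter taxonomic profiles of replicate libraries of one
#' sample: pairwise Jaccard similarity of presence/absence and Pearson
#' correlation of log10 relative abundance over the taxon union (a small
#' pseudo-abundance stands in for absences). Replicates with no surviving
#' taxa are flagged and excluded, since a replicate can legitimately lose all
#' species to filtering.
#'
#' @param study A filtered study tibble.
#' @param replicate_ids Sample ids of the replicates (>= 2 usable required).
#' @param pseudo Pseudo relative abundance for absent taxa (default 1e-6).
#' @param rank Rank considered (default `"species"`).
#' @return A tibble `sample_a`, `sample_b`, `jaccard`, `pearson_log_abund`,
#'   with excluded replicate ids in `attr(, "excluded")`.
#' @export
replicate_concordance <- function(study, replicate_ids, pseudo = 1e-6,
                                  rank = "species") {
  recs <- tibble::as_tibble(study)
  recs <- recs[recs$rank == rank & recs$sample_id %in% replicate_ids &
                 recs$reads > 0, , drop = FALSE]
  present <- split(recs$taxon_id, recs$sample_id)
  usable <- replicate_ids[replicate_ids %in% names(present)]
  excluded <- setdiff(replicate_ids, usable)
  if (length(excluded) > 0) {
    warn(sprintf("replicate(s) with no surviving taxa excluded: %s",
                 paste(excluded, collapse = ", ")))
  }
  if (length(usable) < 2) {
    stop_analysis("fewer than 2 usable replicates after filtering")
  }
  ra <- split(setNames(recs$rel_abundance, recs$taxon_id), recs$sample_id)
  pairs <- utils::combn(usable, 2)
  out <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    sa <- present[[a]]; sb <- present[[b]]
    jac <- length(intersect(sa, sb)) / length(union(sa, sb))
    univ <- as.character(union(sa, sb))
    va <- log10(ifelse(is.na(ra[[a]][univ]), pseudo, ra[[a]][univ]))
    vb <- log10(ifelse(is.na(ra[[b]][univ]), pseudo, ra[[b]][univ]))
    r <- if (sd(va) == 0 || sd(vb) == 0) NA_real_ else cor(va, vb)
    tibble::tibble(sample_a = a, sample_b = b, jaccard = jac,
                   pearson_log_abund = r)
  })
  attr(out, "excluded") <- excluded
  out
}
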