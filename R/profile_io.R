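# Readers and writers for classified-read report tables and study designs.
#
# Two dialects are supported:
#   * "flat_tsv"     -- the package's native interchange format, a TSV with
#                       explicit headers (taxon_id, name, rank, reads,
#                       unique_kmers, marker_coverage, dup).
#   * "kraken_report" -- the 9-column KrakenUniq-style report
#                       (%, reads, taxReads, kmers, dup, cov, taxID, rank,
#                       taxName; '#'-prefixed comment lines; indented names).

FLAT_COLS <- c("taxon_id", "name", "rank", "reads", "unique_kmers",
               "marker_coverage", "dup")

#' Read a classified-read report into a per-sample profile
#'
#' Parses one sample's taxonomic report into a tidy profile tibble with one
#' row per taxon. Species-level relative abundance is computed from reads
#' assigned at species rank over the total species-level classified reads in
#' the sample (unclassified reads never enter the denominator).
#'
#' @param path Path to the report file.
#' @param dialect Either `"flat_tsv"` (native interchange TSV) or
#'   `"kraken_report"` (9-column classifier report with unique marker k-mer
#'   statistics).
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @param counts For the Kraken dialect, whether to use clade-inclusive
#'   (`"clade"`, default) or taxon-exclusive (`"taxon"`) read counts.
#' @return A tibble with columns `sample_id`, `taxon_id`, `name`, `rank`,
#'   `reads`, `unique_kmers`, `marker_coverage`, `dup`, `rel_abundance`.
#' @examples
#' p <- system.file("extdata", "example_profile.tsv", package = "cleanroomr")
#' read_report(p, sample_id = "demo")
#' @export
read_report <- function(path, dialect = c("flat_tsv", "kraken_report"),
                        sample_id = NULL, counts = c("clade", "taxon")) {
  dialect <- match.arg(dialect)
  counts <- match.arg(counts)
  if (!file.exists(path)) {
    stop_format("report file does not exist: %s", path)
  }
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))

  raw <- switch(dialect,
    flat_tsv = read_flat_tsv(path),
    kraken_report = read_kraken_report(path, counts)
  )

  profile <- raw |>
    dplyr::mutate(
      sample_id = sample_id,
      rank = ifelse(.data$rank %in% RANK_LEVELS, .data$rank, "other")
    ) |>
    recompute_rel_abundance() |>
    dplyr::select(dplyr::all_of(PROFILE_COLS))
  validate_profile(profile)
  profile
}

read_flat_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  require_columns(df, FLAT_COLS, sprintf("flat TSV report '%s'", path))
  coerce_numeric_rows(df, path)
}

read_kraken_report <- function(path, counts) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  df <- readr::read_tsv(I(paste(lines, collapse = "\n")),
                        col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  names(df) <- sub("^%$", "pct", names(df))
  kraken_cols <- c("reads", "taxReads", "kmers", "dup", "cov", "taxID",
                   "rank", "taxName")
  require_columns(df, kraken_cols, sprintf("kraken-style report '%s'", path))
  df |>
    dplyr::transmute(
      taxon_id = .data$taxID,
      name = trimws(.data$taxName),
      rank = .data$rank,
      reads = if (counts == "clade") .data$reads else .data$taxReads,
      unique_kmers = .data$kmers,
      marker_coverage = .data$cov,
      dup = .data$dup
    ) |>
    coerce_numeric_rows(path)
}

# Convert numeric columns from character, dropping rows that fail to parse
# (with a warning); negative counts are a hard validation error.
coerce_numeric_rows <- function(df, path) {
  num_cols <- c("taxon_id", "reads", "unique_kmers", "marker_coverage", "dup")
  out <- df |>
    dplyr::mutate(dplyr::across(dplyr::all_of(num_cols),
                                ~ suppressWarnings(as.numeric(.x))))
  bad <- !stats::complete.cases(out[num_cols])
  if (any(bad)) {
    warn(sprintf("%s: dropped %d row(s) with unparseable numeric fields",
                 basename(path), sum(bad)))
    out <- out[!bad, , drop = FALSE]
  }
  out |>
    dplyr::mutate(
      taxon_id = as.integer(.data$taxon_id),
      reads = as.integer(round(.data$reads)),
      unique_kmers = as.integer(round(.data$unique_kmers)),
      # classifier reports occasionally print coverage slightly above 1
      marker_coverage = pmin(.data$marker_coverage, 1)
    )
}

#' Write a profile as a flat TSV report
#'
#' The column order (`taxon_id`, `name`, `rank`, `reads`, `unique_kmers`,
#' `marker_coverage`, `dup`) is stable and readable by
#' [read_report()] with `dialect = "flat_tsv"`; reading back a written
#' profile reproduces it (relative abundance is recomputed on read).
#'
#' @param profile A profile tibble as returned by [read_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(profile, path) {
  validate_profile(profile)
  readr::write_tsv(profile[FLAT_COLS], path, progress = FALSE)
  invisible(path)
}

#' Load a study design table
#'
#' Reads a CSV with columns `sample_id`, `category` (1--5), `iso_group`
#' (`ISO-5`, `ISO-6-8.5` or `control`) and `is_control` (logical), and
#' validates it: duplicate sample ids and unknown ISO labels are errors.
#'
#' @param path Path to the design CSV.
#' @return A validated design tibble.
#' @export
load_design <- function(path) {
  if (!file.exists(path)) {
    stop_format("design file does not exist: %s", path)
  }
  design <- readr::read_csv(path, col_types = readr::cols(
    sample_id = "c", category = "i", iso_group = "c", is_control = "l"
  ), progress = FALSE)
  require_columns(design, c("sample_id", "category", "iso_group", "is_control"),
                  sprintf("design '%s'", path))
  if (nrow(design) == 0) {
    warn(sprintf("design '%s' is empty", path))
  }
  validate_design(design)
  design
}

#' Merge per-sample profiles with a study design
#'
#' Binds per-sample profile tables into one long study table and joins the
#' design columns (`category`, `iso_group`, `is_control`) onto every record.
#' Records are kept sparse: a (taxon, sample) pair absent from the table has
#' zero reads by construction; use [study_matrix()] for the dense taxa-by-
#' sample view with explicit zeros.
#'
#' @param profiles A list of profile tibbles (or a single profile).
#' @param design A design tibble covering every profiled sample.
#' @return A long study tibble of class `pp_study` carrying the design as an
#'   attribute.
#' @export
merge_profiles <- function(profiles, design) {
  if (is.data.frame(profiles)) {
    profiles <- list(profiles)
  }
  validate_design(design)
  purrr::walk(profiles, validate_profile)
  ids <- purrr::map_chr(profiles, ~ unique(.x$sample_id)[1] %||% NA_character_)
  ids <- ids[!is.na(ids)]
  if (anyDuplicated(ids) > 0) {
    stop_validation("duplicate sample profile(s): %s",
                    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  missing <- setdiff(ids, design$sample_id)
  if (length(missing) > 0) {
    stop_validation("profile sample_id(s) missing from design: %s",
                    paste(missing, collapse = ", "))
  }
  records <- dplyr::bind_rows(profiles) |>
    dplyr::left_join(design, by = "sample_id")
  new_study(records, design)
}

new_study <- function(records, design = attr(records, "design")) {
  out <- tibble::as_tibble(records)
  attr(out, "design") <- design
  class(out) <- unique(c("pp_study", class(out)))
  out
}

#' Extract the design attached to a study table
#'
#' Falls back to reconstructing a design from the study's own columns when
#' the attribute has been dropped by data-frame manipulation.
#'
#' @param study A study tibble from [merge_profiles()].
#' @return A design tibble.
#' @export
study_design <- function(study) {
  d <- attr(study, "design")
  if (!is.null(d)) {
    return(d)
  }
  require_columns(study, c("sample_id", "category", "iso_group", "is_control"),
                  "study table")
  dplyr::distinct(tibble::as_tibble(study), .data$sample_id, .data$category,
                  .data$iso_group, .data$is_control)
}

#' Dense sample-by-taxon matrix from a study table
#'
#' @param study A study tibble.
#' @param value Which field to spread: `"reads"` (default), `"unique_kmers"`
#'   or `"rel_abundance"`.
#' @param rank Taxonomic rank to include (default `"species"`).
#' @param all_samples If `TRUE` (default) include design samples with no
#'   surviving records as all-zero rows.
#' @return A numeric matrix, samples in rows, taxa (ids) in columns. Absent
#'   (taxon, sample) pairs are 0.
#' @export
study_matrix <- function(study, value = "reads", rank = "species",
                         all_samples = TRUE) {
  stopifnot(value %in% c("reads", "unique_kmers", "rel_abundance"))
  recs <- dplyr::filter(tibble::as_tibble(study), .data$rank == !!rank)
  samples <- unique(recs$sample_id)
  if (all_samples) {
    d <- tryCatch(study_design(study), error = function(e) NULL)
    if (!is.null(d)) samples <- union(samples, d$sample_id)
  }
  taxa <- sort(unique(recs$taxon_id))
  m <- matrix(0, nrow = length(samples), ncol = length(taxa),
              dimnames = list(samples, as.character(taxa)))
  if (nrow(recs) > 0) {
    m[cbind(match(recs$sample_id, samples),
            match(recs$taxon_id, taxa))] <- recs[[value]]
  }
  m
}

#' Write a merged study table as wide CSV matrices
#'
#' Writes the taxa-by-sample read-count matrix and the parallel unique-k-mer
#' matrix (taxa in rows, samples in columns).
#'
#' @param study A study tibble.
#' @param dir Output directory (created if needed).
#' @return Paths of the two files, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(reads = file.path(dir, "study_reads.csv"),
             kmers = file.path(dir, "study_unique_kmers.csv"))
  for (v in c("reads", "unique_kmers")) {
    m <- t(study_matrix(study, value = v))
    df <- tibble::as_tibble(m, rownames = "taxon_id")
    readr::write_csv(df, paths[[if (v == "reads") "reads" else "kmers"]],
                     progress = FALSE)
  }
  invisible(paths)
}
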