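# Orchestration: configuration and the end-to-end run stringing all stages
# into one workflow (k-mer QC -> merge -> thresholds -> control rule ->
# diversity -> trait annotation -> growth calls), with a checksummed output
# manifest. Optional inputs (FASTQ, coverage tracks, trait directory) skip
# their stage with a logged notice. The package's functions are the
# programmatic interface; `run_all()` is the one-call pipeline over a
# directory of inputs.

#' Build a run configuration
#'
#' Every threshold of the retention and growth procedures appears as a named
#' key with its standard default. Paths may be `NULL` to skip optional
#' stages.
#'
#' @param reports_dir Directory of per-sample report TSVs.
#' @param design Path to the design CSV.
#' @param out_dir Output directory.
#' @param fastq_dir Optional directory of FASTQ files for k-mer QC.
#' @param coverage_dir Optional directory of coverage-track TSVs, named
#'   `<species>__<sample_id>.tsv`.
#' @param trait_directory Optional trait-directory TSV (defaults to the
#'   bundled fixture).
#' @param dialect Report dialect (see [read_report()]).
#' @param params A [filter_params()] object.
#' @param diversity_depth Rarefaction depth (default 1000).
#' @param alpha Growth-call significance level (default 0.05).
#' @param max_het Maximum strain heterogeneity (default 0.5).
#' @param kmer_k K-mer length for QC (default 31).
#' @param seed Seed for the stochastic stages.
#' @return A `pp_run_config` list.
#' @export
run_config <- function(reports_dir, design, out_dir,
                       fastq_dir = NULL, coverage_dir = NULL,
                       trait_directory = NULL,
                       dialect = "flat_tsv", params = filter_params(),
                       diversity_depth = 1000, alpha = 0.05, max_het = 0.5,
                       kmer_k = 31, seed = 1) {
  cfg <- list(reports_dir = reports_dir, design = design, out_dir = out_dir,
              fastq_dir = fastq_dir, coverage_dir = coverage_dir,
              trait_directory = trait_directory, dialect = dialect,
              params = params, diversity_depth = diversity_depth,
              alpha = alpha, max_het = max_het, kmer_k = kmer_k, seed = seed)
  for (p in c("reports_dir", "design")) {
    if (!file.exists(cfg[[p]])) {
      stop_validation("config path '%s' does not exist: %s", p, cfg[[p]])
    }
  }
  structure(cfg, class = "pp_run_config")
}

#' Load a run configuration from a YAML file
#'
#' Flat key-value YAML whose keys mirror the arguments of [run_config()];
#' filter thresholds go under `min_reads`, `min_kmers`, `min_kmer_per_read`,
#' `marker_fold`, `read_fold`, `min_supporting_samples`.
#'
#' @param path Path to the YAML file.
#' @return A `pp_run_config` list.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  fp_keys <- names(formals(filter_params))
  fp <- do.call(filter_params, y[intersect(names(y), fp_keys)])
  args <- y[setdiff(names(y), fp_keys)]
  args$params <- fp
  do.call(run_config, args)
}

pipeline_log <- function(fmt, ...) {
  message(sprintf("[cleanroomr] %s", sprintf(fmt, ...)))
}

#' Run the full pipeline
#'
#' Executes, in order: k-mer QC (if FASTQ given), report reading and merge,
#' evidence thresholds, the negative-control contamination rule, the
#' diversity suite (alpha summary, Jaccard distances, MDS ordination,
#' prevalence), trait annotation (if a directory is available) and growth
#' calls (if coverage tracks are given). Each stage logs its input/output
#' row counts; a stage failure aborts with the stage name, retaining the
#' outputs already written. A manifest of every output file with its MD5
#' checksum is written last.
#'
#' @param config A `pp_run_config` from [run_config()] or [load_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest tibble.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pp_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(df, name) {
    p <- file.path(config$out_dir, name)
    readr::write_csv(tibble::as_tibble(df), p, progress = FALSE)
    outputs <<- c(outputs, p)
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            class = "cleanroomr_stage_error")
    })
  }
  results <- list()

  # -- k-mer QC ---------------------------------------------------------
  if (!is.null(config$fastq_dir)) {
    results$kmer_qc <- stage("kmer_qc", {
      fq <- list.files(config$fastq_dir, pattern = "\\.(fastq|fq)(\\.gz)?$",
                       full.names = TRUE)
      qc <- kmer_qc_summary(fq, k = config$kmer_k)
      pipeline_log("kmer_qc: %d samples", nrow(qc))
      emit(qc, "kmer_qc.csv")
      qc
    })
  } else {
    pipeline_log("kmer_qc: no FASTQ directory given, stage skipped")
  }

  # -- merge ------------------------------------------------------------
  study <- stage("merge", {
    design <- load_design(config$design)
    files <- list.files(config$reports_dir, pattern = "\\.tsv$",
                        full.names = TRUE)
    profiles <- purrr::map(files, read_report, dialect = config$dialect)
    st <- merge_profiles(profiles, design)
    pipeline_log("merge: %d samples, %d records", length(files), nrow(st))
    st
  })
  results$design <- study_design(study)

  # -- filters ----------------------------------------------------------
  study <- stage("thresholds", {
    out <- apply_thresholds(study, config$params)
    rep <- filter_report(out)
    pipeline_log("thresholds: %d -> %d records (%d assignments removed)",
                 nrow(study), nrow(out), nrow(rep$removed_by_threshold))
    emit(tidy(rep), "threshold_report.csv")
    out
  })
  study <- stage("control_filter", {
    out <- control_contamination_filter(study, config$params)
    rep <- filter_report(out)
    pipeline_log("control_filter: %d control taxa seen, %d removed, %d kept",
                 length(rep$control_taxa_seen),
                 length(rep$removed_as_contaminant),
                 length(rep$retained_despite_control))
    emit(tidy(rep), "contamination_report.csv")
    out
  })
  results$study <- study
  emit(study, "filtered_study.csv")
  stage("matrices", write_study(study, config$out_dir))
  outputs <- c(outputs, file.path(config$out_dir,
                                  c("study_reads.csv",
                                    "study_unique_kmers.csv")))

  # -- diversity --------------------------------------------------------
  results$diversity <- stage("diversity", {
    div <- diversity_summary(study, depth = config$diversity_depth)
    emit(div, "diversity.csv")
    dmat <- jaccard_matrix(study)
    emit(tibble::as_tibble(dmat, rownames = "sample_id"),
         "jaccard_distance.csv")
    ord <- embed_2d(dmat, seed = config$seed)
    emit(ord, "ordination.csv")
    prev <- prevalence(study)
    emit(prev, "prevalence.csv")
    pipeline_log("diversity: %d samples summarised", nrow(div))
    list(summary = div, distance = dmat, ordination = ord,
         prevalence = prev)
  })

  # -- trait annotation -------------------------------------------------
  results$traits <- stage("traits", {
    dir_tbl <- read_trait_directory(config$trait_directory)
    taxa <- tibble::as_tibble(study) |>
      dplyr::filter(.data$rank == "species") |>
      dplyr::distinct(species = .data$name) |>
      dplyr::mutate(genus = vapply(strsplit(.data$species, " "), `[`,
                                   character(1), 1))
    ann <- annotate_taxa(taxa, dir_tbl)
    pipeline_log("traits: %d taxa annotated", nrow(taxa))
    emit(ann, "trait_annotation.csv")
    ann
  })

  # -- growth -----------------------------------------------------------
  if (!is.null(config$coverage_dir)) {
    results$growth <- stage("growth", {
      files <- list.files(config$coverage_dir, pattern = "\\.tsv$",
                          full.names = TRUE)
      est <- purrr::map_dfr(files, function(f) {
        parts <- strsplit(sub("\\.tsv$", "", basename(f)), "__")[[1]]
        e <- estimate_ptr(read_coverage_track(f),
                          sample_id = parts[min(2, length(parts))])
        e$species <- parts[1]
        e
      })
      emit(est, "growth_estimates.csv")
      kept <- filter_heterogeneity(est, max_het = config$max_het)
      calls <- call_growing_species(kept, results$design,
                                    alpha = config$alpha)
      emit(calls, "growth_calls.csv")
      emit(growing_species(calls), "growth_species.csv")
      pipeline_log("growth: %d/%d estimates pass QC, %d species growing",
                   nrow(kept), nrow(est),
                   sum(growing_species(calls)$growing, na.rm = TRUE))
      list(estimates = est, calls = calls)
    })
  } else {
    pipeline_log("growth: no coverage directory given, stage skipped")
  }

  # -- manifest ---------------------------------------------------------
  manifest <- tibble::tibble(
    file = basename(outputs),
    md5 = unname(tools::md5sum(outputs)),
    bytes = file.size(outputs)
  )
  readr::write_csv(manifest, file.path(config$out_dir, "manifest.csv"),
                   progress = FALSE)
  results$manifest <- manifest
  pipeline_log("done: %d output files", nrow(manifest))
  invisible(results)
}
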