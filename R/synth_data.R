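# Seeded synthetic-data generators emulating every input the pipeline
# consumes: study designs, classified-read reports with marker-saturation
# behaviour, contaminant structure, coverage tracks with known replication
# rates, FASTQ reads, and trait/gene/genome-quality fixtures.
#
# Unique-marker counts follow a collector's curve: with M marker k-mers in a
# taxon's reference set and about m observable markers per read, r reads
# reveal u = M * (1 - (1 - 1/M)^(m r)) distinct markers in expectation
# (an urn model with replacement over marker draws). Genuine taxa are
# simulated with m >= 2.5 markers per read; false-positive-like taxa with
# m ~ 1, reproducing the diagnostic that a unique-k-mers-per-read ratio
# near 1 flags a dubious assignment.

GENUS_POOL <- c("Bacillus", "Staphylococcus", "Micrococcus", "Paracoccus",
                "Pseudomonas", "Acinetobacter", "Cutibacterium", "Kocuria",
                "Sphingomonas", "Methylobacterium", "Curtobacterium",
                "Brevundimonas", "Stenotrophomonas", "Moraxella",
                "Geodermatophilus", "Ramlibacter", "Flavobacterium",
                "Streptococcus", "Corynebacterium", "Deinococcus")

#' Simulate a study design
#'
#' Builds a cleanroom sampling design with five sample categories, an ISO
#' split within each category, and flagged negative controls. The defaults
#' mirror a 51-sample campaign: category sizes 12, 12, 10, 10, 5 (cases and
#' within-category controls) plus buffer controls. Construction is
#' deterministic given the counts.
#'
#' @param n_cases Cases per category 1..5 (default `c(10, 10, 8, 10, 5)`).
#' @param n_iso5 How many of each category's cases are ISO-5 (default
#'   `c(5, 3, 6, 5, 0)`); the rest are ISO-6-8.5.
#' @param n_category_controls Controls per category (default
#'   `c(2, 2, 2, 0, 0)`).
#' @param n_buffer_controls Extra buffer controls (default 2).
#' @return A design tibble (`sample_id`, `category`, `iso_group`,
#'   `is_control`).
#' @export
simulate_design <- function(n_cases = c(10, 10, 8, 10, 5),
                            n_iso5 = c(5, 3, 6, 5, 0),
                            n_category_controls = c(2, 2, 2, 0, 0),
                            n_buffer_controls = 2) {
  stopifnot(length(n_cases) == 5, length(n_iso5) == 5,
            length(n_category_controls) == 5, all(n_iso5 <= n_cases),
            all(n_cases >= 0), n_buffer_controls >= 0)
  rows <- purrr::map_dfr(1:5, function(cat) {
    iso <- c(rep("ISO-5", n_iso5[cat]),
             rep("ISO-6-8.5", n_cases[cat] - n_iso5[cat]))
    cases <- tibble::tibble(
      sample_id = sprintf("S%d-%02d", cat, seq_len(n_cases[cat])),
      category = cat, iso_group = iso, is_control = FALSE
    )
    ctrls <- tibble::tibble(
      sample_id = sprintf("C%d-%02d", cat,
                          seq_len(n_category_controls[cat])),
      category = cat, iso_group = "control", is_control = TRUE
    )
    dplyr::bind_rows(cases, ctrls)
  })
  buffer <- tibble::tibble(
    sample_id = sprintf("BUF-%02d", seq_len(n_buffer_controls)),
    category = 1L, iso_group = "control", is_control = TRUE
  )
  out <- dplyr::bind_rows(rows, buffer) |>
    dplyr::mutate(category = as.integer(.data$category))
  validate_design(out)
  out
}

#' Simulate a community with known ground truth
#'
#' Creates a taxon table with planted structure recoverable by the pipeline:
#' * `n_contaminants` laboratory contaminants, strong in controls and at
#'   comparable levels in cases -- they must **fail** the 5x-markers /
#'   2x-reads rescue rule;
#' * `n_shared` genuine residents that also appear (weakly) in controls but
#'   far exceed both folds in cases -- they must be **retained**;
#' * `n_control_only` reagent-style taxa present only in controls;
#' * `n_false_positive` taxa with ~1 marker per read (ratio-threshold bait);
#' * the remainder are ordinary residents absent from controls, with
#'   log-normal case abundances.
#'
#' A subset of taxa (`growing_fraction`) gets a true peak-to-trough ratio
#' drawn from `ptr_range`; the rest are static (PTR 1). Trait flags are
#' seeded Bernoulli draws.
#'
#' @param n_taxa Total taxa (default 60).
#' @param n_contaminants,n_shared,n_control_only,n_false_positive Planted
#'   group sizes (defaults 5, 5, 3, 0).
#' @param marker_set_size Marker k-mers per taxon reference set (M, default
#'   2e5).
#' @param markers_per_read Observable markers per read for genuine taxa (m,
#'   default 3).
#' @param growing_fraction Fraction of taxa with true PTR > 1 (default 0.2).
#' @param ptr_range Range of true PTR for growing taxa (default
#'   `c(1.2, 3)`).
#' @param seed Seed.
#' @return A truth tibble with one row per taxon: identifiers, case/control
#'   abundances, marker parameters, `is_contaminant`, `true_ptr`,
#'   `genome_length` and trait flags.
#' @export
simulate_community <- function(n_taxa = 60, n_contaminants = 5, n_shared = 5,
                               n_control_only = 3, n_false_positive = 0,
                               marker_set_size = 2e5, markers_per_read = 3,
                               growing_fraction = 0.2, ptr_range = c(1.2, 3),
                               seed = 1) {
  n_normal <- n_taxa - n_contaminants - n_shared - n_control_only -
    n_false_positive
  stopifnot(n_normal >= 0)
  withr::with_seed(seed, {
    role <- c(rep("contaminant", n_contaminants), rep("shared", n_shared),
              rep("control_only", n_control_only),
              rep("false_positive", n_false_positive),
              rep("normal", n_normal))
    genus <- sample(GENUS_POOL, n_taxa, replace = TRUE)
    name <- sprintf("%s synthetica%02d", genus, seq_len(n_taxa))

    # case-side abundance budget: contaminants 0.15, shared 0.20,
    # false positives 0.05 (when present), remainder to normal residents
    case_ab <- numeric(n_taxa)
    case_ab[role == "contaminant"] <- 0.15 / max(1, n_contaminants)
    case_ab[role == "shared"] <- 0.20 / max(1, n_shared)
    case_ab[role == "false_positive"] <- 0.05 / max(1, n_false_positive)
    rest <- 1 - sum(case_ab)
    w <- stats::rlnorm(n_normal, meanlog = 0, sdlog = 1)
    case_ab[role == "normal"] <- rest * w / sum(w)

    # control-side budget: contaminants 0.60, shared residents 0.05,
    # control-only fillers the rest; ordinary residents are absent
    ctrl_ab <- numeric(n_taxa)
    ctrl_ab[role == "contaminant"] <- 0.60 / max(1, n_contaminants)
    ctrl_ab[role == "shared"] <- 0.05 / max(1, n_shared)
    if (n_control_only > 0) {
      ctrl_ab[role == "control_only"] <-
        (1 - sum(ctrl_ab)) / n_control_only
    } else if (n_contaminants > 0) {
      ctrl_ab[role == "contaminant"] <-
        ctrl_ab[role == "contaminant"] +
        (1 - sum(ctrl_ab)) / n_contaminants
    }

    growing <- runif(n_taxa) < growing_fraction
    true_ptr <- ifelse(growing, runif(n_taxa, ptr_range[1], ptr_range[2]), 1)

    tibble::tibble(
      taxon_id = seq_len(n_taxa) + 1000L,
      name = name, genus = genus, rank = "species", role = role,
      case_abundance = case_ab, control_abundance = ctrl_ab,
      marker_set_size = marker_set_size,
      markers_per_read = ifelse(role == "false_positive", 1,
                                markers_per_read),
      genome_length = round(runif(n_taxa, 2e6, 6e6)),
      is_contaminant = role %in% c("contaminant", "control_only"),
      true_ptr = true_ptr,
      spore_forming = runif(n_taxa) < 0.3,
      radiophile = runif(n_taxa) < 0.15,
      psychrophile = runif(n_taxa) < 0.15,
      desiccation_resistant = runif(n_taxa) < 0.2
    )
  })
}

#' Simulate classified-read reports for a whole study
#'
#' Per sample, reads are multinomial over the truth's case (or control)
#' abundance vector; unique marker k-mers follow the collector's curve
#' `u = M (1 - (1 - 1/M)^(m r))`, duplication is `m r / u` and marker
#' coverage `u / M`. Sampling is seeded hierarchically per sample, so adding
#' a sample never perturbs another sample's draws. Reads are conserved:
#' each sample's records sum to its total.
#'
#' @param truth A truth tibble from [simulate_community()]; case and control
#'   abundance vectors must each sum to 1 (+- 1e-9).
#' @param design A design tibble from [simulate_design()].
#' @param case_reads,control_reads Total classified reads per case/control
#'   sample (defaults 1e5 and 5e4).
#' @param seed Seed.
#' @return A study tibble (class `pp_study`) in the same shape as
#'   [merge_profiles()] output.
#' @export
simulate_reports <- function(truth, design, case_reads = 1e5,
                             control_reads = 5e4, seed = 1) {
  validate_design(design)
  for (col in c("case_abundance", "control_abundance")) {
    s <- sum(truth[[col]])
    if (abs(s - 1) > 1e-9) {
      stop_validation("%s sums to %.12f, not 1", col, s)
    }
  }
  seeds <- split_seed(seed, nrow(design))
  profiles <- purrr::map(seq_len(nrow(design)), function(i) {
    ctrl <- design$is_control[i]
    p <- if (ctrl) truth$control_abundance else truth$case_abundance
    total <- if (ctrl) control_reads else case_reads
    r <- withr::with_seed(seeds[i], as.integer(rmultinom(1, total, p)))
    keep <- r > 0
    m <- truth$markers_per_read[keep]
    M <- truth$marker_set_size[keep]
    rr <- r[keep]
    u <- pmax(1L, as.integer(round(M * (1 - exp(m * rr * log1p(-1 / M))))))
    tibble::tibble(
      sample_id = design$sample_id[i],
      taxon_id = truth$taxon_id[keep],
      name = truth$name[keep],
      rank = truth$rank[keep],
      reads = rr,
      unique_kmers = u,
      marker_coverage = u / M,
      dup = pmax(1, m * rr / u),
      rel_abundance = rr / sum(rr)
    )
  })
  merge_profiles(profiles, design)
}

#' Simulate a binned coverage track with known replication rate
#'
#' Bin depths are proportional to `2^(-a d(x))` where `d(x)` is the circular
#' distance from the replication origin normalised to 1 at the antipode and
#' `2^a` is the true peak-to-trough ratio; the track is scaled to the
#' requested mean depth. With `noise = "poisson"`, per-bin read counts are
#' Poisson draws at the corresponding expectation. With the origin on a bin
#' anchor and an even number of bins, the noiseless peak/trough depth ratio
#' equals `true_ptr` exactly.
#'
#' @param genome_id Genome identifier.
#' @param genome_length Genome length in bp (default 3e6).
#' @param true_ptr True peak-to-trough ratio (>= 1).
#' @param mean_depth Mean fold-coverage (> 0, default 5).
#' @param n_bins Number of bins (default 100).
#' @param ori_position Origin position as a fraction of the genome
#'   (default 0).
#' @param noise `"none"` or `"poisson"`.
#' @param read_length Read length used to convert depth to read counts for
#'   the Poisson model (default 100).
#' @param seed Seed (used only under Poisson noise).
#' @return A coverage-track tibble (`genome_id`, `start`, `end`, `depth`).
#' @export
simulate_coverage <- function(genome_id = "g1", genome_length = 3e6,
                              true_ptr = 1, mean_depth = 5, n_bins = 100,
                              ori_position = 0, noise = c("none", "poisson"),
                              read_length = 100, seed = 1) {
  noise <- match.arg(noise)
  stopifnot(true_ptr >= 1, mean_depth > 0)
  a <- log2(true_ptr)
  x <- (seq_len(n_bins) - 1) / n_bins
  d <- 2 * pmin(abs(x - ori_position), 1 - abs(x - ori_position))
  raw <- 2^(-a * d)
  depth <- raw * mean_depth / mean(raw)
  bin_len <- genome_length / n_bins
  if (noise == "poisson") {
    lambda <- depth * bin_len / read_length
    counts <- withr::with_seed(seed, rpois(n_bins, lambda))
    depth <- counts * read_length / bin_len
  }
  tibble::tibble(
    genome_id = genome_id,
    start = (seq_len(n_bins) - 1) * bin_len,
    end = seq_len(n_bins) * bin_len,
    depth = depth
  )
}

#' Simulate FASTQ reads from a genome
#'
#' Uniform start positions on a (random or supplied) genome, substitution
#' errors at `error_rate`, constant qualities. Byte-identical output under a
#' fixed seed.
#'
#' @param path Output FASTQ path.
#' @param n_reads Number of reads.
#' @param read_length Read length in bp (default 150).
#' @param genome A DNA string; by default a seeded random genome of
#'   `genome_length` bp.
#' @param genome_length Length of the random genome (default 10000).
#' @param error_rate Per-base substitution probability (default 0).
#' @param seed Seed.
#' @return `path`, invisibly.
#' @export
simulate_reads <- function(path, n_reads, read_length = 150, genome = NULL,
                           genome_length = 10000, error_rate = 0, seed = 1) {
  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    if (is.null(genome)) {
      genome <- paste(sample(bases, genome_length, replace = TRUE),
                      collapse = "")
    }
    G <- nchar(genome)
    stopifnot(G >= read_length)
    lines <- character(0)
    if (n_reads > 0) {
      starts <- sample.int(G - read_length + 1, n_reads, replace = TRUE)
      seqs <- substring(genome, starts, starts + read_length - 1)
      if (error_rate > 0) {
        seqs <- vapply(seqs, function(s) {
          ch <- strsplit(s, "")[[1]]
          err <- runif(read_length) < error_rate
          if (any(err)) {
            ch[err] <- vapply(ch[err], function(b) {
              sample(setdiff(bases, b), 1)
            }, character(1))
          }
          paste(ch, collapse = "")
        }, character(1), USE.NAMES = FALSE)
      }
      qual <- strrep("I", read_length)
      lines <- as.vector(rbind(sprintf("@read_%d", seq_len(n_reads)),
                               seqs, "+", qual))
    }
    writeLines(lines, path)
  })
  invisible(path)
}

#' Simulate a genome-quality table
#'
#' Draft-genome quality rows (completeness, contamination, genus, novelty)
#' spanning both sides of the 80% / <5% screening boundary.
#'
#' @param n_genomes Number of bins (default 30).
#' @param novel_fraction Fraction flagged as novel (default 0.5).
#' @param seed Seed.
#' @return A tibble `bin_id`, `completeness`, `contamination`,
#'   `assigned_genus`, `is_novel`.
#' @export
simulate_genome_quality <- function(n_genomes = 30, novel_fraction = 0.5,
                                    seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    bin_id = sprintf("bin_%02d", seq_len(n_genomes)),
    completeness = round(runif(n_genomes, 50, 100), 1),
    contamination = round(stats::rexp(n_genomes, rate = 1 / 4), 2),
    assigned_genus = sample(GENUS_POOL, n_genomes, replace = TRUE),
    is_novel = runif(n_genomes) < novel_fraction
  ))
}
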