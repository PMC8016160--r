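# Sample-level sequence-complexity QC from a k-mer spectrum of cleaned reads.
#
# Low-biomass libraries sequenced to saturation show few unique k-mers, a low
# singleton fraction and low k-mer entropy; these statistics flag degenerate
# libraries before any taxonomic interpretation.

#' Count canonical k-mers in a FASTQ file
#'
#' Each read of length L contributes `max(0, L - k + 1)` k-mer windows;
#' windows containing ambiguous bases (anything outside A/C/G/T) are skipped
#' rather than substituted. Counting is strand-canonical: a k-mer and its
#' reverse complement are collapsed onto the lexicographically smaller of the
#' two. Singletons are retained -- they carry most of the QC signal in
#' low-complexity libraries.
#'
#' @param path Path to a FASTQ file (plain or gzip).
#' @param k K-mer length (default 31, a common marker-k-mer size).
#' @return An object of class `kmer_spectrum`: a list with `k`, `n_reads`,
#'   and `counts` (a named integer vector, canonical k-mer -> occurrences).
#' @export
count_kmers <- function(path, k = 31) {
  stopifnot(k >= 1)
  reads <- read_fastq_sequences(path)
  counts <- integer(0)
  if (length(reads) > 0) {
    kmers <- unlist(lapply(reads, extract_kmers, k = k), use.names = FALSE)
    if (length(kmers) > 0) {
      canon <- canonical_kmers(kmers)
      tab <- table(canon)
      counts <- as.integer(tab)
      names(counts) <- names(tab)
    }
  }
  structure(list(k = k, n_reads = length(reads), counts = counts),
            class = "kmer_spectrum")
}

read_fastq_sequences <- function(path) {
  if (!file.exists(path)) {
    stop_format("FASTQ file does not exist: %s", path)
  }
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) {
      stop_format("malformed FASTQ '%s': %s", basename(path),
                  conditionMessage(e))
    }
  )
  toupper(as.character(seqs))
}

# All k-length windows of one read, dropping windows with ambiguous bases.
extract_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) {
    return(character(0))
  }
  km <- substring(seq, 1:(L - k + 1), k:L)
  km[!grepl("[^ACGT]", km)]
}

canonical_kmers <- function(kmers) {
  rc <- revcomp_chr(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

#' Fraction of k-mers seen exactly once
#'
#' The number of distinct k-mers observed once divided by the total number of
#' distinct k-mers. Deeply saturated (or heavily duplicated) libraries drive
#' this toward 0; diverse, undersampled libraries toward 1.
#'
#' @param spectrum A `kmer_spectrum` from [count_kmers()].
#' @return A fraction in \[0, 1\]; errors on an empty spectrum.
#' @export
singleton_fraction <- function(spectrum) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  n <- length(spectrum$counts)
  if (n == 0) {
    stop_analysis("singleton_fraction is undefined for an empty spectrum")
  }
  sum(spectrum$counts == 1L) / n
}

#' Shannon entropy of the k-mer spectrum (nats)
#'
#' Entropy of the probability of drawing each distinct k-mer at random,
#' `H = -sum p_i log(p_i)` with `p_i = count_i / total`, reported in nats.
#'
#' @param spectrum A `kmer_spectrum` from [count_kmers()].
#' @return Entropy in nats; errors on an empty spectrum.
#' @export
kmer_entropy <- function(spectrum) {
  stopifnot(inherits(spectrum, "kmer_spectrum"))
  if (length(spectrum$counts) == 0) {
    stop_analysis("kmer_entropy is undefined for an empty spectrum")
  }
  p <- spectrum$counts / sum(spectrum$counts)
  -sum(p * log(p))
}

#' Count reads in a FASTQ file
#'
#' @param path Path to a FASTQ file (plain or gzip).
#' @return Number of records.
#' @export
read_count <- function(path) {
  length(read_fastq_sequences(path))
}

#' Per-sample k-mer QC summary
#'
#' Runs [count_kmers()] on each FASTQ and returns the one-row-per-sample QC
#' table (read count, distinct k-mers, singleton fraction, entropy in nats).
#'
#' @param paths Named character vector of FASTQ paths; names are sample ids
#'   (defaulting to file names).
#' @param k K-mer length passed to [count_kmers()].
#' @return A tibble: `sample_id`, `n_reads`, `n_distinct_kmers`,
#'   `singleton_fraction`, `kmer_entropy`. Samples with an empty spectrum get
#'   `NA` statistics.
#' @export
kmer_qc_summary <- function(paths, k = 31) {
  ids <- names(paths) %||% sub("\\.(fastq|fq)(\\.gz)?$", "", basename(paths))
  purrr::map2(paths, ids, function(p, id) {
    sp <- count_kmers(p, k = k)
    empty <- length(sp$counts) == 0
    tibble::tibble(
      sample_id = id,
      n_reads = sp$n_reads,
      n_distinct_kmers = length(sp$counts),
      singleton_fraction = if (empty) NA_real_ else singleton_fraction(sp),
      kmer_entropy = if (empty) NA_real_ else kmer_entropy(sp)
    )
  }) |>
    dplyr::bind_rows()
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat(sprintf("<kmer_spectrum> k=%d, %d reads, %d distinct k-mers\n",
              x$k, x$n_reads, length(x$counts)))
  invisible(x)
}
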