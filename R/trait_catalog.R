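# Survival-trait annotation of taxa, gene-category counting for genomes,
# and completeness/contamination screening of metagenome-assembled genomes.

TRAIT_FLAGS <- c("psychrophile", "radiophile", "spore_forming",
                 "biofilm_forming", "extreme_environment",
                 "desiccation_resistant")

GENE_CATEGORIES <- c("dna_repair", "chemotaxis_motility", "biocide_resistance",
                     "sporulation", "antimicrobial_resistance")

#' Read a trait directory
#'
#' A TSV keyed by (`name`, `rank` in species/genus) with boolean columns for
#' planetary-protection-relevant traits: psychrophily, radiation resistance,
#' spore formation, biofilm formation, presence in extreme environments and
#' desiccation resistance. A small curated fixture with well-known
#' exemplars (e.g. *Geodermatophilus obscurus*, *Ramlibacter tataouinensis*)
#' ships with the package; supply a fuller directory for production use.
#'
#' @param path Path to the TSV; defaults to the bundled fixture.
#' @return A validated trait-directory tibble.
#' @export
read_trait_directory <- function(path = NULL) {
  path <- path %||% system.file("extdata", "trait_directory.tsv",
                                package = "cleanroomr")
  df <- readr::read_tsv(path, col_types = readr::cols(
    name = "c", rank = "c", .default = "l"
  ), progress = FALSE)
  require_columns(df, c("name", "rank", TRAIT_FLAGS),
                  sprintf("trait directory '%s'", path))
  if (!all(df$rank %in% c("species", "genus"))) {
    stop_validation("trait directory rank must be 'species' or 'genus'")
  }
  if (anyDuplicated(df[c("name", "rank")]) > 0) {
    stop_validation("trait directory has duplicated (name, rank) keys")
  }
  df
}

#' Annotate taxa with survival traits, with genus-level expansion
#'
#' For each queried taxon and each trait the annotation reports two tiers:
#' `species_direct` (the species' own directory entry) and `genus_expanded`,
#' true when the species itself, its genus entry, or **any** congeneric
#' species in the directory carries the trait. A taxon entirely absent from
#' the directory reports `NA` ("unknown") rather than `FALSE`: absence of
#' evidence is not evidence of trait absence.
#'
#' @param taxa A tibble with columns `species` and `genus` (one row per
#'   queried taxon).
#' @param directory A trait directory from [read_trait_directory()].
#' @return A long tibble: `species`, `genus`, `trait`, `species_direct`,
#'   `genus_expanded`.
#' @export
annotate_taxa <- function(taxa, directory = read_trait_directory()) {
  require_columns(taxa, c("species", "genus"), "taxa table")
  sp_rows <- directory[directory$rank == "species", , drop = FALSE]
  gn_rows <- directory[directory$rank == "genus", , drop = FALSE]
  sp_rows$genus_of <- vapply(strsplit(sp_rows$name, " "), `[`, character(1), 1)

  purrr::map_dfr(seq_len(nrow(taxa)), function(i) {
    sp <- taxa$species[i]
    gn <- taxa$genus[i]
    own <- sp_rows[sp_rows$name == sp, , drop = FALSE]
    congeners <- sp_rows[sp_rows$genus_of == gn, , drop = FALSE]
    genus_row <- gn_rows[gn_rows$name == gn, , drop = FALSE]
    purrr::map_dfr(TRAIT_FLAGS, function(tr) {
      direct <- if (nrow(own) == 1) own[[tr]] else NA
      genus_vals <- c(
        if (nrow(own) == 1) own[[tr]],
        if (nrow(congeners) > 0) congeners[[tr]],
        if (nrow(genus_row) == 1) genus_row[[tr]]
      )
      expanded <- if (length(genus_vals) == 0) {
        NA
      } else {
        any(genus_vals, na.rm = TRUE)
      }
      # the expansion tier can only add evidence, never subtract it
      if (isTRUE(direct)) expanded <- TRUE
      tibble::tibble(species = sp, genus = gn, trait = tr,
                     species_direct = direct, genus_expanded = expanded)
    })
  })
}

#' Read gene-category matching rules
#'
#' A TSV with columns `category` (exactly the five survival-relevant
#' categories: DNA repair, chemotaxis/motility, biocide resistance,
#' sporulation, antimicrobial resistance), `pattern`, and `match_mode`
#' (`exact_symbol` for gene symbols, `substring_product` for
#' case-insensitive product-description matching). Every category must have
#' at least one rule. A default editable fixture ships with the package.
#'
#' @param path Path to the rules TSV; defaults to the bundled fixture.
#' @return A validated rules tibble.
#' @export
read_gene_rules <- function(path = NULL) {
  path <- path %||% system.file("extdata", "gene_category_rules.tsv",
                                package = "cleanroomr")
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  require_columns(df, c("category", "pattern", "match_mode"),
                  sprintf("gene rules '%s'", path))
  validate_gene_rules(df)
}

validate_gene_rules <- function(df) {
  if (!setequal(unique(df$category), GENE_CATEGORIES)) {
    stop_validation("gene rules must cover exactly the categories: %s",
                    paste(GENE_CATEGORIES, collapse = ", "))
  }
  if (!all(df$match_mode %in% c("exact_symbol", "substring_product"))) {
    stop_validation("match_mode must be exact_symbol or substring_product")
  }
  if (any(!nzchar(df$pattern))) {
    stop_validation("empty pattern in gene rules")
  }
  df
}

#' Count survival-relevant genes per genome and category
#'
#' Each annotation row (gene symbol + product string) is tested against the
#' rules of every category; a row matching any rule of a category increments
#' that category's count by one (a row may contribute to several categories,
#' but at most once to each). Duplicated annotation rows count separately.
#'
#' @param gene_table A tibble with columns `genome_id`, `gene_symbol`,
#'   `product`.
#' @param rules A rules tibble from [read_gene_rules()].
#' @return A tibble `genome_id` x category count columns (zero-filled).
#' @export
count_gene_categories <- function(gene_table, rules = read_gene_rules()) {
  require_columns(gene_table, c("genome_id", "gene_symbol", "product"),
                  "gene table")
  validate_gene_rules(rules)
  if (nrow(gene_table) == 0) {
    warn("empty gene table: all category counts are zero")
  }
  matches <- purrr::map(GENE_CATEGORIES, function(cat) {
    r <- rules[rules$category == cat, , drop = FALSE]
    hit <- rep(FALSE, nrow(gene_table))
    for (j in seq_len(nrow(r))) {
      hit <- hit | if (r$match_mode[j] == "exact_symbol") {
        tolower(gene_table$gene_symbol) == tolower(r$pattern[j])
      } else {
        grepl(r$pattern[j], gene_table$product, ignore.case = TRUE,
              fixed = FALSE)
      }
    }
    hit
  })
  names(matches) <- GENE_CATEGORIES
  out <- tibble::tibble(genome_id = gene_table$genome_id, !!!matches) |>
    dplyr::group_by(.data$genome_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(GENE_CATEGORIES),
                                   ~ sum(.x)), .groups = "drop")
  out
}

#' Screen metagenome-assembled genomes by quality
#'
#' Keeps genomes with completeness of at least `min_completeness` percent
#' and contamination strictly below `max_contamination` percent (the
#' conventional 80% / <5% draft-quality screen). Idempotent; output is a
#' subset of the input rows.
#'
#' @param quality A tibble with columns `bin_id`, `completeness`,
#'   `contamination` (percent), and optionally `assigned_genus`, `is_novel`.
#' @param min_completeness Inclusive lower bound on completeness (default 80).
#' @param max_contamination Exclusive upper bound on contamination (default 5).
#' @return The retained rows.
#' @export
screen_genomes <- function(quality, min_completeness = 80,
                           max_contamination = 5) {
  require_columns(quality, c("bin_id", "completeness", "contamination"),
                  "genome quality table")
  if (any(quality$completeness < 0 | quality$completeness > 100)) {
    stop_validation("completeness must lie in [0, 100]")
  }
  if (any(quality$contamination < 0)) {
    stop_validation("contamination must be >= 0")
  }
  quality |>
    dplyr::filter(.data$completeness >= min_completeness,
                  .data$contamination < max_contamination)
}
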