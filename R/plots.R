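# ggplot2 figures for each result type. All plot functions return ggplot
# objects so callers can restyle them.

#' Alpha-diversity by group
#'
#' Boxplots of a per-sample diversity metric across design groups.
#'
#' @param summary A [diversity_summary()] tibble.
#' @param metric Column to plot (`"shannon"`, `"richness_rarefied"`,
#'   `"richness_obs"`).
#' @param group Grouping column (default `"iso_group"`).
#' @return A ggplot.
#' @export
plot_alpha_diversity <- function(summary, metric = "shannon",
                                 group = "iso_group") {
  require_columns(summary, c(metric, group), "diversity summary")
  ggplot2::ggplot(summary, ggplot2::aes(x = .data[[group]],
                                        y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}

#' @describeIn embed_2d Plot an ordination, optionally coloured by a design
#'   column joined from `design`.
#' @param object A `pp_ordination` tibble.
#' @param design Optional design tibble to colour points by `colour`.
#' @param colour Design column used for colour (default `"iso_group"`).
#' @param ... Unused.
#' @method autoplot pp_ordination
#' @export
autoplot.pp_ordination <- function(object, design = NULL,
                                   colour = "iso_group", ...) {
  df <- object
  aes <- ggplot2::aes(x = .data$axis1, y = .data$axis2)
  if (!is.null(design)) {
    df <- dplyr::left_join(df, design, by = "sample_id")
    aes <- ggplot2::aes(x = .data$axis1, y = .data$axis2,
                        colour = .data[[colour]])
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "axis 1", y = "axis 2") +
    ggplot2::theme_minimal()
}

#' Rarefaction / accumulation curves
#'
#' @param curves Output of [rarefaction_curves()].
#' @param group Column identifying the curves (default `"iso_group"`).
#' @return A ggplot with one ribboned curve per group.
#' @export
plot_rarefaction <- function(curves, group = "iso_group") {
  require_columns(curves, c(group, "x", "mean"), "curves")
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$x, y = .data$mean,
                                       colour = .data[[group]],
                                       fill = .data[[group]])) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "samples / reads", y = "expected unique taxa") +
    ggplot2::theme_minimal()
}

#' Trait heat-tiles
#'
#' Tile map of trait annotations per taxon: filled by the genus-expanded
#' tier, outlined where the species itself carries the trait; unknowns stay
#' grey.
#'
#' @param annotation Output of [annotate_taxa()].
#' @return A ggplot.
#' @export
plot_trait_tiles <- function(annotation) {
  require_columns(annotation, c("species", "trait", "genus_expanded"),
                  "trait annotation")
  df <- annotation |>
    dplyr::mutate(status = dplyr::case_when(
      is.na(.data$genus_expanded) ~ "unknown",
      .data$genus_expanded & isTRUE(.data$species_direct) ~ "species",
      .data$genus_expanded ~ "genus only",
      TRUE ~ "absent"
    ))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trait, y = .data$species,
                                   fill = .data$status)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(
      species = "#b2182b", `genus only` = "#ef8a62", absent = "#2166ac",
      unknown = "grey85"
    )) +
    ggplot2::labs(x = NULL, y = NULL, fill = "trait evidence") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Replication-score distributions per species
#'
#' @param estimates Rows from [estimate_ptr()] with a `species` column
#'   (falls back to `genome_id`).
#' @return A ggplot; the dashed line at 1 marks no replication.
#' @export
plot_growth_scores <- function(estimates) {
  df <- tibble::as_tibble(estimates)
  if (!"species" %in% names(df)) {
    df$species <- df$genome_id
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$species, y = .data$score)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "peak-to-trough score") +
    ggplot2::theme_minimal()
}
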