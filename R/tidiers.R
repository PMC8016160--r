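# Broom-style tidiers and print methods for the package's result objects.

#' @export
print.pp_filter_report <- function(x, ...) {
  cat("<filter report>\n")
  cat(sprintf("  assignments removed by thresholds: %d\n",
              nrow(x$removed_by_threshold)))
  cat(sprintf("  taxa seen in controls: %d\n", length(x$control_taxa_seen)))
  cat(sprintf("  removed as contaminants: %d\n",
              length(x$removed_as_contaminant)))
  cat(sprintf("  retained despite control detection: %d\n",
              length(x$retained_despite_control)))
  invisible(x)
}

#' Tidy a filter report
#'
#' One row per filtering decision: threshold removals carry the sample and
#' assignment evidence; contamination decisions carry the taxon and whether
#' it was removed or rescued.
#'
#' @param x A `pp_filter_report` (see [filter_report()]).
#' @param ... Unused.
#' @return A tibble `stage`, `sample_id`, `taxon_id`, `decision`.
#' @method tidy pp_filter_report
#' @export
tidy.pp_filter_report <- function(x, ...) {
  thr <- x$removed_by_threshold |>
    dplyr::transmute(stage = "threshold", sample_id = .data$sample_id,
                     taxon_id = .data$taxon_id, decision = "removed")
  ctl <- tibble::tibble(
    stage = "control_rule",
    sample_id = NA_character_,
    taxon_id = c(x$removed_as_contaminant, x$retained_despite_control),
    decision = c(rep("removed", length(x$removed_as_contaminant)),
                 rep("retained", length(x$retained_despite_control)))
  )
  dplyr::bind_rows(thr, ctl)
}

#' Glance at a filter report
#'
#' @param x A `pp_filter_report`.
#' @param ... Unused.
#' @return A one-row tibble of decision counts.
#' @method glance pp_filter_report
#' @export
glance.pp_filter_report <- function(x, ...) {
  tibble::tibble(
    n_removed_by_threshold = nrow(x$removed_by_threshold),
    n_control_taxa = length(x$control_taxa_seen),
    n_removed_contaminant = length(x$removed_as_contaminant),
    n_retained_despite_control = length(x$retained_despite_control)
  )
}

#' Tidy growth calls
#'
#' @param x A `pp_growth_calls` table from [call_growing_species()].
#' @param ... Unused.
#' @return The per-group test table as a plain tibble.
#' @method tidy pp_growth_calls
#' @export
tidy.pp_growth_calls <- function(x, ...) {
  tibble::as_tibble(unclass(x)[setdiff(names(unclass(x)), character(0))])
}

#' Glance at growth calls
#'
#' @param x A `pp_growth_calls` table.
#' @param ... Unused.
#' @return A one-row tibble: species tested, called growing, untestable,
#'   and the significance level used.
#' @method glance pp_growth_calls
#' @export
glance.pp_growth_calls <- function(x, ...) {
  sp <- growing_species(x)
  tibble::tibble(
    n_species = nrow(sp),
    n_growing = sum(sp$growing, na.rm = TRUE),
    n_untestable = sum(sp$untestable),
    alpha = attr(x, "alpha") %||% 0.05
  )
}
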