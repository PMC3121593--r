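# Conversion of mean log2 expression ratios to KEGG pathway color codes.

round_half_up <- function(x) floor(x + 0.5)

#' Convert a log2 expression ratio to a KEGG color code
#'
#' Ratios are clamped to \[-2.5, +2.5\] and interpolated linearly in RGB
#' over two segments: +2.5 maps to pure green `#00FF00`, 0 to yellow
#' `#FFFF00` and -2.5 to pure red `#FF0000`. For r in \[0, 2.5\] the red
#' channel falls as `round(255 * (1 - r/2.5))` with green saturated; for r
#' in \[-2.5, 0\] the green channel falls as `round(255 * (1 + r/2.5))`
#' with red saturated. Channel rounding is round-half-up. The blue channel
#' is always 0.
#'
#' @param mean_log2_ratio Numeric vector of finite log2 ratios.
#' @return Character vector of uppercase `#RRGGBB` codes.
#' @examples
#' ratio_to_color(c(-2.5, 0, 2.5)) # "#FF0000" "#FFFF00" "#00FF00"
#' @export
ratio_to_color <- function(mean_log2_ratio) {
  if (any(!is.finite(mean_log2_ratio))) {
    abort("ratios must be finite")
  }
  r <- pmin(pmax(mean_log2_ratio, -2.5), 2.5)
  red <- ifelse(r >= 0, round_half_up(255 * (1 - r / 2.5)), 255)
  green <- ifelse(r >= 0, 255, round_half_up(255 * (1 + r / 2.5)))
  sprintf("#%02X%02X00", as.integer(red), as.integer(green))
}

#' Mean post-onset log2 ratio per protein
#'
#' The average of a protein's log2 ratios over all post-onset time points
#' and replicates, the quantity painted onto pathways. Pre-onset values sit
#' near 0 by normalization and would only dilute the signal.
#'
#' @param matrix Log2-stage, onset-aligned `protein_matrix` (t = 0 at
#'   onset).
#' @param from_min Earliest onset-relative time included (default 0,
#'   exclusive).
#' @return Tibble `protein_id`, `mean_log2_ratio`, `n_obs`.
#' @export
mean_post_onset_ratio <- function(matrix, from_min = 0) {
  if (!identical(matrix_stage(matrix), "log2")) {
    abort("mean_post_onset_ratio() expects a log2-stage protein matrix")
  }
  tibble::as_tibble(matrix) |>
    dplyr::filter(.data$time_min > from_min, !is.na(.data$value)) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(mean_log2_ratio = mean(.data$value),
                     n_obs = dplyr::n(), .groups = "drop")
}

#' Export per-protein colors for KEGG pathway mapping
#'
#' Joins mean log2 ratios to a user-supplied accession-to-KEGG mapping
#' (no live KEGG queries), converts ratios to background colors with
#' [ratio_to_color()], fixes the foreground to black, and writes the KEGG
#' mapper input file via [write_kegg_colors()]. Unmapped proteins are
#' reported, not fatal.
#'
#' @param mean_ratios Tibble `protein_id`, `mean_log2_ratio` (e.g. from
#'   [mean_post_onset_ratio()]).
#' @param mapping Tibble `protein_id`, `kegg_id`.
#' @param path Output file path.
#' @return Invisibly, the tibble of written entries; unmapped protein ids
#'   in the `unmapped` attribute.
#' @export
export_pathway_colors <- function(mean_ratios, mapping, path) {
  joined <- dplyr::inner_join(mean_ratios, mapping, by = "protein_id")
  unmapped <- setdiff(mean_ratios$protein_id, mapping$protein_id)
  entries <- tibble::tibble(
    entry_id = joined$kegg_id,
    bg_hex = if (nrow(joined) > 0) ratio_to_color(joined$mean_log2_ratio)
    else character(0),
    fg_hex = rep("#000000", nrow(joined))
  )
  write_kegg_colors(entries, path)
  if (length(unmapped) > 0) {
    rlang::inform(sprintf("%d protein(s) had no KEGG mapping",
                          length(unmapped)))
  }
  attr(entries, "unmapped") <- unmapped
  invisible(entries)
}
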