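# Protein-level quantitation: unique-peptide rollup, reference-protein and
# earliest-time-point normalization, log2 transform. The protein matrix is
# a long tibble (protein_id, run_id, replicate, time_min, value) carrying a
# `stage` attribute that only moves raw -> normalized -> log2.

new_protein_matrix <- function(x, stage, extra = list()) {
  attrs <- c(list(stage = stage), extra)
  for (nm in names(attrs)) attr(x, nm) <- attrs[[nm]]
  class(x) <- unique(c("protein_matrix", class(x)))
  x
}

#' Stage of a protein matrix
#' @param x A `protein_matrix`.
#' @return `"raw"`, `"normalized"` or `"log2"`.
#' @export
matrix_stage <- function(x) attr(x, "stage")

#' Map peptides to the single protein they belong to
#'
#' Only peptides attributable to exactly one protein are used for protein
#' quantitation; peptides shared between proteins are excluded and the
#' exclusion list is reported as the `excluded` attribute.
#'
#' @param ids Merged identifications (with `protein_accessions`,
#'   ";"-separated). Decoy records are never mapped.
#' @return Tibble `peptide`, `charge`, `protein_id`; attribute `excluded`
#'   holds the shared (multi-parent) peptides.
#' @export
assign_unique_peptides <- function(ids) {
  if (nrow(ids) == 0) {
    out <- tibble::tibble(peptide = character(), charge = integer(),
                          protein_id = character())
    attr(out, "excluded") <- tibble::tibble(peptide = character(),
                                            protein_accessions = character())
    return(out)
  }
  n_parents <- lengths(strsplit(ids$protein_accessions, ";", fixed = TRUE))
  is_decoy <- if ("is_decoy" %in% names(ids)) ids$is_decoy else
    startsWith(ids$protein_accessions, "DECOY_")
  unique_ok <- n_parents == 1 & !is_decoy
  out <- tibble::tibble(
    peptide = ids$peptide[unique_ok],
    charge = ids$charge[unique_ok],
    protein_id = ids$protein_accessions[unique_ok]
  )
  attr(out, "excluded") <- tibble::tibble(
    peptide = ids$peptide[n_parents > 1],
    protein_accessions = ids$protein_accessions[n_parents > 1]
  )
  out
}

#' Roll peptide intensities up to proteins
#'
#' Protein abundance in a sample is the sum of the present intensities of
#' its unique peptides; missing peptides are skipped, and a protein whose
#' peptides are all missing in a sample stays missing there. Proteins with
#' no unique peptide never appear (they are unquantifiable under the
#' unique-peptide rule).
#'
#' @param matrix A `peptide_matrix` from [build_peptide_matrix()].
#' @param mapping Peptide-to-protein map from [assign_unique_peptides()].
#' @return A raw-stage `protein_matrix`.
#' @export
rollup <- function(matrix, mapping) {
  joined <- dplyr::inner_join(
    matrix, mapping, by = c("peptide", "charge"))
  out <- joined |>
    dplyr::group_by(.data$protein_id, .data$run_id, .data$replicate,
                    .data$time_min) |>
    dplyr::summarise(
      value = if (all(is.na(.data$intensity))) NA_real_ else
        sum(.data$intensity, na.rm = TRUE),
      n_peptides = sum(!is.na(.data$intensity)),
      .groups = "drop"
    )
  new_protein_matrix(out, "raw")
}

#' Normalize a raw protein matrix
#'
#' Two steps, following the rule "normalized against the most abundant
#' protein and the earliest time point":
#' 1. per sample, divide every value by the reference protein's intensity
#'    in that sample. With `reference = "global"` (default) the reference
#'    is the single protein with the largest summed intensity over all
#'    samples; with `reference = "per_sample"` each sample is divided by
#'    its own maximum protein intensity.
#' 2. per protein and replicate, divide by the protein's value at that
#'    replicate's earliest time point, so every retained profile starts
#'    at exactly 1.
#'
#' Proteins missing at any replicate's earliest time point are dropped
#' (reported in the `dropped` attribute); no imputation.
#'
#' @param matrix Raw-stage `protein_matrix`.
#' @param reference `"global"` or `"per_sample"` (see above).
#' @return Normalized-stage `protein_matrix`; attributes
#'   `reference_protein` (under the global reading) and `dropped`.
#' @export
normalize <- function(matrix, reference = c("global", "per_sample")) {
  reference <- match.arg(reference)
  if (identical(matrix_stage(matrix), "normalized")) {
    return(matrix)  # idempotent at the normalized stage
  }
  if (!identical(matrix_stage(matrix), "raw")) {
    abort("normalize() expects a raw-stage protein matrix")
  }
  x <- tibble::as_tibble(matrix)

  if (reference == "global") {
    totals <- x |>
      dplyr::group_by(.data$protein_id) |>
      dplyr::summarise(total = sum(.data$value, na.rm = TRUE),
                       .groups = "drop")
    ref <- totals$protein_id[which.max(totals$total)]
    ref_vals <- x |>
      dplyr::filter(.data$protein_id == ref) |>
      dplyr::select("run_id", ref_value = "value")
    missing_runs <- setdiff(unique(x$run_id),
                            ref_vals$run_id[!is.na(ref_vals$ref_value)])
    if (length(missing_runs) > 0) {
      abort(sprintf(
        "reference protein '%s' missing in sample(s): %s", ref,
        paste(missing_runs, collapse = ", ")),
        class = "diauxielfq_normalization_error")
    }
  } else {
    ref <- NA_character_
    ref_vals <- x |>
      dplyr::group_by(run_id = .data$run_id) |>
      dplyr::summarise(ref_value = max(.data$value, na.rm = TRUE),
                       .groups = "drop")
  }
  x <- dplyr::left_join(x, ref_vals, by = "run_id")
  x$value <- x$value / x$ref_value
  x$ref_value <- NULL

  earliest <- x |>
    dplyr::group_by(.data$replicate) |>
    dplyr::summarise(t0 = min(.data$time_min), .groups = "drop")
  x <- dplyr::left_join(x, earliest, by = "replicate")
  t0_vals <- x |>
    dplyr::filter(.data$time_min == .data$t0) |>
    dplyr::select("protein_id", "replicate", t0_value = "value")
  x <- dplyr::left_join(x, t0_vals, by = c("protein_id", "replicate"))

  dropped <- x |>
    dplyr::filter(is.na(.data$t0_value)) |>
    dplyr::distinct(.data$protein_id)
  x <- x[!(x$protein_id %in% dropped$protein_id), , drop = FALSE]
  x$value <- x$value / x$t0_value
  x <- dplyr::select(x, -"t0", -"t0_value")

  new_protein_matrix(x, "normalized",
                     list(reference_protein = ref,
                          dropped = dropped$protein_id))
}

#' Log2-transform a normalized protein matrix
#'
#' Element-wise log base 2; missing values stay missing. A zero or negative
#' present value is an error naming the offending cell (the upstream
#' pipeline cannot produce one, so it indicates corrupted input).
#'
#' @param matrix Normalized-stage `protein_matrix`.
#' @return Log2-stage `protein_matrix`.
#' @export
log2_transform <- function(matrix) {
  if (!identical(matrix_stage(matrix), "normalized")) {
    abort("log2_transform() expects a normalized-stage protein matrix")
  }
  bad <- which(!is.na(matrix$value) & matrix$value <= 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "non-positive value for protein %s in sample %s",
      matrix$protein_id[bad[1]], matrix$run_id[bad[1]]),
      class = "diauxielfq_transform_error")
  }
  keep_attrs <- list(reference_protein = attr(matrix, "reference_protein"),
                     dropped = attr(matrix, "dropped"))
  matrix$value <- log2(matrix$value)
  new_protein_matrix(matrix, "log2", keep_attrs)
}
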