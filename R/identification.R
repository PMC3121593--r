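# Identification-level processing: ion-score filtering, decoy-based FDR
# estimation, and merging per-run identification lists into one record per
# (peptide, charge).

#' Filter identifications by ion score
#'
#' Keeps exactly the records with `ion_score >= threshold` (the boundary is
#' kept: "at least 25" includes 25), preserving input order. Idempotent.
#'
#' @param ids Identification tibble (see [read_identifications()]).
#' @param threshold Minimum ion score, default 25.
#' @return Filtered tibble.
#' @export
filter_by_score <- function(ids, threshold = 25) {
  if (!is.finite(threshold)) abort("threshold must be finite")
  ids[ids$ion_score >= threshold, , drop = FALSE]
}

#' Estimate the peptide-level false discovery rate from decoys
#'
#' Concatenated target-decoy estimator D/T: the number of decoy
#' identifications over the number of target identifications at the current
#' score cut. Returns 0 when there are no decoys; raises an error when
#' there are no targets (the rate is undefined).
#'
#' @param ids Identification tibble with an `is_decoy` column.
#' @return FDR estimate in `[0, 1]` (can exceed 1 only if decoys outnumber
#'   targets; callers usually cap downstream).
#' @export
estimate_fdr <- function(ids) {
  if (nrow(ids) == 0) abort("ids must be non-empty")
  n_decoy <- sum(ids$is_decoy)
  n_target <- sum(!ids$is_decoy)
  if (n_target == 0) {
    abort("no target identifications: FDR undefined",
          class = "diauxielfq_undefined_rate")
  }
  n_decoy / n_target
}

#' Merge per-run identification lists
#'
#' Collapses identifications (already on the master retention-time base)
#' to one record per (peptide, charge): best ion score is the maximum over
#' runs, the consensus retention time is the score-weighted mean of
#' contributing observations, and protein accession lists are unioned.
#' Identical peptides at different charges stay separate records. The
#' theoretical m/z is recomputed from the sequence.
#'
#' @param per_run_ids A single identification tibble covering all runs, or
#'   a list of per-run tibbles.
#' @return Tibble with `peptide`, `charge`, `protein_accessions`,
#'   `best_ion_score`, `rt_master`, `mz_theoretical`, `n_runs`, `is_decoy`.
#' @export
merge_identifications <- function(per_run_ids) {
  if (is.list(per_run_ids) && !is.data.frame(per_run_ids)) {
    per_run_ids <- dplyr::bind_rows(per_run_ids)
  }
  merged <- per_run_ids |>
    dplyr::group_by(.data$peptide, .data$charge) |>
    dplyr::summarise(
      best_ion_score = max(.data$ion_score),
      rt_master = sum(.data$rt_observed * .data$ion_score) /
        sum(.data$ion_score),
      n_runs = dplyr::n_distinct(.data$run_id),
      is_decoy = all(.data$is_decoy),
      .groups = "drop"
    )

  # accession union: groups almost always agree on one accession string,
  # so only the rare disagreeing groups pay for a string-split union
  acc <- dplyr::distinct(per_run_ids, .data$peptide, .data$charge,
                         .data$protein_accessions)
  multi <- acc |>
    dplyr::group_by(.data$peptide, .data$charge) |>
    dplyr::filter(dplyr::n() > 1) |>
    dplyr::summarise(
      protein_accessions = paste(
        sort(unique(unlist(strsplit(.data$protein_accessions, ";",
                                    fixed = TRUE)))), collapse = ";"),
      .groups = "drop")
  single <- dplyr::anti_join(acc, multi, by = c("peptide", "charge"))
  merged <- dplyr::left_join(merged, dplyr::bind_rows(single, multi),
                             by = c("peptide", "charge"))
  merged$mz_theoretical <- (peptide_mass(merged$peptide) +
                              merged$charge * MASS_PROTON) / merged$charge
  merged
}
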