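# Windowed extracted-ion quantitation: for every merged identification and
# every aligned feature map, take the maximum-intensity feature inside an
# m/z (ppm) by retention-time (min) window, and assemble the
# peptide-by-sample matrix.

# Vectorised matcher: features of ONE run against many ids.
# Returns one row per id with intensity NA when the window is empty.
# Ties on maximum intensity break by smallest |rt_apex - rt_master|, then
# smallest relative m/z error, then lowest m/z (a total order, so the
# result does not depend on feature order).
match_features <- function(features, ids, mz_tol_ppm, rt_window_min) {
  n_ids <- nrow(ids)
  empty <- tibble::tibble(
    intensity = rep(NA_real_, n_ids),
    rt_start = NA_real_, rt_end = NA_real_, feature_mz = NA_real_,
    feature_rt = NA_real_
  )
  if (nrow(features) == 0 || n_ids == 0) return(empty)

  ord <- order(features$mz)
  fmz <- features$mz[ord]
  lo <- findInterval(ids$mz_theoretical * (1 - mz_tol_ppm * 1e-6), fmz) + 1L
  hi <- findInterval(ids$mz_theoretical * (1 + mz_tol_ppm * 1e-6), fmz)
  n_cand <- pmax(hi - lo + 1L, 0L)
  if (sum(n_cand) == 0) return(empty)

  id_idx <- rep.int(seq_len(n_ids), n_cand)
  feat_pos <- sequence(n_cand, from = lo)
  feat_idx <- ord[feat_pos]

  cand <- tibble::tibble(
    id_idx = id_idx,
    intensity = features$intensity[feat_idx],
    rt_apex = features$rt_apex[feat_idx],
    rt_start = features$rt_start[feat_idx],
    rt_end = features$rt_end[feat_idx],
    feature_mz = features$mz[feat_idx]
  )
  cand$rt_diff <- abs(cand$rt_apex - ids$rt_master[cand$id_idx])
  cand$mz_err <- abs(cand$feature_mz - ids$mz_theoretical[cand$id_idx]) /
    ids$mz_theoretical[cand$id_idx]
  cand <- cand[cand$rt_diff <= rt_window_min, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)

  best <- cand |>
    dplyr::arrange(.data$id_idx, dplyr::desc(.data$intensity),
                   .data$rt_diff, .data$mz_err, .data$feature_mz) |>
    dplyr::distinct(.data$id_idx, .keep_all = TRUE)

  out <- empty
  out$intensity[best$id_idx] <- best$intensity
  out$rt_start[best$id_idx] <- best$rt_start
  out$rt_end[best$id_idx] <- best$rt_end
  out$feature_mz[best$id_idx] <- best$feature_mz
  out$feature_rt[best$id_idx] <- best$rt_apex
  out
}

#' Extract the intensity of one peptide from one feature map
#'
#' Among features with relative m/z error at most `mz_tol_ppm` ppm from the
#' id's theoretical m/z and apex retention time within `rt_window_min`
#' minutes of the id's master retention time, returns the maximum
#' intensity; `NA` when the window is empty (missing is a value, not an
#' error). The matched feature's chromatographic span is reported as the
#' integration bounds.
#'
#' @param features Feature map tibble of one run, already warped onto the
#'   master time base.
#' @param id One-row tibble with `mz_theoretical` and `rt_master`.
#' @param mz_tol_ppm m/z half-window, ppm (default 5, FTICR-grade).
#' @param rt_window_min RT half-window, minutes (default 1).
#' @return One-row tibble `intensity`, `rt_start`, `rt_end`, `feature_mz`,
#'   `feature_rt`.
#' @export
extract_peptide_intensity <- function(features, id, mz_tol_ppm = 5,
                                      rt_window_min = 1) {
  stopifnot(nrow(id) == 1)
  match_features(features, id, mz_tol_ppm, rt_window_min)
}

#' Assemble the peptide-by-sample intensity matrix
#'
#' Applies the windowed-maximum extraction of every merged identification
#' to every (warped) per-sample feature map. The result is a long tibble:
#' one row per (peptide, charge, run), with `NA` intensity where no feature
#' fell in the window and per-cell provenance (matched feature m/z, apex
#' and integration span).
#'
#' @param maps Feature tibble covering all runs (columns `run_id`,
#'   `replicate`, `time_min`, `mz`, `rt_apex`, `rt_start`, `rt_end`,
#'   `intensity`), warped onto the master time base.
#' @param ids Merged identifications from [merge_identifications()].
#' @param mz_tol_ppm,rt_window_min Window half-widths.
#' @return A `peptide_matrix` tibble: `peptide`, `charge`, `run_id`,
#'   `replicate`, `time_min`, `intensity`, `rt_start`, `rt_end`,
#'   `feature_mz`, `feature_rt`.
#' @export
build_peptide_matrix <- function(maps, ids, mz_tol_ppm = 5,
                                 rt_window_min = 1) {
  run_info <- dplyr::distinct(maps, .data$run_id, .data$replicate,
                              .data$time_min)
  if (anyDuplicated(run_info$run_id)) {
    abort("duplicate sample labels: run_id must map to a unique (replicate, time)")
  }
  parts <- lapply(seq_len(nrow(run_info)), function(i) {
    feats <- maps[maps$run_id == run_info$run_id[i], , drop = FALSE]
    hit <- match_features(feats, ids, mz_tol_ppm, rt_window_min)
    dplyr::bind_cols(
      tibble::tibble(peptide = ids$peptide, charge = ids$charge,
                     run_id = run_info$run_id[i],
                     replicate = run_info$replicate[i],
                     time_min = run_info$time_min[i]),
      hit
    )
  })
  out <- dplyr::bind_rows(parts)
  class(out) <- c("peptide_matrix", class(out))
  out
}
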