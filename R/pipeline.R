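# End-to-end orchestration: simulate -> filter -> align -> merge ->
# quantify -> rollup -> normalize -> log2 -> onset -> cluster, with the
# lacZ-analogue fold-change recovery used as the pipeline's headline
# self-check.

#' Recover a protein's induction fold change
#'
#' 2 raised to the mean post-shift log2 expression ratio over all
#' plateau time points (onset-relative time at least `plateau_start_min`)
#' and replicates.
#'
#' @param aligned Log2-stage, onset-aligned `protein_matrix`.
#' @param protein_id Protein to evaluate.
#' @param plateau_start_min Start of the post-shift plateau in
#'   onset-relative minutes (default 60, by when the logistic response has
#'   essentially saturated).
#' @return The recovered fold change (scalar).
#' @export
recover_fold_change <- function(aligned, protein_id,
                                plateau_start_min = 60) {
  if (!identical(matrix_stage(aligned), "log2")) {
    abort("recover_fold_change() expects a log2-stage protein matrix")
  }
  v <- aligned$value[aligned$protein_id == protein_id &
                       aligned$time_min >= plateau_start_min &
                       !is.na(aligned$value)]
  if (length(v) == 0) {
    abort(sprintf("no plateau observations for protein '%s'", protein_id))
  }
  2^mean(v)
}

# warp RT columns of one run's rows in place
warp_run_features <- function(features, warp) {
  features$rt_apex <- apply_warp(warp, features$rt_apex)
  features$rt_start <- apply_warp(warp, features$rt_start)
  features$rt_end <- apply_warp(warp, features$rt_end)
  features
}

#' Run the full label-free diauxie quantitation pipeline
#'
#' Generates a synthetic diauxie experiment (ground-truth proteome, growth
#' curves, tryptic peptides, per-run feature maps and identification
#' lists) and pushes it through every analysis stage: ion-score filtering
#' with decoy FDR estimates before and after the cut, per-run
#' retention-time alignment onto the master run, identification merging,
#' windowed intensity extraction, unique-peptide protein rollup,
#' normalization, log2 transform, growth-curve onset detection, replicate
#' time alignment, expression clustering, and recovery of the lacZ
#' analogue's induction fold change.
#'
#' @param n_proteins,fraction_up,fraction_down Proteome composition.
#' @param design An [experiment_design()].
#' @param intensity_cv,dropout_rate,decoy_fraction,id_prob Generator noise
#'   settings (see [simulate_feature_maps()]).
#' @param score_threshold Ion-score cut (default 25).
#' @param mz_tol_ppm,rt_window_min Extraction window half-widths.
#' @param n_knots,outlier_sd Warp-fit settings (see [fit_warp()]).
#' @param reference Normalization reference reading (see [normalize()]).
#' @param k Number of expression clusters.
#' @param plateau_start_min Post-shift plateau start for fold recovery.
#' @param seed Master seed; all stage seeds derive from it.
#' @param verbose Log per-stage record counts?
#' @return A list of class `diauxie_pipeline` with every intermediate
#'   (truth, growth, simulation, fdr estimates, warps, merged ids, peptide
#'   and protein matrices, onsets, aligned matrix, clusters,
#'   `lacz_fold_change`).
#' @export
run_pipeline <- function(n_proteins = 1000, fraction_up = 0.2,
                         fraction_down = 0.2,
                         design = experiment_design(),
                         intensity_cv = 0.2, dropout_rate = 0.1,
                         decoy_fraction = 0.1, id_prob = 0.6,
                         score_threshold = 25,
                         mz_tol_ppm = 5, rt_window_min = 1,
                         n_knots = 5, outlier_sd = 3,
                         reference = "global", k = 3,
                         plateau_start_min = 60,
                         seed = 42L, verbose = FALSE) {
  say <- function(...) if (verbose) rlang::inform(sprintf(...))

  truth <- generate_proteome(n_proteins, fraction_up, fraction_down,
                             seed = seed)
  peptides <- digest_proteins(truth)
  say("proteome: %d proteins, %d tryptic peptides", nrow(truth),
      nrow(peptides))

  growth <- lapply(seq_len(design$n_replicates), function(r) {
    simulate_growth_curve(design, seed = seed + r)
  })
  sim <- simulate_feature_maps(truth, peptides, design, growth,
                               intensity_cv = intensity_cv,
                               dropout_rate = dropout_rate,
                               decoy_fraction = decoy_fraction,
                               id_prob = id_prob, seed = seed + 100L)
  say("simulated %d features, %d identifications over %d runs",
      nrow(sim$features), nrow(sim$identifications),
      dplyr::n_distinct(sim$features$run_id))

  fdr_before <- estimate_fdr(sim$identifications)
  ids <- filter_by_score(sim$identifications, score_threshold)
  fdr_after <- estimate_fdr(ids)
  say("score >= %g filter: %d -> %d ids (FDR %.3f -> %.3f)",
      score_threshold, nrow(sim$identifications), nrow(ids),
      fdr_before, fdr_after)

  # per-run warp onto the master run, applied to ids and feature maps
  ids_master <- ids[ids$run_id == sim$master_run, , drop = FALSE]
  run_ids <- unique(sim$features$run_id)
  id_rows <- split(seq_len(nrow(ids)), ids$run_id)
  feat_rows <- split(seq_len(nrow(sim$features)), sim$features$run_id)

  warps <- list()
  warped_ids <- ids
  warped_feats <- sim$features
  for (rid in run_ids) {
    rows_i <- id_rows[[rid]]
    rows_f <- feat_rows[[rid]]
    if (rid == sim$master_run) {
      w <- identity_warp()
    } else {
      anchors <- find_anchors(ids[rows_i, , drop = FALSE], ids_master,
                              min_score = score_threshold)
      w <- fit_warp(anchors, n_knots = n_knots, outlier_sd = outlier_sd)
    }
    warps[[rid]] <- w
    warped_ids$rt_observed[rows_i] <- apply_warp(w, ids$rt_observed[rows_i])
    warped_feats[rows_f, ] <- warp_run_features(
      sim$features[rows_f, , drop = FALSE], w)
  }

  merged <- merge_identifications(warped_ids)
  targets <- merged[!merged$is_decoy, , drop = FALSE]
  say("merged to %d (peptide, charge) records (%d targets)",
      nrow(merged), nrow(targets))

  pep_matrix <- build_peptide_matrix(warped_feats, targets,
                                     mz_tol_ppm = mz_tol_ppm,
                                     rt_window_min = rt_window_min)
  mapping <- assign_unique_peptides(targets)
  prot_raw <- rollup(pep_matrix, mapping)
  prot_norm <- normalize(prot_raw, reference = reference)
  prot_log2 <- log2_transform(prot_norm)
  say("protein matrix: %d proteins (reference %s)",
      dplyr::n_distinct(prot_log2$protein_id),
      attr(prot_norm, "reference_protein") %||% "per-sample")

  onsets <- dplyr::bind_rows(lapply(seq_len(design$n_replicates), function(r) {
    oc <- detect_onset(growth[[r]], replicate_id = paste0("r", r))
    dplyr::mutate(oc, replicate = r)
  }))
  aligned <- align_time_scales(prot_log2, onsets)

  clusters <- cluster_profiles(aligned, k = k, seed = seed)

  lacz_id <- truth$protein_id[truth$is_lacz]
  lacz_fold <- recover_fold_change(aligned, lacz_id,
                                   plateau_start_min = plateau_start_min)
  say("lacZ analogue %s: recovered fold change %.2f", lacz_id, lacz_fold)

  mean_ratios <- mean_post_onset_ratio(aligned)

  structure(
    list(truth = truth, peptides = peptides, growth = growth, sim = sim,
         fdr_before_filter = fdr_before, fdr_after_filter = fdr_after,
         warps = warps, merged_ids = merged,
         peptide_matrix = pep_matrix, protein_raw = prot_raw,
         protein_normalized = prot_norm, protein_log2 = prot_log2,
         onsets = onsets, aligned = aligned, clusters = clusters,
         mean_ratios = mean_ratios,
         lacz_id = lacz_id, lacz_fold_change = lacz_fold,
         params = list(seed = seed, score_threshold = score_threshold,
                       mz_tol_ppm = mz_tol_ppm,
                       rt_window_min = rt_window_min,
                       plateau_start_min = plateau_start_min)),
    class = "diauxie_pipeline"
  )
}

#' @export
print.diauxie_pipeline <- function(x, ...) {
  cat(sprintf(
    paste0("<diauxie_pipeline> %d proteins, %d merged peptide ids, ",
           "FDR %.3f -> %.3f, lacZ fold %.2f\n"),
    nrow(x$truth), nrow(x$merged_ids), x$fdr_before_filter,
    x$fdr_after_filter, x$lacz_fold_change))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `diauxie_pipeline`.
#' @param ... Unused.
#' @export
glance.diauxie_pipeline <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x$truth),
    n_peptides = nrow(x$peptides),
    n_merged_ids = nrow(x$merged_ids),
    n_quantified_proteins = dplyr::n_distinct(x$protein_log2$protein_id),
    fdr_before_filter = x$fdr_before_filter,
    fdr_after_filter = x$fdr_after_filter,
    mean_onset_min = mean(x$onsets$onset_min),
    lacz_fold_change = x$lacz_fold_change
  )
}
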