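# Shared fixtures, generated in code. Small scales keep the default test
# run fast; the acceptance tests run the study-scale configuration.

tiny_design <- function(seed = 11L) {
  experiment_design(
    n_replicates = 2,
    sampling_times = c(seq(0, 180, 30), seq(190, 310, 10),
                       seq(340, 520, 30)),
    seed = seed
  )
}

# small but complete simulated experiment (cached per test run)
tiny_sim_cache <- new.env(parent = emptyenv())
tiny_sim <- function() {
  if (is.null(tiny_sim_cache$sim)) {
    design <- tiny_design()
    truth <- generate_proteome(n_proteins = 25, seed = 11)
    peptides <- digest_proteins(truth)
    growth <- lapply(seq_len(design$n_replicates),
                     function(r) simulate_growth_curve(design, seed = 11 + r))
    sim <- simulate_feature_maps(truth, peptides, design, growth, seed = 111)
    tiny_sim_cache$sim <- list(design = design, truth = truth,
                               peptides = peptides, growth = growth,
                               sim = sim)
  }
  tiny_sim_cache$sim
}

# identification tibble builder for unit tests
make_ids <- function(peptide, score = 30, run_id = "r1", charge = 2L,
                     accession = "P1", rt = 10, decoy = FALSE) {
  n <- max(lengths(list(peptide, score, run_id, charge, accession, rt,
                        decoy)))
  tibble::tibble(
    run_id = rep_len(run_id, n),
    peptide = rep_len(peptide, n),
    protein_accessions = rep_len(accession, n),
    charge = rep_len(as.integer(charge), n),
    mz_observed = rep_len(500, n),
    rt_observed = rep_len(rt, n),
    ion_score = rep_len(score, n),
    is_decoy = rep_len(decoy, n)
  )
}

# feature map builder
make_features <- function(mz, rt, intensity, run_id = "r1", width = 0.5,
                          replicate = 1L, time_min = 0) {
  tibble::tibble(
    run_id = run_id, replicate = replicate, time_min = time_min,
    mz = mz, rt_start = rt - width / 2, rt_apex = rt,
    rt_end = rt + width / 2, intensity = intensity, charge = 2L
  )
}

# brute-force extraction oracle: full scan over all features
oracle_extract <- function(features, ids, mz_tol_ppm, rt_window_min) {
  vapply(seq_len(nrow(ids)), function(i) {
    ok <- abs(features$mz - ids$mz_theoretical[i]) /
      ids$mz_theoretical[i] <= mz_tol_ppm * 1e-6 &
      abs(features$rt_apex - ids$rt_master[i]) <= rt_window_min
    if (!any(ok)) NA_real_ else max(features$intensity[ok])
  }, numeric(1))
}

# three-archetype log2 protein matrix with known classes, for clustering
archetype_matrix <- function(n_per_class = 50, noise_sd = 0.3, seed = 1,
                             n_replicates = 2) {
  times <- seq(-120, 240, by = 30)
  traj <- function(amp) amp * stats::plogis(times / 15)
  withr::with_seed(seed, {
    rows <- list()
    classes <- c(up = 4, down = -4, flat = 0)
    idx <- 0
    for (cl in names(classes)) {
      for (i in seq_len(n_per_class)) {
        idx <- idx + 1
        for (r in seq_len(n_replicates)) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            protein_id = sprintf("%s%03d", cl, i),
            run_id = paste0("r", r, "_", times),
            replicate = r,
            time_min = times,
            value = traj(classes[[cl]]) + rnorm(length(times), 0, noise_sd),
            truth_class = cl
          )
        }
      }
    }
    out <- dplyr::bind_rows(rows)
    m <- dplyr::select(out, -"truth_class")
    m <- diauxielfq:::new_protein_matrix(m, "log2")
    list(matrix = m,
         truth = dplyr::distinct(out[, c("protein_id", "truth_class")]))
  })
}
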