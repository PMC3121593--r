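# Onset detection, replicate time alignment, profile clustering and
# protein-mRNA lag estimation.

test_that("onset is found at glucose exhaustion, scale-invariantly", {
  design <- tiny_design()
  g <- simulate_growth_curve(design, noise_sd = 0, seed = 2)
  truth_onset <- attr(g, "onset_true_min")
  oc <- detect_onset(g)
  # within one sampling interval of the true glucose-exhaustion time
  step <- max(diff(g$time_min[g$time_min >= truth_onset - 30 &
                                g$time_min <= truth_onset + 30]))
  expect_lte(abs(oc$onset_min - truth_onset), step)
  expect_gte(oc$onset_min, oc$plateau_start_min)
  expect_lte(oc$onset_min, oc$plateau_end_min)

  # cell density at onset is about a quarter of the final density
  expect_equal(oc$od_at_onset / g$od600[nrow(g)], 0.25, tolerance = 0.08)

  # invariant to uniform OD rescaling
  g10 <- g
  g10$od600 <- g10$od600 * 10
  oc10 <- detect_onset(g10)
  expect_equal(oc10$onset_min, oc$onset_min)
  expect_equal(oc10$od_at_onset, 10 * oc$od_at_onset)
})

test_that("a culture that never exhausts glucose has no onset", {
  t <- seq(0, 300, 30)
  curve <- tibble::tibble(
    time_min = t, od600 = 0.01 * exp(0.0173 * t),
    glucose_g_per_L = seq(5, 4, length.out = length(t)),
    lactose_g_per_L = 0)
  expect_error(detect_onset(curve), class = "diauxielfq_no_onset")
  expect_error(detect_onset(curve[1:4, ]), "6 points")
})

test_that("replicate time scales shift to t = 0 at onset", {
  m <- tibble::tibble(
    protein_id = "P1",
    run_id = c("a", "b", "c", "d"),
    replicate = c(1, 1, 2, 2),
    time_min = c(120, 150, 110, 140),
    value = 1:4)
  onsets <- tibble::tibble(replicate = c(1, 2), onset_min = c(120, 130))
  out <- align_time_scales(m, onsets)
  expect_equal(out$time_min, c(0, 30, -20, 10))
  # shifting again with zero onsets is the identity
  zero <- tibble::tibble(replicate = c(1, 2), onset_min = c(0, 0))
  expect_equal(align_time_scales(out, zero)$time_min, out$time_min)
  expect_error(align_time_scales(m, onsets[1, ]), "replicate")
})

test_that("well-separated archetypes are labelled perfectly", {
  fx <- archetype_matrix(n_per_class = 50, noise_sd = 0, seed = 3)
  cl <- cluster_profiles(fx$matrix, seed = 1)
  j <- dplyr::inner_join(cl$labels, fx$truth, by = "protein_id")
  expect_equal(mean(j$class == j$truth_class), 1)
  expect_error(cluster_profiles(fx$matrix, k = 1), "k must be")
})

test_that("noisy archetypes reach 0.9 agreement; clustering is seeded", {
  fx <- archetype_matrix(n_per_class = 40, noise_sd = 0.3, seed = 5)
  cl1 <- cluster_profiles(fx$matrix, seed = 9)
  cl2 <- cluster_profiles(fx$matrix, seed = 9)
  expect_identical(cl1$labels, cl2$labels)
  expect_identical(cl1$total_dissimilarity, cl2$total_dissimilarity)
  j <- dplyr::inner_join(cl1$labels, fx$truth, by = "protein_id")
  expect_gte(mean(j$class == j$truth_class), 0.9)
  expect_s3_class(tidy(cl1), "tbl_df")
  expect_equal(glance(cl1)$k, 3)
})

test_that("labels agree with clara on complete data (independent route)", {
  fx <- archetype_matrix(n_per_class = 30, noise_sd = 0.2, seed = 7)
  cl <- cluster_profiles(fx$matrix, seed = 2)

  wide <- tidyr::pivot_wider(
    dplyr::mutate(tibble::as_tibble(fx$matrix),
                  col = paste0("r", replicate, "_", time_min)),
    id_cols = "protein_id", names_from = "col", values_from = "value")
  m <- as.matrix(wide[, -1])
  ref <- cluster::clara(m, k = 3, samples = 5, pamLike = TRUE)
  # same partition up to label permutation: compare co-membership
  a <- cl$labels$cluster[match(wide$protein_id, cl$labels$protein_id)]
  co_a <- outer(a, a, "==")
  co_b <- outer(ref$clustering, ref$clustering, "==")
  expect_gte(mean(co_a == co_b), 0.95)
})

test_that("profiles with too many missing points are excluded", {
  fx <- archetype_matrix(n_per_class = 10, noise_sd = 0.1, seed = 11)
  m <- fx$matrix
  victim <- m$protein_id == "up001"
  m$value[victim & m$replicate == 1] <- NA  # half the points gone
  cl <- cluster_profiles(m, seed = 3)
  expect_true("up001" %in% cl$excluded)
  expect_false("up001" %in% cl$labels$protein_id)
})

test_that("mRNA lag is recovered on the shift-scan grid", {
  times <- c(seq(0, 180, 30), seq(190, 310, 10), seq(340, 520, 30))
  prot <- tibble::tibble(
    time_min = times,
    value = expression_trajectory(times, 235, 16, lag_min = 10))
  mrna_t <- seq(0, 520, 5)
  mrna <- tibble::tibble(
    time_min = mrna_t,
    relative_expression = expression_trajectory(mrna_t, 235, 16,
                                                lag_min = 0))
  res <- compare_with_mrna(prot, mrna)
  expect_lte(abs(res$lag_min - 10), 1 / 6 + 1e-9)
  expect_gt(res$peak_correlation, 0.999)

  # identical series: zero lag, perfect correlation
  same <- compare_with_mrna(
    prot, dplyr::rename(prot, relative_expression = value))
  expect_equal(same$lag_min, 0)
  expect_equal(same$peak_correlation, 1)

  # lag is never negative by construction
  expect_gte(res$lag_min, 0)

  flat <- tibble::tibble(time_min = times, value = rep(1, length(times)))
  expect_error(
    compare_with_mrna(flat, mrna),
    class = "diauxielfq_zero_variance")
})

test_that("lacZ-analogue protein trails its transcript in generator data", {
  truth <- generate_proteome(n_proteins = 5, seed = 17)
  lacz <- truth[truth$is_lacz, ]
  times <- seq(150, 400, 10)
  prot <- tibble::tibble(
    time_min = times,
    value = expression_trajectory(times, 235, lacz$fold_change,
                                  lacz$lag_min))
  mrna <- simulate_mrna_profiles(truth, onset_min = 235)
  res <- compare_with_mrna(prot,
                           mrna[mrna$gene_id == lacz$protein_id, ])
  expect_equal(res$lag_min, lacz$lag_min, tolerance = 1 / 6 / 10 + 0.02)
})
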