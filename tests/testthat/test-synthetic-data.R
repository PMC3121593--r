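# Generator: proteome truths, growth curves, digestion, feature maps and
# mRNA profiles.

test_that("proteome class fractions, lacZ designation and determinism", {
  one <- generate_proteome(n_proteins = 1, fraction_up = 1,
                           fraction_down = 0, seed = 1)
  expect_equal(one$expression_class, "up")

  p <- generate_proteome(n_proteins = 200, fraction_up = 0.2,
                         fraction_down = 0.3, seed = 5)
  expect_equal(sum(p$expression_class == "up"), 40)
  expect_equal(sum(p$expression_class == "down"), 60)
  expect_equal(sum(p$is_lacz), 1)
  expect_equal(p$fold_change[p$is_lacz], 16)
  expect_equal(p$expression_class[p$is_lacz], "up")

  # class/fold invariants
  expect_true(all(p$fold_change[p$expression_class == "up"] > 1))
  expect_true(all(p$fold_change[p$expression_class == "down"] < 1))
  expect_true(all(p$fold_change[p$expression_class == "flat"] == 1))
  expect_true(all(nchar(p$sequence) >= 50))

  # same seed, bit-identical truth
  expect_identical(p, generate_proteome(n_proteins = 200, fraction_up = 0.2,
                                        fraction_down = 0.3, seed = 5))
  expect_error(generate_proteome(10, fraction_up = 0.7, fraction_down = 0.5),
               "fraction")
})

test_that("growth curve matches closed-form sugar accounting", {
  design <- tiny_design()
  g <- simulate_growth_curve(design, noise_sd = 0, seed = 1)
  onset <- attr(g, "onset_true_min")
  # plateau OD: first sampled point at or after glucose exhaustion
  od_onset <- g$od600[which(g$time_min >= onset)[1]]
  od_final <- g$od600[nrow(g)]

  # equal yields: biomass at onset / final = glucose / total sugar
  expect_equal(od_onset / od_final, 0.25, tolerance = 0.01 / 0.25)
  expect_gte(od_final, 2.2)
  expect_lte(od_final, 2.4)
  expect_true(all(diff(g$od600) >= -1e-12))
  expect_true(all(diff(g$glucose_g_per_L) <= 1e-12))
  expect_true(all(diff(g$lactose_g_per_L) <= 1e-12))

  # sugar mass balance per phase (noiseless): biomass gained equals
  # yield times sugar consumed, measured at the plateau boundary
  yield <- 1.145
  gained1 <- od_onset - g$od600[1]
  used1 <- g$glucose_g_per_L[1] - g$glucose_g_per_L[g$time_min >= onset][1]
  expect_equal(gained1, yield * used1, tolerance = 1e-9)
  gained2 <- od_final - od_onset
  used2 <- max(g$lactose_g_per_L) - g$lactose_g_per_L[nrow(g)]
  expect_equal(gained2, yield * used2, tolerance = 1e-9)

  expect_error(simulate_growth_curve(design, glucose0 = 0), "glucose0")
})

test_that("lactose-free culture plateaus permanently after glucose runs out", {
  g <- simulate_growth_curve(tiny_design(), lactose0 = 0, noise_sd = 0,
                             seed = 1)
  post <- g$od600[g$time_min > attr(g, "onset_true_min")]
  expect_true(all(abs(post - post[1]) < 1e-12))
})

test_that("tryptic digestion obeys the KR-not-before-P rule", {
  prot <- tibble::tibble(protein_id = "P1",
                         sequence = "AAAKPAAARGGGGGK")
  pep <- digest_proteins(prot, length_range = c(3, 30))
  # K before P is not cleaved; cleavage after R and terminal K
  expect_setequal(pep$peptide, c("AAAKPAAAR", "GGGGGK"))

  shared <- tibble::tibble(
    protein_id = c("P1", "P2"),
    sequence = c("AAAGGGKLLLLLLR", "CCCGGGKLLLLLLR"))
  pep2 <- digest_proteins(shared, length_range = c(3, 30))
  row <- pep2[pep2$peptide == "LLLLLLR", ]
  expect_equal(row$protein_accessions, "P1;P2")
  expect_equal(row$n_parents, 2L)

  expect_error(digest_proteins(tibble::tibble(protein_id = "P1",
                                              sequence = "AAXKGG")),
               "X")
})

test_that("peptide masses match independently computed monoisotopic values", {
  # frozen oracle values (summed published residue masses / pyteomics)
  expect_equal(peptide_mass("PEPTIDE"), 799.3600, tolerance = 0.001 / 799)
  expect_equal(peptide_mass("AAGTRWK"), 788.4293, tolerance = 0.001 / 788)
  expect_equal(peptide_mz("MLNSFK", 2), 370.1940, tolerance = 0.001 / 370)
  expect_error(peptide_mass("PEPTIDEZ"), "Z")
})

test_that("noiseless feature maps reproduce trajectories exactly", {
  design <- tiny_design()
  truth <- generate_proteome(n_proteins = 6, fraction_up = 0.5,
                             fraction_down = 0, seed = 3)
  peptides <- digest_proteins(truth)
  growth <- simulate_growth_curve(design, noise_sd = 0, seed = 3)
  sim <- simulate_feature_maps(truth, peptides, design, growth,
                               intensity_cv = 0, dropout_rate = 0,
                               mz_ppm_error = 0, rt_noise_sd = 0,
                               apex_noise_sd = 0, decoy_fraction = 0,
                               id_prob = 1, seed = 9)

  # flat protein: identical intensity at every time point
  flat_id <- truth$protein_id[truth$expression_class == "flat"][1]
  flat_pep <- peptides$peptide[peptides$protein_accessions == flat_id][1]
  ints <- sim$features$intensity[sim$features$run_id %in%
                                   unique(sim$features$run_id) &
                                   abs(sim$features$mz -
                                     peptide_mz(flat_pep, 2)) < 1e-9]
  expect_true(all(abs(ints - ints[1]) < 1e-9 * ints[1]))

  # identity warp on the master run: feature RTs equal master RTs
  mast <- sim$features[sim$features$run_id == sim$master_run, ]
  rt_map <- setNames(sim$peptide_rt$rt_true,
                     round(sim$peptide_rt$mz_theoretical, 6))
  expect_equal(mast$rt_apex,
               unname(rt_map[as.character(round(mast$mz, 6))]),
               tolerance = 1e-9)

  # lacZ analogue: late-plateau / earliest intensity ratio = 16
  lacz <- truth$protein_id[truth$is_lacz]
  tp <- sim$truth_protein[sim$truth_protein$protein_id == lacz &
                            sim$truth_protein$replicate == 1, ]
  ratio <- tp$abundance[which.max(tp$time_min)] /
    tp$abundance[which.min(tp$time_min)]
  expect_equal(ratio, 16, tolerance = 0.01)

  # noiseless end-to-end trajectory equals the trajectory formula exactly
  onset <- attr(growth, "onset_true_min")
  i <- which(truth$is_lacz)
  expected <- truth$baseline_abundance[i] *
    expression_trajectory(tp$time_min, onset, truth$fold_change[i],
                          truth$lag_min[i])
  expect_equal(tp$abundance, expected, tolerance = 1e-12)
})

test_that("feature simulation is reproducible and decoys hit their rate", {
  fx <- tiny_sim()
  sim2 <- simulate_feature_maps(fx$truth, fx$peptides, fx$design,
                                fx$growth, seed = 111)
  expect_identical(fx$sim$features, sim2$features)
  expect_identical(fx$sim$identifications, sim2$identifications)

  ids <- fx$sim$identifications
  n <- nrow(ids)
  expect_gt(n, 1000)
  p_hat <- mean(ids$is_decoy)
  expect_lt(abs(p_hat - 0.1), 2 * sqrt(0.1 * 0.9 / n) + 1 / n)
})

test_that("mRNA profiles lead proteins by the configured lag", {
  truth <- generate_proteome(n_proteins = 4, fraction_up = 0.5,
                             fraction_down = 0.25, seed = 2)
  mrna <- simulate_mrna_profiles(truth, onset_min = 235)

  flat_id <- truth$protein_id[truth$expression_class == "flat"][1]
  flat <- mrna[mrna$gene_id == flat_id, ]
  expect_true(all(flat$relative_expression == 1))

  up <- truth[truth$expression_class == "up", ][1, ]
  m <- mrna[mrna$gene_id == up$protein_id, ]
  half <- 1 + (up$fold_change - 1) / 2
  mrna_half <- min(m$time_min[m$relative_expression >= half])
  prot_traj <- expression_trajectory(m$time_min, 235, up$fold_change,
                                     up$lag_min)
  prot_half <- min(m$time_min[prot_traj >= half])
  expect_lt(mrna_half, prot_half)
})
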