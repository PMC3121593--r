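# Unique-peptide rollup, normalization and log2 transform.

pep_matrix <- function(df) {
  # df: peptide, replicate, time_min, intensity
  df$charge <- 2L
  df$run_id <- paste0("r", df$replicate, "_t", df$time_min)
  class(df) <- c("peptide_matrix", class(df))
  df
}

simple_mapping <- function(peptide, protein_id) {
  tibble::tibble(peptide = peptide, charge = 2L, protein_id = protein_id)
}

test_that("only single-parent target peptides are mapped", {
  ids <- tibble::tibble(
    peptide = c("AAAK", "BBBK", "CCCK", "DDDK"),
    charge = 2L,
    protein_accessions = c("P1", "P1;P2", "DECOY_P3", "P4"),
    is_decoy = c(FALSE, FALSE, TRUE, FALSE))
  mp <- assign_unique_peptides(ids)
  expect_equal(mp$peptide, c("AAAK", "DDDK"))
  expect_equal(mp$protein_id, c("P1", "P4"))
  expect_equal(attr(mp, "excluded")$peptide, "BBBK")

  empty <- assign_unique_peptides(ids[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("rollup sums present peptides and skips missing", {
  m <- pep_matrix(tibble::tibble(
    peptide = c("AAAK", "BBBK", "AAAK", "BBBK"),
    replicate = 1, time_min = c(0, 0, 30, 30),
    intensity = c(10, 20, 40, NA)))
  pr <- rollup(m, simple_mapping(c("AAAK", "BBBK"), "P1"))
  expect_equal(matrix_stage(pr), "raw")
  expect_equal(pr$value[pr$time_min == 0], 30)
  expect_equal(pr$value[pr$time_min == 30], 40)

  # all peptides missing in a sample: protein missing there
  m2 <- pep_matrix(tibble::tibble(
    peptide = "AAAK", replicate = 1, time_min = c(0, 30),
    intensity = c(5, NA)))
  pr2 <- rollup(m2, simple_mapping("AAAK", "P1"))
  expect_true(is.na(pr2$value[pr2$time_min == 30]))

  # permutation invariance in peptide order
  shuffled <- m[c(3, 1, 4, 2), ]
  pr3 <- rollup(shuffled, simple_mapping(c("AAAK", "BBBK"), "P1"))
  expect_equal(as.data.frame(pr3), as.data.frame(pr))
})

test_that("shared peptides never leak into any protein value", {
  ids <- tibble::tibble(
    peptide = c("UNIQK", "SHARK"), charge = 2L,
    protein_accessions = c("P1", "P1;P2"),
    is_decoy = FALSE)
  mp <- assign_unique_peptides(ids)
  m <- pep_matrix(tibble::tibble(
    peptide = c("UNIQK", "SHARK"), replicate = 1, time_min = 0,
    intensity = c(10, 1e9)))
  pr <- rollup(m, mp)
  expect_equal(pr$value, 10)  # the engineered shared intensity is absent
  expect_false("P2" %in% pr$protein_id)
})

test_that("normalization forces 1 at each replicate's earliest point", {
  m <- pep_matrix(tibble::tibble(
    peptide = rep(c("REFK", "AAAK"), each = 4),
    replicate = rep(c(1, 1, 2, 2), 2),
    time_min = rep(c(0, 30), 4),
    intensity = c(100, 100, 200, 200,   # REFK: flat reference, dominant
                  10, 40, 30, 60)))     # AAAK: rising
  pr <- rollup(m, simple_mapping(c("REFK", "AAAK"), c("REF", "PA")))
  nm <- normalize(pr)
  expect_equal(matrix_stage(nm), "normalized")
  expect_equal(attr(nm, "reference_protein"), "REF")
  t0 <- nm[nm$time_min == 0, ]
  expect_true(all(t0$value == 1))
  # AAAK rose 4x in replicate 1 relative to the flat reference
  expect_equal(nm$value[nm$protein_id == "PA" & nm$replicate == 1 &
                          nm$time_min == 30], 4)
  # single protein, single sample normalizes to exactly 1
  one <- rollup(pep_matrix(tibble::tibble(
    peptide = "AAAK", replicate = 1, time_min = 0, intensity = 50)),
    simple_mapping("AAAK", "P1"))
  expect_equal(normalize(one)$value, 1)
  # idempotent at the normalized stage
  expect_identical(normalize(nm), nm)
})

test_that("per-sample reference reading pins the top protein to 1", {
  m <- pep_matrix(tibble::tibble(
    peptide = rep(c("REFK", "AAAK"), each = 2),
    replicate = 1, time_min = rep(c(0, 30), 2),
    intensity = c(100, 110, 10, 40)))
  pr <- rollup(m, simple_mapping(c("REFK", "AAAK"), c("REF", "PA")))
  nm <- normalize(pr, reference = "per_sample")
  # before the t0 division, every sample's max protein sits at 1; the
  # reference protein is that max here, so its profile is constant 1
  expect_true(all(nm$value[nm$protein_id == "REF"] == 1))
})

test_that("missing reference or missing-at-earliest cases are handled", {
  m <- pep_matrix(tibble::tibble(
    peptide = rep(c("REFK", "AAAK"), each = 2),
    replicate = 1, time_min = rep(c(0, 30), 2),
    intensity = c(100, NA, 10, 40)))   # reference missing at t30
  pr <- rollup(m, simple_mapping(c("REFK", "AAAK"), c("REF", "PA")))
  expect_error(normalize(pr), class = "diauxielfq_normalization_error")

  m2 <- pep_matrix(tibble::tibble(
    peptide = rep(c("REFK", "AAAK"), each = 2),
    replicate = 1, time_min = rep(c(0, 30), 2),
    intensity = c(100, 100, NA, 40)))  # AAAK missing at earliest point
  pr2 <- rollup(m2, simple_mapping(c("REFK", "AAAK"), c("REF", "PA")))
  nm2 <- normalize(pr2)
  expect_false("PA" %in% nm2$protein_id)
  expect_equal(attr(nm2, "dropped"), "PA")
})

test_that("log2 transform is exact and guards its domain", {
  m <- pep_matrix(tibble::tibble(
    peptide = rep(c("REFK", "AAAK"), each = 4),
    replicate = 1, time_min = rep(c(0, 30, 60, 90), 2),
    intensity = c(1000, 1000, 1000, 1000,  # dominant flat reference
                  8, 128, 2, 8)))
  pr <- rollup(m, simple_mapping(c("REFK", "AAAK"), c("REF", "PA")))
  lg <- log2_transform(normalize(pr))
  expect_equal(matrix_stage(lg), "log2")
  # ratios 1, 16, 0.25, 1 -> log2 0, 4, -2, 0
  expect_equal(lg$value[lg$protein_id == "PA"], c(0, 4, -2, 0))

  # raw matrices cannot skip the normalization stage
  expect_error(log2_transform(pr), "normalized")

  bad <- normalize(pr)
  bad$value[2] <- 0
  expect_error(log2_transform(bad), class = "diauxielfq_transform_error")
})

test_that("noiseless rollup is proportional to truth abundance", {
  design <- tiny_design()
  truth <- generate_proteome(n_proteins = 8, seed = 13)
  peptides <- digest_proteins(truth)
  growth <- simulate_growth_curve(design, noise_sd = 0, seed = 13)
  sim <- simulate_feature_maps(truth, peptides, design, growth,
                               intensity_cv = 0, dropout_rate = 0,
                               mz_ppm_error = 0, rt_noise_sd = 0,
                               apex_noise_sd = 0, decoy_fraction = 0,
                               id_prob = 1, seed = 14)
  ids <- merge_identifications(
    sim$identifications[sim$identifications$run_id == sim$master_run, ])
  feats <- sim$features[sim$features$run_id == sim$master_run, ]
  pm <- build_peptide_matrix(feats, ids)
  pr <- rollup(pm, assign_unique_peptides(ids))
  tp <- sim$truth_protein[sim$truth_protein$run_id == sim$master_run, ]
  j <- dplyr::inner_join(pr, tp, by = c("protein_id", "run_id",
                                        "replicate", "time_min"))
  # protein value = n_unique_peptides x truth abundance, exactly
  ratio <- j$value / j$abundance
  expect_equal(ratio, j$n_peptides, tolerance = 1e-12)
})
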