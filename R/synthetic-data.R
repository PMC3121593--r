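# Synthetic-data generator: ground-truth proteomes, diauxic growth curves,
# tryptic peptides, per-run LC-MS feature maps and identification lists with
# the statistical structure the downstream analysis assumes.

# Approximate E. coli amino-acid frequencies used for random sequences.
AA_FREQ <- c(
  A = 0.095, R = 0.055, N = 0.039, D = 0.051, C = 0.012, Q = 0.044,
  E = 0.058, G = 0.074, H = 0.022, I = 0.060, L = 0.106, K = 0.044,
  M = 0.028, F = 0.039, P = 0.044, S = 0.058, T = 0.054, W = 0.015,
  Y = 0.028, V = 0.071
)

#' Sampling design of a diauxie time-course experiment
#'
#' Samples are drawn every 30 minutes during balanced growth and every
#' 10 minutes inside a dense window around the expected diauxic shift.
#'
#' @param n_replicates Number of biological replicates (separate cultures).
#' @param sampling_times Minutes since inoculation, strictly increasing.
#'   The default interleaves 30-min spacing outside `dense_window` with
#'   10-min spacing inside it (27 time points over 520 min).
#' @param dense_window `(start, end)` minutes of the densely sampled window.
#' @param seed Integer seed that downstream simulators default to.
#' @return An object of class `experiment_design` (a list).
#' @export
experiment_design <- function(n_replicates = 3,
                              sampling_times = c(seq(0, 180, by = 30),
                                                 seq(190, 310, by = 10),
                                                 seq(340, 520, by = 30)),
                              dense_window = c(190, 310),
                              seed = 42L) {
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  if (is.unsorted(sampling_times, strictly = TRUE)) {
    abort("sampling_times must be strictly increasing")
  }
  structure(
    list(n_replicates = as.integer(n_replicates),
         sampling_times = as.numeric(sampling_times),
         dense_window = as.numeric(dense_window),
         seed = as.integer(seed)),
    class = "experiment_design"
  )
}

#' Generate a ground-truth proteome
#'
#' Draws `n_proteins` proteins split into up-, down- and unchanged (flat)
#' expression classes with random tryptic-ready sequences. Exactly one
#' protein is designated the lacZ analogue: an upregulated protein with a
#' default induction factor of 16 and a 10-min expression lag, mirroring the
#' strong beta-galactosidase induction at the shift. The most abundant
#' protein is fixed to the flat class and boosted well above the rest,
#' emulating the dominance of constitutive proteins (EF-Tu and friends) in
#' an E. coli lysate; it later serves naturally as the normalization
#' reference.
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param fraction_up,fraction_down Fractions assigned to the up/down
#'   classes; must satisfy `0 <= fraction_up + fraction_down <= 1`.
#' @param lacz_fold Induction factor of the lacZ analogue (default 16).
#' @param lacz_lag_min Expression lag of the lacZ analogue in minutes.
#' @param mean_length,sd_length Protein length distribution (residues),
#'   truncated at 50.
#' @param seed Integer seed; identical seeds give identical truths.
#' @return A tibble with columns `protein_id`, `expression_class`
#'   (`up`/`down`/`flat`), `fold_change`, `lag_min`, `baseline_abundance`,
#'   `sequence`, `is_lacz`.
#' @export
generate_proteome <- function(n_proteins = 1000, fraction_up = 0.2,
                              fraction_down = 0.2, lacz_fold = 16,
                              lacz_lag_min = 10,
                              mean_length = 300, sd_length = 80,
                              seed = 42L) {
  if (n_proteins < 1) abort("n_proteins must be >= 1")
  if (fraction_up < 0 || fraction_down < 0 ||
      fraction_up + fraction_down > 1) {
    abort("fraction_up and fraction_down must be non-negative and sum to <= 1")
  }
  withr::with_seed(seed, {
    n_up <- round(fraction_up * n_proteins)
    n_down <- round(fraction_down * n_proteins)
    n_flat <- n_proteins - n_up - n_down
    class <- sample(rep(c("up", "down", "flat"), c(n_up, n_down, n_flat)))

    fold <- rep(1, n_proteins)
    fold[class == "up"] <- 2^runif(sum(class == "up"), 1, 4)
    fold[class == "down"] <- 2^-runif(sum(class == "down"), 1, 4)
    lag <- runif(n_proteins, 2, 20)
    baseline <- rlnorm(n_proteins, meanlog = log(1e6), sdlog = 1)

    len <- pmax(50L, round(rnorm(n_proteins, mean_length, sd_length)))
    sequence <- vapply(len, function(l) {
      paste(sample(names(AA_FREQ), l, replace = TRUE, prob = AA_FREQ),
            collapse = "")
    }, character(1))

    # designated lacZ analogue: first up protein (forced up if none exist)
    i_lacz <- which(class == "up")[1]
    if (is.na(i_lacz)) {
      i_lacz <- 1L
      class[i_lacz] <- "up"
    }
    fold[i_lacz] <- lacz_fold
    lag[i_lacz] <- lacz_lag_min

    # dominant housekeeping reference: flat class, boosted so its summed
    # peptide intensity tops every other protein in every sample (peptide
    # count scales with length, induced proteins gain up to 16x)
    prod <- baseline * len
    cand <- setdiff(order(prod, decreasing = TRUE), i_lacz)[1]
    class[cand] <- "flat"
    fold[cand] <- 1
    baseline[cand] <- 25 * max(prod) / len[cand]

    tibble::tibble(
      protein_id = sprintf("ECP%04d", seq_len(n_proteins)),
      expression_class = class,
      fold_change = fold,
      lag_min = lag,
      baseline_abundance = baseline,
      sequence = sequence,
      is_lacz = seq_len(n_proteins) == i_lacz
    )
  })
}

#' Logistic expression trajectory
#'
#' Relative abundance of a protein over culture time: 1 before the shift,
#' `fold_change` at the post-shift plateau, rising (or falling) along a
#' logistic centred `lag_min` minutes after the diauxic onset.
#'
#' @param time_min Culture time(s), minutes.
#' @param onset_min Diauxic onset, minutes.
#' @param fold_change Plateau / baseline ratio (1 for flat proteins).
#' @param lag_min Delay between onset and the half-maximal response.
#' @param steepness_min Logistic time scale (minutes); the response runs
#'   from ~5% to ~95% of its span over about 6 of these.
#' @return Numeric vector of relative abundances (baseline = 1).
#' @export
expression_trajectory <- function(time_min, onset_min, fold_change, lag_min,
                                  steepness_min = 10) {
  1 + (fold_change - 1) *
    stats::plogis((time_min - onset_min - lag_min) / steepness_min)
}

#' Simulate a diauxic growth curve
#'
#' Two-phase growth: exponential on glucose at rate `mu1` until glucose is
#' exhausted, a plateau of `plateau_min` minutes (the diauxic lag), then
#' exponential on lactose at rate `mu2` until lactose is exhausted, then
#' stationary. Biomass and sugar are tied by `yield_per_g` (OD600 produced
#' per g/L consumed, equal on both sugars), so with the default 0.5 g/L
#' glucose and 1.5 g/L lactose the culture reaches the onset at about one
#' quarter of its final density. Defaults give onset at OD600 ~0.58 around
#' 235 min and a final OD600 of 2.30.
#'
#' @param design An [experiment_design()].
#' @param glucose0,lactose0 Initial sugar concentrations, g/L. Glucose must
#'   be positive; `lactose0 = 0` yields a single-phase curve that plateaus
#'   permanently after glucose runs out.
#' @param yield_per_g OD600 gained per g/L of sugar consumed.
#' @param mu1,mu2 Specific growth rates on glucose/lactose, 1/min.
#' @param plateau_min Duration of the diauxic lag, minutes (20-30 typical).
#' @param od0 Inoculation OD600.
#' @param noise_sd SD of multiplicative (log-scale) OD measurement noise.
#' @param seed Integer seed.
#' @return A `growth_curve` tibble (`time_min`, `od600`, `glucose_g_per_L`,
#'   `lactose_g_per_L`) with attributes `onset_true_min` (the glucose
#'   exhaustion time) and `growth_end_min`.
#' @export
simulate_growth_curve <- function(design = experiment_design(),
                                  glucose0 = 0.5, lactose0 = 1.5,
                                  yield_per_g = 1.145,
                                  mu1 = log(2) / 40, mu2 = 0.007,
                                  plateau_min = 25, od0 = 0.01,
                                  noise_sd = 0.01, seed = design$seed) {
  if (glucose0 <= 0) abort("glucose0 must be positive")
  if (lactose0 < 0) abort("lactose0 must be non-negative")
  if (mu1 <= 0 || mu2 <= 0) abort("growth rates must be positive")

  t <- design$sampling_times
  od_onset <- od0 + yield_per_g * glucose0
  t_glc <- log(od_onset / od0) / mu1          # glucose exhaustion = onset
  t2 <- t_glc + plateau_min                    # growth resumes
  od_final <- od_onset + yield_per_g * lactose0
  # without lactose the plateau is permanent: growth never resumes
  t_end <- if (lactose0 > 0) t2 + log(od_final / od_onset) / mu2 else t2

  od_true <- ifelse(
    t < t_glc, od0 * exp(mu1 * t),
    ifelse(t < t2, od_onset,
           ifelse(t < t_end, od_onset * exp(mu2 * (t - t2)), od_final))
  )
  glucose <- pmax(0, glucose0 - (pmin(od_true, od_onset) - od0) / yield_per_g)
  lactose <- pmax(0, lactose0 - (pmax(od_true, od_onset) - od_onset) /
                    yield_per_g)

  od600 <- withr::with_seed(seed,
    od_true * exp(rnorm(length(t), 0, noise_sd)))

  out <- tibble::tibble(
    time_min = t, od600 = od600,
    glucose_g_per_L = glucose, lactose_g_per_L = lactose
  )
  structure(out,
            class = c("growth_curve", class(out)),
            onset_true_min = t_glc,
            growth_end_min = t_end,
            od_true = od_true)
}

#' In-silico tryptic digestion
#'
#' Cleaves each protein after K or R except when the next residue is P,
#' optionally rejoining up to `max_missed_cleavages` adjacent fragments,
#' and keeps peptides whose length falls in `length_range`. A peptide found
#' in several proteins is listed once with all parents.
#'
#' @param proteome Tibble with `protein_id` and `sequence` columns
#'   (e.g. from [generate_proteome()]).
#' @param max_missed_cleavages Maximum missed cleavage sites per peptide.
#' @param length_range `(min, max)` retained peptide lengths.
#' @return Tibble with `peptide`, `protein_accessions` (";"-separated,
#'   sorted), `n_parents`, `mass_mono` (monoisotopic Da).
#' @export
digest_proteins <- function(proteome, max_missed_cleavages = 0L,
                            length_range = c(6L, 30L)) {
  if (nrow(proteome) == 0 || any(nchar(proteome$sequence) == 0)) {
    abort("proteome sequences must be non-empty")
  }
  bad <- setdiff(unique(unlist(strsplit(proteome$sequence, ""))),
                 names(RESIDUE_MONO_MASS))
  if (length(bad) > 0) {
    abort(paste0("unknown residue letter(s): ", paste(bad, collapse = ", ")),
          class = "diauxielfq_residue_error")
  }

  frag_one <- function(seq) {
    # cut after K/R not followed by P
    cuts <- gregexpr("[KR](?!P)", seq, perl = TRUE)[[1]]
    starts <- c(1L, if (cuts[1] != -1) cuts + 1L)
    ends <- c(if (cuts[1] != -1) cuts, nchar(seq))
    base <- substring(seq, starts, ends)
    n <- length(base)
    out <- base
    if (max_missed_cleavages > 0 && n > 1) {
      for (m in seq_len(min(max_missed_cleavages, n - 1))) {
        idx <- seq_len(n - m)
        joined <- vapply(idx, function(i)
          paste(base[i:(i + m)], collapse = ""), character(1))
        out <- c(out, joined)
      }
    }
    out
  }

  frags <- lapply(proteome$sequence, frag_one)
  tab <- tibble::tibble(
    protein_id = rep(proteome$protein_id, lengths(frags)),
    peptide = unlist(frags)
  )
  tab <- dplyr::filter(tab, nchar(.data$peptide) >= length_range[1],
                       nchar(.data$peptide) <= length_range[2])
  tab <- dplyr::distinct(tab)
  out <- tab |>
    dplyr::group_by(.data$peptide) |>
    dplyr::summarise(
      protein_accessions = paste(sort(unique(.data$protein_id)),
                                 collapse = ";"),
      n_parents = dplyr::n_distinct(.data$protein_id),
      .groups = "drop"
    )
  out$mass_mono <- peptide_mass(out$peptide)
  out
}

# reverse each string in a character vector
str_reverse <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

str_shuffle <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(sample(ch), collapse = ""), character(1))
}

# monotone quadratic-plus-shift RT distortion, invertible on the gradient
distort_rt <- function(rt, a, b, c) a + b * rt + c * rt^2

#' Simulate per-run LC-MS feature maps and identification lists
#'
#' Every peptide receives one true retention time on the master time base
#' (uniform on the gradient window) and a chromatographic peak width. Each
#' run -- one per (replicate, time point) -- distorts true RTs through its
#' own monotone quadratic-plus-shift warp (the master run keeps the
#' identity), perturbs m/z by ppm-scale noise, scales intensities by the
#' parent protein's logistic expression trajectory with multiplicative
#' lognormal noise, and drops a random fraction of features. Each run also
#' yields an MS/MS identification list: true identifications with
#' Gamma(4, 12) ion scores, plus decoys (reversed sequences, `DECOY_`
#' accessions) and an equal number of false target identifications
#' (shuffled sequences assigned to a random protein), both scored from
#' Gamma(2, 8), so the decoy count is an unbiased estimate of the false
#' target count at any score cut.
#'
#' @param truth Proteome truth from [generate_proteome()].
#' @param peptides Peptide table from [digest_proteins()].
#' @param design An [experiment_design()].
#' @param growth A `growth_curve` or list of one per replicate; each
#'   replicate's true onset is taken from its `onset_true_min` attribute.
#' @param mz_ppm_error SD of m/z error in ppm.
#' @param intensity_cv Coefficient of variation of multiplicative lognormal
#'   intensity noise (mean 1).
#' @param dropout_rate Fraction of features omitted uniformly at random.
#' @param decoy_fraction Fraction of each identification list that is decoy
#'   entries (matched by an equal number of false targets).
#' @param id_prob Probability that a peptide is identified in a given run.
#' @param charge_states,charge_probs Charge state mixture (default all 2+).
#' @param rt_gradient `(min, max)` minutes of true RTs (90-min gradient).
#' @param rt_noise_sd SD (min) of identification RT noise.
#' @param apex_noise_sd SD (min) of feature apex RT jitter.
#' @param warp_shift,warp_slope,warp_quad Ranges of the per-run distortion
#'   coefficients `a + b*rt + c*rt^2`.
#' @param seed Integer seed (defaults to the design's seed).
#' @return A list of class `lcms_simulation`: `features` (all runs, long),
#'   `identifications` (all runs, long, with truth column `is_false`),
#'   `truth_protein` (noiseless protein abundance per run), `rt_models`
#'   (per-run distortion coefficients), `peptide_rt` (true master RTs),
#'   `master_run`, `design`, `growth`.
#' @export
simulate_feature_maps <- function(truth, peptides, design = experiment_design(),
                                  growth = NULL,
                                  mz_ppm_error = 1, intensity_cv = 0.2,
                                  dropout_rate = 0.1, decoy_fraction = 0.1,
                                  id_prob = 0.6,
                                  charge_states = 2L, charge_probs = 1,
                                  rt_gradient = c(2, 88),
                                  rt_noise_sd = 0.1, apex_noise_sd = 0.05,
                                  warp_shift = 3, warp_slope = 0.05,
                                  warp_quad = 5e-4,
                                  seed = design$seed) {
  if (dropout_rate < 0 || dropout_rate >= 1) abort("dropout_rate must be in [0, 1)")
  if (decoy_fraction < 0 || decoy_fraction >= 0.5) {
    abort("decoy_fraction must be in [0, 0.5)")
  }
  if (is.null(growth)) growth <- simulate_growth_curve(design, seed = seed)
  if (inherits(growth, "growth_curve")) {
    growth <- rep(list(growth), design$n_replicates)
  }
  if (length(growth) != design$n_replicates) {
    abort("growth must supply one curve per replicate")
  }
  onsets <- vapply(growth, attr, numeric(1), which = "onset_true_min")

  withr::with_seed(seed, {
    n_pep <- nrow(peptides)
    pep <- peptides
    pep$charge <- if (length(charge_states) == 1) {
      rep(as.integer(charge_states), n_pep)
    } else {
      sample(as.integer(charge_states), n_pep, replace = TRUE,
             prob = charge_probs)
    }
    pep$mz_theoretical <- (pep$mass_mono + pep$charge * MASS_PROTON) /
      pep$charge
    pep$rt_true <- runif(n_pep, rt_gradient[1], rt_gradient[2])
    pep$peak_width <- runif(n_pep, 0.3, 1.0)
    pep$rev_seq <- str_reverse(pep$peptide)
    pep$shuf_seq <- str_shuffle(pep$peptide)
    pep$rev_mz <- (peptide_mass(pep$rev_seq) + pep$charge * MASS_PROTON) /
      pep$charge
    pep$shuf_mz <- pep$rev_mz  # permutation preserves composition and mass
    pep$first_parent <- sub(";.*$", "", pep$protein_accessions)

    # peptide x parent incidence for intensity synthesis
    pairs <- tibble::tibble(
      pep_idx = rep(seq_len(n_pep),
                    lengths(strsplit(pep$protein_accessions, ";", fixed = TRUE))),
      protein_id = unlist(strsplit(pep$protein_accessions, ";", fixed = TRUE))
    ) |>
      dplyr::left_join(
        dplyr::select(truth, "protein_id", "baseline_abundance",
                      "fold_change", "lag_min"),
        by = "protein_id")

    runs <- tidyr::expand_grid(
      replicate = seq_len(design$n_replicates),
      time_min = design$sampling_times
    )
    runs$run_id <- paste0("r", runs$replicate, "_t", runs$time_min)
    master_run <- runs$run_id[1]

    n_runs <- nrow(runs)
    rt_models <- tibble::tibble(
      run_id = runs$run_id,
      a = runif(n_runs, -warp_shift, warp_shift),
      b = runif(n_runs, 1 - warp_slope, 1 + warp_slope),
      c = runif(n_runs, -warp_quad, warp_quad)
    )
    rt_models[rt_models$run_id == master_run, c("a", "b", "c")] <-
      list(0, 1, 0)

    sigma <- sqrt(log(1 + intensity_cv^2))
    proton <- MASS_PROTON

    per_run <- function(i) {
      rep_i <- runs$replicate[i]
      t_i <- runs$time_min[i]
      traj <- expression_trajectory(t_i, onsets[rep_i],
                                    pairs$fold_change, pairs$lag_min)
      abn <- rowsum(pairs$baseline_abundance * traj, pairs$pep_idx,
                    reorder = TRUE)[, 1]
      noise <- if (sigma > 0) {
        rlnorm(n_pep, meanlog = -sigma^2 / 2, sdlog = sigma)
      } else rep(1, n_pep)
      a <- rt_models$a[i]; b <- rt_models$b[i]; cc <- rt_models$c[i]
      rt_apex <- distort_rt(pep$rt_true, a, b, cc) +
        rnorm(n_pep, 0, apex_noise_sd)
      mz <- pep$mz_theoretical * (1 + rnorm(n_pep, 0, mz_ppm_error) * 1e-6)
      keep <- runif(n_pep) >= dropout_rate

      feats <- tibble::tibble(
        run_id = runs$run_id[i], replicate = rep_i, time_min = t_i,
        mz = mz[keep],
        rt_start = rt_apex[keep] - pep$peak_width[keep] / 2,
        rt_apex = rt_apex[keep],
        rt_end = rt_apex[keep] + pep$peak_width[keep] / 2,
        intensity = (abn * noise)[keep],
        charge = pep$charge[keep]
      )

      ided <- which(runif(n_pep) < id_prob)
      n_true <- length(ided)
      n_extra <- round(decoy_fraction * n_true / (1 - 2 * decoy_fraction))
      i_dec <- sample.int(n_pep, min(n_extra, n_pep))
      i_fal <- sample.int(n_pep, min(n_extra, n_pep))
      ids <- tibble::tibble(
        run_id = runs$run_id[i],
        peptide = c(pep$peptide[ided], pep$rev_seq[i_dec],
                    pep$shuf_seq[i_fal]),
        protein_accessions = c(
          pep$protein_accessions[ided],
          paste0("DECOY_", pep$first_parent[i_dec], recycle0 = TRUE),
          sample(truth$protein_id, length(i_fal), replace = TRUE)),
        charge = c(pep$charge[ided], pep$charge[i_dec], pep$charge[i_fal]),
        mz_observed = c(
          pep$mz_theoretical[ided] *
            (1 + rnorm(n_true, 0, mz_ppm_error) * 1e-6),
          pep$rev_mz[i_dec] *
            (1 + rnorm(length(i_dec), 0, mz_ppm_error) * 1e-6),
          pep$shuf_mz[i_fal] *
            (1 + rnorm(length(i_fal), 0, mz_ppm_error) * 1e-6)),
        rt_observed = c(
          distort_rt(pep$rt_true[ided], a, b, cc) +
            rnorm(n_true, 0, rt_noise_sd),
          runif(length(i_dec), rt_gradient[1], rt_gradient[2]),
          runif(length(i_fal), rt_gradient[1], rt_gradient[2])),
        ion_score = c(rgamma(n_true, shape = 4, scale = 12),
                      rgamma(length(i_dec), shape = 2, scale = 8),
                      rgamma(length(i_fal), shape = 2, scale = 8)),
        is_decoy = rep(c(FALSE, TRUE, FALSE),
                       c(n_true, length(i_dec), length(i_fal))),
        is_false = rep(c(FALSE, FALSE, TRUE),
                       c(n_true, length(i_dec), length(i_fal)))
      )
      list(feats = feats, ids = ids)
    }

    parts <- lapply(seq_len(n_runs), per_run)

    truth_protein <- tidyr::expand_grid(
      dplyr::select(truth, "protein_id", "baseline_abundance",
                    "fold_change", "lag_min"),
      runs
    )
    truth_protein$abundance <- truth_protein$baseline_abundance *
      expression_trajectory(truth_protein$time_min,
                            onsets[truth_protein$replicate],
                            truth_protein$fold_change,
                            truth_protein$lag_min)

    structure(
      list(
        features = dplyr::bind_rows(lapply(parts, `[[`, "feats")),
        identifications = dplyr::bind_rows(lapply(parts, `[[`, "ids")),
        truth_protein = dplyr::select(truth_protein, "protein_id", "run_id",
                                      "replicate", "time_min", "abundance"),
        rt_models = rt_models,
        peptide_rt = dplyr::select(pep, "peptide", "charge", "rt_true",
                                   "mz_theoretical"),
        master_run = master_run,
        design = design,
        growth = growth
      ),
      class = "lcms_simulation"
    )
  })
}

#' Simulate mRNA expression profiles
#'
#' mRNA trajectories share each protein's expression class and fold change
#' but respond with zero lag: transcription reacts immediately to glucose
#' exhaustion while the protein accumulates later, so the protein always
#' lags its transcript.
#'
#' @param truth Proteome truth from [generate_proteome()].
#' @param onset_min Diauxic onset, minutes.
#' @param times Sampling times of the mRNA series (minutes).
#' @return Tibble `gene_id`, `time_min`, `relative_expression`.
#' @export
simulate_mrna_profiles <- function(truth, onset_min,
                                   times = seq(0, 520, by = 5)) {
  if (nrow(truth) == 0) abort("truth must be non-empty")
  out <- tidyr::expand_grid(
    dplyr::select(truth, gene_id = "protein_id", "fold_change"),
    time_min = as.numeric(times)
  )
  out$relative_expression <- expression_trajectory(
    out$time_min, onset_min, out$fold_change, lag_min = 0)
  dplyr::select(out, "gene_id", "time_min", "relative_expression")
}
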