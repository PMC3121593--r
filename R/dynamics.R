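# Biological-time operations: diauxic onset detection from the growth
# curve, alignment of replicate time scales to t = 0 at onset, CLARA-style
# k-medoids clustering of log2 expression profiles, and protein-vs-mRNA
# lag estimation by a cross-correlation shift scan.

med3 <- function(x) {
  # 3-point running median, endpoints passed through
  if (length(x) < 3) return(x)
  n <- length(x)
  c(x[1],
    vapply(2:(n - 1), function(i) median(x[(i - 1):(i + 1)]), numeric(1)),
    x[n])
}

#' Detect the diauxic onset from a growth curve
#'
#' The onset is the earliest sampled time at which the specific growth rate
#' (centred difference of log OD600, after a 3-point median filter on the
#' OD series) has fallen below `rate_drop_frac` times its pre-shift maximum
#' while glucose is depleted to at most `glucose_frac` of its initial
#' concentration -- the 20-30 minute plateau coinciding with glucose
#' exhaustion. The reported plateau span is the contiguous low-rate
#' interval containing the onset. Invariant to uniform rescaling of the OD
#' values.
#'
#' @param curve A `growth_curve` tibble.
#' @param rate_drop_frac Rate threshold as a fraction of the pre-shift
#'   maximum rate (default 0.25).
#' @param glucose_frac Glucose threshold as a fraction of the initial
#'   concentration (default 0.05).
#' @param replicate_id Label carried into the result.
#' @return An `onset_call` tibble (one row): `replicate_id`, `onset_min`,
#'   `od_at_onset`, `plateau_start_min`, `plateau_end_min`.
#' @export
detect_onset <- function(curve, rate_drop_frac = 0.25, glucose_frac = 0.05,
                         replicate_id = "r1") {
  if (nrow(curve) < 6) abort("curve must have at least 6 points")
  t <- curve$time_min
  od <- med3(curve$od600)
  n <- length(t)
  rate <- rep(NA_real_, n)
  idx <- 2:(n - 1)
  rate[idx] <- (log(od[idx + 1]) - log(od[idx - 1])) / (t[idx + 1] - t[idx - 1])

  glc0 <- curve$glucose_g_per_L[1]
  depleted <- curve$glucose_g_per_L <= glucose_frac * glc0
  pre_max <- max(rate[!depleted], na.rm = TRUE)
  if (!is.finite(pre_max) || pre_max <= 0) {
    abort("no pre-shift growth phase found",
          class = "diauxielfq_no_onset")
  }
  low <- !is.na(rate) & rate < rate_drop_frac * pre_max
  hit <- which(low & depleted)
  if (length(hit) == 0) {
    abort("no onset: growth rate never drops with glucose depleted",
          class = "diauxielfq_no_onset")
  }
  i_on <- hit[1]
  # contiguous low-rate interval containing the onset
  j0 <- i_on
  while (j0 > 1 && isTRUE(low[j0 - 1])) j0 <- j0 - 1
  j1 <- i_on
  while (j1 < n && isTRUE(low[j1 + 1])) j1 <- j1 + 1

  out <- tibble::tibble(
    replicate_id = replicate_id,
    onset_min = t[i_on],
    od_at_onset = od[i_on],
    plateau_start_min = t[j0],
    plateau_end_min = t[j1]
  )
  class(out) <- c("onset_call", class(out))
  out
}

#' Align replicate time scales to the diauxic onset
#'
#' Shifts each replicate's column times by its own onset so that t = 0
#' marks the observed onset of the diauxic shift in every replicate;
#' columns keep their replicate labels and no interpolation is performed.
#'
#' @param matrix A `protein_matrix` (any stage) with `replicate` and
#'   `time_min` columns.
#' @param onsets Tibble of onset calls, one row per replicate, with
#'   `replicate` (integer, matching the matrix) and `onset_min` columns.
#' @return The matrix with `time_min` replaced by onset-relative time.
#' @export
align_time_scales <- function(matrix, onsets) {
  reps <- unique(matrix$replicate)
  missing <- setdiff(reps, onsets$replicate)
  if (length(missing) > 0) {
    abort(paste0("no onset for replicate(s): ",
                 paste(missing, collapse = ", ")))
  }
  shift <- setNames(onsets$onset_min, onsets$replicate)
  stage <- matrix_stage(matrix)
  keep <- list(reference_protein = attr(matrix, "reference_protein"),
               dropped = attr(matrix, "dropped"))
  matrix$time_min <- matrix$time_min -
    unname(shift[as.character(matrix$replicate)])
  if (!is.null(stage)) matrix <- new_protein_matrix(matrix, stage, keep)
  matrix
}

# NA-tolerant squared Euclidean distance between rows of m and rows of
# medoids, rescaled by the fraction of shared-present coordinates (the
# same convention stats::dist uses).
dist_to_medoids <- function(m, medoids) {
  p <- ncol(m)
  out <- matrix(NA_real_, nrow(m), nrow(medoids))
  for (j in seq_len(nrow(medoids))) {
    d2 <- sweep(m, 2, medoids[j, ])^2
    shared <- rowSums(!is.na(d2))
    out[, j] <- sqrt(rowSums(d2, na.rm = TRUE) * p / shared)
  }
  out
}

#' Cluster protein expression profiles (CLARA-style k-medoids)
#'
#' Divides log2 expression profiles into k groups (default 3: upregulated,
#' downregulated, unchanged). Following CLARA, `n_subsamples` random
#' subsets of `subsample_size` profiles are each clustered by full
#' k-medoids (PAM build + swap, via [cluster::pam()]) under Euclidean
#' distance restricted to time points present in both profiles; the medoid
#' set with the smallest total dissimilarity over *all* profiles wins, and
#' every profile is labelled by its nearest medoid. Profiles with less than
#' 80% of time points present are excluded. Clusters are then given
#' semantic names by the end-minus-start slope of their medoid: most
#' positive = `up`, most negative = `down`, the rest = `flat`.
#'
#' @param matrix Log2-stage `protein_matrix` (typically onset-aligned).
#' @param k Number of clusters (>= 2; default 3).
#' @param n_subsamples Number of CLARA subsamples (default 5).
#' @param subsample_size Rows per subsample (default `min(n, 40 + 2k)`).
#' @param seed Random seed for the subsampling (default 42).
#' @param min_presence Minimum fraction of present time points (default
#'   0.8).
#' @return A `profile_clusters` object: `labels` (tibble `protein_id`,
#'   `cluster`, `class`), `medoids` (long tibble of medoid profiles),
#'   `total_dissimilarity`, `k`, `n_clustered`, `excluded`.
#' @export
cluster_profiles <- function(matrix, k = 3, n_subsamples = 5,
                             subsample_size = NULL, seed = 42,
                             min_presence = 0.8) {
  if (k < 2) abort("k must be >= 2")
  wide <- tibble::as_tibble(matrix) |>
    dplyr::mutate(col = paste0("r", .data$replicate, "_", .data$time_min)) |>
    dplyr::select("protein_id", "col", "value") |>
    tidyr::pivot_wider(names_from = "col", values_from = "value")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$protein_id
  presence <- rowMeans(!is.na(m))
  excluded <- rownames(m)[presence < min_presence]
  m <- m[presence >= min_presence, , drop = FALSE]
  n <- nrow(m)
  if (n < k) {
    abort(sprintf("only %d complete-enough profiles for k = %d", n, k),
          class = "diauxielfq_clustering_error")
  }
  if (is.null(subsample_size)) {
    subsample_size <- min(n, 40 + 2 * k)
  }
  subsample_size <- max(k, min(subsample_size, n))

  best <- withr::with_seed(seed, {
    candidates <- lapply(seq_len(n_subsamples), function(s) {
      idx <- sample.int(n, subsample_size)
      d <- dist(m[idx, , drop = FALSE])
      fit <- cluster::pam(d, k = k, diss = TRUE)
      med_idx <- idx[fit$id.med]
      dmat <- dist_to_medoids(m, m[med_idx, , drop = FALSE])
      list(med_idx = med_idx,
           total = sum(apply(dmat, 1, min)),
           dmat = dmat)
    })
    candidates[[which.min(vapply(candidates, `[[`, numeric(1), "total"))]]
  })

  assignment <- apply(best$dmat, 1, which.min)
  med_ids <- rownames(m)[best$med_idx]

  # semantic names from medoid end-minus-start slope
  med_m <- m[best$med_idx, , drop = FALSE]
  times <- as.numeric(sub("^r[0-9]+_", "", colnames(m)))
  first_cols <- which(times == min(times))
  last_cols <- which(times == max(times))
  slope <- rowMeans(med_m[, last_cols, drop = FALSE], na.rm = TRUE) -
    rowMeans(med_m[, first_cols, drop = FALSE], na.rm = TRUE)
  class_name <- rep("flat", k)
  class_name[which.max(slope)] <- "up"
  class_name[which.min(slope)] <- "down"

  labels <- tibble::tibble(
    protein_id = rownames(m),
    cluster = as.integer(assignment),
    class = class_name[assignment]
  )
  medoids <- tibble::tibble(
    cluster = rep(seq_len(k), each = ncol(m)),
    class = rep(class_name, each = ncol(m)),
    medoid_protein = rep(med_ids, each = ncol(m)),
    column = rep(colnames(m), k),
    time_min = rep(times, k),
    value = as.vector(t(med_m))
  )
  structure(
    list(labels = labels, medoids = medoids,
         total_dissimilarity = best$total,
         k = as.integer(k), n_clustered = n, excluded = excluded),
    class = "profile_clusters"
  )
}

#' @export
print.profile_clusters <- function(x, ...) {
  cat(sprintf("<profile_clusters> k = %d, %d profiles, total dissimilarity %.2f\n",
              x$k, x$n_clustered, x$total_dissimilarity))
  print(table(x$labels$class))
  invisible(x)
}

#' @rdname cluster_profiles
#' @param x A `profile_clusters`.
#' @param ... Unused.
#' @export
tidy.profile_clusters <- function(x, ...) x$labels

#' @rdname cluster_profiles
#' @export
glance.profile_clusters <- function(x, ...) {
  tibble::tibble(k = x$k, n_clustered = x$n_clustered,
                 n_excluded = length(x$excluded),
                 total_dissimilarity = x$total_dissimilarity)
}

#' Estimate the lag between protein and mRNA dynamics
#'
#' Standardizes both series, interpolates the mRNA series linearly onto
#' shifted protein times, and scans shifts on a 10-second grid in
#' `[0, max_lag_min]` for the one maximizing the Pearson correlation
#' between protein(t) and mRNA(t - shift). The lag is non-negative by
#' construction: protein accumulation can only trail transcription.
#'
#' @param protein_profile Tibble `time_min`, `value` (linear-scale protein
#'   abundance or expression ratio).
#' @param mrna_profile Tibble `time_min`, `relative_expression` for one
#'   gene.
#' @param max_lag_min Largest shift scanned, minutes (default 30).
#' @param grid_min Shift grid step, minutes (default 1/6 = 10 s).
#' @return One-row tibble `lag_min`, `peak_correlation`.
#' @export
compare_with_mrna <- function(protein_profile, mrna_profile,
                              max_lag_min = 30, grid_min = 1 / 6) {
  tp <- protein_profile$time_min
  vp <- protein_profile$value
  tm <- mrna_profile$time_min
  vm <- mrna_profile$relative_expression
  if (stats::sd(vp) == 0 || stats::sd(vm) == 0) {
    abort("zero variance: correlation undefined for flat profiles",
          class = "diauxielfq_zero_variance")
  }
  shifts <- seq(0, max_lag_min, by = grid_min)
  cors <- vapply(shifts, function(s) {
    at <- tp - s
    ok <- at >= min(tm) & at <= max(tm)
    if (sum(ok) < 5) return(NA_real_)
    mi <- approx(tm, vm, xout = at[ok])$y
    if (stats::sd(mi) == 0 || stats::sd(vp[ok]) == 0) return(NA_real_)
    cor(vp[ok], mi)
  }, numeric(1))
  if (all(is.na(cors))) {
    abort("insufficient overlap between protein and mRNA series")
  }
  i <- which.max(cors)
  tibble::tibble(lag_min = shifts[i], peak_correlation = cors[i])
}
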