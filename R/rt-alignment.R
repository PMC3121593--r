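# Retention-time alignment: estimate a strictly monotone piecewise-linear
# warp from each run onto the master run using shared identified peptides
# as anchors, then apply it to identifications and feature maps.

#' Find retention-time anchors between two runs
#'
#' Matches identifications on (peptide, charge); a peptide identified more
#' than once in either run contributes its highest-scoring instance. Pairs
#' are returned sorted by the run's retention time.
#'
#' @param ids_run,ids_master Score-filtered identification tibbles.
#' @param min_score Additional minimum ion score applied to both sides.
#' @return Tibble `peptide`, `charge`, `rt_run`, `rt_master`.
#' @export
find_anchors <- function(ids_run, ids_master, min_score = 25) {
  best <- function(ids) {
    ids |>
      dplyr::filter(.data$ion_score >= min_score) |>
      dplyr::arrange(dplyr::desc(.data$ion_score)) |>
      dplyr::distinct(.data$peptide, .data$charge, .keep_all = TRUE)
  }
  a <- best(ids_run)
  b <- best(ids_master)
  anchors <- dplyr::inner_join(
    dplyr::select(a, "peptide", "charge", rt_run = "rt_observed"),
    dplyr::select(b, "peptide", "charge", rt_master = "rt_observed"),
    by = c("peptide", "charge")
  ) |>
    dplyr::arrange(.data$rt_run)
  if (nrow(anchors) < 4) {
    abort(sprintf("only %d anchor(s) shared between runs; >= 4 required",
                  nrow(anchors)),
          class = "diauxielfq_insufficient_anchors")
  }
  anchors
}

# least-squares monotone piecewise-linear fit on fixed knots:
# y(x) = intercept + sum_j s_j * ramp_j(x), slopes s_j >= min_slope.
# The intercept is profiled out and the slope bound handled by shifting,
# leaving a nonnegative least-squares problem.
fit_monotone_pwl <- function(x, y, knots, min_slope = 1e-6) {
  n_seg <- length(knots) - 1
  ramp <- function(x) {
    A <- matrix(0, length(x), n_seg)
    for (j in seq_len(n_seg)) {
      A[, j] <- pmin(pmax(x - knots[j], 0), knots[j + 1] - knots[j])
    }
    A
  }
  A <- ramp(x)
  y_adj <- y - min_slope * (x - knots[1])
  Ac <- sweep(A, 2, colMeans(A))
  yc <- y_adj - mean(y_adj)
  s <- pracma::lsqnonneg(Ac, yc)$x
  intercept <- mean(y_adj) - sum(colMeans(A) * s)
  slopes <- s + min_slope
  # all ramps vanish at knots[1], so the curve starts at the intercept
  knot_y <- intercept + c(0, cumsum(slopes * diff(knots)))
  list(knots_x = knots, knots_y = knot_y, slopes = slopes)
}

eval_pwl <- function(x, kx, ky) {
  # piecewise-linear with linear extrapolation from the terminal segments
  n <- length(kx)
  seg <- findInterval(x, kx, all.inside = TRUE)
  slope <- (ky[seg + 1] - ky[seg]) / (kx[seg + 1] - kx[seg])
  ky[seg] + slope * (x - kx[seg])
}

#' Fit a monotone retention-time warp
#'
#' Robust strictly monotone piecewise-linear fit mapping the run's RT axis
#' onto the master's: anchors with absolute residual above `outlier_sd`
#' residual standard deviations are discarded iteratively (at most
#' `max_iter` rounds, guarding against mis-identified anchors), then the
#' final fit places `n_knots` equally spaced knots over the anchor range
#' and solves a least-squares problem with slopes constrained positive.
#' Outside the anchor range the warp extrapolates linearly from the
#' terminal segments, covering the full gradient window.
#'
#' @param anchors Anchor tibble from [find_anchors()].
#' @param n_knots Number of knots (default 5).
#' @param outlier_sd Residual rejection threshold in SD units (default 3).
#' @param max_iter Maximum outlier-rejection rounds (default 5).
#' @return An `rt_warp` object with elements `knots` (tibble `x`, `y`),
#'   `anchor_pairs`, `fit_residual_sd`, `n_anchors_used`.
#' @export
fit_warp <- function(anchors, n_knots = 5, outlier_sd = 3, max_iter = 5) {
  if (nrow(anchors) < 4) abort(">= 4 anchors required")
  if (n_knots < 2) abort("n_knots must be >= 2")
  keep <- anchors
  fit <- NULL
  for (it in seq_len(max_iter)) {
    knots <- seq(min(keep$rt_run), max(keep$rt_run), length.out = n_knots)
    if (any(diff(knots) <= 0)) {
      abort("degenerate anchors: zero retention-time spread",
            class = "diauxielfq_fit_error")
    }
    fit <- fit_monotone_pwl(keep$rt_run, keep$rt_master, knots)
    res <- keep$rt_master - eval_pwl(keep$rt_run, fit$knots_x, fit$knots_y)
    sd_res <- stats::sd(res)
    if (!is.finite(sd_res) || sd_res == 0) break
    drop <- abs(res) > outlier_sd * sd_res
    if (!any(drop) || sum(!drop) < 4) break
    keep <- keep[!drop, , drop = FALSE]
  }
  res <- keep$rt_master - eval_pwl(keep$rt_run, fit$knots_x, fit$knots_y)
  if (any(diff(fit$knots_y) <= 0)) {
    abort("monotonicity infeasible for these anchors",
          class = "diauxielfq_fit_error")
  }
  structure(
    list(
      knots = tibble::tibble(x = fit$knots_x, y = fit$knots_y),
      anchor_pairs = keep,
      fit_residual_sd = stats::sd(res),
      n_anchors_used = nrow(keep)
    ),
    class = "rt_warp"
  )
}

#' Identity warp
#'
#' Convenience constructor mapping a run onto itself (used for the master
#' run).
#'
#' @param range RT range covered by the knots, minutes.
#' @return An `rt_warp`.
#' @export
identity_warp <- function(range = c(0, 90)) {
  structure(
    list(knots = tibble::tibble(x = range, y = range),
         anchor_pairs = tibble::tibble(peptide = character(),
                                       charge = integer(),
                                       rt_run = numeric(),
                                       rt_master = numeric()),
         fit_residual_sd = 0,
         n_anchors_used = 0L),
    class = "rt_warp"
  )
}

#' Apply a retention-time warp
#'
#' Pure, order-preserving function: strictly increasing inputs map to
#' strictly increasing outputs (slopes are constrained positive at fit
#' time).
#'
#' @param warp An `rt_warp` from [fit_warp()].
#' @param rts Retention times (minutes) to map onto the master time base.
#' @return Warped retention times.
#' @export
apply_warp <- function(warp, rts) {
  stopifnot(inherits(warp, "rt_warp"))
  eval_pwl(rts, warp$knots$x, warp$knots$y)
}

#' @export
print.rt_warp <- function(x, ...) {
  cat(sprintf(
    "<rt_warp> %d knots over [%.2f, %.2f] min, %d anchors, residual sd %.4f min\n",
    nrow(x$knots), min(x$knots$x), max(x$knots$x), x$n_anchors_used,
    x$fit_residual_sd))
  invisible(x)
}

#' @rdname fit_warp
#' @param x An `rt_warp`.
#' @param ... Unused.
#' @export
tidy.rt_warp <- function(x, ...) {
  out <- x$knots
  out$segment_slope <- c(NA, diff(out$y) / diff(out$x))
  out
}

#' @rdname fit_warp
#' @export
glance.rt_warp <- function(x, ...) {
  tibble::tibble(
    n_knots = nrow(x$knots),
    n_anchors_used = x$n_anchors_used,
    fit_residual_sd = x$fit_residual_sd
  )
}
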