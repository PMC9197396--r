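#' Inter-sampling interval of one trial
#'
#' Mean time between consecutive paid screen touches; shorter intervals
#' indicate faster sampling. Undefined (NA, with a message) for trials with
#' fewer than two paid touches — such trials are skipped when aggregating.
#'
#' @param paid_times Numeric vector of paid-touch timestamps, seconds from
#'   trial onset, in order.
#' @return Mean successive difference in seconds, or `NA_real_`.
#' @examples
#' inter_sampling_interval(c(2, 5, 9.5))  # 3.75
#' @export
inter_sampling_interval <- function(paid_times) {
  stopifnot(is.numeric(paid_times))
  if (length(paid_times) < 2) {
    message("fewer than two paid touches; ISI undefined for this trial")
    return(NA_real_)
  }
  if (is.unsorted(paid_times)) stop("paid-touch timestamps must be ordered")
  mean(diff(paid_times))
}

#' Subjective uncertainty from confidence ratings
#'
#' Confidence ratings are z-scored within participant (sample SD) and
#' sign-flipped, so the result has mean 0, SD 1, and decreases with
#' confidence.
#'
#' @param ratings Numeric vector of one participant's confidence ratings.
#' @return Z-scored, sign-flipped vector. Constant ratings return all zeros
#'   with a warning.
#' @export
subjective_uncertainty <- function(ratings) {
  stopifnot(is.numeric(ratings), length(ratings) >= 2)
  s <- stats::sd(ratings)
  if (s == 0) {
    warning("constant confidence ratings; subjective uncertainty set to 0")
    return(rep(0, length(ratings)))
  }
  -(ratings - mean(ratings)) / s
}

#' Affective-burden score from depression and anxiety questionnaires
#'
#' Standardises the paired depression (BDI-II) and anxiety (HADS-anxiety)
#' scores and extracts their first principal component, oriented so that
#' higher scores mean more depressed/anxious. For two standardised
#' variables with correlation `r` the first component carries
#' `100 * (1 + |r|) / 2` percent of the total variance.
#'
#' @param bdi Numeric vector of BDI-II scores (0-63).
#' @param hads_anx Numeric vector of HADS anxiety scores (0-21), same
#'   length.
#' @return List with `scores` (PC1 score per participant), `loadings`
#'   (length-2), and `variance_explained` (percent of total variance on
#'   PC1).
#' @examples
#' ab <- affective_burden(c(1, 5, 9, 20), c(2, 4, 7, 15))
#' ab$variance_explained
#' @export
affective_burden <- function(bdi, hads_anx) {
  stopifnot(is.numeric(bdi), is.numeric(hads_anx),
            length(bdi) == length(hads_anx))
  ok <- stats::complete.cases(bdi, hads_anx)
  if (sum(ok) < 3) stop("need at least 3 complete score pairs")
  z <- scale(cbind(bdi = bdi[ok], hads_anx = hads_anx[ok]))
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  load <- pc$rotation[, 1]
  flip <- if (sum(load) < 0) -1 else 1  # orient positively with both scores
  scores <- rep(NA_real_, length(bdi))
  scores[ok] <- flip * pc$x[, 1]
  vars <- pc$sdev^2
  list(scores = scores, loadings = flip * load,
       variance_explained = 100 * vars[1] / sum(vars))
}

# rank-residualise y on covariates (with intercept) by least squares
rank_residuals <- function(y, covariates) {
  X <- cbind(1, covariates)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stop("rank-deficient covariates")
  qr.resid(qr_x, y)
}

#' Partial Spearman correlation with a permutation test
#'
#' Rank-transforms all variables, residualises the ranked `x` and `y` on the
#' ranked covariates by least squares, and correlates the residuals
#' (Pearson). The two-sided p-value comes from random permutations of the
#' pairing between the two residual vectors (reproducible under
#' `set.seed()`).
#'
#' @param x,y Numeric vectors.
#' @param covariates Numeric vector or matrix of controlling variables.
#' @param n_perm Number of permutations (default 10000).
#' @return List with `rho`, `p_value`, `n` (complete cases used) and
#'   `n_perm`.
#' @export
partial_spearman <- function(x, y, covariates, n_perm = 10000) {
  covariates <- as.matrix(covariates)
  ok <- stats::complete.cases(x, y, covariates)
  x <- x[ok]; y <- y[ok]
  covariates <- covariates[ok, , drop = FALSE]
  n <- length(x)
  if (n < ncol(covariates) + 3) stop("too few complete cases")
  rz <- apply(covariates, 2, rank)
  rx <- rank_residuals(rank(x), rz)
  ry <- rank_residuals(rank(y), rz)
  rho <- stats::cor(rx, ry)
  perm <- vapply(seq_len(n_perm), function(i) {
    stats::cor(rx, ry[sample.int(n)])
  }, numeric(1))
  p <- (1 + sum(abs(perm) >= abs(rho))) / (n_perm + 1)
  list(rho = rho, p_value = p, n = n, n_perm = n_perm)
}

#' Permutation contrast between two groups
#'
#' Observed difference of group means (first level minus second level of
#' `group`), with a two-sided p-value from random relabellings
#' (reproducible under `set.seed()`). A desk-scale substitute for
#' cohort-level mixed-effects group tests on participant summaries.
#'
#' @param values Numeric vector of per-participant summaries.
#' @param group Factor or character vector with exactly two levels.
#' @param n_perm Number of permutations (default 10000).
#' @return List with `mean_difference`, `p_value`, `levels`, `n_perm`.
#' @export
permutation_group_contrast <- function(values, group, n_perm = 10000) {
  ok <- stats::complete.cases(values, group)
  values <- values[ok]
  group <- factor(group[ok])
  if (nlevels(group) != 2) stop("`group` must have exactly two levels")
  if (any(table(group) < 2)) stop("each group needs at least 2 observations")
  g1 <- group == levels(group)[1]
  n1 <- sum(g1)
  total <- sum(values)
  n <- length(values)
  obs <- sum(values[g1]) / n1 - (total - sum(values[g1])) / (n - n1)
  perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, n1)
    s1 <- sum(values[idx])
    s1 / n1 - (total - s1) / (n - n1)
  }, numeric(1))
  p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  list(mean_difference = obs, p_value = p, levels = levels(group),
       n_perm = n_perm)
}

#' Bonferroni-corrected significance threshold
#'
#' @param k Number of tests in the family.
#' @param alpha Family-wise error rate (default 0.05).
#' @return Per-test threshold `alpha / k`.
#' @export
bonferroni_threshold <- function(k, alpha = 0.05) {
  stopifnot(k >= 1)
  alpha / k
}

#' Per-participant behavioural summary
#'
#' Aggregates trial-level behaviour into one row per participant: mean
#' inter-sampling interval (over trials with at least two paid touches),
#' mean paid-sample count, mean final expected error, mean localisation
#' error, plus the fitted extraction rate and the mean deviation from the
#' optimal sample count when fits are supplied.
#'
#' @param trials Trial table (see [load_dataset()] schema).
#' @param samples Sample table with `participant_id`, `trial_id`, `t_s`,
#'   `paid`.
#' @param fits Optional named list of efficiency fits per participant.
#' @param trajectories Optional named list (per participant) of per-trial
#'   `EE_opt` trajectories, used for the mean final `EE`.
#' @param deviations Optional output of [deviation_from_optimal()].
#' @param groups Optional data.frame `participant_id`, `group`.
#' @return Data.frame, one row per participant.
#' @export
behavioural_summary <- function(trials, samples, fits = NULL,
                                trajectories = NULL, deviations = NULL,
                                groups = NULL) {
  ids <- unique(trials$participant_id)
  rows <- lapply(ids, function(id) {
    tr <- trials[trials$participant_id == id, ]
    sm <- samples[samples$participant_id == id & samples$paid == 1, ]
    isis <- vapply(split(sm$t_s, sm$trial_id), function(tt) {
      if (length(tt) < 2) NA_real_ else mean(diff(sort(tt)))
    }, numeric(1))
    fin <- if (!is.null(trajectories)) {
      mean(vapply(trajectories[[as.character(id)]],
                  function(v) v[length(v)], numeric(1)))
    } else NA_real_
    data.frame(
      participant_id = id,
      mean_ISI = mean(isis, na.rm = TRUE),
      mean_samples = mean(tr$n_paid_samples),
      alpha = if (!is.null(fits)) fits[[as.character(id)]]$alpha else NA_real_,
      deviation = if (!is.null(deviations)) {
        mean(deviations$deviation[deviations$participant_id == id])
      } else NA_real_,
      mean_final_EE = fin,
      mean_error = mean(tr$error_px),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(groups)) {
    out <- merge(groups[, c("participant_id", "group")], out,
                 by = "participant_id", sort = FALSE)
  }
  out
}
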