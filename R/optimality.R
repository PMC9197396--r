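#' Expected-value curve over the number of paid samples
#'
#' Replaces the localisation error in the score rule by the expected error
#' predicted from a participant's decay fit:
#' \deqn{\widehat{EV}(s) = R_0 - s\,\eta_s - \eta_e\,\widehat{EE}(s+1),}
#' where `s` counts paid samples, so the screen shows `s + 1` dots (the free
#' initial dot plus `s` paid ones) and the `EE` term is [predict_ee()] at
#' dot count `s + 1`. The softmax stopping distribution and the optimal
#' sample count \eqn{s^\star} (smallest argmax of the curve) are attached.
#'
#' @param fit A [fit_extraction_rate()] object.
#' @param R0 Initial credit reserve.
#' @param eta_s Cost per paid sample, credits.
#' @param eta_e Cost per pixel of error, credits (default 1.2).
#' @param s_max Largest paid-sample count evaluated. Default: smallest `s`
#'   at which the predicted decay term is within 0.1\% of the asymptote,
#'   capped at 60 (the softmax tail mass beyond is negligible because EV
#'   then decreases linearly).
#' @return An object of class `cq_evcurve`: list with `s` (0..`s_max`),
#'   `ev` (credits), `stop_prob` (softmax over `ev`), and `s_star`.
#' @examples
#' fit <- structure(list(alpha = 0.5, ee_inf = 20, baseline = 100),
#'                  class = "cq_efficiency")
#' ev <- expected_value_curve(fit, R0 = 130, eta_s = 5, s_max = 5)
#' ev$ev      # 10 53 72 79 80 78
#' ev$s_star  # 4
#' @export
expected_value_curve <- function(fit, R0, eta_s, eta_e = 1.2, s_max = NULL) {
  stopifnot(inherits(fit, "cq_efficiency"))
  if (is.null(s_max)) {
    gap <- fit$baseline - fit$ee_inf
    tol <- 1e-3 * fit$ee_inf
    s_max <- if (gap <= tol) 1L else {
      ceiling(log(tol / gap) / log(1 - fit$alpha))
    }
    s_max <- as.integer(min(max(s_max, 1), 60))
  }
  stopifnot(s_max >= 1)
  s <- 0:s_max
  ev <- R0 - s * eta_s - eta_e * predict_ee(fit, s + 1)
  p <- stopping_distribution(ev)
  structure(
    list(s = s, ev = ev, stop_prob = p, s_star = s[which.max(ev)]),
    class = "cq_evcurve"
  )
}

#' @export
print.cq_evcurve <- function(x, ...) {
  cat(sprintf(
    "Expected-value curve over s = 0..%d paid samples; s* = %d (EV %.1f credits)\n",
    max(x$s), x$s_star, max(x$ev)))
  invisible(x)
}

#' Softmax stopping distribution over expected values
#'
#' \deqn{p(s) = \exp(EV(s)) / \sum_i \exp(EV(i)),} computed overflow-safely
#' (max-subtraction; the softmax is invariant to additive shifts). EV is
#' taken in raw credits with unit temperature.
#'
#' @param ev Numeric vector of finite expected values.
#' @return Probabilities summing to 1.
#' @examples
#' stopping_distribution(c(1, 0))  # 0.731, 0.269
#' @export
stopping_distribution <- function(ev) {
  if (length(ev) == 0) stop("empty expected-value vector")
  if (any(!is.finite(ev))) stop("expected values must be finite")
  w <- exp(ev - max(ev))
  w / sum(w)
}

#' Optimal number of paid samples
#'
#' The smallest `s` at which the expected-value curve is maximal; equals the
#' mode of the softmax stopping distribution.
#'
#' @param ev A `cq_evcurve` object, or a numeric vector of EV values taken
#'   to correspond to `s = 0, 1, 2, ...`.
#' @return Integer sample count.
#' @export
optimal_sample_count <- function(ev) {
  if (inherits(ev, "cq_evcurve")) return(ev$s_star)
  stopifnot(is.numeric(ev), length(ev) >= 1)
  which.max(ev) - 1L
}

#' Deviation from the optimal sample count
#'
#' Per participant and condition, the mean number of paid samples actually
#' acquired minus that participant-condition's optimal count \eqn{s^\star}
#' (positive = over-sampling, negative = under-sampling).
#'
#' @param trials Trial table with columns `participant_id`, `R0`, `eta_s`,
#'   `n_paid_samples`.
#' @param fits Named list of [fit_extraction_rate()] objects, one per
#'   participant id appearing in `trials`.
#' @param config A [task_config()] object (supplies `eta_e` and the level
#'   labels for `R0`/`eta_s`).
#' @return Data.frame: `participant_id`, `R0_level`, `cost_level`,
#'   `mean_samples`, `s_star`, `deviation`. Participants missing a condition
#'   are omitted from it with a warning.
#' @export
deviation_from_optimal <- function(trials, fits, config) {
  stopifnot(is.data.frame(trials),
            all(c("participant_id", "R0", "eta_s", "n_paid_samples") %in%
                  names(trials)),
            inherits(config, "cq_task"))
  ids <- unique(trials$participant_id)
  missing_fit <- setdiff(as.character(ids), names(fits))
  if (length(missing_fit)) {
    stop("no efficiency fit for participant(s): ",
         paste(missing_fit, collapse = ", "))
  }
  conds <- expand.grid(R0_level = c("low", "high"),
                       cost_level = c("low", "high"),
                       stringsAsFactors = FALSE)
  rows <- vector("list", length(ids) * nrow(conds))
  k <- 0L
  n_missing <- 0L
  for (id in ids) {
    fit <- fits[[as.character(id)]]
    for (j in seq_len(nrow(conds))) {
      R0 <- unname(config$initial_credit[conds$R0_level[j]])
      eta_s <- unname(config$sample_cost[conds$cost_level[j]])
      sel <- trials$participant_id == id & trials$R0 == R0 &
        trials$eta_s == eta_s
      if (!any(sel)) { n_missing <- n_missing + 1L; next }
      curve <- expected_value_curve(fit, R0, eta_s, config$error_cost)
      k <- k + 1L
      rows[[k]] <- data.frame(
        participant_id = id,
        R0_level = conds$R0_level[j], cost_level = conds$cost_level[j],
        mean_samples = mean(trials$n_paid_samples[sel]),
        s_star = curve$s_star, stringsAsFactors = FALSE)
    }
  }
  if (n_missing > 0) {
    warning(n_missing, " participant-condition cell(s) had no trials and were omitted")
  }
  out <- do.call(rbind, rows[seq_len(k)])
  out$deviation <- out$mean_samples - out$s_star
  out
}
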