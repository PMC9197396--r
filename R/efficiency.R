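#' Fit the exponential uncertainty-decay model (information extraction rate)
#'
#' Across a participant's trials, the minimal expected error decays roughly
#' exponentially with the number of dots on screen. With `s` counting dots
#' (the free initial dot is `s = 1`) the model is
#' \deqn{\widehat{EE}(s) = (EE_1 - EE_\infty)(1-\alpha)^{s-1} + EE_\infty,}
#' where the baseline \eqn{EE_1} is fixed to the mean first-dot expected
#' error over the participant's trials, \eqn{\alpha \in (0,1)} is the
#' information extraction rate (per-sample proportional decay of
#' uncertainty) and \eqn{EE_\infty > 0} the asymptote imposed by task
#' geometry. \eqn{(\alpha, EE_\infty)} minimise the summed squared error
#' over all trials and dot indices.
#'
#' For fixed \eqn{\alpha} the objective is quadratic in \eqn{EE_\infty}, so
#' the asymptote is profiled out in closed form and \eqn{\alpha} is found by
#' a coarse grid search followed by local refinement, within the bounds
#' `(1e-6, 1 - 1e-6)` for \eqn{\alpha} and `(1e-6, baseline)` for
#' \eqn{EE_\infty}.
#'
#' @param trajectories List of numeric vectors, one per trial: `EE_opt`
#'   after each dot (element 1 = free initial dot). Trials of length 1
#'   contribute only to the baseline.
#' @return An object of class `cq_efficiency` with components `alpha`,
#'   `ee_inf`, `baseline`, `sse`, `n_trials` and the stacked model frame
#'   `data` (`trial`, `s`, `ee`). Supports `print()`, `summary()`,
#'   `coef()`, `predict()`, `fitted()`, `residuals()` and `plot()`.
#' @seealso [predict_ee()], [expected_value_curve()]
#' @examples
#' tr <- simulate_ee_trajectories(alpha = 0.3, ee_inf = 15, baseline = 90,
#'                                n_trials = 10, n_dots = 8)
#' fit <- fit_extraction_rate(tr)
#' coef(fit)
#' @export
fit_extraction_rate <- function(trajectories) {
  if (!is.list(trajectories) || length(trajectories) == 0) {
    stop("`trajectories` must be a non-empty list of numeric vectors")
  }
  lens <- lengths(trajectories)
  if (any(lens < 1)) stop("empty trajectory supplied")
  if (all(lens == 1)) {
    stop("all trajectories have a single dot; nothing to fit")
  }
  baseline <- mean(vapply(trajectories, `[`, numeric(1), 1))

  dat <- data.frame(
    trial = rep(seq_along(trajectories), lens),
    s = unlist(lapply(lens, seq_len), use.names = FALSE),
    ee = unlist(trajectories, use.names = FALSE)
  )

  lo <- 1e-6
  profile <- function(alpha) {
    g <- (1 - alpha)^(dat$s - 1)
    u <- 1 - g
    denom <- sum(u^2)
    ee_inf <- if (denom > 0) sum(u * (dat$ee - baseline * g)) / denom else baseline
    ee_inf <- min(max(ee_inf, lo), baseline)
    resid <- dat$ee - (baseline - ee_inf) * g - ee_inf
    list(ee_inf = ee_inf, sse = sum(resid^2))
  }

  grid <- seq(0.01, 0.99, by = 0.01)
  sse_grid <- vapply(grid, function(a) profile(a)$sse, numeric(1))
  if (diff(range(sse_grid)) < 1e-12) {
    alpha <- lo  # flat objective (e.g. constant trajectories): lower bound
  } else {
    i <- which.min(sse_grid)
    lower <- if (i == 1) lo else grid[i - 1]
    upper <- if (i == length(grid)) 1 - lo else grid[i + 1]
    alpha <- stats::optimize(function(a) profile(a)$sse,
                             c(lower, upper), tol = 1e-10)$minimum
    alpha <- min(max(alpha, lo), 1 - lo)
  }
  pr <- profile(alpha)

  structure(
    list(alpha = alpha, ee_inf = pr$ee_inf, baseline = baseline,
         sse = pr$sse, n_trials = length(trajectories), data = dat),
    class = "cq_efficiency"
  )
}

#' Predicted expected error at a given dot count
#'
#' Evaluates the fitted decay curve
#' \eqn{(EE_1 - EE_\infty)(1-\alpha)^{s-1} + EE_\infty} at dot count `s`
#' (`s = 1` is the free initial dot and returns the baseline).
#'
#' @param fit A [fit_extraction_rate()] object.
#' @param s Dot count(s), integer-valued, `>= 1`.
#' @return Predicted `EE` in px, same length as `s`.
#' @export
predict_ee <- function(fit, s) {
  stopifnot(inherits(fit, "cq_efficiency"))
  if (any(s < 1)) stop("dot count `s` must be >= 1")
  (fit$baseline - fit$ee_inf) * (1 - fit$alpha)^(s - 1) + fit$ee_inf
}

#' @export
coef.cq_efficiency <- function(object, ...) {
  c(alpha = object$alpha, ee_inf = object$ee_inf, baseline = object$baseline)
}

#' @rdname predict_ee
#' @param object A `cq_efficiency` fit.
#' @param ... Unused.
#' @export
predict.cq_efficiency <- function(object, s = sort(unique(object$data$s)), ...) {
  predict_ee(object, s)
}

#' @export
fitted.cq_efficiency <- function(object, ...) {
  predict_ee(object, object$data$s)
}

#' @export
residuals.cq_efficiency <- function(object, ...) {
  object$data$ee - fitted(object)
}

#' @export
print.cq_efficiency <- function(x, digits = 4, ...) {
  cat("Exponential uncertainty-decay fit\n")
  cat(sprintf("  extraction rate alpha: %.*g\n", digits, x$alpha))
  cat(sprintf("  asymptote EE_inf     : %.*g px\n", digits, x$ee_inf))
  cat(sprintf("  baseline EE (s = 1)  : %.*g px\n", digits, x$baseline))
  cat(sprintf("  trials: %d, points: %d, SSE: %.*g\n",
              x$n_trials, nrow(x$data), digits, x$sse))
  invisible(x)
}

#' @export
summary.cq_efficiency <- function(object, ...) {
  res <- residuals(object)
  out <- list(coefficients = coef(object),
              n_trials = object$n_trials,
              n_points = nrow(object$data),
              rmse = sqrt(mean(res^2)),
              sse = object$sse)
  class(out) <- "summary.cq_efficiency"
  out
}

#' @export
print.summary.cq_efficiency <- function(x, ...) {
  cat("Exponential uncertainty-decay fit\n\nCoefficients:\n")
  print(round(x$coefficients, 4))
  cat(sprintf("\n%d trials, %d dot observations, residual RMSE %.3f px\n",
              x$n_trials, x$n_points, x$rmse))
  invisible(x)
}

#' @export
plot.cq_efficiency <- function(x, ...) {
  agg <- stats::aggregate(ee ~ s, data = x$data, FUN = mean)
  s_max <- max(x$data$s)
  curve_s <- seq(1, s_max, length.out = 100)
  graphics::plot(agg$s, agg$ee, pch = 19,
                 xlab = "dots on screen (s)",
                 ylab = "expected error at ideal placement (px)",
                 ylim = range(0, agg$ee), ...)
  graphics::lines(curve_s, predict_ee(x, curve_s), col = "purple", lwd = 2)
  graphics::abline(h = x$ee_inf, lty = 3)
  graphics::legend("topright", bty = "n",
                   legend = c("observed mean", "fitted decay", "asymptote"),
                   pch = c(19, NA, NA), lty = c(NA, 1, 3),
                   col = c("black", "purple", "black"), lwd = c(NA, 2, 1))
  invisible(x)
}

#' Generate expected-error trajectories from the decay model
#'
#' Forward-simulates the decay curve, optionally with additive Gaussian
#' noise — the generating process the fit is meant to invert, used for
#' parameter-recovery studies.
#'
#' @param alpha,ee_inf,baseline Generating parameters (see
#'   [fit_extraction_rate()]).
#' @param n_trials Number of trials.
#' @param n_dots Dots per trial (scalar or length `n_trials`).
#' @param noise_sd SD of additive Gaussian noise, px (0 = noiseless).
#' @return List of numeric trajectories.
#' @export
simulate_ee_trajectories <- function(alpha, ee_inf, baseline,
                                     n_trials = 60, n_dots = 10,
                                     noise_sd = 0) {
  stopifnot(alpha > 0, alpha < 1, ee_inf > 0, baseline >= ee_inf)
  n_dots <- rep_len(n_dots, n_trials)
  lapply(seq_len(n_trials), function(i) {
    s <- seq_len(n_dots[i])
    y <- (baseline - ee_inf) * (1 - alpha)^(s - 1) + ee_inf
    if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
    y
  })
}
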