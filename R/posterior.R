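#' Uniform prior over hidden-circle centres
#'
#' The ideal observer discretises candidate hidden-circle centres on a
#' square lattice of stride `config$grid_stride`. The prior is uniform over
#' all lattice points at which the hidden circle lies fully inside the
#' search field, i.e. within `field_radius - circle_radius` of the centre.
#'
#' @param config A [task_config()] object.
#' @return An object of class `cq_posterior`: list with lattice coordinates
#'   `x`, `y` (lexicographically sorted), probability `mass`, the number of
#'   observations absorbed `stage`, and the grid geometry.
#' @examples
#' g <- prior_grid(task_config(grid_stride = 16))
#' sum(g$mass)  # 1
#' @export
prior_grid <- function(config) {
  stopifnot(inherits(config, "cq_task"))
  rs <- config$field_radius - config$circle_radius
  stride <- config$grid_stride
  if (stride > rs) stop("grid stride exceeds the prior support radius")
  v <- seq(-floor(rs / stride) * stride, floor(rs / stride) * stride,
           by = stride)
  pts <- expand.grid(y = v, x = v)  # x varies slowest -> (x, y) lexicographic
  keep <- pts$x^2 + pts$y^2 <= rs^2
  x <- pts$x[keep]
  y <- pts$y[keep]
  structure(
    list(x = x, y = y, mass = rep(1 / length(x), length(x)),
         stage = 0L, stride = stride, support_radius = rs,
         circle_radius = config$circle_radius,
         field_radius = config$field_radius),
    class = "cq_posterior"
  )
}

#' @export
print.cq_posterior <- function(x, ...) {
  cat(sprintf(
    "Posterior over hidden-circle centres: %d support points (stride %g px), stage %d\n",
    sum(x$mass > 0), x$stride, x$stage))
  invisible(x)
}

#' Sequential Bayesian update from one sample observation
#'
#' Applies Bayes' rule with the deterministic dot-colour likelihood: a
#' centre \eqn{\lambda} is consistent with a purple dot at \eqn{\sigma} iff
#' \eqn{|\lambda - \sigma| \le r} (boundary inclusive) and with a white dot
#' iff \eqn{|\lambda - \sigma| > r}. The posterior is the renormalised
#' restriction of the prior to the consistent centres.
#'
#' @param grid A `cq_posterior` object.
#' @param touch Numeric length-2, the sampled location (px).
#' @param colour `"purple"` (inside) or `"white"` (outside).
#' @param r Hidden-circle radius, px; defaults to the radius stored in
#'   `grid`.
#' @return The updated `cq_posterior`, with `stage` incremented.
#' @export
update_posterior <- function(grid, touch, colour, r = grid$circle_radius) {
  stopifnot(inherits(grid, "cq_posterior"), length(touch) == 2, r > 0)
  colour <- match.arg(colour, c("purple", "white"))
  inside <- (grid$x - touch[1])^2 + (grid$y - touch[2])^2 <= r^2
  lik <- if (colour == "purple") inside else !inside
  mass <- grid$mass * lik
  total <- sum(mass)
  if (total <= 0) {
    stop("observations are inconsistent with every candidate centre ",
         "(contradictory or corrupt sample data)")
  }
  grid$mass <- mass / total
  grid$stage <- grid$stage + 1L
  grid
}

#' Batch feasible-set posterior (independent oracle)
#'
#' Constructs the posterior directly as the uniform distribution over the
#' feasible set: all prior-support centres within \eqn{r} of every purple
#' dot and strictly farther than \eqn{r} from every white dot. Because the
#' dot-colour likelihood is 0/1 and observations are conditionally
#' independent, this equals sequential Bayesian updating bit-for-bit on the
#' same grid, and is invariant to observation order.
#'
#' @param observations A data.frame with columns `x`, `y`, `colour`
#'   (`"purple"`/`"white"`); zero rows return the prior.
#' @param config A [task_config()] object.
#' @return A `cq_posterior` object at stage `nrow(observations)`.
#' @export
batch_posterior <- function(observations, config) {
  stopifnot(is.data.frame(observations),
            all(c("x", "y", "colour") %in% names(observations)))
  grid <- prior_grid(config)
  if (nrow(observations) == 0) return(grid)
  r2 <- config$circle_radius^2
  feasible <- rep(TRUE, length(grid$x))
  for (i in seq_len(nrow(observations))) {
    inside <- (grid$x - observations$x[i])^2 +
      (grid$y - observations$y[i])^2 <= r2
    feasible <- feasible & if (observations$colour[i] == "purple") inside else !inside
  }
  if (!any(feasible)) {
    stop("observations are inconsistent with every candidate centre ",
         "(contradictory or corrupt sample data)")
  }
  grid$mass <- ifelse(feasible, 1, 0) / sum(feasible)
  grid$stage <- nrow(observations)
  grid
}

# Stride-aligned candidate lattice over the bounding box of the support,
# ordered lexicographically by (x, y). The minimiser of the expected-error
# map is a Weber point of the posterior, which lies in the convex hull of
# the support, hence inside this box.
support_candidates <- function(grid) {
  pos <- grid$mass > 0
  xs <- grid$x[pos]; ys <- grid$y[pos]
  vx <- seq(min(xs), max(xs), by = grid$stride)
  vy <- seq(min(ys), max(ys), by = grid$stride)
  pts <- expand.grid(y = vy, x = vx)
  cbind(x = pts$x, y = pts$y)
}

#' Expected-error map over candidate placements
#'
#' For each candidate placement \eqn{\lambda}, the expected error is the
#' posterior-weighted mean distance to the possible hidden-circle centres:
#' \deqn{EE_s(\lambda) = \sum_i p_s(\lambda_i)\,|\lambda - \lambda_i|.}
#' The ideal placement \eqn{\lambda^\star} minimises this map; ties are
#' broken to the lexicographically smallest candidate.
#'
#' @param grid A `cq_posterior` object.
#' @param candidates Optional two-column matrix/data.frame of candidate
#'   placements (px). Defaults to the stride-aligned lattice covering the
#'   bounding box of the posterior support.
#' @return An object of class `cq_eemap`: list with candidate coordinates
#'   `x`, `y`, expected errors `ee`, the ideal placement `lambda_star` and
#'   its value `ee_opt`, and the posterior `stage`.
#' @export
expected_error_map <- function(grid, candidates = NULL) {
  stopifnot(inherits(grid, "cq_posterior"))
  if (is.null(candidates)) {
    candidates <- support_candidates(grid)
  } else {
    candidates <- as.matrix(candidates)
    if (ncol(candidates) != 2 || nrow(candidates) == 0) {
      stop("`candidates` must be a non-empty two-column matrix of points")
    }
  }
  pos <- grid$mass > 0
  ee <- cq_ee_map_cpp(candidates[, 1], candidates[, 2],
                      grid$x[pos], grid$y[pos], grid$mass[pos])
  best <- which.min(ee)
  structure(
    list(x = candidates[, 1], y = candidates[, 2], ee = ee,
         lambda_star = c(candidates[best, 1], candidates[best, 2]),
         ee_opt = ee[best], stage = grid$stage),
    class = "cq_eemap"
  )
}

#' @export
print.cq_eemap <- function(x, ...) {
  cat(sprintf(
    "Expected-error map: %d candidates, EE_opt = %.2f px at (%g, %g), stage %d\n",
    length(x$ee), x$ee_opt, x$lambda_star[1], x$lambda_star[2], x$stage))
  invisible(x)
}

#' Ideal placement from an expected-error map
#'
#' @param eemap A `cq_eemap` object.
#' @return List with `lambda_star` (numeric length-2, px) and `ee_opt` (px).
#' @export
optimal_placement <- function(eemap) {
  stopifnot(inherits(eemap, "cq_eemap"))
  list(lambda_star = eemap$lambda_star, ee_opt = eemap$ee_opt)
}

# EE_opt for the current posterior without materialising the full map.
ee_opt_of <- function(grid) {
  cand <- support_candidates(grid)
  pos <- grid$mass > 0
  res <- cq_ee_min_cpp(cand[, 1], cand[, 2],
                       grid$x[pos], grid$y[pos], grid$mass[pos])
  list(lambda_star = c(cand[res$index, 1], cand[res$index, 2]),
       ee_opt = res$ee_opt)
}

#' Trajectory of minimal expected error over a trial's samples
#'
#' Replays a trial through the ideal observer: element `k` is the minimal
#' expected error `EE_opt` after absorbing the first `k` dots on screen
#' (the free initial dot included).
#'
#' @param samples A data.frame with columns `x`, `y`, `colour`, ordered by
#'   time (first row = free initial dot).
#' @param config A [task_config()] object.
#' @return Numeric vector of `EE_opt` values (px), one per dot.
#' @export
ee_trajectory <- function(samples, config) {
  stopifnot(is.data.frame(samples), nrow(samples) >= 1,
            all(c("x", "y", "colour") %in% names(samples)))
  grid <- prior_grid(config)
  out <- numeric(nrow(samples))
  for (k in seq_len(nrow(samples))) {
    grid <- update_posterior(grid, c(samples$x[k], samples$y[k]),
                             samples$colour[k])
    out[k] <- ee_opt_of(grid)$ee_opt
  }
  out
}
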