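#' Task configuration for the hidden-circle sampling paradigm
#'
#' Bundles the geometry, economics and timing of the active-sampling task:
#' a circular search field in which a circle of fixed radius is hidden, a
#' per-sample cost \eqn{\eta_s}, a per-pixel localisation penalty
#' \eqn{\eta_e}, and an initial credit reserve \eqn{R_0}. The default field
#' radius is chosen so that the hidden circle covers 5.80\% of the search
#' field (130 / sqrt(0.058) = 539.8 px).
#'
#' @param field_radius Radius of the circular search field, px.
#' @param circle_radius Radius of the hidden circle (and of the localisation
#'   disc), px.
#' @param dot_radius Radius of the displayed sample dots, px (cosmetic:
#'   classification uses the touch point only).
#' @param error_cost \eqn{\eta_e}, credits lost per pixel of localisation
#'   error.
#' @param sample_cost Named numeric of length 2, credits per paid sample at
#'   the `low` and `high` cost levels.
#' @param initial_credit Named numeric of length 2, starting credit reserve
#'   \eqn{R_0} at the `low` and `high` levels.
#' @param sampling_duration Length of the free-sampling phase, seconds.
#' @param placement_duration Length of the placement phase, seconds.
#' @param trials_per_block Active trials per condition block.
#' @param grid_stride Lattice stride, px, used to discretise candidate
#'   hidden-circle centres. Smaller strides approach the per-pixel
#'   computation at quadratic cost (see the methods vignette for the
#'   accuracy/runtime trade-off).
#'
#' @return An object of class `cq_task`: a validated list of the above
#'   fields.
#' @examples
#' cfg <- task_config()
#' round(100 * (cfg$circle_radius / cfg$field_radius)^2, 2)  # 5.8% coverage
#' @export
task_config <- function(field_radius = 540,
                        circle_radius = 130,
                        dot_radius = 4,
                        error_cost = 1.2,
                        sample_cost = c(low = 1, high = 5),
                        initial_credit = c(low = 95, high = 130),
                        sampling_duration = 18,
                        placement_duration = 6,
                        trials_per_block = 15,
                        grid_stride = 4) {
  stopifnot(
    is.numeric(field_radius), field_radius > 0,
    is.numeric(circle_radius), circle_radius > 0,
    circle_radius < field_radius,
    is.numeric(dot_radius), dot_radius > 0,
    is.numeric(error_cost), error_cost > 0,
    is.numeric(grid_stride), grid_stride >= 1,
    grid_stride <= field_radius - circle_radius,
    sampling_duration > 0, placement_duration > 0,
    trials_per_block >= 1
  )
  if (!all(c("low", "high") %in% names(sample_cost)) ||
      !all(c("low", "high") %in% names(initial_credit))) {
    stop("`sample_cost` and `initial_credit` need elements named 'low' and 'high'")
  }
  structure(
    list(
      field_radius = field_radius,
      circle_radius = circle_radius,
      dot_radius = dot_radius,
      error_cost = error_cost,
      sample_cost = sample_cost[c("low", "high")],
      initial_credit = initial_credit[c("low", "high")],
      sampling_duration = sampling_duration,
      placement_duration = placement_duration,
      trials_per_block = trials_per_block,
      grid_stride = grid_stride
    ),
    class = "cq_task"
  )
}

#' @export
print.cq_task <- function(x, ...) {
  cat("Active-sampling task configuration\n")
  cat(sprintf("  search field radius : %g px\n", x$field_radius))
  cat(sprintf("  hidden circle radius: %g px (%.2f%% of field)\n",
              x$circle_radius, 100 * (x$circle_radius / x$field_radius)^2))
  cat(sprintf("  error cost eta_e    : %g credits/px\n", x$error_cost))
  cat(sprintf("  sample cost eta_s   : low %g / high %g credits\n",
              x$sample_cost[["low"]], x$sample_cost[["high"]]))
  cat(sprintf("  initial credit R0   : low %g / high %g credits\n",
              x$initial_credit[["low"]], x$initial_credit[["high"]]))
  cat(sprintf("  sampling window     : %g s (+%g s placement)\n",
              x$sampling_duration, x$placement_duration))
  cat(sprintf("  grid stride         : %g px\n", x$grid_stride))
  invisible(x)
}

#' Condition schedule for one participant
#'
#' The four blocks cross the two initial-credit levels with the two
#' sampling-cost levels; each (R0, eta_s) pair occupies exactly one block of
#' `trials_per_block` trials. Block order is permuted per participant
#' (counterbalancing), using the current RNG state.
#'
#' @param config A [task_config()] object.
#' @param randomize_order Permute block order? Default `TRUE`.
#' @return A data.frame with one row per block: `block_index`, `R0_level`,
#'   `cost_level`, `R0`, `eta_s`.
#' @export
condition_schedule <- function(config, randomize_order = TRUE) {
  stopifnot(inherits(config, "cq_task"))
  grid <- expand.grid(R0_level = c("low", "high"),
                      cost_level = c("low", "high"),
                      stringsAsFactors = FALSE)
  ord <- if (randomize_order) sample.int(4L) else 1:4
  grid <- grid[ord, , drop = FALSE]
  data.frame(
    block_index = 1:4,
    R0_level = grid$R0_level,
    cost_level = grid$cost_level,
    R0 = unname(config$initial_credit[grid$R0_level]),
    eta_s = unname(config$sample_cost[grid$cost_level]),
    row.names = NULL
  )
}

#' Classify a sample touch as inside or outside the hidden circle
#'
#' A touch yields a purple dot iff it lies within the hidden circle,
#' boundary included: \eqn{|\lambda - \sigma| \le r}.
#'
#' @param hidden_center Numeric length-2, centre of the hidden circle (px).
#' @param touch Numeric length-2, touch location (px).
#' @param r Hidden-circle radius, px.
#' @return `"purple"` (inside) or `"white"` (outside).
#' @examples
#' classify_sample(c(0, 0), c(130, 0), 130)  # boundary -> "purple"
#' @export
classify_sample <- function(hidden_center, touch, r) {
  stopifnot(length(hidden_center) == 2, length(touch) == 2, r > 0)
  d <- sqrt(sum((hidden_center - touch)^2))
  if (d <= r) "purple" else "white"
}

#' Trial score
#'
#' The score rule of the active task: the initial reserve minus the sampling
#' cost and the localisation penalty,
#' \deqn{Score = R_0 - s\,\eta_s - e\,\eta_e.}
#' Scores may be negative when costs exceed the reserve.
#'
#' @param R0 Initial credit reserve.
#' @param eta_s Cost per paid sample, credits.
#' @param s Number of paid samples (the free initial dot is not charged).
#' @param eta_e Cost per pixel of localisation error, credits.
#' @param e Localisation error, px.
#' @return Score in credits.
#' @examples
#' score_trial(95, 1, 10, 1.2, 50)  # 25
#' @export
score_trial <- function(R0, eta_s, s, eta_e, e) {
  stopifnot(is.numeric(s), is.numeric(e))
  if (any(s < 0)) stop("negative sample count")
  if (any(e < 0)) stop("negative localisation error")
  R0 - s * eta_s - e * eta_e
}
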