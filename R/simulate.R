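#' Parameters of a simulated sampling agent
#'
#' The agent touches the screen at lognormally distributed intervals. With
#' probability `q` a touch is informative: it is chosen from a coarse
#' proposal set as the location that minimises the expected one-step-ahead
#' `EE_opt` (under an area-scaling approximation, see the methods
#' vignette); otherwise the touch is uniform over the search field. The
#' agent stops when the myopic expected-value gain of one more sample drops
#' below `stop_threshold` (lower thresholds mean more sampling), except
#' with probability `lapse` per step, or when the sampling window runs out.
#'
#' @param isi_mean Mean inter-touch interval, seconds.
#' @param isi_sigma Lognormal sigma of inter-touch intervals.
#' @param q Probability of an informative (greedy) rather than uniform
#'   touch, in `[0, 1]`; maps onto the fitted extraction rate.
#' @param stop_threshold Myopic stop margin, credits: stop when the expected
#'   gain of one more sample falls below it.
#' @param lapse Probability of ignoring the stop rule on a given step.
#' @param jitter_sd SD of Gaussian motor noise added to the final
#'   placement, px.
#' @return An object of class `cq_agent`.
#' @export
agent_params <- function(isi_mean = 1.7, isi_sigma = 0.35, q = 0.75,
                         stop_threshold = 0, lapse = 0.05, jitter_sd = 0) {
  stopifnot(isi_mean > 0, isi_sigma > 0, q >= 0, q <= 1,
            lapse >= 0, lapse <= 1, jitter_sd >= 0)
  structure(
    list(isi_mu = log(isi_mean) - isi_sigma^2 / 2,  # lognormal mean = isi_mean
         isi_sigma = isi_sigma, q = q,
         stop_threshold = stop_threshold, lapse = lapse,
         jitter_sd = jitter_sd),
    class = "cq_agent"
  )
}

#' Synthetic cohort configuration
#'
#' Defaults emulate the study conditions the analysis expects: 27 controls
#' and 27 participants with subjective cognitive impairment (SCI), each
#' completing 4 condition blocks of active trials plus 100 passive offers;
#' questionnaire means/SDs follow the published cohort demographics, with a
#' positive depression-anxiety correlation. SCI agents sample faster
#' (shorter ISI) and stop later (lower stop threshold, hence more samples)
#' with unchanged policy quality `q`, reproducing the "faster but equally
#' efficient" group structure. The default shifts equal 2 between-subject
#' SDs on ISI and on the stop threshold.
#'
#' @param n_control,n_sci Group sizes.
#' @param isi_mean,isi_between_sd Control-group mean inter-touch interval
#'   and its between-participant SD, seconds.
#' @param delta_isi SCI shift of the mean ISI, seconds (negative = faster).
#' @param isi_sigma Within-trial lognormal sigma of intervals.
#' @param stop_mean,stop_between_sd Control-group mean myopic stop
#'   threshold (credits) and its between-participant SD.
#' @param delta_stop SCI shift of the stop threshold (negative = more
#'   samples).
#' @param q_mean,q_between_sd Policy quality mean and between-participant
#'   SD (shared by both groups: equal sampling efficiency).
#' @param delta_q SCI shift of policy quality (default 0).
#' @param lapse,jitter_sd Passed to every agent.
#' @param rho Depression-anxiety correlation in the questionnaire model.
#' @param questionnaire_means,questionnaire_sds Named lists (`control`,
#'   `sci`) of per-group means/SDs for `bdi`, `hads_anx`, `hads_dep`,
#'   `ace_iii`, `age`.
#' @param seed Optional integer seed applied by [simulate_cohort()].
#' @return An object of class `cq_cohort_config`.
#' @export
cohort_config <- function(n_control = 27, n_sci = 27,
                          isi_mean = 1.7, isi_between_sd = 0.2,
                          delta_isi = -0.4, isi_sigma = 0.35,
                          stop_mean = 0, stop_between_sd = 2.5,
                          delta_stop = -5,
                          q_mean = 0.75, q_between_sd = 0.08, delta_q = 0,
                          lapse = 0.05, jitter_sd = 0,
                          rho = 0.68,
                          questionnaire_means = list(
                            control = c(bdi = 4.59, hads_anx = 4.30,
                                        hads_dep = 1.48, ace_iii = 97.89,
                                        age = 62.04),
                            sci = c(bdi = 15.44, hads_anx = 7.04,
                                    hads_dep = 5.26, ace_iii = 95.41,
                                    age = 59.81)),
                          questionnaire_sds = list(
                            control = c(bdi = 4.36, hads_anx = 3.16,
                                        hads_dep = 1.81, ace_iii = 1.80,
                                        age = 6.28),
                            sci = c(bdi = 11.24, hads_anx = 3.32,
                                    hads_dep = 4.61, ace_iii = 4.21,
                                    age = 7.70)),
                          seed = NULL) {
  stopifnot(n_control >= 1, n_sci >= 1, abs(rho) < 1,
            isi_mean > 0, isi_between_sd >= 0, isi_sigma > 0,
            q_mean >= 0, q_mean <= 1)
  structure(as.list(environment()), class = "cq_cohort_config")
}

#' Propose the agent's next sampling location
#'
#' With probability `q` returns the proposal (drawn from the posterior
#' support) with the best expected one-step uncertainty reduction under the
#' area-scaling approximation \eqn{E[EE'] \approx EE\,(p_{in}^{3/2} +
#' p_{out}^{3/2})}, where \eqn{p_{in}} is the posterior probability that
#' the touch lands inside the hidden circle; otherwise returns a uniform
#' draw from the search field. Deterministic given the RNG state.
#'
#' @param grid A `cq_posterior` object.
#' @param agent An [agent_params()] object.
#' @param n_proposals Size of the coarse proposal set.
#' @return Numeric length-2 touch location (px).
#' @export
next_sample_location <- function(grid, agent, n_proposals = 12) {
  stopifnot(inherits(grid, "cq_posterior"), inherits(agent, "cq_agent"))
  if (stats::runif(1) >= agent$q) {
    rad <- grid$field_radius * sqrt(stats::runif(1))
    ang <- 2 * pi * stats::runif(1)
    return(c(rad * cos(ang), rad * sin(ang)))
  }
  pos <- which(grid$mass > 0)
  idx <- pos[sample.int(length(pos), n_proposals, replace = TRUE)]
  # probes: feasible centres displaced by up to ~r, clipped to the field,
  # so the circle boundary can cut through small feasible sets
  d <- stats::runif(n_proposals, 0, 1.05 * grid$circle_radius)
  a <- 2 * pi * stats::runif(n_proposals)
  sx <- grid$x[idx] + d * cos(a)
  sy <- grid$y[idx] + d * sin(a)
  nrm <- pmax(sqrt(sx^2 + sy^2), 1e-12)
  clip <- nrm > grid$field_radius
  sx[clip] <- sx[clip] * grid$field_radius / nrm[clip]
  sy[clip] <- sy[clip] * grid$field_radius / nrm[clip]
  r2 <- grid$circle_radius^2
  w <- grid$mass[pos] / sum(grid$mass[pos])
  score <- vapply(seq_len(n_proposals), function(k) {
    inside <- (grid$x[pos] - sx[k])^2 + (grid$y[pos] - sy[k])^2 <= r2
    p_in <- sum(w[inside])
    p_in^1.5 + (1 - p_in)^1.5
  }, numeric(1))
  best <- which.min(score)
  c(sx[best], sy[best])
}

#' Simulate one active trial
#'
#' Places the hidden centre uniformly over the prior support (snapped to
#' the observer lattice), shows a free purple dot uniformly inside the
#' hidden circle, then runs the agent: lognormal inter-touch intervals
#' within the sampling window, informative-or-random touches, myopic
#' stopping, ideal placement at the final \eqn{\lambda^\star} (plus
#' optional motor jitter) and the score rule.
#'
#' @param agent An [agent_params()] object.
#' @param condition List or one-row data.frame with `R0` and `eta_s`.
#' @param config A [task_config()] object.
#' @param grid Optional precomputed [prior_grid()] (reused across trials).
#' @param ee_cap Point cap for the simulator's expected-error evaluations
#'   (accuracy/runtime knob; see the methods vignette).
#' @param n_proposals Proposal-set size for informative touches.
#' @return List with `samples` (data.frame `t_s`, `x`, `y`, `colour`,
#'   `paid`), `hidden`, `placement`, `n_paid_samples`, `error_px`, `score`,
#'   and the observer's `ee_trajectory` (one value per dot).
#' @export
simulate_trial <- function(agent, condition, config, grid = NULL,
                           ee_cap = 400, n_proposals = 12) {
  stopifnot(inherits(agent, "cq_agent"), inherits(config, "cq_task"))
  if (is.null(grid)) grid <- prior_grid(config)
  i <- sample.int(length(grid$x), 1)
  hidden <- c(grid$x[i], grid$y[i])
  rad <- config$circle_radius * sqrt(stats::runif(1))
  ang <- 2 * pi * stats::runif(1)
  free <- hidden + c(rad * cos(ang), rad * sin(ang))

  res <- cq_simulate_trial_cpp(
    grid$x, grid$y, hidden[1], hidden[2], free[1], free[2],
    config$circle_radius, config$field_radius, grid$stride,
    condition$R0, condition$eta_s, config$error_cost,
    config$sampling_duration,
    agent$isi_mu, agent$isi_sigma, agent$q, agent$stop_threshold,
    agent$lapse, as.integer(n_proposals), as.integer(ee_cap),
    agent$jitter_sd)

  list(
    samples = data.frame(
      t_s = res$t, x = res$x, y = res$y,
      colour = ifelse(res$colour == 1, "purple", "white"),
      paid = res$paid, stringsAsFactors = FALSE),
    hidden = hidden,
    placement = c(res$placement_x, res$placement_y),
    n_paid_samples = res$n_paid,
    error_px = res$error_px,
    score = res$score,
    ee_trajectory = res$ee_trajectory
  )
}

# truncated normal by resampling (clips after 50 tries)
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  for (k in 1:50) {
    bad <- x < lower | x > upper
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, lower), upper)
}

#' Simulate questionnaire scores for a cohort
#'
#' Depression (BDI-II), anxiety (HADS-A) and HADS-depression scores are
#' drawn from a correlated latent Gaussian (correlation `rho` between all
#' pairs), scaled to per-group means/SDs, rounded and clipped to the
#' instrument ranges (BDI 0-63, HADS 0-21, ACE-III 0-100). Cognitive score
#' and age are independent truncated normals.
#'
#' @param cohort A [cohort_config()] object.
#' @return Data.frame: `participant_id`, `group`, `bdi`, `hads_anx`,
#'   `hads_dep`, `ace_iii`, `age`.
#' @export
simulate_questionnaires <- function(cohort) {
  stopifnot(inherits(cohort, "cq_cohort_config"))
  groups <- c(rep("control", cohort$n_control), rep("SCI", cohort$n_sci))
  n <- length(groups)
  key <- ifelse(groups == "control", "control", "sci")
  m <- do.call(rbind, cohort$questionnaire_means[key])
  s <- do.call(rbind, cohort$questionnaire_sds[key])

  # shared latent factor induces correlation rho between affect scores
  f <- stats::rnorm(n)
  lat <- function() sqrt(cohort$rho) * f +
    sqrt(1 - cohort$rho) * stats::rnorm(n)
  clipr <- function(z, mu, sd, lo, hi) pmin(pmax(round(mu + sd * z), lo), hi)
  data.frame(
    participant_id = sprintf("P%02d", seq_len(n)),
    group = groups,
    bdi = clipr(lat(), m[, "bdi"], s[, "bdi"], 0, 63),
    hads_anx = clipr(lat(), m[, "hads_anx"], s[, "hads_anx"], 0, 21),
    hads_dep = clipr(lat(), m[, "hads_dep"], s[, "hads_dep"], 0, 21),
    ace_iii = pmin(pmax(round(rnorm_trunc(n, m[, "ace_iii"], s[, "ace_iii"])),
                        0), 100),
    age = round(rnorm_trunc(n, m[, "age"], s[, "age"], 30, 95)),
    stringsAsFactors = FALSE
  )
}

# default experimentally defined uncertainty bands (px)
default_ee_bands <- function() {
  matrix(c(16.3, 24.4, 27.1, 38.9, 57.5, 58.9, 73.33, 74.18, 91.9, 93.3),
         ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("lo", "hi")))
}

# One consistent 4-purple/4-white dot configuration around hidden centre c0.
# The random geometry (angles, radial factors) is fixed in `real`; `knob`
# deterministically scales it, so EE(knob) is continuous and decreasing and
# can be bisected onto a narrow band.
#   spread mode: purples at radius knob * a_i * r (knob in [0, 1]); whites far
#     outside the feasible region (consistent, uninformative).
#   pinch mode: purples tight around c0; two whites at distance `knob` from c0
#     on opposite sides (knob > r keeps them outside the circle). They pinch
#     the feasible disk into two lobes, raising EE above the single-dot
#     ceiling 2r/3.
draw_offer_realisation <- function(pinch) {
  list(pa = 2 * pi * stats::runif(4),
       pr = if (pinch) 0.04 * sqrt(stats::runif(4)) else
         0.7 + 0.3 * stats::runif(4),
       th = 2 * pi * stats::runif(1),
       fa = 2 * pi * stats::runif(if (pinch) 2 else 4),
       fr = stats::runif(if (pinch) 2 else 4, 0.93, 0.99))
}

build_offer_dots <- function(c0, r, field_radius, real, knob, pinch) {
  rad <- if (pinch) real$pr * r else knob * real$pr * r
  px <- c0[1] + rad * cos(real$pa)
  py <- c0[2] + rad * sin(real$pa)
  if (pinch) {
    wx <- c(c0[1] + knob * cos(real$th), c0[1] - knob * cos(real$th),
            real$fr * field_radius * cos(real$fa))
    wy <- c(c0[2] + knob * sin(real$th), c0[2] - knob * sin(real$th),
            real$fr * field_radius * sin(real$fa))
  } else {
    wx <- real$fr * field_radius * cos(real$fa)
    wy <- real$fr * field_radius * sin(real$fa)
  }
  data.frame(x = c(px, wx), y = c(py, wy),
             colour = rep(c("purple", "white"), each = 4),
             stringsAsFactors = FALSE)
}

#' Generate the passive-task offer set
#'
#' Builds dot configurations (four purple, four white, all consistent with
#' one hidden-circle realisation) whose ideal-observer `EE_opt` falls inside
#' each of five experimentally defined uncertainty bands, crossed with four
#' reward levels; each of the 20 offer types is repeated `reps` times
#' (default 5, i.e. 100 presentations). Configurations are found by guided
#' rejection sampling: a spread knob (purple scatter) is bisected for the
#' lower bands, and for bands above the single-purple-dot ceiling
#' (2r/3 = 86.7 px) two white dots pinch the feasible disk into two lobes,
#' with the pinch distance bisected.
#'
#' @param config A [task_config()] object; `config$grid_stride` sets the
#'   observer resolution used to band the configurations.
#' @param bands Two-column matrix of EE band limits, px (defaults to the
#'   five study bands).
#' @param rewards Reward levels, credits.
#' @param reps Presentations per offer type.
#' @param max_attempts Attempt cap per offer type before signalling an
#'   unreachable band.
#' @return List with `offers` (one row per presentation: `offer_id`,
#'   `presentation`, `ee_band`, `reward`, `ee_px`) and `dots` (8 rows per
#'   offer type: `offer_id`, `dot_index`, `x`, `y`, `colour`).
#' @export
generate_passive_offer_set <- function(config,
                                       bands = default_ee_bands(),
                                       rewards = c(40, 65, 90, 115),
                                       reps = 5,
                                       max_attempts = 400) {
  stopifnot(inherits(config, "cq_task"), ncol(bands) == 2,
            all(bands[, 2] > bands[, 1]), reps >= 1)
  r <- config$circle_radius
  offer_rows <- list(); dot_rows <- list()
  offer_id <- 0L
  for (b in seq_len(nrow(bands))) {
    lo <- bands[b, 1]; hi <- bands[b, 2]
    pinch <- lo > 0.9 * (2 * r / 3)  # band above what purple spread reaches
    for (rew in rewards) {
      offer_id <- offer_id + 1L
      found <- FALSE
      attempts <- 0L
      while (!found && attempts < max_attempts) {
        # fresh random geometry, then bisect its deterministic scale knob
        ca <- 2 * pi * stats::runif(1)
        c0 <- 60 * sqrt(stats::runif(1)) * c(cos(ca), sin(ca))
        real <- draw_offer_realisation(pinch)
        lo_k <- if (pinch) r + 1 else 0
        hi_k <- if (pinch) r + 90 else 1
        for (iter in 1:24) {
          attempts <- attempts + 1L
          knob <- (lo_k + hi_k) / 2
          dots <- build_offer_dots(c0, r, config$field_radius, real, knob,
                                   pinch)
          ee <- tryCatch(
            ee_opt_of(batch_posterior(dots, config))$ee_opt,
            error = function(e) NA_real_)
          if (is.na(ee)) break  # contradictory draw; redraw geometry
          if (ee >= lo && ee <= hi) {
            found <- TRUE
            break
          }
          # EE decreases with both knobs (purple spread / pinch distance)
          if (ee > hi) lo_k <- knob else hi_k <- knob
        }
      }
      if (!found) {
        stop(sprintf(
          "could not reach EE band [%g, %g] px within %d attempts; geometry/prior mismatch",
          lo, hi, max_attempts))
      }
      for (pres in seq_len(reps)) {
        offer_rows[[length(offer_rows) + 1L]] <- data.frame(
          offer_id = offer_id, presentation = pres, ee_band = b,
          reward = rew, ee_px = ee)
      }
      dot_rows[[offer_id]] <- data.frame(
        offer_id = offer_id, dot_index = 1:8,
        x = dots$x, y = dots$y, colour = dots$colour,
        stringsAsFactors = FALSE)
    }
  }
  list(offers = do.call(rbind, offer_rows), dots = do.call(rbind, dot_rows))
}

#' Simulate a full cohort dataset
#'
#' Draws per-agent parameters around the configured group means, simulates
#' every active trial through the ideal-observer agent, and generates
#' questionnaires and (optionally) passive-task responses. Fully
#' reproducible: the same `cohort$seed` yields byte-identical tables.
#'
#' @param cohort A [cohort_config()] object.
#' @param task A [task_config()] object.
#' @param include_passive Generate the passive offers/responses stage?
#' @param ee_cap,n_proposals Simulator fidelity knobs, see
#'   [simulate_trial()].
#' @return List of class `cq_dataset`: data.frames `trials`, `samples`,
#'   `questionnaires`, `agents` (true generating parameters), the per-trial
#'   observer `trajectories` (list by participant), and when requested
#'   `passive` plus `offers`/`offer_dots`.
#' @export
simulate_cohort <- function(cohort = cohort_config(), task = task_config(),
                            include_passive = TRUE,
                            ee_cap = 400, n_proposals = 12) {
  stopifnot(inherits(cohort, "cq_cohort_config"), inherits(task, "cq_task"))
  if (!is.null(cohort$seed)) set.seed(cohort$seed)
  grid <- prior_grid(task)
  qn <- simulate_questionnaires(cohort)
  n <- nrow(qn)
  sci <- qn$group == "SCI"

  isi_means <- rnorm_trunc(n, cohort$isi_mean + ifelse(sci, cohort$delta_isi, 0),
                           cohort$isi_between_sd, lower = 0.4)
  stops <- stats::rnorm(n, cohort$stop_mean + ifelse(sci, cohort$delta_stop, 0),
                        cohort$stop_between_sd)
  qs <- rnorm_trunc(n, cohort$q_mean + ifelse(sci, cohort$delta_q, 0),
                    cohort$q_between_sd, lower = 0, upper = 1)

  agents <- data.frame(participant_id = qn$participant_id, group = qn$group,
                       isi_mean = isi_means, stop_threshold = stops, q = qs,
                       stringsAsFactors = FALSE)

  trial_rows <- list(); sample_rows <- list()
  trajectories <- vector("list", n)
  names(trajectories) <- qn$participant_id
  for (p in seq_len(n)) {
    agent <- agent_params(isi_mean = isi_means[p],
                          isi_sigma = cohort$isi_sigma, q = qs[p],
                          stop_threshold = stops[p], lapse = cohort$lapse,
                          jitter_sd = cohort$jitter_sd)
    sched <- condition_schedule(task)
    tid <- 0L
    ptraj <- vector("list", 4L * task$trials_per_block)
    for (b in seq_len(nrow(sched))) {
      for (k in seq_len(task$trials_per_block)) {
        tid <- tid + 1L
        tr <- simulate_trial(agent, sched[b, ], task, grid = grid,
                             ee_cap = ee_cap, n_proposals = n_proposals)
        trial_rows[[length(trial_rows) + 1L]] <- data.frame(
          participant_id = qn$participant_id[p], trial_id = tid,
          block_index = sched$block_index[b],
          R0_level = sched$R0_level[b], cost_level = sched$cost_level[b],
          R0 = sched$R0[b], eta_s = sched$eta_s[b],
          hidden_x = tr$hidden[1], hidden_y = tr$hidden[2],
          placement_x = tr$placement[1], placement_y = tr$placement[2],
          n_paid_samples = tr$n_paid_samples,
          error_px = tr$error_px, score = tr$score,
          stringsAsFactors = FALSE)
        sample_rows[[length(sample_rows) + 1L]] <- data.frame(
          participant_id = qn$participant_id[p], trial_id = tid,
          sample_index = seq_len(nrow(tr$samples)),
          t_s = tr$samples$t_s, x = tr$samples$x, y = tr$samples$y,
          colour = tr$samples$colour, paid = tr$samples$paid,
          stringsAsFactors = FALSE)
        ptraj[[tid]] <- tr$ee_trajectory
      }
    }
    trajectories[[p]] <- ptraj
  }

  out <- list(trials = do.call(rbind, trial_rows),
              samples = do.call(rbind, sample_rows),
              questionnaires = qn, agents = agents,
              trajectories = trajectories)

  if (include_passive) {
    off <- generate_passive_offer_set(config = task)
    pr <- list()
    for (p in seq_len(n)) {
      o <- off$offers
      # confidence declines with uncertainty; 1-10 rating scale
      conf <- round(10 - 9 * (o$ee_px - 10) / 90 +
                      stats::rnorm(nrow(o), 0, 1))
      conf <- pmin(pmax(conf, 1), 10)
      p_acc <- stats::plogis(0.5 + 1.5 * (o$reward - 77.5) / 30 -
                               1.5 * (o$ee_px - 50) / 30)
      pr[[p]] <- data.frame(
        participant_id = qn$participant_id[p],
        offer_id = o$offer_id, presentation = o$presentation,
        ee_band = o$ee_band, reward = o$reward, ee_px = o$ee_px,
        confidence = conf,
        subjective_uncertainty = subjective_uncertainty(conf),
        accept = as.integer(stats::runif(nrow(o)) < p_acc),
        stringsAsFactors = FALSE)
    }
    out$passive <- do.call(rbind, pr)
    out$offers <- off$offers
    out$offer_dots <- off$dots
  }
  class(out) <- "cq_dataset"
  out
}

#' @export
print.cq_dataset <- function(x, ...) {
  cat("Synthetic active-sampling dataset\n")
  cat(sprintf("  participants : %d (%s)\n", nrow(x$questionnaires),
              paste(names(table(x$questionnaires$group)),
                    table(x$questionnaires$group),
                    sep = " = ", collapse = ", ")))
  cat(sprintf("  active trials: %d (%d samples)\n",
              nrow(x$trials), nrow(x$samples)))
  if (!is.null(x$passive)) {
    cat(sprintf("  passive rows : %d (%d offer types)\n",
                nrow(x$passive), length(unique(x$passive$offer_id))))
  }
  invisible(x)
}
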