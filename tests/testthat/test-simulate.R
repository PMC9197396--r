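test_that("simulated trials respect the task rules", {
  cfg <- coarse_task()
  g <- prior_grid(cfg)
  agent <- agent_params()
  set.seed(21)
  for (i in 1:15) {
    tr <- simulate_trial(agent, list(R0 = 95, eta_s = 1), cfg, grid = g)
    s <- tr$samples
    expect_equal(s$t_s[1], 0)
    expect_equal(s$paid[1], 0)                      # free dot is never charged
    expect_equal(s$colour[1], "purple")
    expect_true(all(diff(s$t_s) >= 0))
    expect_lte(max(s$t_s), cfg$sampling_duration)   # 18 s budget
    expect_equal(tr$n_paid_samples, sum(s$paid))
    expect_length(tr$ee_trajectory, nrow(s))
    # every dot colour is consistent with the hidden circle
    d <- sqrt((s$x - tr$hidden[1])^2 + (s$y - tr$hidden[2])^2)
    expect_equal(s$colour, ifelse(d <= cfg$circle_radius, "purple", "white"))
    # the reported score is the score rule recomputed
    expect_equal(tr$score, score_trial(95, 1, tr$n_paid_samples, 1.2,
                                       tr$error_px))
  }
})

test_that("an infinite stop threshold stops before any paid sample", {
  cfg <- coarse_task()
  set.seed(2)
  tr <- simulate_trial(agent_params(stop_threshold = Inf, lapse = 0),
                       list(R0 = 130, eta_s = 5), cfg)
  expect_equal(tr$n_paid_samples, 0)
  expect_equal(nrow(tr$samples), 1)
  expect_length(tr$ee_trajectory, 1)
})

test_that("trial simulation is reproducible under a fixed seed", {
  cfg <- coarse_task()
  agent <- agent_params()
  set.seed(31); t1 <- simulate_trial(agent, list(R0 = 95, eta_s = 5), cfg)
  set.seed(31); t2 <- simulate_trial(agent, list(R0 = 95, eta_s = 5), cfg)
  expect_identical(t1, t2)
})

test_that("proposed touches stay on the field and beat random sampling", {
  cfg <- coarse_task()
  g <- update_posterior(prior_grid(cfg), c(100, 50), "purple")
  set.seed(41)
  pts <- replicate(30, next_sample_location(g, agent_params(q = 1)))
  expect_true(all(colSums(pts^2) <= cfg$field_radius^2 + 1e-6))
  # uniform fallback is used when q = 0
  set.seed(42)
  unif <- replicate(200, next_sample_location(g, agent_params(q = 0)))
  expect_true(all(colSums(unif^2) <= cfg$field_radius^2 + 1e-6))
  expect_gt(mean(sqrt(colSums(unif^2))), 0.4 * cfg$field_radius)

  # greedy probing reduces EE (one step ahead, in expectation) more than a
  # random touch does, on a disk-shaped posterior
  one_step_ee <- function(touch) {
    r <- cfg$circle_radius
    inside <- (g$x - touch[1])^2 + (g$y - touch[2])^2 <= r^2
    p_in <- sum(g$mass[inside])
    ee <- 0
    for (col in c("purple", "white")) {
      p <- if (col == "purple") p_in else 1 - p_in
      if (p > 0) {
        ee <- ee + p * circlequest:::ee_opt_of(
          update_posterior(g, touch, col))$ee_opt
      }
    }
    ee
  }
  set.seed(43)
  greedy <- mean(replicate(12, one_step_ee(
    next_sample_location(g, agent_params(q = 1)))))
  rand <- mean(replicate(12, one_step_ee(
    next_sample_location(g, agent_params(q = 0)))))
  expect_lt(greedy, rand)
})

test_that("questionnaires respect instrument ranges and correlations", {
  set.seed(55)
  qn <- simulate_questionnaires(cohort_config(n_control = 200, n_sci = 200))
  expect_equal(nrow(qn), 400)
  expect_true(all(qn$bdi >= 0 & qn$bdi <= 63))
  expect_true(all(qn$hads_anx >= 0 & qn$hads_anx <= 21))
  expect_true(all(qn$hads_dep >= 0 & qn$hads_dep <= 21))
  expect_true(all(qn$ace_iii <= 100))
  expect_gt(cor(qn$bdi, qn$hads_anx), 0.4)       # configured rho = 0.68
  # group shift: SCI more depressed/anxious on average
  expect_gt(mean(qn$bdi[qn$group == "SCI"]), mean(qn$bdi[qn$group == "control"]))
  set.seed(56)
  qn0 <- simulate_questionnaires(cohort_config(n_control = 300, n_sci = 300,
                                               rho = 0))
  ctrl0 <- qn0[qn0$group == "control", ]  # within group: no mixture effect
  expect_lt(abs(cor(ctrl0$bdi, ctrl0$hads_anx)), 0.15)
})

test_that("passive offers hit their uncertainty bands by construction", {
  set.seed(66)
  cfg <- coarse_task()
  off <- generate_passive_offer_set(cfg)
  expect_equal(nrow(off$offers), 100)             # 20 types x 5 repetitions
  types <- unique(off$offers[c("ee_band", "reward")])
  expect_equal(nrow(types), 20)
  expect_setequal(unique(off$offers$reward), c(40, 65, 90, 115))
  bands <- circlequest:::default_ee_bands()
  for (id in unique(off$offers$offer_id)) {
    dots <- off$dots[off$dots$offer_id == id, ]
    expect_equal(sum(dots$colour == "purple"), 4)
    expect_equal(sum(dots$colour == "white"), 4)
    # independent recompute of the configuration's uncertainty
    em <- expected_error_map(batch_posterior(dots, cfg))
    b <- off$offers$ee_band[off$offers$offer_id == id][1]
    expect_gte(em$ee_opt, bands[b, 1])
    expect_lte(em$ee_opt, bands[b, 2])
  }
})

test_that("cohort simulation has the study's structure and is seeded", {
  co <- cohort_config(n_control = 2, n_sci = 2, seed = 123)
  ds <- simulate_cohort(co, coarse_task(), include_passive = FALSE)
  expect_equal(nrow(ds$questionnaires), 4)
  expect_equal(nrow(ds$trials), 4 * 60)           # 4 blocks x 15 trials each
  expect_equal(as.vector(table(ds$trials$participant_id)), rep(60L, 4))
  expect_named(ds$trajectories, ds$questionnaires$participant_id)
  expect_length(ds$trajectories[[1]], 60)
  ds2 <- simulate_cohort(co, coarse_task(), include_passive = FALSE)
  expect_identical(ds$trials, ds2$trials)         # byte-identical under seed
  expect_identical(ds$samples, ds2$samples)
})

test_that("agents with better sampling policies earn higher fitted rates", {
  set.seed(91)
  cfg <- coarse_task()
  qs <- seq(0.05, 1, length.out = 20)
  alphas <- vapply(qs, function(q) {
    agent <- agent_params(q = q, stop_threshold = -100, lapse = 0)
    co <- cohort_config(n_control = 1, n_sci = 1)
    g <- prior_grid(cfg)
    traj <- lapply(1:60, function(i) {
      simulate_trial(agent, list(R0 = 130, eta_s = 1), cfg, grid = g)$ee_trajectory
    })
    fit_extraction_rate(traj)$alpha
  }, numeric(1))
  expect_gt(cor(qs, alphas, method = "spearman"), 0.8)
})
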