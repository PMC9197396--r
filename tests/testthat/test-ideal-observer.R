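test_that("the prior is uniform over fully contained circle centres", {
  g <- prior_grid(coarse_task())
  expect_equal(g$support_radius, 410)  # 540 - 130
  expect_true(all(g$x^2 + g$y^2 <= 410^2))
  expect_equal(sum(g$mass), 1, tolerance = 1e-12)
  expect_equal(g$stage, 0L)
  expect_true(all(g$mass == g$mass[1]))
  # halving the stride roughly quadruples the support
  n8 <- length(prior_grid(coarse_task(8))$x)
  n4 <- length(prior_grid(coarse_task(4))$x)
  expect_equal(n4 / n8, 4, tolerance = 0.02)
  too_coarse <- coarse_task()
  too_coarse$grid_stride <- 500  # cannot be built through the constructor
  expect_error(prior_grid(too_coarse), "stride exceeds")
})

test_that("single updates equal the closed-form feasible-set restriction", {
  cfg <- coarse_task()
  g <- prior_grid(cfg)
  r <- cfg$circle_radius
  for (touch in list(c(0, 0), c(200, 120), c(-370, 0))) {
    inside <- (g$x - touch[1])^2 + (g$y - touch[2])^2 <= r^2
    purple <- update_posterior(g, touch, "purple")
    expect_equal(purple$mass, inside / sum(inside), tolerance = 1e-12)
    expect_equal(purple$stage, 1L)
    white <- update_posterior(g, touch, "white")
    expect_equal(white$mass, (!inside) / sum(!inside), tolerance = 1e-12)
  }
})

test_that("contradictory observations are rejected, not absorbed", {
  g <- prior_grid(coarse_task())
  g2 <- update_posterior(g, c(0, 0), "purple")
  expect_error(update_posterior(g2, c(0, 0), "white"), "inconsistent")
  obs <- data.frame(x = c(0, 0), y = c(0, 0),
                    colour = c("purple", "white"))
  expect_error(batch_posterior(obs, coarse_task()), "inconsistent")
})

test_that("sequential Bayes equals the batch feasible-set construction", {
  cfg <- coarse_task()
  set.seed(101)
  for (i in 1:30) {
    obs <- random_trial_obs(cfg, n_obs = sample(3:10, 1))
    seq_post <- prior_grid(cfg)
    for (k in seq_len(nrow(obs))) {
      seq_post <- update_posterior(seq_post, c(obs$x[k], obs$y[k]),
                                   obs$colour[k])
    }
    batch <- batch_posterior(obs, cfg)
    # identical feasible sets; masses agree to renormalisation round-off
    expect_identical(seq_post$mass > 0, batch$mass > 0)
    expect_equal(seq_post$mass, batch$mass, tolerance = 1e-12)
    # 0/1 likelihoods make the posterior order-invariant
    perm <- batch_posterior(obs[sample.int(nrow(obs)), ], cfg)
    expect_identical(batch$mass, perm$mass)
  }
  expect_identical(batch_posterior(data.frame(x = numeric(), y = numeric(),
                                              colour = character()), cfg)$mass,
                   prior_grid(cfg)$mass)
})

test_that("expected error is the posterior-weighted mean distance", {
  # single atom: EE(c) = |c - atom|
  g <- point_mass_posterior(x = c(3, 50), y = c(4, 60), mass = c(1, 0))
  cand <- cbind(c(0, 3, 30), c(0, 4, 40))
  em <- expected_error_map(g, cand)
  expect_equal(em$ee, c(5, 0, sqrt(27^2 + 36^2)))
  expect_equal(em$lambda_star, c(3, 4))
  expect_equal(em$ee_opt, 0)

  # two equal atoms distance d apart: EE at either atom is d/2, every point
  # between them ties, and the tie goes to the lexicographically smallest
  g2 <- point_mass_posterior(x = c(-8, 8), y = c(0, 0), mass = c(1, 1))
  cand2 <- cbind(seq(-8, 8, by = 4), 0)
  em2 <- expected_error_map(g2, cand2)
  expect_equal(em2$ee, rep(8, 5))
  expect_equal(em2$lambda_star, c(-8, 0))
  expect_equal(optimal_placement(em2)$ee_opt, 8)
})

test_that("EE_opt is the map minimum and converges to 2r/3 on the disk", {
  cfg <- coarse_task()
  set.seed(7)
  for (i in 1:5) {
    obs <- random_trial_obs(cfg, n_obs = 4)
    em <- expected_error_map(batch_posterior(obs, cfg))
    expect_true(all(em$ee >= em$ee_opt))
    expect_gte(em$ee_opt, 0)
  }
  # uniform disk of radius r: analytic mean distance from the centre-placed
  # disc is 2r/3; the grid observer must be within 1% at stride 2
  g <- update_posterior(prior_grid(coarse_task(2)), c(0, 0), "purple")
  em <- expected_error_map(g)
  expect_equal(em$ee_opt, 2 * 130 / 3, tolerance = 0.01)
  expect_lt(sqrt(sum(em$lambda_star^2)), 2 * 2)  # centre, up to one stride
})

test_that("trial replay yields one EE per dot with shrinking support", {
  cfg <- coarse_task()
  set.seed(13)
  obs <- random_trial_obs(cfg, n_obs = 6)
  traj <- ee_trajectory(obs, cfg)
  expect_length(traj, nrow(obs))
  # the feasible set can only shrink as dots accumulate
  g <- prior_grid(cfg)
  supp <- numeric(nrow(obs))
  for (k in seq_len(nrow(obs))) {
    g <- update_posterior(g, c(obs$x[k], obs$y[k]), obs$colour[k])
    supp[k] <- sum(g$mass > 0)
  }
  expect_true(all(diff(supp) <= 0))
  # single free dot at the centre: uniform-disk uncertainty
  traj1 <- ee_trajectory(data.frame(x = 0, y = 0, colour = "purple"),
                         coarse_task(4))
  expect_equal(traj1, 2 * 130 / 3, tolerance = 0.02)
})
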