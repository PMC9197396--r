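ref_fit <- structure(list(alpha = 0.5, ee_inf = 20, baseline = 100),
                     class = "cq_efficiency")

test_that("the expected-value curve matches direct arithmetic", {
  ev <- expected_value_curve(ref_fit, R0 = 130, eta_s = 5, s_max = 5)
  # EV(s) = 130 - 5 s - 1.2 * (80 * 0.5^s + 20)
  expect_equal(ev$ev, c(10, 53, 72, 79, 80, 78))
  expect_equal(ev$s_star, 4)
  expect_equal(optimal_sample_count(ev), 4)
  # cheaper sampling pushes the optimum later
  expect_equal(expected_value_curve(ref_fit, 130, eta_s = 1)$s_star, 6)
})

test_that("the optimal count is invariant to the credit reserve", {
  for (eta_s in c(0.5, 1, 2, 5)) {
    a <- expected_value_curve(ref_fit, 95, eta_s, s_max = 30)
    b <- expected_value_curve(ref_fit, 130, eta_s, s_max = 30)
    expect_equal(b$ev, a$ev + 35)
    expect_equal(a$s_star, b$s_star)
  }
})

test_that("the optimal count weakly decreases with sampling cost", {
  stars <- vapply(seq(0.25, 8, by = 0.25), function(eta_s) {
    expected_value_curve(ref_fit, 130, eta_s, s_max = 40)$s_star
  }, numeric(1))
  expect_true(all(diff(stars) <= 0))
  # free sampling: EV increases toward the asymptotic value
  free <- expected_value_curve(ref_fit, 130, eta_s = 0, s_max = 20)
  expect_true(all(diff(free$ev) > 0))
})

test_that("faster extraction brings the optimal stopping point earlier", {
  # marginal EE gain of sample s is eta_e * alpha (1-alpha)^s (EE_1 - EE_inf):
  # beyond a small alpha, higher rates exhaust the information sooner, so
  # s* weakly decreases over the practically relevant range (empirical sweep)
  for (eta_s in c(1, 5)) {
    stars <- vapply(seq(0.1, 0.95, by = 0.05), function(a) {
      f <- structure(list(alpha = a, ee_inf = 20, baseline = 100),
                     class = "cq_efficiency")
      expected_value_curve(f, 130, eta_s, s_max = 60)$s_star
    }, numeric(1))
    expect_true(all(diff(stars) <= 0))
  }
  # degenerate low-rate limit: no sample is worth its cost
  f0 <- structure(list(alpha = 0.005, ee_inf = 20, baseline = 100),
                  class = "cq_efficiency")
  expect_equal(expected_value_curve(f0, 130, 5, s_max = 60)$s_star, 0)
})

test_that("the softmax stopping distribution is a proper distribution", {
  expect_equal(stopping_distribution(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(stopping_distribution(c(1, 0)),
               c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-12)
  set.seed(9)
  for (i in 1:20) {
    ev <- rnorm(sample(2:30, 1), sd = 50)
    p <- stopping_distribution(ev)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p >= 0))
    expect_equal(p, stopping_distribution(ev + runif(1, -1e4, 1e4)),
                 tolerance = 1e-12)  # shift invariance
  }
  expect_equal(stopping_distribution(c(1e6, 1e6 - 1)),
               stopping_distribution(c(1, 0)))  # overflow-safe
  expect_error(stopping_distribution(numeric()), "empty")
  expect_error(stopping_distribution(c(1, Inf)), "finite")
})

test_that("argmax ties break to the smallest sample count", {
  expect_equal(optimal_sample_count(rep(5, 7)), 0)
  expect_equal(optimal_sample_count(c(1, 3, 3, 2)), 1)
  ev <- expected_value_curve(ref_fit, 130, 5, s_max = 10)
  expect_equal(ev$s_star, ev$s[which.max(ev$stop_prob)])  # mode of p(s)
})

test_that("deviation tables contrast acquired samples with the optimum", {
  cfg <- task_config()
  trials <- expand.grid(participant_id = "p1",
                        R0 = c(95, 130), eta_s = c(1, 5))
  trials <- trials[rep(1:4, each = 3), ]
  trials$n_paid_samples <- rep(c(10, 9, 12, 11), each = 3)
  dev <- deviation_from_optimal(trials, list(p1 = ref_fit), cfg)
  expect_equal(nrow(dev), 4)
  expect_equal(dev$deviation, dev$mean_samples - dev$s_star)
  sel <- dev$R0_level == "low" & dev$cost_level == "high"
  expect_equal(dev$s_star[sel], 4)
  expect_equal(dev$mean_samples[sel], 12)
  expect_equal(dev$deviation[sel], 8)
  # a perfectly rational agent has zero deviation in every condition
  opt <- trials
  for (i in seq_len(nrow(opt))) {
    opt$n_paid_samples[i] <- expected_value_curve(
      ref_fit, opt$R0[i], opt$eta_s[i], cfg$error_cost)$s_star
  }
  dev0 <- deviation_from_optimal(opt, list(p1 = ref_fit), cfg)
  expect_equal(dev0$deviation, rep(0, 4))
  # missing condition cells are dropped with a warning; missing fits error
  expect_warning(deviation_from_optimal(trials[trials$eta_s == 1, ],
                                        list(p1 = ref_fit), cfg),
                 "omitted")
  expect_error(deviation_from_optimal(trials, list(), cfg), "no efficiency fit")
})
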