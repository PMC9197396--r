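# shared fixtures: coarse grids keep the observer cheap in unit tests

coarse_task <- function(stride = 8, ...) task_config(grid_stride = stride, ...)

# a random but self-consistent observation sequence: touches classified
# against a hidden centre drawn from the prior support
random_trial_obs <- function(config, n_obs = 8) {
  g <- prior_grid(config)
  i <- sample.int(length(g$x), 1)
  hidden <- c(g$x[i], g$y[i])
  rad <- config$field_radius * sqrt(runif(n_obs))
  ang <- 2 * pi * runif(n_obs)
  x <- rad * cos(ang)
  y <- rad * sin(ang)
  colour <- ifelse(sqrt((x - hidden[1])^2 + (y - hidden[2])^2) <=
                     config$circle_radius, "purple", "white")
  # lead with a guaranteed purple dot so the feasible set never empties
  data.frame(x = c(hidden[1], x), y = c(hidden[2], y),
             colour = c("purple", colour), stringsAsFactors = FALSE)
}

# posterior object with arbitrary point masses, for expected-error tests
point_mass_posterior <- function(x, y, mass, stride = 1) {
  structure(
    list(x = x, y = y, mass = mass / sum(mass), stage = 0L, stride = stride,
         support_radius = 410, circle_radius = 130, field_radius = 540),
    class = "cq_posterior")
}
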