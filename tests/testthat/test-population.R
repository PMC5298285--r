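test_that("population model constructor enforces scales and conventions", {
  pop <- population_model()
  expect_equal(pop$omega_ktu_ROS, 1.145)
  expect_equal(pop$b, 0.09932)
  expect_error(population_model(b = 0), "b must")
  expect_error(population_model(b = 1), "b must")
  expect_error(population_model(omega_ktu_ROS = -1), "omegas")
  # variance convention converts to SD
  pv <- population_model(omega_ktu_ROS = 4, omega_scale = "var")
  expect_equal(pv$omega_ktu_ROS, 2)
})

test_that("study-parameter sampler is lognormal, seeded and degenerate at omega 0", {
  pop0 <- population_model(omega_ktu_ROS = 0, omega_a_gluros = 0)
  p <- sample_study_parameters(pop0, seed = 3)
  expect_equal(unclass(p)[names(ros_params())], unclass(ros_params()))

  pop <- population_model()
  a <- sample_study_parameters(pop, n = 5, seed = 42)
  b <- sample_study_parameters(pop, n = 5, seed = 42)
  expect_identical(lapply(a, unclass), lapply(b, unclass))
  # only ktu_ROS and a_gluros move
  expect_equal(a[[1]]$EC50_ad, pop$params$EC50_ad)
  expect_equal(a[[1]]$ktu_ROS,
               pop$params$ktu_ROS * exp(attr(a[[1]], "eta")[["ktu_ROS"]]))
})

test_that("proportional residual error is exact at b = 0, seeded and positive", {
  expect_equal(apply_residual_error(c(1, 2, 3), 0), c(1, 2, 3))
  y1 <- apply_residual_error(rep(2, 100), 0.1, seed = 5)
  y2 <- apply_residual_error(rep(2, 100), 0.1, seed = 5)
  expect_identical(y1, y2)
  # even absurdly noisy draws stay positive via resampling
  y3 <- apply_residual_error(rep(0.5, 2000), 0.9, seed = 6)
  expect_true(all(y3 > 0))
  expect_error(apply_residual_error(c(1, -1), 0.1), "positive")
})

test_that("likelihood collapses to a hand-computed normal density sum without random effects", {
  # one study, two observations, NG protocol: f = 1 exactly (closed form)
  pr <- make_ng(5, 100)
  data <- data.frame(study_id = "s1", protocol_id = "ng",
                     time_h = c(24, 72), ros_norm = c(0.9, 1.2))
  pop0 <- population_model(omega_ktu_ROS = 0, omega_a_gluros = 0, b = 0.1)
  ll <- loglik_population(pop0, data, list(ng = pr))
  hand <- sum(-log(0.1) - 0.5 * log(2 * pi) -
                (c(0.9, 1.2) - 1)^2 / (2 * 0.1^2))
  expect_equal(as.numeric(ll), hand, tolerance = 1e-10)
})

test_that("an exact duplicate study doubles its likelihood contribution", {
  d <- generate_studies(seed = 8, designs = default_designs()[c(2, 4)])
  pop <- population_model()
  base <- as.numeric(loglik_population(pop, d$observations, d$protocols))
  dup <- d$observations[d$observations$study_id == "study02", ]
  solo <- as.numeric(loglik_population(pop, dup, d$protocols))
  dup$study_id <- "study02b"
  both <- as.numeric(loglik_population(pop, rbind(d$observations, dup),
                                       d$protocols))
  expect_equal(both, base + solo, tolerance = 1e-6)
})

test_that("adaptive quadrature stabilizes as nodes double", {
  d <- generate_studies(seed = 42)
  pop <- population_model()
  ll21 <- as.numeric(loglik_population(pop, d$observations, d$protocols,
                                       nodes = 21))
  ll42 <- as.numeric(loglik_population(pop, d$observations, d$protocols,
                                       nodes = 42))
  expect_lt(abs(ll42 - ll21), 0.01)
})

test_that("predictions are consistent with trajectories and monotone in the first day", {
  pr <- make_cg(20, 336)
  f24 <- predict_observations(table1, pr, 24)
  tr <- simulate_protocol(pr, table1, times = c(0, 24))
  expect_equal(f24, tr$ROS[2], tolerance = 1e-8)
  # NG protocol: all predictions at baseline
  expect_equal(predict_observations(table1, make_ng(5, 100), c(10, 50, 99)),
               rep(1, 3), tolerance = 1e-9)
  # unsorted times honoured: same values as the sorted call, reordered
  f <- predict_observations(table1, pr, c(100, 10, 200))
  expect_equal(f[order(c(100, 10, 200))],
               predict_observations(table1, pr, c(10, 100, 200)))
  # first 24 h under CG: drive constant, adaptation negligible -> monotone
  f1d <- predict_observations(table1, pr, 1:24)
  expect_true(all(diff(f1d) > 0))
})

test_that("vpc bands collapse without variability, widen with it, and are seeded", {
  pr <- make_cg(20, 336)
  tt <- c(24, 168, 336)
  pop0 <- population_model(omega_ktu_ROS = 1e-12, omega_a_gluros = 1e-12,
                           b = 1e-12)
  v0 <- vpc(pop0, pr, tt, n_sim = 50, seed = 1)
  expect_equal(v0$p5, v0$p95, tolerance = 1e-6)
  expect_equal(v0$p50, v0$f_pop, tolerance = 1e-6)

  mk <- function(om, b) population_model(ros_params(), om, om, b)
  width <- function(pop) {
    v <- vpc(pop, pr, tt, n_sim = 150, seed = 2)
    mean(v$p95 - v$p5)
  }
  w_small <- width(mk(0.2, 0.05))
  w_b <- width(mk(0.2, 0.2))
  w_om <- width(mk(0.8, 0.05))
  expect_gt(w_b, w_small)
  expect_gt(w_om, w_small)

  v1 <- vpc(population_model(), pr, tt, n_sim = 50, seed = 9)
  v2 <- vpc(population_model(), pr, tt, n_sim = 50, seed = 9)
  expect_identical(v1, v2)
})
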