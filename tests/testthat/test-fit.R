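# Fitting-layer tests on reduced problem sizes (few studies, Laplace
# likelihood) so the whole suite stays fast; the full-scale recovery runs
# in test-acceptance.R.

test_that("input validation catches unusable observation tables", {
  d <- generate_studies(seed = 2, designs = default_designs()[1:2])
  expect_error(ros_fit(d$observations[1:4, ], d$protocols), "at least 2")
  bad <- d$observations
  names(bad)[4] <- "value"
  expect_error(ros_fit(bad, d$protocols), "columns")
  expect_error(ros_fit(d$observations, d$protocols,
                       estimate = c("ktu_ROS", "GLU_basal")),
               "cannot estimate")
  expect_error(ros_fit(d$observations, list()), "unresolvable")
})

test_that("fit on data without inter-study variability flags the omega boundary", {
  pop0 <- population_model(omega_ktu_ROS = 0, omega_a_gluros = 0, b = 0.05)
  d <- generate_studies(pop0, seed = 31, n_studies = 12)
  start <- population_model(
    ros_params(ktu_ROS = 0.05, ktu_AD = 0.01, a_gluros = 0.25, EC50_ad = 5),
    omega_ktu_ROS = 0.3, omega_a_gluros = 0.3, b = 0.1)
  fit <- suppressWarnings(
    ros_fit(d$observations, d$protocols, start = start,
            compute_rse = FALSE))
  est <- coef(fit)
  expect_lt(abs(est[["b"]] - 0.05) / 0.05, 0.3)
  # omegas collapse toward zero (up to small-sample noise)
  expect_lt(est[["omega_ktu_ROS"]], 0.2)
  expect_lt(est[["omega_a_gluros"]], 0.2)
  # an omega numerically at its box bound must carry the boundary flag
  at_bound <- est[c("omega_ktu_ROS", "omega_a_gluros")] < 2e-4
  expect_equal(unname(fit$convergence$boundary), unname(at_bound))
  expect_lt(abs(est[["a_gluros"]] - 0.364) / 0.364, 0.15)
  # logLik/AIC bookkeeping
  expect_equal(fit$aic, 2 * 7 - 2 * fit$loglik)
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_equal(AIC(fit), fit$aic)
})

test_that("estimates do not depend on the starting point", {
  pop0 <- population_model(omega_ktu_ROS = 0, omega_a_gluros = 0, b = 0.05)
  d <- generate_studies(pop0, seed = 57, n_studies = 5)
  starts <- list(
    population_model(ros_params(ktu_ROS = 0.05, ktu_AD = 0.01,
                                a_gluros = 0.25, EC50_ad = 5),
                     0.2, 0.2, 0.1),
    population_model(ros_params(ktu_ROS = 0.02, ktu_AD = 0.004,
                                a_gluros = 0.6, EC50_ad = 8),
                     0.4, 0.4, 0.2))
  fits <- lapply(starts, function(s)
    suppressWarnings(ros_fit(d$observations, d$protocols, start = s,
                             compute_rse = FALSE)))
  # the full-scale identifiability claim is agreement to 1%; at this
  # deliberately tiny problem size the optimum is shallower, so a few
  # percent is what start-independence looks like here
  for (nm in c("ktu_ROS", "a_gluros", "EC50_ad"))
    expect_lt(abs(coef(fits[[1]])[[nm]] - coef(fits[[2]])[[nm]]) /
                coef(fits[[1]])[[nm]], 0.03)
})

test_that("reported RSEs agree with empirical spread across seeded replicates", {
  # scaled-down precision check: 3 replicate 9-study datasets
  ests <- NULL
  rse1 <- NULL
  start <- population_model(
    ros_params(ktu_ROS = 0.05, ktu_AD = 0.01, a_gluros = 0.25, EC50_ad = 5),
    omega_ktu_ROS = 0.6, omega_a_gluros = 0.6, b = 0.12)
  for (s in 1:3) {
    d <- generate_studies(seed = 300 + s)
    fit <- suppressWarnings(
      ros_fit(d$observations, d$protocols, start = start,
              compute_rse = (s == 1)))
    if (s == 1) rse1 <- fit$rse
    ests <- rbind(ests, coef(fit))
  }
  # log-scale empirical SD vs reported RSE (as SE of the log), factor 4:
  # with 3 replicates the empirical SD itself is noisy, so the bound is
  # generous; it still distinguishes working error propagation from a
  # broken Hessian
  for (nm in c("a_gluros", "EC50_ad", "b")) {
    if (is.na(rse1[[nm]])) next
    emp <- sd(log(ests[, nm]))
    expect_lt(rse1[[nm]] / 100, 4 * emp + 0.05)
    expect_gt(rse1[[nm]] / 100, emp / 4 - 0.05)
  }
})

test_that("vpc bands from a fit enclose most held-out observations", {
  d <- generate_studies(seed = 77)
  start <- population_model(
    ros_params(ktu_ROS = 0.05, ktu_AD = 0.01, a_gluros = 0.25, EC50_ad = 5),
    omega_ktu_ROS = 0.6, omega_a_gluros = 0.6, b = 0.12)
  fit <- suppressWarnings(ros_fit(d$observations, d$protocols,
                                  start = start, compute_rse = FALSE))
  held <- generate_studies(seed = 78)      # fresh draws, same designs
  covered <- 0L; total <- 0L
  for (pid in names(held$protocols)) {
    sel <- held$observations$protocol_id == pid
    tt <- sort(unique(held$observations$time_h[sel]))
    band <- vpc(fit, held$protocols[[pid]], tt, n_sim = 300, seed = 5)
    for (i in which(sel)) {
      row <- match(held$observations$time_h[i], band$time_h)
      total <- total + 1L
      if (held$observations$ros_norm[i] >= band$p5[row] &&
          held$observations$ros_norm[i] <= band$p95[row])
        covered <- covered + 1L
    }
  }
  expect_gte(covered / total, 0.85)        # nominal 90% band
})

test_that("fit methods expose predictions, residuals and simulations", {
  d <- generate_studies(seed = 2, designs = default_designs()[c(2, 4, 7)])
  fit <- suppressWarnings(
    ros_fit(d$observations, d$protocols,
            start = population_model(ros_params(ktu_ROS = 0.04,
              a_gluros = 0.3), 0.5, 0.5, 0.12),
            control = list(rel.tol = 1e-6), polish = FALSE,
            compute_rse = FALSE))
  f_pop <- predict(fit)
  f_ind <- predict(fit, type = "individual")
  expect_length(f_pop, nrow(d$observations))
  expect_true(all(f_pop >= 1 - 1e-8))
  # individual predictions track the data at least as well as population
  sse <- function(f) sum(((d$observations$ros_norm - f) / f)^2)
  expect_lte(sse(f_ind), sse(f_pop) + 1e-8)
  r <- residuals(fit)
  expect_equal(r, (d$observations$ros_norm - f_ind) / (fit$pop$b * f_ind))
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sims, 2)
  expect_equal(dim(sims[[1]]), dim(d$observations))
  expect_false(identical(sims[[1]]$ros_norm, sims[[2]]$ros_norm))
  # serialization
  f <- tempfile(fileext = ".json")
  write_fit(fit, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$estimates$a_gluros, coef(fit)[["a_gluros"]])
})
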