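test_that("normoglycemic schedules leave the healthy state untouched for 21 days", {
  for (eng in c("lsoda", "dp45")) {
    tr <- simulate_protocol(make_ng(5, 21 * 24), table1, engine = eng)
    expect_true(all(abs(tr$ROS - 1) < 1e-7))
    expect_true(all(abs(tr$MM) < 1e-7))
    expect_true(all(abs(tr$AD) < 1e-7))
  }
})

test_that("solver AD matches the closed-form relaxation on constant segments", {
  for (lv in seq(9, 25, by = 2)) {
    ge <- max(lv - table1$GLU_basal, 0)
    tr <- simulate_protocol(make_cg(lv, 336), table1,
                            times = c(24, 100, 336))
    expect_equal(tr$AD, ad_relax(c(24, 100, 336), ge, 0, table1),
                 tolerance = 1e-6)
  }
  # and across a CG -> NG switch, segment-wise
  tr <- simulate_protocol(make_cg(20, 336, ng_duration_h = 336), table1,
                          times = c(336, 500, 672))
  ad336 <- ad_relax(336, 11, 0, table1)
  expect_equal(tr$AD, ad_relax(c(0, 164, 336), 0, ad336, table1),
               tolerance = 1e-6)
})

test_that("the two solver engines agree over CG and OG protocols", {
  tt <- c(0, 1, 23.5, 24, 100, 336, 1000, 2016)
  for (mk in list(cg20_2w, og520_2w)) {
    a <- simulate_protocol(mk(), table1, times = tt)
    b <- simulate_protocol(mk(), table1, times = tt, engine = "dp45")
    expect_equal(b$ROS, a$ROS, tolerance = 1e-7)
    expect_equal(b$MM, a$MM, tolerance = 1e-7)
    expect_equal(b$AD, a$AD, tolerance = 1e-6)
  }
})

test_that("states respect lower bounds under arbitrary non-negative schedules", {
  set.seed(11)
  for (i in 1:5) {
    segs <- lapply(1:4, function(j) {
      if (runif(1) < 0.5) list(duration_h = runif(1, 10, 200),
                               level = runif(1, 0, 25))
      else list(duration_h = runif(1, 48, 200), low = runif(1, 0, 8),
                high = runif(1, 10, 25), half_period = sample(6:48, 1))
    })
    pr <- glucose_protocol(segs)
    tr <- simulate_protocol(pr, table1)
    expect_true(all(tr$ROS >= 1 - 1e-7))
    expect_true(all(tr$MM >= -1e-9))
    expect_true(all(tr$AD >= -1e-9))
    expect_true(all(tr$AD_ef >= 1 - table1$Fmax_ad - 1e-9 & tr$AD_ef <= 1))
  }
})

test_that("constant high glucose produces bell-shaped ROS dynamics", {
  tr <- simulate_protocol(cg20_2w(), table1)
  exposure <- tr[tr$time <= 336, ]
  expect_gt(max(exposure$ROS), exposure$ROS[nrow(exposure)])
  expect_gt(max(exposure$ROS), 1.5)   # a real excursion, not noise
})

test_that("post-normalization steady state sits on the equilibrium family", {
  # trivial: healthy cells under NG stay at (1, 0)
  ss0 <- post_ng_steady_state(make_ng(5, 48), table1)
  expect_equal(ss0$ros_ss, 1, tolerance = 1e-8)
  expect_equal(ss0$mm_ss, 0, tolerance = 1e-8)

  ss <- post_ng_steady_state(make_cg(20, 336, ng_duration_h = 24), table1)
  expect_true(ss$converged)
  expect_gt(ss$ros_ss, 1)
  expect_gt(ss$mm_ss, 0)
  expect_equal(ss$ros_ss, 1 + ss$mm_ss, tolerance = 1e-4)

  expect_error(post_ng_steady_state(make_og(5, 20, 24, 336), table1),
               "constant")
})

test_that("halving solver tolerances leaves the steady state unchanged to 1e-4", {
  pr <- make_cg(20, 336, ng_duration_h = 24)
  a <- post_ng_steady_state(pr, table1, rtol = 1e-8, atol = 1e-10)
  b <- post_ng_steady_state(pr, table1, rtol = 5e-9, atol = 5e-11)
  expect_lt(abs(a$ros_ss - b$ros_ss), 1e-4)
})

test_that("a_rosmm < 1 restores the system to baseline after exposure", {
  p <- ros_params(a_rosmm = 0.5)
  pr <- make_cg(20, 336, ng_duration_h = 12 * 7 * 24 - 336)
  tr <- simulate_protocol(pr, p, times = c(336, 12 * 7 * 24))
  expect_lt(tr$ROS[2] - 1, 0.01)
  ss <- post_ng_steady_state(pr, p)
  expect_equal(ss$ros_ss, 1, tolerance = 1e-3)
  expect_equal(ss$mm_ss, 0, tolerance = 1e-3)
})

test_that("CG level sweep separates gradual accumulation from bell-shaped dynamics", {
  sw <- sweep_cg(levels = c(9, 12, 25), duration_h = 21 * 24, params = table1,
                 times = seq(0, 21 * 24, by = 4))
  flat <- sw[sw$level == 9, ]
  expect_true(all(abs(flat$ROS - 1) < 1e-7))   # at basal: no drive
  low <- sw[sw$level == 12, ]
  expect_true(all(diff(low$ROS) > -1e-7))      # monotone accumulation
  high <- sw[sw$level == 25, ]
  expect_gt(max(high$ROS), high$ROS[nrow(high)] + 0.1)  # interior maximum
})

test_that("post-NG steady states grow with exposure duration, and with level when exposure is short", {
  sw <- sweep_exposure(levels = c(9, 15, 25), durations_h = c(1, 336),
                       params = table1)
  expect_true(all(sw$converged))
  expect_true(all(abs(sw$ros_ss[sw$level == 9] - 1) < 1e-6))
  # 1 h of exposure: little memory (though the post-exposure ROS transient
  # still feeds some in during normalization), monotone in level
  short <- sw[sw$duration_h == 1, ]
  expect_lt(max(short$ros_ss), 1.05)
  expect_true(all(diff(short$ros_ss[order(short$level)]) > 0))
  # at fixed level, longer exposure leaves more memory
  for (lv in c(15, 25))
    expect_gt(sw$ros_ss[sw$level == lv & sw$duration_h == 336],
              sw$ros_ss[sw$level == lv & sw$duration_h == 1])
  # at two weeks the ordering inverts: stronger adaptation at 25 mM
  # suppresses ROS (and hence memory) below the 15 mM outcome
  two_w <- sw[sw$duration_h == 336, ]
  expect_lt(two_w$ros_ss[two_w$level == 25], two_w$ros_ss[two_w$level == 15])
})

test_that("oscillating exposure is more detrimental than constant exposure", {
  og <- simulate_protocol(make_og(5, 20, 24, 336), table1)
  cg <- simulate_protocol(make_cg(20, 336), table1)
  n <- nrow(og)
  expect_gt(og$ROS[n], cg$ROS[n])
  expect_gt(og$MM[n], cg$MM[n])
  # ROS stays above baseline even in the NG troughs after the first period
  expect_gt(min(og$ROS[og$time >= 48]), 1)
})

test_that("amplitude-zero oscillation sweeps degenerate to constant exposure", {
  tt <- seq(0, 336, by = 12)
  swm <- sweep_og(amplitudes = c(0, 15), encoding = "fixed_max",
                  max_level = 25, duration_h = 336, params = table1,
                  times = tt)
  cg25 <- simulate_protocol(make_cg(25, 336), table1, times = tt)
  expect_equal(swm$ROS[swm$amplitude == 0], cg25$ROS, tolerance = 1e-9)
  swf <- sweep_og(amplitudes = 0, encoding = "fixed_min", min_level = 5,
                  duration_h = 336, params = table1, times = tt)
  expect_true(all(abs(swf$ROS - 1) < 1e-7))    # constant 5 mM: no stress
})

test_that("post-NG steady state is similar to the final-period mean of OG exposure", {
  ss <- post_ng_steady_state(make_og(5, 20, 24, 336, ng_duration_h = 24),
                             table1)
  tr <- simulate_protocol(make_og(5, 20, 24, 336), table1,
                          times = seq(288, 336, by = 1))
  run_mean <- mean(tr$ROS)
  expect_lt(abs(ss$ros_ss - run_mean) / run_mean, 0.2)
})

test_that("trajectories and sweeps export as tidy long CSV", {
  tr <- simulate_protocol(make_cg(20, 48), table1, times = c(0, 24, 48))
  f <- tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  long <- read.csv(f)
  expect_named(long, c("protocol", "time_h", "variable", "value"))
  expect_setequal(unique(long$variable), c("GLU", "ROS", "MM", "AD", "AD_ef"))
  expect_equal(nrow(long), 3 * 5)
})
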