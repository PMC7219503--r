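test_that("angle primitives match closed-form values", {
  # in-plane and normal-aligned vectors
  expect_equal(angle_vector_plane(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_equal(angle_vector_plane(c(0, 2, 0), c(0, 1, 0)), 90)
  expect_equal(angle_vector_plane(c(1, 1, 0), c(0, 1, 0)), 45, tolerance = 1e-9)
  expect_equal(angle_between_vectors(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(angle_between_vectors(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(angle_between_vectors(c(1, 0, 0), c(1, 1, 0)), 45, tolerance = 1e-9)
  # absolute values fold antiparallel to zero
  expect_equal(angle_between_vectors(c(1, 0, 0), c(-1, 0, 0)), 0)
  expect_error(angle_vector_plane(c(0, 0, 0), c(0, 1, 0)), "degenerate")
  expect_error(angle_between_vectors(c(0, 0, 0), c(1, 0, 0)), "degenerate")
})

test_that("finite differences recover constant, linear and quadratic motion", {
  ts <- (0:29) / 15
  p0 <- matrix(1.5, 30, 3)
  k0 <- finite_difference_kinematics(p0, ts)
  expect_true(all(k0$velocity == 0) && all(k0$acceleration == 0))

  p1 <- cbind(ts, 0, 0)
  k1 <- finite_difference_kinematics(p1, ts)
  expect_equal(k1$velocity[, 1], rep(1, 30), tolerance = 1e-12)
  expect_equal(k1$acceleration[, 1], rep(0, 30), tolerance = 1e-9)

  # p_y = t^2 / 2: the discrete second difference is exactly 1 everywhere
  p2 <- cbind(0, ts^2 / 2, 0)
  k2 <- finite_difference_kinematics(p2, ts)
  expect_equal(k2$acceleration[, 2], rep(1, 30), tolerance = 1e-9)

  expect_error(finite_difference_kinematics(p1[1:2, ], ts[1:2]), "3 frames")
  expect_error(finite_difference_kinematics(p1, rev(ts)), "strictly increasing")
})

test_that("static poses produce the expected angle features and zero kinematics", {
  fn <- feature_names()
  expect_length(fn, 38L)
  expect_equal(sum(startsWith(fn, "theta_")), 11L)

  # arm horizontal in the coronal plane (lateral T-pose)
  f_t <- extract_features(static_arm_session(90, 90))$features
  expect_lt(max(abs(f_t[, "theta_SE_CP"])), 1e-6)
  expect_lt(max(abs(f_t[, "theta_SE_TP"])), 1e-6)
  expect_gt(min(f_t[, "theta_SE_SP"]), 90 - 1e-6)
  kin <- f_t[, grepl("^[va]_", colnames(f_t))]
  expect_lt(max(abs(kin)), 1e-9)

  # arm straight down at the side
  f_d <- extract_features(static_arm_session(0, 0))$features
  expect_gt(min(f_d[, "theta_SE_TP"]), 90 - 1e-6)

  # arm horizontal to the front (sagittal plane)
  f_f <- extract_features(static_arm_session(90, 0))$features
  expect_lt(max(abs(f_f[, "theta_SE_TP"])), 1e-6)
  expect_lt(max(abs(f_f[, "theta_SE_SP"])), 1e-6)
})

test_that("a simulated flexion session traces the expected elevation profile", {
  s <- simulate_session("flexion", duration_s = 6, seed = 2, noise_sd = 0)
  f <- extract_features(s)$features
  th <- f[, "theta_SE_TP"]   # |elevation from horizontal|
  expect_gt(th[1], 85)                    # starts at the side (down)
  expect_lt(min(th), 5)                   # passes the horizontal front
  expect_gt(max(th[40:60]), 85)           # reaches overhead
  expect_gt(th[length(th)], 80)           # returns to the side
  expect_true(all(f[, 1:11] >= 0 & f[, 1:11] <= 90))
})

test_that("velocities scale with playback speed and features stay view-invariant", {
  s <- simulate_session("adduction", duration_s = 4, seed = 8, noise_sd = 0)
  f1 <- extract_features(s)
  s_fast <- s
  s_fast$timestamps <- s$timestamps / 2   # halve dt: velocities double
  f2 <- extract_features(s_fast)
  vcols <- grepl("^v_", colnames(f1$features))
  expect_equal(f2$features[, vcols], 2 * f1$features[, vcols],
               tolerance = 1e-9)

  set.seed(7)
  for (i in 1:10) {
    s_r <- apply_rigid(s, random_rotation(), rnorm(3))
    f_r <- extract_features(s_r)
    expect_lt(max(abs(f_r$features[, 1:11] - f1$features[, 1:11])), 1e-6)
  }
})
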