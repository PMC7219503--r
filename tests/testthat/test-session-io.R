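test_that("CSV and JSON writers round-trip coordinates and timestamps exactly", {
  s <- simulate_session("h_abd_add", duration_s = 3, seed = 3,
                        participant_id = "P01", noise_sd = 0.005)
  for (fmt in c("csv", "json")) {
    dir <- withr::local_tempdir()
    manifest <- write_sessions(list(s), dir, format = fmt)
    expect_equal(nrow(manifest), 1L)
    expect_true(file.exists(file.path(dir, "manifest.csv")))
    s2 <- read_sessions(dir)[[1]]
    expect_identical(s2$timestamps, s$timestamps)
    expect_identical(unname(s2$joints[, , "rH"]), unname(s$joints[, , "rH"]))
    expect_equal(s2$joints[, , dimnames(s$joints)[[3]]], s$joints,
                 tolerance = 0)
    expect_identical(s2$participant_id, s$participant_id)
    expect_identical(s2$exercise, s$exercise)
    expect_identical(s2$label, s$label)
  }
})

test_that("manifest reflects the cohort composition and empty input", {
  dir <- withr::local_tempdir()
  expect_equal(nrow(write_sessions(list(), dir)), 0L)
  coh <- generate_cohort(participant_profile("P01", "td_like"),
                         exercises_used = "flexion",
                         n_correct = 2L, n_incorrect = 2L, seed = 4)
  m <- write_sessions(coh$sessions, dir)
  expect_equal(nrow(m), 4L)
  expect_equal(sum(m$label == "correct"), 2L)
  expect_equal(sum(m$label == "incorrect"), 2L)
})

test_that("non-monotone timestamps are rejected with the offending file named", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "bad.csv")
  writeLines(c("# participant_id: X", "# exercise: flexion",
               "# label: correct", "# frame_rate: 15",
               "frame,timestamp,joint,x,y,z",
               unlist(lapply(0:3, function(k) {
                 t <- c(0, 0.2, 0.1, 0.3)[k + 1]
                 paste0(k, ",", t, ",", required_joints(), ",0,0,0")
               }))), f)
  expect_error(read_sessions(f), "bad.csv")
  expect_error(read_sessions(f), "strictly increasing")
})

test_that("interior missing-joint gaps are linearly interpolated, long gaps rejected", {
  s <- static_arm_session(90, 0, L = 6L)
  s$joints[1:6, 1, "rW"] <- seq(0, 1, length.out = 6)  # known ramp on x
  s_na <- s
  s_na$joints[3, , "rW"] <- NA
  fixed <- validate_session(s_na, missing_joint_policy = "interpolate")
  expect_equal(length(fixed$timestamps), 6L)
  # hand-computed linear interpolation between frames 2 and 4
  expect_equal(fixed$joints[3, 1, "rW"],
               (s$joints[2, 1, "rW"] + s$joints[4, 1, "rW"]) / 2,
               tolerance = 1e-12)
  expect_equal(fixed$joints[3, 2:3, "rW"], s$joints[3, 2:3, "rW"],
               tolerance = 1e-12)

  # gap longer than max_gap: frames dropped instead
  s_long <- static_arm_session(90, 0, L = 8L)
  s_long$joints[2:5, , "rW"] <- NA
  shrunk <- validate_session(s_long, missing_joint_policy = "interpolate",
                             max_gap = 3L)
  expect_equal(length(shrunk$timestamps), 4L)

  # reject-frame policy drops the frame outright
  rej <- validate_session(s_na, missing_joint_policy = "reject-frame")
  expect_equal(length(rej$timestamps), 5L)

  # fewer than 3 valid frames is an error
  s_tiny <- s
  s_tiny$joints[1:4, , "rW"] <- NA
  expect_error(validate_session(s_tiny, missing_joint_policy = "reject-frame"),
               "fewer than 3")
})

test_that("validation is idempotent", {
  s <- simulate_session("flexion", duration_s = 3, seed = 9)
  once <- validate_session(s)
  twice <- validate_session(once)
  expect_identical(once, twice)
})
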