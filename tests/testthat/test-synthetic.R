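test_that("session length follows duration x frame rate and seeds reproduce bits", {
  s <- simulate_session("flexion", duration_s = 6.8, seed = 1)
  expect_equal(length(s$timestamps), round(6.8 * 15))   # 102 frames
  expect_equal(diff(s$timestamps), rep(1 / 15, 101), tolerance = 1e-12)
  s2 <- simulate_session("flexion", duration_s = 6.8, seed = 1)
  expect_identical(s$joints, s2$joints)
  s3 <- simulate_session("flexion", duration_s = 6.8, seed = 2)
  expect_false(identical(s$joints, s3$joints))
})

test_that("the rigid-body model conserves segment lengths without noise", {
  body <- body_model()
  s <- simulate_session("adduction", duration_s = 5, seed = 4, noise_sd = 0)
  seg <- function(a, b) sqrt(rowSums((s$joints[, , a] - s$joints[, , b])^2))
  expect_lt(max(abs(seg("rS", "rE") - body$upper_arm)), 1e-9)
  expect_lt(max(abs(seg("rE", "rW") - body$forearm)), 1e-9)
  expect_lt(max(abs(seg("rW", "rH") - body$hand)), 1e-9)
  # elbow bend changes the elbow angle but not the segment lengths
  s_b <- simulate_session("adduction", duration_s = 5, seed = 4, noise_sd = 0,
                          impairment = impairment_profile(elbow_bend = 30))
  seg_b <- function(a, b) sqrt(rowSums((s_b$joints[, , a] - s_b$joints[, , b])^2))
  expect_lt(max(abs(seg_b("rE", "rW") - body$forearm)), 1e-9)
  f <- extract_features(s_b)$features
  expect_gt(stats::median(f[, "theta_SE_EW"]), 25)
})

test_that("cohort generation reproduces the acquisition design", {
  coh <- generate_cohort(participant_profile("P01", "cp_like"),
                         n_correct = 30L, n_incorrect = 30L, seed = 6)
  m <- coh$manifest
  expect_equal(nrow(m), 180L)
  tab <- table(m$exercise, m$label)
  expect_true(all(tab == 30L))
  expect_true(all(m$duration_s >= 1))
  # same seed, same manifest
  coh2 <- generate_cohort(participant_profile("P01", "cp_like"), seed = 6)
  expect_identical(coh$manifest, coh2$manifest)
  # two participants double the count
  coh3 <- generate_cohort(list(participant_profile("A", "td_like"),
                               participant_profile("B", "td_like")),
                          exercises_used = "flexion",
                          n_correct = 2L, n_incorrect = 2L, seed = 6)
  expect_equal(nrow(coh3$manifest), 8L)
})

test_that("star layouts match the games and full-ROM runs collect every star", {
  expect_equal(nrow(star_layout("flexion")), 9L)
  expect_equal(nrow(star_layout("h_abd_add")), 9L)
  expect_equal(nrow(star_layout("adduction")), 13L)
  s0 <- simulate_session("flexion", duration_s = 5, seed = 3,
                         impairment = impairment_profile(rom_fraction = 1))
  expect_equal(game_score(s0), 9L)
  # zero movement collects nothing
  s_static <- static_arm_session(0, 0, L = 30L)
  s_static$exercise <- "flexion"
  expect_equal(game_score(s_static), 0L)
  # halved range of motion strictly reduces the score
  s_half <- simulate_session("flexion", duration_s = 5, seed = 3,
                             impairment = impairment_profile(rom_fraction = 0.5))
  expect_lt(game_score(s_half), 9L)
  expect_error(game_score(s0, exercise_spec("adduction")), "mismatch")
})

test_that("tremor amplitude drives the acceleration features monotonically", {
  acc_mag <- function(amp) {
    s <- simulate_session("flexion", duration_s = 4, seed = 12, noise_sd = 0,
                          label = "unlabeled",
                          impairment = impairment_profile(tremor_amplitude = amp))
    f <- extract_features(s)$features
    mean(abs(f[, grepl("^a_", colnames(f))]))
  }
  mags <- vapply(c(0, 0.01, 0.02), acc_mag, numeric(1))
  expect_true(all(diff(mags) > 0))
})

test_that("labels derive from the impairment profile unless overridden", {
  expect_identical(simulate_session("flexion", 3, seed = 1)$label, "correct")
  s <- simulate_session("flexion", 3, seed = 1,
                        impairment = impairment_profile(rom_fraction = 0.5))
  expect_identical(s$label, "incorrect")
  expect_error(impairment_profile(rom_fraction = 1.2))
  expect_error(impairment_profile(rom_fraction = 0))
})
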