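seated_skeleton <- function() {
  s <- static_arm_session(90, 90, L = 3L)   # arm lateral, in the coronal plane
  t(s$joints[1, , ])
}

test_that("upright pose yields axis-aligned anatomical planes", {
  sk <- seated_skeleton()
  b <- compute_body_basis(sk)
  # subject faces the sensor (-z): coronal normal along sensor z,
  # transverse normal along sensor y, sagittal normal along sensor x
  expect_equal(abs(sum(b$n_CP * c(0, 0, 1))), 1, tolerance = 1e-12)
  expect_equal(abs(sum(b$n_TP * c(0, 1, 0))), 1, tolerance = 1e-12)
  expect_equal(abs(sum(b$n_SP * c(1, 0, 0))), 1, tolerance = 1e-12)
  # orientation: anterior toward the sensor, superior up, x to subject's left
  expect_equal(b$n_CP, c(0, 0, -1), tolerance = 1e-12)
  expect_equal(b$n_TP, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(b$n_SP, c(-1, 0, 0), tolerance = 1e-12)
})

test_that("basis satisfies its orthonormality and plane-membership invariants", {
  sk <- seated_skeleton()
  sk["SS", ] <- sk["SS", ] + c(0, 0.004, -0.01)  # SS slightly off the shoulder line
  b <- compute_body_basis(sk)
  for (n in list(b$n_CP, b$n_TP, b$n_SP))
    expect_lt(abs(sqrt(sum(n^2)) - 1), 1e-9)
  expect_lt(abs(sum(b$n_CP * b$n_TP)), 1e-6)
  expect_lt(abs(sum(b$n_CP * b$n_SP)), 1e-6)
  expect_lt(abs(sum(b$n_TP * b$n_SP)), 1e-6)
  expect_equal(b$rotation %*% t(b$rotation), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  # rS, lS, SB all lie in the coronal plane
  for (j in c("rS", "lS", "SB"))
    expect_lt(abs(sum(b$n_CP * (sk[j, ] - b$origin))), 1e-9)
  # virtual joints: 0.2 m shifts and hip-height match
  expect_equal(sqrt(sum((b$SS_hat - sk["SS", ])^2)), 0.2, tolerance = 1e-12)
  expect_equal(sqrt(sum((b$rS_hat - sk["rS", ])^2)), 0.2, tolerance = 1e-12)
  expect_lt(abs(to_body_frame(b$rS_hathat, b)[2] -
                to_body_frame(sk["rHI", ], b)[2]), 1e-9)
})

test_that("right shoulder maps to origin and the coronal normal to +z", {
  sk <- seated_skeleton()
  b <- compute_body_basis(sk)
  expect_equal(to_body_frame(sk["rS", ], b), c(0, 0, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(to_body_frame(b$origin + b$n_CP, b), c(0, 0, 1),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("body-frame coordinates are invariant under rigid motions of the sensor frame", {
  s <- static_arm_session(55, 30, L = 3L)
  sk <- t(s$joints[1, , ])
  b0 <- compute_body_basis(sk)
  p0 <- to_body_frame(sk[c("rE", "rW", "rH"), ], b0)
  set.seed(42)
  for (i in 1:100) {
    R <- random_rotation()
    tv <- rnorm(3, sd = 2)
    sk2 <- t(R %*% t(sk) + tv)
    rownames(sk2) <- rownames(sk)
    b2 <- compute_body_basis(sk2)
    p2 <- to_body_frame(sk2[c("rE", "rW", "rH"), ], b2)
    expect_lt(max(abs(p2 - p0)), 1e-9)
  }
})

test_that("degenerate defining joints raise a geometry error", {
  sk <- seated_skeleton()
  sk["lS", ] <- sk["rS", ]
  expect_error(compute_body_basis(sk), "degenerate.*coronal")
  sk2 <- seated_skeleton()
  sk2["rHI", 2] <- sk2["rS", 2]   # hip at shoulder height
  expect_error(compute_body_basis(sk2), "sagittal")
})
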