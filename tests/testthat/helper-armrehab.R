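# Builders and independent oracles shared across the test files.

# Static session with the right arm held straight at elevation psi /
# azimuth alpha (degrees); no noise, torso from the default body model.
static_arm_session <- function(psi, alpha, L = 10L, frame_rate = 15,
                               body = body_model()) {
  rest <- armrehab:::rest_skeleton(body)
  u <- drop(armrehab:::arm_direction_sensor(psi, alpha))
  rest["rE", ] <- rest["rS", ] + body$upper_arm * u
  rest["rW", ] <- rest["rE", ] + body$forearm * u
  rest["rH", ] <- rest["rW", ] + body$hand * u
  joints <- array(rep(t(rest), each = L), dim = c(L, 3, nrow(rest)),
                  dimnames = list(NULL, c("x", "y", "z"), rownames(rest)))
  session("T1", "flexion", "unlabeled", frame_rate,
          (seq_len(L) - 1L) / frame_rate, joints)
}

# Uniform random proper rotation (det +1) via QR of a Gaussian matrix.
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Apply a rigid motion p -> R p + t to every joint of a session.
apply_rigid <- function(s, R, tvec) {
  L <- dim(s$joints)[1]
  for (k in seq_len(L)) {
    s$joints[k, , ] <- R %*% s$joints[k, , ] + tvec
  }
  s
}

# Exhaustive-path DTW oracle: enumerates every monotone warping path from
# (1,1) to (L1,L2) with steps (1,0),(0,1),(1,1) and minimizes the summed
# Euclidean frame costs. Independent of the dynamic program it checks.
bf_dtw_distance <- function(A, B) {
  L1 <- nrow(A); L2 <- nrow(B)
  cost <- function(i, j) sqrt(sum((A[i, ] - B[j, ])^2))
  best <- Inf
  rec <- function(i, j, acc) {
    acc <- acc + cost(i, j)
    if (i == L1 && j == L2) {
      best <<- min(best, acc)
      return(invisible())
    }
    if (i < L1) rec(i + 1L, j, acc)
    if (j < L2) rec(i, j + 1L, acc)
    if (i < L1 && j < L2) rec(i + 1L, j + 1L, acc)
    invisible()
  }
  rec(1L, 1L, 0)
  best
}

# Bank of plain feature matrices whose class signal sits in `informative`
# columns (class means -mu / +mu) with unit-ish noise elsewhere.
toy_bank <- function(n_per_side = 6L, L = 8L, informative = "theta_SE_CP",
                     mu = 4, noise_sd = 0.1, seed = 1) {
  fn <- feature_names()
  make_side <- function(center) {
    lapply(seq_len(n_per_side), function(i) {
      m <- matrix(rnorm(L * length(fn), 0, 1), L, length(fn),
                  dimnames = list(NULL, fn))
      m[, informative] <- center + rnorm(L * length(informative), 0, noise_sd)
      m
    })
  }
  armrehab:::with_seed(seed,
    gold_standard_bank(make_side(mu), make_side(-mu)))
}
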