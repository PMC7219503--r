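#' Kinematic body model for the session simulator
#'
#' Segment lengths (meters) and the static seated torso pose used by the
#' forward-kinematics simulator. The 17 joints not used by the assessment
#' are generated as a static seated skeleton so files are format-complete;
#' the right arm is articulated from the shoulder. Defaults are plausible
#' child/adult anthropometry, not estimates of any study population.
#'
#' @param shoulder_width Distance between the shoulder joints.
#' @param upper_arm,forearm,hand Right-arm segment lengths.
#' @param torso_position Sensor-frame position of the spine base; the
#'   subject faces the sensor (anterior = `-z` in sensor coordinates).
#' @return An object of class `"body_model"`.
#' @export
body_model <- function(shoulder_width = 0.35, upper_arm = 0.30,
                       forearm = 0.25, hand = 0.08,
                       torso_position = c(0, 0, 2)) {
  lens <- c(shoulder_width = shoulder_width, upper_arm = upper_arm,
            forearm = forearm, hand = hand)
  if (any(lens <= 0)) stop("segment lengths must be positive")
  structure(list(shoulder_width = shoulder_width, upper_arm = upper_arm,
                 forearm = forearm, hand = hand,
                 torso_position = torso_position),
            class = "body_model")
}

# Static seated 25-joint rest pose (J x 3, sensor frame). Subject faces the
# sensor: anterior = (0,0,-1), superior = (0,1,0), subject's right = (1,0,0).
rest_skeleton <- function(body) {
  hw <- body$shoulder_width / 2
  o <- body$torso_position
  ra_y <- 0.42 - body$upper_arm            # left-arm rest heights mirror right
  rw_y <- ra_y - body$forearm
  rh_y <- rw_y - body$hand
  m <- rbind(
    SB   = c(0, 0, 0),       SM  = c(0, 0.22, 0),  SS = c(0, 0.42, 0),
    Neck = c(0, 0.48, 0),    Head = c(0, 0.60, 0),
    lS = c(-hw, 0.42, 0),    lE = c(-hw - 0.02, ra_y, 0),
    lW = c(-hw - 0.025, rw_y, 0), lH = c(-hw - 0.025, rh_y, 0),
    rS = c(hw, 0.42, 0),     rE = c(hw + 0.02, ra_y, 0),
    rW = c(hw + 0.025, rw_y, 0),  rH = c(hw + 0.025, rh_y, 0),
    lHI = c(-0.09, -0.02, 0), lK = c(-0.09, -0.06, -0.42),
    lA = c(-0.09, -0.46, -0.38), lF = c(-0.09, -0.52, -0.52),
    rHI = c(0.09, -0.02, 0),  rK = c(0.09, -0.06, -0.42),
    rA = c(0.09, -0.46, -0.38), rF = c(0.09, -0.52, -0.52),
    lHT = c(-hw - 0.025, rh_y - 0.04, 0), lTH = c(-hw + 0.005, rw_y - 0.03, -0.02),
    rHT = c(hw + 0.025, rh_y - 0.04, 0),  rTH = c(hw - 0.005, rw_y - 0.03, -0.02))
  sweep(m, 2, o, "+")[kinect_joints(), , drop = FALSE]
}

#' Impairment profile for incorrect executions
#'
#' Parameterizes the simulated impairment modes: limited range of motion
#' (`rom_fraction` scales the angular excursion), unstable movement
#' (`tremor_amplitude`, meters of band-limited 4-8 Hz jitter on the
#' elbow/wrist/hand), a bent elbow (degrees, violating the
#' arm-kept-straight instruction), a global `speed_factor` on the session
#' duration, and wrong movement patterns (`"wrong_path"` swaps the
#' movement plane, `"premature_stop"` freezes the arm at 60% of the
#' session). The null profile (all defaults) reproduces the
#' correct-execution generator.
#'
#' @param rom_fraction Fraction of the target range of motion in (0, 1].
#' @param tremor_amplitude Jitter amplitude (m) on rE/rW/rH.
#' @param tremor_frequency Center frequency band is fixed at 4-8 Hz; kept
#'   for reporting.
#' @param speed_factor Multiplier on the nominal session duration.
#' @param elbow_bend Elbow flexion in degrees.
#' @param pattern_error `"none"`, `"wrong_path"`, or `"premature_stop"`.
#' @return An object of class `"impairment_profile"`.
#' @export
impairment_profile <- function(rom_fraction = 1, tremor_amplitude = 0,
                               tremor_frequency = 6, speed_factor = 1,
                               elbow_bend = 0,
                               pattern_error = c("none", "wrong_path",
                                                 "premature_stop")) {
  pattern_error <- match.arg(pattern_error)
  stopifnot(rom_fraction > 0, rom_fraction <= 1, tremor_amplitude >= 0,
            speed_factor > 0, elbow_bend >= 0, elbow_bend < 150)
  structure(list(rom_fraction = rom_fraction,
                 tremor_amplitude = tremor_amplitude,
                 tremor_frequency = tremor_frequency,
                 speed_factor = speed_factor,
                 elbow_bend = elbow_bend,
                 pattern_error = pattern_error),
            class = "impairment_profile")
}

is_null_impairment <- function(imp) {
  imp$rom_fraction == 1 && imp$tremor_amplitude == 0 &&
    imp$elbow_bend == 0 && imp$pattern_error == "none"
}

#' Exercise waypoints and star layout
#'
#' Encodes each game as a sequence of arm-direction waypoints
#' `(psi, alpha)`: `psi` is the shoulder elevation measured from the
#' resting arm-down direction (0 = down, 90 = horizontal, 180 =
#' overhead) and `alpha` the movement-plane azimuth (0 = anterior /
#' sagittal plane, 90 = lateral / coronal plane, negative = across the
#' body). Flexion: rest -> front-horizontal -> overhead (hold) -> rest,
#' all sagittal. Horizontal abduction/adduction: raise to the front
#' (hold), sweep laterally to 90, then across the body to -60.
#' Adduction: raise laterally to overhead (hold), then lateral descent
#' back down along the 180-degree arc. The terminal hold lasts between 1
#' and 2 s. Star counts: 9 (flexion), 9 (horizontal abduction/adduction),
#' 13 (adduction); stars sit on the projection of the ideal full-ROM hand
#' path onto the screen.
#'
#' @param exercise One of [exercises()].
#' @param hold_s Hold duration in seconds (in `[1, 2]`).
#' @return An object of class `"exercise_spec"`: `waypoints` (matrix with
#'   columns `psi`, `alpha`), `hold_after` (seconds of hold after each
#'   waypoint), `stars` (screen coordinates), `capture_radius`.
#' @export
exercise_spec <- function(exercise, hold_s = 1.5) {
  exercise <- match.arg(exercise, exercises())
  stopifnot(hold_s >= 1, hold_s <= 2)
  w <- switch(exercise,
    flexion = list(
      waypoints = cbind(psi = c(0, 90, 180, 0), alpha = c(0, 0, 0, 0)),
      hold_after = c(0, 0, hold_s, 0)),
    h_abd_add = list(
      waypoints = cbind(psi = c(0, 90, 90, 90), alpha = c(0, 0, 90, -60)),
      hold_after = c(0, hold_s, 0, 0)),
    adduction = list(
      waypoints = cbind(psi = c(0, 180, 0), alpha = c(90, 90, 90)),
      hold_after = c(0, hold_s, 0)))
  structure(list(exercise = exercise,
                 waypoints = w$waypoints,
                 hold_after = w$hold_after,
                 stars = star_layout(exercise),
                 capture_radius = 0.05),
            class = "exercise_spec")
}

#' @rdname exercise_spec
#' @export
star_layout <- function(exercise) {
  exercise <- match.arg(exercise, exercises())
  proj <- function(psi, alpha) {
    u <- arm_direction_body(psi, alpha)
    cbind(x = 0.5 - u[, 1] / 2, y = 0.5 + u[, 2] / 2)
  }
  # star sequences start above the resting pose so a motionless session
  # scores zero; the last star sits at the full-ROM terminal position
  switch(exercise,
    flexion = proj(seq(30, 180, length.out = 9), 0),
    h_abd_add = proj(90, seq(90, -60, length.out = 9)),
    adduction = proj(seq(180, 15, length.out = 13), 90))
}

# Unit arm direction in body coordinates (x = subject's left, y = superior,
# z = anterior) for elevation psi and azimuth alpha, degrees.
arm_direction_body <- function(psi, alpha) {
  n <- max(length(psi), length(alpha))
  psi <- rep_len(psi, n) * pi / 180
  alpha <- rep_len(alpha, n) * pi / 180
  cbind(-sin(psi) * sin(alpha), -cos(psi), sin(psi) * cos(alpha))
}

# Same direction in the simulator's sensor frame (subject facing the
# sensor): left = (-1,0,0), up = (0,1,0), anterior = (0,0,-1).
arm_direction_sensor <- function(psi, alpha) {
  u <- arm_direction_body(psi, alpha)
  cbind(-u[, 1], u[, 2], -u[, 3])
}

min_jerk <- function(tau) tau^3 * (10 - 15 * tau + 6 * tau^2)

# Piecewise minimum-jerk schedule through waypoints with holds; returns the
# (psi, alpha) trajectory sampled at the given times.
waypoint_trajectory <- function(waypoints, hold_after, times, duration) {
  seg_len <- sqrt(rowSums(diff(waypoints)^2))
  hold_total <- min(sum(hold_after), 0.5 * duration)
  if (sum(hold_after) > 0)
    hold_after <- hold_after * hold_total / sum(hold_after)
  move_time <- duration - hold_total
  if (sum(seg_len) <= 0) {
    return(matrix(rep(waypoints[1, ], each = length(times)), ncol = 2,
                  dimnames = list(NULL, c("psi", "alpha"))))
  }
  seg_time <- move_time * seg_len / sum(seg_len)
  # event table: alternating moves and holds
  n_seg <- length(seg_len)
  starts <- numeric(n_seg)
  t0 <- hold_after[1]
  for (i in seq_len(n_seg)) {
    starts[i] <- t0
    t0 <- t0 + seg_time[i] + hold_after[i + 1]
  }
  out <- matrix(NA_real_, length(times), 2,
                dimnames = list(NULL, c("psi", "alpha")))
  for (k in seq_along(times)) {
    t <- min(times[k], duration)
    i <- findInterval(t, starts)
    if (i < 1L) { out[k, ] <- waypoints[1, ]; next }
    dt <- t - starts[i]
    if (dt >= seg_time[i] || seg_time[i] <= 0) {
      out[k, ] <- waypoints[i + 1, ]
    } else {
      s <- min_jerk(dt / seg_time[i])
      out[k, ] <- waypoints[i, ] + s * (waypoints[i + 1, ] - waypoints[i, ])
    }
  }
  out
}

# Band-limited (4-8 Hz) unit-RMS jitter signal of length L at rate fs.
band_noise <- function(L, fs, n_comp = 5L) {
  t <- (seq_len(L) - 1L) / fs
  f <- runif(n_comp, 4, 8)
  ph <- runif(n_comp, 0, 2 * pi)
  s <- rowSums(vapply(seq_len(n_comp), function(i)
    sin(2 * pi * f[i] * t + ph[i]), numeric(L)))
  s / sqrt(n_comp / 2)   # unit RMS
}

rodrigues <- function(v, axis, angle_deg) {
  th <- angle_deg * pi / 180
  k <- axis / sqrt(sum(axis^2))
  v * cos(th) + cross3(k, v) * sin(th) + k * sum(k * v) * (1 - cos(th))
}

#' Simulate one game-playing session
#'
#' Forward-kinematics generation of a 25-joint skeleton session: the arm
#' direction follows the exercise waypoints with minimum-jerk
#' interpolation and the prescribed holds, the trunk is held static
#' (seated, straight), and the chosen impairment perturbations plus
#' i.i.d. Gaussian measurement noise (default SD 5 mm per coordinate,
#' Kinect-v2-like) are applied. Same seed, same session, bit for bit.
#'
#' @param exercise One of [exercises()].
#' @param duration_s Nominal session duration in seconds (before
#'   `speed_factor`).
#' @param body A [body_model()].
#' @param impairment An [impairment_profile()].
#' @param frame_rate Frames per second (reference protocol: 15).
#' @param seed Seed for hold draw, tremor and measurement noise.
#' @param participant_id Metadata.
#' @param label If `NULL`, `"correct"` when the impairment is the null
#'   profile and `"incorrect"` otherwise.
#' @param noise_sd Measurement noise SD in meters (0 disables).
#' @param hold_s Hold duration; if `NULL`, drawn uniformly from `[1, 2]`.
#' @return A validated `"session"`.
#' @export
simulate_session <- function(exercise, duration_s = 5,
                             body = body_model(),
                             impairment = impairment_profile(),
                             frame_rate = 15, seed = NULL,
                             participant_id = "SIM1", label = NULL,
                             noise_sd = 0.005, hold_s = NULL) {
  exercise <- match.arg(exercise, exercises())
  stopifnot(inherits(body, "body_model"),
            inherits(impairment, "impairment_profile"))
  with_seed(seed, {
    dur <- duration_s * impairment$speed_factor
    if (dur < 0.5) stop("session duration too short to simulate")
    L <- max(3L, round(dur * frame_rate))
    ts <- (seq_len(L) - 1L) / frame_rate
    if (is.null(hold_s)) hold_s <- runif(1, 1, 2)
    spec <- exercise_spec(exercise, hold_s = min(2, max(1, hold_s)))

    wp <- spec$waypoints
    if (impairment$pattern_error == "wrong_path")
      wp[, "alpha"] <- 90 - wp[, "alpha"]
    wp <- sweep(sweep(wp, 2, wp[1, ]) * impairment$rom_fraction, 2, wp[1, ], "+")
    ang <- waypoint_trajectory(wp, spec$hold_after, ts, dur)
    if (impairment$pattern_error == "premature_stop") {
      freeze <- ts > 0.6 * dur
      if (any(freeze)) {
        last <- which(!freeze)
        hold_row <- if (length(last)) max(last) else 1L
        ang[freeze, ] <- matrix(ang[hold_row, ], sum(freeze), 2, byrow = TRUE)
      }
    }

    rest <- rest_skeleton(body)
    u <- arm_direction_sensor(ang[, "psi"], ang[, "alpha"])
    u_fore <- u
    if (impairment$elbow_bend > 0) {
      anterior <- c(0, 0, -1)
      for (k in seq_len(L)) {
        axis <- cross3(u[k, ], anterior)
        if (sqrt(sum(axis^2)) < 1e-6) axis <- cross3(u[k, ], c(0, 1, 0))
        u_fore[k, ] <- rodrigues(u[k, ], axis, impairment$elbow_bend)
      }
    }
    J <- nrow(rest)
    joints <- array(rep(t(rest), each = L), dim = c(L, 3, J),
                    dimnames = list(NULL, c("x", "y", "z"), rownames(rest)))
    rS <- rest["rS", ]
    rE <- sweep(u * body$upper_arm, 2, rS, "+")
    rW <- rE + u_fore * body$forearm
    rH <- rW + u_fore * body$hand
    # tremor: band-limited jitter on the distal joints (drawn even at zero
    # amplitude so seeded noise streams are comparable across amplitudes)
    for (j in c("rE", "rW", "rH")) {
      trem <- vapply(1:3, function(d) band_noise(L, frame_rate), numeric(L))
      pos <- switch(j, rE = rE, rW = rW, rH = rH)
      pos <- pos + impairment$tremor_amplitude * trem
      assign(j, pos)
    }
    joints[, , "rE"] <- rE
    joints[, , "rW"] <- rW
    joints[, , "rH"] <- rH
    if (noise_sd > 0)
      joints <- joints + array(rnorm(L * 3 * J, 0, noise_sd), dim = c(L, 3, J))
    if (is.null(label))
      label <- if (is_null_impairment(impairment)) "correct" else "incorrect"
    session(participant_id = participant_id, exercise = exercise,
            label = label, frame_rate = frame_rate, timestamps = ts,
            joints = joints)
  })
}

#' Participant profile for cohort generation
#'
#' Bundles the session-duration distribution and the impairment-parameter
#' ranges from which a participant's correct and incorrect sessions are
#' drawn. The two groups mirror the study design: `"td_like"`
#' (typically-developing-like) participants produce short sessions
#' (means 4.4 / 4.9 / 6.2 s for the three exercises) with cleanly
#' separated correct vs incorrect kinematics; `"cp_like"` (cerebral
#' palsy-like) participants produce longer, more variable sessions
#' (means 6.8 / 7.6 / 11.4 s, SDs 5.1 / 4.4 / 5.0 s) whose correct
#' executions already carry mild tremor and reduced range, overlapping
#' the incorrect ones. All ranges are configurable stand-ins; the study's
#' labeling criteria were qualitative.
#'
#' @param id Participant identifier.
#' @param group `"td_like"` or `"cp_like"`.
#' @param duration_mean,duration_sd Named numeric vectors over
#'   [exercises()] (seconds); defaults per group.
#' @param correct_rom,incorrect_rom Ranges for the ROM fraction.
#' @param correct_tremor,incorrect_tremor Ranges for tremor amplitude (m).
#' @param incorrect_elbow Range for elbow bend (degrees).
#' @param pattern_prob Probability an incorrect session also uses a wrong
#'   movement pattern.
#' @param duration_floor Truncation floor for drawn durations (s).
#' @return An object of class `"participant_profile"`.
#' @export
participant_profile <- function(id, group = c("td_like", "cp_like"),
                                duration_mean = NULL, duration_sd = NULL,
                                correct_rom = NULL, incorrect_rom = NULL,
                                correct_tremor = NULL, incorrect_tremor = NULL,
                                incorrect_elbow = NULL, pattern_prob = NULL,
                                duration_floor = 3) {
  group <- match.arg(group)
  d <- if (group == "cp_like") {
    list(duration_mean = c(flexion = 6.8, h_abd_add = 7.6, adduction = 11.4),
         duration_sd = c(flexion = 5.1, h_abd_add = 4.4, adduction = 5.0),
         correct_rom = c(0.85, 1), incorrect_rom = c(0.50, 0.80),
         correct_tremor = c(0.001, 0.004), incorrect_tremor = c(0.008, 0.025),
         incorrect_elbow = c(10, 35), pattern_prob = 0.25)
  } else {
    list(duration_mean = c(flexion = 4.4, h_abd_add = 4.9, adduction = 6.2),
         duration_sd = c(flexion = 1.2, h_abd_add = 1.6, adduction = 1.5),
         correct_rom = c(0.95, 1), incorrect_rom = c(0.40, 0.65),
         correct_tremor = c(0, 0), incorrect_tremor = c(0.015, 0.030),
         incorrect_elbow = c(0, 20), pattern_prob = 0.3)
  }
  structure(list(
    id = id, group = group,
    duration_mean = duration_mean %||% d$duration_mean,
    duration_sd = duration_sd %||% d$duration_sd,
    correct_rom = correct_rom %||% d$correct_rom,
    incorrect_rom = incorrect_rom %||% d$incorrect_rom,
    correct_tremor = correct_tremor %||% d$correct_tremor,
    incorrect_tremor = incorrect_tremor %||% d$incorrect_tremor,
    incorrect_elbow = incorrect_elbow %||% d$incorrect_elbow,
    pattern_prob = pattern_prob %||% d$pattern_prob,
    duration_floor = duration_floor), class = "participant_profile")
}

#' Generate a synthetic cohort of game-playing sessions
#'
#' Emulates the reference acquisition protocol: for every participant and
#' every exercise, 30 correct and 30 incorrect sessions (180 per
#' participant over the three exercises) at 15 frames/s, with durations
#' drawn from the participant's group distribution truncated at a
#' positive floor. Correct sessions use near-null impairments (ROM and
#' tremor drawn from the profile's `correct_*` ranges). A participant's
#' motor limitation is treated as a stable trait: one impairment style
#' (ROM center, tremor amplitude, elbow bend, and — with probability
#' `pattern_prob` — a wrong movement pattern) is drawn per participant
#' from the `incorrect_*` ranges, and each incorrect session jitters
#' around that style, mirroring how a patient's limitation (or a
#' typically developing subject instructed to replicate one) is
#' consistent across sessions.
#'
#' @param participants A `"participant_profile"` or list of them.
#' @param exercises_used Which exercises to generate.
#' @param n_correct,n_incorrect Sessions per label per exercise.
#' @param frame_rate Frames per second.
#' @param seed Base seed; every session uses a distinct derived seed.
#' @param noise_sd Measurement noise SD (m).
#' @return A list with `sessions` (list of `"session"`) and `manifest`
#'   (data frame: participant, exercise, label, frames, duration).
#' @export
generate_cohort <- function(participants, exercises_used = exercises(),
                            n_correct = 30L, n_incorrect = 30L,
                            frame_rate = 15, seed = 1L, noise_sd = 0.005) {
  if (inherits(participants, "participant_profile"))
    participants <- list(participants)
  exercises_used <- match.arg(exercises_used, exercises(), several.ok = TRUE)
  sessions <- list()
  counter <- 0L
  for (pi in seq_along(participants)) {
    p <- participants[[pi]]
    stopifnot(inherits(p, "participant_profile"))
    style <- with_seed(seed * 7919L + pi, list(
      rom = runif(1, p$incorrect_rom[1], p$incorrect_rom[2]),
      tremor = runif(1, p$incorrect_tremor[1], p$incorrect_tremor[2]),
      elbow = runif(1, p$incorrect_elbow[1], p$incorrect_elbow[2]),
      pattern = if (runif(1) < p$pattern_prob)
        sample(c("wrong_path", "premature_stop"), 1) else "none"))
    for (ex in exercises_used) {
      for (lab in c(rep("correct", n_correct), rep("incorrect", n_incorrect))) {
        counter <- counter + 1L
        s_seed <- seed * 1000L + counter
        sessions[[counter]] <- with_seed(s_seed, {
          dur <- max(p$duration_floor,
                     rnorm(1, p$duration_mean[[ex]], p$duration_sd[[ex]]))
          imp <- if (lab == "correct") {
            impairment_profile(
              rom_fraction = runif(1, p$correct_rom[1], p$correct_rom[2]),
              tremor_amplitude = runif(1, p$correct_tremor[1], p$correct_tremor[2]))
          } else {
            impairment_profile(
              rom_fraction = min(1, max(0.05, style$rom * runif(1, 0.9, 1.1))),
              tremor_amplitude = style$tremor * runif(1, 0.8, 1.2),
              elbow_bend = style$elbow * runif(1, 0.8, 1.2),
              pattern_error = style$pattern)
          }
          simulate_session(ex, duration_s = dur, impairment = imp,
                           frame_rate = frame_rate, seed = s_seed + 1L,
                           participant_id = p$id, label = lab,
                           noise_sd = noise_sd)
        })
      }
    }
  }
  manifest <- do.call(rbind, lapply(sessions, function(s) data.frame(
    participant_id = s$participant_id, exercise = s$exercise,
    label = s$label, n_frames = length(s$timestamps),
    duration_s = diff(range(s$timestamps)), stringsAsFactors = FALSE)))
  list(sessions = sessions, manifest = manifest)
}

#' Score a session against the game's star layout
#'
#' Projects the right-hand trajectory, expressed in the body-attached
#' frame, orthographically onto the coronal plane, scales it to the unit
#' screen (shoulder at the center, arm reach = half screen), and counts
#' the stars whose capture radius (0.05 screen units) the hand enters.
#' One point per star, as in the games.
#'
#' @param x A `"session"`.
#' @param spec An [exercise_spec()]; defaults to the session's exercise.
#' @return Integer score between 0 and the star count (9, 9, or 13).
#' @export
game_score <- function(x, spec = exercise_spec(x$exercise)) {
  stopifnot(inherits(x, "session"), inherits(spec, "exercise_spec"))
  if (spec$exercise != x$exercise)
    stop("exercise mismatch between session and spec")
  L <- length(x$timestamps)
  ph <- matrix(NA_real_, L, 3)
  for (k in seq_len(L)) {
    jk <- t(x$joints[k, , ])
    basis <- compute_body_basis(jk)
    ph[k, ] <- to_body_frame(jk["rH", ], basis)
  }
  reach <- max(sqrt(rowSums(ph^2)))
  if (reach <= 0) return(0L)
  sx <- 0.5 - ph[, 1] / (2 * reach)
  sy <- 0.5 + ph[, 2] / (2 * reach)
  stars <- spec$stars
  sum(vapply(seq_len(nrow(stars)), function(i)
    min(sqrt((sx - stars[i, "x"])^2 + (sy - stars[i, "y"])^2)) <=
      spec$capture_radius, logical(1)))
}
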