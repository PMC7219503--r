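#' Angle between a vector and an anatomical plane
#'
#' `asin(|V . n| / ||V||)` in degrees, clamped to `[0, 90]`; `n` must be a
#' unit plane normal. A vector lying in the plane gives 0 degrees, a
#' vector along the normal 90 degrees.
#'
#' @param v Non-zero 3-vector.
#' @param n Unit normal 3-vector of the plane.
#' @return Angle in degrees in `[0, 90]`.
#' @export
angle_vector_plane <- function(v, n) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("degenerate vector: zero length")
  d <- sum(v * n)
  # atan2 form of asin(|d|/||v||): well-conditioned at both 0 and 90 deg
  atan2(abs(d), sqrt(max(0, nv^2 - d^2))) * 180 / pi
}

#' Angle between two vectors (folded to `[0, 90]`)
#'
#' `acos(|U . V| / (||U|| ||V||))` in degrees. The absolute value folds
#' the angle, so antiparallel vectors give 0 degrees.
#'
#' @param u,v Non-zero 3-vectors.
#' @return Angle in degrees in `[0, 90]`.
#' @export
angle_between_vectors <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12) stop("degenerate vector: zero length")
  cr <- cross3(u, v)
  # atan2 form of acos(|u.v|/(|u||v|)): well-conditioned at 0 and 90 deg
  atan2(sqrt(sum(cr^2)), abs(sum(u * v))) * 180 / pi
}

#' First-difference velocities and accelerations
#'
#' `v(k) = (p(k) - p(k-1)) / dt_k` and `a(k) = (v(k) - v(k-1)) / dt_k`,
#' with `dt_k` taken from the actual timestamp differences (robust to
#' dropped frames). Boundary frames are padded with the nearest valid
#' value (`v(1) := v(2)`, `a(1) := a(2) := a(3)`, 1-based) so the series
#' keeps length `L`.
#'
#' @param positions `L x d` matrix of positions.
#' @param timestamps Strictly increasing numeric vector of length `L >= 3`.
#' @return List with `velocity` and `acceleration`, both `L x d`.
#' @export
finite_difference_kinematics <- function(positions, timestamps) {
  positions <- as.matrix(positions)
  L <- nrow(positions)
  if (L < 3L) stop("at least 3 frames are needed for acceleration features")
  dt <- diff(timestamps)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  v <- positions
  v[-1L, ] <- diff(positions) / dt
  v[1L, ] <- v[2L, ]
  a <- v
  a[-1L, ] <- diff(v) / dt
  a[1L, ] <- a[3L, ]
  a[2L, ] <- a[3L, ]
  list(velocity = v, acceleration = a)
}

#' Extract the 38 per-frame features of a session
#'
#' For every frame, builds the body-attached basis
#' ([compute_body_basis()]), transforms the right-arm joints into it, and
#' computes the feature vector: the angles between the upper-arm
#' (`SE = rE - rS`), forearm (`EW = rW - rE`) and hand (`WH = rH - rW`)
#' vectors and the coronal/transverse/sagittal planes (9), the
#' inter-segment angles `theta_SE_EW` and `theta_EW_WH` (2), and the
#' body-frame positions, velocities and accelerations of `rE`, `rW`, `rH`
#' along `x`, `y`, `z` (27). Angles are in degrees; kinematics in m, m/s,
#' m/s^2.
#'
#' @param x A `"session"`.
#' @return An object of class `"feature_series"`: list with `features`
#'   (an `L x 38` matrix with columns [feature_names()]), `timestamps`,
#'   and the session metadata.
#' @export
extract_features <- function(x) {
  stopifnot(inherits(x, "session"))
  L <- length(x$timestamps)
  ang <- matrix(NA_real_, L, 11)
  pos <- array(NA_real_, c(L, 3, 3), dimnames = list(NULL, c("x", "y", "z"),
                                                     c("rE", "rW", "rH")))
  for (k in seq_len(L)) {
    jk <- t(x$joints[k, , ])                  # J x 3, rownames joints
    basis <- tryCatch(compute_body_basis(jk), error = function(e)
      stop("frame ", k, ": ", conditionMessage(e), call. = FALSE))
    p <- to_body_frame(rbind(rS = jk["rS", ], rE = jk["rE", ],
                             rW = jk["rW", ], rH = jk["rH", ]), basis)
    SE <- p["rE", ] - p["rS", ]
    EW <- p["rW", ] - p["rE", ]
    WH <- p["rH", ] - p["rW", ]
    # plane normals in body coordinates are the coordinate axes
    nb <- list(CP = c(0, 0, 1), TP = c(0, 1, 0), SP = c(1, 0, 0))
    kang <- tryCatch(c(
      vapply(list(SE, EW, WH), function(v)
        c(angle_vector_plane(v, nb$CP),
          angle_vector_plane(v, nb$TP),
          angle_vector_plane(v, nb$SP)), numeric(3)),
      angle_between_vectors(SE, EW),
      angle_between_vectors(EW, WH)), error = function(e)
        stop("frame ", k, ": ", conditionMessage(e), call. = FALSE))
    ang[k, ] <- kang
    pos[k, , "rE"] <- p["rE", ]
    pos[k, , "rW"] <- p["rW", ]
    pos[k, , "rH"] <- p["rH", ]
  }
  pmat <- cbind(pos[, , "rE"], pos[, , "rW"], pos[, , "rH"])
  kin <- finite_difference_kinematics(pmat, x$timestamps)
  feats <- cbind(ang, pmat, kin$velocity, kin$acceleration)
  colnames(feats) <- feature_names()
  structure(list(features = feats,
                 timestamps = x$timestamps,
                 participant_id = x$participant_id,
                 exercise = x$exercise,
                 label = x$label,
                 frame_rate = x$frame_rate),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> %s | %s | %s | %d frames x %d features\n",
              x$participant_id, x$exercise, x$label,
              nrow(x$features), ncol(x$features)))
  invisible(x)
}

#' @export
as.data.frame.feature_series <- function(x, ...) {
  data.frame(frame = seq_len(nrow(x$features)) - 1L,
             timestamp = x$timestamps, x$features, check.names = FALSE)
}
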