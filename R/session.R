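#' Construct a skeleton-tracking session
#'
#' A session is one iteration of a game-based exercise: an ordered series
#' of skeleton frames, each holding the 3D positions (meters, sensor
#' coordinates) of the 25 tracked joints, plus metadata identifying the
#' participant, the exercise, and the physiotherapist-style correctness
#' label.
#'
#' @param participant_id Character scalar.
#' @param exercise One of [exercises()].
#' @param label One of `"correct"`, `"incorrect"`, `"unlabeled"`.
#' @param frame_rate Acquisition rate in Hz (15 for the reference
#'   protocol).
#' @param timestamps Numeric vector of length `L`, seconds, strictly
#'   increasing.
#' @param joints Numeric array `L x 3 x J` with `dimnames[[3]]` naming the
#'   joints; must include all of [required_joints()]. Coordinates in
#'   meters, sensor frame.
#' @param validate If `TRUE` (default), run [validate_session()].
#' @param ... Passed to [validate_session()] (e.g. `missing_joint_policy`).
#'
#' @return An object of class `"session"`: a list with the fields above.
#' @seealso [read_sessions()], [simulate_session()], [extract_features()]
#' @export
session <- function(participant_id, exercise, label = "unlabeled",
                    frame_rate = 15, timestamps, joints,
                    validate = TRUE, ...) {
  stopifnot(is.character(participant_id), length(participant_id) == 1L)
  exercise <- match.arg(exercise, exercises())
  label <- match.arg(label, session_labels())
  if (!is.array(joints) || length(dim(joints)) != 3L || dim(joints)[2] != 3L)
    stop("'joints' must be an L x 3 x J array")
  if (is.null(dimnames(joints)[[3]]))
    stop("'joints' must have joint names as dimnames[[3]]")
  if (length(timestamps) != dim(joints)[1])
    stop("length(timestamps) must equal the number of frames")
  x <- structure(
    list(participant_id = participant_id,
         exercise = exercise,
         label = label,
         frame_rate = as.numeric(frame_rate),
         timestamps = as.numeric(timestamps),
         joints = joints),
    class = "session")
  if (validate) x <- validate_session(x, ...) else x
}

#' Validate (and repair) a session
#'
#' Checks the session invariants: strictly increasing timestamps, at least
#' 3 frames, and finite coordinates for the eight joints the assessment
#' requires. Frames in which a required joint is missing (any `NA`
#' coordinate) are handled per `missing_joint_policy`:
#' `"interpolate"` (default) fills interior gaps of at most `max_gap`
#' frames by linear interpolation over time and drops frames it cannot
#' fill; `"reject-frame"` drops every frame with a missing required joint.
#' Validation is idempotent.
#'
#' @param x A `"session"`.
#' @param missing_joint_policy `"interpolate"` or `"reject-frame"`.
#' @param max_gap Longest interior gap (frames) that interpolation fills.
#' @return The validated `"session"` (possibly with fewer frames).
#' @export
validate_session <- function(x, missing_joint_policy = c("interpolate", "reject-frame"),
                             max_gap = 3L) {
  stopifnot(inherits(x, "session"))
  missing_joint_policy <- match.arg(missing_joint_policy)
  jn <- dimnames(x$joints)[[3]]
  missing <- setdiff(required_joints(), jn)
  if (length(missing))
    stop("session '", session_id(x), "' lacks required joints: ",
         paste(missing, collapse = ", "))
  ts <- x$timestamps
  if (any(!is.finite(ts)) || any(diff(ts) <= 0))
    stop("session '", session_id(x), "': timestamps must be finite and strictly increasing")

  jt <- x$joints
  L <- dim(jt)[1]
  bad <- matrix(FALSE, L, length(required_joints()))
  for (k in seq_along(required_joints())) {
    bad[, k] <- apply(is.na(jt[, , required_joints()[k], drop = FALSE]), 1, any)
  }
  if (any(bad)) {
    if (missing_joint_policy == "interpolate") {
      for (k in which(colSums(bad) > 0)) {
        j <- required_joints()[k]
        runs <- rle(bad[, k])
        ends <- cumsum(runs$lengths)
        starts <- ends - runs$lengths + 1L
        for (r in which(runs$values)) {
          interior <- starts[r] > 1L && ends[r] < L
          if (interior && runs$lengths[r] <= max_gap) {
            for (d in 1:3) {
              ok <- !bad[, k]
              jt[starts[r]:ends[r], d, j] <-
                approx(ts[ok], jt[ok, d, j], xout = ts[starts[r]:ends[r]])$y
            }
            bad[starts[r]:ends[r], k] <- FALSE
          }
        }
      }
    }
    keep <- rowSums(bad) == 0L
    jt <- jt[keep, , , drop = FALSE]
    ts <- ts[keep]
  }
  if (dim(jt)[1] < 3L)
    stop("session '", session_id(x), "' has fewer than 3 valid frames (",
         dim(jt)[1], ")")
  x$joints <- jt
  x$timestamps <- ts
  x
}

session_id <- function(x) {
  paste(x$participant_id, x$exercise, x$label, sep = "/")
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("<session> %s | %s | %s | %d frames @ %g Hz (%.2f s)\n",
              x$participant_id, x$exercise, x$label,
              length(x$timestamps), x$frame_rate,
              diff(range(x$timestamps))))
  invisible(x)
}

#' @export
length.session <- function(x) length(x$timestamps)
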