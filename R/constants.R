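#' Skeleton joints, exercises, and the canonical feature set
#'
#' `kinect_joints()` lists the 25 joints tracked by a Kinect-v2-class
#' sensor, using short codes for the eight joints the assessment uses
#' (`lS`, `rS`, `SS`, `rHI`, `SB`, `rE`, `rW`, `rH`) and descriptive names
#' for the rest. `required_joints()` is the subset every frame must carry.
#' `exercises()` names the three shoulder games. `feature_names()` is the
#' canonical ordering of the 38 per-frame features: 9 vector-plane angles,
#' 2 inter-segment angles, then positions, velocities and accelerations of
#' the right elbow, wrist and hand along the body axes.
#'
#' @return A character vector.
#' @examples
#' length(feature_names())
#' @export
kinect_joints <- function() {
  c("SB", "SM", "SS", "Neck", "Head",
    "lS", "lE", "lW", "lH",
    "rS", "rE", "rW", "rH",
    "lHI", "lK", "lA", "lF",
    "rHI", "rK", "rA", "rF",
    "lHT", "lTH", "rHT", "rTH")
}

#' @rdname kinect_joints
#' @export
required_joints <- function() {
  c("lS", "rS", "SS", "rHI", "SB", "rE", "rW", "rH")
}

#' @rdname kinect_joints
#' @export
exercises <- function() {
  c("flexion", "h_abd_add", "adduction")
}

#' @rdname kinect_joints
#' @export
feature_names <- function() {
  vecs <- c("SE", "EW", "WH")
  planes <- c("CP", "TP", "SP")
  plane_angles <- as.vector(t(outer(vecs, planes,
                                    function(v, p) paste0("theta_", v, "_", p))))
  joint_feats <- unlist(lapply(c("p", "v", "a"), function(q) {
    unlist(lapply(c("rE", "rW", "rH"), function(j) {
      paste0(q, "_", j, "_", c("x", "y", "z"))
    }))
  }))
  c(plane_angles, "theta_SE_EW", "theta_EW_WH", joint_feats)
}

# session labels
session_labels <- function() c("correct", "incorrect", "unlabeled")

`%||%` <- function(a, b) if (is.null(a)) b else a
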