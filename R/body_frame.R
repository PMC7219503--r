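#' Body-attached anatomical coordinate system
#'
#' Builds, for a single frame, the reference frame in which all features
#' are expressed: origin at the right shoulder (`rS`) and three mutually
#' orthogonal anatomical planes.
#'
#' * **Coronal plane (CP)** through `rS`, `lS`, `SB`; its unit normal,
#'   oriented anteriorly, is the `+z` axis. Anteriority is resolved
#'   intrinsically from skeleton chirality: the anterior direction has a
#'   positive projection on `(SS - SB) x (rS - lS)`, which is invariant
#'   under any rigid motion of the sensor frame.
#' * **Transverse plane (TP)** through `rS`, `lS` and the virtual joint
#'   `SS^ = SS + 0.2 z` (the spine-shoulder joint shifted 0.2 m along the
#'   coronal normal so the three points are non-collinear). Its normal,
#'   oriented superiorly (toward `SS - SB`), is the `+y` axis; any small
#'   out-of-coronal-plane component of `SS` is removed by orthogonalizing
#'   against `z`, so the basis is exactly orthonormal.
#' * **Sagittal plane (SP)** through `rS`, the virtual joint
#'   `rS^ = rS + 0.2 z`, and `rS^^` = `rS` shifted along `-y` to the
#'   height (body-frame `y` coordinate) of the right hip `rHI`. Its
#'   normal is the `+x` axis (`x = y cross z`, pointing to the subject's
#'   left).
#'
#' The basis is recomputed independently at every frame; no temporal
#' smoothing is applied.
#'
#' @param joints Either a named list of 3-vectors or a `J x 3` matrix with
#'   joint names as rownames; must contain `rS`, `lS`, `SB`, `SS`, `rHI`.
#' @return An object of class `"body_basis"`: list with `origin` (the
#'   `rS` position), `rotation` (3x3 orthonormal matrix whose rows are the
#'   `x`, `y`, `z` unit axes in sensor coordinates), the plane normals
#'   `n_CP`, `n_TP`, `n_SP`, and the virtual joints `SS_hat`, `rS_hat`,
#'   `rS_hathat`.
#' @seealso [to_body_frame()]
#' @examples
#' sk <- rbind(rS = c(0.175, 0.42, 2), lS = c(-0.175, 0.42, 2),
#'             SS = c(0, 0.42, 2), SB = c(0, 0, 2), rHI = c(0.09, 0, 2))
#' b <- compute_body_basis(sk)
#' b$rotation %*% t(b$rotation)  # identity
#' @export
compute_body_basis <- function(joints) {
  g <- joint_getter(joints)
  rS <- g("rS"); lS <- g("lS"); SB <- g("SB"); SS <- g("SS"); rHI <- g("rHI")

  a <- lS - rS
  b <- SB - rS
  n <- cross3(a, b)
  if (sqrt(sum(n^2)) < 1e-8)
    stop("degenerate geometry: rS, lS, SB are collinear (coronal plane undefined)")
  z <- n / sqrt(sum(n^2))
  anterior_ref <- cross3(SS - SB, rS - lS)
  if (sum(z * anterior_ref) < 0) z <- -z

  SS_hat <- SS + 0.2 * z
  nTP <- cross3(lS - rS, SS_hat - rS)
  if (sqrt(sum(nTP^2)) < 1e-8)
    stop("degenerate geometry: rS, lS, SS^ are collinear (transverse plane undefined)")
  y <- nTP / sqrt(sum(nTP^2))
  if (sum(y * (SS - SB)) < 0) y <- -y
  y <- y - sum(y * z) * z          # exact orthogonality to the coronal normal
  ny <- sqrt(sum(y^2))
  if (ny < 1e-8)
    stop("degenerate geometry: transverse normal parallel to coronal normal")
  y <- y / ny
  x <- cross3(y, z)

  rS_hat <- rS + 0.2 * z
  dy <- sum((rHI - rS) * y)        # body-frame y of the right hip
  if (abs(dy) < 1e-8)
    stop("degenerate geometry: rHI at shoulder height (sagittal plane undefined)")
  rS_hathat <- rS + dy * y
  nSP <- cross3(rS_hat - rS, rS_hathat - rS)
  nSP <- nSP / sqrt(sum(nSP^2))
  if (sum(nSP * x) < 0) nSP <- -nSP

  structure(list(origin = rS,
                 rotation = rbind(x = x, y = y, z = z),
                 n_CP = z, n_TP = y, n_SP = nSP,
                 SS_hat = SS_hat, rS_hat = rS_hat, rS_hathat = rS_hathat),
            class = "body_basis")
}

#' Transform sensor-frame points into the body-attached frame
#'
#' Applies `p_body = R (p_sensor - origin)`; the right shoulder maps to
#' the origin `(0, 0, 0)`.
#'
#' @param points A 3-vector or an `n x 3` matrix of sensor-frame
#'   positions.
#' @param basis A `"body_basis"` from [compute_body_basis()].
#' @return Coordinates in the body frame, same shape as `points`.
#' @export
to_body_frame <- function(points, basis) {
  stopifnot(inherits(basis, "body_basis"))
  if (is.null(dim(points))) {
    drop(basis$rotation %*% (points - basis$origin))
  } else {
    sweep(points, 2, basis$origin) %*% t(basis$rotation)
  }
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

joint_getter <- function(joints) {
  if (is.matrix(joints)) {
    function(j) {
      if (!j %in% rownames(joints)) stop("joint '", j, "' not present")
      as.numeric(joints[j, ])
    }
  } else {
    function(j) {
      if (is.null(joints[[j]])) stop("joint '", j, "' not present")
      as.numeric(joints[[j]])
    }
  }
}
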