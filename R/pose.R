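rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}

#' Rotation matrix from RELION ZYZ intrinsic Euler angles
#'
#' Angles (rot, tilt, psi) in degrees. The returned matrix maps model/world
#' coordinates to the particle frame: a pseudo-atom at `c` appears in the
#' image at the first two components of `R %*% c` (plus the in-plane shift).
#'
#' @param rot,tilt,psi Euler angles in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
euler_matrix <- function(rot, tilt, psi) {
  d <- pi / 180
  rot_z(psi * d) %*% rot_y(tilt * d) %*% rot_z(rot * d)
}

#' Project 3D points under a pose
#'
#' Applies the pose rotation and drops the z (beam) axis, then adds the
#' in-plane shift in Angstrom.
#'
#' @param centers N x 3 matrix of positions (Angstrom).
#' @param pose list with `rot`, `tilt`, `psi` (degrees) and `shift`
#'   (length-2, Angstrom), or a precomputed 3 x 3 matrix in `R`.
#' @return N x 2 matrix of image-plane coordinates (Angstrom).
#' @export
project_points <- function(centers, pose) {
  R <- if (!is.null(pose$R)) pose$R
       else euler_matrix(pose$rot, pose$tilt, pose$psi)
  shift <- if (!is.null(pose$shift)) pose$shift else c(0, 0)
  xy <- centers %*% t(R[1:2, , drop = FALSE])
  xy[, 1] <- xy[, 1] + shift[1]
  xy[, 2] <- xy[, 2] + shift[2]
  xy
}

# Precompute rotation matrices for all rows of a particle metadata table.
pose_matrices <- function(meta) {
  lapply(seq_len(nrow(meta)), function(i)
    euler_matrix(meta$rot[i], meta$tilt[i], meta$psi[i]))
}
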