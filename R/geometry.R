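# Experiment geometry for the continuous-rotation setup. Lab frame: the beam
# axis is +z and the incident wavevector k = (0, 0, -K) (anti-parallel to the
# beam axis); the goniometer axis is perpendicular to the beam (default x).
# A reciprocal-lattice vector at goniometer angle alpha is
#   g_lab = C R(alpha) R0 B h
# with B the reciprocal basis, R0 the crystal mounting orientation, R(alpha)
# the goniometer rotation and C an optional small correction rotation about
# the lab x/y axes (frame misorientation / virtual-frame correction).

#' Rotation matrix about an arbitrary axis
#'
#' @param axis length-3 axis (normalized internally).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  ct * diag(3) + st * ux + (1 - ct) * tcrossprod(u)
}

#' Experiment geometry
#'
#' @param beam a [relativistic_beam()].
#' @param axis goniometer rotation axis in the lab frame (must be
#'   perpendicular to the beam axis z).
#' @param R0 initial crystal orientation matrix (crystal Cartesian to lab).
#' @return `ded_geometry` list.
#' @export
experiment_geometry <- function(beam, axis = c(1, 0, 0), R0 = diag(3)) {
  axis <- axis / sqrt(sum(axis^2))
  if (abs(axis[3]) > 1e-8) stop("rotation axis must be perpendicular to the beam (z) axis")
  if (max(abs(crossprod(R0) - diag(3))) > 1e-10 || abs(det(R0) - 1) > 1e-10)
    stop("R0 must be a proper rotation matrix")
  structure(list(beam = beam, axis = axis, R0 = R0), class = "ded_geometry")
}

# goniometer rotation at angle alpha (degrees), including mounting
.orientation_matrix <- function(geom, alpha, corr = NULL) {
  R <- rotation_about(geom$axis, alpha) %*% geom$R0
  if (!is.null(corr)) R <- corr %*% R
  R
}

# correction rotation from two small angles about lab x and y (degrees)
.correction_matrix <- function(delta) {
  if (is.null(delta) || all(delta == 0)) return(NULL)
  rotation_about(c(1, 0, 0), delta[1]) %*% rotation_about(c(0, 1, 0), delta[2])
}

#' Excitation error
#'
#' Signed distance of reciprocal-lattice points from the Ewald sphere:
#' \eqn{S_g = (K^2 - |k+g|^2) / (2K)} with incident wavevector
#' \eqn{k = (0,0,-K)}. Positive when the point lies inside the sphere.
#'
#' @param g_lab 3 x n matrix of reciprocal vectors in the lab frame
#'   (1/Angstrom), or a single length-3 vector.
#' @param K incident wavevector magnitude (1/Angstrom), positive.
#' @return excitation errors in 1/Angstrom.
#' @export
excitation_error <- function(g_lab, K) {
  if (K <= 0) stop("K must be positive")
  g <- if (is.matrix(g_lab)) g_lab else matrix(g_lab, nrow = 3)
  # |k+g|^2 = |g|^2 - 2 K g_z + K^2  =>  S = g_z - |g|^2/(2K)
  drop(g[3, ] - colSums(g^2) / (2 * K))
}

# excitation errors of a fixed set of crystal-frame vectors G0 (3 x n) at a
# set of angles, with optional correction rotation; returns n x length(alpha)
.excitation_grid <- function(geom, G0, alphas, corr = NULL) {
  K <- geom$beam$K
  g2 <- colSums(G0^2)
  vapply(alphas, function(a) {
    gl <- .orientation_matrix(geom, a, corr) %*% G0
    gl[3, ] - g2 / (2 * K)
  }, numeric(ncol(G0)))
}
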