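#' Unit cell
#'
#' Construct a triclinic unit cell from lengths (\eqn{\AA}) and angles
#' (degrees). Derived quantities -- cell volume, direct and reciprocal metric
#' tensors, and the reciprocal orthogonalization matrix -- are computed once
#' and stored.
#'
#' The orthogonalization convention places \eqn{a} along the Cartesian x axis
#' and \eqn{b} in the xy plane. The reciprocal basis matrix `B` has the
#' reciprocal basis vectors (\eqn{\AA^{-1}}, no \eqn{2\pi} factor) as columns,
#' so that a reciprocal-lattice vector is `g = B %*% hkl`.
#'
#' @param a,b,c cell lengths in Angstrom, all positive.
#' @param alpha,beta,gamma cell angles in degrees, each in (0, 180).
#' @return An object of class `ded_cell` with elements `a,b,c,alpha,beta,
#'   gamma`, `volume`, `A` (direct basis, columns), `B` (reciprocal basis,
#'   columns), `G` (direct metric tensor), `Gstar` (reciprocal metric tensor).
#' @examples
#' cl <- unit_cell(6, 8, 10)
#' d_spacing(cl, c(1, 2, 3))
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  if (any(c(a, b, c) <= 0)) stop("cell lengths must be positive")
  if (any(c(alpha, beta, gamma) <= 0) || any(c(alpha, beta, gamma) >= 180)) {
    stop("cell angles must lie in (0, 180) degrees")
  }
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180); cg <- cos(gamma * pi / 180)
  sg <- sin(gamma * pi / 180)
  # closed-form triclinic volume
  vol <- a * b * c * sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  if (!is.finite(vol) || vol <= 0) stop("cell angles do not define a valid cell")
  # direct basis as columns: a || x, b in xy plane
  A <- matrix(c(
    a, 0, 0,
    b * cg, b * sg, 0,
    c * cb, c * (ca - cb * cg) / sg, vol / (a * b * sg)
  ), nrow = 3)
  B <- t(solve(A))           # reciprocal basis, columns; A^T B = I
  G <- crossprod(A)          # direct metric
  Gstar <- crossprod(B)      # reciprocal metric
  structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta,
                 gamma = gamma, volume = vol, A = A, B = B,
                 G = G, Gstar = Gstar),
            class = "ded_cell")
}

#' Resolution of a reflection
#'
#' d-spacing in Angstrom of Miller indices `hkl`, via the reciprocal metric
#' tensor: \eqn{1/d^2 = h^T G^* h}.
#'
#' @param cell a [unit_cell()].
#' @param hkl integer triple or matrix with reflections in rows.
#' @return d in Angstrom (vector if `hkl` is a matrix).
#' @export
d_spacing <- function(cell, hkl) {
  h <- if (is.matrix(hkl)) hkl else matrix(hkl, nrow = 1)
  q2 <- rowSums((h %*% cell$Gstar) * h)
  1 / sqrt(q2)
}

#' Reciprocal-lattice vectors in the crystal Cartesian frame
#'
#' @param cell a [unit_cell()].
#' @param hkl matrix of reflections in rows (or a single triple).
#' @return 3 x n matrix of Cartesian reciprocal vectors in 1/Angstrom.
#' @export
recip_cart <- function(cell, hkl) {
  h <- if (is.matrix(hkl)) hkl else matrix(hkl, nrow = 1)
  cell$B %*% t(h)
}

#' @export
print.ded_cell <- function(x, ...) {
  cat(sprintf("unit cell  a=%.4f b=%.4f c=%.4f  alpha=%.3f beta=%.3f gamma=%.3f  V=%.3f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}
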