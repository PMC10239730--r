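# Bloch-wave dynamical diffraction engine: beam selection, structure-matrix
# assembly and eigen-propagation. The structure matrix A has diagonal
# 2*K*S_g and off-diagonal potential coefficients U_{g-h} (A^-2) with
#   U_g = gamma_rel * F_g / (pi * V_c),
# F_g the kinematical structure factor (with Debye-Waller) in Angstrom.
# No absorption is modelled: A is Hermitian and total intensity is conserved.

.potential_coefficients <- function(st, beam, hkl) {
  Fg <- structure_factor(st, hkl)
  beam$gamma_rel * Fg / (pi * st$cell$volume)
}

# fast path used by the pipeline: precomputed expanded sites + coefficients
.sf_context <- function(st) {
  ex <- expand_sites(st)
  tab <- scattering_table()
  elems <- unique(ex$element)
  cf <- .sf_coeffs(elems, tab)
  list(frac = ex$frac, occ = ex$occ, uiso = ex$uiso,
       elem = match(ex$element, elems), acoef = cf$a, bcoef = cf$b)
}

.potential_fast <- function(ctx, cell, beam, hkl, svals) {
  Fg <- cpp_structure_factors(hkl, svals, ctx$frac, ctx$occ, ctx$uiso,
                              ctx$elem, ctx$acoef, ctx$bcoef)
  beam$gamma_rel * Fg / (pi * cell$volume)
}

#' Select beams for a Bloch-wave calculation
#'
#' Includes the transmitted beam 000 plus every reciprocal-lattice vector
#' with \eqn{|g| \le g_{max}} and \eqn{|S_g| \le S_{max}} at the given
#' orientation, ordered deterministically by |S| then lexicographically.
#' Potential coefficients for all beam differences are assembled into the
#' Hermitian off-diagonal part of the structure matrix.
#'
#' @param st a [crystal_structure()].
#' @param geom a [experiment_geometry()].
#' @param alpha goniometer angle (degrees) of the orientation.
#' @param g_max resolution cutoff in 1/Angstrom.
#' @param s_max excitation-error cutoff in 1/Angstrom.
#' @param force_hkl optional reflections (matrix rows) always included.
#' @param max_beams beam-count cap; exceeding it is an error suggesting
#'   tighter cutoffs.
#' @return `ded_beamset` with `hkl` (N x 3, 000 first), `S`, `Ug` (per-beam
#'   column of the potential), `Aoff` (N x N off-diagonal structure matrix),
#'   `K`.
#' @export
select_beams <- function(st, geom, alpha, g_max, s_max,
                         force_hkl = NULL, max_beams = 150) {
  if (g_max <= 0 || s_max <= 0) stop("g_max and s_max must be positive")
  cell <- st$cell
  hmax <- ceiling(g_max * c(cell$a, cell$b, cell$c)) + 1
  grid <- as.matrix(expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                                l = -hmax[3]:hmax[3]))
  colnames(grid) <- NULL
  grid <- grid[rowSums(abs(grid)) > 0, , drop = FALSE]
  gnorm2 <- rowSums((grid %*% cell$Gstar) * grid)
  grid <- grid[gnorm2 <= g_max^2, , drop = FALSE]
  G0 <- .orientation_matrix(geom, alpha) %*% recip_cart(cell, grid)
  S <- excitation_error(G0, geom$beam$K)
  sel <- abs(S) <= s_max
  if (!is.null(force_hkl)) {
    fh <- if (is.matrix(force_hkl)) force_hkl else matrix(force_hkl, nrow = 1)
    key <- paste(grid[, 1], grid[, 2], grid[, 3])
    sel[match(paste(fh[, 1], fh[, 2], fh[, 3]), key)] <- TRUE
  }
  hkl <- grid[sel, , drop = FALSE]
  S <- S[sel]
  o <- order(abs(S), hkl[, 1], hkl[, 2], hkl[, 3])
  hkl <- rbind(c(0L, 0L, 0L), hkl[o, , drop = FALSE])
  S <- c(0, S[o])
  if (nrow(hkl) > max_beams) {
    stop(sprintf("beam count %d exceeds cap %d; tighten g_max/s_max",
                 nrow(hkl), max_beams))
  }
  .finalize_beamset(st, geom$beam, hkl, S)
}

.finalize_beamset <- function(st, beam, hkl, S) {
  n <- nrow(hkl)
  # all pairwise differences g_i - g_j
  di <- hkl[rep(1:n, each = n), ] - hkl[rep(1:n, n), ]
  di <- matrix(di, ncol = 3)
  key <- paste(di[, 1], di[, 2], di[, 3])
  uk <- !duplicated(key)
  diffs <- di[uk, , drop = FALSE]
  idx <- matrix(match(key, key[uk]), n, n, byrow = TRUE)  # idx[i,j] -> g_i - g_j
  sv <- 1 / (2 * d_spacing(st$cell, diffs))
  sv[!is.finite(sv)] <- 0
  U <- .potential_coefficients(st, beam, diffs)
  Aoff <- matrix(U[idx], n, n)
  diag(Aoff) <- 0
  Aoff <- (Aoff + Conj(t(Aoff))) / 2
  structure(list(hkl = hkl, S = S, Ug = Aoff[, 1], Aoff = Aoff, K = beam$K),
            class = "ded_beamset")
}

#' Manually constructed beam set
#'
#' Builds a `ded_beamset` directly from excitation errors and potential
#' coefficients (first beam must be 000), e.g. for the closed-form two-beam
#' checks.
#'
#' @param hkl N x 3 integer matrix, first row 000.
#' @param S excitation errors (1/Angstrom), first entry 0.
#' @param Ug complex potential coefficients U_{g-0} per beam (first entry
#'   ignored); all other differences are set to zero.
#' @param K wavevector magnitude (1/Angstrom).
#' @export
beam_set_manual <- function(hkl, S, Ug, K) {
  n <- nrow(hkl)
  Aoff <- matrix(0 + 0i, n, n)
  Aoff[, 1] <- Ug
  Aoff[1, ] <- Conj(Ug)
  diag(Aoff) <- 0
  structure(list(hkl = hkl, S = S, Ug = Aoff[, 1], Aoff = Aoff, K = K),
            class = "ded_beamset")
}

#' @export
print.ded_beamset <- function(x, ...) {
  cat(sprintf("beam set: %d beams, |S| <= %.4g 1/A, K = %.2f 1/A\n",
              nrow(x$hkl), max(abs(x$S)), x$K))
  invisible(x)
}

#' Bloch-wave propagation through a parallel-sided crystal
#'
#' Eigendecomposes the Hermitian structure matrix and propagates the
#' boundary condition (all intensity in the transmitted beam at t = 0) to
#' thickness `t`, returning the diffracted intensity of every beam as a
#' fraction of the incident intensity.
#'
#' @param beamset a [select_beams()] / [beam_set_manual()] result.
#' @param t crystal thickness in Angstrom (scalar or vector), >= 0.
#' @return intensity matrix (beams x thicknesses); a plain vector for a
#'   single thickness, named by beam index.
#' @export
propagate <- function(beamset, t) {
  if (any(t < 0)) stop("thickness must be >= 0")
  out <- cpp_propagate(beamset$Aoff, beamset$S, as.numeric(t), beamset$K)
  rownames(out) <- apply(beamset$hkl, 1, paste, collapse = " ")
  if (length(t) == 1) drop(out) else out
}

#' Rocking curve of one reflection
#'
#' Dynamical intensity of `hkl` across a grid of goniometer angles (e.g. the
#' angular range of one virtual frame). The beam set is selected once, at
#' the grid angle where the reflection is closest to the Bragg condition,
#' and held fixed across the grid; only the excitation errors vary. If the
#' reflection falls outside the selection cutoffs it is force-included.
#'
#' @param st a [crystal_structure()].
#' @param geom a [experiment_geometry()].
#' @param hkl reflection (integer triple).
#' @param alphas ordered grid of goniometer angles (degrees), length >= 2.
#' @param t thickness (Angstrom).
#' @param g_max,s_max,max_beams beam-selection cutoffs, see [select_beams()].
#' @return `ded_rocking` with `alphas`, `intensity`, `hkl`.
#' @export
rocking_curve <- function(st, geom, hkl, alphas, t,
                          g_max = 1.2, s_max = 0.02, max_beams = 150) {
  if (length(alphas) < 1 || is.unsorted(alphas)) {
    stop("alphas must be a non-empty increasing grid")
  }
  G0 <- recip_cart(st$cell, hkl)
  Sg <- vapply(alphas, function(a)
    excitation_error(.orientation_matrix(geom, a) %*% G0, geom$beam$K), 0)
  a_star <- alphas[which.min(abs(Sg))]
  bs <- select_beams(st, geom, a_star, g_max, s_max,
                     force_hkl = hkl, max_beams = max_beams)
  target <- match(paste(hkl, collapse = " "),
                  apply(bs$hkl, 1, paste, collapse = " "))
  Gb <- recip_cart(st$cell, bs$hkl)
  smat <- matrix(.excitation_grid(geom, Gb, alphas), nrow = ncol(Gb))
  n <- nrow(bs$hkl)
  idx <- matrix(seq_len(n * n), n, n)  # direct per-pair indexing
  U <- as.vector(bs$Aoff)              # column-major: U[idx[i,j]] = Aoff[i,j]
  curves <- cpp_bloch_curves(list(list(idx = idx, smat = smat,
                                       target = target)),
                             U, t, bs$K)[[1]]
  structure(list(alphas = alphas, intensity = drop(curves), hkl = hkl,
                 beamset = bs), class = "ded_rocking")
}
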