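# Overlapping virtual frames (OVFs): the data-reduction unit of the method.
# A continuous-rotation experiment yields frames of width dalpha; N_F
# consecutive frames are combined into one virtual frame of angular range
# dalpha_v = N_F * dalpha, consecutive virtual frames sharing N_O frames.
# Experimental intensities are summed over the contributing frames; model
# intensities are obtained by numerical integration of the calculated
# rocking curve over the same angular range, so both sides of the
# least-squares are integrated consistently.

#' Experimental frame table
#'
#' @param alphas frame-center goniometer angles (degrees), uniformly spaced.
#' @param dalpha frame angular width (degrees).
#' @return `ded_frames` data.frame with columns `frame`, `alpha`.
#' @export
experimental_frames <- function(alphas, dalpha) {
  if (dalpha <= 0) stop("dalpha must be positive")
  if (length(alphas) >= 2) {
    steps <- diff(alphas)
    if (any(steps <= 0) || max(abs(steps - steps[1])) > 1e-6)
      stop("frame centers must be increasing and uniformly spaced")
  }
  out <- data.frame(frame = seq_along(alphas), alpha = alphas)
  attr(out, "dalpha") <- dalpha
  class(out) <- c("ded_frames", "data.frame")
  out
}

#' Build overlapping virtual frames
#'
#' Groups `N_F` consecutive frames into virtual frames advancing by
#' `N_F - N_O` frames, so consecutive OVFs share exactly `N_O` frames. A
#' right-aligned trailing OVF is appended when the regular sequence leaves
#' frames uncovered, so every experimental frame contributes to at least one
#' OVF.
#'
#' @param frames a [experimental_frames()] table.
#' @param N_F frames per OVF, between 2 and 50.
#' @param N_O overlap with the next OVF, `1 <= N_O < N_F`.
#' @return `ded_ovfs`: data.frame with `vf`, `alpha_v` (mean contributing
#'   center), `dalpha_v` = `N_F * dalpha`; attribute `members` is a list of
#'   contributing frame ids.
#' @export
build_virtual_frames <- function(frames, N_F, N_O = round(N_F / 2)) {
  if (N_F < 2 || N_F > 50) stop("N_F must be between 2 and 50")
  if (N_O < 1 || N_O >= N_F) stop("overlap N_O must satisfy 1 <= N_O < N_F")
  dalpha <- attr(frames, "dalpha")
  n <- nrow(frames)
  if (n < N_F) {
    warning("fewer than N_F frames; emitting a single virtual frame")
    starts <- 1L
    N_F <- n
  } else {
    step <- N_F - N_O
    starts <- seq(1L, n - N_F + 1L, by = step)
    if (max(starts) + N_F - 1L < n) starts <- c(starts, n - N_F + 1L)
  }
  members <- lapply(starts, function(s) frames$frame[s:(s + N_F - 1L)])
  out <- data.frame(
    vf = seq_along(starts),
    alpha_v = vapply(members, function(m) mean(frames$alpha[match(m, frames$frame)]), 0),
    dalpha_v = N_F * dalpha
  )
  attr(out, "members") <- members
  attr(out, "dalpha") <- dalpha
  attr(out, "N_F") <- N_F
  attr(out, "N_O") <- N_O
  class(out) <- c("ded_ovfs", "data.frame")
  out
}

#' Assign reflection records to virtual frames
#'
#' For each OVF and each reflection recorded on at least one contributing
#' frame, sums the per-frame intensities (quadrature sum for the
#' uncertainties). No scale factors and no Lorentz correction are applied on
#' this (dynamical) path. The same reflection appearing on several OVFs
#' yields independent observations; they are never merged before refinement.
#'
#' @param records data.frame with columns `h,k,l,I,sigma,frame`.
#' @param ovfs a [build_virtual_frames()] result.
#' @return data.frame with `h,k,l,vf,I_obs,sigma,nframes`.
#' @export
assign_observations <- function(records, ovfs) {
  bad <- records$sigma <= 0
  if (any(bad)) {
    message(sum(bad), " record(s) with non-positive sigma rejected")
    records <- records[!bad, , drop = FALSE]
  }
  members <- attr(ovfs, "members")
  out <- vector("list", nrow(ovfs))
  for (i in seq_len(nrow(ovfs))) {
    rr <- records[records$frame %in% members[[i]], , drop = FALSE]
    if (!nrow(rr)) {
      warning("virtual frame ", ovfs$vf[i], " has no observations; dropped")
      next
    }
    key <- paste(rr$h, rr$k, rr$l)
    agg <- lapply(split(seq_len(nrow(rr)), key), function(ix) {
      data.frame(h = rr$h[ix[1]], k = rr$k[ix[1]], l = rr$l[ix[1]],
                 vf = ovfs$vf[i],
                 I_obs = sum(rr$I[ix]),
                 sigma = sqrt(sum(rr$sigma[ix]^2)),
                 nframes = length(ix))
    })
    out[[i]] <- do.call(rbind, agg)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Geometric filtering of partial intensities
#'
#' Reflections in diffracting condition close to one of the two limiting
#' Ewald spheres of an OVF (the sphere positions at the extreme orientations
#' `alpha_v +- dalpha_v/2`) have truncated rocking curves and must be
#' excluded. For every observation this computes the excitation error `S_v`
#' at the average orientation, the distance `D_Sg` to the nearer limiting
#' sphere (measured along the sphere normal, i.e. the excitation error
#' magnitude at the extreme orientations) and the ratio
#' \eqn{R_{Sg} = |S_g| / (D_{Sg} + |S_g|)}; an observation is included iff
#' `D_Sg >= D_min` and `R_Sg <= R_max`.
#'
#' @param obs observation table from [assign_observations()].
#' @param cell a [unit_cell()].
#' @param geom a [experiment_geometry()].
#' @param ovfs the OVF table.
#' @param D_min minimum limiting-sphere distance (1/Angstrom), default
#'   0.002 (typical useful values 0.0015--0.0030).
#' @param R_max maximum ratio, default 0.65 (typical useful values 0.5--0.8).
#' @return `obs` with added columns `S_v, D_Sg, R_Sg, included`.
#' @export
geometry_filter <- function(obs, cell, geom, ovfs, D_min = 0.002, R_max = 0.65) {
  if (D_min <= 0) stop("D_min must be positive")
  if (R_max <= 0 || R_max >= 1) stop("R_max must lie in (0,1)")
  obs$S_v <- NA_real_; obs$D_Sg <- NA_real_; obs$R_Sg <- NA_real_
  for (i in seq_len(nrow(ovfs))) {
    sel <- which(obs$vf == ovfs$vf[i])
    if (!length(sel)) next
    hkl <- as.matrix(obs[sel, c("h", "k", "l")])
    G0 <- recip_cart(cell, hkl)
    av <- ovfs$alpha_v[i]; hw <- ovfs$dalpha_v[i] / 2
    S3 <- matrix(.excitation_grid(geom, G0, c(av - hw, av, av + hw)),
                 nrow = ncol(G0))
    obs$S_v[sel] <- S3[, 2]
    obs$D_Sg[sel] <- pmin(abs(S3[, 1]), abs(S3[, 3]))
    obs$R_Sg[sel] <- abs(S3[, 2]) / (obs$D_Sg[sel] + abs(S3[, 2]))
  }
  obs$included <- obs$D_Sg >= D_min & obs$R_Sg <= R_max
  obs
}

#' Integrate a calculated rocking curve
#'
#' Trapezoidal integral of the per-orientation intensity over the angular
#' range, with the angle expressed in radians -- the same convention in
#' which the experimental intensities are summed, so observed and calculated
#' integrated intensities differ only by the per-OVF scale.
#'
#' @param curve a [rocking_curve()] result, or a list with `alphas`
#'   (degrees) and `intensity`.
#' @return integrated intensity (dimensionless angle-integral).
#' @export
integrate_calculated <- function(curve) {
  a <- curve$alphas * pi / 180
  y <- curve$intensity
  if (length(a) < 3) stop("need at least 3 grid points")
  sum(diff(a) * (y[-1] + y[-length(y)]) / 2)
}

#' Rotation-method Lorentz correction
#'
#' The Lorentz factor of the rotation method is the reciprocal of the speed
#' at which a reciprocal-lattice point traverses the Ewald sphere,
#' \eqn{L = 1/|dS_g/d\alpha|} (alpha in radians). Intensities on the
#' kinematical (merged) path are divided by it. Reflections moving
#' essentially parallel to the sphere (speed below `min_speed`) cannot be
#' corrected and are flagged for exclusion.
#'
#' @param obs observation table with `h,k,l,vf` columns.
#' @param cell,geom,ovfs geometry objects as in [geometry_filter()].
#' @param min_speed smallest usable traversal speed (1/Angstrom/radian).
#' @return `obs` with added `lorentz` (the factor L), `I_corr`, `sigma_corr`
#'   and logical `lorentz_ok`.
#' @export
lorentz_correction <- function(obs, cell, geom, ovfs, min_speed = 1e-4) {
  obs$lorentz <- NA_real_
  for (i in seq_len(nrow(ovfs))) {
    sel <- which(obs$vf == ovfs$vf[i])
    if (!length(sel)) next
    hkl <- as.matrix(obs[sel, c("h", "k", "l")])
    G0 <- recip_cart(cell, hkl)
    glab <- .orientation_matrix(geom, ovfs$alpha_v[i]) %*% G0
    # dS/dalpha = (axis x g)_z per radian of rotation
    ax <- geom$axis
    dg <- rbind(ax[2] * glab[3, ] - ax[3] * glab[2, ],
                ax[3] * glab[1, ] - ax[1] * glab[3, ],
                ax[1] * glab[2, ] - ax[2] * glab[1, ])
    speed <- abs(dg[3, ] - colSums(glab * dg) / geom$beam$K)
    obs$lorentz[sel] <- 1 / speed
  }
  obs$lorentz_ok <- is.finite(obs$lorentz) & obs$lorentz < 1 / min_speed
  obs$I_corr <- obs$I_obs / obs$lorentz
  obs$sigma_corr <- obs$sigma / obs$lorentz
  obs
}
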