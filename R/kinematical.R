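# Kinematical refinement paths. The classic path mirrors conventional
# processing: Lorentz-corrected intensities, per-frame scales optimized from
# the Laue symmetry, pre-refinement merging, then least squares on
# I = scale * E(x) * |F_h|^2. The frame-based path fits the kinematical
# model against exactly the same filtered virtual-frame observations as the
# dynamical refinement (per-OVF scales, Lorentz factor applied to the
# model), so dynamical and kinematical results can be compared on identical
# data.

#' Per-frame scales from Laue symmetry
#'
#' Iterative least-squares scaling: each OVF scale is fitted so that its
#' (Lorentz-corrected) intensities match the current Laue-group means.
#'
#' @param obs included observations with `I_corr` (Lorentz-corrected).
#' @param sg a [space_group()].
#' @param n_iter scaling sweeps.
#' @return numeric vector of scales indexed by OVF id.
#' @export
kinematical_frame_scales <- function(obs, sg, n_iter = 10) {
  reps <- t(vapply(seq_len(nrow(obs)), function(i)
    laue_representative(c(obs$h[i], obs$k[i], obs$l[i]), sg), integer(3)))
  key <- paste(reps[, 1], reps[, 2], reps[, 3])
  vfs <- sort(unique(obs$vf))
  s <- rep(1, length(vfs))
  names(s) <- vfs
  for (it in seq_len(n_iter)) {
    In <- obs$I_corr / s[as.character(obs$vf)]
    mu <- vapply(split(In, key), mean, 0)[key]
    for (j in seq_along(vfs)) {
      sel <- obs$vf == vfs[j]
      denom <- sum(mu[sel]^2)
      if (denom > 0) s[j] <- max(sum(obs$I_corr[sel] * mu[sel]) / denom, 1e-12)
    }
    s <- s / s[1]
  }
  s
}

#' Kinematical refinement
#'
#' @param rd a [reduce_experiment()] result.
#' @param st0 starting model.
#' @param frame_based if `TRUE`, refine against the filtered virtual-frame
#'   observations (identical data to the dynamical path) via
#'   [run_least_squares()]; otherwise use the classic merged path.
#' @param spec a [refine_spec()]; `thickness` is ignored (kinematical
#'   intensities carry no thickness).
#' @param options iteration controls as in [run_least_squares()].
#' @return a `ded_refinement` (frame-based) or `ded_kinrefinement`
#'   (classic) with R-factors, merged data and the refined model.
#' @export
kinematical_refinement <- function(rd, st0, frame_based = FALSE,
                                   spec = refine_spec(uiso = TRUE),
                                   options = list()) {
  if (frame_based) {
    spec$extinction <- TRUE
    return(run_least_squares(rd, st0, spec = spec, mode = "frame_kinematical",
                             options = options))
  }
  obs <- rd$obs[rd$obs$included, , drop = FALSE]
  obs <- lorentz_correction(obs, rd$cell, rd$geom, rd$ovfs)
  obs <- obs[obs$lorentz_ok, , drop = FALSE]
  scales <- kinematical_frame_scales(obs, st0$sg)
  sv <- scales[as.character(obs$vf)]
  In <- obs$I_corr / sv
  sn <- obs$sigma_corr / sv
  reps <- t(vapply(seq_len(nrow(obs)), function(i)
    laue_representative(c(obs$h[i], obs$k[i], obs$l[i]), st0$sg), integer(3)))
  key <- paste(reps[, 1], reps[, 2], reps[, 3])
  groups <- split(seq_len(nrow(obs)), key)
  merged <- do.call(rbind, lapply(groups, function(ix) {
    n <- length(ix)
    Ibar <- mean(In[ix])
    sig <- if (n >= 2) sqrt(sum((In[ix] - Ibar)^2) / (n * (n - 1))) else 0
    if (sig <= 0) sig <- sqrt(sum(sn[ix]^2)) / n
    data.frame(h = reps[ix[1], 1], k = reps[ix[1], 2], l = reps[ix[1], 3],
               n = n, I_obs = Ibar, sigma = sig)
  }))
  rownames(merged) <- NULL
  .classic_kin_refine(merged, st0, spec, options)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gauss-Newton on merged kinematical data: I = s * E(x) * |F|^2
.classic_kin_refine <- function(merged, st0, spec, options = list()) {
  opt <- modifyList(list(max_iter = 50, conv = 0.01, max_halvings = 10), options)
  hkl <- as.matrix(merged[, c("h", "k", "l")])
  w <- 1 / pmax(merged$sigma, 0.01 * stats::median(merged$sigma))^2
  dirs <- .riding_dirs(st0)
  st <- .apply_riding(st0, dirs, 0)
  ptab <- .param_table(st, modifyList(spec, list(thickness = FALSE, scales = FALSE)),
                       integer(0))
  refine_ext <- isTRUE(spec$extinction)
  F2_of <- function(st) Mod(structure_factor(st, hkl))^2
  F2 <- F2_of(st)
  scl <- sum(merged$I_obs * F2) / sum(F2^2)
  ext <- 0
  Ic_of <- function(F2, scl, ext) scl * (1 + ext * F2)^(-0.5) * F2
  wR_of <- function(Ic) sqrt(sum(w * (merged$I_obs - Ic)^2) / sum(w * merged$I_obs^2))
  Ic <- Ic_of(F2, scl, ext)
  wR <- wR_of(Ic)
  theta <- c(.pack_params(list(st = st, t = 0, scales = numeric(), ext = 0, dl = 0), ptab),
             scale = scl, if (refine_ext) c(x.ext = ext))
  np <- length(ptab)
  converged <- FALSE
  esd <- rep(NA_real_, length(theta))
  for (iter in seq_len(opt$max_iter)) {
    J <- matrix(0, nrow(merged), length(theta))
    for (j in seq_len(np)) {
      p <- ptab[[j]]
      thp <- theta; thp[j] <- thp[j] + p$step
      thm <- theta; thm[j] <- thm[j] - p$step
      stp <- .apply_params(list(st = st, t = 0, scales = numeric(), ext = 0, dl = 0), thp[seq_len(np)], ptab, dirs)$st
      stm <- .apply_params(list(st = st, t = 0, scales = numeric(), ext = 0, dl = 0), thm[seq_len(np)], ptab, dirs)$st
      J[, j] <- scl * (1 + ext * F2)^(-0.5) * (F2_of(stp) - F2_of(stm)) / (2 * p$step)
    }
    J[!is.finite(J)] <- 0
    J[, np + 1] <- Ic / scl
    if (refine_ext) J[, np + 2] <- scl * (-0.5) * F2^2 * (1 + ext * F2)^(-1.5)
    sw <- sqrt(w)
    Jw <- J * sw; rw <- (merged$I_obs - Ic) * sw
    cn <- sqrt(colSums(Jw^2)); cn[cn == 0] <- 1
    sol <- .solve_lsq(Jw, rw, cn, names(theta))
    delta <- sol$delta
    gof2 <- sum(rw^2) / max(nrow(merged) - length(theta), 1)
    esd <- sol$esd_unit * sqrt(gof2)
    lam <- 1; accepted <- FALSE
    for (h in 0:opt$max_halvings) {
      thn <- theta + lam * delta
      stn <- .apply_params(list(st = st, t = 0, scales = numeric(), ext = 0, dl = 0), thn[seq_len(np)], ptab, dirs)$st
      scln <- max(thn[np + 1], 1e-12)
      extn <- if (refine_ext) max(thn[np + 2], 0) else 0
      F2n <- F2_of(stn)
      Icn <- Ic_of(F2n, scln, extn)
      wRn <- wR_of(Icn)
      if (is.finite(wRn) && wRn <= wR + 1e-14) { accepted <- TRUE; break }
      lam <- lam / 2
    }
    if (!accepted) break
    shift_esd <- max(abs(lam * delta / pmax(esd, 1e-300)))
    st <- stn; scl <- scln; ext <- extn; F2 <- F2n; Ic <- Icn; wR <- wRn
    theta <- thn; theta[np + 1] <- scl; if (refine_ext) theta[np + 2] <- ext
    if (shift_esd < opt$conv) { converged <- TRUE; break }
  }
  merged$I_calc <- Ic
  rf <- residuals_and_rfactors(merged$I_obs, merged$sigma, Ic, w)
  structure(list(structure = st, scale = scl, ext = ext, esd = esd,
                 rfactors = rf, merged = merged, converged = converged,
                 mode = "classic_kinematical"),
            class = "ded_kinrefinement")
}

#' @export
print.ded_kinrefinement <- function(x, ...) {
  cat(sprintf("classic kinematical refinement: wR_all=%.4f R_obs=%.4f (%d merged), %s\n",
              x$rfactors$wR_all, x$rfactors$R_obs, nrow(x$merged),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
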