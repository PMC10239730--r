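# Weighted least-squares refinement against virtual-frame intensities.
# Dynamical mode: I_calc(obs) = scale_vf * [Bloch rocking-curve integral].
# Frame-based kinematical mode: I_calc(obs) = scale_vf * E(x) * |F_h|^2 * L,
# with L the rotation-method Lorentz factor and E a one-parameter isotropic
# extinction attenuation E(x) = (1 + x |F|^2)^(-1/2).
# Minimization: damped Gauss-Newton on the weighted intensity residual,
# weights 1/sigma^2 (sigma floored at 0.01 * median sigma), derivatives by
# central finite differences for structural parameters (analytic for scales
# and extinction), esds from the inverse normal matrix scaled by the
# goodness of fit.

#' Refinement parameter specification
#'
#' @param coords atoms whose fractional coordinates refine: `TRUE` (all
#'   non-riding atoms), `FALSE`, or a character vector of labels.
#' @param uiso atoms whose isotropic displacement parameters refine (same
#'   convention).
#' @param global_uiso refine one common isotropic displacement parameter
#'   for all atoms instead of individual ones (the quick absolute-structure
#'   mode).
#' @param thickness refine the (single) crystal thickness.
#' @param scales refine one scale per virtual frame (frames with fewer than
#'   3 included observations keep a fixed scale).
#' @param extinction refine the kinematical extinction parameter.
#' @return `ded_refspec` list.
#' @export
refine_spec <- function(coords = TRUE, uiso = FALSE, global_uiso = FALSE,
                        thickness = TRUE, scales = TRUE, extinction = FALSE) {
  structure(list(coords = coords, uiso = uiso, global_uiso = global_uiso,
                 thickness = thickness, scales = scales,
                 extinction = extinction), class = "ded_refspec")
}

# Riding-hydrogen machinery. The bond topology (parent and its non-H
# neighbours) is fixed once; each application regenerates the hydrogen from
# the parent's current geometry by idealized placement -- along the
# negative resultant of the parent's bond vectors (tetrahedral/trigonal
# completion) -- at the target distance (+ dl), with U_iso = 1.2 x parent.
# A hydrogen therefore rides its parent exactly: the same heavy-atom
# geometry always reproduces the same hydrogen position.
.riding_dirs <- function(st) {
  labs <- vapply(st$atoms, `[[`, "", "label")
  bonds <- bond_list(st)
  dirs <- list()
  for (i in seq_along(st$atoms)) {
    at <- st$atoms[[i]]
    if (is.null(at$riding)) next
    ip <- match(at$riding$parent, labs)
    if (is.na(ip)) stop("riding parent ", at$riding$parent, " not found")
    nb <- c(bonds$b[bonds$a == labs[ip]], bonds$a[bonds$b == labs[ip]])
    nbi <- match(setdiff(nb, labs[i]), labs)
    # fallback direction from the input geometry, for parents without
    # resolvable neighbours or degenerate (symmetric) environments
    d0 <- at$xyz - st$atoms[[ip]]$xyz
    d0 <- d0 - round(d0)
    u0 <- st$cell$A %*% d0
    dirs[[labs[i]]] <- list(parent = ip, nbrs = nbi,
                            u0 = u0 / sqrt(sum(u0^2)), dist = at$riding$dist)
  }
  dirs
}

.apply_riding <- function(st, dirs, dl = 0) {
  if (!length(dirs)) return(st)
  A <- st$cell$A
  Ainv <- solve(A)
  labs <- vapply(st$atoms, `[[`, "", "label")
  for (lb in names(dirs)) {
    dr <- dirs[[lb]]
    i <- match(lb, labs)
    p <- st$atoms[[dr$parent]]
    u <- NULL
    if (length(dr$nbrs)) {
      acc <- c(0, 0, 0)
      for (j in dr$nbrs) {
        d <- st$atoms[[j]]$xyz - p$xyz
        d <- d - round(d)
        dc <- drop(A %*% d)
        acc <- acc + dc / sqrt(sum(dc^2))
      }
      if (sqrt(sum(acc^2)) > 0.2) u <- -acc / sqrt(sum(acc^2))
    }
    if (is.null(u)) u <- drop(dr$u0)
    xyz <- p$xyz + drop(Ainv %*% (u * (dr$dist + dl)))
    st$atoms[[i]]$xyz <- xyz %% 1
    st$atoms[[i]]$uiso <- 1.2 * p$uiso
  }
  st
}

# parameter table for a spec; each row maps one scalar to the model
.param_table <- function(st, spec, scales_refinable) {
  labs <- vapply(st$atoms, `[[`, "", "label")
  riding <- vapply(st$atoms, function(a) !is.null(a$riding), TRUE)
  pick <- function(sel) {
    if (isTRUE(sel)) labs[!riding]
    else if (identical(sel, FALSE)) character(0)
    else sel
  }
  rows <- list()
  for (lb in pick(spec$coords)) {
    for (cmp in 1:3) rows[[length(rows) + 1]] <-
        list(kind = "coord", atom = match(lb, labs), comp = cmp,
             name = paste0(c("x", "y", "z")[cmp], ".", lb), step = 1e-4)
  }
  if (spec$global_uiso) {
    rows[[length(rows) + 1]] <- list(kind = "uglobal", atom = NA, comp = NA,
                                     name = "Uiso.global", step = 1e-4)
  } else {
    for (lb in pick(spec$uiso)) rows[[length(rows) + 1]] <-
        list(kind = "uiso", atom = match(lb, labs), comp = NA,
             name = paste0("U.", lb), step = 1e-4)
  }
  if (spec$thickness) rows[[length(rows) + 1]] <-
      list(kind = "thickness", atom = NA, comp = NA, name = "t", step = 1)
  if (spec$extinction) rows[[length(rows) + 1]] <-
      list(kind = "extinction", atom = NA, comp = NA, name = "x.ext", step = 1e-3)
  if (spec$scales) {
    for (v in scales_refinable) rows[[length(rows) + 1]] <-
        list(kind = "scale", atom = v, comp = NA,
             name = paste0("scale.", v), step = NA)
  }
  rows
}

.apply_params <- function(state, theta, ptab, dirs) {
  st <- state$st
  for (j in seq_along(ptab)) {
    p <- ptab[[j]]
    if (p$kind == "coord") st$atoms[[p$atom]]$xyz[p$comp] <- theta[j]
    else if (p$kind == "uiso") st$atoms[[p$atom]]$uiso <- max(theta[j], 0)
    else if (p$kind == "uglobal") {
      for (i in seq_along(st$atoms)) st$atoms[[i]]$uiso <- max(theta[j], 0)
    } else if (p$kind == "thickness") state$t <- max(theta[j], 1e-3)
    else if (p$kind == "extinction") state$ext <- max(theta[j], 0)
    else if (p$kind == "scale") state$scales[p$atom] <- max(theta[j], 1e-12)
  }
  state$st <- .apply_riding(st, dirs, state$dl)
  state
}

.pack_params <- function(state, ptab) {
  vapply(ptab, function(p) {
    switch(p$kind,
           coord = state$st$atoms[[p$atom]]$xyz[p$comp],
           uiso = state$st$atoms[[p$atom]]$uiso,
           uglobal = state$st$atoms[[which(!vapply(state$st$atoms, function(a) !is.null(a$riding), TRUE))[1]]]$uiso,
           thickness = state$t,
           extinction = state$ext,
           scale = state$scales[p$atom])
  }, 0)
}

# SVD least-squares solve of the column-scaled weighted system. A parameter
# with no leverage at all (zero column) is a hard error naming it; singular
# directions below 1e-8 of the largest singular value (e.g. the floating
# origin of intensity-only kinematical refinement) are truncated out of the
# step and the covariance, pseudoinverse-style, and reported in `dropped`.
.solve_lsq <- function(Jw, rw, cn, pnames) {
  dead <- !is.finite(cn) | cn == 0
  if (all(dead)) {
    stop("singular normal matrix; null-space parameters: ",
         paste(pnames[dead], collapse = ", "))
  }
  if (any(dead)) {
    # parameters with (transiently) no leverage are frozen this iteration
    Jw[, dead] <- 0
    cn[dead] <- 1
  }
  Js <- sweep(Jw, 2, cn, "/")
  sv <- svd(Js)
  keep <- sv$d >= 1e-8 * sv$d[1]
  dropped <- if (all(keep)) character(0) else {
    pnames[apply(abs(sv$v[, !keep, drop = FALSE]), 1, max) > 0.3]
  }
  dinv <- ifelse(keep, 1 / sv$d, 0)
  delta <- sv$v %*% (dinv * crossprod(sv$u, rw))
  cov_unit <- sv$v %*% (dinv^2 * t(sv$v))
  esd_unit <- sqrt(pmax(diag(cov_unit), 0)) / cn
  if (any(dead)) esd_unit[dead] <- Inf
  list(delta = drop(delta) / cn,
       esd_unit = esd_unit,
       dropped = c(dropped, pnames[dead]))
}

#' R-factors of a refinement
#'
#' \eqn{wR = \sqrt{\sum w (I_{obs}-I_{calc})^2 / \sum w I_{obs}^2}} with
#' \eqn{w = 1/\sigma^2}; `R_obs` (and `wR_obs`) restrict to "observed"
#' reflections with \eqn{I_{obs} > 3\sigma};
#' \eqn{R = \sum |I_{obs}-I_{calc}| / \sum I_{obs}}.
#'
#' @param I_obs,sigma,I_calc aligned observation vectors.
#' @param w optional weights (default `1/sigma^2` with the sigma floor).
#' @return list with `wR_all`, `wR_obs`, `R_obs`, `n_all`, `n_obs`.
#' @export
residuals_and_rfactors <- function(I_obs, sigma, I_calc, w = NULL) {
  if (!length(I_obs)) stop("empty observation set")
  if (is.null(w)) w <- 1 / pmax(sigma, 0.01 * stats::median(sigma))^2
  r <- I_obs - I_calc
  obs_sel <- I_obs > 3 * sigma
  list(
    wR_all = sqrt(sum(w * r^2) / sum(w * I_obs^2)),
    wR_obs = if (any(obs_sel)) sqrt(sum(w[obs_sel] * r[obs_sel]^2) /
                                    sum(w[obs_sel] * I_obs[obs_sel]^2)) else NA_real_,
    R_obs = if (any(obs_sel)) sum(abs(r[obs_sel])) / sum(I_obs[obs_sel]) else NA_real_,
    n_all = length(I_obs), n_obs = sum(obs_sel)
  )
}

#' Initialize thickness and per-frame scales
#'
#' With the structural model fixed, the thickness is found by a grid search
#' minimizing wR (per-frame scales set to
#' \eqn{\sum I_{obs} / \sum I_{calc}} at each grid point), followed by one
#' least-squares cycle over scales and thickness only.
#'
#' @param rd a [reduce_experiment()] result.
#' @param st the (fixed) structural model.
#' @param t_grid thickness grid in Angstrom.
#' @param engine optional prebuilt engine (internal reuse).
#' @return list with `t`, `scales` (one per OVF), `wR`, `grid`
#'   (data.frame thickness/wR).
#' @export
initialize_scales <- function(rd, st, t_grid = seq(100, 2000, length.out = 20),
                              engine = NULL) {
  eng <- if (is.null(engine)) .make_engine(rd) else engine
  obs <- eng$obs
  w <- 1 / pmax(obs$sigma, 0.01 * stats::median(obs$sigma))^2
  raw <- eng$eval_raw(st, t_grid)
  vfi <- eng$vf_of_obs
  nvf <- nrow(rd$ovfs)
  best <- NULL
  wRs <- numeric(length(t_grid))
  for (it in seq_along(t_grid)) {
    ri <- raw[, it]
    s <- vapply(seq_len(nvf), function(v) {
      sel <- vfi == v
      if (!any(sel) || sum(ri[sel]) <= 0) return(1)
      sum(obs$I_obs[sel]) / sum(ri[sel])
    }, 0)
    Ic <- s[vfi] * ri
    wRs[it] <- sqrt(sum(w * (obs$I_obs - Ic)^2) / sum(w * obs$I_obs^2))
    if (is.null(best) || wRs[it] < best$wR) best <- list(t = t_grid[it], scales = s, wR = wRs[it])
  }
  # one least-squares cycle over scales + thickness
  res <- run_least_squares(rd, st,
                           spec = refine_spec(coords = FALSE, uiso = FALSE,
                                              thickness = TRUE, scales = TRUE),
                           t0 = best$t, scales0 = best$scales,
                           options = list(max_iter = 1), engine = eng)
  list(t = res$thickness, scales = res$scales, wR = res$rfactors$wR_all,
       grid = data.frame(thickness = t_grid, wR = wRs), t_grid_pick = best$t)
}

#' Damped Gauss-Newton least-squares refinement
#'
#' @param rd a [reduce_experiment()] result.
#' @param st0 starting structural model.
#' @param spec a [refine_spec()].
#' @param mode `"dynamical"` (Bloch-wave intensities) or
#'   `"frame_kinematical"` (kinematical model against the identical
#'   filtered observations).
#' @param t0,scales0 starting thickness / per-OVF scales; when `NULL` they
#'   come from [initialize_scales()] (dynamical) or are set to least-squares
#'   ratios (kinematical).
#' @param dl riding-hydrogen bond-length offset Delta-l (Angstrom).
#' @param options list overriding `max_iter` (50), `conv` (0.01, on max
#'   |shift/esd|), `max_halvings` (10), `fd_t_step` (1 Angstrom).
#' @param engine internal engine reuse.
#' @return `ded_refinement`: refined `structure`, `thickness`, `scales`,
#'   `ext`, `esd` (named vector), `rfactors`, `obs` (with `I_calc`,
#'   `weight`), `log`, `converged`.
#' @export
run_least_squares <- function(rd, st0, spec = refine_spec(),
                              mode = c("dynamical", "frame_kinematical"),
                              t0 = NULL, scales0 = NULL, dl = 0,
                              options = list(), engine = NULL) {
  mode <- match.arg(mode)
  if (mode == "frame_kinematical") spec$thickness <- FALSE
  opt <- modifyList(list(max_iter = 50, conv = 0.01, max_halvings = 10,
                         fd_t_step = 1), options)
  eng <- if (is.null(engine)) .make_engine(rd) else engine
  obs <- eng$obs
  if (!nrow(obs)) stop("no included observations")
  w <- 1 / pmax(obs$sigma, 0.01 * stats::median(obs$sigma))^2
  vfi <- eng$vf_of_obs
  nvf <- nrow(rd$ovfs)
  nobs_per_vf <- tabulate(vfi, nvf)
  scales_refinable <- which(nobs_per_vf >= 3)
  dirs <- .riding_dirs(st0)
  if (is.null(t0) || is.null(scales0)) {
    if (mode == "dynamical") {
      ini <- initialize_scales(rd, .apply_riding(st0, dirs, dl), engine = eng)
      t0 <- ini$t; scales0 <- ini$scales
    } else {
      t0 <- if (is.null(t0)) 500 else t0
      scales0 <- NULL  # set below from kinematical ratios
    }
  }
  state <- list(st = .apply_riding(st0, dirs, dl), t = t0,
                scales = scales0, ext = 0, dl = dl)
  # model evaluation -------------------------------------------------------
  kinL <- if (mode == "frame_kinematical") eng$lorentz else NULL
  raw_of <- function(state, tvec = state$t) {
    if (mode == "dynamical") {
      eng$eval_raw(state$st, tvec)
    } else {
      F2 <- eng$eval_kin(state$st)
      E <- (1 + state$ext * F2)^(-0.5)
      matrix(E * F2 * kinL, ncol = 1)[, rep(1, length(tvec)), drop = FALSE]
    }
  }
  if (is.null(state$scales)) {
    ri <- raw_of(state)[, 1]
    s_glob <- sum(obs$I_obs) / max(sum(ri), 1e-300)
    state$scales <- vapply(seq_len(nvf), function(v) {
      sel <- vfi == v
      # frames whose model intensities nearly vanish keep the global ratio
      if (!any(sel) || sum(ri[sel]) <= 1e-9 * sum(ri)) return(s_glob)
      sum(obs$I_obs[sel]) / sum(ri[sel])
    }, 0)
  }
  ptab <- .param_table(state$st, spec, scales_refinable)
  if (!length(ptab)) stop("no refinable parameters")
  pnames <- vapply(ptab, `[[`, "", "name")
  theta <- .pack_params(state, ptab)
  names(theta) <- pnames
  wR_of <- function(Ic) sqrt(sum(w * (obs$I_obs - Ic)^2) / sum(w * obs$I_obs^2))
  Icalc_of <- function(state) state$scales[vfi] * raw_of(state)[, 1]
  Ic <- Icalc_of(state)
  wR <- wR_of(Ic)
  log <- data.frame(iter = 0, wR = wR, max_shift_esd = NA)
  converged <- wR < 1e-10   # already at a (numerically) perfect fit
  esd <- rep(NA_real_, length(theta))
  fails <- 0
  for (iter in seq_len(if (converged) 0 else opt$max_iter)) {
    # Jacobian ------------------------------------------------------------
    J <- matrix(0, nrow(obs), length(theta))
    struct_kinds <- c("coord", "uiso", "uglobal")
    raw_base <- NULL
    for (j in seq_along(ptab)) {
      p <- ptab[[j]]
      if (p$kind %in% struct_kinds) {
        thp <- theta; thp[j] <- thp[j] + p$step
        thm <- theta; thm[j] <- thm[j] - p$step
        rp <- raw_of(.apply_params(state, thp, ptab, dirs))[, 1]
        rm <- raw_of(.apply_params(state, thm, ptab, dirs))[, 1]
        J[, j] <- state$scales[vfi] * (rp - rm) / (2 * p$step)
      } else if (p$kind == "thickness") {
        dtt <- opt$fd_t_step
        rr <- raw_of(state, c(state$t - dtt, state$t + dtt))
        J[, j] <- state$scales[vfi] * (rr[, 2] - rr[, 1]) / (2 * dtt)
      } else if (p$kind == "extinction") {
        F2 <- eng$eval_kin(state$st)
        dE <- -0.5 * F2 * (1 + state$ext * F2)^(-1.5)
        J[, j] <- state$scales[vfi] * dE * F2 * kinL
      } else if (p$kind == "scale") {
        sel <- vfi == p$atom
        J[sel, j] <- Ic[sel] / state$scales[p$atom]
      }
    }
    # solve scaled weighted normal equations ------------------------------
    J[!is.finite(J)] <- 0
    sw <- sqrt(w)
    Jw <- J * sw
    rw <- (obs$I_obs - Ic) * sw
    cn <- sqrt(colSums(Jw^2))
    sol <- .solve_lsq(Jw, rw, cn, pnames)
    delta <- sol$delta
    gof2 <- sum(rw^2) / max(nrow(obs) - length(theta), 1)
    esd <- sol$esd_unit * sqrt(gof2)
    names(esd) <- pnames
    # damped step ---------------------------------------------------------
    lam <- 1
    accepted <- FALSE
    for (h in 0:opt$max_halvings) {
      thn <- theta + lam * delta
      stn <- .apply_params(state, thn, ptab, dirs)
      thn <- .pack_params(stn, ptab)  # respect clamping
      Icn <- Icalc_of(stn)
      wRn <- wR_of(Icn)
      if (is.finite(wRn) && wRn <= wR + 1e-14) { accepted <- TRUE; break }
      lam <- lam / 2
    }
    if (!accepted) {
      fails <- fails + 1
      if (fails >= 3) break
      log <- rbind(log, data.frame(iter = iter, wR = wR, max_shift_esd = NA))
      next
    }
    fails <- 0
    shift_esd <- max(abs(lam * delta / pmax(esd, 1e-300)))
    improved <- wR - wRn
    state <- stn; theta <- thn; names(theta) <- pnames; Ic <- Icn; wR <- wRn
    log <- rbind(log, data.frame(iter = iter, wR = wR, max_shift_esd = shift_esd))
    if (shift_esd < opt$conv || wR < 1e-10 ||
        improved < 1e-9 * (wR + 1e-300)) { converged <- TRUE; break }
  }
  obs_out <- rd$obs
  obs_out$I_calc <- NA_real_
  obs_out$weight <- NA_real_
  obs_out$I_calc[eng$incl] <- Ic
  obs_out$weight[eng$incl] <- w
  rf <- residuals_and_rfactors(obs$I_obs, obs$sigma, Ic, w)
  structure(list(structure = state$st, thickness = state$t,
                 scales = state$scales, ext = state$ext, dl = dl,
                 esd = esd, rfactors = rf, obs = obs_out, log = log,
                 converged = converged, mode = mode, spec = spec,
                 scales_refinable = scales_refinable),
            class = "ded_refinement")
}

#' @export
print.ded_refinement <- function(x, ...) {
  cat(sprintf("%s refinement: wR_all=%.4f R_obs=%.4f (n=%d/%d), t=%.0f A, %s\n",
              x$mode, x$rfactors$wR_all, x$rfactors$R_obs,
              x$rfactors$n_obs, x$rfactors$n_all, x$thickness,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
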