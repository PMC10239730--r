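# Evaluation engine: computes model integrated intensities for the included
# observations of a reduced data set, for any structure parameter values.
# Geometry (beam sets, quadrature grids, excitation errors) is precomputed
# and cached; per evaluation only the potential coefficients and the
# eigen-propagation are redone.
#
# Observations sharing a reflection pass share its beam set and rocking
# curve: the curve is propagated once per pass on a contiguous node grid
# (m nodes per frame plus shared frame-boundary nodes) and every
# observation integrates its own node range (the frames of its virtual
# frame that lie on the pass) by the trapezoid rule. Virtual-frame
# orientation corrections break this sharing, so corrected evaluations go
# through a per-observation path.

# contiguous quadrature grid over a run of uniformly spaced frames
.contig_grid <- function(frame_alphas, dalpha, m) {
  nf <- length(frame_alphas)
  a_lo <- frame_alphas[1] - dalpha / 2
  list(alphas = a_lo + dalpha / m * (0:(m * nf)), m = m, nf = nf)
}

# trapezoid weights (radians) for a window of nb frames sampled at m
# sub-intervals per frame
.trap_weights <- function(nb, m, dalpha) {
  (dalpha * pi / 180) / m * c(0.5, rep(1, nb * m - 1), 0.5)
}

.make_engine <- function(rd) {
  incl <- which(rd$obs$included)
  obs <- rd$obs[incl, , drop = FALSE]
  used_passes <- sort(unique(obs$pass))
  bsets <- .pass_beam_hkl(rd$cell, rd$geom, rd$passes[used_passes],
                          rd$opts$g_beam, rd$opts$s_beam, rd$opts$max_beams)
  dt <- .build_diff_table(rd$cell, bsets)
  members <- attr(rd$ovfs, "members")
  dalpha <- attr(rd$frames, "dalpha")
  m <- rd$opts$m
  n <- nrow(obs)
  np <- length(used_passes)
  # pass-level node grids -------------------------------------------------
  pass_grid <- vector("list", np)
  pass_target <- integer(np)
  for (p in seq_len(np)) {
    ps <- rd$passes[[used_passes[p]]]
    pass_grid[[p]] <- .contig_grid(rd$frames$alpha[match(ps$frames, rd$frames$frame)],
                                   dalpha, m)
    pass_target[p] <- match(paste(ps$hkl[1], ps$hkl[2], ps$hkl[3]),
                            paste(bsets[[p]][, 1], bsets[[p]][, 2], bsets[[p]][, 3]))
  }
  # per-observation node ranges -------------------------------------------
  obs_ctx <- vector("list", n)
  for (i in seq_len(n)) {
    p <- match(obs$pass[i], used_passes)
    ps <- rd$passes[[used_passes[p]]]
    mem <- members[[match(obs$vf[i], rd$ovfs$vf)]]
    fsel <- which(ps$frames %in% mem)   # contiguous block within the pass
    nodes <- ((min(fsel) - 1) * m + 1):(max(fsel) * m + 1)
    obs_ctx[[i]] <- list(p = p, nodes = nodes,
                         weights = .trap_weights(length(fsel), m, dalpha))
  }
  # drop pass nodes not used by any included observation, remap indices
  pass_smat <- vector("list", np)
  for (p in seq_len(np)) {
    mine <- which(vapply(obs_ctx, function(cx) cx$p == p, TRUE))
    used <- sort(unique(unlist(lapply(obs_ctx[mine], `[[`, "nodes"))))
    pass_grid[[p]]$alphas <- pass_grid[[p]]$alphas[used]
    for (i in mine) obs_ctx[[i]]$nodes <- match(obs_ctx[[i]]$nodes, used)
    pass_smat[[p]] <- .pass_smat(rd$cell, rd$geom, bsets[[p]],
                                 list(alphas = pass_grid[[p]]$alphas))
  }
  env <- new.env(parent = emptyenv())
  env$rd <- rd; env$obs <- obs; env$incl <- incl
  env$dt <- dt; env$bsets <- bsets
  env$pass_grid <- pass_grid; env$pass_target <- pass_target
  env$used_passes <- used_passes; env$obs_ctx <- obs_ctx
  env$vf_of_obs <- match(obs$vf, rd$ovfs$vf)
  env$corr <- rep(list(NULL), nrow(rd$ovfs))  # per-OVF correction angles
  env$cpp_passes <- lapply(seq_len(np), function(p)
    list(idx = dt$idx[[p]], smat = pass_smat[[p]], target = pass_target[p]))
  env$potential <- function(st) {
    ctx <- .sf_context(st)
    .potential_fast(ctx, rd$cell, rd$geom$beam, env$dt$diffs, env$dt$svals)
  }
  # raw (unscaled) integrated model intensities: n_obs x length(tvec)
  env$eval_raw <- function(st, tvec) {
    U <- env$potential(st)
    curves <- cpp_bloch_curves(env$cpp_passes, U, as.numeric(tvec),
                               rd$geom$beam$K)
    out <- matrix(0, n, length(tvec))
    for (i in seq_len(n)) {
      cx <- obs_ctx[[i]]
      out[i, ] <- crossprod(cx$weights, curves[[cx$p]][cx$nodes, , drop = FALSE])
    }
    corrected <- which(!vapply(env$corr, is.null, TRUE))
    for (v in corrected) {
      sel <- which(env$vf_of_obs == v)
      if (length(sel)) {
        U_v <- U
        out[sel, ] <- env$eval_obs_corrected(U_v, tvec, sel, env$corr[[v]])
      }
    }
    out
  }
  # per-observation path with a virtual-frame orientation correction:
  # integrates the observations in `subset` with correction angles `delta`
  # (degrees, about the lab x/y axes), at fixed potential U
  env$eval_obs_corrected <- function(U, tvec, subset, delta) {
    corr <- .correction_matrix(delta)
    cpp <- lapply(subset, function(i) {
      cx <- obs_ctx[[i]]
      sm <- .pass_smat(rd$cell, rd$geom, bsets[[cx$p]],
                       list(alphas = pass_grid[[cx$p]]$alphas[cx$nodes]),
                       corr)
      list(idx = env$dt$idx[[cx$p]], smat = sm, target = pass_target[cx$p])
    })
    curves <- cpp_bloch_curves(cpp, U, as.numeric(tvec), rd$geom$beam$K)
    out <- matrix(0, length(subset), length(tvec))
    for (j in seq_along(subset)) {
      out[j, ] <- crossprod(obs_ctx[[subset[j]]]$weights, curves[[j]])
    }
    out
  }
  # kinematical model parts: |F|^2 per observation (compiled SF path)
  env$kin_hkl <- as.matrix(obs[, c("h", "k", "l")])
  storage.mode(env$kin_hkl) <- "integer"
  env$kin_svals <- 1 / (2 * d_spacing(rd$cell, env$kin_hkl))
  env$eval_kin <- function(st) {
    ctx <- .sf_context(st)
    Mod(cpp_structure_factors(env$kin_hkl, env$kin_svals, ctx$frac, ctx$occ,
                              ctx$uiso, ctx$elem, ctx$acoef, ctx$bcoef))^2
  }
  env$lorentz <- {
    lo <- lorentz_correction(obs, rd$cell, rd$geom, rd$ovfs)
    L <- lo$lorentz
    # slow-moving reflections have a finite window integral even though the
    # point-speed Lorentz factor diverges; cap the factor accordingly
    cap <- 50 * stats::median(L[is.finite(L)])
    pmin(L, cap)
  }
  env
}
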