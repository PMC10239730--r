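# Virtual-frame orientation optimization: each OVF may carry two small
# correction rotations about the lab axes normal to the beam, compensating
# goniometer wobble and crystal bending. With the structural model fixed,
# the corrections of each OVF are optimized by a downhill simplex on that
# OVF's weighted R-factor.

#' Optimize virtual-frame orientations
#'
#' Runs a Nelder-Mead simplex (standard coefficients: reflection 1,
#' expansion 2, contraction 0.5, shrink 0.5) over the two correction angles
#' of every virtual frame, within `bound` degrees, minimizing the wR of the
#' reflections assigned to that frame. The per-OVF scales and the
#' structural model are held fixed, so the total wR cannot increase. The
#' returned engine carries the optimized corrections; re-refining with it
#' uses the corrected geometry.
#'
#' @param rd a [reduce_experiment()] result.
#' @param result a converged [run_least_squares()] dynamical refinement.
#' @param bound correction bound in degrees (default 0.5).
#' @param tol angular convergence tolerance in degrees.
#' @param engine optional engine reuse (its corrections are updated in
#'   place).
#' @return list with `corrections` (OVF x 2 matrix, degrees), `wR_before`,
#'   `wR_after`, `per_vf` (per-OVF wR before/after), `engine`.
#' @export
optimize_frame_orientations <- function(rd, result, bound = 0.5, tol = 1e-4,
                                        engine = NULL) {
  eng <- if (is.null(engine)) .make_engine(rd) else engine
  obs <- eng$obs
  w <- 1 / pmax(obs$sigma, 0.01 * stats::median(obs$sigma))^2
  scales <- result$scales
  tth <- result$thickness
  vfi <- eng$vf_of_obs
  U <- eng$potential(result$structure)
  total_wR <- function() {
    raw <- eng$eval_raw(result$structure, tth)[, 1]
    Ic <- scales[vfi] * raw
    sqrt(sum(w * (obs$I_obs - Ic)^2) / sum(w * obs$I_obs^2))
  }
  wR_before <- total_wR()
  corrections <- matrix(0, nrow(rd$ovfs), 2)
  per_vf <- data.frame(vf = rd$ovfs$vf, wR_before = NA_real_,
                       wR_after = NA_real_, n_obs = tabulate(vfi, nrow(rd$ovfs)))
  for (k in seq_len(nrow(rd$ovfs))) {
    subset <- which(vfi == k)
    if (!length(subset)) next
    sv <- scales[k]
    Iov <- obs$I_obs[subset]; wv <- w[subset]
    objective <- function(d) {
      if (max(abs(d)) > bound) return(1e6 + sum(d^2))
      raw <- eng$eval_obs_corrected(U, tth, subset, d)[, 1]
      sqrt(sum(wv * (Iov - sv * raw)^2) / sum(wv * Iov^2))
    }
    f0 <- objective(c(0, 0))
    per_vf$wR_before[k] <- f0
    # rocking-curve mismatch objectives are multimodal (shifting by one
    # oscillation gives local minima): coarse grid scan, then simplex
    grid <- as.matrix(expand.grid(d1 = seq(-0.4, 0.4, by = 0.2),
                                  d2 = seq(-0.4, 0.4, by = 0.2)))
    gvals <- apply(grid, 1, objective)
    start <- grid[which.min(gvals), ]
    op <- stats::optim(start, objective, method = "Nelder-Mead",
                       control = list(reltol = 1e-10, maxit = 150))
    if (op$value < f0 - 1e-12) {
      corrections[k, ] <- op$par
      per_vf$wR_after[k] <- op$value
      eng$corr[k] <- list(op$par)
    } else {
      per_vf$wR_after[k] <- f0
      eng$corr[k] <- list(NULL)
    }
  }
  wR_after <- total_wR()
  list(corrections = corrections, wR_before = wR_before, wR_after = wR_after,
       per_vf = per_vf, engine = eng)
}
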