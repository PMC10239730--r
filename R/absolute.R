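# Absolute-structure determination. Dynamical intensities of Bijvoet pairs
# are inequivalent for noncentrosymmetric crystals, so refining both
# enantiomorphs against the same data and comparing the fits assigns the
# handedness. The significance statistic counts, reflection by reflection,
# which enantiomorph matches better: under the null hypothesis (no
# preference) the count is binomial with p = 1/2; the z-score is adjusted
# for comparisons that are expected to be decided by experimental noise
# alone.

#' Count per-reflection enantiomorph preferences
#'
#' N counts comparisons with unequal absolute residuals
#' \eqn{|I_{calc,1} - I_{obs}|} vs \eqn{|I_{calc,2} - I_{obs}|}; k counts
#' those favouring model 1. Exact ties are excluded from both.
#'
#' @param I_obs,I_calc1,I_calc2 aligned intensity vectors.
#' @return list with `k` and `N`.
#' @export
count_matches <- function(I_obs, I_calc1, I_calc2) {
  if (!length(I_obs)) stop("empty observation list")
  if (length(I_calc1) != length(I_obs) || length(I_calc2) != length(I_obs))
    stop("misaligned input lists")
  d1 <- abs(I_calc1 - I_obs)
  d2 <- abs(I_calc2 - I_obs)
  list(k = sum(d1 < d2), N = sum(d1 != d2))
}

#' Expected background-noise miscounts
#'
#' \eqn{w = \sum_i [1 - \Phi(|I_{calc,1} - I_{calc,2}| / (2\sigma(I_{obs})))]}:
#' the number of reflections whose preference is expected to be decided by
#' experimental noise rather than by the model difference.
#'
#' @param I_calc1,I_calc2,sigma aligned vectors, `sigma > 0`.
#' @return w (non-negative scalar).
#' @export
noise_term <- function(I_calc1, I_calc2, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  sum(1 - stats::pnorm(abs(I_calc1 - I_calc2) / (2 * sigma)))
}

#' Adjusted z-score of an enantiomorph comparison
#'
#' \eqn{z = (2k - N) / \sqrt{N - w}} with probability \eqn{\Phi(z)} that
#' the assignment is correct. Also reports the unadjusted score
#' \eqn{(k - N/2)/(\sqrt N / 2)} and the exact binomial tail
#' \eqn{P(K \ge k \mid N, p = 1/2)}.
#'
#' @param k,N counts from [count_matches()].
#' @param w noise term from [noise_term()]; must satisfy `w < N`.
#' @return list `z`, `probability`, `z_unadjusted`, `binom_tail`.
#' @export
z_score <- function(k, N, w = 0) {
  if (k < 0 || k > N) stop("k must lie in [0, N]")
  if (N <= w) stop("degenerate noise estimate: N <= w")
  z <- (2 * k - N) / sqrt(N - w)
  list(z = z, probability = stats::pnorm(z),
       z_unadjusted = (2 * k - N) / sqrt(N),
       binom_tail = stats::pbinom(k - 1, N, 0.5, lower.tail = FALSE))
}

#' Dual-enantiomorph refinement and comparison
#'
#' Refines the model and its inverse ([invert_structure()]) in two
#' independent refinements against the same data, filters and options --
#' equivalent to fixing a Flack parameter at 0 or 1 -- and evaluates the
#' z-score statistic on the common included observations. Virtual-frame
#' orientation corrections are deliberately left at zero for both
#' refinements (they are conditioned on the assumed handedness).
#'
#' Stages: `"initial"` refines only per-OVF scales, one thickness and one
#' global isotropic displacement parameter (the quick mode for unrefined
#' solution models); `"refined"` also refines coordinates and individual
#' displacement parameters with riding hydrogens.
#'
#' @param rd a [reduce_experiment()] result (or list of them; the partition
#'   statistic is then reported per data set).
#' @param st0 candidate model (enantiomorph 1).
#' @param stage `"initial"` or `"refined"`.
#' @param options iteration controls for [run_least_squares()].
#' @return `ded_enantio`: `fit1`, `fit2` (refinements or lists thereof),
#'   `wR1`, `wR2`, `k`, `N`, `w`, `z`, `probability`, `z_unadjusted`,
#'   `per_dataset` (data.frame), `favoured` (1, 2 or 0 for a null result).
#' @export
refine_both_enantiomorphs <- function(rd, st0, stage = c("refined", "initial"),
                                      options = list()) {
  stage <- match.arg(stage)
  st2 <- withCallingHandlers(invert_structure(st0),
                             warning = function(w) invokeRestart("muffleWarning"))
  centro <- st0$sg$centrosymmetric
  spec <- if (stage == "initial") {
    refine_spec(coords = FALSE, global_uiso = TRUE, thickness = TRUE,
                scales = TRUE)
  } else {
    refine_spec(coords = TRUE, uiso = TRUE, thickness = TRUE, scales = TRUE)
  }
  rds <- if (inherits(rd, "ded_refdata")) list(rd) else rd
  fit_one <- function(st) lapply(rds, function(d)
    run_least_squares(d, st, spec = spec, mode = "dynamical",
                      options = options))
  fit1 <- tryCatch(fit_one(st0), error = function(e)
    stop("enantiomorph 1 refinement failed: ", conditionMessage(e)))
  fit2 <- tryCatch(fit_one(st2), error = function(e)
    stop("enantiomorph 2 refinement failed: ", conditionMessage(e)))
  per <- lapply(seq_along(rds), function(i) {
    o1 <- fit1[[i]]$obs; o2 <- fit2[[i]]$obs
    sel <- o1$included & !is.na(o1$I_calc) & !is.na(o2$I_calc)
    km <- count_matches(o1$I_obs[sel], o1$I_calc[sel], o2$I_calc[sel])
    wn <- noise_term(o1$I_calc[sel], o2$I_calc[sel], o1$sigma[sel])
    c(N = km$N, k = km$k, w = min(wn, km$N * 0.999),
      wR1 = fit1[[i]]$rfactors$wR_all, wR2 = fit2[[i]]$rfactors$wR_all)
  })
  per <- as.data.frame(do.call(rbind, per))
  per$dataset <- seq_len(nrow(per))
  N <- sum(per$N); k <- sum(per$k); wn <- sum(per$w)
  if (N == 0) {
    zs <- list(z = 0, probability = 0.5, z_unadjusted = 0, binom_tail = 1)
  } else {
    zs <- z_score(k, N, min(wn, 0.999 * N))
  }
  per$z <- ifelse(per$N > per$w & per$N > 0,
                  (2 * per$k - per$N) / sqrt(per$N - per$w), 0)
  favoured <- if (centro || abs(zs$z) < 3) 0L else if (zs$z > 0) 1L else 2L
  structure(list(fit1 = if (length(fit1) == 1) fit1[[1]] else fit1,
                 fit2 = if (length(fit2) == 1) fit2[[1]] else fit2,
                 wR1 = sum(per$wR1 * per$N) / sum(pmax(per$N, 1)),
                 wR2 = sum(per$wR2 * per$N) / sum(pmax(per$N, 1)),
                 k = k, N = N, w = wn, z = zs$z,
                 probability = zs$probability,
                 z_unadjusted = zs$z_unadjusted,
                 binom_tail = zs$binom_tail,
                 per_dataset = per, stage = stage, favoured = favoured,
                 centrosymmetric = centro),
            class = "ded_enantio")
}

#' @export
print.ded_enantio <- function(x, ...) {
  cat(sprintf("dual-enantiomorph comparison (%s stage)\n", x$stage))
  cat(sprintf("  wR_all: %.4f (model) vs %.4f (inverted)\n", x$wR1, x$wR2))
  cat(sprintf("  k/N = %d/%d, w = %.1f, z = %.2f, P = %.5f\n",
              x$k, x$N, x$w, x$z, x$probability))
  cat(if (x$favoured == 0) "  null result (|z| < 3 or centrosymmetric)\n"
      else sprintf("  favoured: enantiomorph %d\n", x$favoured))
  invisible(x)
}
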