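# Post-refinement symmetry merging. Dynamical intensities of symmetry
# equivalents are not expected to be equal, so merging is meaningful only
# after the refinement, on scale-normalized observed and calculated
# intensities; the resulting MR-factors are the dynamical counterpart of
# conventional merged R-factors.

#' Merge symmetry-equivalent observations
#'
#' Groups the included observations of a refinement by Laue orbit after
#' dividing out the per-OVF scales, averages observed and calculated
#' intensities, and assigns merged uncertainties
#' \eqn{\sigma(\bar I) = \sqrt{\sum (I - \bar I)^2 / (n (n-1))}} for
#' multiplicity \eqn{n \ge 2}; for n = 1 (or an all-identical group, where
#' the formula gives 0) the quadrature-propagated input sigma is used.
#'
#' @param result a [run_least_squares()] result (needs `I_calc`).
#' @param sg the [space_group()] whose Laue class defines equivalence.
#' @return `ded_merged`: data.frame `h,k,l` (orbit representative), `n`,
#'   `I_obs`, `sigma`, `I_calc`; plus attribute `mr` with the MR-factors
#'   (`MR_obs`, `MwR_all`) computed from the merged values.
#' @export
merge_equivalents <- function(result, sg) {
  obs <- result$obs
  obs <- obs[obs$included & !is.na(obs$I_calc), , drop = FALSE]
  if (!nrow(obs)) stop("no included observations with calculated intensities")
  s <- result$scales[match(obs$vf, seq_along(result$scales))]
  In <- obs$I_obs / s
  Icn <- obs$I_calc / s
  sn <- obs$sigma / s
  reps <- t(vapply(seq_len(nrow(obs)), function(i)
    laue_representative(c(obs$h[i], obs$k[i], obs$l[i]), sg), integer(3)))
  key <- paste(reps[, 1], reps[, 2], reps[, 3])
  groups <- split(seq_len(nrow(obs)), key)
  rows <- lapply(groups, function(ix) {
    n <- length(ix)
    Ibar <- mean(In[ix])
    sig <- if (n >= 2) sqrt(sum((In[ix] - Ibar)^2) / (n * (n - 1))) else 0
    if (sig <= 0) sig <- sqrt(sum(sn[ix]^2)) / n
    data.frame(h = reps[ix[1], 1], k = reps[ix[1], 2], l = reps[ix[1], 3],
               n = n, I_obs = Ibar, sigma = sig, I_calc = mean(Icn[ix]))
  })
  merged <- do.call(rbind, rows)
  rownames(merged) <- NULL
  rf <- residuals_and_rfactors(merged$I_obs, merged$sigma, merged$I_calc)
  attr(merged, "mr") <- list(MR_obs = rf$R_obs, MwR_all = rf$wR_all,
                             MwR_obs = rf$wR_obs)
  class(merged) <- c("ded_merged", "data.frame")
  merged
}

#' @export
print.ded_merged <- function(x, ...) {
  mr <- attr(x, "mr")
  cat(sprintf("%d merged reflections; MR_obs=%.4f MwR_all=%.4f\n",
              nrow(x), mr$MR_obs, mr$MwR_all))
  invisible(x)
}
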