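# Reduction of per-frame reflection records into filtered virtual-frame
# observations plus everything the refinement engine needs (reflection
# passes, beam-set geometry). Pass enumeration is deterministic, so a data
# set written to file and read back reduces to the identical object.

#' Model/engine options
#'
#' Cutoffs controlling the forward model: recorded resolution, the
#' recording cutoff on the excitation error, Bloch beam-selection cutoffs
#' and the rocking-curve quadrature density.
#'
#' @param g_res recorded resolution (1/Angstrom).
#' @param S_record recording cutoff on |S_g| (1/Angstrom).
#' @param g_beam,s_beam,max_beams beam-selection cutoffs.
#' @param m quadrature sub-intervals per experimental frame (an OVF of
#'   `N_F` frames is sampled at `N_F * m + N_F` rocking-curve orientations).
#' @return list of options.
#' @export
model_options <- function(g_res = 0.75, S_record = 0.045, g_beam = 0.9,
                          s_beam = 0.012, max_beams = 150, m = 4) {
  list(g_res = g_res, S_record = S_record, g_beam = g_beam,
       s_beam = s_beam, max_beams = max_beams, m = m)
}

#' Reduce an experiment to refinement-ready observations
#'
#' Builds overlapping virtual frames, assigns and filters the observations,
#' enumerates the reflection passes of the rotation geometry and links each
#' observation to its pass.
#'
#' @param x a [simulate_experiment()] result, or a list with `records`,
#'   `frames`, `geom`.
#' @param cell a [unit_cell()] (defaults to the one implied by `x` when it
#'   carries a truth structure).
#' @param N_F frames per virtual frame.
#' @param N_O overlap; defaults to `round(N_F/2)`.
#' @param D_min,R_max geometric filter thresholds, see [geometry_filter()].
#' @param opts a [model_options()] list; for simulated input the
#'   simulation's own cutoffs are reused by default.
#' @return `ded_refdata`: `obs`, `ovfs`, `frames`, `geom`, `cell`,
#'   `passes`, `opts`.
#' @export
reduce_experiment <- function(x, cell = NULL, N_F = 4, N_O = round(N_F / 2),
                              D_min = 0.002, R_max = 0.65, opts = NULL) {
  if (inherits(x, "ded_experiment")) {
    if (is.null(cell)) cell <- x$truth$structure$cell
    if (is.null(opts)) {
      opts <- model_options(g_res = x$design$g_res, S_record = x$design$S_record,
                            g_beam = x$design$g_beam, s_beam = x$design$s_beam,
                            max_beams = x$design$max_beams, m = x$design$m)
    }
  }
  if (is.null(cell)) stop("a unit cell is required")
  if (is.null(opts)) opts <- model_options()
  ovfs <- build_virtual_frames(x$frames, N_F, N_O)
  obs <- assign_observations(x$records, ovfs)
  obs <- geometry_filter(obs, cell, x$geom, ovfs, D_min = D_min, R_max = R_max)
  passes <- find_passes(cell, x$geom, x$frames, opts$g_res, opts$S_record)
  obs$pass <- .match_obs_passes(obs, passes, ovfs)
  obs$included <- obs$included & !is.na(obs$pass)
  structure(list(obs = obs, ovfs = ovfs, frames = x$frames, geom = x$geom,
                 cell = cell, passes = passes, opts = opts,
                 D_min = D_min, R_max = R_max),
            class = "ded_refdata")
}

# observation -> pass: same reflection, contributing frames intersect the
# OVF members; nearest crossing wins if several qualify
.match_obs_passes <- function(obs, passes, ovfs) {
  members <- attr(ovfs, "members")
  pass_key <- vapply(passes, function(p) paste(p$hkl, collapse = " "), "")
  out <- rep(NA_integer_, nrow(obs))
  okey <- paste(obs$h, obs$k, obs$l)
  by_key <- split(seq_along(passes), pass_key)
  for (i in seq_len(nrow(obs))) {
    cand <- by_key[[okey[i]]]
    if (is.null(cand)) next
    mem <- members[[match(obs$vf[i], ovfs$vf)]]
    hit <- cand[vapply(cand, function(p) any(passes[[p]]$frames %in% mem), TRUE)]
    if (!length(hit)) next
    if (length(hit) > 1) {
      av <- ovfs$alpha_v[match(obs$vf[i], ovfs$vf)]
      hit <- hit[which.min(abs(vapply(hit, function(p) passes[[p]]$alpha_star, 0) - av))]
    }
    out[i] <- hit[1]
  }
  out
}

#' @export
print.ded_refdata <- function(x, ...) {
  cat(sprintf("reduced 3D ED data: %d observations (%d included) on %d virtual frames\n",
              nrow(x$obs), sum(x$obs$included), nrow(x$ovfs)))
  invisible(x)
}
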