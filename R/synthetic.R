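# Synthetic fixtures and a forward simulator of continuous-rotation 3D ED
# experiments. All fixture coordinates are invented (no real compound's
# structure is claimed); they are chosen to give chemically plausible bond
# networks and collision-free symmetry packing.

#' Bundled synthetic crystal structures
#'
#' * `chiral_org`: an invented chiral organic molecule (8 C/N/O atoms plus
#'   riding hydrogens) in the Sohncke group P212121, cell 6 x 8 x 10 A --
#'   the fixture for absolute-structure experiments.
#' * `quartz_like`: an SiO2 framework in P3221 with quartz-like geometry
#'   (synthetic coordinates), exhibiting the 3_2 screw absences.
#' * `centro_org`: a small invented organic fragment in centrosymmetric
#'   P21/n.
#'
#' @param name one of `"chiral_org"`, `"quartz_like"`, `"centro_org"`.
#' @return a [crystal_structure()].
#' @export
make_fixture <- function(name = c("chiral_org", "quartz_like", "centro_org")) {
  name <- match.arg(name)
  switch(name,
    chiral_org = {
      cell <- unit_cell(6.0, 8.0, 10.0)
      atoms <- list(
        atom_site("O1", "O", c(0.1950, 0.0620, 0.1100), uiso = 0.020),
        atom_site("C1", "C", c(0.3480, 0.1330, 0.1710), uiso = 0.016),
        atom_site("C2", "C", c(0.3070, 0.1680, 0.3170), uiso = 0.015),
        atom_site("N1", "N", c(0.4660, 0.2650, 0.3670), uiso = 0.018),
        atom_site("C3", "C", c(0.4440, 0.3100, 0.5030), uiso = 0.017),
        atom_site("C4", "C", c(0.0880, 0.2730, 0.3350), uiso = 0.019),
        atom_site("C5", "C", c(0.5620, 0.0380, 0.1290), uiso = 0.021),
        atom_site("O2", "O", c(0.3880, 0.4300, 0.5700), uiso = 0.024),
        atom_site("H1", "H", c(0.2840, 0.0680, 0.3760), uiso = 0.018,
                  riding = list(parent = "C2", dist = 1.083)),
        atom_site("H2", "H", c(0.5790, 0.3360, 0.3190), uiso = 0.022,
                  riding = list(parent = "N1", dist = 1.009)),
        atom_site("H3", "H", c(0.0480, 0.3020, 0.4310), uiso = 0.023,
                  riding = list(parent = "C4", dist = 1.083)),
        atom_site("H4", "H", c(0.0990, 0.1050, 0.0650), uiso = 0.024,
                  riding = list(parent = "O1", dist = 0.983))
      )
      st <- crystal_structure(cell, space_group("P212121"), atoms)
      # snap hydrogens exactly onto their riding targets so that the
      # constrained model can reproduce the fixture without residual
      .apply_riding(st, .riding_dirs(st), 0)
    },
    quartz_like = {
      cell <- unit_cell(4.92, 4.92, 5.41, 90, 90, 120)
      atoms <- list(
        atom_site("Si1", "Si", c(0.4700, 0.0000, 2 / 3), uiso = 0.006),
        atom_site("O1", "O", c(0.4140, 0.2680, 0.7860), uiso = 0.010)
      )
      crystal_structure(cell, space_group("P3221"), atoms)
    },
    centro_org = {
      cell <- unit_cell(7.0, 9.0, 11.0, 90, 95, 90)
      atoms <- list(
        atom_site("O1", "O", c(0.1300, 0.0900, 0.1200), uiso = 0.022),
        atom_site("C1", "C", c(0.2600, 0.1500, 0.1800), uiso = 0.018),
        atom_site("C2", "C", c(0.2700, 0.3000, 0.2200), uiso = 0.017),
        atom_site("N1", "N", c(0.4200, 0.3500, 0.3000), uiso = 0.020),
        atom_site("C3", "C", c(0.4400, 0.4900, 0.3500), uiso = 0.019)
      )
      crystal_structure(cell, space_group("P21/n"), atoms)
    })
}

#' Experiment design for the simulator
#'
#' Defaults mirror a typical continuous-rotation 3D ED acquisition: frame
#' width a fraction of a degree, a rotation range of tens of degrees,
#' thickness a few hundred Angstrom, 200 kV. The random seed fully
#' determines the simulated output.
#'
#' @param alpha_range length-2 goniometer range in degrees (spanning at
#'   least 10 frame widths).
#' @param dalpha frame width in degrees.
#' @param thickness crystal thickness in Angstrom.
#' @param voltage_kv acceleration voltage in kV.
#' @param gain detector gain of the Poisson component (counts per quantum);
#'   0 disables counting noise.
#' @param sigma_add additive Gaussian read-noise (counts).
#' @param sigma_rel relative Gaussian noise component (fraction of the
#'   clean intensity), modelling multiplicative error sources.
#' @param drift_amp relative amplitude of the smooth per-frame scale drift.
#' @param misorientation_deg standard deviation of the per-frame random
#'   misorientation (two small rotations about the lab axes normal to the
#'   beam), degrees.
#' @param misorientations optional explicit 2 x n_frames matrix of
#'   misorientation angles (degrees), overriding the random draw.
#' @param flux incident-intensity scale converting angle-integrated
#'   intensity fractions into detector counts.
#' @param g_res resolution cutoff of recorded reflections (1/Angstrom).
#' @param S_record recording cutoff on |S_g| (1/Angstrom).
#' @param g_beam,s_beam,max_beams Bloch beam-selection cutoffs.
#' @param m rocking-curve quadrature sub-intervals per frame.
#' @param axis goniometer axis (lab frame, normal to the beam).
#' @param R0 crystal mounting orientation; `"random"` draws one from the
#'   seed.
#' @param seed integer random seed.
#' @return `ded_design` list of the above.
#' @export
experiment_design <- function(alpha_range = c(-50, 50), dalpha = 0.5,
                              thickness = 500, voltage_kv = 200,
                              gain = 1, sigma_add = 2, sigma_rel = 0,
                              drift_amp = 0.1, misorientation_deg = 0,
                              misorientations = NULL,
                              flux = 2e7, g_res = 0.75, S_record = 0.045,
                              g_beam = 0.9, s_beam = 0.012, max_beams = 150,
                              m = 4, axis = c(1, 0, 0), R0 = "random",
                              seed = 1) {
  if (dalpha <= 0) stop("dalpha must be positive")
  if (diff(alpha_range) < 10 * dalpha) stop("alpha range must span >= 10 frame widths")
  if (thickness <= 0) stop("thickness must be positive")
  structure(as.list(environment()), class = "ded_design")
}

# deterministic random rotation matrix
.random_rotation <- function() {
  repeat {
    q <- rnorm(4)
    n <- sqrt(sum(q^2))
    if (n > 1e-6) { q <- q / n; break }
  }
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

#' Simulate a continuous-rotation 3D ED experiment
#'
#' Generates per-frame reflection intensities by integrating Bloch-wave
#' rocking curves over every frame's angular interval, applies a smooth
#' per-frame scale drift and optional per-frame misorientations, then adds
#' Poisson-plus-Gaussian noise with reported uncertainty
#' \eqn{\sigma = \sqrt{gain \cdot I + \sigma_{add}^2}}. The output bundles
#' the reflection records with a ground-truth sidecar (true thickness,
#' per-frame scales, misorientations, seed).
#'
#' @param st a [crystal_structure()] -- the simulation truth.
#' @param design a [experiment_design()].
#' @return `ded_experiment` with `records` (h,k,l,I,sigma,frame,alpha),
#'   `frames`, `geom`, `design`, `truth`.
#' @export
simulate_experiment <- function(st, design) {
  set.seed(design$seed)
  beam <- relativistic_beam(design$voltage_kv)
  R0 <- if (identical(design$R0, "random")) .random_rotation() else design$R0
  geom <- experiment_geometry(beam, axis = design$axis, R0 = R0)
  n_frames <- floor(diff(design$alpha_range) / design$dalpha + 1e-9)
  alphas <- design$alpha_range[1] + design$dalpha * (seq_len(n_frames) - 0.5)
  frames <- experimental_frames(alphas, design$dalpha)
  passes <- find_passes(st$cell, geom, frames, design$g_res, design$S_record)
  if (!length(passes)) stop("experiment design produces no reflections within the resolution limit")
  bsets <- .pass_beam_hkl(st$cell, geom, passes, design$g_beam, design$s_beam,
                          design$max_beams)
  dt <- .build_diff_table(st$cell, bsets)
  ctx <- .sf_context(st)
  U <- .potential_fast(ctx, st$cell, beam, dt$diffs, dt$svals)
  # per-frame misorientation correction matrices
  mis <- matrix(rnorm(2 * n_frames, 0, design$misorientation_deg), 2, n_frames)
  if (design$misorientation_deg == 0) mis[] <- 0
  if (!is.null(design$misorientations)) {
    mis <- design$misorientations
    stopifnot(nrow(mis) == 2, ncol(mis) == n_frames)
  }
  corr_by_frame <- lapply(seq_len(n_frames), function(f) .correction_matrix(mis[, f]))
  cpp_passes <- vector("list", length(passes))
  grids <- vector("list", length(passes))
  for (p in seq_along(passes)) {
    ps <- passes[[p]]
    fidx <- match(ps$frames, frames$frame)
    grid <- .node_grid(frames$alpha[fidx], design$dalpha, design$m)
    smat <- .pass_smat(st$cell, geom, bsets[[p]], grid,
                       if (all(mis == 0)) NULL else corr_by_frame[fidx])
    target <- match(paste(ps$hkl, collapse = " "),
                    apply(bsets[[p]], 1, paste, collapse = " "))
    cpp_passes[[p]] <- list(idx = dt$idx[[p]], smat = smat, target = target)
    grids[[p]] <- grid
  }
  curves <- cpp_bloch_curves(cpp_passes, U, design$thickness, beam$K)
  # frame scales: flux with a smooth sinusoidal drift
  scales <- design$flux * (1 + design$drift_amp *
                             sin(2 * pi * seq_len(n_frames) / n_frames))
  rec <- vector("list", length(passes))
  for (p in seq_along(passes)) {
    ps <- passes[[p]]; grid <- grids[[p]]
    cur <- curves[[p]][, 1]
    fint <- as.vector(rowsum(cur * grid$weights, grid$frame_block))
    fidx <- match(ps$frames, frames$frame)
    rec[[p]] <- data.frame(h = ps$hkl[1], k = ps$hkl[2], l = ps$hkl[3],
                           I = fint * scales[fidx],
                           frame = ps$frames,
                           alpha = frames$alpha[fidx],
                           pass = p)
  }
  records <- do.call(rbind, rec)
  Iclean <- records$I
  if (design$gain > 0) {
    records$I <- design$gain * rpois(nrow(records), Iclean / design$gain)
  }
  if (design$sigma_add > 0) {
    records$I <- records$I + rnorm(nrow(records), 0, design$sigma_add)
  }
  if (design$sigma_rel > 0) {
    records$I <- records$I + rnorm(nrow(records), 0, design$sigma_rel * Iclean)
  }
  records$I <- pmax(records$I, 0)
  sig <- sqrt(design$gain * Iclean + design$sigma_add^2 +
                (design$sigma_rel * Iclean)^2)
  if (design$gain == 0 && design$sigma_add == 0 && design$sigma_rel == 0) {
    sig <- pmax(1e-6 * Iclean, 1e-6 * stats::median(Iclean[Iclean > 0]))
  }
  records$sigma <- sig
  rownames(records) <- NULL
  structure(list(records = records, frames = frames, geom = geom,
                 design = design,
                 truth = list(structure = st, thickness = design$thickness,
                              frame_scales = scales, misorientations = mis,
                              I_clean = Iclean, seed = design$seed)),
            class = "ded_experiment")
}

#' @export
print.ded_experiment <- function(x, ...) {
  cat(sprintf("simulated 3D ED experiment: %d frames (dalpha=%.3g deg), %d reflection records\n",
              nrow(x$frames), attr(x$frames, "dalpha"), nrow(x$records)))
  invisible(x)
}
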