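# Shared fixtures for the simulation batteries. Problem sizes are scaled
# for the test runs (the methods vignette documents the choices): a 9
# degree rotation range at 0.5 degree frames, 1.67 A resolution, thickness
# 500 A. Heavier computations are memoized so several tests can share one
# battery.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

battery_design <- function(seed, thickness = 500, sigma_rel = 0.05,
                           gain = 0, sigma_add = 0, drift_amp = 0.05,
                           alpha_half = 4.5, g_res = 0.6, ...) {
  experiment_design(alpha_range = c(-alpha_half, alpha_half), dalpha = 0.5,
                    thickness = thickness, gain = gain, sigma_add = sigma_add,
                    sigma_rel = sigma_rel, drift_amp = drift_amp,
                    misorientation_deg = 0, seed = seed,
                    g_res = g_res, s_beam = 0.008, g_beam = g_res + 0.15,
                    m = 2, ...)
}

battery_reduce <- function(st, des, N_F = 4) {
  reduce_experiment(simulate_experiment(st, des), N_F = N_F)
}

perturb_coords <- function(st, amount, seed) {
  set.seed(seed)
  Ainv <- solve(st$cell$A)
  for (i in seq_along(st$atoms)) {
    if (!is.null(st$atoms[[i]]$riding)) next
    d <- rnorm(3)
    d <- d / sqrt(sum(d^2)) * amount
    st$atoms[[i]]$xyz <- (st$atoms[[i]]$xyz + drop(Ainv %*% d)) %% 1
  }
  st
}

# per-coordinate signed errors (fractional), esds, and Cartesian distances
coord_errors <- function(result, truth) {
  labs <- vapply(truth$atoms, `[[`, "", "label")
  err <- c(); esd <- c(); cart <- c()
  for (i in seq_along(truth$atoms)) {
    if (!is.null(truth$atoms[[i]]$riding)) next
    d3 <- result$structure$atoms[[i]]$xyz - truth$atoms[[i]]$xyz
    d3 <- d3 - round(d3)
    cart <- c(cart, sqrt(sum((truth$cell$A %*% d3)^2)))
    for (cmp in 1:3) {
      err <- c(err, d3[cmp])
      esd <- c(esd, result$esd[[paste0(c("x", "y", "z")[cmp], ".", labs[i])]])
    }
  }
  list(err = err, esd = esd, cart = cart)
}

# the 20-replicate noisy recovery battery shared by several acceptance
# criteria: dynamical and frame-based kinematical refinements per replicate
recovery_battery <- function(n_rep = 20) {
  memo(paste0("battery", n_rep), {
    st <- make_fixture("chiral_org")
    lapply(seq_len(n_rep), function(r) {
      rd <- battery_reduce(st, battery_design(seed = 1000 + r))
      eng <- dyned:::.make_engine(rd)
      start <- perturb_coords(st, 0.02, seed = 2000 + r)
      dyn <- run_least_squares(rd, start,
                               spec = refine_spec(coords = TRUE,
                                                  thickness = TRUE,
                                                  scales = TRUE),
                               engine = eng, options = list(max_iter = 4))
      kin <- kinematical_refinement(rd, dyn$structure, frame_based = TRUE,
                                    spec = refine_spec(coords = TRUE,
                                                       uiso = TRUE),
                                    options = list(max_iter = 4))
      list(dyn = dyn, kin = kin, errors = coord_errors(dyn, st))
    })
  })
}

# noiseless perturbed-start recovery (shared by the acceptance criterion
# and the refinement unit tests)
noiseless_recovery <- function() {
  memo("noiseless_recovery", {
    st <- make_fixture("chiral_org")
    rd <- memo("ref_rd_noiseless", battery_reduce(st, battery_design(
      seed = 9, sigma_rel = 0, gain = 0, sigma_add = 0, drift_amp = 0)))
    eng <- memo("ref_eng_noiseless", dyned:::.make_engine(rd))
    start <- perturb_coords(st, 0.03, seed = 5)
    res <- run_least_squares(rd, start,
                             spec = refine_spec(coords = TRUE, thickness = TRUE,
                                                scales = TRUE),
                             engine = eng, options = list(conv = 1e-4))
    list(res = res, errors = coord_errors(res, st))
  })
}

min_image_dist <- function(cell, frac1, frac2) {
  d <- frac1 - frac2
  d <- d - round(d)
  sqrt(sum((cell$A %*% d)^2))
}
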