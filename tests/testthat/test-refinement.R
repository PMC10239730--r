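# Least-squares machinery: R-factors, merging, scale initialization,
# riding hydrogens, frame-orientation optimization, bond-length RMSD.

test_that("R-factor formulas reproduce hand arithmetic", {
  # two observations (I_obs, sigma, I_calc) = (4,1,2), (16,1,16)
  rf <- residuals_and_rfactors(c(4, 16), c(1, 1), c(2, 16), w = c(1, 1))
  expect_equal(rf$wR_all, sqrt(4 / 272), tolerance = 1e-12)
  # perfect fit: all zero
  rf0 <- residuals_and_rfactors(c(4, 16), c(1, 1), c(4, 16))
  expect_equal(rf0$wR_all, 0)
  expect_equal(rf0$R_obs, 0)
  # homogeneity: common scaling of I, sigma, I_calc leaves wR unchanged
  rf1 <- residuals_and_rfactors(c(4, 16, 9), c(1, 2, 1.5), c(5, 15, 9.5))
  rf2 <- residuals_and_rfactors(7 * c(4, 16, 9), 7 * c(1, 2, 1.5), 7 * c(5, 15, 9.5))
  expect_equal(rf1$wR_all, rf2$wR_all, tolerance = 1e-12)
  expect_equal(rf1$R_obs, rf2$R_obs, tolerance = 1e-12)
  expect_error(residuals_and_rfactors(numeric(0), numeric(0), numeric(0)), "empty")
})

test_that("merging follows the sigma(Ibar) formula and MR reduces to R at n = 1", {
  # group {1, 3}: Ibar = 2, sigma = sqrt(sum (I-Ibar)^2 / (n(n-1))) = 1
  fake <- structure(list(
    scales = c(1, 1),
    obs = data.frame(h = c(1, -1), k = c(2, -2), l = c(3, -3), vf = c(1, 2),
                     I_obs = c(1, 3), sigma = c(0.5, 0.5),
                     I_calc = c(1.5, 2.5), included = TRUE)),
    class = "ded_refinement")
  mg <- merge_equivalents(fake, space_group("P-1"))
  expect_equal(nrow(mg), 1)
  expect_equal(mg$I_obs, 2)
  expect_equal(mg$sigma, 1)
  expect_equal(mg$I_calc, 2)
  # all equivalents identical -> propagated input sigma replaces the zero
  fake$obs$I_obs <- c(2, 2)
  mg2 <- merge_equivalents(fake, space_group("P-1"))
  expect_equal(mg2$sigma, sqrt(0.5^2 + 0.5^2) / 2)
  # multiplicity-1 data: MR-factors equal unmerged R-factors
  fake3 <- structure(list(
    scales = 1,
    obs = data.frame(h = c(1, 2, 3), k = c(0, 1, 1), l = c(0, 0, 1), vf = 1,
                     I_obs = c(10, 20, 30), sigma = c(1, 2, 3),
                     I_calc = c(11, 18, 33), included = TRUE)),
    class = "ded_refinement")
  mg3 <- merge_equivalents(fake3, space_group("P1"))
  # P1 Laue class is -1: merge Friedel mates; these three are all distinct
  expect_equal(nrow(mg3), 3)
  rf <- residuals_and_rfactors(fake3$obs$I_obs, fake3$obs$sigma, fake3$obs$I_calc)
  expect_equal(attr(mg3, "mr")$MwR_all, rf$wR_all, tolerance = 1e-12)
  expect_equal(attr(mg3, "mr")$MR_obs, rf$R_obs, tolerance = 1e-12)
})

test_that("scale initialization recovers the simulated thickness and scales", {
  st <- make_fixture("chiral_org")
  rd <- memo("ref_rd_noiseless", battery_reduce(st, battery_design(
    seed = 9, sigma_rel = 0, gain = 0, sigma_add = 0, drift_amp = 0)))
  ini <- initialize_scales(rd, st, t_grid = seq(100, 2000, by = 100))
  # grid pick within one step of the simulated 500 A
  expect_lte(abs(ini$t_grid_pick - 500), 100)
  expect_lt(abs(ini$t - 500), 20)
  # per-OVF scales equal the simulated flux on noiseless drift-free data
  expect_equal(unname(ini$scales), rep(2e7, length(ini$scales)), tolerance = 1e-5)
})

test_that("refinement at the truth is a fixed point and recovers perturbed starts", {
  st <- make_fixture("chiral_org")
  rd <- memo("ref_rd_noiseless", battery_reduce(st, battery_design(
    seed = 9, sigma_rel = 0, gain = 0, sigma_add = 0, drift_amp = 0)))
  eng <- memo("ref_eng_noiseless", dyned:::.make_engine(rd))
  res0 <- run_least_squares(rd, st, spec = refine_spec(coords = TRUE,
                                                       thickness = TRUE,
                                                       scales = TRUE),
                            engine = eng)
  expect_lt(res0$rfactors$wR_all, 1e-6)
  expect_lte(max(res0$log$iter), 2)
  # 0.03 A perturbation on noiseless data recovers to 1e-3 A
  rec <- noiseless_recovery()
  expect_lt(max(rec$errors$cart), 1e-3)
  expect_true(rec$res$converged)
  # accepted iterations never increase wR (damping contract)
  expect_true(all(diff(rec$res$log$wR) <= 1e-14))
})

test_that("riding hydrogens regenerate from the parent geometry", {
  st <- make_fixture("chiral_org")
  dirs <- dyned:::.riding_dirs(st)
  labs <- vapply(st$atoms, `[[`, "", "label")
  st2 <- dyned:::.apply_riding(st, dirs, dl = 0)
  for (lb in names(dirs)) {
    i <- match(lb, labs)
    p <- st2$atoms[[dirs[[lb]]$parent]]
    expect_equal(min_image_dist(st$cell, st2$atoms[[i]]$xyz, p$xyz),
                 dirs[[lb]]$dist, tolerance = 1e-10)
    expect_equal(st2$atoms[[i]]$uiso, 1.2 * p$uiso)
  }
  # with an offset dl
  st3 <- dyned:::.apply_riding(st, dirs, dl = 0.05)
  i <- match("H1", labs)
  expect_equal(min_image_dist(st$cell, st3$atoms[[i]]$xyz,
                              st3$atoms[[dirs[["H1"]]$parent]]$xyz),
               dirs[["H1"]]$dist + 0.05, tolerance = 1e-10)
})

test_that("bond-length RMSD matches a direct per-bond recomputation", {
  st <- make_fixture("chiral_org")
  expect_equal(bond_length_rmsd(st, st), 0)
  # displace one atom and verify against the brute-force bond table
  st2 <- st
  i <- 2  # C1
  st2$atoms[[i]]$xyz <- st2$atoms[[i]]$xyz + c(0.01, 0, 0)
  ref_bonds <- bond_list(st)
  labs <- vapply(st2$atoms, `[[`, "", "label")
  dev <- mapply(function(a, b, lref) {
    d <- st2$atoms[[match(b, labs)]]$xyz - st2$atoms[[match(a, labs)]]$xyz
    d <- d - round(d)
    sqrt(sum((st2$cell$A %*% d)^2)) - lref
  }, ref_bonds$a, ref_bonds$b, ref_bonds$length)
  expect_equal(bond_length_rmsd(st2, st), sqrt(mean(dev^2)), tolerance = 1e-12)
  # invariant under a rigid origin shift
  st3 <- st
  for (j in seq_along(st3$atoms)) st3$atoms[[j]]$xyz <- (st3$atoms[[j]]$xyz + 0.25) %% 1
  expect_equal(bond_length_rmsd(st3, st), 0, tolerance = 1e-12)
  # missing atom errors
  st4 <- st; st4$atoms <- st4$atoms[-1]
  expect_error(bond_length_rmsd(st4, st), "lacks")
})

test_that("frame-orientation optimization recovers an injected misorientation", {
  st <- make_fixture("chiral_org")
  base <- battery_design(seed = 13, sigma_rel = 0.01, drift_amp = 0,
                         alpha_half = 3, g_res = 0.55)
  n_frames <- 12
  mis <- matrix(0, 2, n_frames)
  mis[1, 5:8] <- 0.2  # constant 0.2 deg twist on the frames of OVF 3
  des <- battery_design(seed = 13, sigma_rel = 0.01, drift_amp = 0,
                        alpha_half = 3, g_res = 0.55,
                        misorientations = mis)
  rd <- reduce_experiment(simulate_experiment(st, des), N_F = 4)
  res <- run_least_squares(rd, st, spec = refine_spec(coords = FALSE,
                                                      thickness = TRUE,
                                                      scales = TRUE),
                           options = list(max_iter = 3))
  opt <- optimize_frame_orientations(rd, res)
  expect_lte(opt$wR_after, opt$wR_before + 1e-12)
  expect_true(all(opt$per_vf$wR_after <= opt$per_vf$wR_before + 1e-12, na.rm = TRUE))
  # OVF 3 covers frames 5-8: its correction should recover ~0.2 deg about x
  expect_lt(abs(opt$corrections[3, 1] - 0.2), 0.05)
  # clean data without misorientation: corrections stay near zero
  rd0 <- reduce_experiment(simulate_experiment(st, base), N_F = 4)
  res0 <- run_least_squares(rd0, st, spec = refine_spec(coords = FALSE,
                                                        thickness = TRUE,
                                                        scales = TRUE),
                            options = list(max_iter = 3))
  opt0 <- optimize_frame_orientations(rd0, res0)
  expect_lt(max(abs(opt0$corrections)), 0.02)
})

test_that("the hydrogen distance scan locates the simulated bond length", {
  st <- make_fixture("chiral_org")
  rd <- memo("ref_rd_noiseless", battery_reduce(st, battery_design(
    seed = 9, sigma_rel = 0, gain = 0, sigma_add = 0, drift_amp = 0)))
  eng <- memo("ref_eng_noiseless", dyned:::.make_engine(rd))
  sc <- hydrogen_distance_scan(rd, st, bond_class = "all",
                               dl_grid = seq(-0.04, 0.04, by = 0.02),
                               options = list(max_iter = 2), engine = eng)
  # simulated H at the reference distance: minimum within 0.01 A of zero
  expect_lt(abs(attr(sc, "dl_min")), 0.01)
  # wR at the grid minimum is below both ends
  expect_lt(min(sc$wR_all), sc$wR_all[1])
  expect_lt(min(sc$wR_all), sc$wR_all[nrow(sc)])
  # data simulated with a +0.05 A offset: recovered within 0.02 A
  st_off <- dyned:::.apply_riding(st, dyned:::.riding_dirs(st), dl = 0.05)
  des <- battery_design(seed = 10, sigma_rel = 0, gain = 0, sigma_add = 0,
                        drift_amp = 0)
  rd_off <- reduce_experiment(simulate_experiment(st_off, des), N_F = 4)
  sc2 <- hydrogen_distance_scan(rd_off, st, bond_class = "all",
                                dl_grid = seq(-0.02, 0.08, by = 0.02),
                                options = list(max_iter = 2))
  expect_lt(abs(attr(sc2, "dl_min") - 0.05), 0.02)
})
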