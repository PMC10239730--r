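# Overlapping virtual frames, observation assignment, geometric filters,
# rocking-curve integration, Lorentz correction.

test_that("the worked 12-frame example yields 5 OVFs", {
  frames <- experimental_frames(seq(0.25, 5.75, by = 0.5), dalpha = 0.5)
  ovfs <- build_virtual_frames(frames, N_F = 4, N_O = 2)
  expect_equal(nrow(ovfs), 5)
  expect_equal(ovfs$alpha_v, c(1, 2, 3, 4, 5))
  expect_equal(unique(ovfs$dalpha_v), 2)
  members <- attr(ovfs, "members")
  # consecutive OVFs share exactly N_O frames
  for (i in 1:4) expect_length(intersect(members[[i]], members[[i + 1]]), 2)
  # every frame covered
  expect_setequal(unlist(members), frames$frame)
})

test_that("virtual frame construction handles edges and bad input", {
  frames <- experimental_frames(seq(0.25, 6.25, by = 0.5), dalpha = 0.5)  # 13 frames
  ovfs <- build_virtual_frames(frames, N_F = 4, N_O = 2)
  expect_setequal(unlist(attr(ovfs, "members")), frames$frame)  # trailing OVF
  expect_error(build_virtual_frames(frames, N_F = 4, N_O = 4), "overlap")
  expect_error(build_virtual_frames(frames, N_F = 1, N_O = 0), "N_F")
  expect_warning(build_virtual_frames(experimental_frames(c(0.25, 0.75), 0.5),
                                      N_F = 4, N_O = 2), "single")
})

test_that("observations are summed per OVF with quadrature uncertainties", {
  frames <- experimental_frames(seq(0.25, 5.75, by = 0.5), dalpha = 0.5)
  ovfs <- build_virtual_frames(frames, N_F = 4, N_O = 2)
  records <- data.frame(h = 1, k = 0, l = 0, I = c(10, 14), sigma = c(3, 4),
                        frame = c(3, 4))
  # OVFs without any record legitimately warn and are dropped
  obs <- suppressWarnings(assign_observations(records, ovfs))
  # frames 3,4 belong to OVFs 1 and 2: two independent observations
  expect_equal(nrow(obs), 2)
  expect_equal(obs$I_obs, c(24, 24))
  expect_equal(obs$sigma, c(5, 5))
  # non-positive sigma records are rejected
  bad <- rbind(records, data.frame(h = 2, k = 0, l = 0, I = 5, sigma = 0, frame = 3))
  expect_message(obs2 <- suppressWarnings(assign_observations(bad, ovfs)), "rejected")
  expect_equal(nrow(obs2), 2)
})

test_that("the geometric filter computes R_Sg as specified", {
  st <- make_fixture("chiral_org")
  rd <- memo("vf_rd", battery_reduce(st, battery_design(seed = 4, sigma_rel = 0.02)))
  obs <- rd$obs
  # R = |S| / (D + |S|): verify the identity on every observation
  expect_equal(obs$R_Sg, abs(obs$S_v) / (obs$D_Sg + abs(obs$S_v)),
               tolerance = 1e-12)
  # |S| = D -> R = 1/2 (from the formula, on constructed values)
  expect_equal(0.01 / (0.01 + 0.01), 0.5)
  expect_true(all(obs$R_Sg >= 0 & obs$R_Sg < 1))
  # tightening R_max can only shrink the included set (monotonicity)
  n08 <- sum(obs$D_Sg >= 0.002 & obs$R_Sg <= 0.8)
  n065 <- sum(obs$D_Sg >= 0.002 & obs$R_Sg <= 0.65)
  n05 <- sum(obs$D_Sg >= 0.002 & obs$R_Sg <= 0.5)
  expect_true(n08 >= n065 && n065 >= n05)
  # R_Sg monotone: increasing |S| at fixed D increases R
  expect_true(all(diff(sapply(c(0.001, 0.002, 0.004), function(s) s / (0.003 + s))) > 0))
  expect_true(all(diff(sapply(c(0.001, 0.002, 0.004), function(D) 0.002 / (D + 0.002))) < 0))
})

test_that("rocking-curve integration matches a high-resolution quadrature oracle", {
  # constant curve over a window of width w integrates to c * w
  alphas <- seq(0, 2, length.out = 21)
  expect_equal(integrate_calculated(list(alphas = alphas,
                                         intensity = rep(0.3, 21))),
               0.3 * 2 * pi / 180, tolerance = 1e-12)
  # thin-crystal two-beam curve vs analytic integral through dS/dalpha
  K <- relativistic_beam(200)$K
  U <- 0.012; t <- 150
  dSda <- 0.5                       # 1/A per radian, fixed mapping
  a_deg <- seq(-1, 1, length.out = 201)
  Sg <- dSda * a_deg * pi / 180
  xi <- K / U
  curve <- sin(pi * t * sqrt(Sg^2 + 1 / xi^2))^2 / (1 + (Sg * xi)^2)
  got <- integrate_calculated(list(alphas = a_deg, intensity = curve))
  oracle <- stats::integrate(function(a) {
    S <- dSda * a
    sin(pi * t * sqrt(S^2 + 1 / xi^2))^2 / (1 + (S * xi)^2)
  }, -pi / 180, pi / 180, rel.tol = 1e-10)$value
  expect_equal(got, oracle, tolerance = 5e-3)
  # doubling the grid changes the integral by < 0.1%
  a2 <- seq(-1, 1, length.out = 401)
  S2 <- dSda * a2 * pi / 180
  c2 <- sin(pi * t * sqrt(S2^2 + 1 / xi^2))^2 / (1 + (S2 * xi)^2)
  got2 <- integrate_calculated(list(alphas = a2, intensity = c2))
  expect_lt(abs(got2 - got) / got2, 1e-3)
})

test_that("the Lorentz factor equals a finite-difference traversal speed", {
  st <- make_fixture("chiral_org")
  rd <- memo("vf_rd", battery_reduce(st, battery_design(seed = 4, sigma_rel = 0.02)))
  obs <- lorentz_correction(rd$obs[1:40, ], rd$cell, rd$geom, rd$ovfs)
  geom <- rd$geom
  for (i in c(1, 7, 19, 33)) {
    G0 <- recip_cart(rd$cell, c(obs$h[i], obs$k[i], obs$l[i]))
    av <- rd$ovfs$alpha_v[match(obs$vf[i], rd$ovfs$vf)]
    eps <- 1e-4
    Sp <- excitation_error(dyned:::.orientation_matrix(geom, av + eps) %*% G0, geom$beam$K)
    Sm <- excitation_error(dyned:::.orientation_matrix(geom, av - eps) %*% G0, geom$beam$K)
    speed_fd <- abs(Sp - Sm) / (2 * eps * pi / 180)
    expect_equal(1 / obs$lorentz[i], speed_fd, tolerance = 1e-6)
  }
  expect_true(all(is.finite(obs$lorentz) & obs$lorentz > 0))
})

test_that("reflection and virtual-frame files round-trip exactly", {
  st <- make_fixture("chiral_org")
  des <- battery_design(seed = 4, sigma_rel = 0.02, alpha_half = 3, g_res = 0.45)
  ex <- simulate_experiment(st, des)
  path <- tempfile(fileext = ".tsv")
  write_reflections(ex, path)
  back <- read_reflections(path)
  expect_identical(back$records$I, ex$records$I)
  expect_identical(back$records$sigma, ex$records$sigma)
  expect_identical(back$records[, 1:3], ex$records[, 1:3])
  expect_equal(back$geom$R0, ex$geom$R0, tolerance = 0)
  # reduction of the file equals reduction of the in-memory experiment
  rd1 <- reduce_experiment(ex, N_F = 4)
  rd2 <- reduce_experiment(back, cell = back$cell, N_F = 4, opts = back$opts)
  expect_equal(rd2$obs$I_obs, rd1$obs$I_obs, tolerance = 0)
  expect_equal(rd2$obs$included, rd1$obs$included)
  vfp <- tempfile(fileext = ".tsv")
  write_virtual_frames(rd1$ovfs, vfp)
  ov2 <- read_virtual_frames(vfp)
  expect_equal(ov2$alpha_v, rd1$ovfs$alpha_v, tolerance = 0)
  expect_identical(attr(ov2, "members"), attr(rd1$ovfs, "members"))
})
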