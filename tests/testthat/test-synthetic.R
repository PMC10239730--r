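# Synthetic fixtures and the forward simulator.

test_that("fixtures have the advertised symmetry properties", {
  ch <- make_fixture("chiral_org")
  expect_true(ch$sg$sohncke)
  expect_false(ch$sg$centrosymmetric)
  # the inverse is a genuinely different structure (not superposable by a
  # pure translation): inverted coordinates differ from any symmetry image
  inv <- invert_structure(ch)
  expect_gt(bond_length_rmsd(inv, ch) + abs(min_image_dist(
    ch$cell, inv$atoms[[1]]$xyz, ch$atoms[[1]]$xyz)), 1e-3)
  co <- make_fixture("centro_org")
  expect_true(co$sg$centrosymmetric)
  Fc <- structure_factor(co, rbind(c(1, 2, 3), c(2, -1, 4), c(0, 3, 1)))
  expect_lt(max(abs(Im(Fc))), 1e-10)
  qz <- make_fixture("quartz_like")
  # kinematical absences of the 3_2 screw: (0,0,l), l != 3n
  F00l <- Mod(structure_factor(qz, rbind(c(0, 0, 1), c(0, 0, 2), c(0, 0, 4), c(0, 0, 5))))
  expect_lt(max(F00l), 1e-10)
  expect_gt(Mod(structure_factor(qz, c(0, 0, 3))), 0.1)
})

test_that("simulation is deterministic given the seed", {
  st <- make_fixture("chiral_org")
  des <- battery_design(seed = 99, alpha_half = 3, g_res = 0.45)
  p1 <- tempfile(); p2 <- tempfile()
  write_reflections(simulate_experiment(st, des), p1)
  write_reflections(simulate_experiment(st, des), p2)
  expect_identical(readLines(p1), readLines(p2))
  # a different seed changes the noise
  des2 <- battery_design(seed = 100, alpha_half = 3, g_res = 0.45)
  write_reflections(simulate_experiment(st, des2), p2)
  expect_false(identical(readLines(p1), readLines(p2)))
})

test_that("noise realizations match the stated variance model", {
  st <- make_fixture("chiral_org")
  # many repeated noisy draws of the same underlying experiment
  zs <- c()
  for (r in 1:15) {
    des <- experiment_design(alpha_range = c(-3, 3), dalpha = 0.5,
                             thickness = 500, gain = 2, sigma_add = 3,
                             sigma_rel = 0.02, drift_amp = 0,
                             misorientation_deg = 0, seed = 500 + r,
                             g_res = 0.45, s_beam = 0.008, g_beam = 0.6,
                             m = 2, R0 = diag(3))
    ex <- simulate_experiment(st, des)
    keep <- ex$truth$I_clean > 20   # Gaussian regime of the Poisson part
    zs <- c(zs, (ex$records$I[keep] - ex$truth$I_clean[keep]) /
              ex$records$sigma[keep])
  }
  expect_gt(length(zs), 1000)
  # standardized residual variance within 10% of 1
  expect_lt(abs(sd(zs) - 1), 0.1)
  expect_lt(abs(mean(zs)), 0.05)
})

test_that("thin crystals are kinematical and thick ones are not", {
  st <- make_fixture("chiral_org")
  beam <- relativistic_beam(200)
  # full per-pass rocking integrals vs the kinematical sinc^2 prediction
  # over the same recorded support
  cors <- sapply(c(40, 500), function(tt) {
    des <- battery_design(seed = 77, sigma_rel = 0, gain = 0, sigma_add = 0,
                          drift_amp = 0, thickness = tt)
    ex <- simulate_experiment(st, des)
    tot <- aggregate(I ~ h + k + l + pass, data = ex$records, FUN = sum)
    K <- beam$K
    hkl <- as.matrix(tot[, c("h", "k", "l")])
    Ug <- Mod(beam$gamma_rel * structure_factor(st, hkl) / (pi * st$cell$volume))
    pred <- vapply(seq_len(nrow(tot)), function(i) {
      rec <- ex$records[ex$records$pass == tot$pass[i], ]
      G0 <- recip_cart(st$cell, hkl[i, ])
      S <- vapply(rec$alpha, function(a)
        excitation_error(dyned:::.orientation_matrix(ex$geom, a) %*% G0, K), 0)
      x <- pi * S * tt
      sinc2 <- ifelse(abs(x) < 1e-12, 1, (sin(x) / x)^2)
      (pi * tt * Ug[i] / K)^2 * sum(sinc2) * des$dalpha * pi / 180
    }, 0)
    # amplitude correlation, the standard F_obs-vs-F_calc comparison
    cor(sqrt(tot$I), sqrt(pred))
  })
  expect_gt(cors[1], 0.99)  # t = 40 A: kinematical regime
  expect_lt(cors[2], 0.95)  # t = 500 A: dynamical deviations present
})

test_that("Bijvoet pairs are dynamically inequivalent in the chiral fixture", {
  st <- make_fixture("chiral_org")
  des <- battery_design(seed = 55, sigma_rel = 0, gain = 0, sigma_add = 0,
                        drift_amp = 0, thickness = 500)
  ex <- simulate_experiment(st, des)
  # full rocking integral per reflection pass (noiseless, drift-free)
  tot <- aggregate(I ~ h + k + l + pass, data = ex$records, FUN = sum)
  # one value per reflection: strongest pass
  tot <- tot[order(-tot$I), ]
  tot <- tot[!duplicated(tot[, c("h", "k", "l")]), ]
  key <- paste(tot$h, tot$k, tot$l)
  mate <- match(paste(-tot$h, -tot$k, -tot$l), key)
  ok <- which(!is.na(mate) & seq_along(mate) < mate & tot$I > 1e-3 * max(tot$I))
  asym <- abs(tot$I[ok] - tot$I[mate[ok]]) /
    (0.5 * (tot$I[ok] + tot$I[mate[ok]]))
  expect_gt(length(asym), 10)
  # at t = 500 A a sizeable fraction of pairs differ well beyond noise
  expect_gt(mean(asym > 0.05), 0.10)
  # kinematically the same pairs are identical
  hkl <- as.matrix(tot[ok, c("h", "k", "l")])
  expect_equal(Mod(structure_factor(st, hkl)),
               Mod(structure_factor(st, -hkl)), tolerance = 1e-12)
})

test_that("zero-noise zero-drift data refined with the true model is exact", {
  st <- make_fixture("chiral_org")
  rd <- memo("ref_rd_noiseless", battery_reduce(st, battery_design(
    seed = 9, sigma_rel = 0, gain = 0, sigma_add = 0, drift_amp = 0)))
  res <- run_least_squares(rd, st,
                           spec = refine_spec(coords = FALSE, thickness = TRUE,
                                              scales = TRUE),
                           engine = memo("ref_eng_noiseless", dyned:::.make_engine(rd)))
  expect_lt(res$rfactors$wR_all, 1e-6)
})
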