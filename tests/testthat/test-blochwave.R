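# Dynamical diffraction engine: excitation errors, beam selection,
# propagation, rocking curves.

test_that("excitation error matches independent arithmetic", {
  K <- 40
  expect_equal(excitation_error(c(0, 0, 0), K), 0)
  # a point exactly on the Ewald sphere (|k+g| = K by construction):
  # g = K (sin phi, 0, 1 - cos phi) for incident k = (0, 0, -K)
  phi <- 0.02
  g_on <- K * c(sin(phi), 0, 1 - cos(phi))
  expect_lt(abs(excitation_error(g_on, K)), 1e-12)
  set.seed(1)
  for (i in 1:50) {
    g <- rnorm(3, 0, 0.5)
    kv <- c(0, 0, -K)
    brute <- (K - sqrt(sum((kv + g)^2))) * (K + sqrt(sum((kv + g)^2))) / (2 * K)
    expect_lt(abs(excitation_error(g, K) - brute), 1e-12)
  }
})

test_that("beam selection reproduces a brute-force enumeration on a cubic cell", {
  cl <- unit_cell(4, 4, 4)
  st <- crystal_structure(cl, space_group("P1"),
                          list(atom_site("C1", "C", c(0.1, 0.2, 0.3), uiso = 0.01)))
  beam <- relativistic_beam(200)
  geom <- experiment_geometry(beam)
  g_max <- 1; s_max <- 0.1
  bs <- select_beams(st, geom, alpha = 10, g_max = g_max, s_max = s_max)
  # exhaustive loop oracle over the index box
  cnt <- 1
  for (h in -6:6) for (k in -6:6) for (l in -6:6) {
    if (h == 0 && k == 0 && l == 0) next
    g <- drop(dyned:::.orientation_matrix(geom, 10) %*% recip_cart(cl, c(h, k, l)))
    if (sqrt(sum(g^2)) <= g_max && abs(excitation_error(g, beam$K)) <= s_max)
      cnt <- cnt + 1
  }
  expect_equal(nrow(bs$hkl), cnt)
  expect_equal(bs$hkl[1, ], c(0L, 0L, 0L))
  expect_equal(bs$S[1], 0)
  # g_max -> 0 leaves only the transmitted beam
  expect_equal(nrow(select_beams(st, geom, 10, g_max = 1e-6, s_max = 0.1)$hkl), 1)
  # centrosymmetric structure: all potential coefficients real
  stc <- make_fixture("centro_org")
  bsc <- select_beams(stc, experiment_geometry(beam), 5, 0.7, 0.02)
  expect_lt(max(abs(Im(bsc$Aoff))), 1e-12)
  # beam cap triggers an actionable error
  expect_error(select_beams(st, geom, 10, 1.5, 0.5, max_beams = 10), "cap")
})

test_that("two-beam propagation matches the closed-form Pendelloesung", {
  K <- relativistic_beam(200)$K
  U <- 0.015 * exp(0.7i)
  hkl <- rbind(c(0L, 0L, 0L), c(1L, 0L, 0L))
  set.seed(7)
  for (i in 1:25) {
    S <- runif(1, -0.01, 0.01)
    t <- runif(1, 20, 3000)
    bs <- beam_set_manual(hkl, c(0, S), c(0i, U), K)
    I <- propagate(bs, t)
    xi <- K / Mod(U)
    seff <- sqrt(S^2 + 1 / xi^2)
    Ith <- sin(pi * t * seff)^2 / (1 + (S * xi)^2)
    expect_equal(unname(I[2]), Ith, tolerance = 1e-8)
    expect_equal(unname(sum(I)), 1, tolerance = 1e-10)
  }
  # t = 0: all intensity in the transmitted beam
  bs <- beam_set_manual(hkl, c(0, 0.003), c(0i, U), K)
  I0 <- propagate(bs, 0)
  expect_equal(unname(I0), c(1, 0), tolerance = 1e-14)
})

test_that("intensity is conserved for multi-beam propagation", {
  st <- make_fixture("chiral_org")
  geom <- experiment_geometry(relativistic_beam(200))
  set.seed(3)
  for (i in 1:8) {
    bs <- select_beams(st, geom, alpha = runif(1, -60, 60),
                       g_max = 0.7, s_max = 0.01)
    I <- propagate(bs, runif(1, 50, 1500))
    expect_equal(unname(sum(I)), 1, tolerance = 1e-10)
  }
})

test_that("rocking curves are consistent with single-orientation propagation", {
  st <- make_fixture("chiral_org")
  geom <- experiment_geometry(relativistic_beam(200))
  # find an orientation where (1,1,1) is near the Bragg condition
  G0 <- recip_cart(st$cell, c(1, 1, 1))
  alphas <- seq(-60, 60, by = 0.2)
  S <- vapply(alphas, function(a)
    excitation_error(dyned:::.orientation_matrix(geom, a) %*% G0, geom$beam$K), 0)
  a0 <- alphas[which.min(abs(S))]
  grid <- seq(a0 - 0.5, a0 + 0.5, length.out = 11)
  rc <- rocking_curve(st, geom, c(1, 1, 1), grid, t = 400,
                      g_max = 0.7, s_max = 0.01)
  expect_true(all(rc$intensity >= 0 & rc$intensity <= 1))
  # thickness 0 gives an identically zero curve
  rc0 <- rocking_curve(st, geom, c(1, 1, 1), grid, t = 0,
                       g_max = 0.7, s_max = 0.01)
  expect_equal(max(rc0$intensity), 0, tolerance = 1e-14)
  # two-beam fixture: curve maximum at S = 0 for t below xi/2
  K <- geom$beam$K
  U <- 0.012
  Sgrid <- seq(-0.004, 0.004, length.out = 41)
  I2 <- vapply(Sgrid, function(S) {
    bs <- beam_set_manual(rbind(c(0L, 0L, 0L), c(1L, 0L, 0L)), c(0, S), c(0i, U + 0i), K)
    unname(propagate(bs, 800)[2])   # t < xi/2 = K/U/2 ~ 1660 A
  }, 0)
  expect_equal(which.max(I2), which.min(abs(Sgrid)))
})
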