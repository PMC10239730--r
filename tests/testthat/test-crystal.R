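# Crystallographic core: cells, symmetry, scattering factors, structure
# factors, inversion.

test_that("relativistic electron wavelength matches the closed-form oracle", {
  # independent evaluation of lambda = h/sqrt(2 m0 e V (1 + eV/2m0c^2))
  oracle <- function(kV) {
    h <- 6.62607015e-34; m0 <- 9.1093837015e-31
    e <- 1.602176634e-19; cc <- 299792458; V <- kV * 1e3
    1e10 * h / sqrt(2 * m0 * e * V * (1 + e * V / (2 * m0 * cc^2)))
  }
  expect_equal(relativistic_beam(200)$lambda, oracle(200), tolerance = 1e-12)
  expect_equal(relativistic_beam(300)$lambda, oracle(300), tolerance = 1e-12)
  # frozen values from the oracle
  expect_equal(relativistic_beam(200)$lambda, 0.02507934, tolerance = 1e-6)
  expect_equal(relativistic_beam(300)$lambda, 0.01968749, tolerance = 1e-6)
  expect_lt(relativistic_beam(400)$lambda, relativistic_beam(200)$lambda)
  expect_gte(relativistic_beam(100)$gamma_rel, 1)
  expect_error(relativistic_beam(-5), "positive")
})

test_that("cell volume, metric tensor and reciprocal basis are mutually consistent", {
  set.seed(42)
  for (i in 1:200) {
    repeat {
      ang <- runif(3, 60, 120)
      ok <- try(unit_cell(runif(1, 3, 20), runif(1, 3, 20), runif(1, 3, 20),
                          ang[1], ang[2], ang[3]), silent = TRUE)
      if (!inherits(ok, "try-error")) break
    }
    cl <- ok
    # volume from the direct basis determinant
    expect_equal(det(cl$A), cl$volume, tolerance = 1e-10)
    # d-spacing two ways: metric tensor vs explicit reciprocal basis
    h <- matrix(sample(-6:6, 9, replace = TRUE), 3)
    h <- h[rowSums(abs(h)) > 0, , drop = FALSE]
    if (!nrow(h)) next
    d1 <- d_spacing(cl, h)
    d2 <- 1 / sqrt(colSums(recip_cart(cl, h)^2))
    expect_equal(d1, d2, tolerance = 1e-10)
  }
})

test_that("form factors follow the packaged Gaussian parameterization", {
  tab <- scattering_table()
  for (el in tab$element) {
    # f(0) = sum of a_i by construction
    expect_equal(form_factor(el, 0),
                 sum(tab[tab$element == el, paste0("a", 1:5)]))
    # monotone non-increasing on [0, 1.5]
    s <- seq(0, 1.5, by = 0.01)
    expect_true(all(diff(form_factor(el, s)) <= 1e-12))
  }
  # carbon at s = 0.5: independent summation of the Gaussian terms
  cfs <- tab[tab$element == "C", ]
  f_direct <- sum(vapply(1:5, function(k)
    cfs[[paste0("a", k)]] * exp(-cfs[[paste0("b", k)]] * 0.25), 0))
  expect_equal(form_factor("C", 0.5), f_direct, tolerance = 1e-12)
  expect_error(form_factor("Xx", 0.1), "tabulated")
})

test_that("structure factors agree with a brute-force direct summation", {
  cl <- unit_cell(6, 8, 10)
  sg <- space_group("P212121")
  atoms <- list(atom_site("C1", "C", c(0.12, 0.23, 0.34), uiso = 0.02),
                atom_site("N1", "N", c(0.45, 0.11, 0.78), uiso = 0.015),
                atom_site("O1", "O", c(0.81, 0.62, 0.05), uiso = 0.025),
                atom_site("H1", "H", c(0.60, 0.40, 0.20), uiso = 0.03),
                atom_site("S1", "S", c(0.25, 0.85, 0.55), uiso = 0.012))
  st <- crystal_structure(cl, sg, atoms)
  hkl <- rbind(c(1, 2, 3), c(2, 0, 1), c(-3, 1, 2), c(1, 1, 1), c(4, -2, 5))
  Fpkg <- structure_factor(st, hkl)
  Fbrute <- vapply(seq_len(nrow(hkl)), function(i) {
    h <- hkl[i, ]
    s <- 1 / (2 * d_spacing(cl, h))
    tot <- 0 + 0i
    for (at in atoms) for (op in sg$ops) {
      r <- (op$R %*% at$xyz + op$t) %% 1
      tot <- tot + at$occ * form_factor(at$element, s) *
        exp(-8 * pi^2 * at$uiso * s^2) * exp(2i * pi * sum(h * r))
    }
    tot
  }, complex(1))
  expect_equal(Fpkg, Fbrute, tolerance = 1e-12)
  # Friedel identity |F(h)| = |F(-h)| for real form factors
  expect_equal(Mod(structure_factor(st, hkl)),
               Mod(structure_factor(st, -hkl)), tolerance = 1e-12)
  # single atom at origin with U = 0: F = f(s) for every h
  st1 <- crystal_structure(cl, space_group("P1"),
                           list(atom_site("C1", "C", c(0, 0, 0), uiso = 0)))
  for (h in list(c(1, 0, 0), c(2, 3, 1))) {
    expect_equal(structure_factor(st1, h) + 0i,
                 form_factor("C", 1 / (2 * d_spacing(cl, h))) + 0i,
                 tolerance = 1e-12)
  }
  # centrosymmetric pair: F = 2 f T cos(2 pi h.r), zero imaginary part
  r0 <- c(0.13, 0.27, 0.41)
  stc <- crystal_structure(cl, space_group("P1"),
                           list(atom_site("C1", "C", r0, uiso = 0.01),
                                atom_site("C2", "C", -r0, uiso = 0.01)))
  h <- c(2, -1, 3)
  s <- 1 / (2 * d_spacing(cl, h))
  expect_equal(structure_factor(stc, h) + 0i,
               2 * form_factor("C", s) * exp(-8 * pi^2 * 0.01 * s^2) *
                 cos(2 * pi * sum(h * r0)) + 0i,
               tolerance = 1e-10)
})

test_that("Laue orbits have the expected sizes", {
  expect_equal(nrow(laue_equivalents(c(1, 2, 3), space_group("P1"))), 2)
  expect_setequal(apply(laue_equivalents(c(1, 2, 3), space_group("P-1")), 1, paste,
                        collapse = ","), c("1,2,3", "-1,-2,-3"))
  expect_equal(nrow(laue_equivalents(c(1, 2, 3), space_group("P21/n"))), 4)
  # Laue class of P6522 (6/mmm): general orbit size 24 by enumeration
  sg <- space_group("P6522")
  expect_equal(length(sg$laue_ops), 24)
  expect_equal(nrow(laue_equivalents(c(1, 2, 3), sg)), 24)
})

test_that("inversion swaps enantiomorphic space groups and is an involution", {
  st <- make_fixture("chiral_org")
  sti <- invert_structure(st)
  expect_equal(sti$sg$symbol, "P212121")
  for (i in seq_along(st$atoms)) {
    expect_equal(sti$atoms[[i]]$xyz, (-st$atoms[[i]]$xyz) %% 1)
  }
  # enantiomorphic pair
  hex <- crystal_structure(unit_cell(12, 12, 9, 90, 90, 120), space_group("P6122"),
                           list(atom_site("Si1", "Si", c(0.23, 0.41, 0.07), uiso = 0.01)))
  expect_equal(invert_structure(hex)$sg$symbol, "P6522")
  expect_equal(invert_structure(invert_structure(hex))$sg$symbol, "P6122")
  # double inversion preserves the bond-length set
  st2 <- invert_structure(invert_structure(st))
  expect_equal(sort(bond_list(st2)$length), sort(bond_list(st)$length),
               tolerance = 1e-12)
  # centrosymmetric input warns
  expect_warning(invert_structure(make_fixture("centro_org")), "centrosymmetric")
})

test_that("symmetry expansion rejects colliding sites", {
  cl <- unit_cell(6, 8, 10)
  expect_error(
    crystal_structure(cl, space_group("P212121"),
                      list(atom_site("C1", "C", c(0.10, 0.10, 0.10)),
                           atom_site("C2", "C", c(0.101, 0.10, 0.10)))),
    "collision")
})

test_that("CIF files round-trip cell, symmetry and sites", {
  st <- make_fixture("chiral_org")
  path <- tempfile(fileext = ".cif")
  write_cif(st, path)
  st2 <- read_cif(path)
  expect_equal(st2$cell$volume, st$cell$volume, tolerance = 1e-6)
  expect_equal(length(st2$sg$ops), length(st$sg$ops))
  expect_equal(length(st2$atoms), length(st$atoms))
  for (i in seq_along(st$atoms)) {
    expect_equal(st2$atoms[[i]]$xyz, st$atoms[[i]]$xyz, tolerance = 1e-6)
    expect_equal(st2$atoms[[i]]$uiso, st$atoms[[i]]$uiso, tolerance = 1e-6)
    expect_equal(st2$atoms[[i]]$element, st$atoms[[i]]$element)
  }
  # structure factors agree after the round trip
  h <- rbind(c(1, 2, 3), c(2, 1, 0))
  expect_equal(Mod(structure_factor(st2, h)), Mod(structure_factor(st, h)),
               tolerance = 1e-4)
})
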