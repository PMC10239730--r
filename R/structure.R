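#' Atom site
#'
#' One site of the asymmetric unit. Fractional coordinates are reduced to
#' [0,1). Displacement is isotropic (`uiso`, Angstrom^2) unless a 3x3
#' anisotropic `uani` tensor (Angstrom^2, must be positive semi-definite) is
#' supplied. Riding-hydrogen constraints reference a parent atom label and a
#' target distance.
#'
#' @param label unique site label, e.g. `"C1"`.
#' @param element element symbol.
#' @param xyz fractional coordinates (length 3).
#' @param occ occupancy in [0,1].
#' @param uiso isotropic displacement parameter in Angstrom^2 (>= 0).
#' @param uani optional 3x3 anisotropic U tensor (Angstrom^2).
#' @param riding optional list `list(parent =, dist =)` marking the site as a
#'   hydrogen riding on `parent` at `dist` Angstrom.
#' @return `ded_atom` list.
#' @export
atom_site <- function(label, element, xyz, occ = 1, uiso = 0.01,
                      uani = NULL, riding = NULL) {
  if (occ < 0 || occ > 1) stop("occupancy must lie in [0,1]")
  if (uiso < 0) stop("uiso must be >= 0")
  if (!is.null(uani)) {
    uani <- (uani + t(uani)) / 2
    if (min(eigen(uani, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
      stop("anisotropic U tensor must be positive semi-definite")
  }
  list(label = label, element = element, xyz = as.numeric(xyz) %% 1,
       occ = occ, uiso = uiso, uani = uani, riding = riding)
}

#' Crystal structure
#'
#' Bundles a unit cell, space-group setting and the asymmetric unit. On
#' construction the symmetry expansion is checked for site collisions: no two
#' expanded positions may fall closer than 0.1 Angstrom unless they are
#' images of the same site (special positions are allowed and their
#' duplicate images removed with a multiplicity correction absorbed into the
#' stored per-site image list).
#'
#' @param cell a [unit_cell()].
#' @param sg a [space_group()] (or symbol passed through to it).
#' @param atoms list of [atom_site()]s.
#' @return `ded_structure`.
#' @export
crystal_structure <- function(cell, sg, atoms) {
  if (is.character(sg)) sg <- space_group(sg)
  labels <- vapply(atoms, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("duplicate atom labels")
  st <- structure(list(cell = cell, sg = sg, atoms = atoms),
                  class = "ded_structure")
  ex <- expand_sites(st)
  # collision check between images of different sites
  n <- nrow(ex$frac)
  if (n > 1) {
    cart <- t(cell$A %*% t(ex$frac))
    for (i in seq_len(n - 1)) {
      dfrac <- ex$frac[(i + 1):n, , drop = FALSE]
      dfrac <- sweep(dfrac, 2, ex$frac[i, ])
      dfrac <- dfrac - round(dfrac)       # minimum image
      dc <- t(cell$A %*% t(dfrac))
      dd <- sqrt(rowSums(dc^2))
      bad <- which(dd < 0.1 & ex$site[(i + 1):n] != ex$site[i])
      if (length(bad)) {
        stop(sprintf("site collision: %s and %s are %.3f A apart",
                     labels[ex$site[i]], labels[ex$site[i + bad[1]]],
                     dd[bad[1]]))
      }
    }
  }
  st
}

#' Symmetry-expand the asymmetric unit
#'
#' Applies all space-group operations to every site, removing duplicate
#' images of the same site on special positions (closer than 0.01 Angstrom
#' after reduction).
#'
#' @param st a [crystal_structure()].
#' @return list with `frac` (n x 3 fractional coordinates), `site` (index
#'   into `st$atoms` for each image), `occ`, `uiso`, `element`.
#' @export
expand_sites <- function(st) {
  frac <- NULL; site <- integer(0)
  for (ia in seq_along(st$atoms)) {
    at <- st$atoms[[ia]]
    imgs <- t(vapply(st$sg$ops, function(op) (op$R %*% at$xyz + op$t) %% 1,
                     numeric(3)))
    keep <- rep(TRUE, nrow(imgs))
    for (i in seq_len(nrow(imgs))) {
      if (!keep[i]) next
      if (i < nrow(imgs)) {
        d <- sweep(imgs[(i + 1):nrow(imgs), , drop = FALSE], 2, imgs[i, ])
        d <- d - round(d)
        dc <- t(st$cell$A %*% t(d))
        keep[(i + 1):nrow(imgs)][sqrt(rowSums(dc^2)) < 0.01] <- FALSE
      }
    }
    imgs <- imgs[keep, , drop = FALSE]
    frac <- rbind(frac, imgs)
    site <- c(site, rep(ia, nrow(imgs)))
  }
  list(frac = frac, site = site,
       occ = vapply(st$atoms, `[[`, 0, "occ")[site],
       uiso = vapply(st$atoms, `[[`, 0, "uiso")[site],
       element = vapply(st$atoms, `[[`, "", "element")[site])
}

#' Kinematical structure factor
#'
#' \eqn{F_h = \sum_j occ_j f_j(s) T_j(s) \exp(+2\pi i\, h\cdot r_j)} over all
#' symmetry-expanded sites, with \eqn{s = 1/(2d)} and Debye-Waller factor
#' \eqn{T_j = \exp(-8\pi^2 U_{iso,j} s^2)} (anisotropic form
#' \eqn{\exp(-2\pi^2 \sum U^{ij} h_i h_j a^*_i a^*_j)} when a U tensor is
#' present). Electron form factors come from the packaged table.
#'
#' @param st a [crystal_structure()].
#' @param hkl integer triple or matrix of reflections in rows.
#' @return complex structure factor(s) in Angstrom.
#' @export
structure_factor <- function(st, hkl) {
  h <- if (is.matrix(hkl)) hkl else matrix(hkl, nrow = 1)
  ex <- expand_sites(st)
  s <- 1 / (2 * d_spacing(st$cell, h))
  cf <- .sf_coeffs(ex$element)
  # f: nref x nsite
  f <- matrix(0, nrow(h), nrow(ex$frac))
  for (k in 1:5) f <- f + outer(s^2, cf$b[, k], function(ss, b) exp(-b * ss)) *
      matrix(cf$a[, k], nrow(h), nrow(ex$frac), byrow = TRUE)
  anis <- vapply(seq_along(ex$site), function(i) !is.null(st$atoms[[ex$site[i]]]$uani), TRUE)
  Tw <- exp(-8 * pi^2 * outer(s^2, ex$uiso))
  if (any(anis)) {
    astar <- sqrt(diag(st$cell$Gstar))
    for (i in which(anis)) {
      U <- st$atoms[[ex$site[i]]]$uani
      hs <- sweep(h, 2, astar, `*`)
      Tw[, i] <- exp(-2 * pi^2 * rowSums((hs %*% U) * hs))
    }
  }
  phase <- exp(2i * pi * (h %*% t(ex$frac)))
  drop((f * Tw * phase) %*% ex$occ)
}

#' Invert a structure through the origin
#'
#' Negates all fractional coordinates (modulo 1) and, when the space group
#' has an enantiomorphic partner, replaces the group by that partner (e.g.
#' P6122 <-> P6522); otherwise the group is kept. Applying the operation
#' twice returns a structure equivalent to the input. For centrosymmetric
#' input the inversion is a symmetry operation and a warning is raised --
#' comparing the two "enantiomorphs" is then meaningless.
#'
#' @param st a [crystal_structure()].
#' @return the inverted `ded_structure`.
#' @export
invert_structure <- function(st) {
  if (st$sg$centrosymmetric) {
    warning("structure is centrosymmetric; inversion is a symmetry operation")
  }
  sg2 <- if (!is.na(st$sg$enantiomorph_partner)) {
    space_group(st$sg$enantiomorph_partner)
  } else st$sg
  atoms2 <- lapply(st$atoms, function(at) {
    at$xyz <- (-at$xyz) %% 1
    at
  })
  crystal_structure(st$cell, sg2, atoms2)
}

#' @export
print.ded_structure <- function(x, ...) {
  cat(sprintf("crystal structure: %d site(s) in %s,\n  ",
              length(x$atoms), x$sg$symbol))
  print(x$cell)
  invisible(x)
}

#' Covalent bond list of a structure
#'
#' Bonds between non-hydrogen sites of the asymmetric unit (minimum-image
#' convention), using a covalent-radius sum + 0.45 Angstrom cutoff.
#'
#' @param st a [crystal_structure()].
#' @return data.frame with columns `a`, `b` (labels) and `length` (Angstrom).
#' @export
bond_list <- function(st) {
  radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57, Na = 1.66,
             Al = 1.21, Si = 1.11, P = 1.07, S = 1.05, Co = 1.26)
  ats <- Filter(function(a) a$element != "H", st$atoms)
  n <- length(ats)
  out <- list()
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d <- ats[[j]]$xyz - ats[[i]]$xyz
      d <- d - round(d)
      len <- sqrt(sum((st$cell$A %*% d)^2))
      cutoff <- radii[[ats[[i]]$element]] + radii[[ats[[j]]$element]] + 0.45
      if (len <= cutoff) {
        out[[length(out) + 1]] <- data.frame(a = ats[[i]]$label,
                                             b = ats[[j]]$label,
                                             length = len)
      }
    }
  }
  if (!length(out)) return(data.frame(a = character(), b = character(),
                                      length = numeric()))
  do.call(rbind, out)
}

#' RMS deviation of covalent bond lengths between two models
#'
#' Computes the bond list of the reference model and re-measures the same
#' label pairs in `model`; errors if a label is missing.
#'
#' @param model,reference two [crystal_structure()]s with matched labelling.
#' @return RMSD in Angstrom over the common bond set.
#' @export
bond_length_rmsd <- function(model, reference) {
  ref_bonds <- bond_list(reference)
  if (!nrow(ref_bonds)) stop("reference model has no covalent bonds")
  labs <- vapply(model$atoms, `[[`, "", "label")
  missing <- setdiff(unique(c(ref_bonds$a, ref_bonds$b)), labs)
  if (length(missing)) stop("model lacks atoms present in reference: ",
                            paste(missing, collapse = ", "))
  dev <- mapply(function(a, b, lref) {
    ia <- match(a, labs); ib <- match(b, labs)
    d <- model$atoms[[ib]]$xyz - model$atoms[[ia]]$xyz
    d <- d - round(d)
    sqrt(sum((model$cell$A %*% d)^2)) - lref
  }, ref_bonds$a, ref_bonds$b, ref_bonds$length)
  sqrt(mean(dev^2))
}
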