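# Hydrogen bond-length analysis: electrostatic-potential maxima of X-H
# bonds do not coincide with the internuclear distance, so the constrained
# riding distance is scanned and the wR minimum located.

#' Reference riding-hydrogen distances (Angstrom)
#'
#' Internuclear X-H distances from neutron-diffraction statistics, per bond
#' class; used as the default riding target distances.
#'
#' @return named numeric vector for classes `C-H`, `N-H`, `O-H`.
#' @export
riding_reference_distances <- function() {
  c("C-H" = 1.083, "N-H" = 1.009, "O-H" = 0.983)
}

#' Attach riding constraints to free hydrogen atoms
#'
#' Hydrogens without a riding constraint (e.g. after reading a CIF, which
#' does not carry constraint metadata) are tied to their nearest non-H
#' atom at the reference distance of the corresponding bond class.
#'
#' @param st a [crystal_structure()].
#' @return the structure with riding constraints on all hydrogens.
#' @export
assign_riding <- function(st) {
  refs <- riding_reference_distances()
  heavy <- which(vapply(st$atoms, function(a) a$element != "H", TRUE))
  for (i in seq_along(st$atoms)) {
    at <- st$atoms[[i]]
    if (at$element != "H" || !is.null(at$riding)) next
    d <- vapply(heavy, function(j) {
      dd <- at$xyz - st$atoms[[j]]$xyz
      dd <- dd - round(dd)
      sqrt(sum((st$cell$A %*% dd)^2))
    }, 0)
    j <- heavy[which.min(d)]
    cls <- paste0(st$atoms[[j]]$element, "-H")
    dist <- if (cls %in% names(refs)) refs[[cls]] else refs[["C-H"]]
    st$atoms[[i]]$riding <- list(parent = st$atoms[[j]]$label, dist = dist)
  }
  st
}

#' Scan the riding-hydrogen distance offset
#'
#' Re-refines the non-hydrogen model for each offset Delta-l applied to the
#' riding hydrogens of the requested bond class and records wR_all; the
#' minimizing offset is estimated by a parabola through the grid minimum
#' and its neighbours.
#'
#' @param rd a [reduce_experiment()] result.
#' @param st0 converged starting model with riding hydrogens.
#' @param bond_class one of `"C-H"`, `"N-H"`, `"O-H"`, or `"all"`.
#' @param dl_grid offsets in Angstrom.
#' @param spec refinement parameters for the re-refinements (default:
#'   scales and thickness only, the quick scan mode).
#' @param options,engine passed to [run_least_squares()].
#' @return `ded_hscan`: data.frame `dl`, `wR_all`, `converged`; attributes
#'   `dl_min` (parabola minimum) and `bond_class`.
#' @export
hydrogen_distance_scan <- function(rd, st0, bond_class = "all",
                                   dl_grid = seq(-0.06, 0.06, by = 0.02),
                                   spec = refine_spec(coords = FALSE,
                                                      thickness = TRUE,
                                                      scales = TRUE),
                                   options = list(), engine = NULL) {
  eng <- if (is.null(engine)) .make_engine(rd) else engine
  labs <- vapply(st0$atoms, `[[`, "", "label")
  sel_class <- function(at) {
    if (is.null(at$riding)) return(FALSE)
    if (bond_class == "all") return(TRUE)
    parent <- st0$atoms[[match(at$riding$parent, labs)]]
    paste0(parent$element, "-H") == bond_class
  }
  hsel <- vapply(st0$atoms, sel_class, TRUE)
  if (!any(hsel)) stop("no riding hydrogens of class ", bond_class)
  out <- data.frame(dl = dl_grid, wR_all = NA_real_, converged = NA)
  t0 <- NULL; s0 <- NULL
  for (i in seq_along(dl_grid)) {
    res <- tryCatch(
      run_least_squares(rd, st0, spec = spec, dl = dl_grid[i],
                        t0 = t0, scales0 = s0, options = options,
                        engine = eng),
      error = function(e) NULL)
    if (is.null(res)) next
    out$wR_all[i] <- res$rfactors$wR_all
    out$converged[i] <- res$converged
    t0 <- res$thickness; s0 <- res$scales
  }
  ok <- which(!is.na(out$wR_all))
  imin <- ok[which.min(out$wR_all[ok])]
  dl_min <- out$dl[imin]
  if (imin > 1 && imin < nrow(out) &&
      !is.na(out$wR_all[imin - 1]) && !is.na(out$wR_all[imin + 1])) {
    y <- out$wR_all[(imin - 1):(imin + 1)]
    x <- out$dl[(imin - 1):(imin + 1)]
    denom <- y[1] - 2 * y[2] + y[3]
    h <- (x[3] - x[1]) / 2
    if (denom > 0) dl_min <- x[2] + h * (y[1] - y[3]) / (2 * denom)
  }
  structure(out, dl_min = dl_min, bond_class = bond_class,
            class = c("ded_hscan", "data.frame"))
}
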