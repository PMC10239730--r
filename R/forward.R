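# Shared forward model of a continuous-rotation experiment.
#
# A "pass" is one traversal of a reflection through (or near) the Ewald
# sphere: a maximal contiguous run of frames on which |S_g| stays below the
# recording cutoff. The Bloch-wave beam set of a pass is selected once, at
# the exact Bragg-crossing orientation of the pass (refined by bisection),
# and held fixed while the rocking curve is sampled across the pass. The
# simulator and the refinement both evaluate intensities through this very
# machinery, so a model evaluated at the simulation truth reproduces the
# noiseless observations except for quadrature-grid differences.

#' Enumerate reflection passes of a rotation experiment
#'
#' @param cell a [unit_cell()].
#' @param geom a [experiment_geometry()].
#' @param frames a [experimental_frames()] table.
#' @param g_res resolution cutoff for recorded reflections (1/Angstrom).
#' @param S_record excitation-error recording cutoff (1/Angstrom): a
#'   reflection is considered on a frame while |S_g| at the frame center is
#'   below this value.
#' @return list of passes: `hkl`, `alpha_star` (degrees), `frames`
#'   (contributing frame ids).
#' @export
find_passes <- function(cell, geom, frames, g_res = 0.8, S_record = 0.03) {
  hkl <- .hkl_sphere(cell, g_res)
  G0 <- recip_cart(cell, hkl)
  smat <- matrix(.excitation_grid(geom, G0, frames$alpha), nrow = ncol(G0))
  passes <- list()
  Sfun <- function(i) {
    g2 <- sum(G0[, i]^2)
    function(a) {
      gl <- .orientation_matrix(geom, a) %*% G0[, i, drop = FALSE]
      gl[3] - g2 / (2 * geom$beam$K)
    }
  }
  for (i in seq_len(nrow(hkl))) {
    inside <- abs(smat[i, ]) <= S_record
    if (!any(inside)) next
    r <- rle(inside)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      fr <- starts[j]:ends[j]
      svals <- smat[i, fr]
      sf <- Sfun(i)
      cross <- which(diff(sign(svals)) != 0)
      if (length(cross)) {
        lo <- frames$alpha[fr[cross[1]]]; hi <- frames$alpha[fr[cross[1] + 1]]
        for (it in 1:48) {
          mid <- (lo + hi) / 2
          if (sign(sf(mid)) == sign(sf(lo))) lo <- mid else hi <- mid
        }
        a_star <- (lo + hi) / 2
      } else {
        a_star <- frames$alpha[fr[which.min(abs(svals))]]
      }
      passes[[length(passes) + 1]] <- list(hkl = hkl[i, ], alpha_star = a_star,
                                           frames = frames$frame[fr])
    }
  }
  passes
}

# all lattice points with 0 < |g| <= g_max
.hkl_sphere <- function(cell, g_max) {
  hmax <- ceiling(g_max * c(cell$a, cell$b, cell$c)) + 1
  grid <- as.matrix(expand.grid(-hmax[1]:hmax[1], -hmax[2]:hmax[2], -hmax[3]:hmax[3]))
  colnames(grid) <- NULL
  grid <- grid[rowSums(abs(grid)) > 0, , drop = FALSE]
  grid[rowSums((grid %*% cell$Gstar) * grid) <= g_max^2, , drop = FALSE]
}

# Beam sets (geometric part only) for every pass: reflections with
# |g| <= g_beam and |S| <= s_beam at the pass orientation, 000 first, the
# pass reflection always included; deterministic (|S|, lexicographic) order.
.pass_beam_hkl <- function(cell, geom, passes, g_beam, s_beam, max_beams = 150) {
  cand <- .hkl_sphere(cell, g_beam)
  Gc <- recip_cart(cell, cand)
  g2 <- colSums(Gc^2)
  key <- paste(cand[, 1], cand[, 2], cand[, 3])
  lapply(passes, function(ps) {
    gl <- .orientation_matrix(geom, ps$alpha_star) %*% Gc
    S <- gl[3, ] - g2 / (2 * geom$beam$K)
    sel <- abs(S) <= s_beam
    sel[match(paste(ps$hkl[1], ps$hkl[2], ps$hkl[3]), key)] <- TRUE
    hh <- cand[sel, , drop = FALSE]
    ss <- S[sel]
    o <- order(abs(ss), hh[, 1], hh[, 2], hh[, 3])
    out <- rbind(c(0L, 0L, 0L), hh[o, , drop = FALSE])
    if (nrow(out) > max_beams)
      stop(sprintf("beam count %d exceeds cap %d; tighten beam cutoffs",
                   nrow(out), max_beams))
    out
  })
}

# Global table of unique beam-difference vectors plus per-pass index
# matrices idx[i,j] -> row of the table holding g_i - g_j.
.build_diff_table <- function(cell, beam_hkl) {
  dict <- new.env(parent = emptyenv())
  diffs <- list(); cnt <- 0
  idx_list <- vector("list", length(beam_hkl))
  for (p in seq_along(beam_hkl)) {
    bh <- beam_hkl[[p]]
    n <- nrow(bh)
    di <- bh[rep(1:n, times = n), , drop = FALSE] - bh[rep(1:n, each = n), , drop = FALSE]
    key <- paste(di[, 1], di[, 2], di[, 3])
    uk <- unique(key)
    new <- uk[!vapply(uk, exists, TRUE, envir = dict)]
    if (length(new)) {
      rows <- di[match(new, key), , drop = FALSE]
      for (q in seq_along(new)) assign(new[q], cnt + q, envir = dict)
      diffs[[length(diffs) + 1]] <- rows
      cnt <- cnt + length(new)
    }
    ids <- vapply(key, get, 0, envir = dict)
    # di row order: (i varies slowest? see rep usage) -> build matrix col-major
    idx_list[[p]] <- matrix(ids, n, n)  # idx[i,j] = g_i - g_j
    storage.mode(idx_list[[p]]) <- "integer"
  }
  diffs <- do.call(rbind, diffs)
  sv <- numeric(nrow(diffs))
  nz <- rowSums(abs(diffs)) > 0
  sv[nz] <- 1 / (2 * d_spacing(cell, diffs[nz, , drop = FALSE]))
  list(diffs = diffs, svals = sv, idx = idx_list)
}

# Node grid over a set of frames: m equal sub-intervals per frame
# (m+1 nodes); trapezoid weights in radians.
.node_grid <- function(frame_alphas, dalpha, m) {
  offs <- dalpha * (-0.5 + (0:m) / m)
  alphas <- as.vector(vapply(frame_alphas, function(a) a + offs, numeric(m + 1)))
  w1 <- (dalpha * pi / 180) / m * c(0.5, rep(1, m - 1), 0.5)
  list(alphas = alphas, weights = rep(w1, length(frame_alphas)),
       frame_block = rep(seq_along(frame_alphas), each = m + 1),
       m = m)
}

# excitation-error matrix (beams x nodes) for a pass beam set over a node
# grid; `corr` either NULL, a single 3x3 correction, or a list of per-frame
# corrections aligned with `frame_block`.
.pass_smat <- function(cell, geom, bh, grid, corr = NULL) {
  G0 <- recip_cart(cell, bh)
  if (is.null(corr) || is.matrix(corr)) {
    sm <- .excitation_grid(geom, G0, grid$alphas, corr)
  } else {
    sm <- vapply(seq_along(grid$alphas), function(i) {
      .excitation_grid(geom, G0, grid$alphas[i], corr[[grid$frame_block[i]]])
    }, numeric(nrow(bh)))
  }
  matrix(sm, nrow = nrow(bh))
}
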