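# Difference electrostatic-potential (DESP) maps. After refinement the
# merged observed intensities provide |F_obs| estimates via
# |F_obs| = |F_calc| * sqrt(I_obs / I_calc) per merged reflection (the
# standard estimate on the dynamical path, where observed amplitudes are
# not directly available); phases come from the model. The Fourier
# difference synthesis
#   dV(r) = (1/V_c) sum_h (|F_obs| - |F_calc|) exp(i phi_calc) exp(-2 pi i h r)
# is evaluated on a grid by FFT, symmetry-completed over the full sphere;
# the F_000 term is omitted so the map has zero mean.

#' Difference electrostatic-potential map
#'
#' @param merged a [merge_equivalents()] table (or any data.frame with
#'   `h,k,l,I_obs,I_calc`).
#' @param st the refined [crystal_structure()] (source of phases and
#'   symmetry completion).
#' @param grid target voxels per axis, or `NULL` for >= `voxels_per_A`
#'   voxels per Angstrom.
#' @param voxels_per_A grid density default.
#' @param max_ratio cap on the amplitude rescaling factor
#'   \eqn{\sqrt{I_{obs}/I_{calc}}}: reflections whose intensity match
#'   failed so badly that the implied observed amplitude exceeds this
#'   multiple of the calculated one carry no usable phase information and
#'   would only inject noise into the synthesis.
#' @return `ded_map`: 3d array `values` (e/A), `cell`, `sigma` (RMS voxel
#'   value), `grid`.
#' @export
difference_map <- function(merged, st, grid = NULL, voxels_per_A = 4,
                           max_ratio = 5) {
  if (is.null(grid)) {
    grid <- vapply(c(st$cell$a, st$cell$b, st$cell$c),
                   function(L) 2 * ceiling(voxels_per_A * L / 2), 0)
  }
  grid <- as.integer(grid)
  keep <- merged$I_calc > 0
  skipped <- sum(!keep)
  if (skipped) message(skipped, " reflection(s) with non-positive I_calc skipped")
  mg <- merged[keep, , drop = FALSE]
  ratio <- pmin(sqrt(mg$I_obs / mg$I_calc), max_ratio)
  # expand every merged unique reflection over its Laue orbit; compute
  # F_calc (hence the phase) directly for each image so the map carries the
  # full space-group symmetry
  arr <- array(0 + 0i, grid)
  seen <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(mg))) {
    orbit <- laue_equivalents(c(mg$h[i], mg$k[i], mg$l[i]), st$sg)
    new <- !vapply(paste(orbit[, 1], orbit[, 2], orbit[, 3]), exists, TRUE,
                   envir = seen)
    orbit <- orbit[new, , drop = FALSE]
    if (!nrow(orbit)) next
    for (kk in paste(orbit[, 1], orbit[, 2], orbit[, 3]))
      assign(kk, TRUE, envir = seen)
    Fc <- structure_factor(st, orbit)
    dF <- (ratio[i] - 1) * Fc
    ijk <- sweep(orbit, 2, grid, "%%") + 1
    for (q in seq_len(nrow(orbit))) {
      arr[ijk[q, 1], ijk[q, 2], ijk[q, 3]] <-
        arr[ijk[q, 1], ijk[q, 2], ijk[q, 3]] + dF[q]
    }
  }
  vals <- Re(fft(arr)) / st$cell$volume
  structure(list(values = vals, cell = st$cell, grid = grid,
                 sigma = sqrt(mean(vals^2)), sg = st$sg),
            class = "ded_map")
}

#' Map noise level and peak search
#'
#' sigma is the root-mean-square voxel value over the full cell. Peaks are
#' local maxima (26-neighbourhood, periodic boundaries) above
#' `n * sigma`, localized by per-axis quadratic interpolation and merged
#' under the space-group symmetry.
#'
#' @param map a [difference_map()].
#' @param n threshold multiple of sigma.
#' @param merge_dist peaks closer than this (Angstrom, after symmetry
#'   expansion) are considered one site.
#' @return list with `sigma` and `peaks` (data.frame `x,y,z` fractional,
#'   `height`, `height_sigma`).
#' @export
map_sigma_and_peaks <- function(map, n = 3, merge_dist = 0.5) {
  v <- map$values
  sig <- map$sigma
  dims <- dim(v)
  if (sig == 0) return(list(sigma = 0, peaks = data.frame(
    x = numeric(), y = numeric(), z = numeric(),
    height = numeric(), height_sigma = numeric())))
  is_max <- array(TRUE, dims)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    shifted <- v[(seq_len(dims[1]) - 1 + dx) %% dims[1] + 1,
                 (seq_len(dims[2]) - 1 + dy) %% dims[2] + 1,
                 (seq_len(dims[3]) - 1 + dz) %% dims[3] + 1]
    is_max <- is_max & (v >= shifted)
  }
  idx <- which(is_max & v > n * sig, arr.ind = TRUE)
  if (!nrow(idx)) return(list(sigma = sig, peaks = data.frame(
    x = numeric(), y = numeric(), z = numeric(),
    height = numeric(), height_sigma = numeric())))
  peaks <- lapply(seq_len(nrow(idx)), function(r) {
    ijk <- idx[r, ]
    frac <- numeric(3)
    for (ax in 1:3) {
      im <- ijk; ip <- ijk
      im[ax] <- (ijk[ax] - 2) %% dims[ax] + 1
      ip[ax] <- ijk[ax] %% dims[ax] + 1
      y0 <- v[im[1], im[2], im[3]]; y1 <- v[ijk[1], ijk[2], ijk[3]]
      y2 <- v[ip[1], ip[2], ip[3]]
      den <- y0 - 2 * y1 + y2
      off <- if (den < 0) 0.5 * (y0 - y2) / den else 0
      frac[ax] <- (ijk[ax] - 1 + off) / dims[ax]
    }
    c(frac %% 1, v[ijk[1], ijk[2], ijk[3]])
  })
  pk <- do.call(rbind, peaks)
  pk <- pk[order(-pk[, 4]), , drop = FALSE]
  # merge symmetry-equivalent peaks
  keep <- rep(TRUE, nrow(pk))
  A <- map$cell$A
  for (i in seq_len(nrow(pk))) {
    if (!keep[i]) next
    imgs <- t(vapply(map$sg$ops, function(op) (op$R %*% pk[i, 1:3] + op$t) %% 1,
                     numeric(3)))
    if (i < nrow(pk)) for (j in (i + 1):nrow(pk)) {
      if (!keep[j]) next
      d <- sweep(imgs, 2, pk[j, 1:3])
      d <- d - round(d)
      if (min(sqrt(rowSums(t(A %*% t(d))^2))) < merge_dist) keep[j] <- FALSE
    }
  }
  pk <- pk[keep, , drop = FALSE]
  list(sigma = sig,
       peaks = data.frame(x = pk[, 1], y = pk[, 2], z = pk[, 3],
                          height = pk[, 4], height_sigma = pk[, 4] / sig))
}

#' Histogram of map values
#'
#' Fixed-width binning of the voxel values (for comparing the noise
#' distributions of kinematical and dynamical maps).
#'
#' @param map a [difference_map()].
#' @param bin_width bin width in e/Angstrom (default 0.0033).
#' @return data.frame `mid`, `count`.
#' @export
map_histogram <- function(map, bin_width = 0.0033) {
  v <- as.vector(map$values)
  lo <- floor(min(v) / bin_width) * bin_width
  br <- seq(lo, max(v) + bin_width, by = bin_width)
  h <- hist(v, breaks = br, plot = FALSE)
  data.frame(mid = h$mids, count = h$counts)
}

#' Write a map in CCP4/MRC binary format (mode 2, float)
#'
#' @param map a [difference_map()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ccp4_map <- function(map, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  dims <- dim(map$values)
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(dims)                      # NC NR NS
  wi(2)                         # MODE float
  wi(c(0, 0, 0))                # start
  wi(dims)                      # intervals
  wf(c(map$cell$a, map$cell$b, map$cell$c,
       map$cell$alpha, map$cell$beta, map$cell$gamma))
  wi(c(1, 2, 3))                # axis order
  wf(c(min(map$values), max(map$values), mean(map$values)))
  wi(c(1, 0))                   # ISPG, NSYMBT
  wi(rep(0, 25))                # extra
  wf(c(0, 0, 0))                # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  wi(16708)                     # machine stamp (little endian)
  wf(map$sigma)
  wi(0)                         # NLABL
  writeChar(strrep(" ", 800), con, nchars = 800, eos = NULL)
  wf(as.vector(map$values))
  invisible(path)
}

#' Plain-text voxel dump of a map
#'
#' @param map a [difference_map()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_map_text <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  dims <- dim(map$values)
  writeLines(c(sprintf("# dyned difference map  grid %d %d %d", dims[1], dims[2], dims[3]),
               sprintf("# cell %.6f %.6f %.6f %.4f %.4f %.4f", map$cell$a,
                       map$cell$b, map$cell$c, map$cell$alpha, map$cell$beta,
                       map$cell$gamma),
               sprintf("# sigma %.8g", map$sigma)), con)
  idx <- arrayInd(seq_along(map$values), dims)
  utils::write.table(data.frame(i = idx[, 1] - 1, j = idx[, 2] - 1,
                                k = idx[, 3] - 1,
                                value = as.vector(map$values)),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.ded_map <- function(x, ...) {
  cat(sprintf("difference potential map %dx%dx%d, sigma = %.5g e/A\n",
              x$grid[1], x$grid[2], x$grid[3], x$sigma))
  invisible(x)
}
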