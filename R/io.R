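# Plain-text data formats: the documented tab-separated reflection list
# (per-frame records plus the experiment geometry in the header) and the
# virtual-frame table. Numbers are written with 17 significant digits so
# both formats round-trip value-exactly.

#' Write a reflection list
#'
#' Tab-separated records `h k l I sigma frame alpha` preceded by a header
#' carrying the cell, wavelength/voltage, goniometer axis, mounting
#' orientation, frame width and the forward-model cutoffs -- everything
#' needed to reduce the file with no side information.
#'
#' @param x a [simulate_experiment()] result (or a compatible list with
#'   `records`, `frames`, `geom` and a `design`/`opts` entry).
#' @param path output file.
#' @param cell a [unit_cell()]; defaults to the truth cell for simulated
#'   input.
#' @return `path`, invisibly.
#' @export
write_reflections <- function(x, path, cell = NULL) {
  if (is.null(cell) && !is.null(x$truth)) cell <- x$truth$structure$cell
  if (is.null(cell)) stop("a unit cell is required")
  op <- if (!is.null(x$design)) x$design else x$opts
  g <- function(v) sprintf("%.17g", v)
  hdr <- c(
    "# dyned reflection list",
    paste("# cell", paste(g(c(cell$a, cell$b, cell$c, cell$alpha, cell$beta, cell$gamma)), collapse = " ")),
    paste("# voltage_kv", g(x$geom$beam$voltage_kv)),
    paste("# axis", paste(g(x$geom$axis), collapse = " ")),
    paste("# R0", paste(g(as.vector(x$geom$R0)), collapse = " ")),
    paste("# dalpha", g(attr(x$frames, "dalpha"))),
    paste("# opts", paste(g(c(op$g_res, op$S_record, op$g_beam, op$s_beam,
                              op$max_beams, op$m)), collapse = " ")),
    "h\tk\tl\tI\tsigma\tframe\talpha"
  )
  rec <- x$records
  lines <- sprintf("%d\t%d\t%d\t%s\t%s\t%d\t%s", rec$h, rec$k, rec$l,
                   g(rec$I), g(rec$sigma), rec$frame, g(rec$alpha))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a reflection list
#'
#' @param path file written by [write_reflections()].
#' @return list with `records`, `frames`, `geom`, `opts`, `cell` --
#'   accepted directly by [reduce_experiment()].
#' @export
read_reflections <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  getv <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key))]
    if (!length(ln)) stop("reflection list header lacks '", key, "'")
    as.numeric(strsplit(sub(paste0("# ", key, " +"), "", ln[1]), " +")[[1]])
  }
  cl <- getv("cell")
  cell <- unit_cell(cl[1], cl[2], cl[3], cl[4], cl[5], cl[6])
  beam <- relativistic_beam(getv("voltage_kv"))
  geom <- experiment_geometry(beam, axis = getv("axis"),
                              R0 = matrix(getv("R0"), 3, 3))
  dalpha <- getv("dalpha")
  ov <- getv("opts")
  opts <- model_options(g_res = ov[1], S_record = ov[2], g_beam = ov[3],
                        s_beam = ov[4], max_beams = ov[5], m = ov[6])
  body <- lines[!startsWith(lines, "#")]
  body <- body[-1]  # column header
  rec <- utils::read.table(text = body, sep = "\t",
                           col.names = c("h", "k", "l", "I", "sigma", "frame", "alpha"))
  fr <- unique(rec[, c("frame", "alpha")])
  fr <- fr[order(fr$frame), ]
  frames <- experimental_frames(fr$alpha, dalpha)
  frames$frame <- fr$frame
  list(records = rec, frames = frames, geom = geom, opts = opts, cell = cell)
}

#' Write a virtual-frame table
#'
#' @param ovfs a [build_virtual_frames()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_virtual_frames <- function(ovfs, path) {
  members <- attr(ovfs, "members")
  g <- function(v) sprintf("%.17g", v)
  hdr <- c("# dyned virtual frames",
           paste("# dalpha", g(attr(ovfs, "dalpha"))),
           paste("# N_F", attr(ovfs, "N_F"), "N_O", attr(ovfs, "N_O")),
           "vf\talpha_v\tdalpha_v\tframes")
  lines <- sprintf("%d\t%s\t%s\t%s", ovfs$vf, g(ovfs$alpha_v), g(ovfs$dalpha_v),
                   vapply(members, paste, "", collapse = ","))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a virtual-frame table
#'
#' @param path file written by [write_virtual_frames()].
#' @return a data.frame equivalent to the [build_virtual_frames()] result.
#' @export
read_virtual_frames <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  num <- function(key) as.numeric(sub(paste0(".*# ", key, " +([^ ]+).*"), "\\1",
                                      hdr[grepl(paste0("# ", key), hdr)][1]))
  body <- lines[!startsWith(lines, "#")][-1]
  parts <- strsplit(body, "\t")
  out <- data.frame(vf = as.integer(vapply(parts, `[[`, "", 1)),
                    alpha_v = as.numeric(vapply(parts, `[[`, "", 2)),
                    dalpha_v = as.numeric(vapply(parts, `[[`, "", 3)))
  attr(out, "members") <- lapply(parts, function(p) as.integer(strsplit(p[4], ",")[[1]]))
  attr(out, "dalpha") <- num("dalpha")
  nfo <- hdr[grepl("# N_F", hdr)][1]
  attr(out, "N_F") <- as.integer(sub(".*N_F +([0-9]+).*", "\\1", nfo))
  attr(out, "N_O") <- as.integer(sub(".*N_O +([0-9]+).*", "\\1", nfo))
  class(out) <- c("ded_ovfs", "data.frame")
  out
}

#' Write a refinement run summary as JSON
#'
#' @param result a `ded_refinement` (or `ded_kinrefinement` / `ded_enantio`).
#' @param path output file.
#' @param extra named list merged into the summary.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(result, path, extra = list()) {
  base <- if (inherits(result, "ded_enantio")) {
    list(kind = "enantiomorph_comparison", stage = result$stage,
         wR1 = result$wR1, wR2 = result$wR2, k = result$k, N = result$N,
         w = result$w, z = result$z, probability = result$probability,
         favoured = result$favoured)
  } else {
    list(kind = paste0(result$mode, "_refinement"),
         rfactors = result$rfactors,
         thickness = if (!is.null(result$thickness)) result$thickness,
         converged = result$converged)
  }
  jsonlite::write_json(c(base, extra), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
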