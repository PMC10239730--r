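# Minimal core-CIF reader/writer for structure models: cell, symmetry xyz
# loop, atom_site loop with occupancy and U_iso (B_iso accepted on input).

.cif_tokens <- function(lines) {
  lines <- sub("#.*$", "", lines)
  toks <- character(0)
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    # split respecting quotes
    while (nzchar(ln)) {
      if (startsWith(ln, "'") || startsWith(ln, "\"")) {
        q <- substring(ln, 1, 1)
        rest <- substring(ln, 2)
        pos <- regexpr(q, rest, fixed = TRUE)
        if (pos < 0) stop("unterminated quoted CIF value")
        toks <- c(toks, substring(rest, 1, pos - 1))
        ln <- trimws(substring(rest, pos + 1))
      } else {
        pos <- regexpr("[ \t]", ln)
        if (pos < 0) { toks <- c(toks, ln); ln <- "" }
        else { toks <- c(toks, substring(ln, 1, pos - 1)); ln <- trimws(substring(ln, pos + 1)) }
      }
    }
  }
  toks
}

.cif_num <- function(x) as.numeric(sub("\\(.*\\)$", "", x))

#' Read a crystal structure from a core-CIF file
#'
#' Understands `_cell_length_*` / `_cell_angle_*`, a symmetry-operation loop
#' (`_symmetry_equiv_pos_as_xyz` or `_space_group_symop_operation_xyz`), the
#' space-group symbol tags, and an `_atom_site_` loop with fractional
#' coordinates, occupancy and `U_iso_or_equiv` (or `B_iso_or_equiv`,
#' converted via \eqn{U = B/8\pi^2}).
#'
#' @param path CIF file path.
#' @return a [crystal_structure()].
#' @export
read_cif <- function(path) {
  toks <- .cif_tokens(readLines(path, warn = FALSE))
  vals <- list(); i <- 1; n <- length(toks)
  loops <- list()
  while (i <= n) {
    tk <- toks[i]
    if (tolower(tk) == "loop_") {
      hdr <- character(0); i <- i + 1
      while (i <= n && startsWith(toks[i], "_")) { hdr <- c(hdr, tolower(toks[i])); i <- i + 1 }
      body <- character(0)
      while (i <= n && !startsWith(toks[i], "_") && tolower(toks[i]) != "loop_" &&
             !startsWith(tolower(toks[i]), "data_")) {
        body <- c(body, toks[i]); i <- i + 1
      }
      m <- matrix(body, ncol = length(hdr), byrow = TRUE)
      colnames(m) <- hdr
      loops[[length(loops) + 1]] <- m
    } else if (startsWith(tk, "_")) {
      vals[[tolower(tk)]] <- toks[i + 1]; i <- i + 2
    } else i <- i + 1
  }
  getv <- function(...) {
    for (k in c(...)) if (!is.null(vals[[k]])) return(vals[[k]])
    NULL
  }
  cell <- unit_cell(.cif_num(getv("_cell_length_a")),
                    .cif_num(getv("_cell_length_b")),
                    .cif_num(getv("_cell_length_c")),
                    .cif_num(getv("_cell_angle_alpha")),
                    .cif_num(getv("_cell_angle_beta")),
                    .cif_num(getv("_cell_angle_gamma")))
  symbol <- getv("_space_group_name_h-m_alt", "_symmetry_space_group_name_h-m")
  xyz <- NULL
  for (lp in loops) {
    cn <- colnames(lp)
    k <- intersect(c("_symmetry_equiv_pos_as_xyz", "_space_group_symop_operation_xyz"), cn)
    if (length(k)) xyz <- unname(lp[, k[1]])
  }
  sg <- if (!is.null(xyz)) {
    space_group(if (is.null(symbol)) "custom" else symbol, xyz = xyz)
  } else space_group(symbol)
  atoms <- list()
  for (lp in loops) {
    cn <- colnames(lp)
    if (!"_atom_site_label" %in% cn) next
    for (r in seq_len(nrow(lp))) {
      u <- if ("_atom_site_u_iso_or_equiv" %in% cn) .cif_num(lp[r, "_atom_site_u_iso_or_equiv"])
           else if ("_atom_site_b_iso_or_equiv" %in% cn)
             .cif_num(lp[r, "_atom_site_b_iso_or_equiv"]) / (8 * pi^2)
           else 0.01
      occ <- if ("_atom_site_occupancy" %in% cn) .cif_num(lp[r, "_atom_site_occupancy"]) else 1
      el <- if ("_atom_site_type_symbol" %in% cn) unname(lp[r, "_atom_site_type_symbol"])
            else gsub("[0-9]+$", "", unname(lp[r, "_atom_site_label"]))
      atoms[[length(atoms) + 1]] <- atom_site(
        label = unname(lp[r, "_atom_site_label"]), element = el,
        xyz = c(.cif_num(lp[r, "_atom_site_fract_x"]),
                .cif_num(lp[r, "_atom_site_fract_y"]),
                .cif_num(lp[r, "_atom_site_fract_z"])),
        occ = occ, uiso = u)
    }
  }
  crystal_structure(cell, sg, atoms)
}

#' Write a crystal structure as a core-CIF file
#'
#' Writes cell, symmetry xyz loop and atom_site loop (fractional coordinates,
#' occupancy, U_iso) with enough digits for a value-exact round trip through
#' [read_cif()].
#'
#' @param st a [crystal_structure()].
#' @param path output file path.
#' @param data_name data block name.
#' @return `path`, invisibly.
#' @export
write_cif <- function(st, path, data_name = "dyned") {
  ln <- c(
    paste0("data_", data_name),
    sprintf("_cell_length_a      %.6f", st$cell$a),
    sprintf("_cell_length_b      %.6f", st$cell$b),
    sprintf("_cell_length_c      %.6f", st$cell$c),
    sprintf("_cell_angle_alpha   %.5f", st$cell$alpha),
    sprintf("_cell_angle_beta    %.5f", st$cell$beta),
    sprintf("_cell_angle_gamma   %.5f", st$cell$gamma),
    sprintf("_cell_volume        %.5f", st$cell$volume),
    sprintf("_space_group_name_H-M_alt  '%s'", st$sg$symbol),
    "loop_",
    "_space_group_symop_operation_xyz",
    sprintf("  '%s'", st$sg$xyz),
    "loop_",
    "_atom_site_label",
    "_atom_site_type_symbol",
    "_atom_site_fract_x",
    "_atom_site_fract_y",
    "_atom_site_fract_z",
    "_atom_site_occupancy",
    "_atom_site_U_iso_or_equiv",
    vapply(st$atoms, function(a)
      sprintf("  %s %s %.8f %.8f %.8f %.5f %.7f", a$label, a$element,
              a$xyz[1], a$xyz[2], a$xyz[3], a$occ, a$uiso), "")
  )
  writeLines(ln, path)
  invisible(path)
}
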