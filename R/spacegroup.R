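# Space-group handling: a small registry of explicit general positions covers
# the groups used by the bundled fixtures; arbitrary groups can be built from
# xyz operator strings (e.g. parsed out of a CIF symmetry loop).

.sg_registry <- list(
  "P1"       = c("x,y,z"),
  "P-1"      = c("x,y,z", "-x,-y,-z"),
  "P21/n"    = c("x,y,z", "-x+1/2,y+1/2,-z+1/2", "-x,-y,-z", "x+1/2,-y+1/2,z+1/2"),
  "P212121"  = c("x,y,z", "-x+1/2,-y,z+1/2", "x+1/2,-y+1/2,-z", "-x,y+1/2,-z+1/2"),
  "P3121"    = c("x,y,z", "-y,x-y,z+1/3", "-x+y,-x,z+2/3",
                 "y,x,-z", "x-y,-y,-z+2/3", "-x,-x+y,-z+1/3"),
  "P3221"    = c("x,y,z", "-y,x-y,z+2/3", "-x+y,-x,z+1/3",
                 "y,x,-z", "x-y,-y,-z+1/3", "-x,-x+y,-z+2/3"),
  "P6122"    = c("x,y,z", "x-y,x,z+1/6", "-y,x-y,z+1/3", "-x,-y,z+1/2",
                 "-x+y,-x,z+2/3", "y,-x+y,z+5/6", "-y,-x,-z+5/6",
                 "-x,-x+y,-z+2/3", "-x+y,y,-z+1/2", "y,x,-z+1/3",
                 "x,x-y,-z+1/6", "x-y,-y,-z"),
  "P6522"    = c("x,y,z", "x-y,x,z+5/6", "-y,x-y,z+2/3", "-x,-y,z+1/2",
                 "-x+y,-x,z+1/3", "y,-x+y,z+1/6", "-y,-x,-z+1/6",
                 "-x,-x+y,-z+1/3", "-x+y,y,-z+1/2", "y,x,-z+2/3",
                 "x,x-y,-z+5/6", "x-y,-y,-z")
)

# the 11 enantiomorphic space-group pairs (both directions)
.sg_enantiomorph_pairs <- c(
  "P41" = "P43", "P43" = "P41",
  "P4122" = "P4322", "P4322" = "P4122",
  "P41212" = "P43212", "P43212" = "P41212",
  "P31" = "P32", "P32" = "P31",
  "P3112" = "P3212", "P3212" = "P3112",
  "P3121" = "P3221", "P3221" = "P3121",
  "P61" = "P65", "P65" = "P61",
  "P62" = "P64", "P64" = "P62",
  "P6122" = "P6522", "P6522" = "P6122",
  "P6222" = "P6422", "P6422" = "P6222",
  "P4132" = "P4332", "P4332" = "P4132"
)

.sg_normalize_symbol <- function(symbol) {
  gsub("[ _]", "", symbol)
}

#' Parse an xyz symmetry operator string
#'
#' Converts strings like `"-x+1/2,y+1/2,-z"` into a 3x3 integer rotation
#' matrix and a translation vector (components reduced to [0,1)).
#'
#' @param s operator string with three comma-separated components.
#' @return list with `R` (3x3 integer matrix) and `t` (length-3 numeric).
#' @export
parse_symop <- function(s) {
  parts <- strsplit(gsub("[ ]", "", tolower(s)), ",")[[1]]
  if (length(parts) != 3) stop("malformed symmetry operator: ", s)
  R <- matrix(0L, 3, 3)
  tr <- numeric(3)
  for (i in 1:3) {
    expr <- parts[i]
    # tokenize into signed terms
    expr <- gsub("-", "+-", expr)
    terms <- strsplit(expr, "+", fixed = TRUE)[[1]]
    terms <- terms[nzchar(terms)]
    for (tm in terms) {
      sign <- 1
      if (startsWith(tm, "-")) { sign <- -1; tm <- substring(tm, 2) }
      if (tm %in% c("x", "y", "z")) {
        R[i, match(tm, c("x", "y", "z"))] <- R[i, match(tm, c("x", "y", "z"))] + sign
      } else if (grepl("/", tm, fixed = TRUE)) {
        fr <- as.numeric(strsplit(tm, "/", fixed = TRUE)[[1]])
        tr[i] <- tr[i] + sign * fr[1] / fr[2]
      } else {
        tr[i] <- tr[i] + sign * as.numeric(tm)
      }
    }
  }
  list(R = R, t = tr %% 1)
}

.symop_to_xyz <- function(op) {
  axes <- c("x", "y", "z")
  comp <- character(3)
  for (i in 1:3) {
    s <- ""
    for (j in 1:3) {
      r <- op$R[i, j]
      if (r != 0) {
        s <- paste0(s, if (r > 0 && nzchar(s)) "+" else if (r < 0) "-" else "",
                    if (abs(r) != 1) abs(r) else "", axes[j])
      }
    }
    tv <- op$t[i] %% 1
    if (abs(tv) > 1e-9) {
      fr <- .as_fraction(tv)
      s <- paste0(s, "+", fr)
    }
    comp[i] <- s
  }
  paste(comp, collapse = ",")
}

.as_fraction <- function(x) {
  for (den in c(2, 3, 4, 6, 12)) {
    num <- x * den
    if (abs(num - round(num)) < 1e-9) return(paste0(round(num), "/", den))
  }
  format(x)
}

#' Space-group setting
#'
#' Builds a space-group object either from a registered Hermann-Mauguin
#' symbol or from a list of explicit xyz operator strings. Checks closure of
#' the operations under composition modulo lattice translations, derives the
#' Laue-class point operations, a Sohncke flag (proper rotations only) and
#' the enantiomorphic partner symbol when one exists.
#'
#' @param symbol Hermann-Mauguin symbol (spaces/underscores ignored), e.g.
#'   `"P212121"` or `"P 61 2 2"`.
#' @param xyz optional character vector of operator strings; when supplied it
#'   overrides the registry lookup.
#' @return A `ded_spacegroup` with `symbol`, `ops` (list of `R`,`t` pairs),
#'   `laue_ops` (list of 3x3 matrices incl. inversion-composed ones),
#'   `centrosymmetric`, `sohncke`, `enantiomorph_partner` (or `NA`).
#' @export
space_group <- function(symbol, xyz = NULL) {
  sym <- .sg_normalize_symbol(symbol)
  if (is.null(xyz)) {
    if (!sym %in% names(.sg_registry)) {
      stop("space group '", symbol, "' is not in the built-in registry; ",
           "supply xyz operator strings")
    }
    xyz <- .sg_registry[[sym]]
  }
  ops <- lapply(xyz, parse_symop)
  # closure / identity checks (modulo lattice translations)
  keyR <- function(R) paste(R, collapse = ",")
  keys <- vapply(ops, function(o) paste(keyR(o$R), paste(round(o$t * 12) %% 12, collapse = ",")),
                 "")
  if (anyDuplicated(keys)) stop("duplicate symmetry operations")
  idkey <- paste(keyR(diag(3L)), "0,0,0")
  if (!idkey %in% keys) stop("identity operation missing")
  for (a in ops) for (b in ops) {
    Rc <- a$R %*% b$R
    tc <- (a$R %*% b$t + a$t) %% 1
    kc <- paste(keyR(Rc), paste(round(tc * 12) %% 12, collapse = ","))
    if (!kc %in% keys) stop("operations not closed under composition")
  }
  Rmats <- lapply(ops, `[[`, "R")
  centro <- any(vapply(Rmats, function(R) all(R == -diag(3L)), TRUE))
  sohncke <- all(vapply(Rmats, function(R) round(det(R)) == 1, TRUE))
  # Laue class: point operations united with their inversion-composed images
  laue <- list()
  lk <- character(0)
  for (R in c(Rmats, lapply(Rmats, function(R) -R))) {
    k <- keyR(R)
    if (!k %in% lk) { laue[[length(laue) + 1]] <- R; lk <- c(lk, k) }
  }
  partner <- if (sym %in% names(.sg_enantiomorph_pairs)) {
    unname(.sg_enantiomorph_pairs[sym])
  } else NA_character_
  structure(list(symbol = sym, ops = ops, xyz = vapply(ops, .symop_to_xyz, ""),
                 laue_ops = laue, centrosymmetric = centro,
                 sohncke = sohncke, enantiomorph_partner = partner),
            class = "ded_spacegroup")
}

#' @export
print.ded_spacegroup <- function(x, ...) {
  cat(sprintf("space group %s  (%d ops, Laue order %d%s%s)\n",
              x$symbol, length(x$ops), length(x$laue_ops),
              if (x$sohncke) ", Sohncke" else "",
              if (!is.na(x$enantiomorph_partner))
                paste0(", enantiomorph partner ", x$enantiomorph_partner) else ""))
  invisible(x)
}

#' Laue-equivalent reflections
#'
#' Orbit of a reflection under the Laue class of a space group (always
#' includes the Friedel mate). Used for post-refinement merging and
#' MR-factors only -- never inside the dynamical intensity calculation.
#'
#' @param hkl integer triple.
#' @param sg a [space_group()].
#' @return integer matrix of distinct equivalent reflections in rows.
#' @export
laue_equivalents <- function(hkl, sg) {
  h <- as.integer(round(hkl))
  imgs <- t(vapply(sg$laue_ops, function(R) as.integer(h %*% R), integer(3)))
  unique(imgs)
}

#' Canonical representative of a Laue orbit
#'
#' Picks a deterministic representative (lexicographically largest image) so
#' equivalent reflections map to a common key.
#'
#' @inheritParams laue_equivalents
#' @return integer triple.
#' @export
laue_representative <- function(hkl, sg) {
  eq <- laue_equivalents(hkl, sg)
  o <- order(eq[, 1], eq[, 2], eq[, 3], decreasing = TRUE)
  eq[o[1], ]
}
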