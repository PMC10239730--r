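# Electron atomic scattering factors (5-Gaussian parameterization; see the
# header of inst/extdata/electron_scattering_factors.tsv for the source).

.ded_env <- new.env(parent = emptyenv())

#' Packaged electron scattering-factor table
#'
#' Loads (and caches) the bundled 5-Gaussian electron form-factor
#' coefficients for the elements H, C, N, O, F, Na, Al, Si, P, S, Co.
#'
#' @return data.frame with columns `element`, `a1..a5`, `b1..b5`.
#' @export
scattering_table <- function() {
  if (is.null(.ded_env$sftable)) {
    path <- system.file("extdata", "electron_scattering_factors.tsv",
                        package = "dyned", mustWork = TRUE)
    .ded_env$sftable <- utils::read.table(path, header = TRUE, sep = "\t",
                                          comment.char = "#",
                                          stringsAsFactors = FALSE)
  }
  .ded_env$sftable
}

.sf_coeffs <- function(elements, table = scattering_table()) {
  idx <- match(elements, table$element)
  if (anyNA(idx)) {
    stop("no scattering factors tabulated for element(s): ",
         paste(unique(elements[is.na(idx)]), collapse = ", "))
  }
  list(a = as.matrix(table[idx, paste0("a", 1:5)]),
       b = as.matrix(table[idx, paste0("b", 1:5)]))
}

#' Electron atomic form factor
#'
#' \eqn{f(s) = \sum_i a_i \exp(-b_i s^2)} with \eqn{s = \sin\theta/\lambda}
#' in 1/Angstrom and f in Angstrom.
#'
#' @param element element symbol (must be tabulated).
#' @param s scattering parameter(s) in 1/Angstrom, non-negative.
#' @param table coefficient table, defaults to the packaged one.
#' @return f(s) in Angstrom, same length as `s`.
#' @export
form_factor <- function(element, s, table = scattering_table()) {
  if (any(s < 0)) stop("s must be non-negative")
  cf <- .sf_coeffs(element, table)
  drop(exp(-outer(s^2, drop(cf$b))) %*% drop(cf$a))
}
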