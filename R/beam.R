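#' Relativistic electron beam parameters
#'
#' Electron wavelength, wavevector magnitude and relativistic mass factor for
#' a given acceleration voltage, from the standard relativistic de Broglie
#' relation with CODATA constants:
#' \deqn{\lambda = h / \sqrt{2 m_0 e V (1 + eV / 2 m_0 c^2)}}
#'
#' @param voltage_kv acceleration voltage in kV (positive).
#' @return A `ded_beam` list with `voltage_kv`, `lambda` (Angstrom),
#'   `K` = 1/lambda (1/Angstrom) and `gamma_rel` = 1 + eV/m0c^2.
#' @examples
#' relativistic_beam(200)$lambda  # ~0.02508 Angstrom
#' @export
relativistic_beam <- function(voltage_kv) {
  if (!is.numeric(voltage_kv) || length(voltage_kv) != 1 || !is.finite(voltage_kv) ||
      voltage_kv <= 0) {
    stop("acceleration voltage must be a single positive number (kV)")
  }
  h  <- 6.62607015e-34    # J s
  m0 <- 9.1093837015e-31  # kg
  e  <- 1.602176634e-19   # C
  cc <- 299792458         # m/s
  V  <- voltage_kv * 1e3
  lambda_m <- h / sqrt(2 * m0 * e * V * (1 + e * V / (2 * m0 * cc^2)))
  lambda <- lambda_m * 1e10
  structure(list(voltage_kv = voltage_kv,
                 lambda = lambda,
                 K = 1 / lambda,
                 gamma_rel = 1 + e * V / (m0 * cc^2)),
            class = "ded_beam")
}

#' @export
print.ded_beam <- function(x, ...) {
  cat(sprintf("electron beam  %g kV  lambda=%.6f A  K=%.3f 1/A  gamma=%.4f\n",
              x$voltage_kv, x$lambda, x$K, x$gamma_rel))
  invisible(x)
}
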