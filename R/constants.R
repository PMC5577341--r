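#' Physical constants used throughout the package
#'
#' Internal constants: Boltzmann constant in kcal/mol/K, the electrostatic
#' conversion factor in kcal*Angstrom/(mol*e^2), and unit conversions.
#' Coordinates are stored in nm internally; PDB I/O and surface areas use
#' Angstrom.
#'
#' @name remscape-constants
#' @keywords internal
NULL

#' Boltzmann constant, kcal/(mol K)
#' @keywords internal
KB_KCAL <- 0.0019872

#' Coulomb constant, kcal Angstrom / (mol e^2)
#' @keywords internal
KE_KCAL_A <- 332.0636

NM_PER_ANGSTROM <- 0.1
ANGSTROM_PER_NM <- 10

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Euclidean norm of a length-3 vector
#' @keywords internal
#' @noRd
vnorm <- function(v) sqrt(sum(v * v))

#' Normalize a length-3 vector
#' @keywords internal
#' @noRd
vhat <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

#' Cross product of two length-3 vectors
#' @keywords internal
#' @noRd
vcross <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

#' Angle (radians) at vertex b for points a-b-c
#' @keywords internal
#' @noRd
vangle <- function(a, b, c) {
  u <- vhat(a - b)
  v <- vhat(c - b)
  acos(max(-1, min(1, sum(u * v))))
}
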