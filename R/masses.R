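#' Monoisotopic mass constants
#'
#' Monoisotopic residue masses for the 20 standard amino acids, the mass of
#' water, and the proton mass used for m/z conversion. Values are CODATA /
#' IUPAC monoisotopic masses in daltons.
#'
#' @format `AA_MONO` is a named numeric vector (one-letter residue codes);
#'   `WATER_MONO` and `PROTON_MASS` are length-one numerics.
#' @name mass-constants
NULL

#' @rdname mass-constants
#' @export
AA_MONO <- c(
  G = 57.02146374, A = 71.03711379, S = 87.03202841, P = 97.05276385,
  V = 99.06841392, T = 101.04767847, C = 103.00918448, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
  K = 128.09496302, E = 129.04259309, M = 131.04048461, H = 137.05891186,
  F = 147.06841392, R = 156.10111102, Y = 163.06332853, W = 186.07931295
)

#' @rdname mass-constants
#' @export
WATER_MONO <- 18.01056468

#' @rdname mass-constants
#' @export
PROTON_MASS <- 1.00727646688

# monoisotopic atomic masses used to derive adduct deltas
ATOM_MONO <- c(
  H = 1.0078250319, D = 2.0141017780, C = 12.0, `13C` = 13.0033548378,
  N = 14.0030740052, O = 15.9949146221, S = 31.97207069
)

#' Convert a neutral mass to m/z at a given charge
#'
#' @param neutral_mass Neutral monoisotopic mass in Da.
#' @param charge Positive integer charge state.
#' @return m/z value `(neutral_mass + charge * PROTON_MASS) / charge`.
#' @examples
#' mz(1000, 2) # 501.0073
#' @export
mz <- function(neutral_mass, charge) {
  if (any(charge < 1) || any(charge != as.integer(charge)))
    stop("charge must be a positive integer")
  (neutral_mass + charge * PROTON_MASS) / charge
}

#' Parts-per-million difference between two m/z values
#'
#' @param observed,theoretical m/z values.
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @export
ppm_diff <- function(observed, theoretical) {
  1e6 * (observed - theoretical) / theoretical
}
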