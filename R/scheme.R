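#' Derivatization scheme for histone peptide chemistry
#'
#' Describes the label chemistry applied to histone lysines and peptide
#' N-termini before LC-MS/MS. The default models heavy-isotopic reductive
#' dimethylation (formaldehyde-13C,d2 + NaBD3CN) of free and monomethyl
#' lysines on the intact protein, followed by tryptic digestion and
#' N-terminal propionylation of the resulting peptides:
#' an unmodified lysine receives two heavy methyl groups, a monomethyl
#' lysine one, and di-/tri-methyl or acetyl lysines none.
#'
#' The heavy methyl installed by that chemistry is 13CD3 replacing one amine
#' hydrogen (net 13C + 3D - H = 18.037835 Da); an endogenous (light) methyl
#' is CH2 (14.015650 Da), acetyl is C2H2O (42.010565 Da) and propionyl is
#' C3H4O (56.026215 Da).
#'
#' @param heavy_methyl_delta Net monoisotopic mass (Da) added per installed
#'   heavy methyl.
#' @param light_methyl_delta Net mass (Da) of one endogenous methyl.
#' @param acetyl_delta Net mass (Da) of endogenous lysine acetylation.
#' @param propionyl_delta Net mass (Da) of N-terminal propionylation.
#' @param installed Named integer vector mapping endogenous lysine state
#'   (`un`, `me1`, `me2`, `me3`, `ac`) to the number of heavy methyls the
#'   chemistry installs on it.
#' @return An object of class `derivatization_scheme`.
#' @examples
#' sc <- derivatization_scheme()
#' lysine_adduct_mass("me3", sc) - lysine_adduct_mass("ac", sc) # 0.0364 Da
#' @export
derivatization_scheme <- function(
    heavy_methyl_delta = ATOM_MONO[["13C"]] + 3 * ATOM_MONO[["D"]] - ATOM_MONO[["H"]],
    light_methyl_delta = ATOM_MONO[["C"]] + 2 * ATOM_MONO[["H"]],
    acetyl_delta = 2 * ATOM_MONO[["C"]] + 2 * ATOM_MONO[["H"]] + ATOM_MONO[["O"]],
    propionyl_delta = 3 * ATOM_MONO[["C"]] + 4 * ATOM_MONO[["H"]] + ATOM_MONO[["O"]],
    installed = c(un = 2L, me1 = 1L, me2 = 0L, me3 = 0L, ac = 0L)) {
  if (heavy_methyl_delta <= light_methyl_delta)
    stop("heavy_methyl_delta must exceed light_methyl_delta")
  if (any(c(heavy_methyl_delta, light_methyl_delta, acetyl_delta, propionyl_delta) <= 0))
    stop("all mass deltas must be positive")
  states <- c("un", "me1", "me2", "me3", "ac")
  if (!all(states %in% names(installed)))
    stop("installed must name all of: ", paste(states, collapse = ", "))
  structure(
    list(
      heavy_methyl_delta = heavy_methyl_delta,
      light_methyl_delta = light_methyl_delta,
      acetyl_delta = acetyl_delta,
      propionyl_delta = propionyl_delta,
      installed = installed[states]
    ),
    class = "derivatization_scheme"
  )
}

#' @export
print.derivatization_scheme <- function(x, ...) {
  cat("Derivatization scheme\n")
  cat(sprintf("  heavy methyl: %+.6f Da   light methyl: %+.6f Da\n",
              x$heavy_methyl_delta, x$light_methyl_delta))
  cat(sprintf("  acetyl:       %+.6f Da   N-term propionyl: %+.6f Da\n",
              x$acetyl_delta, x$propionyl_delta))
  cat("  installed heavy methyls per endogenous state:\n   ",
      paste(sprintf("%s=%d", names(x$installed), x$installed), collapse = "  "),
      "\n")
  invisible(x)
}

#' Total adduct mass carried by a lysine in a given endogenous state
#'
#' Sum of the endogenous modification mass (light methyls or acetyl) and the
#' heavy methyls the derivatization chemistry installs on that state.
#'
#' @param state One of `un`, `me1`, `me2`, `me3`, `ac` (vectorized).
#' @param scheme A [derivatization_scheme()].
#' @return Numeric vector of adduct masses in Da.
#' @export
lysine_adduct_mass <- function(state, scheme) {
  endo <- c(
    un = 0,
    me1 = scheme$light_methyl_delta,
    me2 = 2 * scheme$light_methyl_delta,
    me3 = 3 * scheme$light_methyl_delta,
    ac = scheme$acetyl_delta
  )
  bad <- setdiff(unique(state), names(endo))
  if (length(bad)) stop("unknown lysine state(s): ", paste(bad, collapse = ", "))
  unname(endo[state] + scheme$installed[state] * scheme$heavy_methyl_delta)
}

#' Read a derivatization scheme from a YAML file
#'
#' Expects top-level keys `heavy_methyl_delta`, `light_methyl_delta`,
#' `acetyl_delta`, `propionyl_delta` and a mapping `installed` of state to
#' heavy-methyl count. Missing keys fall back to the package defaults.
#'
#' @param path Path to a YAML file.
#' @return A [derivatization_scheme()].
#' @export
read_scheme_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  defaults <- derivatization_scheme()
  getval <- function(key) if (!is.null(y[[key]])) y[[key]] else defaults[[key]]
  installed <- if (!is.null(y$installed)) {
    v <- vapply(y$installed, as.integer, integer(1))
    v
  } else defaults$installed
  derivatization_scheme(
    heavy_methyl_delta = getval("heavy_methyl_delta"),
    light_methyl_delta = getval("light_methyl_delta"),
    acetyl_delta = getval("acetyl_delta"),
    propionyl_delta = getval("propionyl_delta"),
    installed = installed
  )
}
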