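#' Neutral monoisotopic mass of a derivatized PTM isoform
#'
#' Sum of the residue monoisotopic masses, one water, the N-terminal
#' propionyl group, and the per-lysine adduct mass (endogenous methyl/acetyl
#' plus the heavy methyls installed by the labeling chemistry) for every
#' modifiable lysine.
#'
#' @param isoform A [ptm_isoform()].
#' @param scheme A [derivatization_scheme()], or `NULL` for the plain
#'   underivatized peptide (no propionyl, no lysine adducts).
#' @return Neutral monoisotopic mass in Da.
#' @export
derivatized_mass <- function(isoform, scheme = derivatization_scheme()) {
  res <- strsplit(isoform$peptide$sequence, "")[[1]]
  m <- sum(AA_MONO[res]) + WATER_MONO
  if (is.null(scheme)) return(unname(m))
  m <- m + scheme$propionyl_delta
  if (length(isoform$states))
    m <- m + sum(lysine_adduct_mass(isoform$states, scheme))
  unname(m)
}

# per-residue adduct vector (length = peptide length) for one isoform
residue_adducts <- function(isoform, scheme) {
  n <- nchar(isoform$peptide$sequence)
  add <- numeric(n)
  if (is.null(scheme) || length(isoform$states) == 0) return(add)
  pos <- as.integer(names(isoform$states)) - isoform$peptide$start + 1L
  add[pos] <- lysine_adduct_mass(isoform$states, scheme)
  add
}

#' b- and y-series fragment ions of a PTM isoform
#'
#' Standard monoisotopic fragment masses with every site adduct placed on
#' its residue; the N-terminal propionyl travels with the b-series. For a
#' peptide of length n, indices run 1..n-1. Neutral fragment masses obey the
#' closure b_i + y_(n-i) = precursor neutral mass exactly.
#'
#' @param isoform A [ptm_isoform()].
#' @param scheme A [derivatization_scheme()] or `NULL` for no derivatization.
#' @param series `"b"`, `"y"`, or both (default).
#' @param charge Fragment charge state (default 1).
#' @return `data.frame` with columns `series`, `index`, `charge`, `neutral`
#'   (Da) and `mz`.
#' @examples
#' iso <- ptm_isoform(peptide("X", 1, 2, "AG"), character(0))
#' fragment_ions(iso, scheme = NULL) # b1 72.0444, y1 76.0393
#' @export
fragment_ions <- function(isoform, scheme = derivatization_scheme(),
                          series = c("b", "y"), charge = 1L) {
  series <- match.arg(series, c("b", "y"), several.ok = TRUE)
  if (charge < 1) stop("charge must be >= 1")
  res <- strsplit(isoform$peptide$sequence, "")[[1]]
  n <- length(res)
  if (n < 2) stop("fragments require a peptide of length >= 2")
  per_res <- unname(AA_MONO[res]) + residue_adducts(isoform, scheme)
  nterm <- if (is.null(scheme)) 0 else scheme$propionyl_delta
  idx <- seq_len(n - 1L)
  out <- list()
  if ("b" %in% series) {
    neutral <- nterm + cumsum(per_res)[idx]
    out$b <- data.frame(series = "b", index = idx, charge = charge,
                        neutral = neutral, mz = mz(neutral, charge))
  }
  if ("y" %in% series) {
    neutral <- WATER_MONO + rev(cumsum(rev(per_res)))[idx + 1L]
    out$y <- data.frame(series = "y", index = rev(idx), charge = charge,
                        neutral = neutral, mz = mz(neutral, charge))
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df[order(df$series, df$index), , drop = FALSE]
}

#' Fragments that distinguish two isoforms of the same peptide
#'
#' Pairs the b/y fragments of two isoforms by series and index and returns
#' those whose m/z differ by more than the stated ppm tolerance -- the ions
#' by which co-eluting isobaric positional isomers are told apart and
#' apportioned.
#'
#' @param isoA,isoB [ptm_isoform()] objects on the same peptide backbone.
#' @param scheme A [derivatization_scheme()].
#' @param tolerance_ppm Fragments differing by no more than this are treated
#'   as shared.
#' @param charge Fragment charge (default 1).
#' @return List with data.frames `A` and `B` (the distinguishing fragments of
#'   each isoform; same series/index rows, different m/z).
#' @export
unique_fragments <- function(isoA, isoB, scheme = derivatization_scheme(),
                             tolerance_ppm = 10, charge = 1L) {
  if (!identical(isoA$peptide$sequence, isoB$peptide$sequence) ||
      !identical(isoA$peptide$start, isoB$peptide$start))
    stop("isoforms must share the same peptide backbone")
  fa <- fragment_ions(isoA, scheme, charge = charge)
  fb <- fragment_ions(isoB, scheme, charge = charge)
  stopifnot(identical(fa$series, fb$series), identical(fa$index, fb$index))
  dppm <- abs(ppm_diff(fa$mz, fb$mz))
  keep <- dppm > tolerance_ppm
  list(A = fa[keep, , drop = FALSE], B = fb[keep, , drop = FALSE])
}

#' Validate a ppm tolerance against the trimethyl/acetyl mass gap
#'
#' Endogenous trimethyl and acetyl lysine differ by 3 x CH2 - C2H2O =
#' 0.036385 Da, the closest-spaced state pair the MS1 tolerance must resolve.
#' Errors if the requested tolerance cannot separate them at the given
#' precursor m/z and charge.
#'
#' @param tolerance_ppm Proposed MS1 matching tolerance.
#' @param precursor_mz Representative precursor m/z of the quantified
#'   peptide.
#' @param charge Charge state at which the peptide is quantified.
#' @param scheme A [derivatization_scheme()].
#' @return Invisibly, the me3-ac gap in ppm at this m/z.
#' @export
validate_tolerance <- function(tolerance_ppm, precursor_mz, charge,
                               scheme = derivatization_scheme()) {
  gap_da <- 3 * scheme$light_methyl_delta - scheme$acetyl_delta
  gap_ppm <- 1e6 * abs(gap_da) / charge / precursor_mz
  if (tolerance_ppm >= gap_ppm / 2)
    stop(sprintf(paste0(
      "tolerance %.1f ppm cannot resolve the me3/ac gap ",
      "(%.4f Da = %.1f ppm at m/z %.1f, z=%d)"),
      tolerance_ppm, gap_da, gap_ppm, precursor_mz, charge))
  invisible(gap_ppm)
}
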