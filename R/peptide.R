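#' Construct a peptide on a mature histone sequence
#'
#' Residue coordinates are 1-based inclusive on the mature protein, with the
#' initiator methionine excluded (histone community convention: H3 residue 1
#' is the Ala of ARTK...). Lysine positions are given in the same absolute
#' numbering, so K27 of H3 is position 27.
#'
#' @param protein Protein identifier, e.g. `"H3"`.
#' @param start,end 1-based inclusive residue interval on the mature protein.
#' @param sequence Amino-acid sequence of the peptide (must have length
#'   `end - start + 1`).
#' @return An object of class `peptide` with fields `protein`, `start`,
#'   `end`, `sequence` and `lysines` (absolute positions of K residues).
#' @export
peptide <- function(protein, start, end, sequence) {
  sequence <- toupper(sequence)
  if (nchar(sequence) != end - start + 1L)
    stop("sequence length does not match residue interval")
  if (!grepl("^[A-Z]+$", sequence) ||
      !all(strsplit(sequence, "")[[1]] %in% names(AA_MONO)))
    stop("sequence contains invalid amino-acid characters")
  res <- strsplit(sequence, "")[[1]]
  structure(
    list(
      protein = protein, start = as.integer(start), end = as.integer(end),
      sequence = sequence,
      lysines = as.integer(start - 1L + which(res == "K"))
    ),
    class = "peptide"
  )
}

#' @export
print.peptide <- function(x, ...) {
  cat(sprintf("%s %d-%d %s  (K at %s)\n", x$protein, x$start, x$end,
              x$sequence,
              if (length(x$lysines)) paste(x$lysines, collapse = ",") else "-"))
  invisible(x)
}

#' Proteolytic digest with optional lysine blocking
#'
#' Trypsin cleaves C-terminal to K and R but never before proline. When the
#' lysines have been chemically blocked before digestion (the derivatization
#' workflow methylates every free or monomethyl lysine on the intact
#' protein), trypsin behaves Arg-C-like and cleaves after R only.
#'
#' @param protein_sequence Amino-acid string (mature protein, no initiator
#'   Met).
#' @param blocked_lysines If `TRUE` (the derivatized workflow) cleave after R
#'   only; if `FALSE` cleave after K and R. The no-cleavage-before-P rule
#'   applies in both modes.
#' @param missed_cleavages Number of internal missed cleavage sites allowed
#'   (0-2). Peptides with up to this many missed sites are appended after the
#'   fully cleaved set.
#' @param protein Protein id attached to the resulting peptides.
#' @return List of [peptide()] objects in N-to-C order (fully cleaved first).
#' @examples
#' digest("ARTKQTAR", blocked_lysines = TRUE) # AR (1-2), TKQTAR (3-8)
#' @export
digest <- function(protein_sequence, blocked_lysines = TRUE,
                   missed_cleavages = 0L, protein = "H3") {
  protein_sequence <- toupper(protein_sequence)
  if (!nzchar(protein_sequence)) stop("empty protein sequence")
  res <- strsplit(protein_sequence, "")[[1]]
  if (!all(res %in% names(AA_MONO)))
    stop("sequence contains invalid amino-acid characters")
  if (!missed_cleavages %in% 0:2) stop("missed_cleavages must be 0, 1 or 2")
  n <- length(res)
  cleave_after <- if (blocked_lysines) res %in% "R" else res %in% c("K", "R")
  # no cleavage before proline
  cleave_after[seq_len(n - 1)][res[-1] == "P"] <- FALSE
  cleave_after[n] <- FALSE
  cuts <- c(0L, which(cleave_after), n)
  starts <- head(cuts, -1) + 1L
  ends <- cuts[-1]
  full <- Map(function(s, e) {
    peptide(protein, s, e, paste(res[s:e], collapse = ""))
  }, starts, ends)
  out <- full
  if (missed_cleavages > 0) {
    k <- length(full)
    for (m in seq_len(missed_cleavages)) {
      if (k - m < 1) break
      for (i in seq_len(k - m)) {
        s <- full[[i]]$start
        e <- full[[i + m]]$end
        out[[length(out) + 1L]] <-
          peptide(protein, s, e, paste(res[s:e], collapse = ""))
      }
    }
  }
  out
}

#' Mature histone H3 sequence shipped with the package
#'
#' Reads the canonical mature human H3.1 sequence (135 aa, initiator Met
#' removed) from the package FASTA fixture.
#'
#' @return A single character string.
#' @export
h3_sequence <- function() {
  fa <- Biostrings::readAAStringSet(
    system.file("extdata", "H3_mature.fasta", package = "histoneRx")
  )
  as.character(fa[[1]])
}

#' The canonical derivatized H3 tail peptides
#'
#' Digests the mature H3 sequence in lysine-blocked (Arg-C-like) mode and
#' returns the modification-bearing tail peptides keyed by their common
#' names: the K4 peptide (TKQTAR, 3-8), K9/K14 peptide (KSTGGKAPR, 9-17),
#' K18/K23 peptide (KQLATKAAR, 18-26) and the K27/K36/K37 peptide
#' (KSAPATGGVKKPHR, 27-40).
#'
#' @return Named list of [peptide()] objects.
#' @export
h3_tail_peptides <- function() {
  peps <- digest(h3_sequence(), blocked_lysines = TRUE)
  starts <- vapply(peps, function(p) p$start, integer(1))
  list(
    K4 = peps[[match(3L, starts)]],
    K9 = peps[[match(9L, starts)]],
    K18 = peps[[match(18L, starts)]],
    K27 = peps[[match(27L, starts)]]
  )
}

#' Enumerate PTM isoforms of a peptide
#'
#' Forms the Cartesian product of the allowed endogenous states over the
#' peptide's modifiable lysines, in a stable deterministic order
#' (lexicographic by lysine position, states cycling in the order given by
#' `allowed_states`, with the last position varying fastest).
#'
#' @param pep A [peptide()].
#' @param allowed_states Subset of `c("un","me1","me2","me3","ac")`.
#' @return List of `ptm_isoform` objects; a peptide with no lysines yields a
#'   single unmodified isoform.
#' @export
enumerate_isoforms <- function(pep,
                               allowed_states = c("un", "me1", "me2", "me3", "ac")) {
  all_states <- c("un", "me1", "me2", "me3", "ac")
  if (!all(allowed_states %in% all_states))
    stop("allowed_states must be a subset of ", paste(all_states, collapse = ", "))
  sites <- pep$lysines
  if (length(sites) == 0)
    return(list(ptm_isoform(pep, stats::setNames(character(0), character(0)))))
  grid <- expand.grid(
    rev(replicate(length(sites), allowed_states, simplify = FALSE)),
    stringsAsFactors = FALSE
  )[, rev(seq_along(sites)), drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) {
    states <- stats::setNames(as.character(grid[i, ]), as.character(sites))
    ptm_isoform(pep, states)
  })
}

#' Construct a PTM isoform
#'
#' @param pep A [peptide()].
#' @param states Named character vector mapping absolute lysine position to
#'   endogenous state (`un`, `me1`, `me2`, `me3`, `ac`). Every modifiable
#'   lysine of the peptide must be assigned exactly one state.
#' @return An object of class `ptm_isoform` with an `id` of the form
#'   `"K27me1+K36me2+K37un"`.
#' @export
ptm_isoform <- function(pep, states) {
  want <- as.character(pep$lysines)
  if (!setequal(names(states), want))
    stop("states must assign exactly the peptide's lysines: ",
         paste(want, collapse = ","))
  states <- states[want]
  ok <- states %in% c("un", "me1", "me2", "me3", "ac")
  if (!all(ok)) stop("unknown lysine state(s): ", paste(states[!ok], collapse = ","))
  id <- if (length(states)) {
    paste(sprintf("K%s%s", names(states), states), collapse = "+")
  } else {
    "unmodified"
  }
  structure(list(peptide = pep, states = states, id = id),
            class = "ptm_isoform")
}

#' @export
print.ptm_isoform <- function(x, ...) {
  cat(sprintf("%s %d-%d  %s\n", x$peptide$protein, x$peptide$start,
              x$peptide$end, x$id))
  invisible(x)
}
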