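#' Ground truth for a synthetic derivatized LC-MS/MS run
#'
#' Defines the true modification-state composition of one histone peptide:
#' the state combinations present, their true relative abundances (fractions
#' summing to 1), per-combination retention times, and the noise model
#' (multiplicative log-normal noise on MS1 areas, additive uniform floor on
#' MS2 fragment intensities).
#'
#' @param pep A [peptide()].
#' @param combos Named list; each element a named character vector mapping
#'   lysine position to state, as accepted by [ptm_isoform()].
#' @param abundances Numeric vector of true relative abundances, parallel to
#'   `combos`, non-negative, summing to 1 (within 1e-9).
#' @param rts True retention-time apexes (minutes, positive), parallel to
#'   `combos`. Combinations with equal precursor mass and RT within
#'   `rt_window` of each other co-elute into one shared XIC peak.
#' @param sigma_area Log-normal sigma of the multiplicative MS1 area noise
#'   (0 = noiseless).
#' @param frag_noise Additive MS2 noise, as a fraction of the most intense
#'   fragment (0 = noiseless).
#' @param seed Mandatory integer seed; no global random state is used.
#' @return Object of class `ptm_ground_truth`.
#' @export
ptm_ground_truth <- function(pep, combos, abundances, rts,
                             sigma_area = 0.05, frag_noise = 0.01, seed) {
  if (!inherits(pep, "peptide")) stop("unknown peptide: pass a peptide object")
  if (length(combos) != length(abundances) || length(combos) != length(rts))
    stop("combos, abundances and rts must be parallel")
  if (any(abundances < 0)) stop("abundances must be non-negative")
  if (abs(sum(abundances) - 1) > 1e-9) stop("abundances must sum to 1")
  if (any(rts <= 0)) stop("retention times must be positive")
  if (sigma_area < 0 || frag_noise < 0)
    stop("noise parameters must be non-negative")
  if (missing(seed)) stop("seed is a mandatory argument")
  if (is.null(names(combos))) names(combos) <- paste0("combo", seq_along(combos))
  structure(
    list(peptide = pep, combos = combos, abundances = abundances, rts = rts,
         sigma_area = sigma_area, frag_noise = frag_noise,
         seed = as.integer(seed)),
    class = "ptm_ground_truth"
  )
}

#' Simulate XIC peaks and MS2 spectra from a PTM ground truth
#'
#' Builds the derivatized isoform for every true state combination, collapses
#' combinations with identical precursor mass and overlapping retention time
#' into shared XIC peaks (co-eluting isobaric positional isomers), and emits:
#' one MS1 peak per resolvable m/z-RT group and charge state, with area
#' proportional to the summed true abundances times a global scale under
#' multiplicative log-normal noise; and one MS2 spectrum per group whose
#' fragment intensities are proportional to the co-eluters' abundances plus
#' an additive uniform noise floor. Deterministic for a fixed seed.
#'
#' @param truth A [ptm_ground_truth()].
#' @param scheme A [derivatization_scheme()].
#' @param sample Sample label written into the peak table.
#' @param scale Global MS1 intensity scale (area of a 100%-abundant form at
#'   the primary charge).
#' @param charges Charge states at which each form is observed.
#' @param charge_weights Fraction of the total area appearing at each charge
#'   (parallel to `charges`; the first is the primary charge).
#' @param rt_window Retention-time window (min) within which equal-mass
#'   combinations co-elute.
#' @return List with `peaks` (data.frame `sample`, `mz`, `z`, `rt`, `area`),
#'   `spectra` (list of spectra: `precursor_mz`, `z`, `rt`, `fragments`
#'   data.frame), and `isoforms` (the true isoform objects, named by combo).
#' @export
simulate_ptm_run <- function(truth, scheme = derivatization_scheme(),
                             sample = "sample1", scale = 1e6,
                             charges = c(2L, 3L),
                             charge_weights = c(0.7, 0.3),
                             rt_window = 0.5) {
  stopifnot(inherits(truth, "ptm_ground_truth"),
            length(charges) == length(charge_weights))
  isoforms <- lapply(truth$combos, function(s) ptm_isoform(truth$peptide, s))
  masses <- vapply(isoforms, derivatized_mass, numeric(1), scheme = scheme)

  # co-elution groups: identical mass (1e-4 Da) and RT gaps <= rt_window
  mkey <- as.character(round(masses, 4))
  groups <- list()
  for (key in unique(mkey)) {
    ix <- which(mkey == key)
    ix <- ix[order(truth$rts[ix])]
    cur <- ix[1]
    for (j in ix[-1]) {
      if (truth$rts[j] - truth$rts[utils::tail(cur, 1)] <= rt_window) {
        cur <- c(cur, j)
      } else {
        groups[[length(groups) + 1L]] <- cur
        cur <- j
      }
    }
    groups[[length(groups) + 1L]] <- cur
  }

  withr::with_seed(truth$seed, {
    peaks <- list()
    spectra <- list()
    for (g in groups) {
      ab <- truth$abundances[g]
      tot <- sum(ab)
      if (tot == 0) next
      rt <- sum(truth$rts[g] * ab) / tot
      noise <- if (truth$sigma_area > 0)
        exp(stats::rnorm(length(charges), 0, truth$sigma_area)) else 1
      for (k in seq_along(charges)) {
        peaks[[length(peaks) + 1L]] <- data.frame(
          sample = sample,
          mz = mz(unname(masses[g[1]]), charges[k]),
          z = charges[k],
          rt = rt,
          area = scale * charge_weights[k] * tot *
            (if (length(noise) > 1) noise[k] else noise)
        )
      }
      # MS2 spectrum: members' b/y ions at intensity proportional to abundance
      frag <- do.call(rbind, lapply(seq_along(g), function(i) {
        fi <- fragment_ions(isoforms[[g[i]]], scheme)
        data.frame(mz = fi$mz, intensity = 1000 * ab[i])
      }))
      # shared ions (equal m/z) accumulate
      frag <- stats::aggregate(intensity ~ mz,
                               data.frame(mz = round(frag$mz, 4),
                                          intensity = frag$intensity), sum)
      if (truth$frag_noise > 0)
        frag$intensity <- frag$intensity +
          stats::runif(nrow(frag), 0, truth$frag_noise * max(frag$intensity))
      spectra[[length(spectra) + 1L]] <- list(
        precursor_mz = mz(unname(masses[g[1]]), charges[1]),
        z = charges[1], rt = unname(rt), fragments = frag
      )
    }
    list(peaks = do.call(rbind, peaks), spectra = spectra,
         isoforms = isoforms)
  })
}
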