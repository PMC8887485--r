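#' Match observed XIC peaks to candidate PTM isoforms
#'
#' Each MS1 peak is matched to every isoform whose theoretical m/z at the
#' peak's charge lies within `tolerance_ppm`. Candidates are grouped by
#' distinct theoretical neutral mass: members of one mass group are isobaric
#' positional isomers (indistinguishable at MS1, resolved later by fragment
#' ions), while several distinct mass groups within tolerance constitute a
#' genuine ambiguity. Where an ambiguity involves mass groups whose state
#' classes are ordered by `rt_rule` and equally many co-matching peaks
#' exist, the peaks are assigned to groups by retention-time rank; anything
#' still unresolved is carried forward flagged, never dropped.
#'
#' @param peaks `data.frame` of XIC peaks with columns `sample`, `mz`, `z`,
#'   `rt`, `area` (see [read_peaks_tsv()]).
#' @param isoforms List of [ptm_isoform()] objects (the candidate universe,
#'   typically [enumerate_isoforms()] output).
#' @param scheme A [derivatization_scheme()].
#' @param tolerance_ppm MS1 matching tolerance (default 10 ppm).
#' @param rt_rule Character vector of endogenous state classes in elution
#'   order (earlier elutes first), used only to break ties between
#'   non-isobaric mass groups that fall within tolerance. The default
#'   encodes the dimethyl-before-acetyl elution heuristic.
#' @return The `peaks` data.frame with list-column `candidates` (integer
#'   indices into `isoforms`), integer `n_mass_groups`, and logical
#'   `ambiguous`. Unmatched peaks get an empty candidate set.
#' @export
match_peaks <- function(peaks, isoforms, scheme = derivatization_scheme(),
                        tolerance_ppm = 10, rt_rule = c("me2", "ac")) {
  stopifnot(all(c("mz", "z", "rt", "area") %in% names(peaks)))
  masses <- vapply(isoforms, derivatized_mass, numeric(1), scheme = scheme)
  cand <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    theo <- mz(masses, peaks$z[i])
    cand[[i]] <- which(abs(ppm_diff(peaks$mz[i], theo)) <= tolerance_ppm)
  }
  # mass-group structure per peak (isobars collapse to one group)
  groups <- lapply(cand, function(ix) {
    if (!length(ix)) return(list())
    split(ix, round(masses[ix], 4))
  })
  n_groups <- lengths(groups)
  ambiguous <- n_groups > 1L
  # RT-rule disambiguation: peaks sharing an identical multi-group candidate
  # signature are assigned to groups in elution order when counts match
  sig <- vapply(cand, paste, character(1), collapse = ",")
  for (s in unique(sig[ambiguous])) {
    rows <- which(sig == s & ambiguous)
    grp <- groups[[rows[1]]]
    classes <- group_classes(grp, isoforms)
    if (length(rows) == length(grp) && !anyNA(classes) &&
        all(classes %in% rt_rule)) {
      ord_grp <- order(match(classes, rt_rule))
      ord_peak <- order(peaks$rt[rows])
      for (k in seq_along(rows)) {
        r <- rows[ord_peak[k]]
        cand[[r]] <- unname(grp[[ord_grp[k]]])
        ambiguous[r] <- FALSE
        n_groups[r] <- 1L
      }
    }
  }
  peaks$candidates <- cand
  peaks$n_mass_groups <- n_groups
  peaks$ambiguous <- ambiguous
  peaks
}

# the state that sets each mass group apart from the other group sharing a
# peak (two-group collisions only): compare state multisets pairwise and
# return each group's unique state, or NA when no single state distinguishes
group_classes <- function(grp, isoforms) {
  if (length(grp) != 2) return(rep(NA_character_, length(grp)))
  s1 <- sort(unname(isoforms[[grp[[1]][1]]]$states))
  s2 <- sort(unname(isoforms[[grp[[2]][1]]]$states))
  d1 <- setdiff_multiset(s1, s2)
  d2 <- setdiff_multiset(s2, s1)
  c(if (length(d1) == 1) d1 else NA_character_,
    if (length(d2) == 1) d2 else NA_character_)
}

setdiff_multiset <- function(a, b) {
  for (x in b) {
    hit <- match(x, a)
    if (!is.na(hit)) a <- a[-hit]
  }
  a
}

#' Select the quantification peak among charge states
#'
#' The same peptide form is typically observed at several charge states;
#' only the most intense one is used for peak-area quantification. Ties are
#' broken toward the lower charge.
#'
#' @param peaks `data.frame` of candidate XIC peaks (one isoform group
#'   across charge states) with columns `z` and `area`.
#' @return The selected single-row `data.frame`.
#' @export
select_quant_peak <- function(peaks) {
  if (is.null(peaks) || nrow(peaks) == 0) stop("no candidate peaks")
  ord <- order(-peaks$area, peaks$z)
  peaks[ord[1], , drop = FALSE]
}

#' Apportion a shared XIC peak area among co-eluting isobaric isoforms
#'
#' Positional isomers with identical precursor mass share one MS1 peak; the
#' fragment spectrum tells them apart. For every isoform the intensities of
#' its pairwise-unique b/y ions found in the spectrum are summed, and the
#' shared area is split in proportion to those sums. The split conserves the
#' input area exactly.
#'
#' @param shared_area Integrated area of the shared XIC peak.
#' @param spectrum List with element `fragments`: a `data.frame` with
#'   columns `mz` and `intensity` (see [read_spectra_tsv()]).
#' @param isoforms List of pairwise-isobaric [ptm_isoform()] objects.
#' @param scheme A [derivatization_scheme()].
#' @param tolerance_ppm Fragment matching tolerance.
#' @return Named numeric vector (isoform id -> apportioned area) with
#'   attribute `zero_unique`: ids that had unique ions defined but none
#'   detected (assigned area 0).
#' @export
split_isobaric <- function(shared_area, spectrum, isoforms,
                           scheme = derivatization_scheme(),
                           tolerance_ppm = 10) {
  if (length(isoforms) == 1) {
    out <- stats::setNames(shared_area, isoforms[[1]]$id)
    attr(out, "zero_unique") <- character(0)
    return(out)
  }
  frags <- lapply(isoforms, fragment_ions, scheme = scheme)
  n <- length(isoforms)
  sums <- numeric(n)
  for (i in seq_len(n)) {
    fi <- frags[[i]]
    # unique = differs from the matching (series,index) ion of EVERY other
    uniq <- rep(TRUE, nrow(fi))
    for (j in setdiff(seq_len(n), i)) {
      fj <- frags[[j]]
      uniq <- uniq & abs(ppm_diff(fi$mz, fj$mz)) > tolerance_ppm
    }
    if (!any(uniq)) {
      # in >2-way isomer groups a "middle" isomer can lack strictly unique
      # ions; it is unquantifiable here and falls into the zero/warning path
      sums[i] <- 0
      next
    }
    umz <- fi$mz[uniq]
    obs <- spectrum$fragments
    hit <- vapply(umz, function(m) {
      sel <- abs(ppm_diff(obs$mz, m)) <= tolerance_ppm
      if (any(sel)) sum(obs$intensity[sel]) else 0
    }, numeric(1))
    sums[i] <- sum(hit)
  }
  if (all(sums == 0))
    stop("unresolved isobars: no unique fragment of any isoform detected")
  zero <- vapply(isoforms, function(x) x$id, character(1))[sums == 0]
  if (length(zero))
    warning("isoform(s) with no detected unique fragments assigned area 0: ",
            paste(zero, collapse = ", "))
  areas <- shared_area * sums / sum(sums)
  out <- stats::setNames(areas, vapply(isoforms, function(x) x$id, character(1)))
  attr(out, "zero_unique") <- zero
  out
}

#' Quantify one LC-MS/MS run end to end
#'
#' Matches MS1 peaks to candidate isoforms, picks the most intense charge
#' state per isoform group, resolves co-eluting isobaric groups through
#' their MS2 spectra, and normalizes to a per-peptide [relative_abundance()]
#' table.
#'
#' @param peaks XIC peak `data.frame` (`sample`, `mz`, `z`, `rt`, `area`).
#' @param spectra List of MS2 spectra (`precursor_mz`, `z`, `rt`,
#'   `fragments`).
#' @param isoforms Candidate [ptm_isoform()] list (e.g. the full
#'   [enumerate_isoforms()] output for each peptide of interest).
#' @param scheme A [derivatization_scheme()].
#' @param tolerance_ppm MS1/MS2 matching tolerance.
#' @param rt_rule Elution-order rule passed to [match_peaks()].
#' @param rt_window RT window (min) for pairing a shared peak with its MS2
#'   spectrum.
#' @return An `abundance_table`.
#' @export
quantify_ptm_run <- function(peaks, spectra, isoforms,
                             scheme = derivatization_scheme(),
                             tolerance_ppm = 10, rt_rule = c("me2", "ac"),
                             rt_window = 0.5) {
  matched <- match_peaks(peaks, isoforms, scheme, tolerance_ppm, rt_rule)
  matched <- matched[lengths(matched$candidates) > 0, , drop = FALSE]
  if (nrow(matched) == 0) stop("no peak matched any candidate isoform")
  masses <- vapply(isoforms, derivatized_mass, numeric(1), scheme = scheme)
  pep_label <- function(iso)
    sprintf("%s:%d-%d", iso$peptide$protein, iso$peptide$start,
            iso$peptide$end)
  sig <- vapply(matched$candidates, paste, character(1), collapse = ",")
  rows <- list()
  for (s in unique(sig)) {
    grp_peaks <- matched[sig == s, , drop = FALSE]
    sel <- select_quant_peak(grp_peaks)
    cand <- isoforms[grp_peaks$candidates[[1]]]
    if (length(cand) > 1) {
      spec <- find_spectrum(spectra, masses[grp_peaks$candidates[[1]][1]],
                            sel$rt, tolerance_ppm, rt_window)
      if (is.null(spec))
        stop("unresolved isobars: no MS2 spectrum found for shared peak at ",
             sprintf("m/z %.4f", sel$mz))
      # identification before quantification: candidates whose fragment set
      # is poorly covered by the spectrum are not present and would only
      # dilute the strict-uniqueness split
      cand <- screen_isobars(spec, cand, scheme, tolerance_ppm)
    }
    if (length(cand) > 1) {
      areas <- split_isobaric(sel$area, spec, cand, scheme, tolerance_ppm)
    } else {
      areas <- stats::setNames(sel$area, cand[[1]]$id)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      peptide = vapply(cand, pep_label, character(1)),
      iso_id = names(areas), area = as.numeric(areas)
    )
  }
  relative_abundance(do.call(rbind, rows))
}

#' Screen isobaric candidates by MS2 fragment coverage
#'
#' Of a set of co-matching isobaric isoforms, keeps those whose theoretical
#' b/y fragments are (near-)fully represented in the observed spectrum --
#' the identification step that precedes quantification. An isoform that is
#' actually present has every fragment in the spectrum; positional isomers
#' that merely share part of their ladder with the present forms show lower
#' coverage and are excluded before the unique-ion split.
#'
#' @param spectrum List with a `fragments` data.frame (`mz`, `intensity`).
#' @param isoforms List of isobaric [ptm_isoform()] candidates.
#' @param scheme A [derivatization_scheme()].
#' @param tolerance_ppm Fragment matching tolerance.
#' @param min_coverage Keep candidates whose coverage is at least this
#'   fraction of the best candidate's coverage (default 0.98).
#' @return The retained subset of `isoforms` (at least the best-covered one).
#' @export
screen_isobars <- function(spectrum, isoforms,
                           scheme = derivatization_scheme(),
                           tolerance_ppm = 10, min_coverage = 0.98) {
  if (length(isoforms) <= 1) return(isoforms)
  obs <- spectrum$fragments$mz
  cov <- vapply(isoforms, function(iso) {
    theo <- fragment_ions(iso, scheme)$mz
    mean(vapply(theo, function(m)
      any(abs(ppm_diff(obs, m)) <= tolerance_ppm), logical(1)))
  }, numeric(1))
  isoforms[cov >= min_coverage * max(cov)]
}

# locate the MS2 spectrum whose precursor neutral mass matches within
# tolerance and whose RT is nearest (within rt_window)
find_spectrum <- function(spectra, neutral_mass, rt, tolerance_ppm,
                          rt_window) {
  if (!length(spectra)) return(NULL)
  nm <- vapply(spectra, function(sp) sp$precursor_mz * sp$z - sp$z * PROTON_MASS,
               numeric(1))
  rts <- vapply(spectra, function(sp) sp$rt, numeric(1))
  ok <- abs(1e6 * (nm - neutral_mass) / neutral_mass) <= tolerance_ppm &
    abs(rts - rt) <= rt_window
  if (!any(ok)) return(NULL)
  spectra[[which(ok)[which.min(abs(rts[ok] - rt))]]]
}

#' Relative PTM abundances normalized to 100% per peptide
#'
#' The total peak area of a peptide across all its modification forms is
#' taken as 100%, and every form's percentage is its area divided by that
#' total. Marginal per-site state percentages (e.g. "K27me3" summed over all
#' combinations carrying it) are computed alongside the full combinations.
#'
#' @param areas `data.frame` with columns `peptide`, `iso_id`, `area`
#'   (isoform ids as produced by [ptm_isoform()]).
#' @return Object of class `abundance_table`: list with `combinations`
#'   (`peptide`, `iso_id`, `percent`) and `marginals` (`peptide`, `site`,
#'   `state`, `percent`). Peptides whose total area is zero are reported in
#'   `missing` and omitted from both tables.
#' @export
relative_abundance <- function(areas) {
  stopifnot(all(c("peptide", "iso_id", "area") %in% names(areas)))
  if (any(areas$area < 0)) stop("negative peak area")
  tot <- tapply(areas$area, areas$peptide, sum)
  missing <- names(tot)[tot == 0]
  keep <- !(areas$peptide %in% missing)
  areas <- areas[keep, , drop = FALSE]
  comb <- data.frame(
    peptide = areas$peptide,
    iso_id = areas$iso_id,
    percent = 100 * areas$area / as.numeric(tot[areas$peptide])
  )
  # marginals: split "K27me1+K36un" ids into (site, state) tokens
  marg <- do.call(rbind, lapply(seq_len(nrow(comb)), function(i) {
    toks <- strsplit(comb$iso_id[i], "+", fixed = TRUE)[[1]]
    toks <- toks[toks != "unmodified"]
    if (!length(toks)) return(NULL)
    m <- regmatches(toks, regexec("^K([0-9]+)(un|me1|me2|me3|ac)$", toks))
    data.frame(
      peptide = comb$peptide[i],
      site = vapply(m, function(x) paste0("K", x[2]), character(1)),
      state = vapply(m, function(x) x[3], character(1)),
      percent = comb$percent[i]
    )
  }))
  if (!is.null(marg)) {
    marg <- stats::aggregate(percent ~ peptide + site + state, marg, sum)
    marg <- marg[order(marg$peptide, as.integer(sub("^K", "", marg$site)),
                       marg$state), , drop = FALSE]
    rownames(marg) <- NULL
  } else {
    marg <- data.frame(peptide = character(0), site = character(0),
                       state = character(0), percent = numeric(0))
  }
  structure(list(combinations = comb, marginals = marg, missing = missing),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("Abundance table:", length(unique(x$combinations$peptide)),
      "peptide(s),", nrow(x$combinations), "combination(s)\n")
  print(utils::head(x$combinations, 10))
  invisible(x)
}

#' Average abundance tables across replicate runs
#'
#' Percentages are computed per run and then averaged across runs; the
#' across-run standard deviation is reported alongside.
#'
#' @param tables List of `abundance_table` objects (one per replicate run).
#' @param which `"marginals"` or `"combinations"`.
#' @return `data.frame` with the grouping columns plus `percent` (mean) and
#'   `sd`.
#' @export
average_abundance <- function(tables, which = c("marginals", "combinations")) {
  which <- match.arg(which)
  key_cols <- if (which == "marginals") c("peptide", "site", "state")
              else c("peptide", "iso_id")
  df <- do.call(rbind, lapply(seq_along(tables), function(i) {
    d <- tables[[i]][[which]]
    d$run <- i
    d
  }))
  agg_mean <- stats::aggregate(df$percent, df[key_cols], mean)
  agg_sd <- stats::aggregate(df$percent, df[key_cols], stats::sd)
  out <- agg_mean
  names(out)[ncol(out)] <- "percent"
  out$sd <- agg_sd$x
  out
}

#' Log base-1.5 fold-change matrix between two conditions
#'
#' For every key shared by both abundance tables computes
#' `log((pB + pseudocount) / (pA + pseudocount)) / log(1.5)` -- the scale on
#' which a 1.5-fold change reads as 1. A small pseudocount (percentage
#' points) keeps undetected states finite.
#'
#' @param tableA,tableB `abundance_table` objects, or data.frames as
#'   returned by [average_abundance()].
#' @param pseudocount Percentage points added to both terms (default 0.01).
#' @param which `"marginals"` or `"combinations"` when abundance_table
#'   objects are supplied.
#' @return `data.frame` with the key columns, `percent_A`, `percent_B`, and
#'   `log1p5_fc`. Keys present in only one condition are dropped with a
#'   warning.
#' @export
fold_change <- function(tableA, tableB, pseudocount = 0.01,
                        which = c("marginals", "combinations")) {
  which <- match.arg(which)
  pick <- function(x) if (inherits(x, "abundance_table")) x[[which]] else x
  a <- pick(tableA)
  b <- pick(tableB)
  key_cols <- intersect(names(a), c("peptide", "site", "state", "iso_id"))
  a$.key <- do.call(paste, c(a[key_cols], sep = "\r"))
  b$.key <- do.call(paste, c(b[key_cols], sep = "\r"))
  only <- c(setdiff(a$.key, b$.key), setdiff(b$.key, a$.key))
  if (length(only))
    warning(length(only), " key(s) present in only one condition omitted")
  shared <- intersect(a$.key, b$.key)
  a <- a[match(shared, a$.key), , drop = FALSE]
  b <- b[match(shared, b$.key), , drop = FALSE]
  out <- a[key_cols]
  out$percent_A <- a$percent
  out$percent_B <- b$percent
  out$log1p5_fc <- log((b$percent + pseudocount) / (a$percent + pseudocount)) /
    log(1.5)
  rownames(out) <- NULL
  out
}
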