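#' Run the histone-PTM quantification arm
#'
#' Orchestrates one two-condition PTM experiment: for every replicate run of
#' each condition, quantifies the XIC peaks and MS2 spectra into a relative
#' abundance table ([quantify_ptm_run()]), averages percentages across
#' replicates, computes the log base-1.5 fold-change matrix between the two
#' conditions, and writes abundance and fold-change TSVs plus a
#' reproducibility manifest.
#'
#' Inputs come either from ground truths (`truths`: a named list with one
#' element per condition, each a list of [ptm_ground_truth()] replicates,
#' simulated at run time) or from files (`inputs`: per condition, a list of
#' replicates each holding `peaks` and `spectra` TSV paths).
#'
#' @param truths Named list (condition -> list of [ptm_ground_truth()]).
#' @param inputs Named list (condition -> list of lists with `peaks`,
#'   `spectra` paths); ignored when `truths` is given.
#' @param isoforms Candidate isoform list; defaults to the full state
#'   enumeration of the peptides seen in the truths.
#' @param scheme A [derivatization_scheme()].
#' @param out_dir Output directory (created if needed).
#' @param tolerance_ppm,rt_rule Matching parameters (see [match_peaks()]).
#' @param pseudocount Percentage-point pseudocount for [fold_change()].
#' @return List with `abundance` (per-condition averaged marginals),
#'   `fold_change` data.frame, `tables` (per condition, per replicate
#'   `abundance_table`s) and `manifest`.
#' @export
run_ptm_arm <- function(truths = NULL, inputs = NULL, isoforms = NULL,
                        scheme = derivatization_scheme(),
                        out_dir = tempfile("ptm_arm_"),
                        tolerance_ppm = 10, rt_rule = c("me2", "ac"),
                        pseudocount = 0.01) {
  if (is.null(truths) && is.null(inputs))
    stop("provide either truths (synthetic mode) or inputs (file mode)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  conditions <- names(if (!is.null(truths)) truths else inputs)
  if (length(conditions) != 2)
    stop("the PTM arm expects exactly two conditions")

  runs <- list()
  for (cn in conditions) {
    reps <- if (!is.null(truths)) truths[[cn]] else inputs[[cn]]
    runs[[cn]] <- lapply(seq_along(reps), function(i) {
      if (!is.null(truths)) {
        sim <- simulate_ptm_run(reps[[i]], scheme,
                                sample = sprintf("%s_rep%d", cn, i))
        list(peaks = sim$peaks, spectra = sim$spectra,
             peptide = reps[[i]]$peptide)
      } else {
        list(peaks = read_peaks_tsv(reps[[i]]$peaks),
             spectra = read_spectra_tsv(reps[[i]]$spectra), peptide = NULL)
      }
    })
  }
  if (is.null(isoforms)) {
    peps <- unique(unlist(lapply(runs, function(r)
      lapply(r, function(x) x$peptide)), recursive = FALSE))
    peps <- peps[!vapply(peps, is.null, logical(1))]
    if (!length(peps))
      stop("file mode requires an explicit candidate isoform list")
    isoforms <- unlist(lapply(peps, enumerate_isoforms), recursive = FALSE)
  }

  tables <- lapply(runs, function(r) lapply(r, function(x)
    quantify_ptm_run(x$peaks, x$spectra, isoforms, scheme,
                     tolerance_ppm, rt_rule)))
  avg <- lapply(tables, average_abundance, which = "marginals")
  fc <- fold_change(avg[[conditions[1]]], avg[[conditions[2]]],
                    pseudocount = pseudocount)

  paths <- character(0)
  for (cn in conditions) {
    p <- file.path(out_dir, paste0("abundance_", cn, ".tsv"))
    utils::write.table(avg[[cn]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  p_fc <- file.path(out_dir, "fold_change.tsv")
  utils::write.table(fc, p_fc, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p_fc)
  manifest <- write_manifest(
    params = list(conditions = conditions, tolerance_ppm = tolerance_ppm,
                  rt_rule = rt_rule, pseudocount = pseudocount,
                  n_candidate_isoforms = length(isoforms),
                  scheme = unclass(scheme)),
    outputs = paths,
    path = file.path(out_dir, "manifest.json")
  )
  list(abundance = avg, fold_change = fc, tables = tables,
       manifest = manifest, out_dir = out_dir)
}

#' Run the ChIP-Rx domain-dynamics arm
#'
#' Orchestrates one two-condition spike-in ChIP analysis: simulates (or
#' loads) per-sample binned coverage and called peaks, computes per-sample
#' Rx factors from the spike-in counts, normalizes and replicate-averages
#' the tracks, partitions the two peak sets into clusters I/II/III, builds
#' the per-gene signal table over TSS-TES +/- flank windows, classifies
#' strong genes, and computes the composite profile around cluster peak
#' centers. Writes cluster BEDs, the gene table, a summary JSON and a
#' manifest.
#'
#' @param truth A [chiprx_ground_truth()] (synthetic mode).
#' @param experiment A pre-built experiment as returned by
#'   [simulate_chiprx_experiment()]; overrides `truth` simulation (use this
#'   to feed file-loaded samples with the same structure).
#' @param noise Passed to [simulate_chiprx_experiment()].
#' @param out_dir Output directory.
#' @param scale_constant Rx factor numerator (default 1e6).
#' @param min_overlap_bp Minimum shared-peak overlap; defaults to the
#'   truth's read length.
#' @param gene_flank_bp TSS-TES window extension (default 2500).
#' @param profile_flank_bp Profile half-window around peak centers
#'   (default 5000).
#' @param fold_threshold Strong-gene threshold (default 2).
#' @param pseudocount Pseudocount for the gene fold change; default 1% of
#'   the genome-wide median bin value of condition A.
#' @return List with `rx_factors`, `tracks` (per-condition averaged
#'   normalized tracks), `partition`, `gene_table`, `strong_genes`,
#'   `profiles` (per cluster), `manifest`.
#' @export
run_chiprx_arm <- function(truth = NULL, experiment = NULL,
                           noise = "poisson",
                           out_dir = tempfile("chiprx_arm_"),
                           scale_constant = 1e6, min_overlap_bp = NULL,
                           gene_flank_bp = 2500L, profile_flank_bp = 5000L,
                           fold_threshold = 2.0, pseudocount = NULL) {
  if (is.null(truth) && is.null(experiment))
    stop("provide a chiprx_ground_truth or a pre-built experiment")
  if (is.null(experiment))
    experiment <- simulate_chiprx_experiment(truth, noise = noise)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  conds <- names(experiment$peaks)
  if (length(conds) != 2) stop("the ChIP-Rx arm expects two conditions")
  if (is.null(min_overlap_bp))
    min_overlap_bp <- if (!is.null(truth)) truth$read_length else 50L

  by_cond <- split(experiment$samples,
                   vapply(experiment$samples, `[[`, character(1), "condition"))
  if (any(lengths(by_cond) == 0)) stop("a condition has no replicates")
  factors <- lapply(experiment$samples, function(s)
    rx_factor(s$spikein_count, scale_constant))
  names(factors) <- vapply(experiment$samples, `[[`, character(1), "sample")
  tracks <- lapply(conds, function(cn) {
    reps <- by_cond[[cn]]
    norm <- lapply(reps, function(s)
      normalize_track(s$track, rx_factor(s$spikein_count, scale_constant)))
    average_replicates(norm)
  })
  names(tracks) <- conds

  part <- cluster_peaks(experiment$peaks[[conds[1]]],
                        experiment$peaks[[conds[2]]],
                        min_overlap_bp = min_overlap_bp,
                        labels = c(A = conds[1], B = conds[2]))
  gene_tab <- gene_signal_table(tracks[[conds[1]]], tracks[[conds[2]]],
                                experiment$genes, flank_bp = gene_flank_bp,
                                pseudocount = pseudocount)
  strong <- gene_tab$gene_id[gene_tab$fold_change >= fold_threshold]

  profiles <- lapply(
    list(clusterI = part$clusterI, clusterII = part$clusterII_B,
         clusterIII = part$clusterIII),
    function(gr) {
      if (length(gr) == 0) return(NULL)
      anchors <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(gr)),
        pos = floor((GenomicRanges::start(gr) - 1 +
                       GenomicRanges::end(gr)) / 2)
      )
      anchor_profile(tracks[[conds[2]]], anchors,
                     flank_bp = profile_flank_bp)
    })

  paths <- character(0)
  for (nm in c("clusterI", "clusterII_A", "clusterII_B", "clusterIII")) {
    if (length(part[[nm]]) == 0) next
    p <- file.path(out_dir, paste0(nm, ".bed"))
    write_bed(part[[nm]], p)
    paths <- c(paths, p)
  }
  p_gene <- file.path(out_dir, "gene_signal.tsv")
  utils::write.table(gene_tab, p_gene, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p_gene)
  p_sum <- file.path(out_dir, "summary.json")
  jsonlite::write_json(
    list(conditions = conds,
         cluster_sizes = list(I = length(part$clusterI),
                              II = length(part$clusterII_A),
                              III = length(part$clusterIII)),
         n_genes = nrow(gene_tab), n_strong_genes = length(strong),
         rx_factors = lapply(factors, as.numeric)),
    p_sum, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p_sum)
  manifest <- write_manifest(
    params = list(conditions = conds, scale_constant = scale_constant,
                  min_overlap_bp = min_overlap_bp,
                  gene_flank_bp = gene_flank_bp,
                  profile_flank_bp = profile_flank_bp,
                  fold_threshold = fold_threshold, noise = noise),
    outputs = paths, path = file.path(out_dir, "manifest.json"))

  list(rx_factors = factors, tracks = tracks, partition = part,
       gene_table = gene_tab, strong_genes = strong, profiles = profiles,
       manifest = manifest, out_dir = out_dir)
}
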