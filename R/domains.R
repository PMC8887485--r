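#' Partition two peak sets into condition-specific and shared clusters
#'
#' A peak is "shared" iff it overlaps at least one peak of the other set by
#' at least `min_overlap_bp` bases (the field convention discards overlaps
#' shorter than the sequencing tag). Cluster I holds A-only peaks, cluster
#' III B-only peaks, and cluster II the shared peaks recorded from both
#' sides.
#'
#' @param setA,setB `GRanges` peak sets (conditions A and B).
#' @param min_overlap_bp Minimum overlap in bases to count as shared
#'   (default 50, a typical read/tag length; set it to the experiment's
#'   read length).
#' @param labels Named character vector with the A and B condition labels
#'   carried into the partition.
#' @return Object of class `cluster_partition`: list with `clusterI`,
#'   `clusterII_A`, `clusterII_B`, `clusterIII` (`GRanges`) and `labels`.
#' @export
cluster_peaks <- function(setA, setB, min_overlap_bp = 50L,
                          labels = c(A = "A", B = "B")) {
  if (min_overlap_bp < 1) stop("min_overlap_bp must be >= 1")
  shared_A <- IRanges::overlapsAny(setA, setB, minoverlap = min_overlap_bp)
  shared_B <- IRanges::overlapsAny(setB, setA, minoverlap = min_overlap_bp)
  structure(
    list(
      clusterI = setA[!shared_A],
      clusterII_A = setA[shared_A],
      clusterII_B = setB[shared_B],
      clusterIII = setB[!shared_B],
      labels = labels
    ),
    class = "cluster_partition"
  )
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf(
    "Cluster I (%s-only): %d   Cluster II (shared): %d/%d   Cluster III (%s-only): %d\n",
    x$labels[["A"]], length(x$clusterI), length(x$clusterII_A),
    length(x$clusterII_B), x$labels[["B"]], length(x$clusterIII)))
  invisible(x)
}

#' Percentage of one peak set overlapping another
#'
#' @param setA,setB `GRanges` peak sets.
#' @param min_overlap_bp Minimum overlap in bases.
#' @return `100 * (number of A peaks overlapping B) / |A|`.
#' @export
overlap_fraction <- function(setA, setB, min_overlap_bp = 1L) {
  if (length(setA) == 0) stop("overlap fraction undefined for an empty set A")
  100 * sum(IRanges::overlapsAny(setA, setB, minoverlap = min_overlap_bp)) /
    length(setA)
}

#' Peak-width summary statistics
#'
#' @param set A `GRanges` peak set.
#' @return List with `count`, `total_bp` and the five-number summary of the
#'   widths (`min`, `q1`, `median`, `q3`, `max`); an empty set yields an
#'   empty summary.
#' @export
width_stats <- function(set) {
  if (length(set) == 0)
    return(list(count = 0L, total_bp = 0L,
                fivenum = stats::setNames(rep(NA_real_, 5),
                                          c("min", "q1", "median", "q3", "max"))))
  w <- GenomicRanges::width(set)
  list(count = length(w), total_bp = sum(w),
       fivenum = stats::setNames(stats::fivenum(w),
                                 c("min", "q1", "median", "q3", "max")))
}

#' Histogram of peak-center distances to the nearest TSS
#'
#' The distance is signed and strand-aware: positive when the peak center
#' lies downstream (in the gene's transcription direction) of the nearest
#' TSS, negative upstream.
#'
#' @param set A `GRanges` peak set.
#' @param genes A `GRanges` of gene models with strand.
#' @param breaks Histogram bin edges in bp (passed to [hist()]); distances
#'   outside the range are clipped into the extreme bins.
#' @return List with `distance` (per-peak signed distance) and `counts`
#'   (named by interval).
#' @export
tss_distance_distribution <- function(set, genes,
                                      breaks = c(-Inf, -5e4, -1e4, -2e3, 0,
                                                 2e3, 1e4, 5e4, Inf)) {
  if (length(genes) == 0) stop("genes must be non-empty")
  centers <- floor((GenomicRanges::start(set) - 1 + GenomicRanges::end(set)) / 2)
  tss <- gene_tss(genes)
  minus <- as.character(GenomicRanges::strand(genes)) == "-"
  chrom_p <- as.character(GenomicRanges::seqnames(set))
  chrom_g <- as.character(GenomicRanges::seqnames(genes))
  dist <- vapply(seq_along(set), function(i) {
    on_chr <- which(chrom_g == chrom_p[i])
    if (!length(on_chr)) return(NA_real_)
    d <- centers[i] - tss[on_chr]
    j <- on_chr[which.min(abs(d))]
    signed <- centers[i] - tss[j]
    if (minus[j]) -signed else signed
  }, numeric(1))
  cut_lab <- cut(dist, breaks = breaks)
  list(distance = dist, counts = table(cut_lab))
}

#' Assign peaks to genes over TSS-TES +/- flank windows
#'
#' A gene is associated with a peak set iff at least one peak overlaps the
#' window `[TSS - flank, TES + flank]` (equivalently the gene body extended
#' by `flank_bp` on both sides). Each peak is additionally annotated with
#' its nearest gene -- by peak-center-to-TSS distance (the default) or by
#' edge-to-edge distance -- with ties broken by smaller distance then
#' lexicographic gene id, and labeled with a feature category derived from
#' the gene model alone: `promoter` (center within `promoter_bp` of a TSS),
#' `gene_body`, or `intergenic`.
#'
#' @param set A `GRanges` peak set.
#' @param genes A `GRanges` of gene models (`gene_id`, strand).
#' @param flank_bp Window extension on both sides of the gene body
#'   (default 2500).
#' @param nearest `"center_tss"` or `"edge"` distance convention.
#' @param promoter_bp Promoter half-width around the TSS for the feature
#'   label (default 2000).
#' @return List with `gene_peaks` (named list gene_id -> peak indices, only
#'   associated genes), `associated_genes` (character), `peak_annotation`
#'   (`data.frame`: `peak`, `nearest_gene`, `distance`, `feature`), and
#'   `feature_fraction` (named fractions over peaks).
#' @export
assign_peaks_to_genes <- function(set, genes, flank_bp = 2500L,
                                  nearest = c("center_tss", "edge"),
                                  promoter_bp = 2000L) {
  nearest <- match.arg(nearest)
  windows <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(genes),
    ranges = IRanges::IRanges(
      start = pmax(1L, GenomicRanges::start(genes) - flank_bp),
      end = GenomicRanges::end(genes) + flank_bp
    )
  )
  hits <- GenomicRanges::findOverlaps(windows, set)
  gene_ids <- genes$gene_id
  gene_peaks <- split(S4Vectors::subjectHits(hits),
                      gene_ids[S4Vectors::queryHits(hits)])
  gene_peaks <- lapply(gene_peaks, function(ix) sort(unique(ix)))

  centers <- floor((GenomicRanges::start(set) - 1 + GenomicRanges::end(set)) / 2)
  tss <- gene_tss(genes)
  chrom_p <- as.character(GenomicRanges::seqnames(set))
  chrom_g <- as.character(GenomicRanges::seqnames(genes))
  ann <- lapply(seq_along(set), function(i) {
    on_chr <- which(chrom_g == chrom_p[i])
    if (!length(on_chr))
      return(data.frame(peak = i, nearest_gene = NA_character_,
                        distance = NA_real_, feature = "intergenic"))
    d <- if (nearest == "center_tss") {
      abs(centers[i] - tss[on_chr])
    } else {
      s <- GenomicRanges::start(set)[i]; e <- GenomicRanges::end(set)[i]
      gs <- GenomicRanges::start(genes)[on_chr]
      ge <- GenomicRanges::end(genes)[on_chr]
      pmax(0, pmax(gs - e, s - ge))
    }
    ord <- order(d, gene_ids[on_chr])
    j <- on_chr[ord[1]]
    in_body <- chrom_g[j] == chrom_p[i] &
      centers[i] >= GenomicRanges::start(genes)[j] - 1 &
      centers[i] < GenomicRanges::end(genes)[j]
    feature <- if (abs(centers[i] - tss[j]) <= promoter_bp) "promoter"
      else if (in_body) "gene_body" else "intergenic"
    data.frame(peak = i, nearest_gene = gene_ids[j], distance = d[ord[1]],
               feature = feature)
  })
  ann <- do.call(rbind, ann)
  feature_fraction <- if (nrow(ann)) {
    tab <- table(factor(ann$feature,
                        levels = c("promoter", "gene_body", "intergenic")))
    stats::setNames(as.numeric(tab) / nrow(ann), names(tab))
  } else {
    stats::setNames(numeric(3), c("promoter", "gene_body", "intergenic"))
  }
  list(gene_peaks = gene_peaks,
       associated_genes = names(gene_peaks),
       peak_annotation = ann,
       feature_fraction = feature_fraction)
}

#' Per-gene normalized signal table for two conditions
#'
#' Computes the replicate-averaged Rx-normalized mean signal over
#' `TSS - flank .. TES + flank` for every gene in both conditions and the
#' B/A fold change.
#'
#' @param track_A,track_B Replicate-averaged normalized [genomic_track()]s.
#' @param genes A `GRanges` of gene models.
#' @param flank_bp Window extension (default 2500).
#' @param pseudocount Added to numerator and denominator of the fold change;
#'   default 1% of the genome-wide median bin value of condition A (see
#'   [classify_strong_genes()]).
#' @return `data.frame` with `gene_id`, `mean_A`, `mean_B`, `fold_change`.
#' @export
gene_signal_table <- function(track_A, track_B, genes, flank_bp = 2500L,
                              pseudocount = NULL) {
  win <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(genes),
    ranges = IRanges::IRanges(
      start = pmax(1L, GenomicRanges::start(genes) - flank_bp),
      end = GenomicRanges::end(genes) + flank_bp
    )
  )
  # clamp windows at chromosome ends
  lens <- track_A$genome[as.character(GenomicRanges::seqnames(win))]
  GenomicRanges::end(win) <- pmin(GenomicRanges::end(win), lens)
  if (is.null(pseudocount))
    pseudocount <- 0.01 * stats::median(unlist(track_A$values))
  mean_A <- mean_signal(track_A, win)
  mean_B <- mean_signal(track_B, win)
  data.frame(
    gene_id = genes$gene_id,
    mean_A = unname(mean_A), mean_B = unname(mean_B),
    fold_change = (unname(mean_B) + pseudocount) /
      (unname(mean_A) + pseudocount),
    row.names = NULL
  )
}

#' Classify strong genes by fold change of normalized signal
#'
#' A gene is "strong" iff its pseudocounted B/A fold change of mean
#' normalized signal over the TSS-TES window meets the threshold (the field
#' phrasing: at least a two-fold increase).
#'
#' @param signals `data.frame` from [gene_signal_table()] (columns
#'   `gene_id`, `mean_A`, `mean_B`), or one already carrying `fold_change`.
#' @param fold_threshold Minimum fold change (default 2).
#' @param pseudocount Added to both means before the ratio (default 0 when
#'   `fold_change` is present, else required).
#' @return Character vector of strong gene ids.
#' @export
classify_strong_genes <- function(signals, fold_threshold = 2.0,
                                  pseudocount = 0) {
  need <- c("gene_id", "mean_A", "mean_B")
  stopifnot(all(need %in% names(signals)))
  ok <- stats::complete.cases(signals[need])
  if (any(!ok))
    warning(sum(!ok), " gene(s) missing a condition excluded")
  s <- signals[ok, , drop = FALSE]
  fc <- (s$mean_B + pseudocount) / (s$mean_A + pseudocount)
  s$gene_id[!is.na(fc) & fc >= fold_threshold]
}

#' Inclusion-exclusion partition counts of 2-3 named gene sets
#'
#' @param sets Named list of 2 or 3 character vectors.
#' @return Named integer vector of exclusive-region counts; e.g. for two
#'   sets `A_only`, `B_only`, `A_and_B`.
#' @export
gene_set_venn <- function(sets) {
  if (!length(sets) %in% 2:3 || is.null(names(sets)))
    stop("sets must be a named list of 2 or 3 gene sets")
  sets <- lapply(sets, unique)
  nm <- names(sets)
  if (length(sets) == 2) {
    ab <- intersect(sets[[1]], sets[[2]])
    out <- c(length(setdiff(sets[[1]], sets[[2]])),
             length(setdiff(sets[[2]], sets[[1]])),
             length(ab))
    names(out) <- c(paste0(nm[1], "_only"), paste0(nm[2], "_only"),
                    paste(nm[1], "and", nm[2], sep = "_"))
    out
  } else {
    membership <- function(g)
      paste(nm[vapply(sets, function(s) g %in% s, logical(1))], collapse = "_and_")
    all_genes <- unique(unlist(sets))
    tab <- table(vapply(all_genes, membership, character(1)))
    out <- as.integer(tab)
    names(out) <- names(tab)
    out
  }
}

#' Two-group test on per-gene signal values
#'
#' Welch's unpaired two-tailed t-test, or the paired two-tailed Student's
#' t-test when `paired = TRUE` -- the standard comparisons for per-gene or
#' per-peak normalized ChIP signal between conditions.
#'
#' @param x,y Numeric vectors of per-gene values.
#' @param paired Use the paired test (requires equal lengths).
#' @return List with `statistic`, `p_value`, `df` and `method`.
#' @export
two_group_test <- function(x, y, paired = FALSE) {
  if (length(x) < 2 || length(y) < 2) stop("need at least 2 values per group")
  if (paired && length(x) != length(y))
    stop("paired test requires equal-length groups")
  if (paired && all(x - y == 0)) {
    # identical pairs: the difference is identically zero, t = 0, p = 1
    return(list(statistic = 0, p_value = 1, df = length(x) - 1,
                method = "Paired t-test"))
  }
  tt <- if (paired) stats::t.test(x, y, paired = TRUE)
        else stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), method = tt$method)
}
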