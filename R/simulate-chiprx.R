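#' Ground truth for a synthetic spike-in ChIP experiment
#'
#' Describes a two-condition ChIP-Rx experiment with known enriched domains:
#' the primary genome, per-condition true domains (with an enrichment level
#' over a flat background), per-sample sequencing depth and spike-in read
#' counts, read length, bin size, and the gene models used downstream.
#'
#' @param genome Named integer vector of chromosome lengths (bp).
#' @param domains Named list (one element per condition); each a
#'   `data.frame` with `chrom`, `start`, `end` (0-based half-open) and
#'   `enrichment` (per-base signal added inside the domain, unitless).
#'   An empty data.frame gives a flat background track for that condition.
#' @param background Per-base background signal level (>= 0).
#' @param depth Named numeric vector of per-condition depth multipliers
#'   (per-bin Poisson mean = `depth * bin * (background + enrichment)`
#'   scaled per base).
#' @param spikein_counts Named numeric vector of per-condition spike-in read
#'   counts (> 0); both replicates of a condition share the value.
#' @param spikein_genome_size Spike-in genome size in bp (bookkeeping only).
#' @param read_length Sequencing read/tag length in bp (> 0); the default
#'   minimum-overlap for peak clustering.
#' @param bin Bin size in bp (default 20).
#' @param genes Optional `data.frame` of gene models (`gene_id`, `chrom`,
#'   `strand`, `tss`, `tes`, 0-based); when `NULL` one gene is placed inside
#'   every distinct true domain and background genes fill the rest of the
#'   genome.
#' @param seed Mandatory integer seed.
#' @return Object of class `chiprx_ground_truth`.
#' @export
chiprx_ground_truth <- function(genome, domains, background = 1,
                                depth = NULL, spikein_counts = NULL,
                                spikein_genome_size = 1.4e8,
                                read_length = 50L, bin = 20L, genes = NULL,
                                seed) {
  if (missing(seed)) stop("seed is a mandatory argument")
  if (is.null(names(genome)) || any(genome <= 0))
    stop("genome must be a named vector of positive chromosome lengths")
  if (is.null(names(domains))) stop("domains must be named by condition")
  conds <- names(domains)
  for (cn in conds) {
    d <- domains[[cn]]
    if (nrow(d) == 0) next
    stopifnot(all(c("chrom", "start", "end", "enrichment") %in% names(d)))
    if (any(!d$chrom %in% names(genome)))
      stop("domain on unknown chromosome")
    if (any(d$start < 0 | d$end > genome[d$chrom] | d$start >= d$end))
      stop("domains must lie within chromosome bounds")
    if (any(d$enrichment <= 0))
      stop("domain enrichment must exceed the background")
  }
  if (background < 0) stop("background must be >= 0")
  if (read_length <= 0) stop("read length must be positive")
  if (is.null(depth)) depth <- stats::setNames(rep(1, length(conds)), conds)
  if (is.null(spikein_counts))
    spikein_counts <- stats::setNames(rep(1e6, length(conds)), conds)
  if (any(spikein_counts <= 0)) stop("spike-in read counts must be positive")
  structure(
    list(genome = genome, domains = domains, background = background,
         depth = depth[conds], spikein_counts = spikein_counts[conds],
         spikein_genome_size = spikein_genome_size,
         read_length = as.integer(read_length), bin = as.integer(bin),
         genes = genes, seed = as.integer(seed)),
    class = "chiprx_ground_truth"
  )
}

# expected (noise-free) per-bin signal for one condition: per-base rate
# integrated over the bin, so partial-bin domain overlap is exact
expected_bin_means <- function(truth, condition) {
  d <- truth$domains[[condition]]
  lapply(stats::setNames(names(truth$genome), names(truth$genome)),
         function(ch) {
    len <- truth$genome[[ch]]
    nb <- ceiling(len / truth$bin)
    starts <- (seq_len(nb) - 1L) * truth$bin
    ends <- pmin(starts + truth$bin, len)
    mu <- truth$background * (ends - starts)
    if (!is.null(d) && nrow(d)) {
      for (j in which(d$chrom == ch)) {
        ov <- pmax(0, pmin(ends, d$end[j]) - pmax(starts, d$start[j]))
        mu <- mu + d$enrichment[j] * ov
      }
    }
    truth$depth[[condition]] * mu
  })
}

#' Simulate a two-replicate, two-condition ChIP-Rx experiment
#'
#' For every condition, emits two replicate samples with binned raw coverage
#' (independent Poisson counts around `depth x (background + enrichment)`
#' per bin, or the exact means with `noise = "none"`), the per-sample
#' primary and spike-in read counts, and a "called" peak set equal to the
#' condition's true domains -- isolating the downstream interval logic from
#' peak-calling. Gene models come from the truth or are generated (one gene
#' per distinct domain plus background genes). Deterministic per seed.
#'
#' @param truth A [chiprx_ground_truth()].
#' @param noise `"poisson"` (default) or `"none"` (bins carry their exact
#'   expected values; used to verify estimators are exact in the noiseless
#'   limit).
#' @return List with `samples` (list of per-sample lists: `sample`,
#'   `condition`, `replicate`, `primary_count`, `spikein_count`, `track`),
#'   `peaks` (named list of condition `GRanges`), and `genes` (a `GRanges`
#'   with `gene_id` and a `true_domain` flag).
#' @export
simulate_chiprx_experiment <- function(truth, noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  stopifnot(inherits(truth, "chiprx_ground_truth"))
  conds <- names(truth$domains)
  withr::with_seed(truth$seed, {
    samples <- list()
    for (cn in conds) {
      mu <- expected_bin_means(truth, cn)
      for (rep_i in 1:2) {
        vals <- lapply(mu, function(m) {
          if (noise == "poisson") as.numeric(stats::rpois(length(m), m))
          else m
        })
        tr <- genomic_track(truth$genome, truth$bin, vals,
                            sample = sprintf("%s_rep%d", cn, rep_i))
        samples[[length(samples) + 1L]] <- list(
          sample = sprintf("%s_rep%d", cn, rep_i),
          condition = cn, replicate = rep_i,
          primary_count = sum(vapply(vals, sum, numeric(1))),
          spikein_count = unname(truth$spikein_counts[[cn]]),
          track = tr
        )
      }
    }
    peaks <- lapply(truth$domains, function(d) {
      if (nrow(d) == 0) return(GenomicRanges::GRanges())
      gr <- GenomicRanges::GRanges(
        seqnames = d$chrom,
        ranges = IRanges::IRanges(start = d$start + 1L, end = d$end)
      )
      GenomicRanges::sort(gr)
    })
    genes <- if (!is.null(truth$genes)) {
      genes_frame_to_granges(truth$genes)
    } else {
      generate_truth_genes(truth)
    }
    list(samples = samples, peaks = peaks, genes = genes)
  })
}

# one gene per distinct true domain (body = the domain), plus background
# genes tiled into domain-free gaps
generate_truth_genes <- function(truth) {
  all_dom <- unique(do.call(rbind, lapply(truth$domains, function(d)
    d[c("chrom", "start", "end")])))
  rows <- list()
  if (!is.null(all_dom) && nrow(all_dom)) {
    for (i in seq_len(nrow(all_dom))) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = sprintf("domgene_%s_%d", all_dom$chrom[i], all_dom$start[i]),
        chrom = all_dom$chrom[i], strand = "+",
        tss = all_dom$start[i], tes = all_dom$end[i],
        true_domain = TRUE
      )
    }
  }
  gap <- 5e4
  glen <- 2e3
  for (ch in names(truth$genome)) {
    hi <- truth$genome[[ch]] - glen - 1e4
    if (hi < 1e4) next
    pos <- seq(1e4, hi, by = gap)
    for (p in pos) {
      near <- !is.null(all_dom) && nrow(all_dom) > 0 &&
        any(all_dom$chrom == ch &
              all_dom$start - 1e4 < p + glen & all_dom$end + 1e4 > p)
      if (near) next
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = sprintf("bggene_%s_%d", ch, as.integer(p)),
        chrom = ch, strand = "+", tss = as.integer(p),
        tes = as.integer(p + glen), true_domain = FALSE
      )
    }
  }
  if (!length(rows)) {
    gr <- GenomicRanges::GRanges()
    gr$gene_id <- character(0)
    gr$true_domain <- logical(0)
    return(gr)
  }
  genes_frame_to_granges(do.call(rbind, rows))
}

#' Convert a gene-model data.frame to a strand-aware GRanges
#'
#' Input is `gene_id`, `chrom`, `strand`, `tss`, `tes` in 0-based
#' coordinates (TSS is the 5-prime end, so `tss > tes` on the minus strand
#' is accepted and reordered). The result is a `GRanges` whose `gene_id`
#' metadata column is preserved.
#'
#' @param genes The gene-model `data.frame`.
#' @return A `GRanges`.
#' @export
genes_frame_to_granges <- function(genes) {
  stopifnot(all(c("gene_id", "chrom", "strand", "tss", "tes") %in% names(genes)))
  lo <- pmin(genes$tss, genes$tes)
  hi <- pmax(genes$tss, genes$tes)
  bad <- (genes$strand == "+" & genes$tss > genes$tes) |
    (genes$strand == "-" & genes$tss < genes$tes)
  if (any(bad)) stop("TSS must be the 5-prime end for the stated strand")
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = lo + 1L, end = hi),
    strand = genes$strand
  )
  gr$gene_id <- genes$gene_id
  if (!is.null(genes$true_domain)) gr$true_domain <- genes$true_domain
  names(gr) <- genes$gene_id
  gr
}

#' Strand-aware TSS positions of gene models
#'
#' @param genes A `GRanges` of gene bodies with strand.
#' @return Integer vector of 0-based TSS coordinates (start of plus-strand
#'   genes, end of minus-strand genes).
#' @export
gene_tss <- function(genes) {
  minus <- as.character(GenomicRanges::strand(genes)) == "-"
  ifelse(minus, GenomicRanges::end(genes),
         GenomicRanges::start(genes) - 1L)
}
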