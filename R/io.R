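#' Read and write XIC peak tables
#'
#' Tab-separated with header `sample  mz  z  rt  area` (an optional
#' `peptide_hint` column is carried through untouched).
#'
#' @param path File path.
#' @return `data.frame` of peaks.
#' @export
read_peaks_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "mz", "z", "rt", "area")
  if (!all(need %in% names(df)))
    stop("peaks TSV ", path, " must have columns: ", paste(need, collapse = ", "))
  if (any(df$area < 0)) stop("negative area in ", path)
  if (any(df$z < 1)) stop("charge < 1 in ", path)
  df
}

#' @rdname read_peaks_tsv
#' @param peaks Peak `data.frame`.
#' @export
write_peaks_tsv <- function(peaks, path) {
  utils::write.table(peaks[setdiff(names(peaks),
                                   c("candidates", "n_mass_groups", "ambiguous"))],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write MS2 spectra in a long TSV dialect
#'
#' Columns `spectrum_id  precursor_mz  z  rt  fragment_mz  intensity`, one
#' row per fragment; rows sharing `spectrum_id` form one spectrum.
#'
#' @param path File path.
#' @return List of spectra (`precursor_mz`, `z`, `rt`, `fragments`).
#' @export
read_spectra_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("spectrum_id", "precursor_mz", "z", "rt", "fragment_mz", "intensity")
  if (!all(need %in% names(df)))
    stop("spectra TSV ", path, " must have columns: ", paste(need, collapse = ", "))
  if (any(df$intensity < 0)) stop("negative fragment intensity in ", path)
  lapply(split(df, df$spectrum_id), function(d) {
    list(precursor_mz = d$precursor_mz[1], z = d$z[1], rt = d$rt[1],
         fragments = data.frame(mz = d$fragment_mz, intensity = d$intensity))
  })
}

#' @rdname read_spectra_tsv
#' @param spectra List of spectra as produced by [simulate_ptm_run()].
#' @export
write_spectra_tsv <- function(spectra, path) {
  rows <- do.call(rbind, lapply(seq_along(spectra), function(i) {
    sp <- spectra[[i]]
    n <- nrow(sp$fragments)
    data.frame(spectrum_id = rep(sprintf("spec%04d", i), n),
               precursor_mz = rep(unname(sp$precursor_mz), n),
               z = rep(unname(sp$z), n), rt = rep(unname(sp$rt), n),
               fragment_mz = unname(sp$fragments$mz),
               intensity = unname(sp$fragments$intensity))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' BED6 peak-set I/O
#'
#' Thin wrappers over `rtracklayer` BED import/export; internal coordinates
#' are `GRanges` (1-based closed), converted to/from BED's 0-based half-open
#' form by the adapter.
#'
#' @param path File path.
#' @return A `GRanges`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::sort(gr)
}

#' @rdname read_bed
#' @param gr A `GRanges`.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' bedGraph track I/O
#'
#' Writes a [genomic_track()] as bedGraph (one line per run of equal-valued
#' bins, 6-decimal values) and reads one back given the genome; unsorted
#' input lines are accepted and sorted with a warning.
#'
#' @param track A [genomic_track()].
#' @param path File path.
#' @return Invisibly, the path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$genome)) {
    v <- track$values[[ch]]
    if (!length(v)) next
    nb <- length(v)
    starts <- (seq_len(nb) - 1L) * track$bin
    ends <- pmin(starts + track$bin, track$genome[[ch]])
    r <- rle(v)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    writeLines(sprintf("%s\t%d\t%d\t%.6f", ch, starts[idx_start],
                       ends[idx_end], r$values), con)
  }
  invisible(path)
}

#' @rdname write_bedgraph
#' @param genome Named chromosome lengths for the track being read.
#' @param bin Bin size of the track being read.
#' @param normalized Whether the values on disk are Rx-normalized.
#' @export
read_bedgraph <- function(path, genome, bin = 20L, normalized = FALSE) {
  df <- utils::read.delim(path, header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          stringsAsFactors = FALSE)
  if (any(df$start >= df$end))
    stop("bedGraph ", path, ": start >= end at line ",
         which(df$start >= df$end)[1])
  bad <- !df$chrom %in% names(genome)
  if (any(bad))
    stop("bedGraph ", path, ": unknown chromosome '", df$chrom[bad][1],
         "' at line ", which(bad)[1])
  ord <- order(match(df$chrom, names(genome)), df$start)
  if (!identical(ord, seq_len(nrow(df)))) {
    warning("bedGraph lines were unsorted; sorted internally")
    df <- df[ord, , drop = FALSE]
  }
  tr <- genomic_track(genome, bin, normalized = normalized)
  for (i in seq_len(nrow(df))) {
    ch <- df$chrom[i]
    first <- df$start[i] %/% bin + 1L
    last <- (df$end[i] - 1L) %/% bin + 1L
    tr$values[[ch]][first:last] <- df$value[i]
  }
  tr
}

#' Gene-model table I/O (TSV and GTF-lite)
#'
#' The TSV dialect has columns `gene_id  chrom  strand  tss  tes` with
#' 0-based coordinates, TSS being the 5-prime end. `read_genes_gtf()`
#' accepts a GTF file (1-based closed intervals) and keeps `gene`-type
#' records, converting them to the internal convention.
#'
#' @param path File path.
#' @return A `GRanges` of gene bodies with `gene_id`.
#' @export
read_genes_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss", "tes")
  if (!all(need %in% names(df)))
    stop("gene TSV ", path, " must have columns: ", paste(need, collapse = ", "))
  genes_frame_to_granges(df)
}

#' @rdname read_genes_tsv
#' @param genes A `GRanges` of gene bodies (as from
#'   [genes_frame_to_granges()]).
#' @export
write_genes_tsv <- function(genes, path) {
  minus <- as.character(GenomicRanges::strand(genes)) == "-"
  df <- data.frame(
    gene_id = genes$gene_id,
    chrom = as.character(GenomicRanges::seqnames(genes)),
    strand = as.character(GenomicRanges::strand(genes)),
    tss = ifelse(minus, GenomicRanges::end(genes),
                 GenomicRanges::start(genes) - 1L),
    tes = ifelse(minus, GenomicRanges::start(genes) - 1L,
                 GenomicRanges::end(genes))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_genes_tsv
#' @export
read_genes_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "GTF")
  gr <- gr[gr$type == "gene"]
  if (length(gr) == 0) stop("no gene-type records in ", path)
  out <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gr),
    ranges = IRanges::ranges(gr),
    strand = GenomicRanges::strand(gr)
  )
  out$gene_id <- gr$gene_id
  names(out) <- gr$gene_id
  GenomicRanges::sort(out)
}

#' Read a pipeline configuration YAML
#'
#' Validates numeric parameters (all must be positive) and fills defaults:
#' `tolerance_ppm` 10, `pseudocount_pct` 0.01, `bin` 20, `profile_flank_bp`
#' 5000, `gene_flank_bp` 2500, `fold_threshold` 2, `min_overlap_bp` 50,
#' `rt_rule` dimethyl-before-acetyl.
#'
#' @param path YAML file path.
#' @return Named list of configuration values (all defaults materialized).
#' @export
read_config_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(tolerance_ppm = 10, pseudocount_pct = 0.01, bin = 20L,
                   profile_flank_bp = 5000L, gene_flank_bp = 2500L,
                   fold_threshold = 2, min_overlap_bp = 50L,
                   rt_rule = c("me2", "ac"), seed = 1L)
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  num <- c("tolerance_ppm", "pseudocount_pct", "bin", "profile_flank_bp",
           "gene_flank_bp", "fold_threshold", "min_overlap_bp")
  for (k in num)
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0)
      stop("config parameter ", k, " must be a positive number")
  cfg
}

#' Write a reproducibility manifest for a pipeline run
#'
#' Records the package version, every effective parameter (no hidden
#' defaults) and the md5 checksum of every output file, as JSON.
#'
#' @param params Named list of effective parameters.
#' @param outputs Character vector of output file paths.
#' @param path Manifest destination.
#' @return Invisibly, the manifest list.
#' @export
write_manifest <- function(params, outputs, path) {
  manifest <- list(
    package = "histoneRx",
    version = as.character(utils::packageVersion("histoneRx")),
    parameters = params,
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(f) list(path = f,
                                      md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
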