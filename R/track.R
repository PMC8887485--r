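#' Binned genomic coverage track
#'
#' A lightweight fixed-bin coverage container: per-chromosome numeric value
#' vectors at a constant bin size, 0-based half-open coordinates. Bin `i`
#' (1-based in the vector) covers bases `[(i-1)*bin, i*bin)`; the last bin of
#' a chromosome is truncated at the chromosome end.
#'
#' @param genome Named integer vector of chromosome lengths (bp).
#' @param bin Bin size in bp (default 20).
#' @param values Named list of per-chromosome numeric vectors; defaults to
#'   all-zero vectors of the right lengths.
#' @param normalized Logical flag: has an Rx factor been applied?
#' @param sample Optional sample id.
#' @return Object of class `genomic_track`.
#' @export
genomic_track <- function(genome, bin = 20L, values = NULL,
                          normalized = FALSE, sample = NA_character_) {
  if (is.null(names(genome)) || any(genome <= 0))
    stop("genome must be a named vector of positive chromosome lengths")
  bin <- as.integer(bin)
  if (bin < 1) stop("bin size must be >= 1")
  nbin <- ceiling(genome / bin)
  if (is.null(values)) {
    values <- lapply(nbin, numeric)
  } else {
    if (!setequal(names(values), names(genome)))
      stop("values must be named by the genome's chromosomes")
    values <- values[names(genome)]
    ok <- vapply(names(genome), function(ch) length(values[[ch]]) == nbin[[ch]],
                 logical(1))
    if (!all(ok)) stop("value vector length must equal ceiling(chrom/bin)")
  }
  structure(list(genome = genome, bin = bin, values = values,
                 normalized = normalized, sample = sample),
            class = "genomic_track")
}

#' @export
print.genomic_track <- function(x, ...) {
  cat(sprintf("genomic_track: %d chromosome(s), bin %d bp, %s%s\n",
              length(x$genome), x$bin,
              if (x$normalized) "Rx-normalized" else "raw",
              if (is.na(x$sample)) "" else paste0(" [", x$sample, "]")))
  invisible(x)
}

#' Spike-in (Rx) normalization factor
#'
#' The per-sample scaling factor derived from the number of reads aligning
#' to the exogenous spike-in genome: `scale_constant / spikein_count`. With
#' the default `scale_constant = 1e6` this is a reads-per-spike-in-million
#' convention. An alternative convention that additionally divides by the
#' primary-genome depth (in millions) is available via `per_primary_depth`.
#'
#' @param spikein_count Filtered spike-in read count (> 0).
#' @param scale_constant Numerator of the factor (default 1e6).
#' @param primary_count Primary-genome read count; only used when
#'   `per_primary_depth = TRUE`.
#' @param per_primary_depth If `TRUE`, factor is
#'   `scale_constant / spikein_count / (primary_count / 1e6)`.
#' @return A positive scalar of class `rx_factor`.
#' @export
rx_factor <- function(spikein_count, scale_constant = 1e6,
                      primary_count = NULL, per_primary_depth = FALSE) {
  if (spikein_count <= 0) stop("spike-in read count must be positive")
  f <- scale_constant / spikein_count
  if (per_primary_depth) {
    if (is.null(primary_count) || primary_count <= 0)
      stop("per_primary_depth requires a positive primary_count")
    f <- f / (primary_count / 1e6)
  }
  if (!is.finite(f) || f <= 0) stop("Rx factor must be finite and positive")
  structure(f, class = "rx_factor")
}

#' Apply an Rx factor to a raw track
#'
#' Every bin is multiplied by the factor and the track is flagged as
#' normalized; applying a factor twice is an error.
#'
#' @param track A raw [genomic_track()].
#' @param factor An [rx_factor()] (or positive scalar).
#' @return The normalized `genomic_track`.
#' @export
normalize_track <- function(track, factor) {
  stopifnot(inherits(track, "genomic_track"))
  if (track$normalized) stop("track is already Rx-normalized")
  f <- as.numeric(factor)
  if (f <= 0 || !is.finite(f)) stop("factor must be finite and positive")
  track$values <- lapply(track$values, `*`, f)
  track$normalized <- TRUE
  track
}

#' Element-wise mean of replicate tracks
#'
#' @param tracks List of [genomic_track()] objects on the same genome and
#'   bin size.
#' @return A `genomic_track` of per-bin arithmetic means.
#' @export
average_replicates <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  t1 <- tracks[[1]]
  for (t in tracks[-1]) {
    if (!identical(t$genome, t1$genome) || t$bin != t1$bin)
      stop("tracks must share genome and bin size")
  }
  out <- t1
  out$sample <- NA_character_
  out$values <- lapply(names(t1$genome), function(ch) {
    Reduce(`+`, lapply(tracks, function(t) t$values[[ch]])) / length(tracks)
  })
  names(out$values) <- names(t1$genome)
  out
}

#' Length-weighted mean track signal over intervals
#'
#' For each interval the per-bin values are averaged with weights equal to
#' the number of bases of the interval falling in each bin, so partial bin
#' overlap contributes proportionally.
#'
#' @param track A [genomic_track()].
#' @param intervals A `GRanges`, or a `data.frame` with `chrom`, `start`,
#'   `end` in 0-based half-open coordinates.
#' @return Numeric vector of interval means (named by interval names/ids
#'   when present).
#' @export
mean_signal <- function(track, intervals) {
  iv <- as_bed_frame(intervals)
  out <- numeric(nrow(iv))
  for (i in seq_len(nrow(iv))) {
    ch <- iv$chrom[i]
    if (!ch %in% names(track$genome))
      stop("unknown chromosome: ", ch)
    s <- iv$start[i]; e <- iv$end[i]
    if (s < 0 || e > track$genome[[ch]] || s >= e)
      stop(sprintf("interval %s:%d-%d off chromosome (length %d)",
                   ch, s, e, track$genome[[ch]]))
    b <- track$bin
    first <- s %/% b
    last <- (e - 1L) %/% b
    ix <- (first:last) + 1L
    lo <- pmax(s, (ix - 1L) * b)
    hi <- pmin(e, ix * b)
    w <- hi - lo
    out[i] <- sum(track$values[[ch]][ix] * w) / sum(w)
  }
  if (!is.null(iv$name)) names(out) <- iv$name
  out
}

# normalize GRanges / data.frame interval inputs to a 0-based half-open frame
as_bed_frame <- function(x) {
  if (inherits(x, "GRanges")) {
    df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(x)),
      start = GenomicRanges::start(x) - 1L,
      end = GenomicRanges::end(x),
      strand = as.character(GenomicRanges::strand(x))
    )
    nm <- names(x)
    if (is.null(nm) && !is.null(x$gene_id)) nm <- x$gene_id
    if (is.null(nm) && !is.null(x$name)) nm <- x$name
    if (!is.null(nm)) df$name <- nm
    df
  } else {
    stopifnot(all(c("chrom", "start", "end") %in% names(x)))
    as.data.frame(x)
  }
}

#' Anchor and scaled-region signal profiles
#'
#' Point mode (`body_bins = NULL`): each row is one anchor position and the
#' columns cover `[anchor - flank_bp, anchor + flank_bp)` at the track's bin
#' resolution; rows for minus-strand anchors are flipped so that "left"
#' always means 5-prime. Scaled mode: each row is one region whose body is
#' linearly rescaled to `body_bins` columns, flanked by native-resolution
#' flanks on both sides. Bins beyond chromosome ends are `NA` and excluded
#' from the composite column means.
#'
#' @param track A [genomic_track()].
#' @param anchors `data.frame` with `chrom`, `pos` (0-based bp) and optional
#'   `strand` in point mode; `chrom`, `start`, `end`, optional `strand` in
#'   scaled mode. A `GRanges` is accepted in scaled mode.
#' @param flank_bp Flank on each side (default 5000).
#' @param body_bins Number of columns the region body is rescaled to
#'   (default `NULL` = point mode; the field convention is 200).
#' @return List with `matrix` (rows = anchors) and `profile` (column means,
#'   `na.rm`).
#' @export
anchor_profile <- function(track, anchors, flank_bp = 5000L,
                           body_bins = NULL) {
  b <- track$bin
  nflank <- as.integer(flank_bp %/% b)
  bin_value <- function(ch, ix) {
    v <- rep(NA_real_, length(ix))
    ok <- ix >= 1L & ix <= length(track$values[[ch]])
    v[ok] <- track$values[[ch]][ix[ok]]
    v
  }
  if (is.null(body_bins)) {
    stopifnot(all(c("chrom", "pos") %in% names(anchors)))
    strand <- if (!is.null(anchors$strand)) anchors$strand else "+"
    strand <- rep_len(strand, nrow(anchors))
    mat <- t(vapply(seq_len(nrow(anchors)), function(i) {
      ch <- anchors$chrom[i]
      center_bin <- anchors$pos[i] %/% b + 1L
      ix <- (center_bin - nflank):(center_bin + nflank - 1L)
      v <- bin_value(ch, ix)
      if (strand[i] == "-") rev(v) else v
    }, numeric(2L * nflank)))
  } else {
    iv <- as_bed_frame(anchors)
    strand <- if (!is.null(iv$strand)) iv$strand else "+"
    strand <- rep_len(strand, nrow(iv))
    mat <- t(vapply(seq_len(nrow(iv)), function(i) {
      ch <- iv$chrom[i]
      s_bin <- iv$start[i] %/% b + 1L
      e_bin <- (iv$end[i] - 1L) %/% b + 1L
      left <- bin_value(ch, (s_bin - nflank):(s_bin - 1L))
      right <- bin_value(ch, (e_bin + 1L):(e_bin + nflank))
      body_raw <- bin_value(ch, s_bin:e_bin)
      body <- if (length(body_raw) == 1L) {
        rep(body_raw, body_bins)
      } else {
        stats::approx(seq_along(body_raw), body_raw,
                      xout = seq(1, length(body_raw), length.out = body_bins))$y
      }
      v <- c(left, body, right)
      if (strand[i] == "-") rev(v) else v
    }, numeric(2L * nflank + body_bins)))
  }
  # rows that ran past a chromosome end are excluded from the composite
  profile <- colMeans(mat, na.rm = TRUE)
  list(matrix = mat, profile = profile)
}
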