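# Independent oracles used across the suite. These recompute quantities by
# brute force from first principles and never call the code paths they check.

# --- elemental-composition mass oracle -------------------------------------

ORACLE_ATOM <- c(
  H = 1.0078250319, D = 2.0141017780, C = 12.0, C13 = 13.0033548378,
  N = 14.0030740052, O = 15.9949146221, S = 31.97207069
)

# chain-residue formulas as atom-count vectors c(C=, H=, N=, O=, S=)
ORACLE_RESIDUE <- list(
  G = c(C = 2, H = 3, N = 1, O = 1), A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2), P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1), T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2), D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2), K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1), F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

oracle_atoms_add <- function(a, b) {
  keys <- union(names(a), names(b))
  out <- setNames(numeric(length(keys)), keys)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out
}

oracle_atoms_mass <- function(atoms) {
  sum(ORACLE_ATOM[names(atoms)] * atoms)
}

# full elemental bookkeeping for a derivatized isoform: residues + H2O +
# N-terminal propionyl (C3H4O) + per-lysine endogenous methyls (CH2) or
# acetyl (C2H2O) + installed heavy methyls (one 13C, three D, minus one H)
oracle_isoform_mass <- function(sequence, states,
                                installed = c(un = 2, me1 = 1, me2 = 0,
                                              me3 = 0, ac = 0),
                                propionylated = TRUE) {
  atoms <- c(H = 2, O = 1) # water
  for (aa in strsplit(sequence, "")[[1]])
    atoms <- oracle_atoms_add(atoms, ORACLE_RESIDUE[[aa]])
  if (propionylated)
    atoms <- oracle_atoms_add(atoms, c(C = 3, H = 4, O = 1))
  for (st in states) {
    n_me <- switch(st, un = 0, me1 = 1, me2 = 2, me3 = 3, ac = 0)
    if (n_me > 0)
      atoms <- oracle_atoms_add(atoms, c(C = n_me, H = 2 * n_me))
    if (st == "ac")
      atoms <- oracle_atoms_add(atoms, c(C = 2, H = 2, O = 1))
    k <- installed[[st]]
    if (k > 0)
      atoms <- oracle_atoms_add(atoms, c(C13 = k, D = 3 * k, H = -k))
  }
  oracle_atoms_mass(atoms)
}

# --- brute-force interval oracles ------------------------------------------

# 0-based half-open overlap width of two intervals
bf_overlap_bp <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2))

# all-pairs shared flags: is each interval of A overlapped by >= min_bp of
# some interval of B on the same chromosome? (outer loop over A, the inner
# all-pairs comparison done arithmetically against every row of B)
bf_shared <- function(A, B, min_bp) {
  vapply(seq_len(nrow(A)), function(i) {
    if (nrow(B) == 0) return(FALSE)
    ov <- pmin(A$end[i], B$end) - pmax(A$start[i], B$start)
    any(A$chrom[i] == B$chrom & ov >= min_bp)
  }, logical(1))
}

# all-pairs gene association: gene body +/- flank overlaps any peak by >= 1 bp
bf_gene_associated <- function(genes, peaks, flank) {
  vapply(seq_len(nrow(genes)), function(i) {
    ws <- max(0, genes$start[i] - flank)
    we <- genes$end[i] + flank
    ov <- pmin(we, peaks$end) - pmax(ws, peaks$start)
    any(genes$chrom[i] == peaks$chrom & ov >= 1)
  }, logical(1))
}

# per-base mean-signal oracle on a binned track
bf_mean_signal <- function(track, chrom, start, end) {
  vals <- numeric(end - start)
  for (k in seq_len(end - start)) {
    base <- start + k - 1
    vals[k] <- track$values[[chrom]][base %/% track$bin + 1]
  }
  mean(vals)
}

# random peak-set frame on a toy genome (0-based half-open, may overlap
# within the set before use; callers reduce when a set must be disjoint)
random_peak_frame <- function(n, genome, min_w = 50, max_w = 2000) {
  chrom <- sample(names(genome), n, replace = TRUE)
  w <- sample(min_w:max_w, n, replace = TRUE)
  start <- vapply(seq_len(n), function(i)
    sample.int(genome[[chrom[i]]] - w[i], 1) - 1L, integer(1))
  data.frame(chrom = chrom, start = start, end = start + w)
}

frame_to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

# --- shared fixtures --------------------------------------------------------

k27_peptide <- function() h3_tail_peptides()$K27

# the two-condition K27 truth used in several end-to-end tests
k27_truth <- function(abund = c(0.5, 0.25, 0.15, 0.10), sigma = 0,
                      frag_noise = 0, seed = 1) {
  ptm_ground_truth(
    k27_peptide(),
    combos = list(
      un = c("27" = "un", "36" = "un", "37" = "un"),
      me1 = c("27" = "me1", "36" = "un", "37" = "un"),
      me2 = c("27" = "me2", "36" = "un", "37" = "un"),
      me3 = c("27" = "me3", "36" = "un", "37" = "un")
    ),
    abundances = abund, rts = c(10, 12, 14, 16),
    sigma_area = sigma, frag_noise = frag_noise, seed = seed
  )
}

toy_chiprx_truth <- function(seed = 7, k_new = 2, depth = c(A = 1, B = 1),
                             spikein = c(A = 1e6, B = 1e6),
                             genome = c(chr1 = 1e6, chr2 = 8e5)) {
  domA <- data.frame(chrom = "chr1", start = c(1e5, 4e5),
                     end = c(1.2e5, 4.3e5), enrichment = 8)
  new_pool <- data.frame(chrom = c("chr1", "chr2", "chr2"),
                         start = c(7e5, 2e5, 5e5),
                         end = c(7.3e5, 2.2e5, 5.25e5), enrichment = 8)
  domB <- rbind(domA, new_pool[seq_len(k_new), , drop = FALSE])
  chiprx_ground_truth(genome, domains = list(A = domA, B = domB),
                      background = 1, depth = depth,
                      spikein_counts = spikein, seed = seed)
}
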