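---
title: "Quantifying histone PTM and H3K27me3 domain dynamics with histoneRx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying histone PTM and H3K27me3 domain dynamics with histoneRx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histoneRx)
```

# The two analyses

`histoneRx` implements two quantitative epigenomics procedures that are
usually stitched together from ad-hoc scripts, as one tested package.

**Arm 1 — relative histone PTM quantification.** Histones are chemically
derivatized before and after digestion: free and monomethyl lysines on the
intact protein receive heavy-isotopic methyl groups (reductive
dimethylation with ^13^CD~2~O / NaBD~3~CN), which blocks trypsin at lysines
(Arg-C-like digestion), and peptide N-termini are propionylated afterwards.
Each tryptic tail peptide of H3 then exists as a family of modification
isoforms separated by mass (and, for positional isomers, only by fragment
ions). The peak area of each isoform's extracted-ion chromatogram (XIC) is
divided by the summed area of all forms of the same peptide — the total is
taken as 100% — giving relative state abundances, and conditions are
compared on a log base-1.5 fold-change scale.

**Arm 2 — spike-in normalized ChIP-Rx domain dynamics.** ChIP-seq with an
exogenous spike-in genome permits quantitative cross-sample comparison:
each sample is scaled by an Rx factor derived from its spike-in read count,
tracks are binned at 20 bp and averaged across replicates, peak sets from
two conditions are partitioned into condition-A-only (cluster I), shared
(cluster II) and condition-B-only (cluster III) peaks, genes are assigned
to peaks over TSS–TES ± 2.5 kb windows, and genes whose normalized signal
rises at least two-fold are classified as strong.

Both arms are driven by synthetic-data generators with known ground truth,
so every stage is testable at desk scale without external downloads.

# The mass and chemistry model

Monoisotopic masses are used throughout; average-mass mode is deliberately
not provided (the quantified peptides are small enough that monoisotopic
peaks are the measured species). The derivatization scheme is a first-class
object:

```{r}
derivatization_scheme()
```

* a heavy methyl is ^13^CD~3~ replacing one amine hydrogen, net
  +18.037835 Da; an endogenous methyl is CH~2~, +14.015650 Da; acetyl
  +42.010565 Da; N-terminal propionyl +56.026215 Da;
* the installed-count rule is {un → 2, me1 → 1, me2/me3/ac → 0}: after
  labeling, an unmodified lysine carries two heavy methyls and a monomethyl
  lysine one, so every non-acetylated lysine ends fully alkylated and
  trypsin-resistant.

A consequence worth stating explicitly: the derivatized mass is **not**
monotone in methyl count. A me1 lysine (light + heavy = 32.053 Da) is
heavier than me2 (two light = 28.031 Da), and a derivatized unmodified
lysine (two heavy = 36.076 Da) is heavier than both. Monotonicity holds
only for the endogenous chemistry; all five states remain pairwise
mass-resolvable under the scheme, with the closest pair being endogenous
me3 versus acetyl at 0.0364 Da (3×CH~2~ − C~2~H~2~O).

Residue numbering follows the histone community convention: the initiator
methionine is excluded, so H3 residue 1 is the Ala of ARTK… and the K27
peptide is KSAPATGGVKKPHR (residues 27–40, modifiable lysines K27, K36,
K37). The canonical mature H3.1 sequence ships as a FASTA fixture.

Fragment b/y masses place every site adduct on its residue and satisfy the
closure b~i~ + y~n−i~ = precursor neutral mass exactly, which the tests
verify for all 125 isoforms of the K27 peptide against an independent
elemental-composition oracle.

# Quantification: matching, selection, splitting

1. **MS1 matching** (`match_peaks`): peaks are matched to all candidate
   isoforms within a ppm tolerance at the observed charge (default 10 ppm;
   `validate_tolerance()` errors if a requested tolerance cannot resolve
   the me3/ac gap at the quantified m/z — 10 ppm resolves it for the K27
   peptide at z = 2, where the gap is about 23 ppm). Isobaric positional
   isomers deliberately share a match; genuinely distinct masses inside the
   tolerance are a configuration problem, resolved by the retention-time
   rule below or carried forward flagged, never silently dropped.
2. **Charge-state selection** (`select_quant_peak`): the same form shows up
   at several charge states; only the most intense is quantified, ties
   broken toward the lower charge.
3. **Isobar identification then splitting** (`screen_isobars`,
   `split_isobaric`): positional isomers are told apart by the b/y ions
   that differ between them. Before splitting, candidates whose fragment
   ladder is poorly covered by the observed spectrum are dropped
   (`min_coverage` = 0.98 of the best candidate's coverage): with a full
   state enumeration as the candidate universe, most members of an isobar
   group are absent from the sample, and keeping them would dilute the
   strictly-unique ion sets. The shared XIC area is then apportioned in
   proportion to each surviving isoform's summed unique-ion intensities;
   the split conserves the input area exactly.

Two honest limitations of the unique-ion sum rule, both inherent to the
fragment-ratio method rather than to this implementation: in groups of
three or more isomers, a "middle" isomer can have no ion that differs from
*all* others (it is then assigned area 0 with a warning); and when
surviving isomers have unequal numbers of unique ions the sum rule weights
them unequally (the proportional split equals a least-squares fit on unique
ions only when the counts match, which is automatic for two-way positional
isomer pairs, since unique ions arise in same-series/same-index pairs).

4. **Normalization and fold change** (`relative_abundance`,
   `fold_change`): percentages are computed per run (total = 100% per
   peptide), marginal per-site states (e.g. "K27me3" summed over K36/K37
   combinations) are derived by summation, replicates are averaged after
   normalization, and conditions are compared as
   log~1.5~((p~B~ + c)/(p~A~ + c)) with pseudocount c = 0.01 percentage
   points so undetected states stay finite. The marginal table is the
   default reporting level; full combinations are emitted alongside because
   the two answer different questions.

The retention-time heuristic ("dimethyl-class elutes before acetyl-class")
is configuration, not hard-coded: `rt_rule` is an elution-ordered vector of
state classes applied only when several non-isobaric mass groups fall
within tolerance and equally many co-eluting peaks compete; anything it
cannot order stays flagged ambiguous. The underlying chromatographic claim
is empirical and column-dependent, which is why it is a parameter.

# The synthetic LC-MS/MS generator

`ptm_ground_truth()` fixes, per peptide: the state combinations present,
their true fractional abundances (must sum to 1), per-combination retention
times, and two noise knobs. `simulate_ptm_run()` then emits one XIC peak
per resolvable m/z–RT group and charge state (default z = 2 and 3 carrying
70%/30% of the area) and one MS2 spectrum per group.

* **MS1 noise**: multiplicative log-normal with σ = 0.05 by default — the
  typical few-percent run-to-run variability of integrated peak areas.
* **MS2 noise**: fragment intensities proportional to the co-eluters'
  abundances plus a uniform additive floor of 1% of the most intense
  fragment.
* Seeds are mandatory constructor arguments; the generator restores the
  caller's RNG state (`withr::with_seed`), so there is no hidden global
  randomness.

What the generator does **not** emulate: profile-mode chromatograms, raw
peak integration, isotope envelopes, neutral losses, missed fragment ions,
co-isolation of non-isobaric precursors, and cross-run RT drift. Passing
tests therefore demonstrate the correctness of the quantification
arithmetic given integrated areas and centroided fragments — the same
contract as the upstream vendor software that produces those tables — not
robustness to raw-signal pathologies.

# ChIP-Rx: tracks, factors, profiles

`genomic_track` stores per-chromosome value vectors at a fixed bin size
(default 20 bp, matching common browser-track resolution), 0-based
half-open coordinates, with the last bin truncated at the chromosome end.
The Rx factor is `scale_constant / spikein_count` with
`scale_constant = 1e6` (reads-per-spike-in-million); the alternative
convention that also divides by primary depth is available via
`per_primary_depth = TRUE`, because the literature names the factor more
often than its formula. Normalization is plain bin-wise scaling, flagged on
the track so it cannot be applied twice; replicate averaging is the
element-wise mean. Interval means weight partial bins by overlapped bases.
Whether spike-in scaling is applied before or after replicate averaging
does not change the averaged track up to floating point, since both
operations are linear.

`anchor_profile` supports point mode (± flank around anchors at native bin
resolution, default ±5 kb, strand-aware flipping) and scaled mode (gene
body linearly rescaled to `body_bins` = 200 columns with native-resolution
flanks). Rows that run past a chromosome end are padded with `NA` and those
cells are excluded — not zero-filled — from the composite column means,
because zero-filling would bias composite profiles downward near contig
edges.

# Domain analysis

`cluster_peaks` calls a peak "shared" iff it overlaps a peak of the other
set by at least `min_overlap_bp` (default = the read length, following the
convention of discarding overlaps shorter than the sequencing tag). The
partition satisfies |I| + |II~A~| = |A| and |III| + |II~B~| = |B| by
construction, and the implementation (GenomicRanges `findOverlaps` with
`minoverlap`) is tested against a brute-force all-pairs scanner on 1,000
random instances.

Gene assignment is deliberately dual, matching the two phrasings in common
use: a gene is *associated* iff any peak overlaps TSS − 2.5 kb .. TES +
2.5 kb (window overlap), while each peak is *annotated* with its nearest
gene by peak-center-to-TSS distance (edge-to-edge distance available by
flag), ties broken by distance then lexicographic gene id. Because the gene
model carries only TSS/TES/strand, peak feature categories are
promoter (± 2 kb of a TSS), gene body, and intergenic; exon/intron
subdivision would require transcript structure this pipeline does not
consume.

Strong genes are those with (mean~B~ + c)/(mean~A~ + c) ≥ 2 on
replicate-averaged normalized signal over the TSS–TES ± 2.5 kb window; the
default pseudocount is 1% of the genome-wide median bin value of the
baseline condition. Note the pseudocount shrinks ratios toward 1, so a
gene at exactly two-fold with a small baseline can fall just below the
threshold — the tests pin this behavior down. Whether strong-gene status
should additionally require peak association is left to the caller as
composition: `intersect(classify_strong_genes(...),
assign_peaks_to_genes(...)$associated_genes)`.

Two-group comparisons wrap `stats::t.test`: Welch's unpaired two-tailed
test by default, paired Student's t when `paired = TRUE` (with the
identical-pairs edge case returning t = 0, p = 1 rather than an error).

# The synthetic ChIP-Rx generator

`chiprx_ground_truth()` fixes the genome, per-condition true domains with
an enrichment level over a flat background, per-condition depth and
spike-in counts, read length, bin size, and optionally gene models.
`simulate_chiprx_experiment()` emits two replicates per condition with
independent Poisson counts per bin around
depth × (background + enrichment) integrated per base — the minimal model
with the right mean–variance relation for normalization tests — plus
"called" peak sets equal to the true domains, which isolates the in-scope
interval logic from peak calling (out of scope by design). With
`noise = "none"` the bins carry their exact expectations, making every
downstream estimator exact and the recovery tests sharp.

Default study conditions used by the tests and the acceptance script: a
1.8 Mb two-chromosome genome, 20–30 kb domains, background 1 and
enrichment 8 per-base units (bin means of 20 versus 180 at depth 1 — the
order of magnitude of real broad-mark coverage at moderate depth), two
replicates, spike-in counts of 10^6^, and condition B equal to condition A
plus k new domains with doubled depth and proportionally doubled spike-in,
so that Rx normalization is the thing being exercised. When no gene model
is supplied, one gene is generated per distinct domain plus background
genes every 50 kb, giving the strong-gene classifier known positives and
negatives.

What this generator does not emulate: read-level artifacts (duplicates,
blacklist regions, mappability), fragment-length smoothing, domain
boundary diffuseness, input-chromatin bias, and overdispersion beyond
Poisson. Conclusions from passing tests are therefore about the
normalization and interval arithmetic, not about robustness of peak
calling — which this pipeline consumes, not produces.

# Numerical choices

* Masses are compared at 1e-6 Da in tests; MS matching uses ppm tolerances
  (default 10 ppm) because instrument error scales with m/z.
* Isobar grouping keys masses rounded to 1e-4 Da — an order of magnitude
  below any adduct difference the scheme produces.
* `split_isobaric` returns areas that sum to the input exactly (the split
  is a single multiplication by a normalized weight vector).
* Percentages sum to 100 within 1e-6 by construction; the acceptance tests
  assert it end to end.
* Degenerate inputs fail loudly: empty peak sets for overlap fractions,
  all-zero areas per peptide (reported as missing, not emitted as zeros),
  zero spike-in counts, double normalization, intervals off chromosome.

# Problem sizes

The test suite and the acceptance script run everything at desk scale: the
125-isoform K27 enumeration for the mass oracle, 50 replicate simulations
for the noisy-recovery bound, 1,000 random interval instances (≤ 200
intervals each) for the interval oracles, and 20 seeds for noisy
domain-gain recovery on the 1.8 Mb toy genome. These sizes were chosen so
the whole suite completes in a few minutes while keeping every statistical
bound comfortably away from its threshold.

# Known limitations

* The fragment-ratio split quantifies only isomers with strictly unique
  ions; dense isomer groups can contain unquantifiable members (warned,
  assigned zero).
* The RT elution heuristic is a configurable claim about chromatography,
  not a law; with the default 10 ppm tolerance it is rarely consulted.
* Marginal site percentages from a multi-lysine peptide attribute
  combination abundance to each site independently; co-occurrence
  information lives only in the combination table.
* The ChIP arm consumes called peaks and binned coverage; alignment,
  filtering and peak calling are upstream concerns, and the spike-in
  factor formula is a convention with a flag, not a discovery.
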