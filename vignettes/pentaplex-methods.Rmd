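---
title: "Methods: mixed-motif expansion screening and long-read repeat decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-motif expansion screening and long-read repeat decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pentaplex)
```

## Scope and model

Complex tandem-repeat expansions — several adjacent expanded motifs, e.g. a
pathogenic TTTCA tract buried inside expanded TTTTA and TTGTA at a FAME
locus — defeat flank-anchored short-read genotypers. `pentaplex` implements
two complementary inference procedures and the simulator used to validate
them. This vignette records the model assumptions, the tunable parameters,
the numerical choices made where the design was genuinely open, and what a
green test does and does not establish.

## Motif identity

Reads sample either strand in arbitrary phase, so motif identity must be
invariant under rotation and reverse complement. We use as **canonical key**
the lexicographic minimum over the motif's rotations and its reverse
complement's rotations. This is a convention of this package (any
deterministic class representative would do); published motif names (TTTCA,
TTGTA, ...) are preserved as *display* orientation for all reporting, since
the field names motifs by the locus strand, not by a canonical rotation.

## Repeat runs and read profiles

The read-level quantity everything thresholds is the **maximal exact tandem
run**: a maximal substring matching cyclic repetitions of some rotation of a
target motif (both strands by default). Detection is exact and vectorized:
positions with `seq[i] == seq[i+k]` (motif length `k`) delimit period-`k`
stretches; each stretch of sufficient length whose leading k-mer belongs to
a target class is a run. Choices that matter:

- **Minimum run length**: 2 full copies (10 bp for pentamers, 30 bp for the
  15-mer composite). One isolated motif occurrence is not a tandem repeat.
- **`N` handling**: `N` never matches, hence breaks runs — conservative.
- **Exact matching only** at this layer. Illumina error (~0.1%) is far below
  the slack in the screening thresholds; noise tolerance lives in the
  long-read segmenter instead.
- **Maximality and bridges**: a maximal run extends into an abutting block
  of another motif as far as the period happens to continue (up to `k - 1`
  bp, e.g. the shared `TTT` of TTTTA|TTTCA). Per-motif bp therefore slightly
  exceed the synthesized block sizes while the *union* coverage is exact;
  totals, not per-motif sums, are what the screen thresholds.

`profile_read()` reports per-motif union bp, total union bp over all runs
(overlaps not double counted), and the run list.

## The mixed-motif pair screen

`classify_pair()` applies the published defaults verbatim: both reads
`> 125` bp total repeat (strict, matching the published "> 125 bp"
wording), and for **every** target motif `>= 50` bp across the pair in
aggregate ("minimum threshold" wording, hence inclusive). The per-motif
criterion applying to all motifs is the method's point: a pair pure in one
motif never qualifies. Samples are flagged at `>= 3` qualifying pairs.
Open points we resolved:

- *Aggregate vs per-read motif content*: the 50 bp criterion is applied to
  the pair aggregate, following the "across the pair" wording.
- *Exome screens* combined a 125 bp criterion with a `> 90%` in-repeat-read
  purity criterion; we implement the **union** (either route qualifies) and
  record which criterion fired per pair, so an intersection reading can be
  recovered from the output.
- The sample-level rule is generalized from the single-motif exome screen to
  any motif set — same evidence logic, one code path.

No mapping information is used at pair level; pairing comes from mate files
or a pair id. No multiple-testing machinery: this is a screen, and a high
population background of mixed-motif TTTTA+TTTCA pairs is expected.

## Long-read decomposition

Reads overlapping the target region (1-based inclusive region strings,
0-based half-open internally) are kept **whole** — large expansions are
absent from the reference, so alignments anchor in the flanks — and
oriented reference-forward; the mapping strand is retained.

**Wild-type filter**: reads with total repeat `< 800` bp are removed. We
read the published threshold as *repeat* length, not read length (the read
includes amplicon flanks); the boundary value 800 is kept (`>=` keeps).

**TTCCA artifact filter**: some basecaller models miscall large TTTTA/TTTCA
tracts as TTCCA with a strict directional bias. The published exclusion was
by visual inspection; as a reproducible surrogate a read is flagged iff it
mapped to the reverse strand **and** TTCCA run bp exceed 0.5 of the combined
TTCCA+TTTCA+TTTTA run bp. The 0.5 fraction is this package's operational
stand-in, not a published value; it is exposed as a parameter, and flagged
reads are reported, never silently dropped.

**Segmentation** (`segment_read()`) is windowed best-motif voting rather
than an HMM — deterministic, testable, and sufficient since the pentamers
differ at >= 1 of 5 positions:

1. Per position, each candidate motif is scored by its best rotation-phase
   template match fraction within a window of `window_copies = 3` motif
   copies; the best motif wins if its score reaches `min_score = 0.6`
   (below that the position stays unassigned — flanks score ~0.3-0.4
   against these T-rich templates).
2. Majority smoothing over two shortest-motif copies.
3. Run-length encoding; blocks must be **anchored** by an exact tandem run
   of `>= min_block_copies = 2` copies of their motif. Anchoring is the key
   robustness device: an isolated miscall inside a long tract mimics 1-2
   copies of another motif but cannot produce an exact multi-copy run.
4. **Interruptions**: a tract of `<= 3` copies sandwiched inside a single
   other-motif tract is reported in a separate interruption table and the
   tract merged. Rationale: at nanopore-like error rates (2% substitutions),
   a double miscall creates an exact 2-copy mimic inside a 700-copy tract in
   a few percent of reads; embedded micro-tracts this small are statistically
   indistinguishable from such artifacts, so reporting them as structure
   blocks would corrupt the consensus block order while hiding them would
   discard evidence. Genuinely expanded blocks (tens to hundreds of copies)
   are unaffected.
5. **Boundary refinement**: junctions are set to the midpoint of the bridge
   shared by the two flanking exact runs, and terminal block edges snap to
   the exact-run envelope. On error-free input the result equals the exact
   run decomposition, and since bridges are `< k`, rounding `bp / k`
   recovers copy counts exactly. With random (non-repeat) flanks the flank
   can, with probability `4^-j`, continue the repeat period by `j` bp; a
   chance continuation of `>= 3` bp shifts the terminal copy count by one.
   This ambiguity is inherent to the sequence, not the algorithm.

Copy estimates are `round(bp / motif length)`. Supplying different motif
sets changes the decomposition by design: pure
`(TTTTATTTTATTTCA)50` is a single 50-copy block when the 15 bp composite
motif is supplied; without it the window voting reports the tract as
TTTTA-dominated (the 5 bp TTTCA interludes fall below any 2-copy rule) —
no false pure-TTTCA expansion block is produced either way.

`consensus_structure()` takes the modal block order across reads, reports
per-block median bp/copies and the copy-count MAD (mosaicism or PCR-bias
dispersion), and counts discordant reads rather than averaging them in.
`waterfall()` orders reads by total repeat bp (ties by read id) and
tabulates per-motif copy distributions; `plot_waterfall()` renders the
motif-coloured track plot.

## The simulator: what it emulates, what it does not

The generator states the world the tests live in:

- **Alleles**: a diploid pair; a wild-type allele defaults to `(TTTTA)8`
  (short pure TTTTA as in the reference genome; 8 copies is this package's
  default, not a published number) and an expanded allele is any
  configuration string. Flanks are deterministic synthetic random sequence
  (GC 0.40, 500 bp each side, fixed internal seed) — no reference download;
  they stand in for, and do not reproduce, the true locus flanks.
- **Mosaicism**: one block's copy number may be re-drawn per read template
  (lognormal or discrete family). This jointly models PCR bias and true
  somatic mosaicism, which amplicon data cannot distinguish.
- **Short reads**: 151 bp pairs (the published read length), insert
  ~N(400, 60) truncated to [read length, allele length], uniform fragment
  placement at the requested fold coverage, substitutions at 0.1%, constant
  qualities (nothing consumes qualities). No coverage bias, no adapter or
  barcode simulation.
- **Long reads**: full-length amplicon reads per allele (coverage = read
  count per allele), i.i.d. substitutions/insertions/deletions (defaults
  2%/1%/1%), random strand, reverse-strand reads emitted
  reverse-complemented with an alignment-like interval table. The TTCCA
  artifact rewrites the central 90% of each TTTTA/TTTCA block's copies as
  TTCCA in a fraction `artifact_rate` of reverse-strand reads — contiguous
  tracts, mimicking the observed failure mode.
- **Not modeled**: homopolymer-biased nanopore errors, chimeras, quality
  profiles. Acceptance tolerances were chosen to be achievable under the
  i.i.d. model and must be revisited if the error model changes. A green
  test therefore establishes algorithmic correctness under stated noise, not
  performance on real flow-cell data.

Determinism: every simulation takes an explicit seed and restores the
caller's RNG state; identical seeds give identical output on any platform
with R's default RNG.

## Numerical and interface choices

- Coordinates: user-facing region strings are 1-based inclusive as printed
  in genome browsers; internal coordinates are 0-based half-open.
- Structure strings use numeric copy counts, `"(TTTTA)100-(TTTCA)100"`, as
  the machine-readable form of the field's `(TTTTA)exp-(TTTCA)exp`
  notation; `parse_config()`/`format_config()` are exact inverses.
- Ties in per-position voting break toward the earlier motif in the
  caller's list; waterfall ties break by read id — all orderings are
  deterministic.
- TSV outputs carry `#`-prefixed provenance headers (version, config JSON,
  short hash) and no timestamps, so identical configurations are
  byte-identical. Logging goes to stderr.
- `--threads` is accepted and ignored: single-threaded execution is the
  contract (determinism first).

## Known limitations

- The screen assigns no genomic locus to qualifying pairs (follow-up is by
  targeted long reads, the practice the method supports).
- Motif copies are tandem-run copies; isolated, interrupted occurrences
  below two copies do not count. This differs from overlapping
  occurrence-counting and is the intended reading for expansion sizing.
- Per-motif bp of abutting blocks include junction bridges (see above);
  consumers wanting block-partitioned bp should use `segment_read()`, not
  `profile_read()`.
- The segmenter reports, not resolves, reads discordant with the modal
  structure; no haplotype phasing beyond the wild-type length filter.
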