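---
title: "Detecting IESs and modelling their gain and loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting IESs and modelling their gain and loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(iescan)
```

## The biological problem

Ciliates maintain two genomes: a silent germline micronucleus (MIC) and an
expressed somatic macronucleus (MAC) rebuilt from the germline at each
sexual generation. During that rebuild, tens of thousands of short,
unique-copy Internal Eliminated Sequences (IESs) are excised precisely.
Each IES is bounded by two `TA` dinucleotides in the germline; the somatic
junction retains exactly one `TA`. `iescan` implements the two detection
strategies this geometry allows — a read-mapping signal (MIRAA) and an
assembly-comparison signal (MICA) — plus the downstream statistics and a
maximum-likelihood model of IES gain and loss over the whole-genome
duplications (WGDs) of the *Paramecium* lineage.

## Coordinate and sequence conventions

All internal coordinates are 0-based half-open; all GFF3 output is 1-based
inclusive, converted through one shared pair of functions
(`to_gff_coords()` / `from_gff_coords()`). An IES record stores the
insertion point `p` (the first base of the retained somatic `TA`) and a
sequence that *starts with* the left `TA` and *excludes* the right one, so
the reconstruction identity

```
MIC locus = MAC[0:p] + seq + MAC[p:]
```

is exact, `MAC[p:p+2] == "TA"`, and the published minimum IES size (26 bp)
and first-peak position (26–28 bp) come out on this convention without any
offset bookkeeping.

Because an insertion can slide against identical flanking bases, every
record is reported in **leftmost-canonical** form: all equivalent
placements are enumerated by sliding, those that are TA-led with a
TA-retaining reference are kept, and the smallest `p` wins
(`canonicalize_insertion()`). This mirrors standard indel left-alignment
practice, is idempotent, and is checked in the test suite against an
independent brute-force enumeration of all decompositions.

## MIRAA: breakpoint sites from alignment ends

A read that crosses a germline IES junction aligns to the somatic
reference only partially, terminating (soft-clipped) on the residual `TA`.
`detect_breakpoint_sites()` counts, per position, alignments whose clipped
end terminates there: a left-clipped alignment contributes its first
aligned base, a right-clipped one its last. Only clipped terminations
count — natural read ends occur everywhere at depth-proportional rates and
would drown the signal.

A site is emitted when

* clipped-end count `> min_end_count` (default **15**, matching a 10%
  fraction of a ~150x dataset; `min_end_fraction` recomputes the cutoff
  from the observed mean coverage when set),
* the position lies more than `end_margin` (**500 bp**) from both scaffold
  ends, where assembly heterogeneity produces artefacts, and
* local coverage is below `max_coverage` (**300x**), a repeat guard.

Two numerical details matter. First, the two clip registers straddle the
retained `TA` (left-clipped alignments start on it; right-clipped ones end
just after it), so candidate positions within `merge_tol` (**2 bp**, the
blur expected from staggered cleavage) are merged to the position with the
most ends, counts summed. Second, *coverage at the junction base itself is
roughly twice the ambient depth*, because both germline flanks of the
insertion map across it. A repeat guard that read the depth exactly at the
breakpoint would therefore veto true sites at high coverage; the guard
instead uses the **median depth in a 51 bp window** (`cov_window`), which
reflects the neighbourhood the repeat criterion is actually about.

## MICA: TA-bounded insertions in germline contigs

`call_ies()` composes four steps:

1. **Contig filter** — contigs with G+C ≥ 0.5 are discarded (the AT-rich
   genome makes GC-rich contigs almost certainly contaminant-derived).
2. **Anchor chaining** — contigs are seeded on the reference with unique
   21-mers; co-diagonal runs collapse into maximal exact-match anchors and
   the highest-weight colinear chain is selected. Adjacent chained anchors
   may overlap by a few bases — at an insertion the retained `TA` matches
   on both sides of the junction — so overlaps are permitted during
   chaining and trimmed from the downstream anchor afterwards. Contigs
   with two equally scoring chains (repeats) are skipped rather than
   guessed. This bespoke chaining stands in for an external genome-scale
   aligner; the published contribution being reproduced exactly is the
   boundary rule, not the seeding heuristic.
3. **Local realignment** — each inter-anchor gap, with 50 bp of anchored
   flank on either side, is globally realigned under affine scores
   (match +2, mismatch −3, gap open −5, extend −2); the maximal
   contig-only run is the insertion candidate. The flank length is a
   package choice: long enough to pin the alignment, short enough that
   unrelated sequence cannot dominate the score.
4. **Boundary adjustment** — the candidate is accepted iff some equivalent
   placement is TA-led with `TA` retained on the reference, and reported
   leftmost-canonical. No minimum-length filter is applied at detection;
   records shorter than 26 bp are flagged `shorter_than_26` instead, so
   the observed size cutoff remains an observation, not an assumption.

Duplicate calls from overlapping contigs merge with summed support. Two
IESs separated by only a few bases remain a documented blind spot: the
anchor gap spans both insertions and the realigned block is not TA-bounded
as a single unit.

TA-indels — low-level variants of the polyploid somatic genome left by
excision errors — are classified against the catalogue
(`classify_ta_indels()`): exact matches, internal alternative boundaries
(the indel is a TA-bounded sub-segment sharing one boundary `TA`), external
alternative boundaries (one end on an IES boundary, the other at a somatic
`TA` outside it), or unrelated.

## Catalogue statistics

* **Size periodicity** (`size_periodicity()`): counts are smoothed with a
  discrete Gaussian kernel (σ = 1.5 bp, matching the within-peak spread);
  local maxima qualify as peaks only with prominence ≥ 5% of the highest
  smoothed count *and* ≥ 30% of their own height. The relative criterion
  is scale-free, so multinomial noise on a flat distribution never
  qualifies (fewer than three peaks is an error), while genuine peaks of
  any amplitude do. Peak indices are inferred from the median inter-peak
  spacing before the least-squares fit of position on index, so the
  near-empty second peak of real catalogues cannot bias the slope.
* **End logo** (`end_logo()`): computed on the full germline element
  (sequence plus the retained right `TA`), pooling the left end with the
  reverse-complemented right end; positions 1–2 are constitutively `T`,
  `A`. Information content is the Kullback–Leibler divergence from a
  background with the genome's G+C (default 0.28), in bits.
* **Stop-codon classification** (`classify_stop_in_frame()`): defaults to
  the ciliate nuclear code (translation table 6), where `TAA`/`TAG` encode
  glutamine and `TGA` is the only stop — under the standard code most
  AT-rich IESs would be misclassified as stop-containing. Junction codons
  straddling the insertion are completed from flanking coding bases and
  included; with missing flanks they are skipped, never guessed.
* **3n bias** (`chi2_3n_bias()`): a two-cell goodness-of-fit chi-squared
  (df = 1, no continuity correction) of a category's (3n, non-3n) counts
  against the proportions of the non-coding null.
* **Density vs expression** (`density_by_expression()`): equal-count
  expression bins (the alternative — equal-width — leaves extreme bins
  nearly empty); bin density is total IES count over total coding kb, and
  an OLS fit on bin rank summarizes the trend.
* **Positional uniformity** (`positional_uniformity()`): one-sample
  Kolmogorov–Smirnov against Uniform(0, L) with the asymptotic p-value and
  no multiple-testing correction, matching the raw `p < 0.002` convention;
  integer positions produce ties, which the asymptotic approximation
  tolerates and the calibration test quantifies.

## Conservation and the quartet gain/loss model

Conservation between ohnologs is positional: each IES offset maps to its
alignment column, and a pair is conserved when columns agree within
**2 nt** — slack for alignment wobble around the `TA`. Only nucleotide
alignments are supported; back-translated protein alignments of the same
gene pairs could shift a small number of borderline calls.

Clustering of homologous IESs at non-homologous sites replaces
database-scale E-value thresholds with alignment scores (similarity:
local score ≥ 50 covering ≥ 85% of the longer element; site-duplication
exclusion: flank-vs-flank score ≥ 40 over 500 bp flanks), chosen to
approximate stringent BLASTN cutoffs at a few hundred bp scale;
low-complexity members (dinucleotide entropy < 2 bits) are dropped, and
clusters are the transitive closure.

The gain/loss model works on quartets — gene families retained in four
copies through the intermediate and recent WGDs. Assumptions, following
the source analysis:

* an IES present at the same position in ohnologs descends from a single
  ancestral insertion (double insertion at one site is negligible);
* a constant loss rate λ ties every survival factor to one parameter
  `s = e^(−λτ)` per period and branch;
* the two inter-WGD periods have **equal durations** (the lineage's
  protein-divergence branch lengths justify this; the ratio is
  configurable);
* acquisition times are uniform within a period, giving partial-period
  survival `σ = (1−s)/(λτ) = (1−s)/(−log s)`;
* the pre-intermediate-WGD cohort fraction ρ3 absorbs any earlier loss
  (those events are not separately identifiable).

Cohort pattern probabilities are closed-form in `s` (e.g. the
all-four-present probability for the oldest cohort is `s^6`: two branches
times three branch-periods each); the five observable patterns are
multinomial after conditioning on observation, and `fit_gain_loss()`
maximizes the likelihood over `(s, w3, w2, w1)` on an unconstrained scale
(logit `s`, log-ratio weights) with a fixed 3×3×3 Nelder–Mead start grid
and a 1e-12 relative tolerance — deterministic by construction. Observed
weights convert to acquisition fractions by dividing out each cohort's
observation probability. `lrt_all_ancient()` compares the full model to
the single-cohort null (df = 2). Cross-branch single-single patterns
(1010, 1001, 0110, 0101) are lumped, matching how such counts are reported.

Fitting the model to the published pattern counts (190, 64, 1304, 10, 558)
yields cohort fractions within a couple of percentage points of the
published 15%/69%/16% split; the residual difference is the kind of shift
expected from definitional details of the acquisition-time distribution,
which published accounts leave underdetermined.

## What the generator emulates — and what it does not

`simulate_ies_dataset()` produces, deterministically from one seed: an
i.i.d. 28% G+C multi-scaffold genome with tiled gene models (1–3 exons,
20–30 bp introns); IESs planted at existing `TA` dinucleotides (so every
planted locus is canonicalizable) with ≥ 250 bp mutual spacing and a
600 bp scaffold-edge margin; lengths from the periodic mixture (first peak
28 bp, spacing 10.2 bp, per-peak s.d. 1.5 bp, geometric decay 0.65, second
peak damped ×0.05, hard minimum 26 bp); sequences with the degenerate
`TAYAGYNR` consensus at both germline ends and an interior G+C chosen so
the pooled element composition hits 20%; error-free 108 nt reads at 160x
coverage whose somatic alignments are computed analytically (clips equal
the IES overhang beyond the retained `TA`; no extension through chance
homology); and overlapping 1.5 kb contig tiles of the germline.

Real data differ in ways the generator deliberately omits: sequencing
error and quality structure, repeats and low-complexity tracts, assembly
chimeras, imprecisely eliminated germline-specific regions outside the
collinear genome, nested or adjacent IESs, and any dependence between IES
length and end-consensus strength. Passing the simulation-scale tests
therefore demonstrates the correctness of the detection *logic* under the
stated statistical structure — not mapper or assembler robustness on real
libraries, which the published pipelines delegated to external tools.

Problem sizes in the test suite are package choices balancing resolution
against runtime: the end-to-end detection check uses a 500 kb genome with
500 planted IESs at 160x (genome-scale per-site signal at desk-scale
total size), parameter recovery uses 50 replicates of 2,000 quartet loci,
and the periodicity sweep uses 40,000 lengths per spacing.

## Known limitations

* Plain-text SAM only (columns 1–6); BAM/CRAM inputs should be converted
  upstream.
* Single-end alignment evidence; paired-end insert-size signals are not
  used.
* Anchor chaining assumes mostly colinear contigs; large rearrangements
  are skipped, not resolved.
* The quartet classifier requires a joint alignment of the four ohnologs
  and treats within-group position conflicts as ambiguous rather than
  attempting to split them.
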