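---
title: "Methods: comparative plastome analysis with plastcomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative plastome analysis with plastcomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastcomp)
```

# Scope

`plastcomp` implements the analytical core of a comparative chloroplast
genome (plastome) study: quadripartite structure and region statistics,
microsatellite and long-repeat surveys, substitution and InDel extraction
with transition/transversion (Ts/Tv) classification, per-gene Ka/Ks
selection estimates, codon-usage profiling, characterization of the genes
at the single-copy/inverted-repeat junctions, and binned correlation and
co-occurrence analysis of mutational events. A synthetic plastome
generator with exhaustive ground-truth logging makes every stage testable
in a closed loop, without any external data. Read assembly, annotation
transfer, tree search and divergence dating are out of scope; those steps
are consumed from external tools when needed.

# Quadripartite structure detection

Land-plant plastomes are circular molecules of roughly 120–170 kb with a
large single-copy region (LSC), a small single-copy region (SSC) and two
identical inverted repeats (IRa/IRb). `detect_quadripartite()` finds the
IR pair automatically: 21-mers of the sequence are matched against its
reverse complement; a contiguous inverted duplication is colinear in that
transformed space, so co-diagonal seed runs are merged across isolated
mismatches and extended base-by-base at their ends. Because the molecule
is circular and an IR copy may straddle the arbitrary linearization
origin, detection runs in two frames half a genome apart (a copy cannot
straddle the origin in both) and candidates are pooled; distinct physical
duplications tied for maximal length raise an explicit ambiguity error.

Conventions, chosen once and used everywhere:

* Coordinates are 1-based inclusive (the GenBank convention).
* The structure is reported after rotation normalization: the LSC starts
  at position 1 and the region order is LSC–IRb–SSC–IRa, with IRb the
  copy downstream of the LSC. LSC and SSC are disambiguated purely by
  length (LSC is longer).
* The two copies may differ slightly in real assemblies; detection
  accepts a candidate at `min_identity` (default 0.99) over the aligned
  extent, with a `min_ir_len` floor of 10 kb.

Region statistics exclude ambiguous bases (`N`) from both numerator and
denominator of the GC fraction. The gene census counts a gene as
IR-duplicated when two loci share a name and their midpoints fall in the
two different IR copies; the unique count collapses such pairs, so
`total = unique + duplicated_in_ir`.

# Microsatellites (SSRs)

`find_ssrs()` applies the MISA-style thresholds used throughout the
plastome literature: a perfect tandem repeat qualifies at ≥10 copies for
mononucleotide units, ≥5 for di-, ≥4 for tri-, and ≥3 for tetra-, penta-
and hexanucleotide units. Only perfect (uninterrupted) repeats are
reported; compound-SSR merging is deliberately not implemented because
simple locus counts are what comparative surveys report. A run whose unit
is itself periodic (`AAAAAA` read as `AA`×3) is reported only at the
smallest unit, and `N` terminates any run. Loci are maximal: no reported
run can be extended by one unit on either side.

For reporting, a motif is canonicalized to the lexicographically smallest
rotation of its unit and merged with its reverse complement, producing
the conventional class labels (`A/T`, `AT/AT`, `AAT/ATT`, ...). Region
assignment uses the locus start; a locus spanning a region junction is
assigned to its start's region and flagged. Both IR copies are scanned
(the genome is processed as one linear sequence), so an IR-resident SSR
appears twice — mirroring how a whole-genome scan of the deposited record
would behave.

# Oligonucleotide repeats

`find_oligo_repeats()` surveys long dispersed repeat pairs of the four
classical kinds — forward (identical), reverse (reversed), complement
(complemented, not reversed) and palindromic (reverse complement) — at
the customary settings of ≥30 bp and ≥90% identity. The identity model is
Hamming (mismatches only, no gaps): it is deterministic and can be
checked against a dense offset-scan oracle, which an edit-distance model
would frustrate.

Detection is seed-and-extend with exact 11-bp seeds. Extension absorbs a
mismatch block only when (i) the block together with the match run that
follows it itself meets the identity floor, and (ii) the whole pair stays
within the global budget `floor((1 - min_identity) · length)`. The local
condition is what stops a perfect planted copy from creeping into
unrelated flanking sequence (random flanks mismatch ~75% of positions and
never satisfy it) while still crossing the isolated mismatches of a
genuinely degraded copy. Pair ends always fall on matching bases.
Overlapping alternative extensions on one match diagonal are collapsed to
the longest, and pairs nested inside a longer same-kind pair are
suppressed.

The genome-scale IR duplication is itself the largest palindromic repeat
and is reported — flagged `is_genomic_ir` (palindromic pairs ≥1 kb by
default) so per-genome tallies can exclude it, which
`summarize_repeat_kinds()` does by default; published per-genome repeat
counts are small and plainly exclude the IR itself.

# Pairwise alignment and mutational events

Whole plastomes within a genus are typically >99% identical, so
`align_near_identical()` uses an anchored strategy: k-mers (k = 21)
unique in both sequences are chained by longest increasing subsequence,
merged into exact blocks, and the short segments between blocks are
closed by a dense affine-gap Needleman–Wunsch (match +1, mismatch −2, gap
open −5, gap extend −1; a gap of length L costs 5 + L). Ties in the
traceback resolve deterministically (substitution over gap-in-query over
gap-in-reference). Inputs that leave an unanchored segment longer than
2.5 kb, or that align below 95% identity, are rejected with advice to use
an external aligner — this tool is for near-identical genomes only.

Gap runs are then left-shifted to the lowest reference coordinate that
yields an equivalent alignment. This normalization matters: without it,
an InDel inside a homopolymer has as many equally scoring placements as
the run has bases, and downstream binning would be nondeterministic.
Event extraction yields one substitution per mismatching non-gap column
(columns containing `N` are skipped) and one InDel event per maximal gap
run, anchored at the first deleted base (deletions) or the preceding
reference base (insertions). Adjacent gap runs separated by at least one
match column remain separate events. Whether substitutions in
InDel-adjacent columns should be counted is not standardized; this
implementation counts them, and the left-shift convention makes the
choice reproducible.

`summarize_substitutions()` tabulates the six unordered base-pair
categories (A/C, C/T, A/G, A/T, C/G, G/T); transitions are C/T + A/G and
the Ts/Tv ratio is reported to two decimals, `NA` when no transversions
exist.

# Ka/Ks and codon usage

Selection is estimated with the Nei–Gojobori (1986) counting method.
Synonymous (S) and non-synonymous (N) site counts per codon are
normalized to 3 and averaged over the two sequences; mutations creating a
stop codon count as non-synonymous. Observed differences are averaged
over all minimal mutational pathways between differing codons, excluding
pathways that pass through a stop codon (weight redistributed over the
remaining paths; if every path is blocked, all are used). Proportions are
corrected for multiple hits with the Jukes–Cantor transform
`d = −(3/4)·ln(1 − (4/3)·p)`; a proportion at or above 3/4 is reported
`NA`. The implementation reproduces an independent reference
implementation of NG86 to ten decimals on fixed fixtures (see the test
suite). No maximum-likelihood (Goldman–Yang) machinery is attempted: NG86
is deterministic, assumption-light, and sufficient for the purifying-
versus-positive contrasts plastome surveys draw.

Codon pairing is protein-guided: sequences are translated (standard
genetic code; internal stops are hard errors naming gene and codon) and
the proteins globally aligned; codon pairs containing a gap or non-ACGT
base are excluded. Selection categories follow a banding consistent with
how practitioners label ratios: >1.05 positive, 0.95–1.05 neutral,
0.80–0.95 approximately neutral, <0.80 purifying; the band edges are
configurable because the field's labels ("neutral" at 0.96, "approximate
neutral" at 0.86) imply but do not define them.

`codon_profile()` pools codon counts, reports amino-acid frequencies over
non-stop residues, RSCU (observed count over the synonymous-family mean,
so every family averages 1), and the A/T- versus G/C-ending third-position
tally.

# Junction reports

The four junctions are named JLB (LSC/IRb), JSB (IRb/SSC), JSA (SSC/IRa)
and JLA (IRa/LSC, the wrap back to position 1). For each junction the
report gives the gene locus spanning it — with the base count on each
side, which must sum to the locus length — or the nearest locus on each
side within 2 kb, with the distance counted in bases strictly between
junction and locus (so a gene abutting the junction is at distance 0). A
locus sharing its name with a locus that spans the mirrored junction on
the other IR copy is labelled a pseudogene: this is the classic truncated
ycf1 fragment at JSB.

# Hotspot correlation and co-occurrence

Events are binned into fixed 250-bp windows anchored at position 1, the
final partial bin retained. Substitutions and InDels are assigned by
reference position; each repeat copy is assigned by its start, so a pair
contributes two counts, and pairs flagged as the genomic IR are dropped.
Pearson correlations among the three tracks are computed over **all**
bins, including empty ones (a `drop_empty` flag provides the alternative;
which convention published analyses used is usually unstated).

Correlation strength labels use half-open bands on |r|: [0, 0.10) none,
[0.10, 0.20) negligible/very weak, [0.20, 0.30) weak, [0.30, 0.40)
moderate, [0.40, 0.70) strong, [0.70, 1.0) very strong, and exactly 1.0
perfect. The published scale leaves gaps between its printed band edges
(0.19 → 0.20 and so on); the half-open reading closes them so every value
— including averages like 0.195 that fall inside a printed gap — gets a
deterministic label.

Co-occurrence percentages use event-level numerators: "X with Y" is the
share of X events lying in bins that contain at least one Y event. The
event-level denominator is what produces the non-round percentages seen
in published tables (e.g. 16 of 23 InDels → 69.57%); a bin-level variant
would produce different granularity. The three reported pairs are InDels
with substitutions, repeat copies with InDels, and repeat copies with
substitutions.

# The synthetic plastome generator

`generate_plastome()` emits a circular genome laid out LSC + IRb + SSC +
IRa with IRa the exact reverse complement of IRb. Its defaults are the
study conditions the rest of the package is tested under: a ~153 kb
genome (LSC 87 kb, SSC 20 kb, IR 23 kb), 38% GC, a catalog of 113 unique
genes (79 protein-coding, 30 tRNA, 4 rRNA) with 15 IR-duplicated
(4 + 7 + 4), roughly 50 planted SSRs dominated by A/T mononucleotide
runs, a handful of ≥30 bp repeats, and a divergence model with a
substitution rate of 0.0023/bp (a few hundred events per genome pair),
Ts:Tv 1.5, an InDel rate of 2 × 10⁻⁴/bp with geometric lengths (mean 4 bp,
capped at 50 bp — a plausible plastome InDel spectrum), and mutational
hotspots (below).

Design choices that make closed-loop testing sound:

* **Coding sequences** are in-frame ORFs with no internal stops, with
  body codons drawn in proportion to the product of base frequencies at
  the configured GC. This single assumption reproduces the canonical
  plastome amino-acid profile — leucine first (>10%), isoleucine close
  behind, cysteine rare — and the A/T-ending third-position bias, without
  fitting any real codon table.
* **SSR scrubbing.** Random background occasionally contains qualifying
  runs; after gene placement the generator breaks every non-planted run
  (a base flip at a background position inside the run), and gene
  sequences are rejection-sampled to be SSR-free, so the truth log is
  exactly the set of detectable loci.
* **Junction guards.** The planted IR must be *maximal* on the circle, or
  structure detection would legitimately overshoot the planted
  boundaries by chance complementary bases; the generator enforces
  inequality of the four junction-flanking base pairs, repairing any
  violation with a flip that keeps affected reading frames stop-free.
* **The optional junction layout** plants the canonical boundary genes:
  trnH 12 bases into the LSC, rpl2 spanning JLB with 3 bases in the IRb,
  ycf1 spanning JSA with a 266-base IR-side overhang (its truncated
  mirror ending exactly at JSB), and ndhF ending exactly at the JSB
  junction — offsets chosen inside the ranges reported for real
  Calycanthaceae plastomes.
* **Divergence** (`diverge()`) draws substitutions per-site with
  transition probability `tstv/(tstv+1)` and InDels kept ≥100 bp apart
  and clear of planted SSRs and region boundaries, so alignment-based
  event recovery is unambiguous (recall and precision 1.0 in the closed
  loop). With `preserve_ir` (default) events in IRb are mirrored into IRa
  and the IR copies stay identical. A gamma-distributed per-window
  mutation-intensity landscape (mean 1, CV 1, 500-bp windows) is shared
  by substitutions and InDels: this is what makes the two event classes
  co-occur along the genome, and it reproduces the qualitative
  observation that deeper divergence yields stronger substitution–InDel
  correlation while shallow divergence yields weak correlation.

What the generator does **not** emulate — and hence what green tests do
not show about real data: gene order rearrangement, intron evolution,
compound or interrupted SSRs, gap-containing repeat families, selection
acting on codon usage, context-dependent mutation (CpG-like effects), and
assembly or annotation error. Conclusions about those phenomena need real
records.

# Numerical choices and problem sizes

Anchor k = 21 balances uniqueness (random collision probability ~4⁻²¹)
against tolerance of dense substitutions; repeat seeds are 11 bp, below
which seeding cost rises steeply and above which degraded 30-bp repeats
could lack an exact seed. Alignment traceback ties, SSR ties and repeat
containment all resolve deterministically, and every stochastic routine
takes an explicit seed; reruns are byte-identical.

The test suite and the acceptance script run on reduced problem sizes
chosen to exercise every code path at full fidelity: 15-kb quadripartite
genomes (LSC 8 kb, SSC 2 kb, IR 2.5 kb) for closed-loop structure, SSR,
repeat, junction and event tests; the full 153-kb default for the census
and amino-acid profile; 100 random 5-kb draws for the SSR oracle; 50
random 2-kb draws for the repeat oracle; pooled substitution draws for Ts:Tv recovery (≥10,000 in
the test suite, ~40,000 in the acceptance script); 500 replicates of 600
bins for Pearson recovery; and 40 replicates of 300-codon pairs for ω
recovery. These sizes give the
recovery statistics standard errors comfortably inside their asserted
bounds (±0.05 on Ts:Tv, ±0.03 on ρ, ±0.05 on ω).

# Known limitations

* The aligner is for near-identical sequences; above ~5% divergence it
  refuses rather than degrade silently.
* Hamming-only repeat identity undercounts repeats whose copies differ by
  small indels.
* Junction reports assume the rotation-normalized frame; a gene spanning
  the JLA origin itself cannot be represented and the generator never
  creates one.
* NG86 saturates (returns `NA`) when a difference proportion reaches 3/4;
  deep comparisons need model-based estimators outside this package's
  scope.
* The per-unique-region SSR mode (counting IR loci once) is provided as a
  flag but defaults to whole-genome scanning; published totals do not
  state which convention they used.
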