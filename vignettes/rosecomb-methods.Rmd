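---
title: "Models and methods behind the rosecomb package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the rosecomb package}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rosecomb)
```

## The locus and the allelic series

The Rose-comb phenotype in chickens is caused by a large structural
rearrangement on chromosome 7. Two alleles exist. `R1` is a 7.38 Mb
paracentric inversion with breakpoints at galGal3 positions 16,499,781 and
23,881,384–23,881,392. `R2` arose from `R1` by unequal crossing over with a
wild-type chromosome: it does not carry the inversion, but instead an
insertion at the proximal breakpoint consisting of the distal-most 91 kb
(23,790,414–23,881,384) of the inverted region in reverse orientation,
flanked on both sides by a 198 bp fragment (16,499,583–16,499,781). The
rearrangement relocates the `MNR2` homeodomain gene (3 kb inside the distal
breakpoint) to the proximal region in both alleles — the shared lesion behind
the comb phenotype — and in `R1` disrupts `CCDC108` in intron 3, the
candidate for the recessive sperm-motility defect of `R1R1` males.

`rosecomb` models an allele as an ordered list of oriented reference
segments (0-based, half-open). Everything else — junction extraction,
coordinate liftover, read simulation, in-silico PCR, gene effects — is
derived from this segment map, so the three alleles are:

```
r  : [0,a) +
R1 : [0,a) +   [a,b) -   [b,L) +
R2 : [0,a) +   [d,b) -   [c,L) +
```

with `a` = 16,499,781, `b` = 23,881,384, `c` = a − 198, `d` = b − 90,970.

### Coordinate conventions

Printed coordinates are 1-based inclusive; internally every breakpoint is a
0-based half-open *cut* whose numeric value coincides with the printed
position of the last base on its left side. Two printed statements conflict
("198 bp" in one place, "199 bp fragment" in another — inclusive versus
exclusive counting); the package standardizes on the half-open difference of
198 bp, which is also what the printed coordinate pair 16,499,583–16,499,781
yields. The distal breakpoint is ambiguous over 23,881,384–23,881,392
because of junction microhomology; the interval is retained in
`rosecomb_breakpoints()` and the left edge is the canonical construction
coordinate (the exact cut inside a homology tract is unknowable in
principle).

### Junctions and what "the five breakpoints" means

`extract_junctions()` reports one junction per adjacent segment pair whose
reference sides are non-contiguous or orientation-discordant. Wild type has
none and `R1` has two. `R2` has **two** sequence-detectable junctions — not
three — because the boundary where the duplicated 198 bp flank rejoins
wild-type sequence at position `a` is reference-contiguous and concordant:
no sequence feature marks it. The four reference cut positions of the two
`R2` junctions nevertheless recover all four printed `R2` breakpoints
(`a`, `b`, `c`, `d`). The locus's five diagnostic breakpoint *contexts*
(wild-type proximal, wild-type distal, shared novel proximal, `R1`-distal,
`R2` duplication junction) are exactly the five amplicons of the genotyping
assay below.

### Microhomology

At a junction, bases shared between the two joined parental sequences make
the cut ambiguous. `microhomology()` takes three equal-length strings with
the cut at the middle — the junction sequence and the two parental reference
contexts, each read in the orientation the allele traverses it — and
maximizes the contiguous tract `l + r` across the cut (junction bases left
of the cut matched against the right-joined parent, and vice versa) subject
to a mismatch budget. The reported `ambiguity_len` is the tract under zero
mismatches, i.e. the interval over which the cut cannot be placed. The three
junction homologies described for this locus (1 bp at the shared proximal
junction, 7 bp with one mismatch at the `R1` distal junction, 2 bp at the
`R2` crossover junction) are reproduced in the test suite on junctions
constructed to that geometry; on the package's random toy reference the
simulated junctions have whatever short homology arises by chance. The
implementation is checked against an exhaustive O(k²) brute-force scan.

## The synthetic-data generator

All inputs are generated in-repo; nothing external is downloaded.

**Toy scale.** The full architecture spans 24 Mb; simulating it is
pointless for testing the geometry. The default layout
(`rosecomb_coords()`) compresses the inversion 1/100 onto a 300 kb forged
reference (73,816 bp inversion). Two features are deliberately *not* scaled
with it: the 198 bp duplicated flank keeps its natural size, and the 91 kb
duplication is scaled only 1/10 (9,097 bp) so that it remains larger than
the 3.9 kb insert — otherwise fragments would routinely straddle the whole
insertion and junction-spanning geometry would be unrealistic. Pure
coordinate arithmetic (spans, allele lengths, amplicon sizes) is additionally
exercised at the printed coordinates through segment algebra, which needs no
sequence.

**Mate pairs.** `simulate_matepairs()` emulates a SOLiD-style 3.9 kb
mate-pair library: 2×50 bp reads, both on the same strand of the fragment,
Gaussian insert (`mu` 3,900 bp; `sigma` 390 bp, i.e. 10% — the study reports
only the mean, and 10% is typical for kb-scale mate-pair libraries), ~1×
read coverage by default. Fragments are drawn per chromosome at equal
per-base coverage (so the Le Mans-style pool `{R1:4, R2:9, r:3}` weights
junction-spanning fragments 13:4 between the shared proximal junction and
the `R1`-distal junction). Each read is lifted independently through the
segment map; a read overlapping a junction by more than the 5 bp clip
tolerance is flagged unmapped — the emulated mappers predate split-read
alignment — which converts its pair into a one-end-mapped record.
Sequencing errors are available as a uniform substitution rate but default
to 0 because discordance calling uses placements, not base calls. Records
round-trip through a minimal SAM dialect (`write_sam()`/`read_sam()`) whose
optional fields carry the truth tags.

**SNP panel and pedigree.** `simulate_snp_panel()` draws biallelic dosages
under Hardy–Weinberg except that case (`R1R1`) birds share one fixed
homozygous haplotype across the sweep interval 16,424,096–23,854,241,
emulating the fixed inverted haplotype. `simulate_pedigree()` reproduces the
mapping design — 2 carrier (`R1r`) sires × 8 `rr` dams × 383 progeny,
phase-known — by a haplotype walk over the 11-marker map with per-interval
recombination fractions, forced to 0 between loci inside the suppressed
interval (the inversion suppresses recombination in carrier meioses), plus a
1.3% marker missing rate so informative meiosis counts vary by marker (the
emulated top marker has n = 378 of 383).

What the generator does **not** emulate: base-call quality and color-space
chemistry, reference gaps and repeats (the real assembly's gap structure
around 23.79 Mb is why the study mapped few reads there), mapping ambiguity,
between-chromosome coverage imbalance within a pool, and incomplete
penetrance. Passing tests therefore demonstrate the correctness of the
algorithms under clean mapping assumptions, not robustness to real-mapper
artifacts.

## The discordance caller

`classify_pairs()` labels each pair: orientation departing from the
library's expected configuration → `orientation_anomaly` (inversion
signature under same-strand chemistry); otherwise a span strictly exceeding
`mu + 10·sigma` → `distance_anomaly` ("exceeding" is read as strict, so a
span of exactly `mu + 10·sigma` is concordant). Symmetric flagging of short
spans is on by default (a deletion/duplication compresses spans just as an
expansion stretches them) and can be disabled to match the upper-tail-only
reading.

`call_sv_windows()` tiles the reference in non-overlapping 1.5 kb windows
anchored on each mapped end (each pair is counted in the window of either
end, which is what makes the two sides of an event mutually discoverable).
A window is a candidate when ≥ 25% of its pairs are discordant *and* ≥ 25%
of its pairs have partners within 1 kb of each other (single-linkage
chaining), with at least `min_pairs = 4` support — without the floor, a
single stray pair would make a "100% discordant" window at 1× coverage. The
25% clause is applied to *all* of a window's pairs (the published wording is
grammatically ambiguous between all pairs and discordant pairs; both
thresholds are exposed as parameters). Partner clusters are kept separate
per strand pattern so the two reciprocal junctions of an inversion — whose
support clusters abut at both breakpoints — do not fuse into one locus.
Reciprocal candidates merge into one call typed by majority strand pattern,
ties going to inversion (orientation evidence is the stronger signal); the
call size is the distance between the two partner-cluster midpoints, which
is why a pure inversion's size lands within one window of truth.

`refine_breakpoints()` narrows each side geometrically. A junction side is
approached by its support from one direction; which direction follows
deterministically from read order and strand (the fragment-leading read
approaches from below iff it maps `+`; the trailing read iff it maps `-`
under same-strand chemistry), majority-voted over supporting pairs. The
refined interval is the intersection over pairs of
`[inner end, inner end + (mu + 3·sigma − 2·read_len − gap)]` (mirrored for
above-approached sides), where `gap` measures how far a pair's partner end
sits back from the partner-side support frontier; because the frontier
itself sits short of the true cut by about the local read spacing, the
bound is padded by three times `(mu − 2·read_len)/support`. The result is
capped at the input locus width; an empty intersection falls back to the
input interval and is flagged. With support from only one side of a cut the
bound cannot be tighter than read spacing allows — sub-clip-tolerance
refinement would require evidence from both directions, which one call does
not own.

## Junction-PCR genotyping

Five positional primers (primer thermodynamics is out of scope; sequences
for the original assay are not public) are anchored at fixed offsets from
the breakpoints, so all product sizes are invariant under the coordinate
scale factor. In-silico PCR (`predict_amplicons()`) maps each primer through
the segment map — a primer anchors multiple times where its site is
duplicated, and flips strand inside reverse-orientation segments — and
enumerates convergent pairs within 2 kb. The design yields exactly five
diagnostic amplicons, one per breakpoint context, with pairwise size
separation beyond twice the ±5% band-matching tolerance; `rosecomb_assay()`
asserts both this separation and the injectivity of the six-genotype truth
table at design time, and rejects any layout violating either.

A consequence worth noting: `R2` retains intact wild-type sequence across
the *distal* breakpoint (its suffix from position `c` onward is wild type),
so it is positive for the wild-type distal band and the shared proximal
junction band but negative for the `R1`-distal band — the band logic that
first revealed the allele's existence. The wild-type *proximal* amplicon is
absent in `R2` because its primers straddle the insertion and the product
exceeds the length cutoff. Observed patterns that match no truth-table row
(e.g. all five bands at once) are returned as no-calls with a diagnostic,
never coerced.

## Breakpoint annotation

Gene models are ordered exon intervals with a strand, a start codon, and
optional UTRs; `toy_gene_models()` rebuilds the published geometry at any
scale: the proximal cut inside the FKBP7-like 5′UTR 72 bp upstream of its
start codon, the divergent PLEKHA3-like gene with 9 bp between the two
5′UTRs (cut 42 bp from its UTR, 150 bp from its start codon), the
CCDC108-like gene cut in intron 3 with exons 1–3 proximal of the cut, and
the intact MNR2-like gene 3 kb inside the distal breakpoint. Distances are
counted as bases strictly between the cut and the landmark.

`predict_gene_effects()` lifts each gene through the segment map: a gene
with at least one full-length contiguous, orientation-consistent copy is
intact (duplications add partial copies — on `R2`, the CCDC108-like gene is
intact *and* donates its first three exons to the insertion, matching the
allele's transcript biology); a gene with no full copy is disrupted, its
exons partitioned at the cut and a truncated transcript predicted for the
fragment lacking the start-codon side. "Relocated" is defined operationally
as an intact gene lying within 10 kb of a junction on the allele or carried
on a reversed segment — this flags the MNR2-like relocation and also the
FKBP7/PLEKHA3 neighborhood change at the proximal cut, consistent with the
possibility of altered regulation on both sides. Fusion candidates are the
gene pairs facing each other across a junction within the same radius; no
splice-graph prediction is attempted (exon-skipping hybrids are splicing
phenomena a genomic model cannot predict).

## Population genetics

**Heterozygosity scan.** Per-locus `H = 1 − Σ pᵢ²` from sample allele
frequencies, averaged in 500 kb windows (tiled by default; the stride is a
parameter since the original description says "sliding" without stating
one). Windows with `H = 0` in cases and `H > 0` in controls are reported as
candidate sweeps; on the simulated panel the detected run equals exactly the
set of windows fully contained in the configured sweep interval — window
resolution is the scan's native precision.

**Two-point linkage.** For a phase-known backcross, `theta_hat = r/n` over
informative carrier-sire meioses and
`LOD = n(θ̂log₁₀θ̂ + (1−θ̂)log₁₀(1−θ̂) + log₁₀2)` with `0·log₁₀0 ≡ 0`; a fully
linked marker gives `n·log₁₀2`, e.g. 113.8 at `n = 378` — the informative
count back-derived from the published LOD, since the table does not print
`n`. The implementation is property-tested against a grid/optimizer
maximization of the binomial likelihood over `theta ∈ [0, 0.5]`.

**Breeding equilibrium.** Why do Rose-comb flocks keep throwing
single-combed chicks? Homozygous `RR` sires are effectively sterile under
flock mating (sperm competition), while breeders cull single-combed (`rr`)
birds of both sexes. The package's deterministic recursion uses discrete
non-overlapping generations, complete `rr` culling, complete `RR` sire
exclusion, and random mating otherwise, each assumption a parameter. With
offspring collapsed to Hardy–Weinberg proportions at their mean allele
frequency (the default), the wild-type allele frequency obeys
`q' = (1/2 + q/(1+q))/2`, whose fixed point is `q* = (√17 − 1)/8 ≈ 0.390`,
giving an equilibrium single-comb offspring fraction
`q*/(2(1+q*)) ≈ 0.140`. Tracking genotype frequencies exactly instead
(`hardy_weinberg_offspring = FALSE`) gives `(1 − √2/2)/2 ≈ 0.146`, and the
finite-flock Monte Carlo (`simulate_flock()`) converges to that value; the
Monte-Carlo test compares against this matching variant. Both sit near the
folk figure of "about 15%" single-combed chicks; the historical number
traces to a model whose exact assumptions were never printed, so the ~1
percentage-point gap is documented rather than reconciled, and the package
reports its own computed 14.0%.

## Problem sizes and determinism

Default test and demo sizes: 300 kb reference, ~3,000 mate pairs (1×
coverage), cohorts of 200–400 birds, SNP panels of 140 birds × 1,801 loci,
383-progeny pedigrees, and a 10,000-bird × 200-generation Monte-Carlo
flock. Every generator is deterministic under a fixed seed (the SAM output
is byte-identical across runs), and every intermediate file round-trips
through the package's own readers.

## Known limitations

* The caller is a faithful implementation of the windowed discordance rule,
  not a general SV caller: no split-read or assembly breakpointing, no
  copy-number segmentation, no multi-chromosome events.
* Junction detection is sequence-level; duplication boundaries that rejoin
  reference-contiguous sequence (the 198 bp flank's distal edge in `R2`)
  are invisible to it by construction and are covered instead by the assay's
  amplicon logic.
* Genotyping is presence/absence over designed band sizes; real gel scoring
  noise beyond ±5% multiplicative error is not modelled.
* The equilibrium model ignores overlapping generations, partial sperm
  competition, and finite-flock inbreeding other than through the Monte
  Carlo.
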