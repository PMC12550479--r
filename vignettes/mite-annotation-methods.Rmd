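---
title: "Methods: MITE annotation, dating and comparative analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MITE annotation, dating and comparative analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitekit)
```

# The problem

Miniature inverted-repeat transposable elements (MITEs) are short
(50--800 bp) non-autonomous class II transposons. A copy has two structural
hallmarks: a terminal inverted repeat (TIR) -- the 5' end of the element
reappears reverse-complemented at its 3' end -- and a target site
duplication (TSD), a 2--10 bp host motif written on both flanks when the
element inserted. `mitekit` implements a complete annotation workflow
around these hallmarks: de novo candidate discovery, family construction
and curation, superfamily classification, genome-wide copy recovery,
K80-based insertion dating, cross-species orthologous-locus
classification, gene-context profiling, MITE-derived miRNA identification,
and nucleotide-level benchmarking. A synthetic-genome generator with full
ground truth makes every stage testable without external data.

# Candidate discovery

`find_tir_candidates()` seeds on exact reverse-complement word pairs of
length `tir_min_len` (default 10 bp) located through a k-mer index, at
separations compatible with a 50--800 bp element. Each seed pair is
extended outward while the complementarity stays exact, giving a canonical
complementary run.

The subtlety is that popular TSDs are themselves reverse-complement
palindromes: "TA" (Tc1/Mariner, Micron) and, partially, TAA/TTA
(PIF/Harbinger). Exact outward extension therefore absorbs the TSD into
the apparent TIR and overshoots the element boundary. The detector
resolves this by evaluating every retraction depth of the canonical run
(up to one maximal TSD plus a small margin) and selecting the boundary
maximising a *selection score*:

* net TIR evidence: the best prefix value of `length - 2 * mismatches`
  along the mismatch-tolerant inward extension (tolerance
  `tir_max_mismatch_frac`, default 10%);
* plus the TSD length (the longest exact flanking direct repeat, each
  length tested independently);
* plus a signature bonus of 8 when the TSD is a superfamily diagnostic
  (TA, TAA, TTA) or the element starts with the CACTA motif `CACT[AG]`.
  The TSD bonus is withheld in two situations: when the motif lies two or
  more columns inside the complementary run (a fragment of a longer
  absorbed palindrome rather than an insertion site), and when the
  candidate carries no second superfamily mark — a strong TIR (net
  evidence at least 13, the Tc1/PIF range), a CACTA start, or a
  Micron-like microsatellite context — because a bare 10 bp inverted
  repeat flanked by a chance TA repeat is routine in random sequence.

Candidates below `min_candidate_score` (default 18) are dropped; this is
the calibration constant that keeps the false-discovery rate on random
background below one spurious candidate per 100 kb while retaining the
weakest canonical structures (an 8 bp-TSD element with a 10 bp TIR, or a
2 bp-TSD element with a 12 bp signature TIR). The *reported* candidate
score stays the plain `tir_length + tsd_len - tir_mismatches`. Overlapping
candidates (>50% reciprocal) resolve to the highest score, then longer
TSD, then leftmost start.

Single-copy boundary calls remain intrinsically ambiguous in about 1--3%
of cases: a background base that happens to match the element edge, or a
flanking coincidence that extends the true TSD, produces two boundary
hypotheses that no sequence-level rule can separate. These are resolved at
the family level (below).

# Families

`build_families()` chains four steps:

1. **Greedy centroid clustering** (`cluster_candidates()`): candidates are
   processed by decreasing length; each joins the first centroid whose
   global-alignment identity reaches 0.8, where identity is matching
   columns over all alignment columns *including end gaps* (the `iddef 1`
   convention), else founds a new centroid. Families with fewer than three
   members dissolve into singletons. The partition depends on the
   processing order; decreasing length is the convention of the
   clustering tools this emulates.
2. **Flank-distinctness filter** (`flank_distinctness_filter()`): MITEs do
   not transpose with their flanks, so members whose concatenated 50 bp
   flanks align at >= 0.8 identity are one insertion observed twice; the
   higher-scoring record is kept, transitively. The 0.8 figure mirrors the
   clustering threshold -- "entirely distinct" is not otherwise
   quantifiable.
3. **Family-level boundary refinement** (`refine_family_boundaries()`):
   each member is extended by 50 bp of flank, aligned to a reference
   member, and detected boundaries are projected into reference
   coordinates; every member then moves to the modal family boundary and
   its TSD/TIR statistics are recomputed. This is the mechanizable
   analogue of curating ambiguous boundaries against the family, and it
   is what lifts exact-boundary recall on pristine planted elements to
   >= 99%.
4. **Seed selection and classification** (`select_seed()`,
   `classify_superfamily()`): the seed maximises (TSD length, TIR length,
   fewest TIR mismatches), with mean-divergence and leftmost tie-breaks.

When two detection sources are available, `merge_annotation_sets()` treats
records whose starts and ends each differ by <100 bp as the same element
and keeps the one with stricter boundary evidence (longer TIR, then
longer TSD).

# Superfamily classification

The rule table ships as editable YAML (`inst/extdata/superfamily_rules.yaml`)
and encodes the community diagnostics: Micron first (context-defined:
a `(TA)n`/`(CA)n`/`(GT)n` run of >= 5 units starting within 20 bp of a
boundary), then CACTA (2--3 bp TSD, `CACT[AG]` TIR start), Tc1/Mariner
(TSD "TA"), PIF/Harbinger (TAA/TTA), hAT (8 bp TSD with TIR length 5--27),
Mutator (8--10 bp TSD); everything else is "unknown". Exactly one rule
fires, and permuting the input never changes labels. hAT and Mutator
overlap at TSD length 8 and are separated by the TIR-length constraint;
ambiguous families deliberately stay "unknown" rather than being guessed.

# Genome scan

`scan_genome()` recovers all copies of each family from the seed library:
exact 11-mers of each seed (both orientations) are dictionary-matched
against the genome, co-linear anchors group into windows, and the seed is
aligned locally (match +1, mismatch -1, gap open -4, extend -1) inside
each window. Hits are kept when the Kimura two-parameter divergence over
the gap-free alignment columns is at most 0.15 (the `-div 15` convention)
and the score reaches `min_score` (default 50, i.e. the shortest
admissible perfect 50 bp hit under this scoring -- a calibration analogue,
not an equivalence claim, for the conventional score cutoff of 250 under
RepeatMasker's matrices). Same-family overlapping hits merge; cross-family
conflicts (>50% reciprocal overlap) keep the higher score. Hits composed
of more than 80% of one dinucleotide are dropped unless the family is
Micron, which suppresses microsatellite pileup without losing the
microsatellite-context class. A hit is *full length* when it covers at
least 90% of the seed with both ends present (within 10 bp of the seed
termini); the 90% figure is this package's definition of the otherwise
unspecified full-length/fragment distinction, exposed as
`full_length_coverage`.

`summarize_landscape()` reports the four landscape indices: genome
proportion (merged masked bases over genome size, percent), copy density
per Mb, mean hit length, and the number of families hit.

# Insertion dating

Following the copy-vs-consensus convention, `family_divergences()` builds
a center-star multiple alignment of each family around its seed, takes the
majority-rule consensus (columns with gap majority are dropped; residue
ties resolve to the seed symbol, then lexicographically), re-aligns every
member to the consensus and records the K80 distance

\[ K = -\tfrac12 \ln\big((1 - 2P - Q)\sqrt{1 - 2Q}\big) \]

with transitions `P` and transversions `Q` counted over columns where both
residues are in `{A,C,G,T}`. Saturated distances (either logarithm
argument non-positive) are flagged invalid and *excluded*, never clamped:
clamping would fabricate ancient insertions. Insertion age is `T = K/(2r)`
with `r` the host substitution rate per site per year; no default rate is
assumed -- it is an explicit argument, as rates differ across lineages.
Families larger than 500 members are subsampled (seeded) for the consensus
step only; all members are still dated. `amplification_histogram()` bins
ages from zero in fixed windows.

The center-star construction (rather than an external multiple aligner) is
deterministic, dependency-free and adequate for substitution-dominated
MITE families; an externally computed alignment can be supplied to
`consensus_sequence()` directly. All copies are dated, not only
full-length ones; the scan's `full_length` flag lets users restrict.

# Orthologous loci

For each reference element, `build_ortho_query()` concatenates 1 kb of
flank on each side (truncated at contig ends). `search_homologs()` finds
local alignments in a target genome under a +2/-3 scheme, with E-values
from the Karlin-Altschul formula `E = K m n exp(-lambda S)` using the
classical ungapped nucleotide parameters `lambda = 0.625`, `K = 0.41`
(fixed so filtering is bit-reproducible); hits must reach `E < 1e-9` and
identity > 0.8, and hits within 1 kb of each other on the target merge
into one locus region. Iterative masking inside each window recovers
discontiguous blocks, e.g. the two flank images of an empty site.

`classify_species_status()` calls a species **shared** when one region
covers >= 95% of the query including >= 80% of the element span, and an
**empty site** (`specific_absent`) when both flanks are covered >= 80%
with the element span < 20% covered and the target-side gap between the
flank images is < 1 kb; anything else is **unresolved**. The 95/80/20
constants operationalise "entirely aligned" and "element absent", which
have no published numeric values; they live in the function signature.
A locus is `shared` when every non-reference species is shared,
`species_specific` when every one shows the empty site, else `ambiguous`.
Unresolved species states keep a locus out of both headline counts.
Because each locus is classified once from its carrier species, loci
already called shared never re-enter specific-locus calling.

`polymorphism_matrix()` builds the binary species-by-locus matrix; given
an ultrametric tree it assigns each shared locus to the most recent common
ancestor of its carriers and reports per-node counts and counts per My of
the node's stem branch -- the stem-branch normalisation is this package's
interpretation of per-node insertion frequency.

# Gene context

`assign_regions()` places each hit by its midpoint with precedence exon >
intron > flank > intergenic; flanks extend 5 kb each side in 500 bp bins,
strand-aware (upstream means 5' on the gene's own strand); a midpoint near
two genes goes to the nearer boundary, ties preferring the upstream
relationship. The midpoint rule (rather than any-overlap) avoids double
counting hits that straddle a boundary. "Promoter" for gene grouping
means upstream bins 0--3 (0--2 kb). `binned_density()` optionally
normalises counts by total hits and bin width in kb.

# MITE-derived miRNAs

`link_mirnas()` aligns each precursor (U normalised to T) locally against
each MITE under the +2/-3 scheme; a link requires `E < 1e-5`, identity
> 0.8 (strict), and aligned span >= 50% of the precursor length
(inclusive -- "at least half"). `fold_energy()` scores hairpin potential
with a deterministic maximum-weight nested-pairing dynamic programme
(weights GC = -3, AU = -2, GU = -1, minimum loop 3); NMFE is the optimum
divided by length. This is a documented proxy for thermodynamic folding
-- full nearest-neighbour thermodynamics is out of scope -- and an
external folder can be plugged in via the `folder` argument; all NMFE
comparisons are internally consistent under the proxy. One caveat the
test suite makes explicit: with a wobble weight present, the energy is
exactly invariant under sequence reversal but only
approximately under reverse complement (a G:U pair maps to A:C).
`compare_nmfe()` reports medians and a tie-corrected Mann-Whitney U with
a normal-approximation p-value; below 3 observations per group only
medians are returned.

# Benchmarking

`confusion_counts()` merges each interval set per contig and classifies
every base (TP/FP/FN/TN); `benchmark_metrics()` derives sensitivity,
specificity, accuracy, precision, false positive rate and F1, reporting
0/0 ratios as `NaN`, never as 0. The false-positive rate is kept as an
independent quantity `fp/(fp+tn)` alongside specificity.
`element_level_metrics()` provides the secondary element-level view
(>= 80% reciprocal overlap = match).

# The synthetic generator and what passing tests mean

`generate_genome()` plants families with perfect-TIR masters,
superfamily-consistent TSDs (written on both flanks, then mutated together
with the element so old copies carry degenerate TSDs), and per-copy K80
divergence drawn from the age model. Defaults are the package's standard
benchmark conditions: 1 Mb over five contigs at 42% GC, ten families of
twenty copies, divergences uniform in [0, 0.05] (a recent burst -- about
the last 1.9 My at r = 1.3e-8/site/year), and a superfamily mix weighted
toward Mutator (0.35) with Tc1/Mariner 0.20, PIF/Harbinger 0.15, hAT 0.12,
CACTA 0.10, Micron 0.08, echoing the rank order reported for plant
genomes. Background is i.i.d. -- no isochore structure, no indels, no
nested or tandem confounders by default -- so passing tests demonstrate
correctness of the algorithms under the substitution-only K80 model, not
robustness to assembly artefacts or indel-rich histories. A single seed
drives phase-offset RNG streams, so outputs are bit-reproducible and
adding a simulation phase does not shuffle earlier draws.

`generate_ortholog_scenario()` derives species genomes from one ancestral
sequence; a deterministic `round(shared_fraction * n_loci)` of the loci
are ancestral (present in all species), the rest are inserted in exactly
one carrier, leaving contiguous empty sites elsewhere. Each species is
mutated at half of `1 - flank_conservation` so that two species differ by
about the advertised flank divergence. `generate_mirna_set()` emits
precursors that copy >= 60% of their length from a planted element (at 5%
divergence) plus random stem-loop background precursors.

# Problem sizes and numerical choices

The shipped tests exercise: the full pipeline on the standard 1 Mb / 200
copy genome; oracle equivalence on <= 2 kb contigs (detection, against an
all-substring enumerator), <= 10 kb genomes (scan, against iterative
Smith-Waterman with masking), <= 16 nt sequences (folding, against
exhaustive nested-pairing enumeration) and 10 kb bitmaps (confusion
counts); age recovery with 100-copy families at 1, 5 and 20 My; and a
3-species, 20-locus ortholog scenario at 95% flank conservation. These
sizes were chosen so the whole suite runs comfortably on a laptop while
each property is still measured with meaningful statistics.

Numerical conventions worth knowing: internal coordinates are 0-based
half-open everywhere, converting to 1-based inclusive only inside GFF3
text; N is the only ambiguity symbol and never matches anything in
detection; alignment identities count end gaps; K80 saturation yields
`valid = FALSE` rather than a clamped value; and every stochastic
procedure takes an explicit integer seed.

# Known limitations

* Boundary calls for a single copy with a self-complementary TSD are
  ambiguous at the percent level; family refinement fixes members of
  families, but singletons keep the selection-score boundary.
* The scanner's k-mer seeding (11-mers) can miss copies diverged far
  beyond 15% -- irrelevant under the retained-divergence ceiling but a
  caveat if `max_divergence` is raised substantially.
* The folding proxy ranks hairpin stability; its absolute values are not
  thermodynamic free energies.
* Center-star alignment degrades for indel-rich families; the dating
  model assumes substitutions only, consistent with the K80 estimator.
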