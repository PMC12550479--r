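# mitekit

Annotation, dating and comparative analysis of **miniature inverted-repeat
transposable elements** (MITEs) in plant genomes.

MITEs are short (50–800 bp) non-autonomous DNA transposons bounded by
terminal inverted repeats (TIRs) and flanked by a 2–10 bp target site
duplication (TSD). `mitekit` implements the full annotation workflow
around this structure:

* **Detection** — de novo discovery of TIR-bounded, TSD-flanked candidates
  by seeded reverse-complement word matching with signature-aware boundary
  selection.
* **Families** — greedy centroid clustering at 80% global identity
  (end gaps counted), a three-copy minimum, a 50 bp flank-distinctness
  filter that collapses re-detected insertions, family-level boundary
  refinement, and curated seed selection.
* **Classification** — superfamily assignment from TSD/TIR diagnostics
  (Tc1/Mariner, PIF/Harbinger, Mutator, hAT, CACTA, plus the
  microsatellite-context Micron group) via an editable YAML rule table.
* **Genome scan** — recovery of all family copies from the seed library
  (k-mer seeded local alignment, Kimura divergence ≤ 15%), plus the four
  landscape indices (genome proportion, density/Mb, mean length, family
  count).
* **Insertion dating** — per-family consensus, Kimura two-parameter
  distance of every copy to the consensus,
  `K = -1/2 · ln((1-2P-Q)·√(1-2Q))`, and insertion age `T = K/(2r)` for a
  host substitution rate `r`, with amplification histograms.
* **Orthologous loci** — shared vs species-specific classification of
  insertion sites across related genomes from 1 kb flank homology
  (E < 1e-9, identity > 80%, 1 kb region merging), with presence/absence
  matrices and tree-node assignment.
* **Gene context** — exon/intron/flank assignment with strand-aware 500 bp
  bins over 5 kb flanks.
* **miRNA linkage** — MITE-derived miRNA calls (≥ 50% precursor coverage,
  > 80% identity, E < 1e-5) and a deterministic nested-pairing hairpin
  energy (NMFE) with a Mann–Whitney comparison.
* **Benchmarking** — nucleotide-level sensitivity, specificity, accuracy,
  precision, false positive rate and F1 against a reference annotation.
* **Synthetic data** — a seeded generator that plants MITE families with
  known coordinates, ages, superfamilies, orthology and miRNA provenance,
  so every stage is testable against ground truth.

See the methods vignette (`vignettes/mite-annotation-methods.Rmd`) for the
models, parameter defaults and design decisions.

## Worked example

```r
library(mitekit)

# a 1 Mb genome with 10 planted families x 20 copies, divergence <= 5%
spec <- simulation_spec(seed = 42L)
sim  <- generate_genome(spec)

res <- annotate_mites(sim$genome)     # detect -> families -> classify -> scan
length(res$families)
#> [1] 11
nrow(res$hits)
#> [1] 200

m <- benchmark_metrics(confusion_counts(nchar(sim$genome), res$hits,
                                        sim$truth))
round(m, 4)
#>   sensitivity specificity accuracy precision false_positive_rate     f1
#> 1      0.9996           1        1         1                   0 0.9998

res$landscape
#>   proportion_of_genome density_per_mb mean_length family_count
#> 1             4.007509       191.5452      209.22           10
```

The benchmark row reads: 99.9% of planted MITE bases were recovered by the
pipeline with no false-positive bases; the annotation masks 4.0% of the
genome at 191.5 copies/Mb with a mean copy length of 209 bp.

Dating a family and estimating ages:

```r
div <- family_divergences(res$families)
est <- insertion_times(div, rate = 1.3e-8)   # substitutions/site/year
amplification_histogram(est, bin_width = 1e6)  # counts per My bin
```

A command-line interface wraps the same functions
(`exec/mitekit`; run without arguments for usage):

```sh
Rscript exec/mitekit simulate --out-prefix sim --seed 42
Rscript exec/mitekit detect   --genome sim.fa --out cand.tsv
Rscript exec/mitekit families --candidates cand.tsv --genome sim.fa --out-prefix fam
Rscript exec/mitekit scan     --genome sim.fa --seeds fam.seeds.fa --out hits.gff3
Rscript exec/mitekit bench    --genome sim.fa --pred hits.gff3 --truth truth.gff3 --out metrics.tsv
```

All seeded commands are byte-deterministic across runs.

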