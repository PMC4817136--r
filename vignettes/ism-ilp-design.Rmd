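---
title: "Designing intron-spanning and intron-length polymorphism markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing intron-spanning and intron-length polymorphism markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ismilp)
```

## The marker system

Introns evolve under weaker purifying selection than the exons around them,
so between two accessions of the same species an intron frequently differs in
length while the flanking exons are conserved. An **intron-spanning marker
(ISM)** exploits this: a PCR primer pair is anchored in the exonic sequence on
either side of an intron, so the genomic amplicon contains the intron while a
cDNA amplicon does not. When the target intron carries one or more
insertions/deletions (InDels) between a reference and a query genome, the two
genomic amplicons differ in length and the ISM becomes an **intron-length
polymorphism (ILP) marker** — a co-dominant, multi-allelic marker scorable on
a plain agarose gel.

The package implements the complete design path:

1. **Gene models and introns** (`read_fasta()`, `parse_gene_models()`,
   `extract_introns()`) — assemble one transcript per locus from a GFF3
   annotation and cut out every intron together with its exonic flank
   windows (up to 100 bp each side, the region available for primers).
2. **Primer design** (`design_ism_primers()`, `design_expression_primers()`,
   `design_genome_ism()`) — enumerate and score primer candidates inside the
   flanks.
3. **Homology search and InDel calling** (`build_query_index()`,
   `map_intron_to_query()`, `align_and_call_indels()`) — locate each
   reference intron in the query genome and call normalized InDels.
4. **In-silico PCR** (`find_binding_sites()`, `predict_amplicons()`,
   `primer_uniqueness()`) — the independent referee for amplicon lengths and
   primer specificity.
5. **ILP conversion** (`convert_to_ilp()`, `design_ilp()`,
   `run_marker_pipeline()`) — join the above into markers with predicted
   fragment-length polymorphism.
6. **Marker analytics** (`marker_census()`, `flp_distribution()`,
   `validation_summary()`, `map_saturation()`, `allele_stats()`,
   `nei_li_distance()`, `nj_tree()`, `segregation_chi2()`,
   `relative_expression()`).
7. **Simulation** (`simulate_genome_pair()`, `simulate_genotypes()`) — genome
   pairs with machine-readable planted truth, so that every stage is testable
   without rice-genome-scale inputs.

## Coordinates and gene models

Internally every interval is 0-based half-open, which keeps length and
concatenation arithmetic free of off-by-one corrections; all emitted tables
are 1-based inclusive, the GFF3 and community convention. When a gene has
several annotated transcripts the one with the longest total CDS is used
(falling back to the longest exon sum, then the first transcript ID).
Genome-wide design works at the locus level, so alternative splice forms are
collapsed; this is a deliberate simplification — a marker is addressed to a
gene, not an isoform. Genes are classed as transposable-element-associated
when their `Note`/`Name` attributes mention "transposon" or
"retrotransposon"; annotations differ in how they record this, so the rule is
a case-insensitive substring match, and everything downstream treats the
class as a label only.

Intron sequences and flanks are always reported 5'→3' on the coding strand,
with intron ordinals in transcription order, so minus-strand genes need no
special handling downstream. Introns or flanks containing `N` are kept but
flagged; primer design refuses windows containing `N`.

## Primer design model

Candidates are enumerated exhaustively inside each flank (every start
position × every length 18–27 bp) and pass hard filters: melting temperature
57–63 °C, GC 40–60 %, homopolymer runs ≤ 4, no perfect inverted repeat of
≥ 8 bp within the primer (a cheap hairpin/self-dimer proxy), and a genomic
product window (default 100–1000 bp, bracketing the few-hundred-bp products
this marker class typically yields).

Melting temperatures come from SantaLucia's unified nearest-neighbor
thermodynamics with the entropic salt correction
`ΔS' = ΔS + 0.368 (N−1) ln[Na+]` and
`Tm = 1000·ΔH / (ΔS' + R ln(C_T/4)) − 273.15`,
at 50 mM salt and 0.25 µM primer by default. The parameter table is a fixed,
documented constant so tests can recompute any value by hand. The Wallace
rule (`tm_wallace()`) is included only as a sanity-check formula.

Surviving candidates are ranked by a transparent additive penalty — weighted
deviations from the Tm optimum, length optimum, GC window, 3'-terminal
homopolymer length, plus the Tm difference between mates. The penalty is not
a reproduction of any particular design engine's objective; it is monotone in
each deviation (a property the tests assert) and exists to give a stable,
explainable ranking. Ranking ties are broken by position, so identical inputs
give byte-identical outputs; the design stage uses no randomness at all.

For expression assays (`design_expression_primers()`) the spliced-cDNA
product — the exonic part of the genomic amplicon — must additionally fall in
60–100 bp, giving compact qPCR products while the genomic product still spans
the intron, so genomic contamination is visibly larger on a gel.

Per gene, at most *k* markers are kept (default 4, preferring distinct
introns, then penalty); `per_gene = Inf` keeps one marker per designable
intron, the right setting when the goal is complete InDel screening rather
than a catalogue. Marker identifiers (`OsISM#####`, `OsILP#####`) are
assigned in chromosome-then-position order.

Each selected pair must amplify exactly one product from the whole reference
genome (`primer_uniqueness()`, binding model below); non-unique pairs are
dropped and logged.

## Homology search, alignment and InDel calling

Each reference intron is located in the query genome by seed-and-extend:
exact 13-mer seeds against both orientations, clustering of seed hits by
diagonal, then a **semiglobal** affine-gap alignment (all of the intron
against a local window of the query, free end-gaps on the query side only).
The semiglobal form matters: a pure local alignment legitimately trims a gap
near the end of the intron whenever the remaining anchor is worth less than
the gap costs, which silently truncates the homolog; anchoring the whole
intron keeps near-terminal InDels inside the aligned span.

Scoring is match +1, mismatch −2, and affine gaps costing `open + extend·L`
(defaults 5 and 2). Raw scores are converted to bit scores with the
Karlin–Altschul transform `bit = (λS − ln K)/ln 2` at λ = 1.28, K = 0.46 (the
ungapped parameters for +1/−2 scoring), and E-values as `m·n·2^−bit` with the
search space taken as intron length × total query length, without edge
corrections. A reported "E-value of 0" is always an underflow artifact, so
the gate is expressed as a small positive cutoff (default 1e−50, with bit
≥ 500) — these defaults are calibrated to rice-genome-scale search spaces.
**E-value and bit-score thresholds are search-space statements, not
universal constants**: on a desk-scale simulated genome (a few hundred kb) a
bit-500 gate would categorically reject every intron shorter than ~270 bp
regardless of how perfect its match is, so the validation experiments in the
tests and the acceptance script run with `min_bit = 50`,
`max_evalue = 1e-6`, scaled to that search space.

If the runner-up candidate locus reaches 95 % of the best bit score the match
is flagged ambiguous and excluded from ILP conversion; ties are broken toward
the lowest (sequence, start).

InDels are called from a global affine-gap alignment of the intron against
its extracted homolog. Maximal gap runs become single calls, and every call
is **left-normalized** — shifted to the smallest reference position that
preserves the alignment score, the same convention variant callers use — so
positions are reproducible across runs and implementations. Two caveats
follow from alignment theory and are asserted rather than fought in the
tests: insertions of random sequence can admit equal-scoring alternative
placements (the calls are optimal-alignment-consistent, and always conserve
the signed length difference), and two gaps separated by a 1-base anchor are
correctly preferred as one merged gap plus a substitution.

## In-silico PCR and fragment-length polymorphism

A primer binds where it matches within 2 mismatches and its 3'-terminal
trinucleotide matches exactly — a crude but standard proxy for polymerase
extension requirements. Products are all convergent site pairs within 3000 bp
(default). Specificity is judged at the **amplicon** level: two stray binding
sites that cannot form a product do not threaten the assay.

An ISM converts to an ILP marker when its intron carries ≥ 1 InDel, the
homology match is unambiguous, and the same primer pair amplifies exactly one
product from each genome. Two polymorphism sizes are reported:

* `flp_net` — |reference amplicon − query amplicon|, what a gel actually
  resolves; this is the primary statistic.
* `flp_gross` — the summed absolute InDel lengths, which can exceed the net
  when InDels partially cancel.

Markers whose InDels cancel exactly (`flp_net = 0`, `flp_gross > 0`) are not
gel-detectable ILP markers and are emitted to a side table. Markers with
`flp_net ≥ 10` bp are assigned the `gel` assay tier (resolvable on 2.5 %
agarose); smaller polymorphisms are tier `sequencing`.

The central consistency theorem of the pipeline — design arithmetic, InDel
calls and in-silico PCR must tell one story — is enforced by tests: for every
marker the PCR-predicted genomic amplicon equals the design's arithmetic, and
the signed sum of a marker's InDel calls equals its net amplicon difference.

## Marker summaries and genotype analytics

`marker_census()`, `flp_distribution()`, `validation_summary()` and
`map_saturation()` compute the descriptive tables of a marker study
(markers/gene, markers/Mb, FLP size spectrum, amplification and polymorphism
percentages, linkage-map saturation). Ratios are kept at full precision and
rounded only for printing. Mean inter-marker distance is computed as map
length divided by marker count — the convention that reproduces published
per-chromosome saturation tables — not length/(markers−1).

Genotype analytics follow the standard formulations: Botstein's polymorphism
information content `PIC = 1 − Σp²ᵢ − Σᵢ<ⱼ 2p²ᵢp²ⱼ` with frequency
renormalization over observed calls; Nei–Li band-sharing similarity
`S = 2·n_shared/(n_x + n_y)` with each observed allele of each marker treated
as one gel band (heterozygotes contribute both bands) and pairwise deletion
of missing data; neighbor joining via `ape::nj()` with bootstrap support
computed by resampling **markers** with replacement (the sampling unit that
matches how marker panels are collected), seeded and recorded in the tree's
attributes; a Pearson χ² goodness-of-fit screen without continuity
correction for segregation ratios; and the comparative-Ct `2^−ΔΔCt` fold
change with the calibrator pinned at 1.

## The simulator: what it emulates and what it does not

`simulate_genome_pair()` builds a reference genome of non-overlapping gene
models (2–8 exons of 80–400 bp, introns of 60–2000 bp, both strands, random
intergenic spacers of 200–1000 bp) and derives a query genome by planting
substitutions (default 0.005/bp) and InDels (default Poisson 0.4/intron)
inside introns. InDel lengths follow a truncated geometric distribution
(p = 0.21, support 1–101 bp), i.e. dominated by 1–4 bp events with a mean
near 4.8 bp — the small-InDel-dominated regime reported for intron
comparisons between rice accessions. Exons are exactly conserved by default,
isolating intronic signal. The default experiment size — 50 genes, about 200
introns, a few hundred kb of genome — was chosen as the smallest scale at
which every pipeline stage (multi-chromosome, both strands, multi-intron
genes, the uniqueness screen) is exercised meaningfully.

Two structural choices guarantee that planted truth is *identifiable*:
spacers of random sequence keep primer sites unique (a configurable
`duplication_rate` plants verbatim gene copies to exercise the uniqueness
filter in the opposite direction), and every planted InDel keeps an anchor of
at least its own length + 10 bp to either intron end. The latter is not
cosmetic: an InDel of length L closer than roughly the affine gap cost to a
sequence end is *not* the optimal-alignment explanation of the resulting
sequences (mismatching the short anchor scores better than opening the gap),
so truth planted there would be unrecoverable by any optimal aligner — the
margin makes "100 % recovery" a well-posed claim.

`simulate_genotypes()` produces group-structured panels: per marker, 2–4
alleles with Dirichlet ancestral frequencies; with probability
`between_divergence` a group swaps in near-fixed private frequencies (one
allele at 0.95), emulating lineage-differentiating markers, and each
accession jitters its group frequencies by `within_divergence`. The default
panel mirrors a 26-accession study layout (9 indica, 2 japonica, 10 + 3
aromatics, 2 wild).

What the simulator does **not** emulate: real base composition and repeat
content, transposon families, paralogy and segmental duplication beyond
exact copies, splice-isoform complexity, linkage between markers, and any
realistic demography behind the genotype panels. Consequently, passing the
planted-recovery tests demonstrates the pipeline's internal correctness and
consistency — not that real rice genomes would yield any particular marker
count, which depends on genome content the simulator deliberately does not
model.

## Numerical and design choices

* Degenerate inputs return empty results with logged reasons (flank too
  short, no candidate primer, no product in window, ambiguous homology,
  non-unique query binding) rather than errors, so genome-wide runs never
  abort on an awkward locus.
* All randomness flows from explicit seeds; the design stage is entirely
  deterministic, and two runs with equal seeds produce byte-identical output
  tables (asserted by tests).
* Alignment is implemented once in C++ (Gotoh three-state DP with full
  traceback) and exposed in global, local and semiglobal forms; its
  optimality is tested against an independent exhaustive-enumeration oracle
  on short sequences.
* The published summary tables shipped in `inst/extdata/` (marker counts and
  the IR 64 × Sonasal linkage map) are inputs for re-deriving printed
  ratios; one of them (the 1–4 bp FLP share, 12260/16510) is 74.258 % at
  full precision while the source prints 74.2 — the package reports full
  precision and leaves rounding to presentation.

## Known limitations

* The primer penalty is a transparent stand-in, not a thermodynamically
  complete objective: no cross-dimer ΔG, no template secondary structure.
* Homology mapping assumes the homolog is colocated within one seed-cluster
  window (±120 bp); rearrangements that split an intron across loci are
  reported as no-match rather than reconstructed.
* The Karlin–Altschul parameters are fixed for the default +1/−2 scoring;
  changing the scoring matrix without re-deriving λ and K makes bit scores
  nominal.
* Uniqueness screening is exact-arithmetic on the given assembly; it cannot
  see sites absent from the assembly.
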