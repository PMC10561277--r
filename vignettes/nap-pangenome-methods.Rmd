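---
title: "Methods: pangenome profiling of nucleoid-associated proteins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pangenome profiling of nucleoid-associated proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nappan)
```

## The problem

Nucleoid-associated proteins (NAPs — HU, IHF, Fis, H-NS, SMC and their
relatives) shape bacterial chromosome topology and, increasingly
recognized, the biology of mobile genetic elements (MGEs). `nappan`
implements a comparative-genomics pipeline that censuses NAP families
across a set of genomes, partitions the resulting protein families into
core and flexible pangenome compartments, profiles their physicochemical
and positional properties, associates flexible NAPs with plasmids and
integrated elements, and evaluates core NAPs as single-marker phylogenetic
markers. It ships a transcription of a published 93-genome census of the
*Acidithiobacillia* class (16 species-level lineages, 12 NAP families,
1,197 proteins) as fixtures, and a synthetic-pangenome generator so that
every stage is testable without downloading genomes.

## Hit validation and the census

Domain searches (PSI-BLAST/CD-search/hhsearch style) are consumed as hit
tables, not run. A protein is accepted as a NAP candidate when it has at
least one hit with e-value strictly below `1e-5`, a reported probability
strictly above 90 (absent probabilities pass), and — a deliberately
conservative reading — a reported coverage of at least 0.75 (absent
coverages pass). Among passing hits, the family is the profile with the
minimum e-value; ties break by higher probability, then lexicographic
profile id, so validation is order-independent and idempotent. One family
per protein: overlapping assignments resolve to the best hit.

The census counts candidates per lineage × family. Dose ranges are
computed over **carrier genomes only**: a lineage where two of nine
genomes carry HU at 2 and 4 copies reports dose (2, 4), not (0, 4). The
published table's "(range per genome)" does not state this convention;
the carrier reading is the one consistent with its "0 (0)" cells.

### Reconstructing presence from a printed census

The packaged census records totals and dose ranges, not per-genome
presence. Where presence is needed (the core-set rule), it is
reconstructed by the *maximum-spread* rule:
`carriers = min(n_genomes, floor(total / dose_min))` — the reconstruction
that spreads copies across as many genomes as the printed dose range
allows. It is deterministic, consistent with every census cell, and
reproduces the published six-family core under the occupancy rule below.

## Pangenome indices and compartments

* **Frequency index** — carriers / genomes, per lineage × family.
* **Paralogue index** — mean dose over carrier genomes divided by the
  number of distinct protein families (PFs) the family forms in that
  lineage. Averaging is conditional on carrying; the denominator is
  per-family-per-lineage (the published definition leaves this open; the
  choice is flagged here).
* **Core** — families whose class-wide occupancy strictly exceeds 90% of
  all genomes ("more than 90%").
* **Conserved vs non-conserved flexible** — within a lineage, frequency
  index ≥ 0.90 counts as conserved. The source material uses both "> 0.90"
  and "≥ 0.90" in different places; `classify_compartments()` defaults to
  `>=` and exposes the comparator. Lineages represented by a single genome
  default to non-conserved (a frequency of 1/1 is uninformative); a flag
  restores case-by-case treatment.

## Orthology clustering

Two complementary clusterings are provided, mirroring the two-tool
layering of the original workflow; the pipeline caller chooses the order,
since the original does not fully specify which feeds which.

* **Greedy identity clustering** (50% default): sequences sorted by
  length descending (ties lexicographic), each joining the first centroid
  reached at or above the threshold. Identity is computed from a global
  Needleman–Wunsch alignment (BLOSUM62; a gap of length L costs 10 + L)
  as matches over **all** alignment columns, gap columns included — the
  stricter denominator, stated so the 50% threshold is interpretable.
* **BBH triangles**: pairwise hits filtered at 75% coverage and e-value
  1e-5; bidirectional best hits (max score, ties by min e-value then
  lexicographic subject) between genome pairs; triangles of BBH edges
  spanning three genomes seed PFs, and triangles sharing an edge merge.
  Clusters sharing only a vertex are merged as well, so the output is a
  partition — every protein belongs to exactly one PF. Within-genome
  paralogs enter PFs only via the identity route; BBH is cross-genome by
  construction.

## Physicochemistry

Molecular weight is the sum of average residue masses plus one water
(18.0153 Da). The theoretical pI solves net charge = 0 by bisection on
pH ∈ [0, 14] to |charge| < 1e-4; the charge is a Henderson–Hasselbalch sum
over side chains and both termini with the pKa set N-term 8.6, C-term
3.6, K 10.8, R 12.5, H 6.5, D 3.9, E 4.1, C 8.5, Y 10.1 (the constants of
the classic EMBOSS-style calculator, fixed here so values are
reproducible). The charge is strictly decreasing in pH, so the root is
unique. `pi_ph_correlation()` relates lineage-median family pI to optimal
growth pH, with an optional acidophile cut-point; the published
acidophile/moderate/mild partitions (pH < 3.0 / 4.5 / 6.0) are treated as
configurable cut-points, not constants.

## Gene vicinities and positions

Vicinities are all CDS within 5 kb of a gene's boundaries (partial
overlap counts; strand is ignored, as no strand convention is stated for
the analysis; circular replicons wrap). The KEGG vicinity frequency index
is, per family × annotation, the percentage of the family's genes with at
least one neighbor bearing the annotation — counted once per NAP gene
even when several neighbors repeat it. The denominator is the family's
genes with resolvable vicinities (configurable to "genes with ≥ 1
annotated neighbor"; the published table does not say which it used).
Origin-relative positions are `((midpoint − ori) mod length) / length`
with four equal quadrants from the origin.

## MGE association

A NAP maps to an element when its gene **midpoint** falls inside the
element's span (or its replicon is a plasmid) — robust to
boundary-straddling annotations, configurable to full containment.
Nested or overlapping regions resolve to the innermost, so no gene maps
twice. Classification is rule-based over hallmark roles: whole-replicon →
plasmid; T4SS + integrase → ICE; relaxase + integrase without T4SS → IME;
otherwise island. Hallmark roles come from the input annotation table; a
keyword mapper (virB/trb/tra → t4ss, mob/relaxase → relaxase,
xerD/integrase → integrase, …) ships for convenience.

### Inverted repeats

`find_inverted_repeats()` is an exhaustive seed-and-extend scan over all
(inner-pair, loop) seeds: arms of equal length separated by a loop of at
most `max_loop` bases, the right arm the reverse complement of the left
up to `max_mismatch` pairs, with N never matching. Only **maximal**
repeats are reported: extending one pair inward or outward must run off
the sequence, close the loop, or exceed the mismatch budget. A repeat may
therefore end on a mismatched pair when the budget allows it and no
further extension is possible; with a zero budget the familiar
perfect-palindrome behaviour results. The packaged oriT-like fixture is a
**synthetic** sequence (the published figure gives only the architecture:
two IRs with 8- and 10-nt stems and 4-nt loops upstream of a relaxase
gene); it was constructed once from a seeded random background and
verified by brute force to contain exactly the two planted repeats at
min_stem 6, max_loop 10, zero mismatches.

## Expression (RPGC)

Depth tracks (bedGraph; 0-based half-open on disk, converted on read) are
binned at 10 bp as the **mean per-base depth** per bin — depth tracks are
the input, not read alignments, and the constant read length cancels in
the normalization, which keeps aligners out of scope. "Extension of
paired reads" is meaningless for depth-track input and is not applicable
here. RPGC divides bins by total signal / effective genome size, so the
normalized track averages 1.0 over the effective genome; the effective
genome size defaults to the replicon length and accepts the published
constant (3,415,726) when supplied. Normalization is idempotent and
invariant under rescaling of the raw depths. `locus_expression()` reports
per-gene mean RPGC and flags genes below the 1.0 genome average.

## Phylogenetics

Distances are dissimilarities (100 − % identity) with pairwise deletion —
the quantity the source analysis plots — rather than model-corrected
distances. Trees are canonical neighbor joining (via ape), negative
branch lengths clamped to zero; additive metrics are recovered exactly.
Topologies compare by unrooted Robinson–Foulds counts. The original mixes
FastTree ML and NJ/BioNJ across figures; this package standardizes on NJ.

## The synthetic-data generator

`generate_pangenome()` emits one circular chromosome per genome with
planted NAP genes, MGE regions, hallmark genes, passing domain hits, and
decoys, plus a truth table. What it emulates, and how:

* **Presence/dose** — each lineage × family is carried with the spec's
  presence fraction, at a chromosomal dose uniform over the dose range
  (the published census reports only ranges; uniform-on-range is this
  package's choice).
* **MGE load** — region count is Poisson with mean proportional to
  **absolute** genome size (rate expressed per dataset-mean genome);
  lengths are log-uniform on 10–300 kb, matching the size range of the
  published elements. Every region carries relaxase and integrase genes,
  plus a T4SS half the time, yielding an ICE/IME mixture.
* **MGE-borne NAPs** — carrier genomes of flexible families gain one
  *additional* copy per region with probability
  `flexible_in_mge_fraction`, placed inside the element, with a ParA gene
  planted in the 5-kb vicinity at a configurable rate. Making MGE copies
  additive (rather than relocating chromosomal copies) is what plants the
  two covariances the analysis is meant to detect — NAP count with genome
  size, and HU/IHF counts with relaxase counts — while leaving presence
  fractions, hence frequency-index recovery, untouched.
* **Decoys** — 10% of genes receive a non-NAP hit with e-value
  log-uniform on [1e-4, 1], above the validation cutoff, exercising the
  filter.
* **Markers** — `generate_marker_sequences()` evolves sites independently
  along a tree: replacement probability 1 − exp(−rate · branch),
  replacement uniform over the other 19 residues. The simplest model with
  an analytic p-distance expectation, which the tests check exactly.
* **Coverage** — per-base Poisson around mean_depth × multiplier.

What it does **not** emulate: realistic nucleotide/amino-acid
composition, codon structure, indels, assembly fragmentation, annotation
error, or read-level noise. Passing tests therefore demonstrate that the
statistics and rules are implemented correctly and are recoverable under
their own assumptions — not that the pipeline is robust to the noise of
real draft genomes.

### Study conditions used by the checks

Problem sizes were chosen as the package's own desk-scale conditions:
frequency-index recovery uses one 500-genome lineage (3-SD binomial
bands); covariance sign recovery uses 100 replicates of a 4-lineage ×
25-genome pangenome whose lineage mean sizes span 2.2–4.2 (×10⁵ bp at
test scale), mirroring the cross-species structure in which
larger-genome species carry more HU/IHF variants; marker recovery uses a
synthetic 16-leaf reference tree over the fixture's lineage tags
(internal branches ≥ 0.012 substitutions/site, maximum pairwise
divergence ≈ 0.12) with 100 seeded replicates at marker lengths 1,000
(SMC-like) and 80 (Fis-like). Long markers recover the reference topology
essentially always; short markers rarely — the long marker's greater
resolving power is exactly the published contrast.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere internally; bedGraph
  converts on read/write.
* Ties are broken deterministically everywhere (validation: probability
  then profile id; best hits: e-value then subject id; greedy clustering:
  length then id), so all outputs are reproducible across platforms.
* Bisection for pI runs to |charge| < 1e-4 with a 200-iteration cap.
* Empty inputs: empty hit tables validate to empty candidate sets; empty
  candidate lists census to all-zero tables; zero-signal tracks refuse to
  normalize; single-genome lineages are legal but uninformative for
  conservation calls.
* `sessionInfo()`-level randomness is centralized: every generator takes
  one integer seed, and identical seeds give byte-identical output.

## Known limitations

Real-data medians (e.g. the published Fis median pI) require the actual
proteomes and are out of scope; the census fixtures carry totals and
ranges, not per-genome presence, so core-set recovery depends on the
maximum-spread reconstruction; the NJ surrogate will not reproduce
ML-specific topology differences; and the MGE classifier is a rule
engine over given annotations, not a de novo element finder.
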