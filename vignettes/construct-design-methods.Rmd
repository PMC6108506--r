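---
title: "Designing tRNA-promoter-driven CRISPR/Cas9 constructs: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing tRNA-promoter-driven CRISPR/Cas9 constructs: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnacrispr)
```

## The design problem

Delivering a functional guide RNA (gRNA) is the practical bottleneck for
CRISPR/Cas9 mutagenesis in *Aspergillus niger*. RNA polymerase III transcribes
tRNA genes constitutively, and a tRNA gene carries its own internal promoter
elements; prepending the transcript to a gRNA and letting the cell's tRNA
processing machinery release the mature guide turns every tRNA gene into a
candidate gRNA promoter. A usable promoter part is defined here as the entire
tRNA gene (introns included) plus 100 bp of upstream sequence, so that the
upstream binding sites of the Pol III transcription factors come along with
the internal ones. The matching terminator part runs from the first base after
the gene through the first downstream run of consecutive thymidines, the
poly-T signal at which Pol III terminates.

`trnacrispr` implements the computational side of this strategy end to end:

1. **Catalog curation** (`merge_predictions()`, `filter_models()`) — merge
   tRNA gene models from several prediction tools into consensus models and
   remove implausible ones.
2. **Part extraction** (`extract_promoter()`, `extract_terminator()`) — cut
   promoter and terminator parts out of the genome.
3. **Guide design** (`enumerate_guides()`, `scan_offtargets()`,
   `rank_guides()`) — find 20-nt protospacers next to NGG PAMs in a target
   gene and screen the genome for near-matches.
4. **Cassette assembly** (`build_cassette()`, `add_lic_tails()`,
   `simulate_chewback()`, `design_donor()`) — plan the physical construction:
   fusion-PCR fragments, primers, ligation-independent cloning (LIC), donor
   templates for gene replacement.
5. **Mutation classification** (`cut_frame()`, `call_edit()`,
   `format_notation()`, `trace_insertion_origin()`) — read mutant amplicons
   back against the reference in cut-site-relative coordinates.
6. **Fixtures** (`fixture_spec()`, `make_genome()`, `make_preset_mutant()`) —
   generate synthetic genomes and mutants with exact ground truth.

## Coordinate conventions

All internal coordinates are 0-based and half-open on the forward strand;
report output (TSV catalogs, FASTA headers, the CLI) converts to 1-based
inclusive. This removes the off-by-one ambiguity that plagues mixed-dialect
pipelines: tRNAscan-SE tabular input (1-based inclusive, minus strand encoded
as begin > end, genomic intron bounds) and GFF3 are both normalized at read
time, and intron bounds are stored gene-relative, measured from the gene's 5'
end on its coding strand.

### The cut frame

Cas9 cuts bluntly 3 bp 5' of the PAM, between the 17th and 18th protospacer
base. Mutation coordinates are reported relative to that scissile position
with **no position 0**: −1 is the base immediately 5' of the cut and +1 the
base immediately 3', read along the protospacer strand. A deletion of the
three bases immediately 5' of the cut is `(-3 - -1)`; immediately 3',
`(+1 - +3)`. Span lengths are therefore counted over both signs, e.g. a
deletion `(-11 - +429)` covers 11 + 429 = 440 bases. This convention was
chosen because it is the only one under which all the published mutation
spans are internally consistent, and it is applied uniformly by
`call_edit()`, `format_notation()` and `parse_notation()`.

Insertions are bracketed by the retained flanking positions: `(-1 - +1)` is
an insertion exactly at the cut. Non-adjacent flanks, e.g. `(-1 - +4)`,
denote an insertion that *replaced* the interior bases (+1..+3); such events
are represented as a single `delins` segment, and `parse_notation()` recovers
the implied interior deletion, making the notation bijective. Substitutions
are written `X{pos}Y` (`T-817C`: reference T at −817 became C).

## Curation rules and their defaults

* **Consensus ("same genomic region")**: records cluster when they share
  contig and strand and overlap reciprocally by ≥ 50% (single linkage); the
  model supported by the most predictors wins. The 50% threshold is a design
  choice — the source protocol resolved regions manually — and is exposed as
  `min_reciprocal_overlap`. Ties prefer a model with a qualifying poly-T
  terminator, then shorter total intron, then a lexicographic key, so output
  is deterministic.
* **Intron cap** (`max_intron = 100`): no fungal tRNA intron above 100 nt is
  known; models exceeding it are rejected (`intron>100`).
* **Gene length bounds** (`min_gene_len = 60`, `max_gene_len = 130`,
  unspliced): generous bounds around the observed 71–112 bp range; config,
  not hard-coded. Note that with these defaults any model with a >100-nt
  intron also violates the length bound, so such rejections log both rules.
* **Terminator presence** (`term_window = 50`, `min_t_run = 4`): a model
  whose 50-nt downstream window lacks a run of ≥ 4 T cannot supply a
  terminator part and is rejected (`no_polyT_terminator`). The "poly-T
  stretch" is not quantified in the source protocol; ≥ 4 consecutive T
  within 50 nt reproduces the observed 7–42 nt terminator range on the
  published geometry and both knobs are exposed (`--min-t-run`,
  `--term-window`). The terminator is taken to *include* the full poly-T run
  (it ends at the run's last T); this is the reading under which the longest
  published part (42 nt) is recovered.
* **Pseudogenes** are kept in the catalog (flagged from predictor annotations
  only; the published six reflect manual review that is not reproducible
  algorithmically) but are excluded from promoter candidacy, as are
  selenocysteine genes.

## Guide design

Candidates are every 20-mer immediately 5' of an NGG PAM, both strands, with
spacer and PAM fully inside the target window; candidates containing N are
dropped (constructs must be synthesizable). The off-target criterion —
a genomic site within 3 mismatches of the spacer over the full 20-mer,
adjacent to an NGG (optionally also NAG) PAM — is a documented config
default, not a claim of equivalence with any particular desktop tool; the
original screening criterion is unrecoverable. "Clean" means zero such
sites besides the intended locus. The scanner is implemented with
`Biostrings::matchPattern(max.mismatch = ...)` plus PAM filtering, and its
contract is that results equal a position-by-position Hamming oracle; the
test suite enforces exactly that on multi-contig synthetic genomes up to
100 kb. Ranking is clean-first, then distance of the cut to a user anchor
(e.g. the start codon), then 5'-most.

## Cassette anatomy and construction planning

A cassette is the exact concatenation

```
promoter (gene+100) . spacer (20) . scaffold (80) . terminator (7-42)
```

built physically by fusion PCR of two fragments that overlap in exactly the
20-nt spacer: `promoter+spacer` and `spacer+scaffold+terminator`. The 80-nt
tracrRNA scaffold is a replaceable configuration constant
(`default_scaffold()` ships the standard *S. pyogenes* sgRNA scaffold DNA
trimmed/padded to 80 nt, since the exact sequence used in the source work is
not printed); all geometry checks assert length and position, never scaffold
identity. Primer Tm uses the Wallace rule (2(A+T) + 4(G+C)), growing primers
from 15 nt until Tm ≥ 55 °C — adequate for annealing-span bookkeeping and
deliberately simpler than nearest-neighbor models, since no primer design
rules were published.

### LIC planning

The vector carries a 38-bp LIC site with a central blunt-cutting SwaI site
(`ATTTAAAT`). After SwaI linearization, T4 DNA polymerase 3'→5' exonuclease
in the presence of dGTP resects each vector 3' end until the first G
(retained); the insert, amplified with LIC tails, is chewed with dCTP until
the first C. `simulate_chewback()` models exactly this single-dNTP stop
logic. `add_lic_tails()` derives insert tails from the vector site so that
the four exposed 5' overhangs pair as mutual reverse complements at both
junctions and verifies this by simulation; it refuses designs whose
overhangs fall below `min_overhang = 10` nt or whose site halves lack stop
bases. The default site (`default_lic_site()`) places the only G of the 5'
half at its first position and the only C of the 3' half at its last,
yielding 18-nt overhangs; the published tail sequences live in supplementary
material and can be supplied verbatim instead.

### Donor templates

Gene replacement donors are `600 bp upstream arm + payload + 600 bp
downstream arm`, arms read on the locus's coding strand and mapped exactly to
the genome. Given screening-primer offsets outside the locus, the expected
replaced-vs-intact PCR amplicon sizes follow by coordinate arithmetic
(replaced − intact = payload − locus length), mirroring how integration is
scored on a gel.

## Classifying mutant amplicons

`call_edit()` requires ≥ 30 nt of exact flanking match at each end (anchor;
config) — amplicons that do not anchor are rejected as not matching the
locus. The differing core between the anchors is classified directly when it
is pure (reference-only → deletion; mutant-only → insertion; equal length →
substitutions) and otherwise resolved by a global Biostrings alignment of
the core (match 1, mismatch −1, gap opening 5, extension 0.5 — opening
deliberately high so single long gaps beat fragmented ones). Indels in
repeats admit several equivalent placements; the reported one minimizes the
distance of the segment start to the cut, ties toward the 5' side. A
retained block of ≥ 8 nt inside a deleted region splits it into two reported
spans; shorter retained blocks are absorbed into a single `delins` (the
retained bases counted as replaced-and-reinserted), which keeps the
length-conservation identity `len(ref) − len(mut) = deleted − inserted`
exact for every call. Insertions of ≥ 15 nt can be traced to a named source
sequence (e.g. the Cas9/gRNA plasmid, a known pseudo-donor) by exact
substring search on both strands.

## What the synthetic fixtures emulate — and what they do not

`make_genome()` plants, deterministically for a seed: the full 37-part
published geometry (gene length, intron length, anticodon, terminator
length) with 100 nt of upstream context and a 6-nt poly-T run placed so the
terminator rule recovers the published length exactly; prediction records
from four tools including minority-variant and decoy models (oversized
intron, missing terminator, out-of-bounds length, pseudogene annotation); a
target gene with a planted guide site; and mismatched PAM-adjacent
off-target copies. The generator certifies its own off-target truth table
with an internal scan and re-draws the random context (bounded,
deterministic) if an accidental near-match arises, so truth tables are
exact. `make_preset_mutant()` builds one synthetic amplicon per published
mutation row, with the event planted at the published coordinates and the
random context re-drawn until the event is unambiguous under the
normalization above — the expected notations are fixed constants.

Synthetic genomes are uniform-random DNA: they do not reproduce real genome
composition, GC content, repeat structure, or real tRNA secondary structure
(no cloverleaf folding, no Box A/B scoring — neither is quantified in the
source). Passing tests therefore demonstrate correctness of the coordinate
handling, rules and assembly logic under the published geometry, not
biological performance of any part; mutation efficiencies are biology, out
of scope. The real albA/olvA loci are likewise not bundled — mutant presets
carry the events, not native context.

## Problem sizes and determinism

The test and acceptance workloads are sized for interactive runs: a ~15-kb
fixture genome for the pipeline, 100-kb genomes for the off-target oracle
comparison, 500 random single-indel recoveries, and 30 mutation presets;
the full suite runs in about a minute. All randomness flows from explicit
seeds (`fixture_spec(seed=)`, per-preset fixed seeds), and generation
restores the caller's RNG state.

## Known limitations

* Curation reproduces only the documented rules (intron cap, poly-T,
  length bounds, consensus voting); the manual structure review behind the
  published catalog is not algorithmically specified and is not imitated.
* Off-target scanning is mismatch-only (no bulges, no CFD/MIT-style
  scoring), matching the package's contract with its brute-force oracle.
* The classifier handles single Sanger-style amplicons; it is not a
  deep-sequencing deconvolution tool.
* Alignment-based compound calls can in principle choose a different but
  score-equivalent decomposition in repeat-dense cores; the documented
  normalization covers pure indels, and fixtures avoid pathological cores.
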