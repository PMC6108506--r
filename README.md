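# trnacrispr

Design toolkit for CRISPR/Cas9 genome editing in *Aspergillus niger* using
endogenous RNA polymerase III **tRNA promoters** to transcribe the guide RNA.

## The problem and who this is for

Getting a functional gRNA transcribed *in vivo* is the practical bottleneck
for CRISPR mutagenesis in *Aspergillus*: Pol II promoters need ribozyme
flanks, and U6/U3 promoters behave erratically across species. tRNA genes
offer a robust alternative — each gene carries internal Pol III promoter
elements (Box A/Box B), is transcribed constitutively, and the cell's own
tRNA processing releases the downstream gRNA. A promoter part is then simply
**the whole tRNA gene (introns included) plus 100 bp of upstream sequence**,
and the matching terminator runs from the gene end through the first
downstream **poly-T stretch** (7–42 nt in the published parts).

`trnacrispr` is for fungal molecular biologists planning such constructs and
for bioinformaticians curating tRNA-derived part libraries. It covers the
whole computational workflow:

| stage | functions |
|---|---|
| read genome / predictions (FASTA, tRNAscan-SE tabular, GFF3, TSV) | `load_fasta()`, `read_trna_predictions()`, `extract_seq()` |
| curate a tRNA gene catalog (consensus voting + rules) | `merge_predictions()`, `filter_models()`, `summarize_catalog()` |
| extract promoter/terminator parts | `extract_promoter()`, `extract_terminator()`, `extract_parts()` |
| design guides (N20-NGG, off-target Hamming scan) | `enumerate_guides()`, `scan_offtargets()`, `rank_guides()` |
| plan construction (fusion PCR, primers, LIC chew-back, donors) | `build_cassette()`, `add_lic_tails()`, `simulate_chewback()`, `design_donor()` |
| classify Cas9-induced mutations from amplicons | `cut_frame()`, `call_edit()`, `format_notation()`, `trace_insertion_origin()` |
| synthetic fixtures with exact ground truth | `fixture_spec()`, `make_genome()`, `make_preset_mutant()` |

Core conventions (detailed in the methods vignette,
`vignettes/construct-design-methods.Rmd`):

* a gRNA cassette is the exact concatenation
  `promoter (gene+100) · spacer (20 nt) · tracrRNA scaffold (80 nt) ·
  terminator`, built by fusion PCR of two fragments overlapping in the
  spacer;
* the Cas9 cut sits 3 bp 5′ of the NGG PAM; mutation coordinates are
  cut-relative with no position 0 (−1/+1 flank the blunt cut), so a deletion
  of the six bases 3′ of the cut is written `6 bp (+1 - +6)`;
* internal coordinates are 0-based half-open; all report output is 1-based.

## Worked example

Everything below runs on a synthetic genome in which the generator plants
the 37 published promoter/terminator geometries, decoy gene models, a target
gene and known off-target sites — no downloads needed:

```r
library(trnacrispr)

fx <- make_genome(fixture_spec(seed = 1))          # genome + predictions + truth
tg <- fx$truth$targets[1, ]
run <- run_pipeline(run_config(), fx$genome, fx$predictions,
                    genomic_interval(tg$contig, tg$start, tg$end))
print(run)
```

```
design run
  catalog: 38 model(s) kept, 3 rejected
  parts: 37 promoter/terminator pair(s)
  guides: 246 candidate(s), 245 clean; selected CCTGTTAGAGCTTAACCCGT (+)
gRNA cassette plan
  promoter    172 nt (tRNA-A-1)
  spacer       20 nt  CCTGTTAGAGCTTAACCCGT
  scaffold     80 nt
  terminator   16 nt (tRNA-A-1)
  full cassette 288 nt; fragments 192 + 116 nt (20-nt overlap)
  LIC tails added: insert 326 nt, overhangs 18/18 nt
```

Reading: of 41 merged gene models, 3 decoys were rejected (oversized intron,
no poly-T terminator, implausible length — each logged with its rule); the
first usable part pair is an alanine tRNA with a 72-bp gene, giving the
textbook 172-nt promoter and a 288-nt cassette (172+20+80+16). The two
fusion-PCR fragments share exactly the 20-nt spacer, and the LIC tails chew
back (T4 polymerase + dCTP for the insert, dGTP for the vector) to 18-nt
mutually reverse-complementary overhangs.

Classifying a sequenced mutant amplicon against its cut frame:

```r
r <- make_preset_mutant("cys1-albA-3")   # synthetic amplicon, known event
call_edit(r$frame, r$mutant)
```

```
edit call: compound
  deletion  815 bp (-813 - +2)
  mismatch  T-817C
```

i.e. an 815-bp deletion spanning the cut (813 bases 5′, 2 bases 3′) plus a
T→C substitution 817 bases 5′ of the cut.

A thin CLI wraps the same functions
(`inst/scripts/design.R`; subcommands `io-validate`, `curate`, `parts`,
`guides`, `cassette`, `donor`, `call-edits`, `fixtures`, `run`).

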