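# Fixture generator: synthetic genomes with planted tRNA genes, target genes,
# off-target sites, and cut-site mutant amplicons with known ground truth.
# Everything is deterministic for a given seed.

#' Published functional-test geometry of the 37 tRNA promoter/terminator pairs
#'
#' Gene length (unspliced), intron length, anticodon, promoter length
#' (gene + 100) and terminator length for the 37 tRNA promoters functionally
#' tested in A. niger. Used as the default planting geometry of the fixture
#' generator, so synthetic genomes reproduce the published part geometry.
#'
#' @return data.frame with columns `name`, `gene_length`, `intron_length`,
#'   `anticodon`, `promoter_length`, `terminator_length`.
#' @export
published_part_geometry <- function() {
  txt <- "name gene_length intron_length anticodon promoter_length terminator_length
Ala5 72 0 AGC 172 16
Ala23 72 0 AGC 172 7
Arg8 72 0 ACG 172 9
Arg21 72 0 ACG 172 9
Asp2 91 19 GTC 191 18
Asp5 90 18 GTC 190 11
Cys1 72 0 GCA 172 11
Cys2 72 0 GCA 172 15
Gln1 72 0 CTG 172 16
Gln2 92 20 TTG 192 20
Glu1 72 0 TTC 172 17
Glu12 71 0 TTC 171 16
Gly5 71 0 GCC 171 26
Gly13 71 0 GCC 171 16
His2 84 12 GTG 184 42
His3 71 0 GTG 171 32
Ile4 74 0 AAT 174 16
Ile8 74 0 AAT 174 17
Leu6 111 27 AAG 211 17
Leu14 112 27 AAG 212 13
Lys6 73 0 CTT 173 16
Lys17 73 0 CTT 173 18
Met4 72 0 CAT 172 15
Met9 72 0 CAT 172 21
Phe2 73 0 GAA 173 17
Phe12 73 0 GAA 173 11
Pro1 91 19 AGG 191 17
Pro3 91 19 AGG 191 17
Ser4 105 23 GCT 205 13
Ser7 81 0 AGA 181 15
Thr5 73 0 AGT 173 15
Thr6 73 0 AGT 173 13
Tyr3 88 13 GTA 188 22
Tyr7 88 13 GTA 188 21
Val1 74 0 CAC 174 18
Val4 96 23 CAC 196 25
Val15 87 14 TAC 187 18"
  utils::read.table(text = txt, header = TRUE, stringsAsFactors = FALSE)
}

#' Specification for a synthetic fixture genome
#'
#' @param seed integer seed; all randomness in [make_genome()] derives from it.
#' @param planted_trnas data.frame with columns `name`, `gene_length`,
#'   `intron_length`, `anticodon`, `terminator_length` (default: the full
#'   published 37-promoter geometry with a 6-nt poly-T run).
#' @param polyT_len length of the planted terminator poly-T run (default 6;
#'   per gene, capped at `terminator_length - 1`).
#' @param target_lengths lengths of planted target genes (default one 2-kb
#'   target).
#' @param planted_offtargets data.frame with columns `mismatches`, `strand`:
#'   off-target copies of the planted guide site (default: one 2-mismatch
#'   site on `+`, one 3-mismatch site on `-`).
#' @param decoys also plant curation decoys (oversized intron, missing
#'   terminator, out-of-bounds gene length, pseudogene annotation)?
#' @param spacer_gap mean spacing between planted features.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         planted_trnas = NULL,
                         polyT_len = 6L,
                         target_lengths = 2000L,
                         planted_offtargets = data.frame(
                           mismatches = c(2L, 3L), strand = c("+", "-"),
                           stringsAsFactors = FALSE),
                         decoys = TRUE,
                         spacer_gap = 80L) {
  if (is.null(planted_trnas)) {
    planted_trnas <- published_part_geometry()[, c("name", "gene_length",
                                           "intron_length", "anticodon",
                                           "terminator_length")]
  }
  structure(list(seed = as.integer(seed), planted_trnas = planted_trnas,
                 polyT_len = as.integer(polyT_len),
                 target_lengths = as.integer(target_lengths),
                 planted_offtargets = planted_offtargets,
                 decoys = isTRUE(decoys), spacer_gap = as.integer(spacer_gap)),
            class = "fixture_spec")
}

# random DNA avoiding any run of >= min_run consecutive T
rand_dna_no_polyT <- function(n, min_run = 4L) {
  if (n <= 0L) return("")
  repeat {
    s <- rand_dna(n)
    if (!grepl(strrep("T", min_run), s, fixed = TRUE)) return(s)
  }
}

# build one unspliced tRNA-like gene: anticodon planted at spliced offset
# 31-33 (1-based), intron (if any) inserted after spliced position 37
build_trna_gene <- function(gene_length, intron_length, anticodon) {
  spliced_len <- gene_length - intron_length
  stopifnot(spliced_len >= 45L)
  spliced <- rand_dna(spliced_len)
  substr(spliced, 31L, 33L) <- anticodon
  if (intron_length > 0L) {
    intron <- rand_dna(intron_length)
    gene <- paste0(substr(spliced, 1L, 37L), intron,
                   substr(spliced, 38L, spliced_len))
    list(gene = gene, intron_start = 37L, intron_end = 37L + intron_length)
  } else list(gene = spliced, intron_start = NA_integer_, intron_end = NA_integer_)
}

# mutate exactly `m` spread-out positions of a spacer
mutate_spacer <- function(spacer, m) {
  b <- strsplit(spacer, "", fixed = TRUE)[[1]]
  pos <- round(seq(2L, length(b) - 1L, length.out = m))
  for (p in pos) b[p] <- setdiff(c("A", "C", "G", "T"), b[p])[sample.int(3L, 1L)]
  paste(b, collapse = "")
}

#' Generate a synthetic genome with planted features and truth tables
#'
#' Builds a deterministic single-contig genome in which every requested tRNA
#' gene (with 100 nt of unique upstream sequence and a qualifying poly-T
#' terminator), target gene, guide site and off-target copy is planted at a
#' known location, plus optional curation decoys. Prediction records for four
#' predictors are emitted alongside so the curation stage can be exercised
#' end to end. The generator verifies its own off-target truth table (no
#' accidental near-matches of the planted guide survive) and re-draws the
#' random context if necessary, so the truth tables are exact.
#'
#' @param spec a [fixture_spec()].
#' @return list with `genome` (a `genome`), `predictions`
#'   (`trna_predictions`), and `truth` (list of data.frames: `trnas`,
#'   `decoys`, `targets`, `guide`, `offtargets`).
#' @export
make_genome <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  for (attempt in 0:24) {
    fx <- with_seed(spec$seed + 100000L * attempt, build_fixture_once(spec))
    if (fx$ok) return(fx[c("genome", "predictions", "truth")])
  }
  stop("could not build an unambiguous fixture genome for seed ", spec$seed)
}

build_fixture_once <- function(spec) {
  chunks <- character(0); at <- 0L   # 0-based cursor
  push <- function(s) { chunks[[length(chunks) + 1L]] <<- s; at <<- at + nchar(s); invisible(NULL) }
  gap <- function() push(rand_dna(spec$spacer_gap + sample.int(40L, 1L)))

  trna_rows <- list(); pred_rows <- list(); decoy_rows <- list()

  plant_trna <- function(name, glen, ilen, anticodon, term_len, polyT_len,
                         strand, predictors, keep, rules = "",
                         pseudogene = FALSE) {
    g <- build_trna_gene(glen, ilen, anticodon)
    prefix_len <- term_len - polyT_len
    downstream <- paste0(rand_dna_no_polyT(prefix_len), strrep("T", polyT_len),
                         "GACGA")
    upstream <- rand_dna_no_polyT(100L)   # poly-T-free so the minus-strand
                                          # gene's downstream scan is clean
    composite <- paste0(upstream, g$gene, downstream)
    if (strand == "-") composite <- revcomp(composite)
    gstart <- if (strand == "+") at + 100L else at + nchar(downstream)
    gend <- gstart + glen
    push(composite)
    is_rel <- if (is.na(g$intron_start)) "" else as.character(g$intron_start)
    ie_rel <- if (is.na(g$intron_start)) "" else as.character(g$intron_end)
    row <- data.frame(name = name, contig = "chr1", start = gstart, end = gend,
                      strand = strand, anticodon = anticodon,
                      gene_length = glen, intron_length = ilen,
                      intron_starts = is_rel, intron_ends = ie_rel,
                      terminator_length = term_len,
                      promoter_length = glen + 100L,
                      pseudogene = pseudogene, keep = keep, rules = rules,
                      stringsAsFactors = FALSE)
    if (keep) trna_rows[[length(trna_rows) + 1L]] <<- row
    else decoy_rows[[length(decoy_rows) + 1L]] <<- row
    for (p in predictors)
      pred_rows[[length(pred_rows) + 1L]] <<- data.frame(
        predictor = p, contig = "chr1", start = gstart, end = gend,
        strand = strand, anticodon = anticodon,
        intron_starts = is_rel, intron_ends = ie_rel,
        pseudogene = pseudogene, stringsAsFactors = FALSE)
    row
  }

  predictors4 <- c("tRNAscan-SE", "SPLITSX", "ARAGORN", "tRNAfinder")
  pt <- spec$planted_trnas
  for (i in seq_len(nrow(pt))) {
    gap()
    strand <- if (i %% 2L == 0L) "-" else "+"
    polyT <- min(spec$polyT_len, pt$terminator_length[i] - 1L)
    preds <- if (i %% 5L == 0L) predictors4[1:3] else predictors4
    row <- plant_trna(pt$name[i], pt$gene_length[i], pt$intron_length[i],
                      pt$anticodon[i], pt$terminator_length[i], polyT,
                      strand, preds, keep = TRUE)
    if (i %% 5L == 0L) {
      # minority conflicting model from the 4th predictor: 3' end shifted;
      # consensus voting must discard it
      pred_rows[[length(pred_rows) + 1L]] <- data.frame(
        predictor = predictors4[4], contig = "chr1", start = row$start,
        end = row$end + 3L, strand = strand, anticodon = pt$anticodon[i],
        intron_starts = row$intron_starts, intron_ends = row$intron_ends,
        pseudogene = FALSE, stringsAsFactors = FALSE)
    }
  }

  if (spec$decoys) {
    gap()
    plant_trna("decoy_long_intron", 75L + 120L, 120L, "AGC", 12L, 6L, "+",
               "ARAGORN", keep = FALSE,
               rules = "intron>100,gene_length_out_of_bounds")
    gap()
    plant_trna("decoy_out_of_bounds", 150L, 0L, "ACG", 12L, 6L, "+",
               c("ARAGORN", "tRNAfinder"), keep = FALSE,
               rules = "gene_length_out_of_bounds")
    gap()
    # no qualifying poly-T downstream: plant gene followed by T-free filler
    g <- build_trna_gene(72L, 0L, "GCA")
    push(rand_dna_no_polyT(100L))
    s0 <- at
    push(g$gene)
    e0 <- at
    push(rand_dna_no_polyT(60L, min_run = 4L))
    decoy_rows[[length(decoy_rows) + 1L]] <- data.frame(
      name = "decoy_no_terminator", contig = "chr1", start = s0, end = e0,
      strand = "+", anticodon = "GCA", gene_length = 72L, intron_length = 0L,
      intron_starts = "", intron_ends = "", terminator_length = NA_integer_,
      promoter_length = 172L, pseudogene = FALSE, keep = FALSE,
      rules = "no_polyT_terminator", stringsAsFactors = FALSE)
    pred_rows[[length(pred_rows) + 1L]] <- data.frame(
      predictor = "tRNAscan-SE", contig = "chr1", start = s0, end = e0,
      strand = "+", anticodon = "GCA", intron_starts = "", intron_ends = "",
      pseudogene = FALSE, stringsAsFactors = FALSE)
    gap()
    plant_trna("decoy_pseudogene", 72L, 0L, "CTG", 14L, 6L, "+",
               c("tRNAscan-SE", "SPLITSX"), keep = TRUE, pseudogene = TRUE)
  }

  # target genes and planted guide/off-target sites
  target_rows <- list(); guide_row <- NULL; ot_rows <- list()
  spacer <- NULL
  for (tl in spec$target_lengths) {
    gap()
    s0 <- at
    push(rand_dna(tl))
    target_rows[[length(target_rows) + 1L]] <- data.frame(
      name = sprintf("target_%d", length(target_rows) + 1L), contig = "chr1",
      start = s0, end = at, strand = "+", stringsAsFactors = FALSE)
    if (is.null(spacer)) {
      # plant an exact protospacer+PAM site mid-target on the + strand
      spacer <- rand_dna(20L)
      site <- paste0(spacer, "TGG")
      mid <- s0 + (tl %/% 2L)
      chunks[[length(chunks)]] <- local({
        last <- chunks[[length(chunks)]]
        off <- mid - s0
        paste0(substr(last, 1L, off), site,
               substr(last, off + nchar(site) + 1L, nchar(last)))
      })
      guide_row <- data.frame(contig = "chr1", start = mid, end = mid + 20L,
                              strand = "+", spacer = spacer,
                              cut_genomic = mid + 17L, stringsAsFactors = FALSE)
    }
  }
  if (!is.null(spacer) && nrow(spec$planted_offtargets)) {
    for (i in seq_len(nrow(spec$planted_offtargets))) {
      gap()
      m <- spec$planted_offtargets$mismatches[i]
      std <- spec$planted_offtargets$strand[i]
      mut <- mutate_spacer(spacer, m)
      site <- paste0(mut, "AGG")
      if (std == "-") {
        s0 <- at
        push(revcomp(site))
        start0 <- s0 + 3L
      } else {
        s0 <- at
        push(site)
        start0 <- s0
      }
      ot_rows[[length(ot_rows) + 1L]] <- data.frame(
        contig = "chr1", start = start0, end = start0 + 20L, strand = std,
        mismatches = m, stringsAsFactors = FALSE)
    }
  }
  gap()

  genome <- as_genome(c(chr1 = paste(chunks, collapse = "")))

  # self-check the off-target truth: the planted guide must have exactly the
  # planted near-matches (and its own site), nothing accidental
  ok <- TRUE
  if (!is.null(guide_row)) {
    found <- fixture_site_scan(genome[["chr1"]], spacer, 3L)
    want <- rbind(
      data.frame(start = guide_row$start, strand = guide_row$strand,
                 mismatches = 0L, stringsAsFactors = FALSE),
      if (length(ot_rows)) {
        ot <- do.call(rbind, ot_rows)
        data.frame(start = ot$start, strand = ot$strand,
                   mismatches = ot$mismatches, stringsAsFactors = FALSE)
      })
    want <- want[order(want$start, want$strand), , drop = FALSE]
    found <- found[order(found$start, found$strand), , drop = FALSE]
    ok <- nrow(found) == nrow(want) &&
      all(found$start == want$start) && all(found$strand == want$strand) &&
      all(found$mismatches == want$mismatches)
  }

  truth <- list(
    trnas = do.call(rbind, c(trna_rows, list(make.row.names = FALSE))),
    decoys = if (length(decoy_rows))
      do.call(rbind, c(decoy_rows, list(make.row.names = FALSE))) else NULL,
    targets = if (length(target_rows))
      do.call(rbind, c(target_rows, list(make.row.names = FALSE))) else NULL,
    guide = guide_row,
    offtargets = if (length(ot_rows))
      do.call(rbind, c(ot_rows, list(make.row.names = FALSE))) else NULL)
  list(ok = ok, genome = genome,
       predictions = new_predictions(do.call(rbind, c(pred_rows,
                                                      list(make.row.names = FALSE)))),
       truth = truth)
}

# generator-internal vectorized near-match scan (start, strand, mismatches)
# for PAM-adjacent (NGG/NAG) sites; used only to certify the truth table
fixture_site_scan <- function(seq, spacer, max_mm) {
  k <- nchar(spacer)
  scan_strand <- function(s, std) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    L <- length(b)
    npos <- L - k - 2L
    if (npos < 1L) return(NULL)
    sp <- strsplit(spacer, "", fixed = TRUE)[[1]]
    mm <- integer(npos)
    for (j in seq_len(k)) mm <- mm + (b[seq_len(npos) + j - 1L] != sp[j])
    pam_ok <- b[seq_len(npos) + k + 1L] == "G" & b[seq_len(npos) + k + 2L] == "G"
    hit <- which(mm <= max_mm & pam_ok)
    if (!length(hit)) return(NULL)
    start0 <- if (std == "+") hit - 1L else L - (hit - 1L) - k
    data.frame(start = start0, strand = std, mismatches = mm[hit],
               stringsAsFactors = FALSE)
  }
  out <- rbind(scan_strand(seq, "+"), scan_strand(revcomp(seq), "-"))
  if (is.null(out)) data.frame(start = integer(0), strand = character(0),
                               mismatches = integer(0)) else out
}

#' Write fixture files in all supported dialects
#'
#' @param fx result of [make_genome()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly; writes `genome.fa`, `predictions.tsv`,
#'   `predictions.trnascan`, `predictions.gff3`, truth TSVs and a manifest.
#' @export
write_fixtures <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(fx$genome, file.path(dir, "genome.fa"))
  write_trna_predictions(fx$predictions, file.path(dir, "predictions.tsv"))
  write_trnascan_file(fx$predictions, file.path(dir, "predictions.trnascan"))
  write_gff3_file(fx$predictions, file.path(dir, "predictions.gff3"))
  for (nm in names(fx$truth)) {
    if (!is.null(fx$truth[[nm]]))
      utils::write.table(fx$truth[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(c("trnacrispr synthetic fixture bundle",
               paste0("files: genome.fa predictions.{tsv,trnascan,gff3} ",
                      "truth_*.tsv")),
             file.path(dir, "MANIFEST.txt"))
  invisible(dir)
}

# emit predictions in tRNAscan-SE 1.3 tabular form (1-based; minus strand as
# begin > end; genomic intron coordinates)
write_trnascan_file <- function(predictions, path) {
  df <- as.data.frame(predictions)
  lines <- c("Sequence\t\ttRNA\tBounds\ttRNA\tAnti\tIntron Bounds\tCove",
             "Name    \ttRNA #\tBegin\tEnd\tType\tCodon\tBegin\tEnd\tScore",
             "--------\t------\t-----\t---\t----\t-----\t-----\t---\t-----")
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (r$strand == "+") { b <- r$start + 1L; e <- r$end }
    else { b <- r$end; e <- r$start + 1L }
    irel_s <- parse_intron_field(r$intron_starts)
    irel_e <- parse_intron_field(r$intron_ends)
    if (length(irel_s)) {
      if (r$strand == "+") { ib <- r$start + irel_s[1] + 1L; ie <- r$start + irel_e[1] }
      else { ib <- r$end - irel_s[1]; ie <- r$end - irel_e[1] + 1L }
    } else { ib <- 0L; ie <- 0L }
    aa <- classify_anticodon(r$anticodon)
    note <- if (isTRUE(r$pseudogene)) "\tpseudo" else ""
    lines <- c(lines, sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%.2f%s",
                              r$contig, i, b, e, aa, r$anticodon, ib, ie,
                              50 + i %% 30, note))
  }
  writeLines(lines, path)
  invisible(path)
}

# emit predictions as GFF3 (tRNA features with anticodon attribute and
# intron children)
write_gff3_file <- function(predictions, path) {
  df <- as.data.frame(predictions)
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    id <- sprintf("trna%04d", i)
    attrs <- sprintf("ID=%s;anticodon=%s%s", id, r$anticodon,
                     if (isTRUE(r$pseudogene)) ";pseudo=true" else "")
    lines <- c(lines, paste(r$contig, r$predictor, "tRNA", r$start + 1L, r$end,
                            ".", r$strand, ".", attrs, sep = "\t"))
    irel_s <- parse_intron_field(r$intron_starts)
    irel_e <- parse_intron_field(r$intron_ends)
    for (j in seq_along(irel_s)) {
      if (r$strand == "+") { a <- r$start + irel_s[j] + 1L; b <- r$start + irel_e[j] }
      else { a <- r$end - irel_e[j] + 1L; b <- r$end - irel_s[j] }
      lines <- c(lines, paste(r$contig, r$predictor, "tRNA_intron", a, b, ".",
                              r$strand, ".", sprintf("Parent=%s", id), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# Published cut-site mutation presets -----------------------------------------

#' Preset catalog of published cut-site mutation events
#'
#' The 30 sequenced mutants reported for the albA/olvA disruption
#' experiments, encoded as cut-frame events: deletion spans, insertions
#' (with their retained-flank brackets) and substitutions, in the
#' no-position-0 coordinate convention. `del2` holds the second span of
#' two-span deletions; `ins_flanks` the insertion bracket (non-adjacent
#' flanks denote an insertion replacing the interior bases).
#'
#' @return data.frame, one row per preset.
#' @export
mutation_presets <- function() {
  p <- function(id, del = NULL, del2 = NULL, ins_len = NA_integer_,
                ins_flanks = NULL, sub = NULL) {
    data.frame(preset_id = id,
               del_start = if (is.null(del)) NA_integer_ else del[1],
               del_end = if (is.null(del)) NA_integer_ else del[2],
               del2_start = if (is.null(del2)) NA_integer_ else del2[1],
               del2_end = if (is.null(del2)) NA_integer_ else del2[2],
               ins_len = ins_len,
               ins_left = if (is.null(ins_flanks)) NA_integer_ else ins_flanks[1],
               ins_right = if (is.null(ins_flanks)) NA_integer_ else ins_flanks[2],
               sub_pos = if (is.null(sub)) NA_integer_ else as.integer(sub[1]),
               sub_ref = if (is.null(sub)) NA_character_ else sub[2],
               sub_alt = if (is.null(sub)) NA_character_ else sub[3],
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    p("arg21-albA-1", del = c(1L, 6L)),
    p("arg21-albA-2", del = c(1L, 6L)),
    p("arg21-albA-3", del = c(1L, 4L)),
    p("arg21-olvA-1", del = c(1L, 8L)),
    p("arg21-olvA-2", del = c(-11L, 429L), del2 = c(438L, 609L)),
    p("arg21-olvA-3", ins_len = 72L, ins_flanks = c(-1L, 1L)),
    p("cys1-albA-1", del = c(-27L, -1L)),
    p("cys1-albA-2", del = c(-854L, -1L)),
    p("cys1-albA-3", del = c(-813L, 2L), sub = c(-817L, "T", "C")),
    p("cys1-olvA-1", del = c(1L, 18L)),
    p("cys1-olvA-2", del = c(-2L, 8L)),
    p("cys1-olvA-3", del = c(-1L, 6L)),
    p("gln2-albA-1", ins_len = 39L, ins_flanks = c(-2L, -1L)),
    p("gln2-albA-2", del = c(-1L, 11L)),
    p("gln2-albA-3", del = c(-22L, -1L)),
    p("gln2-olvA-1", del = c(-12L, 1L)),
    p("gln2-olvA-2", del = c(-1038L, 58L)),
    p("gln2-olvA-3", del = c(-8L, 3L)),
    p("leu6-albA-1", del = c(-1L, -1L)),
    p("leu6-albA-2", del = c(-3L, 12L)),
    p("leu6-albA-3", del = c(-979L, -1L)),
    p("leu6-olvA-1", del = c(-1L, -1L)),
    p("leu6-olvA-2", ins_len = 88L, ins_flanks = c(-1L, 4L)),
    p("leu6-olvA-3", del = c(-13L, -1L)),
    p("pro1-albA-1", del = c(-7L, -2L)),
    p("pro1-albA-2", del = c(-3L, 1L), sub = c(-6L, "A", "G")),
    p("pro1-albA-3", del = c(-2L, -1L)),
    p("pro1-olvA-1", del = c(-1L, -1L)),
    p("pro1-olvA-2", del = c(-2L, -1L)),
    p("pro1-olvA-3", del = c(-1L, -1L))))
}

preset_expected_segments <- function(pr, ins_seq = NULL) {
  segs <- list()
  if (!is.na(pr$sub_pos))
    segs[[length(segs) + 1L]] <- segment_row("sub", 1L, pr$sub_pos, pr$sub_pos,
                                             seq = pr$sub_alt, ref = pr$sub_ref)
  if (!is.na(pr$del_start))
    segs[[length(segs) + 1L]] <- segment_row(
      "del", count_positions(pr$del_start, pr$del_end), pr$del_start, pr$del_end)
  if (!is.na(pr$del2_start))
    segs[[length(segs) + 1L]] <- segment_row(
      "del", count_positions(pr$del2_start, pr$del2_end), pr$del2_start, pr$del2_end)
  if (!is.na(pr$ins_len)) {
    kind <- if (rel_adjacent(pr$ins_left, pr$ins_right)) "ins" else "delins"
    segs[[length(segs) + 1L]] <- segment_row(kind, pr$ins_len, pr$ins_left,
                                             pr$ins_right,
                                             seq = ins_seq %||% "")
  }
  out <- do.call(rbind, c(segs, list(empty_segments())))
  out[order(out$start_rel), , drop = FALSE]
}

#' Build a synthetic mutant amplicon for a preset event
#'
#' Constructs a synthetic reference amplicon carrying one protospacer+PAM,
#' applies the preset's event, and returns the cut frame, mutant sequence and
#' expected call. The random context is drawn deterministically per preset
#' and re-drawn (bounded, deterministic) until the planted event is
#' unambiguous under the closest-to-cut normalization, so the expected
#' notation -- a fixed constant -- is exactly recoverable. For insertion
#' presets a synthetic 3-kb plasmid containing the inserted sequence is also
#' returned so origin tracing can be exercised.
#'
#' @param preset_id one of `mutation_presets()$preset_id`.
#' @param margin extra anchor context beyond the event extent (default 60).
#' @return list with `frame` (a `cut_frame`), `reference`, `mutant`,
#'   `expected` (list: `call_class`, `segments`, `notation`), and for
#'   insertion presets `plasmid` plus `plasmid_origin`.
#' @export
make_preset_mutant <- function(preset_id, margin = 60L) {
  presets <- mutation_presets()
  pr <- presets[presets$preset_id == preset_id, , drop = FALSE]
  if (nrow(pr) != 1L) stop("unknown preset id: ", preset_id)
  pr <- as.list(pr)
  base_seed <- 70000L + match(preset_id, presets$preset_id) * 101L
  positions <- c(pr$del_start, pr$del_end, pr$del2_start, pr$del2_end,
                 pr$ins_left, pr$ins_right, pr$sub_pos)
  positions <- positions[!is.na(positions)]
  left_ext <- max(1L, -min(c(positions, -1L)))
  right_ext <- max(1L, max(c(positions, 1L)))

  for (attempt in 0:49) {
    built <- with_seed(base_seed + attempt, build_preset_once(pr, left_ext,
                                                             right_ext, margin))
    got <- tryCatch(call_edit(built$frame, built$mutant),
                    error = function(e) NULL)
    if (!is.null(got) &&
        identical(got$call_class, built$expected$call_class) &&
        identical(got$notation, built$expected$notation) &&
        segments_match(got$segments, built$expected$segments))
      return(built)
  }
  stop("could not build an unambiguous context for preset ", preset_id)
}

segments_match <- function(a, b) {
  cols <- c("kind", "length", "start_rel", "end_rel")
  nrow(a) == nrow(b) && all(a[cols] == b[cols])
}

build_preset_once <- function(pr, left_ext, right_ext, margin) {
  cut <- left_ext + margin                      # 0-based scissile index
  n <- left_ext + right_ext + 2L * margin
  ref <- rand_dna(n)
  # protospacer on + strand: cut 3 bp 5' of the PAM at [cut+3, cut+6)
  substr(ref, cut + 4L, cut + 6L) <- "TGG"
  if (!is.na(pr$sub_pos)) {
    i <- index_of_rel(pr$sub_pos, cut)
    substr(ref, i + 1L, i + 1L) <- pr$sub_ref
  }
  ins_seq <- if (!is.na(pr$ins_len)) rand_dna(pr$ins_len) else NULL
  expected_segs <- preset_expected_segments(pr, ins_seq)
  # fill deletion/sub ref content from the constructed reference
  for (j in seq_len(nrow(expected_segs))) {
    k <- expected_segs$kind[j]
    if (k %in% c("del", "delins")) {
      a <- index_of_rel(expected_segs$start_rel[j], cut)
      b <- index_of_rel(expected_segs$end_rel[j], cut)
      if (k == "del")
        expected_segs$ref[j] <- substr(ref, a + 1L, b + 1L)
      else
        expected_segs$ref[j] <- substr(ref, a + 2L, b)
    }
  }
  frame <- cut_frame(ref, cut, "+")
  mutant <- apply_edit(expected_segs, frame)
  cls <- classify_segments(expected_segs)
  expected <- list(call_class = cls, segments = expected_segs,
                   notation = format_notation(list(segments = expected_segs)))
  out <- list(frame = frame, reference = ref, mutant = mutant,
              expected = expected)
  if (!is.null(ins_seq)) {
    pos <- 1200L
    plasmid <- paste0(rand_dna(pos), ins_seq, rand_dna(3000L - pos - nchar(ins_seq)))
    out$plasmid <- c(plasmid_synthetic = plasmid)
    out$plasmid_origin <- list(source_name = "plasmid_synthetic", start = pos,
                               end = pos + nchar(ins_seq), strand = "+")
  }
  out
}
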