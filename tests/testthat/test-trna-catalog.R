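make_record <- function(predictor, start, end, strand = "+", anticodon = "AGC",
                        intron_starts = "", intron_ends = "", contig = "chr1",
                        pseudogene = FALSE) {
  data.frame(predictor = predictor, contig = contig, start = start, end = end,
             strand = strand, anticodon = anticodon,
             intron_starts = intron_starts, intron_ends = intron_ends,
             pseudogene = pseudogene, stringsAsFactors = FALSE)
}

test_that("identical records from several predictors collapse to one model", {
  recs <- rbind(make_record("A", 100, 172), make_record("B", 100, 172),
                make_record("C", 100, 172))
  cat_ <- merge_predictions(recs)
  expect_equal(nrow(cat_), 1L)
  expect_identical(cat_$predictors, "A,B,C")
  expect_identical(cat_$amino_acid, "A")
})

test_that("consensus voting keeps the majority model in a cluster", {
  recs <- rbind(make_record("A", 100, 172), make_record("B", 100, 172),
                make_record("C", 100, 175))
  cat_ <- merge_predictions(recs)
  expect_equal(nrow(cat_), 1L)
  expect_equal(cat_$end, 172L)
  expect_identical(cat_$predictors, "A,B")
})

test_that("random clusters resolve to the exhaustive-vote winner", {
  set.seed(21)
  for (rep in 1:50) {
    base <- sample.int(5000, 1)
    n_variants <- sample(2:4, 1)
    variants <- base + cumsum(c(0, sample(1:3, n_variants - 1, TRUE)))
    votes <- sample(1:4, n_variants)
    votes[sample.int(n_variants, 1)] <- 5L   # unique majority
    recs <- do.call(rbind, lapply(seq_len(n_variants), function(i)
      do.call(rbind, lapply(paste0("P", seq_len(votes[i]), "_", i), function(p)
        make_record(p, base, base + 70 + (variants[i] - base))))))
    cat_ <- merge_predictions(recs)
    expect_equal(nrow(cat_), 1L)
    expect_equal(cat_$end, base + 70 + (variants[which.max(votes)] - base))
  }
})

test_that("non-overlapping records pass through as singleton models", {
  recs <- rbind(make_record("A", 100, 172), make_record("A", 1000, 1072),
                make_record("B", 1000, 1072, strand = "-"))
  cat_ <- merge_predictions(recs)
  expect_equal(nrow(cat_), 3L)   # opposite strands never cluster
  expect_equal(nrow(merge_predictions(recs[0, ])), 0L)
})

test_that("anticodon classification agrees with the codon-table oracle", {
  all_ac <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                              c("A","C","G","T")), 1, paste, collapse = "")
  got <- classify_anticodon(all_ac)
  want <- unname(oracle_codon_table[vapply(all_ac, oracle_revcomp, "")])
  want[vapply(all_ac, oracle_revcomp, "") == "TGA"] <- "SeC"
  expect_identical(got, want)
  expect_identical(classify_anticodon("AGC"), "A")   # Ala
  expect_identical(classify_anticodon("AAG"), "L")   # Leu
  expect_error(classify_anticodon("AXC"), "ACGT")
})

test_that("curation rules fire individually and jointly (rule-by-rule oracle)", {
  fx <- fixture_cache()
  cat_ <- merge_predictions(fx$predictions, fx$genome)
  flt <- filter_models(cat_, fx$genome)
  expect_equal(nrow(flt$kept) + nrow(flt$rejected), nrow(cat_))

  # independent per-model oracle over the merged catalog
  df <- as.data.frame(cat_)
  for (i in seq_len(nrow(df))) {
    introns <- as.integer(strsplit(df$intron_ends[i], ",")[[1]]) -
      as.integer(strsplit(df$intron_starts[i], ",")[[1]])
    len <- df$end[i] - df$start[i]
    dn <- if (df$strand[i] == "+")
      oracle_extract(fx$genome[["chr1"]], df$end[i],
                     min(nchar(fx$genome[["chr1"]]), df$end[i] + 50), "+")
    else oracle_extract(fx$genome[["chr1"]], max(0, df$start[i] - 50),
                        df$start[i], "-")
    expect_rules <- c(
      if (length(introns) && any(introns > 100)) "intron>100",
      if (len < 60 || len > 130) "gene_length_out_of_bounds",
      if (is.na(oracle_polyT_end(dn, 4))) "no_polyT_terminator")
    if (is.null(expect_rules)) {
      expect_true(df$model_id[i] %in% flt$kept$model_id)
    } else {
      j <- match(df$model_id[i], flt$rejected$model_id)
      expect_false(is.na(j))
      expect_identical(flt$rejected$rules[j], paste(expect_rules, collapse = ","))
    }
  }

  # the planted decoys are rejected for exactly the planted reasons
  dec <- fx$truth$decoys[!fx$truth$decoys$keep, ]
  for (i in seq_len(nrow(dec))) {
    m <- df[df$start == dec$start[i] & df$end == dec$end[i], ]
    j <- match(m$model_id, flt$rejected$model_id)
    expect_identical(flt$rejected$rules[j], dec$rules[i], label = dec$name[i])
  }
})

test_that("filtering is idempotent", {
  fx <- fixture_cache()
  flt <- filter_models(merge_predictions(fx$predictions, fx$genome), fx$genome)
  again <- filter_models(flt$kept, fx$genome)
  expect_identical(as.data.frame(again$kept), as.data.frame(flt$kept))
  expect_equal(nrow(again$rejected), 0L)
})

test_that("boundary intron lengths: 100 nt is kept, 101 nt is rejected", {
  # plant two genes with 100- and 101-nt introns in a tiny genome, each with
  # a qualifying terminator; only the intron rule separates them (lengths
  # are bound-checked with widened bounds)
  set.seed(22)
  up <- oracle_dna(100)
  g100 <- paste0(substr(oracle_dna(40), 1, 37), oracle_dna(100), oracle_dna(35))
  g101 <- paste0(substr(oracle_dna(40), 1, 37), oracle_dna(101), oracle_dna(35))
  genome <- as_genome(c(chr1 = paste0(up, g100, "GCTTTTTG", oracle_dna(30),
                                      up, g101, "GCTTTTTG", oracle_dna(30))))
  s1 <- 100L; e1 <- s1 + nchar(g100)
  s2 <- e1 + 8L + 30L + 100L; e2 <- s2 + nchar(g101)
  recs <- rbind(
    make_record("A", s1, e1, intron_starts = "37", intron_ends = "137"),
    make_record("A", s2, e2, intron_starts = "37", intron_ends = "138"))
  flt <- filter_models(merge_predictions(recs, genome), genome,
                       config = list(max_gene_len = 250L))
  expect_equal(nrow(flt$kept), 1L)
  expect_equal(flt$kept$start, s1)
  expect_match(flt$rejected$rules, "intron>100")
})

test_that("catalog summary counts add up", {
  expect_equal(summarize_catalog(merge_predictions(NULL))$total, 0L)
  fx <- fixture_cache()
  flt <- filter_models(merge_predictions(fx$predictions, fx$genome), fx$genome)
  sm <- summarize_catalog(flt$kept)
  expect_equal(sum(sm$aa_counts), sm$total)
  expect_equal(sm$total, nrow(flt$kept))
  expect_equal(sm$n_pseudogene, sum(flt$kept$pseudogene))
  # planted geometry: two Ala genes with anticodon AGC etc.
  tr <- fx$truth$trnas
  want <- table(classify_anticodon(tr$anticodon[!grepl("decoy", tr$name)]))
  for (aa in names(want))
    expect_gte(unname(sm$aa_counts[aa]), unname(want[aa]))
})

test_that("catalog TSV round-trips through 1-based report coordinates", {
  fx <- fixture_cache()
  flt <- filter_models(merge_predictions(fx$predictions, fx$genome), fx$genome)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_catalog_tsv(flt$kept, f)
  back <- read_catalog_tsv(f, fx$genome)
  expect_identical(as.data.frame(back), as.data.frame(flt$kept))
})
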