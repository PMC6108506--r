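# build an unambiguous random frame: PAM planted so the cut sits at a known
# index, with the protospacer on the + strand
random_frame <- function(n = 300, cut = NULL) {
  if (is.null(cut)) cut <- n %/% 2
  ref <- oracle_dna(n)
  substr(ref, cut + 4, cut + 6) <- "TGG"
  cut_frame(ref, cut, "+")
}

test_that("the cut sits 3 bp upstream of the PAM by construction", {
  set.seed(61)
  fr <- random_frame(200, 100)
  # PAM occupies 0-based [103,106); the scissile index is 100, i.e. the cut
  # falls between the 17th and 18th protospacer base
  expect_identical(substr(fr$reference, 104, 106), "TGG")
  expect_equal((103) - fr$cut_index, 3L)
  # and cut_frame_from_guide agrees with guide enumeration geometry
  g <- as_genome(c(amp = fr$reference))
  gs <- enumerate_guides(g, genomic_interval("amp", 0, 200))
  hit <- gs[gs$start == 83 & gs$strand == "+", ]
  expect_equal(nrow(hit), 1L)
  fr2 <- cut_frame_from_guide(fr$reference, hit$start, "+")
  expect_equal(fr2$cut_index, fr$cut_index)
  expect_equal(hit$cut_genomic, fr$cut_index)   # base +1 of the frame
})

test_that("identity amplicon calls none; broken anchors are an error", {
  set.seed(62)
  fr <- random_frame()
  expect_identical(call_edit(fr, fr$reference)$call_class, "none")
  expect_error(call_edit(fr, oracle_dna(300)), "does not match locus")
})

test_that("deletions immediately flanking the cut use the -1/+1 convention", {
  set.seed(63)
  # engineer a context with no repeat ambiguity at the junction
  fr <- random_frame(240, 120)
  ref <- fr$reference
  # deletion of the 3 bases immediately 5' of the cut: indices 117..119
  mut <- paste0(substr(ref, 1, 117), substr(ref, 121, 240))
  cl <- call_edit(fr, mut)
  if (cl$segments$start_rel == -3L) {   # unambiguous context
    expect_identical(unname(cl$notation["deletion"]), "3 bp (-3 - -1)")
  }
  expect_identical(cl$call_class, "deletion")
  expect_equal(cl$segments$length, 3L)
  # deletion of the 3 bases immediately 3': indices 120..122
  mut <- paste0(substr(ref, 1, 120), substr(ref, 124, 240))
  cl <- call_edit(fr, mut)
  expect_equal(cl$segments$length, 3L)
  expect_lte(abs(cl$segments$start_rel), 3L)
})

test_that("deletion length conservation holds for every call", {
  set.seed(64)
  for (i in 1:50) {
    fr <- random_frame(400)
    ref <- fr$reference
    len <- sample(1:30, 1)
    at <- sample(80:280, 1)
    mut <- paste0(substr(ref, 1, at), substr(ref, at + len + 1, 400))
    cl <- call_edit(fr, mut)
    deleted <- sum(cl$segments$length[cl$segments$kind == "del"]) +
      sum(nchar(cl$segments$ref[cl$segments$kind == "delins"]))
    inserted <- sum(cl$segments$length[cl$segments$kind %in% c("ins", "delins")])
    expect_equal(nchar(ref) - nchar(mut), deleted - inserted)
  }
})

test_that("500 random single indels are recovered after closest-to-cut normalization", {
  set.seed(65)
  n_exact <- 0L
  for (i in 1:500) {
    fr <- random_frame(320, 160)
    ref <- fr$reference
    is_del <- i %% 2 == 0
    len <- sample(1:25, 1)
    at <- sample(60:240, 1)                 # 0-based edit point
    if (is_del) {
      mut <- paste0(substr(ref, 1, at), substr(ref, at + len + 1, 320))
      truth_len <- len
    } else {
      ins <- oracle_dna(len)
      mut <- paste0(substr(ref, 1, at), ins, substr(ref, at + 1, 320))
      truth_len <- len
    }
    cl <- call_edit(fr, mut)
    expect_identical(cl$call_class, if (is_del) "deletion" else "insertion")
    expect_equal(cl$segments$length, truth_len)
    # the called representation must regenerate the mutant exactly
    expect_identical(apply_edit(cl, fr), mut)
    # and the called span must be an equivalent placement of the truth:
    # same length, and |called start| never farther from the cut than the
    # planted representation
    planted_rel <- if (at >= fr$cut_index) at - fr$cut_index + 1L
    else at - fr$cut_index
    if (is_del) {
      expect_lte(abs(cl$segments$start_rel), abs(planted_rel))
      if (cl$segments$start_rel == planted_rel) n_exact <- n_exact + 1L
    }
  }
  expect_gte(n_exact, 150L)   # most contexts are unambiguous
})

test_that("minus-strand frames report coordinates along the protospacer strand", {
  set.seed(66)
  fr_plus <- random_frame(300, 150)
  ref_minus <- oracle_revcomp(fr_plus$reference)
  fr_minus <- cut_frame(ref_minus, 300 - 150, "-")
  # delete the 5 bases 3' of the cut in protospacer coordinates
  mut_plus <- paste0(substr(fr_plus$reference, 1, 150),
                     substr(fr_plus$reference, 156, 300))
  cl_plus <- call_edit(fr_plus, mut_plus)
  cl_minus <- call_edit(fr_minus, oracle_revcomp(mut_plus))
  expect_identical(cl_plus$notation, cl_minus$notation)
  expect_identical(apply_edit(cl_minus, fr_minus), oracle_revcomp(mut_plus))
})

test_that("compound two-span deletions keep retained blocks of >= 8 nt apart", {
  set.seed(67)
  r <- make_preset_mutant("arg21-olvA-2")
  cl <- call_edit(r$frame, r$mutant)
  expect_identical(cl$call_class, "compound")
  expect_equal(nrow(cl$segments[cl$segments$kind == "del", ]), 2L)
  expect_identical(unname(cl$notation["deletion"]),
                   "612 bp (-11 - +429; +438 - +609)")
  expect_identical(apply_edit(cl, r$frame), r$mutant)
})

test_that("substitutions are reported in X{pos}Y notation alongside deletions", {
  set.seed(68)
  r <- make_preset_mutant("cys1-albA-3")
  cl <- call_edit(r$frame, r$mutant)
  expect_identical(unname(cl$notation["deletion"]), "815 bp (-813 - +2)")
  expect_identical(unname(cl$notation["mismatch"]), "T-817C")
  expect_identical(cl$call_class, "compound")
})

test_that("insertion origin tracing finds exact hits on either strand", {
  set.seed(69)
  ins <- oracle_dna(72)
  plasmid <- c(p1 = paste0(oracle_dna(500), ins, oracle_dna(500)))
  hit <- trace_insertion_origin(ins, plasmid)
  expect_identical(hit$source_name, "p1")
  expect_equal(hit$start, 500L)
  expect_equal(hit$end, 572L)
  expect_identical(hit$strand, "+")

  plasmid_rc <- c(p1 = paste0(oracle_dna(300), oracle_revcomp(ins),
                              oracle_dna(300)))
  hit <- trace_insertion_origin(ins, plasmid_rc)
  expect_identical(hit$strand, "-")
  expect_equal(hit$start, 300L)

  expect_null(trace_insertion_origin(oracle_dna(72), plasmid))
  expect_null(trace_insertion_origin("ACGTACGT", plasmid))   # below min_len

  # planted hits at random positions equal a naive substring-scan oracle
  for (i in 1:20) {
    ins <- oracle_dna(sample(15:60, 1))
    pos <- sample(1000, 1)
    std <- sample(c("+", "-"), 1)
    body <- paste0(oracle_dna(pos),
                   if (std == "+") ins else oracle_revcomp(ins),
                   oracle_dna(200))
    hit <- trace_insertion_origin(ins, c(src = body))
    naive <- regexpr(if (std == "+") ins else oracle_revcomp(ins), body,
                     fixed = TRUE)
    expect_equal(hit$start, as.integer(naive) - 1L)
    expect_identical(hit$strand, std)
  }
})

test_that("notation formatting and parsing are mutually inverse", {
  set.seed(70)
  # targeted examples
  d6 <- parse_notation(c(deletion = "6 bp (+1 - +6)", insertion = "",
                         mismatch = ""))
  expect_identical(d6$kind, "del")
  expect_equal(d6$length, 6L)
  expect_equal(c(d6$start_rel, d6$end_rel), c(1L, 6L))
  s <- parse_notation(c(deletion = "", insertion = "", mismatch = "T-817C"))
  expect_identical(s$kind, "sub")
  expect_equal(s$start_rel, -817L)
  expect_identical(c(s$ref, s$seq), c("T", "C"))
  i1 <- parse_notation(c(deletion = "", insertion = "72 bp (-1 - +1)",
                         mismatch = ""))
  expect_identical(i1$kind, "ins")
  i2 <- parse_notation(c(deletion = "", insertion = "88 bp (-1 - +4)",
                         mismatch = ""))
  expect_identical(i2$kind, "delins")   # non-adjacent flanks imply replacement

  # random calls round-trip through text
  for (i in 1:100) {
    fr <- random_frame(300, 150)
    ref <- fr$reference
    kind <- sample(c("del", "ins", "sub"), 1)
    at <- sample(80:220, 1)
    len <- sample(1:20, 1)
    mut <- switch(kind,
      del = paste0(substr(ref, 1, at), substr(ref, at + len + 1, 300)),
      ins = paste0(substr(ref, 1, at), oracle_dna(len), substr(ref, at + 1, 300)),
      sub = { m <- ref
              b <- substr(m, at, at)
              substr(m, at, at) <- setdiff(c("A", "C", "G", "T"), b)[1]
              m })
    cl <- call_edit(fr, mut)
    back <- parse_notation(cl$notation)
    cols <- c("kind", "length", "start_rel", "end_rel")
    expect_identical(back[cols], cl$segments[cols])
    rebuilt <- structure(list(segments = cl$segments), class = "edit_call")
    expect_identical(format_notation(rebuilt), cl$notation)
  }
})
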