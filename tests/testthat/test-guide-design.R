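test_that("minimal 23-nt target yields exactly one candidate per orientation", {
  s <- "ACGTACGTACGTACGTACGTAGG"
  g <- as_genome(c(c1 = s))
  gs <- enumerate_guides(g, genomic_interval("c1", 0, 23))
  expect_equal(nrow(gs), 1L)
  expect_identical(gs$spacer, substr(s, 1, 20))
  expect_identical(gs$strand, "+")
  expect_equal(gs$cut_genomic, 17L)

  g2 <- as_genome(c(c1 = oracle_revcomp(s)))
  gs2 <- enumerate_guides(g2, genomic_interval("c1", 0, 23))
  expect_equal(nrow(gs2), 1L)
  expect_identical(gs2$strand, "-")
  expect_identical(gs2$spacer, substr(s, 1, 20))
  expect_equal(gs2$start, 3L)
  expect_equal(gs2$cut_genomic, 5L)

  expect_error(enumerate_guides(g, genomic_interval("c1", 0, 22)), "23")
})

test_that("enumeration equals the position-by-position regex oracle", {
  set.seed(41)
  contig <- oracle_dna(2000)
  g <- as_genome(c(chr = contig))
  gs <- enumerate_guides(g, genomic_interval("chr", 0, 2000))
  want <- oracle_guide_scan(contig)
  got <- as.data.frame(gs)[order(gs$start, gs$strand),
                           c("start", "strand", "spacer", "pam")]
  rownames(got) <- rownames(want) <- NULL
  expect_identical(got, want)
  # every candidate's cut sits 3 bp 5' of its PAM along the protospacer
  expect_true(all(ifelse(gs$strand == "+", gs$end - gs$cut_genomic,
                         gs$cut_genomic - gs$start + 1L) == 3L))
})

test_that("candidates containing N are dropped", {
  s <- paste0("ACGTACGTACGTACGTACGTAGG", "NCGTACGTACGTACGTACGTAGG")
  gs <- enumerate_guides(as_genome(c(c1 = s)), genomic_interval("c1", 0, nchar(s)))
  expect_false(any(grepl("N", gs$spacer)))
  expect_false(any(grepl("N", gs$pam)))
})

test_that("a spacer planted once is clean; a 2-mismatch copy is reported", {
  set.seed(42)
  backbone <- oracle_dna(50000)
  spacer <- oracle_dna(20)
  site <- paste0(spacer, "TGG")
  mm2 <- spacer
  substr(mm2, 5, 5) <- if (substr(mm2, 5, 5) == "A") "C" else "A"
  substr(mm2, 15, 15) <- if (substr(mm2, 15, 15) == "G") "T" else "G"
  g1 <- as_genome(c(chr = paste0(substr(backbone, 1, 10000), site,
                                 substr(backbone, 10024, 50000))))
  gs <- enumerate_guides(g1, genomic_interval("chr", 10000, 10023))
  gs <- gs[gs$start == 10000 & gs$strand == "+", ]
  sc <- scan_offtargets(g1, gs)
  # clean unless the random backbone happens to contain a near match --
  # verify against the oracle either way
  want <- oracle_offtarget_scan(g1[["chr"]], spacer, 3)
  expect_equal(sc$n_offtargets, nrow(want) - 1L)

  g2 <- as_genome(c(chr = paste0(substr(g1[["chr"]], 1, 30000),
                                 mm2, "AGG",
                                 substr(g1[["chr"]], 30024, 50000))))
  gs2 <- scan_offtargets(g2, gs)
  ot <- gs2$offtargets[[1]]
  expect_true(any(ot$start == 30000 & ot$mismatches == 2L))
})

test_that("off-target scan equals the brute-force Hamming oracle", {
  set.seed(43)
  for (i in 1:5) {
    spacer <- oracle_dna(20)
    # plant 0-3 mutated PAM-adjacent copies per contig at known offsets
    plant <- function(backbone) {
      for (k in seq_len(sample(0:3, 1))) {
        b <- strsplit(spacer, "", fixed = TRUE)[[1]]
        for (p in sample(20, sample(0:3, 1)))
          b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
        copy <- paste0(paste(b, collapse = ""), sample(c("TGG", "AGG"), 1))
        if (sample(c(TRUE, FALSE), 1)) copy <- oracle_revcomp(copy)
        at <- sample(nchar(backbone) - 5000, 1) + 1000
        substr(backbone, at, at + 22) <- copy
      }
      backbone
    }
    g <- as_genome(c(chrA = plant(oracle_dna(15000)),
                     chrB = plant(oracle_dna(8000))))
    gs <- new_guides_for_test(spacer)
    sc <- scan_offtargets(g, gs, max_mismatches = 3)
    ot <- sc$offtargets[[1]]
    want <- do.call(rbind, lapply(names(g), function(ct) {
      o <- oracle_offtarget_scan(g[[ct]], spacer, 3)
      if (nrow(o) == 0) NULL else cbind(contig = ct, o,
                                        stringsAsFactors = FALSE)
    }))
    if (is.null(want))
      want <- data.frame(contig = character(0), start = integer(0),
                         strand = character(0), mismatches = integer(0),
                         stringsAsFactors = FALSE)
    want <- want[order(want$contig, want$start, want$strand), , drop = FALSE]
    got <- ot[order(ot$contig, ot$start, ot$strand),
              c("contig", "start", "strand", "mismatches")]
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
    # stored mismatch counts recomputed independently
    for (j in seq_len(nrow(ot))) {
      site <- oracle_extract(g[[ot$contig[j]]], ot$start[j], ot$end[j],
                             ot$strand[j])
      expect_equal(sum(strsplit(site, "")[[1]] != strsplit(spacer, "")[[1]]),
                   ot$mismatches[j])
    }
  }
})

test_that("NAG PAMs are flagged only when the pam_rule allows them", {
  set.seed(44)
  spacer <- oracle_dna(20)
  g <- as_genome(c(chr = paste0(oracle_dna(500), spacer, "TAG",
                                oracle_dna(500))))
  gs <- new_guides_for_test(spacer)
  expect_equal(scan_offtargets(g, gs, pam_rule = "NGG")$n_offtargets, 0L)
  sc <- scan_offtargets(g, gs, pam_rule = c("NGG", "NAG"))
  expect_equal(sc$n_offtargets, 1L)
  expect_identical(sc$offtargets[[1]]$pam, "TAG")
})

test_that("ranking puts clean guides first, then anchor distance, then 5' coord", {
  gs <- new_guide_set_manual(
    spacer = c("A", "B", "C", "D"),
    start = c(100L, 50L, 200L, 60L),
    clean = c(FALSE, TRUE, TRUE, TRUE),
    cut_genomic = c(117L, 67L, 217L, 77L))
  r <- rank_guides(gs, anchor = 220L)
  expect_identical(r$spacer, c("C", "D", "B", "A"))
  # equidistant clean candidates: 5'-most first
  gs2 <- new_guide_set_manual(spacer = c("X", "Y"), start = c(300L, 100L),
                              clean = c(TRUE, TRUE),
                              cut_genomic = c(317L, 117L))
  r2 <- rank_guides(gs2, anchor = 217L)
  expect_identical(r2$spacer, c("Y", "X"))
  expect_error(rank_guides(new_guide_set_manual("Z", 1L, NA, 18L)), "scanned")
})
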