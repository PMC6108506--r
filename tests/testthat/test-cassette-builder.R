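test_that("cassette is the exact concatenation promoter+spacer+scaffold+terminator", {
  set.seed(51)
  prom <- oracle_dna(172)
  spacer <- oracle_dna(20)
  term <- paste0(oracle_dna(12), "TTTT")
  plan <- build_cassette(prom, spacer, term)
  expect_equal(nchar(plan$full_sequence), 172 + 20 + 80 + 16)
  expect_identical(plan$full_sequence,
                   paste0(prom, spacer, default_scaffold(), term))
  # fusion fragments share exactly the 20-nt spacer
  expect_identical(substr(plan$fragment1, nchar(plan$fragment1) - 19,
                          nchar(plan$fragment1)), spacer)
  expect_identical(substr(plan$fragment2, 1, 20), spacer)
  expect_identical(paste0(plan$fragment1,
                          substr(plan$fragment2, 21, nchar(plan$fragment2))),
                   plan$full_sequence)
})

test_that("cassette inputs are validated", {
  set.seed(52)
  prom <- oracle_dna(172); term <- paste0(oracle_dna(8), "TTTT")
  expect_error(build_cassette(prom, oracle_dna(19), term), "20-nt")
  expect_error(build_cassette(prom, sub("A", "N", oracle_dna(20)), term))
  expect_error(build_cassette(prom, oracle_dna(20), ""), "empty")
  expect_error(build_cassette(prom, oracle_dna(20), term,
                              scaffold = oracle_dna(79)), "80 nt")
  p1 <- structure(list(part_kind = "promoter", source_model_id = "m1",
                       sequence = prom), class = "regulatory_part")
  t2 <- structure(list(part_kind = "terminator", source_model_id = "m2",
                       sequence = term), class = "regulatory_part")
  expect_warning(build_cassette(p1, oracle_dna(20), t2), "own terminator")
})

test_that("primer pairs anneal at fragment ends within the Tm window", {
  set.seed(53)
  plan <- build_cassette(oracle_dna(172), oracle_dna(20),
                         paste0(oracle_dna(10), "TTTTT"))
  for (pr in plan$primers) {
    expect_gte(pr$tm_forward, 55)
    expect_gte(pr$tm_reverse, 55)
    expect_equal(wallace_tm(pr$forward), pr$tm_forward)
  }
  f1 <- plan$fragment1
  pr <- plan$primers$fragment1
  expect_identical(pr$forward, substr(f1, 1, nchar(pr$forward)))
  expect_identical(pr$reverse,
                   revcomp(substr(f1, nchar(f1) - nchar(pr$reverse) + 1,
                                  nchar(f1))))
})

test_that("chew-back simulation matches the linear-scan oracle", {
  cb <- simulate_chewback("TTGATTATA", "dGTP")
  expect_identical(cb$resected, "ATTATA")
  expect_identical(cb$retained_3prime, "TTG")
  expect_true(endsWith(cb$retained_3prime, "G"))
  cb <- simulate_chewback("TTCAAAA", "dCTP")
  expect_identical(cb$resected, "AAAA")
  expect_warning(cb <- simulate_chewback("ATTATA", "dGTP"), "full resection")
  expect_identical(cb$resected, "ATTATA")
  expect_identical(cb$retained_3prime, "")

  set.seed(54)
  for (i in 1:100) {
    s <- oracle_dna(30)
    for (dntp in c("dGTP", "dCTP")) {
      stop_base <- if (dntp == "dGTP") "G" else "C"
      want <- oracle_chewback(s, stop_base)
      got <- suppressWarnings(simulate_chewback(s, dntp))
      expect_identical(got$resected, want$resected)
      expect_identical(got$retained_3prime, want$retained)
      # conservation and stop-base invariants
      expect_identical(paste0(got$retained_3prime, got$resected), s)
      expect_false(grepl(stop_base, got$resected, fixed = TRUE))
      expect_identical(got$overhang, oracle_revcomp(got$resected))
    }
  }
})

test_that("LIC tails give mutually reverse-complementary overhangs", {
  set.seed(55)
  plan <- build_cassette(oracle_dna(172), oracle_dna(20),
                         paste0(oracle_dna(12), "TTTT"))
  plan <- add_lic_tails(plan)
  lic <- plan$lic
  expect_equal(nchar(lic$site), 38L)
  expect_equal(gregexpr("ATTTAAAT", lic$site, fixed = TRUE)[[1]][1], 16L)
  expect_identical(lic$insert_overhang_left, revcomp(lic$vector_overhang_right))
  expect_identical(lic$insert_overhang_right, revcomp(lic$vector_overhang_left))
  expect_gte(nchar(lic$insert_overhang_left), 10L)
  expect_gte(nchar(lic$insert_overhang_right), 10L)
  expect_identical(lic$insert_sequence,
                   paste0(lic$tail5, plan$full_sequence, lic$tail3))

  # malformed LIC sites are refused
  expect_error(add_lic_tails(plan, lic_site = oracle_dna(30)), "38")
  bad <- paste0(strrep("A", 15), "ATTTAAAT", strrep("T", 15))
  expect_error(add_lic_tails(plan, lic_site = bad), "design error|exactly once")
})

test_that("donor template has 600-nt arms and amplicon sizes obey arithmetic", {
  set.seed(56)
  contig <- oracle_dna(6000)
  g <- as_genome(c(chr = contig))
  locus <- genomic_interval("chr", 2000, 4000)          # 2.0-kb gene
  payload <- oracle_dna(2400)                           # 2.4-kb payload
  d <- design_donor(g, locus, payload, flank = 600,
                    screen_primer_offsets = c(700L, 700L))
  expect_equal(nchar(d$upstream_flank), 600L)
  expect_equal(nchar(d$downstream_flank), 600L)
  expect_identical(d$upstream_flank, oracle_extract(contig, 1400, 2000, "+"))
  expect_identical(d$downstream_flank, oracle_extract(contig, 4000, 4600, "+"))
  expect_identical(d$full_sequence,
                   paste0(d$upstream_flank, payload, d$downstream_flank))
  # replaced - intact == payload - gene, by coordinate arithmetic
  expect_equal(d$screen_amplicons$replaced_size - d$screen_amplicons$intact_size,
               2400L - 2000L)
  expect_equal(d$screen_amplicons$intact_size, 700L + 2000L + 700L)

  # payload of locus length: identical amplicon sizes
  d2 <- design_donor(g, locus, oracle_dna(2000),
                     screen_primer_offsets = c(700L, 700L))
  expect_equal(d2$screen_amplicons$replaced_size, d2$screen_amplicons$intact_size)

  expect_error(design_donor(g, genomic_interval("chr", 100, 500), payload),
               "insufficient flank")

  # minus-strand locus: arms read on the coding strand
  dm <- design_donor(g, genomic_interval("chr", 2000, 4000, "-"), payload)
  expect_identical(dm$upstream_flank, oracle_extract(contig, 4000, 4600, "-"))
  expect_identical(dm$downstream_flank, oracle_extract(contig, 1400, 2000, "-"))
})
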