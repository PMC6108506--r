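# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals: plain
# character vectors and position-by-position comparisons.

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(x, "", fixed = TRUE)[[1]]]), collapse = "")
}

oracle_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# character-by-character strand-aware slice (0-based half-open input)
oracle_extract <- function(seq, start, end, strand) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  s <- paste(b[(start + 1):end], collapse = "")
  if (strand == "-") oracle_revcomp(s) else s
}

# position-by-position N(20)NGG scan of one sequence (both strands),
# returning 0-based protospacer starts on the forward coordinate system
oracle_guide_scan <- function(seq, spacer_len = 20L) {
  scan <- function(s, strand, L) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    out <- NULL
    for (i in seq_len(length(b) - spacer_len - 2)) {
      pam <- b[(i + spacer_len):(i + spacer_len + 2)]
      sp <- b[i:(i + spacer_len - 1)]
      if (pam[2] == "G" && pam[3] == "G" && !any(c(sp, pam) == "N")) {
        start0 <- if (strand == "+") i - 1L else L - (i - 1L) - spacer_len
        out <- rbind(out, data.frame(
          start = start0, strand = strand,
          spacer = paste(sp, collapse = ""), pam = paste(pam, collapse = ""),
          stringsAsFactors = FALSE))
      }
    }
    out
  }
  L <- nchar(seq)
  out <- rbind(scan(seq, "+", L), scan(oracle_revcomp(seq), "-", L))
  if (is.null(out)) data.frame(start = integer(0), strand = character(0),
                               spacer = character(0), pam = character(0))
  else out[order(out$start, out$strand), , drop = FALSE]
}

# exhaustive Hamming scan for PAM-adjacent near-matches of a spacer
# (vectorized per offset, but still a direct position-by-position count)
oracle_offtarget_scan <- function(seq, spacer, max_mm, pam_rule = "NGG") {
  k <- nchar(spacer)
  sp <- strsplit(spacer, "", fixed = TRUE)[[1]]
  pam2 <- substr(pam_rule, 2, 2)
  scan <- function(s, strand, L) {
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    npos <- length(b) - k - 2
    if (npos < 1) return(NULL)
    mm <- integer(npos)
    for (j in seq_len(k)) mm <- mm + (b[seq_len(npos) + j - 1] != sp[j])
    pam_ok <- (b[seq_len(npos) + k + 1] == pam2 | pam2 == "N") &
      b[seq_len(npos) + k + 2] == "G"
    hit <- which(mm <= max_mm & pam_ok)
    if (!length(hit)) return(NULL)
    start0 <- if (strand == "+") hit - 1L else L - (hit - 1L) - k
    data.frame(start = start0, strand = strand, mismatches = mm[hit],
               stringsAsFactors = FALSE)
  }
  L <- nchar(seq)
  out <- rbind(scan(seq, "+", L), scan(oracle_revcomp(seq), "-", L))
  if (is.null(out)) data.frame(start = integer(0), strand = character(0),
                               mismatches = integer(0))
  else out[order(out$start, out$strand), , drop = FALSE]
}

# linear 3'->5' scan for the chew-back stop base
oracle_chewback <- function(seq, stop_base) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  i <- length(b)
  while (i >= 1 && b[i] != stop_base) i <- i - 1
  list(resected = if (i == length(b)) "" else paste(b[(i + 1):length(b)], collapse = ""),
       retained = if (i < 1) "" else paste(b[1:i], collapse = ""))
}

# first run of >= min_run consecutive T in a string; returns the 1-based end
# of the run, or NA
oracle_polyT_end <- function(seq, min_run = 4) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  run <- 0
  for (i in seq_along(b)) {
    run <- if (b[i] == "T") run + 1 else 0
    if (run >= min_run) {
      j <- i
      while (j < length(b) && b[j + 1] == "T") j <- j + 1
      return(j)
    }
  }
  NA_integer_
}

# standard genetic code lookup for the anticodon oracle
oracle_codon_table <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

# a small shared fixture bundle, built once per test run
fixture_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_genome(fixture_spec(seed = 42L))
    cache
  }
})

# hand-built guide-set rows for tests that bypass enumerate_guides()
new_guides_for_test <- function(spacer, contig = "nowhere", start = -100L) {
  df <- data.frame(spacer = spacer, pam = "TGG", contig = contig,
                   start = start, end = start + 20L, strand = "+",
                   cut_genomic = start + 17L, clean = NA,
                   n_offtargets = NA_integer_, stringsAsFactors = FALSE)
  df$offtargets <- list(NULL)
  class(df) <- c("guide_set", "data.frame")
  df
}

new_guide_set_manual <- function(spacer, start, clean, cut_genomic) {
  df <- data.frame(spacer = spacer, pam = "AGG", contig = "chr",
                   start = start, end = start + 20L, strand = "+",
                   cut_genomic = cut_genomic, clean = clean,
                   n_offtargets = ifelse(is.na(clean), NA_integer_,
                                         as.integer(!clean)),
                   stringsAsFactors = FALSE)
  df$offtargets <- replicate(nrow(df), NULL, simplify = FALSE)
  class(df) <- c("guide_set", "data.frame")
  df
}
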