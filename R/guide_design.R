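# Guide design: protospacer enumeration and genome-wide off-target scanning.
#
# A guide candidate is a 20-nt protospacer immediately 5' of an NGG PAM, on
# either strand. The Cas9 blunt cut falls 3 bp 5' of the PAM; `cut_genomic`
# records the 0-based genomic coordinate of the protospacer base immediately
# 3' of the scissile phosphate (the base 17 positions from the spacer 5' end).

guide_cols <- c("spacer", "pam", "contig", "start", "end", "strand",
                "cut_genomic", "clean", "n_offtargets")

new_guide_set <- function(df, offtargets = NULL) {
  if (is.null(offtargets)) offtargets <- replicate(nrow(df), NULL, simplify = FALSE)
  df <- df[, guide_cols, drop = FALSE]
  df$offtargets <- offtargets
  rownames(df) <- NULL
  class(df) <- c("guide_set", "data.frame")
  df
}

#' @export
print.guide_set <- function(x, ...) {
  cat("guide set:", nrow(x), "candidate(s)\n")
  if (nrow(x))
    print(utils::head(as.data.frame(x)[, guide_cols], 12L))
  invisible(x)
}

pam_regex <- function(pam_rule) {
  # NGG / NAG -> regex character class on the 2nd/3rd base
  pats <- vapply(pam_rule, function(p) {
    p <- toupper(p)
    stopifnot(nchar(p) == 3L)
    paste0(chartr("N", ".", substr(p, 1, 1)),
           chartr("N", ".", substr(p, 2, 2)),
           chartr("N", ".", substr(p, 3, 3)))
  }, character(1))
  paste0("(", paste(pats, collapse = "|"), ")")
}

matches_pam <- function(seqs, pam_rule) {
  grepl(paste0("^", pam_regex(pam_rule), "$"), seqs)
}

#' Enumerate guide candidates in a target region
#'
#' Reports every position, on both strands, where a `spacer_len`-mer lies
#' immediately 5' of an NGG PAM with spacer and PAM fully inside the target
#' interval. Candidates containing N are dropped.
#'
#' @param genome a `genome`.
#' @param target_interval a `genomic_interval` (width >= `spacer_len + 3`).
#' @param spacer_len spacer length (default 20).
#' @return a `guide_set` data.frame; `start`/`end` delimit the protospacer
#'   only (PAM excluded), 0-based half-open.
#' @export
enumerate_guides <- function(genome, target_interval, spacer_len = 20L) {
  genome <- as_genome(genome)
  stopifnot(inherits(target_interval, "genomic_interval"))
  if (interval_width(target_interval) < spacer_len + 3L)
    stop("target interval must be at least ", spacer_len + 3L, " nt wide")
  t0 <- target_interval$start
  fwd <- extract_seq(genome, genomic_interval(target_interval$contig, t0,
                                              target_interval$end, "+"))
  L <- nchar(fwd)
  scan_one <- function(seq) {
    # PAM start positions p (1-based) with a full spacer 5' of the PAM
    hits <- gregexpr("(?=[ACGTN]GG)", seq, perl = TRUE)[[1]]
    p <- hits[hits != -1L]
    p <- p[p >= spacer_len + 1L & p + 2L <= nchar(seq)]
    if (!length(p)) return(NULL)
    spacer <- substring(seq, p - spacer_len, p - 1L)
    pam <- substring(seq, p, p + 2L)
    ok <- !grepl("N", paste0(spacer, pam), fixed = TRUE)
    data.frame(p = p[ok], spacer = spacer[ok], pam = pam[ok],
               stringsAsFactors = FALSE)
  }
  rows <- list()
  f <- scan_one(fwd)
  if (!is.null(f) && nrow(f)) {
    start0 <- t0 + f$p - spacer_len - 1L
    rows[[1]] <- data.frame(spacer = f$spacer, pam = f$pam,
                            contig = target_interval$contig,
                            start = start0, end = start0 + spacer_len,
                            strand = "+", cut_genomic = start0 + 17L,
                            clean = NA, n_offtargets = NA_integer_,
                            stringsAsFactors = FALSE)
  }
  r <- scan_one(revcomp(fwd))
  if (!is.null(r) && nrow(r)) {
    # revcomp index i (1-based) maps to genomic 0-based t0 + L - i; the
    # protospacer's 3'-most rc index (p - 1) is its smallest genomic coord
    start0 <- t0 + L - r$p + 1L
    rows[[2]] <- data.frame(spacer = r$spacer, pam = r$pam,
                            contig = target_interval$contig,
                            start = start0, end = start0 + spacer_len,
                            strand = "-", cut_genomic = start0 + spacer_len - 18L,
                            clean = NA, n_offtargets = NA_integer_,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(spacer = character(0), pam = character(0),
                      contig = character(0), start = integer(0), end = integer(0),
                      strand = character(0), cut_genomic = integer(0),
                      clean = logical(0), n_offtargets = integer(0),
                      stringsAsFactors = FALSE)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  new_guide_set(out)
}

# all mismatch-bounded, PAM-adjacent sites of one spacer in one genome;
# returns a data.frame (contig, start, end, strand, mismatches, pam)
find_sites <- function(genome, spacer, max_mismatches, pam_rule) {
  genome <- as_genome(genome)
  k <- nchar(spacer)
  res <- list()
  for (ct in names(genome)) {
    seq <- genome[[ct]]; L <- nchar(seq)
    for (std in c("+", "-")) {
      subj <- if (std == "+") seq else revcomp(seq)
      m <- Biostrings::matchPattern(Biostrings::DNAString(spacer),
                                    Biostrings::DNAString(subj),
                                    max.mismatch = max_mismatches,
                                    with.indels = FALSE)
      st <- BiocGenerics::start(m)
      st <- st[st >= 1L & st + k + 2L <= L]
      if (!length(st)) next
      pam <- substring(subj, st + k, st + k + 2L)
      keep <- matches_pam(pam, pam_rule)
      st <- st[keep]; pam <- pam[keep]
      if (!length(st)) next
      site <- substring(subj, st, st + k - 1L)
      mm <- vapply(site, function(s) hamming(spacer, s), integer(1))
      drop_n <- grepl("N", paste0(site, pam), fixed = TRUE)
      st <- st[!drop_n]; pam <- pam[!drop_n]; mm <- mm[!drop_n]
      if (!length(st)) next
      if (std == "+") {
        start0 <- st - 1L
      } else {
        start0 <- L - (st + k - 1L)
      }
      res[[length(res) + 1L]] <- data.frame(
        contig = ct, start = start0, end = start0 + k, strand = std,
        mismatches = unname(mm), pam = pam, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(contig = character(0), start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      pam = character(0), stringsAsFactors = FALSE)
  out[order(out$contig, out$start, out$strand), , drop = FALSE]
}

#' Scan the genome for off-target sites of guide candidates
#'
#' Reports every genomic 20-mer adjacent to a PAM (per `pam_rule`) whose
#' Hamming distance to the spacer is at most `max_mismatches`, on both
#' strands, excluding each candidate's intended locus. A candidate is marked
#' `clean` iff its off-target list is empty.
#'
#' @param genome a `genome`.
#' @param guides a `guide_set` (or one row of one).
#' @param max_mismatches maximum Hamming distance (default 3).
#' @param pam_rule character vector of PAM patterns, e.g. `"NGG"` or
#'   `c("NGG", "NAG")`.
#' @return the `guide_set` with `offtargets`, `n_offtargets` and `clean`
#'   populated.
#' @export
scan_offtargets <- function(genome, guides, max_mismatches = 3L,
                            pam_rule = "NGG") {
  genome <- as_genome(genome)
  ot_list <- vector("list", nrow(guides))
  for (i in seq_len(nrow(guides))) {
    sites <- find_sites(genome, guides$spacer[i], max_mismatches, pam_rule)
    own <- sites$contig == guides$contig[i] & sites$start == guides$start[i] &
      sites$strand == guides$strand[i]
    ot_list[[i]] <- sites[!own, , drop = FALSE]
  }
  guides$offtargets <- ot_list
  guides$n_offtargets <- vapply(ot_list, nrow, integer(1))
  guides$clean <- guides$n_offtargets == 0L
  guides
}

#' Rank guide candidates
#'
#' Clean candidates come first; ties are broken by distance of the cut site
#' to `anchor` (a genomic coordinate such as a start codon), then by 5'
#' (smallest start) coordinate.
#'
#' @param guides a scanned `guide_set`.
#' @param anchor optional genomic coordinate (0-based) for the distance
#'   tie-break.
#' @return the reordered `guide_set`.
#' @export
rank_guides <- function(guides, anchor = NULL) {
  if (any(is.na(guides$clean)))
    stop("guides must be scanned with scan_offtargets() before ranking")
  d <- if (is.null(anchor)) rep(0L, nrow(guides))
  else abs(guides$cut_genomic - anchor)
  o <- order(!guides$clean, d, guides$start)
  out <- guides[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write off-target sites of a guide set as BED
#' @param guides a scanned `guide_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
offtargets_to_bed <- function(guides, path) {
  rows <- lapply(seq_len(nrow(guides)), function(i) {
    ot <- guides$offtargets[[i]]
    if (is.null(ot) || nrow(ot) == 0L) return(NULL)
    data.frame(chrom = ot$contig, chromStart = ot$start, chromEnd = ot$end,
               name = sprintf("%s_mm%d", guides$spacer[i], ot$mismatches),
               score = ot$mismatches, strand = ot$strand,
               stringsAsFactors = FALSE)
  })
  bed <- do.call(rbind, rows)
  if (is.null(bed)) bed <- data.frame()
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
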