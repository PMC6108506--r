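# Cassette builder: gRNA expression cassette assembly and construction
# planning (fusion-PCR fragments, primers, LIC tails, chew-back simulation,
# donor templates).
#
# Cassette anatomy: promoter (tRNA gene + upstream pad) . 20-nt spacer .
# 80-nt tracrRNA scaffold . poly-T terminator, as one exact concatenation.
# Physically the cassette is made by fusion PCR of two fragments overlapping
# in the spacer: fragment1 = promoter + spacer, fragment2 = spacer +
# scaffold + terminator.

#' Default 80-nt tracrRNA scaffold (DNA sense)
#'
#' The standard S. pyogenes sgRNA scaffold sequence, trimmed/padded to
#' exactly 80 nt. This is a replaceable configuration constant: supply your
#' own 80-nt scaffold to [build_cassette()] to override it.
#'
#' @return character scalar of length 80.
#' @export
default_scaffold <- function() {
  paste0("GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCAACTTGAAAAAGT",
         "GGCACCGAGTCGGTGCTTTT")
}

#' Wallace-rule melting temperature
#'
#' `Tm = 2(A+T) + 4(G+C)` in degrees C; the simple rule used for short
#' oligonucleotide annealing regions.
#'
#' @param seq DNA character scalar.
#' @return numeric Tm in degrees C.
#' @export
wallace_tm <- function(seq) {
  b <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C"))
}

# grow a primer from a template end until Tm enters the window
design_one_primer <- function(template, tm_range, min_len = 15L, max_len = 35L) {
  L <- nchar(template)
  k <- min_len
  while (k < min(max_len, L) && wallace_tm(substr(template, 1L, k)) < tm_range[1])
    k <- k + 1L
  list(seq = substr(template, 1L, k), tm = wallace_tm(substr(template, 1L, k)),
       len = k)
}

#' Design a forward/reverse primer pair for a template
#'
#' Primers anneal at the template ends; the reverse primer is the reverse
#' complement of the template's 3' span. Lengths grow from 15 nt until the
#' Wallace-rule Tm reaches the lower edge of `tm_range`.
#'
#' @param template DNA character scalar.
#' @param tm_range numeric length-2 Tm window in degrees C (default 55-65).
#' @return object of class `primer_pair` with `forward`, `reverse`,
#'   `tm_forward`, `tm_reverse` and template-relative 0-based half-open
#'   annealing spans.
#' @export
design_primers <- function(template, tm_range = c(55, 65)) {
  stopifnot(nchar(template) >= 30L)
  f <- design_one_primer(template, tm_range)
  r <- design_one_primer(revcomp(template), tm_range)
  structure(list(forward = f$seq, reverse = r$seq,
                 tm_forward = f$tm, tm_reverse = r$tm,
                 anneal_forward = c(0L, f$len),
                 anneal_reverse = c(nchar(template) - r$len, nchar(template))),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("fwd %s (Tm %.0f C)\nrev %s (Tm %.0f C)\n",
              x$forward, x$tm_forward, x$reverse, x$tm_reverse))
  invisible(x)
}

part_seq <- function(x) {
  if (inherits(x, "regulatory_part")) x$sequence else as.character(x)
}
part_id <- function(x) {
  if (inherits(x, "regulatory_part")) x$source_model_id else NA_character_
}

#' Assemble a gRNA expression cassette
#'
#' Builds the full cassette sequence `promoter + spacer + scaffold +
#' terminator` and the two fusion-PCR fragments that share exactly the 20-nt
#' spacer as overlap, with annealing primers for each fragment.
#'
#' @param promoter a promoter `regulatory_part` (or raw DNA text).
#' @param spacer 20-nt guide sequence (ACGT).
#' @param terminator a terminator `regulatory_part` (or raw DNA text).
#' @param scaffold 80-nt tracrRNA scaffold DNA (default [default_scaffold()]).
#' @param tm_range primer Tm window (degrees C).
#' @return object of class `cassette_plan`.
#' @export
build_cassette <- function(promoter, spacer, terminator,
                           scaffold = default_scaffold(),
                           tm_range = c(55, 65)) {
  prom <- toupper(part_seq(promoter)); term <- toupper(part_seq(terminator))
  spacer <- toupper(spacer); scaffold <- toupper(scaffold)
  if (nchar(spacer) != 20L || !is_dna(spacer))
    stop("spacer must be a 20-nt sequence over ACGT")
  if (nchar(scaffold) != 80L)
    stop("scaffold must be exactly 80 nt (got ", nchar(scaffold), ")")
  if (!is_dna(scaffold)) stop("scaffold must be DNA over ACGT")
  if (!nzchar(term)) stop("terminator sequence is empty")
  if (!is_dna(prom) || !is_dna(term))
    stop("promoter/terminator must be DNA over ACGT (no N)")
  pid <- part_id(promoter); tid <- part_id(terminator)
  if (!is.na(pid) && !is.na(tid) && pid != tid)
    warning("terminator (", tid, ") is not from the promoter's model (", pid,
            "); promoters are normally paired with their own terminators")
  fragment1 <- paste0(prom, spacer)
  fragment2 <- paste0(spacer, scaffold, term)
  full <- paste0(prom, spacer, scaffold, term)
  structure(list(promoter = promoter, spacer = spacer, scaffold = scaffold,
                 terminator = terminator, full_sequence = full,
                 fragment1 = fragment1, fragment2 = fragment2,
                 primers = list(fragment1 = design_primers(fragment1, tm_range),
                                fragment2 = design_primers(fragment2, tm_range)),
                 lic = NULL),
            class = "cassette_plan")
}

#' @export
print.cassette_plan <- function(x, ...) {
  cat("gRNA cassette plan\n")
  cat(sprintf("  promoter   %4d nt (%s)\n", nchar(part_seq(x$promoter)),
              part_id(x$promoter)))
  cat(sprintf("  spacer     %4d nt  %s\n", nchar(x$spacer), x$spacer))
  cat(sprintf("  scaffold   %4d nt\n", nchar(x$scaffold)))
  cat(sprintf("  terminator %4d nt (%s)\n", nchar(part_seq(x$terminator)),
              part_id(x$terminator)))
  cat(sprintf("  full cassette %d nt; fragments %d + %d nt (20-nt overlap)\n",
              nchar(x$full_sequence), nchar(x$fragment1), nchar(x$fragment2)))
  if (!is.null(x$lic))
    cat(sprintf("  LIC tails added: insert %d nt, overhangs %d/%d nt\n",
                nchar(x$lic$insert_sequence),
                nchar(x$lic$insert_overhang_left),
                nchar(x$lic$insert_overhang_right)))
  invisible(x)
}

#' Simulate T4 DNA polymerase 3'->5' chew-back
#'
#' In the presence of a single dNTP, T4 DNA polymerase's 3'->5' exonuclease
#' resects a 3' end until it reaches the first base whose partner nucleotide
#' is supplied: the first G (dGTP) or the first C (dCTP), which is retained.
#' The removed span leaves the partner strand single-stranded -- the LIC 5'
#' overhang.
#'
#' @param strand_3prime_context the 3'-terminal sequence of one strand,
#'   written 5'->3'.
#' @param dNTP `"dGTP"` or `"dCTP"`.
#' @return object of class `overhang_result` with `resected` (removed 3'
#'   span, 5'->3'), `retained_3prime`, and `overhang` (the complementary
#'   single-stranded 5' extension exposed on the partner strand, 5'->3').
#' @export
simulate_chewback <- function(strand_3prime_context, dNTP = c("dGTP", "dCTP")) {
  dNTP <- match.arg(dNTP)
  seq <- toupper(strand_3prime_context)
  stopifnot(is_dna(seq, allow_n = FALSE))
  stop_base <- if (dNTP == "dGTP") "G" else "C"
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  hits <- which(b == stop_base)
  if (!length(hits)) {
    warning("no ", stop_base, " in sequence: full resection")
    pos <- 0L
  } else pos <- max(hits)
  resected <- substr(seq, pos + 1L, nchar(seq))
  retained <- substr(seq, 1L, pos)
  structure(list(strand_sequence = seq, stop_base = stop_base,
                 resected = resected, retained_3prime = retained,
                 overhang = revcomp(resected)),
            class = "overhang_result")
}

#' Default 38-bp LIC site with central SwaI recognition sequence
#'
#' A 38-bp ligation-independent-cloning site with the blunt-cutting SwaI
#' site (`ATTTAAAT`) centered. The halves are built so that dGTP chew-back of
#' the SwaI-linearized vector exposes 18-nt 5' overhangs on both ends: the 5'
#' half has its only G at its first position and the 3' half its only C at
#' its last position.
#'
#' @return character scalar of length 38.
#' @export
default_lic_site <- function() {
  paste0("GATCTTACTATTCTA", "ATTTAAAT", "TAGATTAGTTAGATC")
}

#' Add LIC tails to a cassette and verify overhang complementarity
#'
#' Plans LIC cloning of the cassette into a vector carrying `lic_site`:
#' simulates SwaI linearization of the vector and dGTP chew-back of its two
#' 3' ends, derives insert tail sequences such that dCTP chew-back of the
#' tailed insert exposes 5' overhangs that are exact reverse complements of
#' the vector overhangs at both junctions, and verifies this with
#' [simulate_chewback()].
#'
#' @param cassette a `cassette_plan`.
#' @param lic_site the vector's 38-bp LIC site (SwaI site centered);
#'   default [default_lic_site()].
#' @param min_overhang minimum acceptable overhang length (default 10).
#' @return the `cassette_plan` with `$lic` populated (`tail5`, `tail3`,
#'   `insert_sequence`, the four overhangs and the site itself).
#' @export
add_lic_tails <- function(cassette, lic_site = default_lic_site(),
                          min_overhang = 10L) {
  stopifnot(inherits(cassette, "cassette_plan"))
  lic_site <- toupper(lic_site)
  if (nchar(lic_site) != 38L)
    stop("LIC site must be 38 bp (got ", nchar(lic_site), ")")
  swai <- "ATTTAAAT"
  hits <- gregexpr(swai, lic_site, fixed = TRUE)[[1]]
  if (length(hits) != 1L || hits[1] == -1L)
    stop("LIC site must contain the SwaI site ", swai, " exactly once")
  if (hits[1] != 16L)
    stop("SwaI site must be centered in the 38-bp LIC site (expected at ",
         "position 16, found at ", hits[1], ")")
  half5 <- substr(lic_site, 1L, 15L)
  half3 <- substr(lic_site, 24L, 38L)

  # SwaI cuts bluntly in the middle of ATTTAAAT; on the linearized vector the
  # two 3' ends are (top strand) ...half5+ATTT and (bottom strand)
  # revcomp(AAAT+half3...). dGTP chew-back resects both.
  cb_right <- withCallingHandlers(
    simulate_chewback(paste0(half5, "ATTT"), "dGTP"),
    warning = function(w) invokeRestart("muffleWarning"))
  cb_left <- withCallingHandlers(
    simulate_chewback(revcomp(paste0("AAAT", half3)), "dGTP"),
    warning = function(w) invokeRestart("muffleWarning"))
  if (!nzchar(cb_right$retained_3prime) || !nzchar(cb_left$retained_3prime))
    stop("design error: LIC site halves must each contain a chew-back stop ",
         "base (G in the 5' half, C in the 3' half)")
  vector_overhang_right <- cb_right$overhang        # ss 5' ext on bottom strand
  vector_overhang_left <- revcomp(cb_left$resected) # ss 5' ext on top strand
  if (nchar(cb_right$resected) < min_overhang ||
      nchar(cb_left$resected) < min_overhang)
    stop("design error: LIC chew-back overhang shorter than ", min_overhang,
         " nt; place the stop bases further from the SwaI site")

  # Insert tails: the insert top strand must start with the span removed from
  # the vector top strand (then a G to stop the dCTP chew on the bottom
  # strand) and end with a C followed by the vector's left top-strand
  # overhang (C stops the dCTP chew on the top strand).
  tail5 <- paste0(cb_right$resected, "G")
  tail3 <- paste0("C", vector_overhang_left)
  insert <- paste0(tail5, cassette$full_sequence, tail3)

  chew_top <- simulate_chewback(insert, "dCTP")
  chew_bottom <- simulate_chewback(revcomp(insert), "dCTP")
  insert_overhang_left <- chew_bottom$overhang   # ss 5' ext on insert top strand
  insert_overhang_right <- chew_top$overhang     # ss 5' ext on insert bottom strand
  if (!identical(insert_overhang_left, revcomp(vector_overhang_right)) ||
      !identical(insert_overhang_right, revcomp(vector_overhang_left)))
    stop("design error: chewed insert/vector overhangs are not ",
         "complementary; check the LIC site and cassette ends")

  cassette$lic <- list(site = lic_site, tail5 = tail5, tail3 = tail3,
                       insert_sequence = insert,
                       vector_overhang_left = vector_overhang_left,
                       vector_overhang_right = vector_overhang_right,
                       insert_overhang_left = insert_overhang_left,
                       insert_overhang_right = insert_overhang_right)
  cassette
}

#' Design a gene-replacement donor template
#'
#' Extracts homology arms flanking a locus (default 600 nt each, on the
#' locus's coding strand) and assembles `upstream + payload + downstream`.
#' When screening-primer offsets are supplied, computes the expected PCR
#' amplicon sizes for a replaced versus intact locus.
#'
#' @param genome a `genome`.
#' @param locus_interval `genomic_interval` of the coding region to replace.
#' @param payload DNA text to knock in.
#' @param flank homology-arm length in nt (default 600).
#' @param screen_primer_offsets optional integer length-2: distances of the
#'   screening primers outside the locus boundaries (upstream, downstream).
#' @return object of class `donor_template`; `screen_amplicons` holds
#'   `replaced_size` and `intact_size` when offsets were supplied.
#' @export
design_donor <- function(genome, locus_interval, payload, flank = 600L,
                         screen_primer_offsets = NULL) {
  genome <- as_genome(genome)
  stopifnot(inherits(locus_interval, "genomic_interval"))
  payload <- toupper(payload)
  if (!is_dna(payload)) stop("payload must be DNA over ACGT")
  ct <- locus_interval$contig; clen <- nchar(genome[[ct]])
  if (locus_interval$strand == "+") {
    if (locus_interval$start < flank || clen - locus_interval$end < flank)
      stop("insufficient flank: need ", flank, " nt on both sides, have ",
           locus_interval$start, " upstream and ",
           clen - locus_interval$end, " downstream")
    up_iv <- genomic_interval(ct, locus_interval$start - flank,
                              locus_interval$start, "+")
    dn_iv <- genomic_interval(ct, locus_interval$end,
                              locus_interval$end + flank, "+")
  } else {
    if (clen - locus_interval$end < flank || locus_interval$start < flank)
      stop("insufficient flank: need ", flank, " nt on both sides, have ",
           clen - locus_interval$end, " upstream and ",
           locus_interval$start, " downstream")
    up_iv <- genomic_interval(ct, locus_interval$end,
                              locus_interval$end + flank, "-")
    dn_iv <- genomic_interval(ct, locus_interval$start - flank,
                              locus_interval$start, "-")
  }
  up <- extract_seq(genome, up_iv); dn <- extract_seq(genome, dn_iv)
  if (grepl("N", paste0(up, dn), fixed = TRUE))
    stop("homology arm contains N; not synthesizable")
  amplicons <- NULL
  if (!is.null(screen_primer_offsets)) {
    stopifnot(length(screen_primer_offsets) == 2L, all(screen_primer_offsets > 0))
    w <- interval_width(locus_interval)
    amplicons <- list(
      replaced_size = screen_primer_offsets[1] + nchar(payload) +
        screen_primer_offsets[2],
      intact_size = screen_primer_offsets[1] + w + screen_primer_offsets[2])
  }
  structure(list(upstream_flank = up, payload = payload, downstream_flank = dn,
                 full_sequence = paste0(up, payload, dn),
                 locus = locus_interval, flank = as.integer(flank),
                 screen_amplicons = amplicons),
            class = "donor_template")
}

#' @export
print.donor_template <- function(x, ...) {
  cat(sprintf("donor template: %d nt arm + %d nt payload + %d nt arm = %d nt\n",
              nchar(x$upstream_flank), nchar(x$payload),
              nchar(x$downstream_flank), nchar(x$full_sequence)))
  if (!is.null(x$screen_amplicons))
    cat(sprintf("  screening amplicons: replaced %d bp, intact %d bp\n",
                x$screen_amplicons$replaced_size, x$screen_amplicons$intact_size))
  invisible(x)
}
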