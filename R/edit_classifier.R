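# Edit classifier: call Cas9-induced mutations from mutant amplicons in
# cut-site-relative coordinates.
#
# Coordinate convention ("cut frame"): the Cas9 blunt cut sits 3 bp 5' of the
# PAM. Mutation coordinates are relative to the cut and never use a position
# 0: -1 is the base immediately 5' of the scissile phosphate, +1 the base
# immediately 3' of it, read along the protospacer strand. A deletion of the
# three bases immediately 5' of the cut is (-3 - -1); immediately 3',
# (+1 - +3).

#' Cut frame for edit classification
#'
#' @param reference reference amplicon sequence (forward strand, ACGT).
#' @param cut_index 0-based index into `reference` of the scissile phosphate:
#'   the cut lies between forward-strand indices `cut_index - 1` and
#'   `cut_index`.
#' @param orientation strand of the protospacer; coordinates are read 5'->3'
#'   along this strand.
#' @return object of class `cut_frame`.
#' @export
cut_frame <- function(reference, cut_index, orientation = c("+", "-")) {
  orientation <- match.arg(orientation)
  reference <- toupper(reference)
  stopifnot(is_dna(reference))
  cut_index <- as.integer(cut_index)
  if (cut_index < 1L || cut_index > nchar(reference) - 1L)
    stop("cut_index must leave at least one base on each side of the cut")
  structure(list(reference = reference, cut_index = cut_index,
                 orientation = orientation),
            class = "cut_frame")
}

#' Cut frame from a guide landing site
#'
#' Convenience constructor: given where a 20-nt protospacer lands on the
#' reference amplicon, places the cut 3 bp 5' of the PAM.
#'
#' @param reference reference amplicon (forward strand).
#' @param protospacer_start 0-based start of the protospacer on the forward
#'   strand (its 5'-most forward coordinate, PAM excluded).
#' @param strand protospacer strand.
#' @return a `cut_frame`.
#' @export
cut_frame_from_guide <- function(reference, protospacer_start, strand = "+") {
  protospacer_start <- as.integer(protospacer_start)
  ci <- if (strand == "+") protospacer_start + 17L else protospacer_start + 3L
  cut_frame(reference, ci, strand)
}

# relative coordinate of oriented 0-based index i given cut index c:
# i >= c -> i - c + 1 (positive side); i < c -> i - c (negative side)
rel_of_index <- function(i, c) ifelse(i >= c, i - c + 1L, i - c)
index_of_rel <- function(r, c) ifelse(r > 0L, c + r - 1L, c + r)

fmt_rel <- function(r) sprintf("%+d", r)

# positions a < b flank each other directly iff nothing lies between them
rel_adjacent <- function(a, b) (b == a + 1L) || (a == -1L && b == 1L)

orient_frame <- function(frame, mutant) {
  if (frame$orientation == "+") {
    list(ref = frame$reference, mut = toupper(mutant), cut = frame$cut_index)
  } else {
    n <- nchar(frame$reference)
    list(ref = revcomp(frame$reference), mut = revcomp(toupper(mutant)),
         cut = n - frame$cut_index)
  }
}

lcp_len <- function(a, b) {
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  d <- which(a[seq_len(n)] != b[seq_len(n)])
  if (length(d)) d[1L] - 1L else n
}

new_edit_call <- function(call_class, segments, frame = NULL) {
  x <- structure(list(call_class = call_class, segments = segments,
                      frame = frame, insertion_origin = NULL),
                 class = "edit_call")
  x$notation <- format_notation(x)
  x
}

empty_segments <- function() {
  data.frame(kind = character(0), length = integer(0), start_rel = integer(0),
             end_rel = integer(0), seq = character(0), ref = character(0),
             stringsAsFactors = FALSE)
}

segment_row <- function(kind, length, start_rel, end_rel, seq = "", ref = "") {
  data.frame(kind = kind, length = as.integer(length),
             start_rel = as.integer(start_rel), end_rel = as.integer(end_rel),
             seq = seq, ref = ref, stringsAsFactors = FALSE)
}

#' @export
print.edit_call <- function(x, ...) {
  cat("edit call:", x$call_class, "\n")
  nt <- x$notation
  for (k in names(nt)) if (nzchar(nt[[k]])) cat(sprintf("  %-9s %s\n", k, nt[[k]]))
  if (!is.null(x$insertion_origin))
    cat(sprintf("  insertion origin: %s:%d-%d(%s)\n",
                x$insertion_origin$source_name, x$insertion_origin$start + 1L,
                x$insertion_origin$end, x$insertion_origin$strand))
  invisible(x)
}

# choose the deletion representation closest to the cut; ties toward 5'
normalize_deletion <- function(ref_b, s, e, cut) {
  s_min <- s; e_min <- e
  while (s_min > 0L && ref_b[s_min] == ref_b[e_min]) { s_min <- s_min - 1L; e_min <- e_min - 1L }
  s_max <- s; e_max <- e
  n <- length(ref_b)
  while (e_max < n && ref_b[e_max + 1L] == ref_b[s_max + 1L]) { s_max <- s_max + 1L; e_max <- e_max + 1L }
  cands <- seq.int(s_min, s_max)
  score <- abs(rel_of_index(cands, cut))
  best <- cands[order(score, cands)][1L]
  c(best, best + (e - s))
}

# choose the insertion point closest to the cut; ties toward 5'
normalize_insertion <- function(ref_b, q, ins, cut) {
  L <- length(strsplit(ins, "", fixed = TRUE)[[1]])
  ib <- strsplit(ins, "", fixed = TRUE)[[1]]
  reps <- list(list(q = q, ins = ins))
  qq <- q; bb <- ib
  while (qq > 0L && ref_b[qq] == bb[L]) {
    bb <- c(bb[L], bb[-L]); qq <- qq - 1L
    reps[[length(reps) + 1L]] <- list(q = qq, ins = paste(bb, collapse = ""))
  }
  qq <- q; bb <- ib
  while (qq < length(ref_b) && ref_b[qq + 1L] == bb[1L]) {
    bb <- c(bb[-1L], ref_b[qq + 1L]); qq <- qq + 1L
    reps[[length(reps) + 1L]] <- list(q = qq, ins = paste(bb, collapse = ""))
  }
  score <- vapply(reps, function(r) {
    if (r$q == cut) 0L
    else min(abs(rel_of_index(r$q - 1L, cut)), abs(rel_of_index(r$q, cut)))
  }, integer(1))
  qs <- vapply(reps, `[[`, integer(1), "q")
  reps[[order(score, qs)[1L]]]
}

# parse a global alignment into raw (kind, ref-span, seqs) runs
alignment_runs <- function(pa, su, ref_offset) {
  a <- strsplit(pa, "", fixed = TRUE)[[1]]
  b <- strsplit(su, "", fixed = TRUE)[[1]]
  kind <- ifelse(a == "-", "ins", ifelse(b == "-", "del",
                 ifelse(a == b, "match", "sub")))
  r <- rle(kind)
  runs <- list(); pos <- 1L; ri <- ref_offset   # ri: 0-based ref index before run
  for (j in seq_along(r$lengths)) {
    len <- r$lengths[j]; k <- r$values[j]
    idx <- seq.int(pos, pos + len - 1L)
    runs[[j]] <- list(kind = k, ref_start = ri,
                      ref_len = if (k == "ins") 0L else len,
                      ref_seq = paste(a[idx][a[idx] != "-"], collapse = ""),
                      mut_seq = paste(b[idx][b[idx] != "-"], collapse = ""))
    if (k != "ins") ri <- ri + len
    pos <- pos + len
  }
  runs
}

#' Classify a mutant amplicon against a cut frame
#'
#' Computes the longest common prefix and suffix between reference and
#' mutant; the differing core is classified as a deletion (reference-only
#' core), insertion (mutant-only core), substitution(s) (equal-length core)
#' or a compound event resolved by a global alignment of the core
#' (Biostrings). Indels in repeats are placed closest to the cut (ties
#' toward the 5' side). Coordinates are reported in the cut frame.
#'
#' An insertion that replaces interior reference bases is recorded as a
#' single `delins` segment whose `start_rel`/`end_rel` are the retained
#' flanking positions (matching the bracket notation for insertions).
#'
#' @param frame a `cut_frame`.
#' @param mutant_sequence the mutant amplicon (same strand as the frame's
#'   reference).
#' @param anchor_len required exact flanking match at each end (default 30).
#' @param retained_block_min a retained block at least this long inside a
#'   deleted region splits the deletion into two reported spans (default 8);
#'   shorter retained blocks are absorbed as a delins.
#' @return object of class `edit_call`.
#' @export
call_edit <- function(frame, mutant_sequence, anchor_len = 30L,
                      retained_block_min = 8L) {
  stopifnot(inherits(frame, "cut_frame"))
  o <- orient_frame(frame, mutant_sequence)
  if (!is_dna(o$mut)) stop("mutant sequence must be DNA over ACGT")
  if (identical(o$ref, o$mut))
    return(new_edit_call("none", empty_segments(), frame))
  ra <- strsplit(o$ref, "", fixed = TRUE)[[1]]
  ma <- strsplit(o$mut, "", fixed = TRUE)[[1]]
  p <- lcp_len(ra, ma)
  s <- lcp_len(rev(ra), rev(ma))
  over <- p + s - min(length(ra), length(ma))
  if (over > 0L) { s <- s - over }   # prefix wins the overlap
  if (p < anchor_len || s < anchor_len)
    stop("amplicon does not match locus: flanking anchors (", anchor_len,
         " nt exact) not found (prefix ", p, ", suffix ", s, ")")
  cut <- o$cut
  ref_core <- substr(o$ref, p + 1L, length(ra) - s)
  mut_core <- substr(o$mut, p + 1L, length(ma) - s)
  nr <- nchar(ref_core); nm <- nchar(mut_core)

  segments <- empty_segments()
  if (nm == 0L) {                                   # pure deletion
    se <- normalize_deletion(ra, p, p + nr, cut)
    segments <- segment_row("del", nr, rel_of_index(se[1], cut),
                            rel_of_index(se[2] - 1L, cut),
                            ref = substr(o$ref, se[1] + 1L, se[2]))
    cls <- "deletion"
  } else if (nr == 0L) {                            # pure insertion
    rep <- normalize_insertion(ra, p, mut_core, cut)
    segments <- segment_row("ins", nm, rel_of_index(rep$q - 1L, cut),
                            rel_of_index(rep$q, cut), seq = rep$ins)
    cls <- "insertion"
  } else if (nr == nm) {                            # substitution(s)
    rb <- strsplit(ref_core, "", fixed = TRUE)[[1]]
    mb <- strsplit(mut_core, "", fixed = TRUE)[[1]]
    at <- which(rb != mb)
    segs <- lapply(at, function(i)
      segment_row("sub", 1L, rel_of_index(p + i - 1L, cut),
                  rel_of_index(p + i - 1L, cut), seq = mb[i], ref = rb[i]))
    segments <- do.call(rbind, segs)
    cls <- "substitution"
  } else {                                          # mixed: align the cores
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(ref_core), Biostrings::DNAString(mut_core),
      type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = TRUE),
      gapOpening = 5, gapExtension = 0.5)
    runs <- alignment_runs(as.character(Biostrings::alignedPattern(al)[[1]]),
                           as.character(Biostrings::alignedSubject(al)[[1]]),
                           ref_offset = p)
    segments <- runs_to_segments(runs, cut, retained_block_min)
    cls <- classify_segments(segments)
  }
  rownames(segments) <- NULL
  new_edit_call(if (nrow(segments) == 0L) "none" else cls, segments, frame)
}

classify_segments <- function(segments) {
  kinds <- unique(segments$kind)
  if (identical(kinds, "del") && nrow(segments) == 1L) "deletion"
  else if (identical(kinds, "ins") && nrow(segments) == 1L) "insertion"
  else if (identical(kinds, "sub")) "substitution"
  else "compound"
}

# convert alignment runs to reported segments, applying the compound rules:
# - indel (ins/del) runs separated only by retained match runs shorter than
#   retained_block_min are absorbed into a single delins: the interior
#   retained bases count as replaced-and-reinserted, so an insertion that
#   replaces a few reference bases is reported as one event with widened
#   flanks (and two deletions around a micro-match collapse likewise)
# - a retained block >= retained_block_min keeps events apart, which is what
#   produces two-span compound deletions
# - substitution runs always stand as their own segments
runs_to_segments <- function(runs, cut, retained_block_min) {
  # group consecutive indel runs joined across short interior match runs
  groups <- list(); cur <- NULL
  flush <- function() {
    if (!is.null(cur)) groups[[length(groups) + 1L]] <<- cur
    cur <<- NULL
  }
  for (r in runs) {
    if (r$kind %in% c("del", "ins")) {
      cur <- c(cur, list(r))
    } else if (r$kind == "match") {
      if (!is.null(cur) && nchar(r$ref_seq) < retained_block_min) {
        cur <- c(cur, list(r))   # tentative joiner; dropped if trailing
      } else flush()
    } else {                     # sub run: emit standalone, break groups
      flush()
      groups[[length(groups) + 1L]] <- list(r)
    }
  }
  flush()

  segs <- list()
  for (g in groups) {
    # drop trailing match joiners that did not end up joining anything
    while (length(g) && g[[length(g)]]$kind == "match") g[[length(g)]] <- NULL
    if (!length(g)) next
    kinds <- vapply(g, `[[`, character(1), "kind")
    if (length(g) == 1L && kinds == "sub") {
      r <- g[[1L]]
      rb <- strsplit(r$ref_seq, "", fixed = TRUE)[[1]]
      mb <- strsplit(r$mut_seq, "", fixed = TRUE)[[1]]
      for (j in seq_along(rb))
        segs[[length(segs) + 1L]] <- segment_row(
          "sub", 1L, rel_of_index(r$ref_start + j - 1L, cut),
          rel_of_index(r$ref_start + j - 1L, cut), seq = mb[j], ref = rb[j])
    } else if (length(g) == 1L && kinds == "del") {
      r <- g[[1L]]
      segs[[length(segs) + 1L]] <- segment_row(
        "del", r$ref_len, rel_of_index(r$ref_start, cut),
        rel_of_index(r$ref_start + r$ref_len - 1L, cut), ref = r$ref_seq)
    } else if (length(g) == 1L && kinds == "ins") {
      r <- g[[1L]]
      segs[[length(segs) + 1L]] <- segment_row(
        "ins", nchar(r$mut_seq), rel_of_index(r$ref_start - 1L, cut),
        rel_of_index(r$ref_start, cut), seq = r$mut_seq)
    } else {
      # multi-run group -> one delins over the group's reference span
      ref_all <- paste(vapply(g, `[[`, character(1), "ref_seq"), collapse = "")
      mut_all <- paste(vapply(g, `[[`, character(1), "mut_seq"), collapse = "")
      rs <- g[[1L]]$ref_start
      re <- rs + nchar(ref_all)            # exclusive
      if (nchar(ref_all) == 0L) {
        segs[[length(segs) + 1L]] <- segment_row(
          "ins", nchar(mut_all), rel_of_index(rs - 1L, cut),
          rel_of_index(rs, cut), seq = mut_all)
      } else {
        segs[[length(segs) + 1L]] <- segment_row(
          "delins", nchar(mut_all), rel_of_index(rs - 1L, cut),
          rel_of_index(re, cut), seq = mut_all, ref = ref_all)
      }
    }
  }
  do.call(rbind, c(segs, list(empty_segments())))
}

# number of addressable positions in the closed rel range [a, b] (no 0)
count_positions <- function(a, b) {
  if (a > b) return(0L)
  (b - a + 1L) - as.integer(a < 0L && b > 0L)
}

#' Format an edit call in bracket notation
#'
#' Emits the three report columns: deletions as `"N bp (a - b)"` (single-base
#' deletions as `"1 bp (-1)"`, two-span compound deletions joined with a
#' semicolon), insertions as `"N bp (a - b)"` where `a`/`b` are the retained
#' flanking positions (non-adjacent flanks imply the interior bases were
#' replaced), and substitutions as `"X{pos}Y"` (e.g. `"T-817C"`).
#'
#' @param call an `edit_call`.
#' @return named character vector with elements `deletion`, `insertion`,
#'   `mismatch` (empty string where absent).
#' @export
format_notation <- function(call) {
  segs <- call$segments
  out <- c(deletion = "", insertion = "", mismatch = "")
  if (is.null(segs) || nrow(segs) == 0L) return(out)
  dels <- segs[segs$kind == "del", , drop = FALSE]
  if (nrow(dels)) {
    spans <- vapply(seq_len(nrow(dels)), function(i) {
      if (dels$length[i] == 1L) fmt_rel(dels$start_rel[i])
      else paste(fmt_rel(dels$start_rel[i]), "-", fmt_rel(dels$end_rel[i]))
    }, character(1))
    out["deletion"] <- sprintf("%d bp (%s)", sum(dels$length),
                               paste(spans, collapse = "; "))
  }
  ins <- segs[segs$kind %in% c("ins", "delins"), , drop = FALSE]
  if (nrow(ins)) {
    spans <- vapply(seq_len(nrow(ins)), function(i)
      paste(fmt_rel(ins$start_rel[i]), "-", fmt_rel(ins$end_rel[i])),
      character(1))
    out["insertion"] <- sprintf("%d bp (%s)", sum(ins$length),
                                paste(spans, collapse = "; "))
  }
  subs <- segs[segs$kind == "sub", , drop = FALSE]
  if (nrow(subs)) {
    out["mismatch"] <- paste(vapply(seq_len(nrow(subs)), function(i)
      paste0(subs$ref[i], fmt_rel(subs$start_rel[i]), subs$seq[i]),
      character(1)), collapse = "; ")
  }
  out
}

#' Parse bracket notation back into edit segments
#'
#' Inverse of [format_notation()]: reconstructs the segment table (insertion
#' and replaced sequences are not recoverable from notation and are left
#' empty). `parse_notation(format_notation(x))` reproduces `x`'s segment
#' kinds, lengths and coordinates.
#'
#' @param notation named character vector with any of `deletion`,
#'   `insertion`, `mismatch`.
#' @return a segment data.frame as in an `edit_call`.
#' @export
parse_notation <- function(notation) {
  segs <- list()
  del <- notation[["deletion"]] %||NA% ""
  ins <- notation[["insertion"]] %||NA% ""
  mis <- notation[["mismatch"]] %||NA% ""
  parse_spans <- function(txt) {
    m <- regmatches(txt, regexec("^(\\d+) bp \\((.*)\\)$", txt))[[1]]
    if (length(m) == 0L) stop("cannot parse notation: '", txt, "'")
    spans <- strsplit(m[3], ";")[[1]]
    list(total = as.integer(m[2]), spans = lapply(trimws(spans), function(sp) {
      nums <- regmatches(sp, gregexpr("[+-]\\d+", sp))[[1]]
      as.integer(nums)
    }))
  }
  if (nzchar(del)) {
    pd <- parse_spans(del)
    for (sp in pd$spans) {
      a <- sp[1]; b <- if (length(sp) > 1L) sp[2] else sp[1]
      segs[[length(segs) + 1L]] <- segment_row("del", count_positions(a, b), a, b)
    }
  }
  if (nzchar(ins)) {
    pi_ <- parse_spans(ins)
    for (sp in pi_$spans) {
      a <- sp[1]; b <- sp[2]
      kind <- if (rel_adjacent(a, b)) "ins" else "delins"
      segs[[length(segs) + 1L]] <- segment_row(kind, pi_$total, a, b)
    }
  }
  if (nzchar(mis)) {
    for (one in trimws(strsplit(mis, ";")[[1]])) {
      m <- regmatches(one, regexec("^([ACGT])([+-]\\d+)([ACGT])$", one))[[1]]
      if (length(m) == 0L) stop("cannot parse substitution notation: '", one, "'")
      pos <- as.integer(m[3])
      segs[[length(segs) + 1L]] <- segment_row("sub", 1L, pos, pos,
                                               seq = m[4], ref = m[2])
    }
  }
  out <- do.call(rbind, c(segs, list(empty_segments())))
  out[order(out$start_rel), , drop = FALSE]
}

`%||NA%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Apply an edit call to a reference (inverse of classification)
#'
#' Reconstructs the mutant sequence implied by an edit call's segments.
#' Insertion/substitution segments must carry their `seq` content.
#'
#' @param call an `edit_call` (or bare segment data.frame).
#' @param frame a `cut_frame` supplying the reference and coordinates.
#' @return character scalar: the mutant sequence, on the frame's forward
#'   strand.
#' @export
apply_edit <- function(call, frame) {
  segs <- if (inherits(call, "edit_call")) call$segments else call
  o <- orient_frame(frame, frame$reference)
  ref <- o$ref; cut <- o$cut
  if (nrow(segs) == 0L) mut <- ref
  else {
    segs <- segs[order(segs$start_rel, decreasing = TRUE), , drop = FALSE]
    mut <- ref
    for (i in seq_len(nrow(segs))) {
      sg <- segs[i, ]
      if (sg$kind == "del") {
        a <- index_of_rel(sg$start_rel, cut); b <- index_of_rel(sg$end_rel, cut)
        mut <- paste0(substr(mut, 1L, a), substr(mut, b + 2L, nchar(mut)))
      } else if (sg$kind == "ins") {
        if (!nzchar(sg$seq)) stop("insertion segment without sequence content")
        q <- index_of_rel(sg$end_rel, cut)   # insertion sits before this base
        mut <- paste0(substr(mut, 1L, q), sg$seq, substr(mut, q + 1L, nchar(mut)))
      } else if (sg$kind == "delins") {
        if (!nzchar(sg$seq)) stop("delins segment without sequence content")
        a <- index_of_rel(sg$start_rel, cut); b <- index_of_rel(sg$end_rel, cut)
        mut <- paste0(substr(mut, 1L, a + 1L), sg$seq, substr(mut, b + 1L, nchar(mut)))
      } else if (sg$kind == "sub") {
        a <- index_of_rel(sg$start_rel, cut)
        stopifnot(substr(mut, a + 1L, a + 1L) == sg$ref)
        substr(mut, a + 1L, a + 1L) <- sg$seq
      }
    }
  }
  if (frame$orientation == "-") revcomp(mut) else mut
}

#' Trace the origin of an inserted sequence
#'
#' Exact substring search of an insertion (both strands) against named source
#' sequences, e.g. the CRISPR plasmid whose fragments are known to act as
#' pseudo-donor templates. Returns the first full-length exact hit.
#'
#' @param insertion_sequence the inserted DNA (>= `min_len` nt).
#' @param source_sequences named character vector (or `genome`) of candidate
#'   sources.
#' @param min_len minimum insertion length to attempt tracing (default 15).
#' @return `NULL` if no hit (or too short), else list with `source_name`,
#'   `start`, `end` (0-based half-open on the source forward strand) and
#'   `strand`.
#' @export
trace_insertion_origin <- function(insertion_sequence, source_sequences,
                                   min_len = 15L) {
  ins <- toupper(insertion_sequence)
  if (nchar(ins) < min_len) return(NULL)
  srcs <- unclass(source_sequences)
  for (nm in names(srcs)) {
    src <- toupper(srcs[[nm]])
    hit <- regexpr(ins, src, fixed = TRUE)
    if (hit != -1L)
      return(list(source_name = nm, start = as.integer(hit) - 1L,
                  end = as.integer(hit) - 1L + nchar(ins), strand = "+"))
    hit <- regexpr(revcomp(ins), src, fixed = TRUE)
    if (hit != -1L)
      return(list(source_name = nm, start = as.integer(hit) - 1L,
                  end = as.integer(hit) - 1L + nchar(ins), strand = "-"))
  }
  NULL
}
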