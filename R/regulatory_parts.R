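# Regulatory parts: Pol III tRNA promoters and poly-T terminators.
#
# A promoter is the entire (unspliced) tRNA gene plus a fixed upstream pad
# (default 100 nt) on the coding strand; a terminator runs from the first base
# after the gene through the last T of the first qualifying poly-T run.

new_regulatory_part <- function(kind, source_model_id, sequence, derivation,
                                upstream_pad = NULL, polyT_run = NULL) {
  structure(list(part_kind = kind, source_model_id = source_model_id,
                 sequence = sequence, derivation = derivation,
                 upstream_pad = upstream_pad, polyT_run = polyT_run),
            class = "regulatory_part")
}

#' @export
print.regulatory_part <- function(x, ...) {
  cat(sprintf("%s part from %s: %d nt\n", x$part_kind, x$source_model_id,
              nchar(x$sequence)))
  cat(" ", x$sequence, "\n")
  invisible(x)
}

as_model_row <- function(model) {
  if (is.data.frame(model)) {
    stopifnot(nrow(model) == 1L)
    as.list(model)
  } else as.list(model)
}

#' Extract a tRNA promoter (gene + upstream pad)
#'
#' The promoter comprises `upstream_pad` bases 5' of the gene on its coding
#' strand followed by the full unspliced gene (introns retained), so its
#' length is always `gene length + upstream_pad`. Pseudogene and
#' selenocysteine models are refused by default.
#'
#' @param genome a `genome`.
#' @param model one catalog row (or equivalent named list).
#' @param upstream_pad upstream pad in nt (default 100).
#' @param allow_flagged extract even from pseudogene/selenocysteine models.
#' @return a `regulatory_part` of kind `"promoter"`.
#' @export
extract_promoter <- function(genome, model, upstream_pad = 100L,
                             allow_flagged = FALSE) {
  m <- as_model_row(model)
  if (!allow_flagged && (isTRUE(m$pseudogene) || isTRUE(m$selenocysteine)))
    stop("model ", m$model_id, " is flagged (pseudogene/selenocysteine); ",
         "not a promoter candidate")
  genome <- as_genome(genome)
  clen <- nchar(genome[[m$contig]])
  if (m$strand == "+") {
    if (m$start < upstream_pad)
      stop("insufficient upstream flank for ", m$model_id, ": need ",
           upstream_pad, " nt, only ", m$start, " available")
    iv <- genomic_interval(m$contig, m$start - upstream_pad, m$end, "+")
  } else {
    if (clen - m$end < upstream_pad)
      stop("insufficient upstream flank for ", m$model_id, ": need ",
           upstream_pad, " nt, only ", clen - m$end, " available")
    iv <- genomic_interval(m$contig, m$start, m$end + upstream_pad, "-")
  }
  seq <- extract_seq(genome, iv)
  if (grepl("N", seq, fixed = TRUE))
    stop("promoter for ", m$model_id, " contains N; not synthesizable")
  new_regulatory_part("promoter", m$model_id, seq, iv, upstream_pad = upstream_pad)
}

#' Extract a tRNA terminator (through the first poly-T run)
#'
#' Scans the coding-strand sequence 3' of the gene for the first run of at
#' least `min_t_run` consecutive T within `window` nt; the terminator spans
#' from the first base after the gene through the last T of that run.
#'
#' @param genome a `genome`.
#' @param model one catalog row.
#' @param window downstream scan window in nt (default 50).
#' @param min_t_run minimum poly-T run length (default 4).
#' @param max_len plausibility cap on terminator length (default 60).
#' @return a `regulatory_part` of kind `"terminator"` with `polyT_run`, the
#'   gene-relative (0-based half-open, from the base after the gene) run
#'   interval.
#' @export
extract_terminator <- function(genome, model, window = 50L, min_t_run = 4L,
                               max_len = 60L) {
  m <- as_model_row(model)
  genome <- as_genome(genome)
  dn <- downstream_window_seq(genome, m$contig, m$start, m$end, m$strand, window)
  run <- regexpr(paste0("T{", min_t_run, ",}"), dn)
  if (run == -1L)
    stop("no terminator: no run of >=", min_t_run, " T within ", window,
         " nt downstream of ", m$model_id)
  run_start <- as.integer(run)                       # 1-based in dn
  run_end <- run_start + attr(run, "match.length") - 1L
  term_len <- run_end
  if (term_len > max_len)
    stop("terminator for ", m$model_id, " is ", term_len,
         " nt, beyond plausibility bound ", max_len)
  seq <- substr(dn, 1L, term_len)
  if (grepl("N", seq, fixed = TRUE))
    stop("terminator for ", m$model_id, " contains N; not synthesizable")
  iv <- if (m$strand == "+")
    genomic_interval(m$contig, m$end, m$end + term_len, "+")
  else
    genomic_interval(m$contig, m$start - term_len, m$start, "-")
  new_regulatory_part("terminator", m$model_id, seq, iv,
                      polyT_run = c(run_start - 1L, run_end))
}

#' Extract promoter and terminator parts for a whole catalog
#'
#' Convenience wrapper: extracts both parts for every eligible model,
#' collecting failures instead of stopping.
#'
#' @param genome a `genome`.
#' @param catalog a `trna_catalog`.
#' @param upstream_pad,window,min_t_run see [extract_promoter()] and
#'   [extract_terminator()].
#' @return list with `promoters` and `terminators` (named lists of
#'   `regulatory_part`) and `failures` (named character of error messages).
#' @export
extract_parts <- function(genome, catalog, upstream_pad = 100L, window = 50L,
                          min_t_run = 4L) {
  promoters <- list(); terminators <- list(); failures <- character(0)
  for (i in seq_len(nrow(catalog))) {
    m <- catalog[i, ]
    res <- tryCatch({
      p <- extract_promoter(genome, m, upstream_pad = upstream_pad)
      t <- extract_terminator(genome, m, window = window, min_t_run = min_t_run)
      list(p = p, t = t)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) failures[m$model_id] <- res
    else {
      promoters[[m$model_id]] <- res$p
      terminators[[m$model_id]] <- res$t
    }
  }
  list(promoters = promoters, terminators = terminators, failures = failures)
}

#' Write regulatory parts to FASTA with provenance headers
#' @param parts list of `regulatory_part`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
parts_to_fasta <- function(parts, path) {
  seqs <- vapply(parts, `[[`, character(1), "sequence")
  names(seqs) <- vapply(parts, function(p)
    sprintf("%s|%s|%s:%d-%d(%s)", p$source_model_id, p$part_kind,
            p$derivation$contig, p$derivation$start + 1L, p$derivation$end,
            p$derivation$strand), character(1))
  write_fasta(seqs, path)
}
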