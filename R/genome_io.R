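# Genome IO: FASTA loading, strand-aware extraction, tRNA prediction readers.
#
# Internal coordinate convention, used everywhere in this package:
# 0-based, half-open on the forward strand; width = end - start.
# Report output (TSV/FASTA headers emitted for people) is 1-based inclusive.

#' Genomic interval (0-based, half-open)
#'
#' Constructs the interval object used throughout the package. Coordinates are
#' 0-based half-open on the forward strand; `strand` records which strand the
#' feature reads on, it does not change the coordinates.
#'
#' @param contig contig/chromosome identifier.
#' @param start 0-based inclusive start, `>= 0`.
#' @param end exclusive end, `> start`.
#' @param strand `"+"` or `"-"`.
#' @return an object of class `genomic_interval`.
#' @export
genomic_interval <- function(contig, start, end, strand = "+") {
  stopifnot(is.character(contig), length(contig) == 1L, nzchar(contig))
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end)) stop("interval coordinates must be numeric")
  if (start < 0L) stop("interval start must be >= 0, got ", start)
  if (end <= start) stop("interval end (", end, ") must be > start (", start, ")")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-', got '", strand, "'")
  structure(list(contig = contig, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<%s:%d-%d(%s)> width=%d [0-based half-open]\n",
              x$contig, x$start, x$end, x$strand, x$end - x$start))
  invisible(x)
}

#' Width of a genomic interval
#' @param x a `genomic_interval`.
#' @return integer width (`end - start`).
#' @export
interval_width <- function(x) x$end - x$start

#' Load a genome from FASTA
#'
#' Reads a (multi-)FASTA file into a named character vector of uppercase DNA.
#' Softmasked (lowercase) input is uppercased. Record ids are the first token
#' of each header and must be unique.
#'
#' @param path path to a FASTA file.
#' @param n_policy what to do with non-ACGTN characters: `"reject"` (error) or
#'   `"mask"` (replace with N).
#' @return named character vector of class `genome`; one element per record.
#' @export
load_fasta <- function(path, n_policy = c("reject", "mask")) {
  n_policy <- match.arg(n_policy)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("malformed FASTA '", path, "': file is empty (line 1)")
  if (!startsWith(first, ">"))
    stop("malformed FASTA '", path, "': line 1 does not start with '>'")
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate FASTA record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(nchar(seqs) == 0L))
    stop("empty FASTA record: ", ids[nchar(seqs) == 0L][1L])
  bad <- !is_dna(seqs, allow_n = TRUE)
  if (any(bad)) {
    if (n_policy == "reject")
      stop("record '", ids[bad][1L], "' contains characters outside {A,C,G,T,N}")
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  names(seqs) <- ids
  structure(seqs, class = "genome")
}

#' Coerce sequences to a genome object
#'
#' @param x named character vector of DNA sequences (or a `genome`).
#' @return a `genome` object (uppercased, validated).
#' @export
as_genome <- function(x) {
  if (inherits(x, "genome")) return(x)
  stopifnot(is.character(x), !is.null(names(x)), all(nzchar(names(x))))
  if (anyDuplicated(names(x))) stop("duplicate contig ids")
  x <- toupper(x)
  if (!all(is_dna(x, allow_n = TRUE)))
    stop("sequences contain characters outside {A,C,G,T,N}")
  if (any(nchar(x) == 0L)) stop("empty contig sequence")
  structure(x, class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("genome:", length(x), "contig(s),", sum(nchar(x)), "bp total\n")
  for (i in seq_along(x))
    cat(sprintf("  %s  %d bp\n", names(x)[i], nchar(x[[i]])))
  invisible(x)
}

#' Write sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(unclass(seqs))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Extract a strand-aware sequence slice
#'
#' Returns the forward-strand slice for `strand == "+"` and its reverse
#' complement for `strand == "-"`; the result always has length
#' `end - start` and reads 5' to 3' on the requested strand.
#'
#' @param genome a `genome` (named character vector).
#' @param interval a `genomic_interval`.
#' @return character scalar of DNA.
#' @export
extract_seq <- function(genome, interval) {
  stopifnot(inherits(interval, "genomic_interval"))
  genome <- as_genome(genome)
  if (!interval$contig %in% names(genome))
    stop("contig '", interval$contig, "' not in genome (have: ",
         paste(names(genome), collapse = ", "), ")")
  len <- nchar(genome[[interval$contig]])
  if (interval$end > len)
    stop(sprintf("interval out of bounds on %s: requested [%d,%d) but contig has %d bp",
                 interval$contig, interval$start, interval$end, len))
  s <- substr(genome[[interval$contig]], interval$start + 1L, interval$end)
  if (interval$strand == "-") s <- revcomp(s)
  s
}

# Prediction records ----------------------------------------------------------
# One row per raw tRNA gene prediction, all coordinates already normalized to
# the internal convention. Intron bounds are gene-relative (0-based half-open,
# measured from the gene 5' end on the coding strand), comma-joined.

prediction_cols <- c("predictor", "contig", "start", "end", "strand",
                     "anticodon", "intron_starts", "intron_ends", "pseudogene")

new_predictions <- function(df) {
  missing <- setdiff(prediction_cols, names(df))
  if (length(missing)) stop("missing prediction columns: ", paste(missing, collapse = ", "))
  df <- df[, prediction_cols, drop = FALSE]
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$pseudogene <- as.logical(df$pseudogene)
  df$intron_starts <- as.character(df$intron_starts)
  df$intron_ends <- as.character(df$intron_ends)
  rownames(df) <- NULL
  class(df) <- c("trna_predictions", "data.frame")
  df
}

parse_intron_field <- function(s) {
  if (is.na(s) || s == "" || s == ".") return(integer(0))
  as.integer(strsplit(s, ",", fixed = TRUE)[[1]])
}

intron_lengths <- function(row) {
  parse_intron_field(row$intron_ends) - parse_intron_field(row$intron_starts)
}

#' Read tRNA gene predictions
#'
#' Reads raw tRNA gene predictions in one of three dialects and normalizes
#' them to the internal 0-based half-open convention:
#'
#' * `"trnascan"`: tRNAscan-SE 1.3 tabular output (1-based inclusive; minus
#'   strand encoded as begin > end; genomic intron bounds; optional
#'   pseudogene note column).
#' * `"gff3"`: GFF3 with `tRNA` features carrying an `anticodon` attribute and
#'   optional intron child features (`Parent` linkage); the source column is
#'   used as the predictor name unless overridden.
#' * `"tsv"`: the package's internal TSV dialect (already 0-based half-open,
#'   gene-relative introns), as written by [write_trna_predictions()].
#'
#' @param path input file.
#' @param format one of `"trnascan"`, `"gff3"`, `"tsv"`.
#' @param predictor predictor name to record; defaults per format (tRNAscan:
#'   `"tRNAscan-SE"`; GFF3: the source column; TSV: taken from the file).
#' @return data.frame of class `trna_predictions`.
#' @export
read_trna_predictions <- function(path, format = c("trnascan", "gff3", "tsv"),
                                  predictor = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("prediction file not found: ", path)
  switch(format,
         trnascan = read_trnascan(path, predictor %||% "tRNAscan-SE"),
         gff3 = read_gff3_trnas(path, predictor),
         tsv = read_trna_predictions_tsv(path, predictor))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_trnascan <- function(path, predictor) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  # classic output opens with 3 header lines, recognized by a non-numeric
  # Begin field; past the header block a non-numeric coordinate is an error
  is_header <- seq_along(lines) <= 3L & vapply(lines, function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    length(f) < 9 || is.na(suppressWarnings(as.numeric(f[3])))
  }, logical(1))
  if (!any(!is_header)) stop("no data rows in tRNAscan file: ", path)
  rows <- lapply(lines[!is_header], function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    b <- suppressWarnings(as.integer(f[3])); e <- suppressWarnings(as.integer(f[4]))
    ib <- suppressWarnings(as.integer(f[7])); ie <- suppressWarnings(as.integer(f[8]))
    if (anyNA(c(b, e, ib, ie)))
      stop("non-numeric coordinate field in tRNAscan row: ", l)
    strand <- if (b <= e) "+" else "-"
    start <- min(b, e) - 1L; end <- max(b, e)
    if (ib == 0L || ie == 0L) {
      is_rel <- ie_rel <- ""
    } else {
      a <- min(ib, ie) - 1L; bb <- max(ib, ie)
      if (a < start || bb > end) stop("intron outside gene bounds in row: ", l)
      if (strand == "+") { rs <- a - start; re <- bb - start }
      else { rs <- end - bb; re <- end - a }
      is_rel <- as.character(rs); ie_rel <- as.character(re)
    }
    pseudo <- length(f) >= 10 && grepl("pseudo", paste(f[10:length(f)], collapse = " "),
                                       ignore.case = TRUE)
    data.frame(predictor = predictor, contig = f[1], start = start, end = end,
               strand = strand, anticodon = toupper(f[6]),
               intron_starts = is_rel, intron_ends = ie_rel,
               pseudogene = pseudo, stringsAsFactors = FALSE)
  })
  new_predictions(do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

read_gff3_trnas <- function(path, predictor = NULL) {
  g <- as.data.frame(rtracklayer::readGFF(path))
  trna <- g[g$type == "tRNA", , drop = FALSE]
  if (nrow(trna) == 0L) stop("no tRNA features in GFF3: ", path)
  introns <- g[g$type %in% c("intron", "tRNA_intron"), , drop = FALSE]
  rows <- lapply(seq_len(nrow(trna)), function(i) {
    r <- trna[i, ]
    start <- as.integer(r$start) - 1L; end <- as.integer(r$end)
    strand <- as.character(r$strand)
    if (!strand %in% c("+", "-")) stop("tRNA feature without strand in GFF3")
    kid <- if (nrow(introns) && "Parent" %in% names(introns) && !is.null(r$ID)) {
      keep <- vapply(introns$Parent, function(p) as.character(r$ID) %in% as.character(p),
                     logical(1))
      introns[keep, , drop = FALSE]
    } else introns[0, , drop = FALSE]
    if (nrow(kid)) {
      a <- as.integer(kid$start) - 1L; b <- as.integer(kid$end)
      if (strand == "+") { rs <- a - start; re <- b - start }
      else { rs <- end - b; re <- end - a }
      o <- order(rs)
      is_rel <- paste(rs[o], collapse = ","); ie_rel <- paste(re[o], collapse = ",")
    } else is_rel <- ie_rel <- ""
    ac <- if (!is.null(r$anticodon)) toupper(as.character(r$anticodon)) else NA_character_
    pseudo <- isTRUE(as.logical(r$pseudo)) ||
      (!is.null(r$gene_biotype) && identical(as.character(r$gene_biotype), "pseudogene"))
    data.frame(predictor = predictor %||% as.character(r$source),
               contig = as.character(r$seqid), start = start, end = end,
               strand = strand, anticodon = ac,
               intron_starts = is_rel, intron_ends = ie_rel,
               pseudogene = pseudo, stringsAsFactors = FALSE)
  })
  new_predictions(do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

read_trna_predictions_tsv <- function(path, predictor = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(intron_starts = "character",
                                         intron_ends = "character"))
  df$intron_starts[is.na(df$intron_starts)] <- ""
  df$intron_ends[is.na(df$intron_ends)] <- ""
  if (!is.null(predictor)) df$predictor <- predictor
  new_predictions(df)
}

#' Write predictions in the internal TSV dialect
#'
#' @param predictions a `trna_predictions` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trna_predictions <- function(predictions, path) {
  utils::write.table(as.data.frame(predictions), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a genome and prediction files against each other
#'
#' Checks that every prediction falls inside its contig and reports simple
#' summary counts; used by the `io-validate` CLI subcommand.
#'
#' @param genome a `genome` or FASTA path.
#' @param predictions a `trna_predictions` data.frame (or list of them).
#' @return list with `n_contigs`, `n_predictions`, `n_out_of_bounds`,
#'   `out_of_bounds` (row indices).
#' @export
io_validate <- function(genome, predictions) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- load_fasta(genome)
  genome <- as_genome(genome)
  if (is.data.frame(predictions)) predictions <- list(predictions)
  preds <- do.call(rbind, lapply(predictions, as.data.frame))
  bad <- unname(which(!(preds$contig %in% names(genome)) |
                        preds$start < 0L |
                        preds$end > nchar(genome)[match(preds$contig,
                                                        names(genome))]))
  list(n_contigs = length(genome), n_predictions = nrow(preds),
       n_out_of_bounds = length(bad), out_of_bounds = bad)
}
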