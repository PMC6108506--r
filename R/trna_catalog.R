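# tRNA gene catalog: merge multi-predictor models and apply curation rules.
#
# A curated catalog is a data.frame with one row per tRNA gene model; intron
# bounds are gene-relative (0-based half-open from the gene 5' end on the
# coding strand), comma-joined.

catalog_cols <- c("model_id", "contig", "start", "end", "strand", "anticodon",
                  "amino_acid", "selenocysteine", "pseudogene", "gene_length",
                  "intron_starts", "intron_ends", "intron_total", "predictors",
                  "gene_sequence")

new_trna_catalog <- function(df) {
  df <- df[, catalog_cols, drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("trna_catalog", "data.frame")
  df
}

#' @export
print.trna_catalog <- function(x, ...) {
  cat("tRNA gene catalog:", nrow(x), "model(s)\n")
  if (nrow(x)) {
    show <- utils::head(as.data.frame(x)[, c("model_id", "contig", "start", "end",
                                             "strand", "anticodon", "amino_acid",
                                             "gene_length", "intron_total",
                                             "predictors")], 10L)
    print(show)
    if (nrow(x) > 10L) cat("  ...", nrow(x) - 10L, "more\n")
  }
  invisible(x)
}

#' Map an anticodon to its amino acid
#'
#' Reverse-complements each anticodon to its codon and applies the standard
#' genetic code. The anticodon `TCA` (codon `TGA`) is reported as `"SeC"`
#' (selenocysteine candidate) rather than as a stop; the other two stop codons
#' map to `"*"`.
#'
#' @param anticodon character vector of 3-mers over ACGT (DNA alphabet).
#' @return character vector of one-letter amino-acid codes (`"SeC"`/`"*"` as
#'   described).
#' @export
classify_anticodon <- function(anticodon) {
  anticodon <- toupper(anticodon)
  if (!all(grepl("^[ACGT]{3}$", anticodon)))
    stop("anticodon must be a 3-mer over ACGT, got: ",
         paste(anticodon[!grepl("^[ACGT]{3}$", anticodon)], collapse = ", "))
  codon <- vapply(anticodon, revcomp, character(1))
  aa <- unname(Biostrings::GENETIC_CODE[codon])
  aa[codon == "TGA"] <- "SeC"
  aa
}

# qualifying poly-T terminator run downstream of a gene, on the coding strand
downstream_window_seq <- function(genome, contig, start, end, strand, window) {
  genome <- as_genome(genome)
  len <- nchar(genome[[contig]])
  if (strand == "+") {
    if (start < 0 || end >= len) return("")
    extract_seq(genome, genomic_interval(contig, end, min(len, end + window), "+"))
  } else {
    if (start <= 0) return("")
    extract_seq(genome, genomic_interval(contig, max(0L, start - window), start, "-"))
  }
}

has_polyT_terminator <- function(genome, contig, start, end, strand,
                                 window = 50L, min_t_run = 4L) {
  dn <- downstream_window_seq(genome, contig, start, end, strand, window)
  nzchar(dn) && grepl(strrep("T", min_t_run), dn, fixed = TRUE)
}

#' Merge multi-predictor tRNA gene predictions into consensus models
#'
#' Clusters prediction records that lie in the same genomic region (same
#' contig and strand, reciprocal overlap at least `min_reciprocal_overlap`,
#' single linkage) and keeps, within each cluster, the model supported by the
#' most predictors. Ties between equally supported non-identical models are
#' broken by (1) presence of a qualifying downstream poly-T terminator when a
#' genome is supplied, (2) shorter total intron length, (3) lexicographic
#' model key. Singleton clusters pass through.
#'
#' @param records a `trna_predictions` data.frame (possibly from several
#'   predictors, concatenated with `rbind`).
#' @param genome optional `genome`; enables the terminator tie-break and
#'   populates `gene_sequence`.
#' @param min_reciprocal_overlap reciprocal-overlap fraction defining "same
#'   genomic region" (default 0.5).
#' @param term_window,min_t_run terminator scan parameters for the tie-break.
#' @return a `trna_catalog` data.frame; `predictors` records provenance as a
#'   comma-joined, sorted set.
#' @export
merge_predictions <- function(records, genome = NULL, min_reciprocal_overlap = 0.5,
                              term_window = 50L, min_t_run = 4L) {
  if (is.null(records) || nrow(records) == 0L)
    return(new_trna_catalog(empty_catalog_df()))
  df <- as.data.frame(records)
  df$key <- paste(df$contig, df$start, df$end, df$strand,
                  df$anticodon, df$intron_starts, df$intron_ends, sep = "|")

  winners <- list()
  for (grp in split(df, paste(df$contig, df$strand))) {
    grp <- grp[order(grp$start, grp$end), , drop = FALSE]
    # single-linkage clustering by reciprocal overlap
    cl <- integer(nrow(grp)); cur <- 0L
    for (i in seq_len(nrow(grp))) {
      assigned <- 0L
      if (i > 1L) for (j in seq_len(i - 1L)) {
        ov <- min(grp$end[i], grp$end[j]) - max(grp$start[i], grp$start[j])
        wi <- grp$end[i] - grp$start[i]; wj <- grp$end[j] - grp$start[j]
        if (ov > 0 && ov / wi >= min_reciprocal_overlap &&
            ov / wj >= min_reciprocal_overlap) { assigned <- cl[j]; break }
      }
      if (assigned == 0L) { cur <- cur + 1L; assigned <- cur }
      cl[i] <- assigned
    }
    for (k in unique(cl)) {
      sub <- grp[cl == k, , drop = FALSE]
      votes <- tapply(sub$predictor, sub$key, function(p) length(unique(p)))
      best <- names(votes)[votes == max(votes)]
      if (length(best) > 1L) {
        cand <- sub[!duplicated(sub$key) & sub$key %in% best, , drop = FALSE]
        term_ok <- if (!is.null(genome)) {
          vapply(seq_len(nrow(cand)), function(i)
            has_polyT_terminator(genome, cand$contig[i], cand$start[i],
                                 cand$end[i], cand$strand[i],
                                 term_window, min_t_run), logical(1))
        } else rep(FALSE, nrow(cand))
        itot <- vapply(seq_len(nrow(cand)), function(i)
          sum(intron_lengths(cand[i, ])), integer(1))
        o <- order(-term_ok, itot, cand$key)
        best <- cand$key[o][1L]
      }
      row <- sub[sub$key == best, , drop = FALSE][1L, ]
      row$predictors <- paste(sort(unique(sub$predictor[sub$key == best])),
                              collapse = ",")
      row$pseudogene <- any(sub$pseudogene[sub$key == best])
      winners[[length(winners) + 1L]] <- row
    }
  }
  out <- do.call(rbind, c(winners, list(make.row.names = FALSE)))
  out <- out[order(out$contig, out$start, out$end), , drop = FALSE]

  aa <- classify_anticodon(out$anticodon)
  # model ids named by amino-acid identity, numbered in genomic order
  id <- character(nrow(out)); cnt <- new.env()
  aa3 <- ifelse(aa == "*", "Pseudo", ifelse(aa == "SeC", "SeC", aa))
  for (i in seq_len(nrow(out))) {
    n <- get0(aa3[i], envir = cnt, inherits = FALSE, ifnotfound = 0L) + 1L
    assign(aa3[i], n, envir = cnt)
    id[i] <- sprintf("tRNA-%s-%d", aa3[i], n)
  }
  gene_seq <- if (!is.null(genome)) {
    vapply(seq_len(nrow(out)), function(i)
      extract_seq(as_genome(genome),
                  genomic_interval(out$contig[i], out$start[i], out$end[i],
                                   out$strand[i])), character(1))
  } else rep(NA_character_, nrow(out))
  itot <- vapply(seq_len(nrow(out)), function(i) {
    len <- intron_lengths(out[i, ]); if (length(len)) sum(len) else 0L
  }, integer(1))

  new_trna_catalog(data.frame(
    model_id = id, contig = out$contig, start = out$start, end = out$end,
    strand = out$strand, anticodon = out$anticodon, amino_acid = aa,
    selenocysteine = aa == "SeC", pseudogene = out$pseudogene,
    gene_length = out$end - out$start,
    intron_starts = out$intron_starts, intron_ends = out$intron_ends,
    intron_total = itot, predictors = out$predictors,
    gene_sequence = gene_seq, stringsAsFactors = FALSE))
}

empty_catalog_df <- function() {
  data.frame(model_id = character(0), contig = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             anticodon = character(0), amino_acid = character(0),
             selenocysteine = logical(0), pseudogene = logical(0),
             gene_length = integer(0), intron_starts = character(0),
             intron_ends = character(0), intron_total = integer(0),
             predictors = character(0), gene_sequence = character(0),
             stringsAsFactors = FALSE)
}

#' Apply curation rules to a merged catalog
#'
#' Rejects any model with an intron longer than `max_intron` nt (no fungal
#' tRNA intron is known to exceed 100 nt), any model whose downstream window
#' lacks a qualifying poly-T terminator run, and any model whose unspliced
#' gene length falls outside the configured plausibility bounds. Pseudogene
#' models are kept (flagged) but excluded from promoter candidacy downstream.
#' Every rejection is logged with the rule(s) that fired. Filtering is
#' idempotent: filtering a kept set changes nothing.
#'
#' @param catalog a `trna_catalog`.
#' @param genome a `genome`, needed for the terminator window.
#' @param config named list overriding any of: `max_intron` (100),
#'   `min_gene_len` (60), `max_gene_len` (130), `term_window` (50),
#'   `min_t_run` (4).
#' @return list with `kept` (a `trna_catalog`) and `rejected` (data.frame
#'   with `model_id` and comma-joined `rules`).
#' @export
filter_models <- function(catalog, genome, config = list()) {
  cfg <- utils::modifyList(list(max_intron = 100L, min_gene_len = 60L,
                                max_gene_len = 130L, term_window = 50L,
                                min_t_run = 4L), config)
  if (nrow(catalog) == 0L)
    return(list(kept = catalog,
                rejected = data.frame(model_id = character(0), rules = character(0),
                                      stringsAsFactors = FALSE)))
  rules <- vapply(seq_len(nrow(catalog)), function(i) {
    row <- catalog[i, ]
    fired <- character(0)
    il <- intron_lengths(row)
    if (length(il) && any(il > cfg$max_intron)) fired <- c(fired, "intron>100")
    if (row$gene_length < cfg$min_gene_len || row$gene_length > cfg$max_gene_len)
      fired <- c(fired, "gene_length_out_of_bounds")
    if (!has_polyT_terminator(genome, row$contig, row$start, row$end, row$strand,
                              cfg$term_window, cfg$min_t_run))
      fired <- c(fired, "no_polyT_terminator")
    paste(fired, collapse = ",")
  }, character(1))
  keep <- rules == ""
  list(kept = new_trna_catalog(as.data.frame(catalog)[keep, , drop = FALSE]),
       rejected = data.frame(model_id = catalog$model_id[!keep],
                             rules = rules[!keep], stringsAsFactors = FALSE))
}

#' Summarize a curated catalog
#'
#' @param catalog a `trna_catalog`.
#' @return object of class `catalog_summary`: per-amino-acid gene counts,
#'   total, pseudogene and selenocysteine counts.
#' @export
summarize_catalog <- function(catalog) {
  aa <- catalog$amino_acid
  counts <- if (length(aa)) table(aa) else table(factor(character(0)))
  structure(list(aa_counts = counts, total = nrow(catalog),
                 n_pseudogene = sum(catalog$pseudogene),
                 n_selenocysteine = sum(catalog$selenocysteine)),
            class = "catalog_summary")
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat("tRNA catalog summary:", x$total, "gene model(s)\n")
  cat("  pseudogenes:", x$n_pseudogene,
      " selenocysteine:", x$n_selenocysteine, "\n")
  if (length(x$aa_counts)) {
    cat("  per amino acid:\n")
    print(x$aa_counts)
  }
  invisible(x)
}

#' Write a catalog as TSV (1-based inclusive report coordinates)
#' @param catalog a `trna_catalog`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog_tsv <- function(catalog, path) {
  df <- as.data.frame(catalog)
  df$gene_sequence <- NULL
  df$start_1based <- df$start + 1L
  df$end_1based <- df$end
  df$start <- df$end <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a catalog written by [write_catalog_tsv()]
#' @param path TSV path.
#' @param genome optional `genome` to repopulate `gene_sequence`.
#' @return a `trna_catalog`.
#' @export
read_catalog_tsv <- function(path, genome = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(intron_starts = "character",
                                         intron_ends = "character",
                                         model_id = "character",
                                         contig = "character",
                                         strand = "character",
                                         anticodon = "character",
                                         amino_acid = "character",
                                         predictors = "character"))
  df$intron_starts[is.na(df$intron_starts)] <- ""
  df$intron_ends[is.na(df$intron_ends)] <- ""
  df$start <- df$start_1based - 1L
  df$end <- df$end_1based
  df$start_1based <- df$end_1based <- NULL
  df$gene_sequence <- if (!is.null(genome)) {
    vapply(seq_len(nrow(df)), function(i)
      extract_seq(as_genome(genome),
                  genomic_interval(df$contig[i], df$start[i], df$end[i],
                                   df$strand[i])), character(1))
  } else NA_character_
  new_trna_catalog(df)
}
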