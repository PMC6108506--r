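# End-to-end pipeline: curate -> parts -> guides -> cassette for one target.

#' Pipeline configuration
#'
#' Collects every tunable constant of the design pipeline with its default:
#' `upstream_pad` (100 nt promoter pad), `min_t_run` (4, minimum poly-T
#' terminator run), `term_window` (50 nt downstream scan), `max_intron`
#' (100 nt curation cap), `spacer_len` (20), `scaffold` (80-nt tracrRNA DNA),
#' `max_mismatches` (3, off-target Hamming radius), `pam_rule` (`"NGG"`),
#' `flank` (600 nt donor homology arms), `anchor_len` (30 nt classifier
#' anchors), `tm_range` (primer Tm window), `seed`.
#'
#' @param ... overrides for any of the above.
#' @return object of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- utils::modifyList(list(
    upstream_pad = 100L, min_t_run = 4L, term_window = 50L, max_intron = 100L,
    min_gene_len = 60L, max_gene_len = 130L, spacer_len = 20L,
    scaffold = default_scaffold(), max_mismatches = 3L, pam_rule = "NGG",
    flank = 600L, anchor_len = 30L, tm_range = c(55, 65), seed = 1L),
    list(...))
  num <- cfg[c("upstream_pad", "min_t_run", "term_window", "max_intron",
               "min_gene_len", "max_gene_len", "spacer_len", "max_mismatches",
               "flank", "anchor_len")]
  if (any(unlist(num) <= 0)) stop("all pipeline constants must be positive")
  if (nchar(cfg$scaffold) != 80L)
    stop("scaffold must be 80 nt; override build_cassette() directly if you ",
         "really need a nonstandard scaffold")
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("pipeline configuration:\n")
  for (nm in setdiff(names(x), "scaffold"))
    cat(sprintf("  %-15s %s\n", nm, paste(x[[nm]], collapse = "-")))
  cat(sprintf("  %-15s %s\n", "scaffold", x$scaffold))
  invisible(x)
}

#' Parse a "contig:start-end" region string (1-based inclusive)
#'
#' @param x region string like `"chr1:1001-3000"` (1-based inclusive, as in
#'   genome-browser coordinates).
#' @param strand strand for the resulting interval.
#' @return a `genomic_interval` (internal 0-based half-open).
#' @export
parse_region <- function(x, strand = "+") {
  m <- regmatches(x, regexec("^([^:]+):(\\d+)-(\\d+)$", x))[[1]]
  if (length(m) == 0L) stop("cannot parse region '", x, "'; expected contig:start-end")
  genomic_interval(m[2], as.integer(m[3]) - 1L, as.integer(m[4]), strand)
}

#' Run the design pipeline end to end
#'
#' Curates tRNA predictions against the genome, extracts promoter/terminator
#' parts, enumerates and off-target-screens guides in the target region,
#' ranks them, and assembles a gRNA cassette (with LIC tails) from the best
#' clean guide and the requested (or first available) promoter/terminator
#' pair.
#'
#' @param config a [run_config()].
#' @param genome a `genome` or FASTA path.
#' @param predictions a `trna_predictions` data.frame, or paths; paths need
#'   `formats` (parallel character vector).
#' @param target a `genomic_interval` or `"contig:start-end"` string.
#' @param promoter_id model id of the tRNA promoter to use (default: first
#'   model with both parts available).
#' @param anchor optional genomic coordinate for guide ranking.
#' @param formats prediction formats when `predictions` are paths.
#' @return list of class `design_run`: `catalog`, `rejected`, `parts`,
#'   `guides`, `guide`, `cassette`.
#' @export
run_pipeline <- function(config, genome, predictions, target,
                         promoter_id = NULL, anchor = NULL, formats = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!inherits(genome, "genome") && is.character(genome) && length(genome) == 1L)
    genome <- load_fasta(genome)
  genome <- as_genome(genome)
  if (is.character(predictions)) {
    stopifnot(!is.null(formats), length(formats) == length(predictions))
    predictions <- do.call(rbind, Map(read_trna_predictions, predictions, formats))
  }
  if (is.character(target)) target <- parse_region(target)

  catalog <- merge_predictions(predictions, genome,
                               term_window = config$term_window,
                               min_t_run = config$min_t_run)
  flt <- filter_models(catalog, genome,
                       config = config[c("max_intron", "min_gene_len",
                                         "max_gene_len", "term_window",
                                         "min_t_run")])
  parts <- extract_parts(genome, flt$kept, upstream_pad = config$upstream_pad,
                         window = config$term_window,
                         min_t_run = config$min_t_run)
  if (length(parts$promoters) == 0L)
    stop("design failure: no usable promoter/terminator pair in the catalog")

  guides <- enumerate_guides(genome, target, spacer_len = config$spacer_len)
  if (nrow(guides) == 0L)
    stop("design failure: no PAM-adjacent protospacer in the target region")
  guides <- scan_offtargets(genome, guides,
                            max_mismatches = config$max_mismatches,
                            pam_rule = config$pam_rule)
  guides <- rank_guides(guides, anchor = anchor)
  if (!any(guides$clean))
    stop("design failure: no clean guide (all candidates have off-targets)")
  best <- guides[guides$clean, , drop = FALSE][1L, ]

  pid <- promoter_id %||% names(parts$promoters)[1L]
  if (!pid %in% names(parts$promoters))
    stop("promoter id '", pid, "' has no extracted parts")
  cassette <- build_cassette(parts$promoters[[pid]], best$spacer,
                             parts$terminators[[pid]],
                             scaffold = config$scaffold,
                             tm_range = config$tm_range)
  cassette <- add_lic_tails(cassette)

  structure(list(config = config, catalog = catalog, rejected = flt$rejected,
                 parts = parts, guides = guides, guide = best,
                 cassette = cassette),
            class = "design_run")
}

#' @export
print.design_run <- function(x, ...) {
  cat("design run\n")
  cat(sprintf("  catalog: %d model(s) kept, %d rejected\n",
              nrow(x$catalog) - nrow(x$rejected), nrow(x$rejected)))
  cat(sprintf("  parts: %d promoter/terminator pair(s)\n",
              length(x$parts$promoters)))
  cat(sprintf("  guides: %d candidate(s), %d clean; selected %s (%s)\n",
              nrow(x$guides), sum(x$guides$clean), x$guide$spacer,
              x$guide$strand))
  print(x$cassette)
  invisible(x)
}
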