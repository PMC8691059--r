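# Readers/writers for the external formats: event/metadata TSV, gene
# annotations (GFF3/BED), FASTA, contig lengths, and YAML configuration.
# Internal coordinates are 0-based half-open everywhere; GFF3 (1-based
# inclusive) is converted on read. Strand is ignored throughout.

#' Read a candidate-event table (TSV)
#'
#' One row per candidate structural variant: `line_id`, `contig`, `start`
#' (0-based inclusive), `end` (0-based exclusive; equal to `start` for
#' insertions), `sv_type`, `length`, `channel` (`split_read` or
#' `read_depth`), and optionally `copy_number_change`. Lines starting with
#' `#` are treated as comments. Rows are validated against the coordinate
#' invariants and returned in file order.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return Data frame of validated events.
#' @export
read_event_table <- function(path) {
  df <- read_tsv_skip_header(path)
  required <- c("line_id", "contig", "start", "end", "sv_type", "length", "channel")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop_format("%s: missing required column(s): %s", path,
                paste(missing, collapse = ", "))
  df$line_id <- as.character(df$line_id)
  df$contig <- as.character(df$contig)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$length <- as.integer(df$length)
  if (!"copy_number_change" %in% names(df))
    df$copy_number_change <- rep(NA_real_, nrow(df))
  validate_event_table(df)
}

#' Write an event table with a provenance header
#' @param events Event data frame.
#' @param path Output path.
#' @param seed,config Recorded in the header comment.
#' @export
write_event_table <- function(events, path, seed = NULL, config = NULL) {
  write_tsv_with_header(events, path, seed = seed, config = config)
}

#' Read MA-line metadata (TSV)
#'
#' Columns: `line_id`, `genotype`, `population`, `generations` (g >= 1),
#' `callable_sites` (n, bp > 0), `gene_count` (m >= 0). `line_id` must be
#' unique.
#' @param path Path to a tab-separated file with header.
#' @return Data frame of line metadata.
#' @export
read_line_metadata <- function(path) {
  df <- read_tsv_skip_header(path)
  required <- c("line_id", "genotype", "population", "generations",
                "callable_sites", "gene_count")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop_format("%s: missing required column(s): %s", path,
                paste(missing, collapse = ", "))
  df$line_id <- as.character(df$line_id)
  validate_line_metadata(df)
}

validate_line_metadata <- function(df) {
  if (anyDuplicated(df$line_id))
    stop_format("line_id values must be unique (duplicate: %s)",
                df$line_id[duplicated(df$line_id)][1])
  if (any(df$generations < 1)) stop_format("generations must be >= 1")
  if (any(df$callable_sites <= 0)) stop_format("callable_sites must be > 0")
  if (any(df$gene_count < 0)) stop_format("gene_count must be >= 0")
  df
}

#' Write line metadata with a provenance header
#' @inheritParams write_event_table
#' @param metadata Metadata data frame.
#' @export
write_line_metadata <- function(metadata, path, seed = NULL, config = NULL) {
  write_tsv_with_header(metadata, path, seed = seed, config = config)
}

#' Read gene annotations from GFF3 or BED
#'
#' The format is auto-detected from the file extension (`.gff`/`.gff3`
#' vs `.bed`). GFF3 coordinates (1-based inclusive) are converted to the
#' internal 0-based half-open convention; BED is already half-open. For
#' GFF3, only `gene` features are kept when present (all features
#' otherwise). Genes are sorted by (contig, start). Overlapping genes
#' trigger a warning, or are merged when `merge_overlaps = TRUE`.
#'
#' @param path Annotation file.
#' @param merge_overlaps Merge genes that overlap one another instead of
#'   warning. Merged genes take the id of the first member.
#' @return Data frame with `gene_id`, `contig`, `start`, `end`.
#' @export
read_genes <- function(path, merge_overlaps = FALSE) {
  ext <- tolower(tools::file_ext(path))
  gr <- tryCatch({
    if (ext %in% c("gff", "gff3", "gtf")) {
      rtracklayer::import(path, format = "gff3")
    } else if (ext == "bed") {
      rtracklayer::import(path, format = "bed")
    } else {
      stop_format("%s: unrecognized annotation extension '%s' (want gff3 or bed)",
                  path, ext)
    }
  }, error = function(e) {
    stop_format("%s: failed to parse annotation: %s", path, conditionMessage(e))
  })

  if (ext %in% c("gff", "gff3", "gtf")) {
    type <- as.character(gr$type %||% character(0))
    if (any(type == "gene")) gr <- gr[type == "gene"]
  }
  ids <- as.character(gr$ID %||% gr$Name %||% gr$name %||% rep(NA_character_, length(gr)))
  blank <- is.na(ids) | ids == ""
  ids[blank] <- sprintf("gene_%04d", which(blank))

  genes <- data.frame(
    gene_id = ids,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L, # to 0-based half-open
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  genes <- genes[order(genes$contig, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  validate_genes(genes, merge_overlaps = merge_overlaps)
}

validate_genes <- function(genes, merge_overlaps = FALSE) {
  if (nrow(genes) == 0) return(genes)
  if (any(genes$start >= genes$end))
    stop_format("gene '%s': start must be < end",
                genes$gene_id[genes$start >= genes$end][1])
  has_overlap <- any(vapply(split(genes, genes$contig), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    nrow(g) > 1 && any(g$start[-1] < g$end[-nrow(g)])
  }, logical(1)))
  if (has_overlap) {
    if (merge_overlaps) {
      genes <- merge_gene_overlaps(genes)
    } else {
      warning("gene annotation contains overlapping genes; ",
              "overlap counts may double-count (use merge_overlaps = TRUE to merge)",
              call. = FALSE)
    }
  }
  genes
}

merge_gene_overlaps <- function(genes) {
  out <- lapply(split(genes, genes$contig), function(g) {
    g <- g[order(g$start), , drop = FALSE]
    red <- IRanges::reduce(IRanges::IRanges(g$start + 1L, g$end))
    idx <- findInterval(g$start, IRanges::start(red) - 1L)
    data.frame(gene_id = tapply(g$gene_id, idx, `[`, 1L),
               contig = g$contig[1],
               start = IRanges::start(red) - 1L,
               end = IRanges::end(red),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a FASTA file into a named character vector
#'
#' Case is preserved; duplicate contig names are an error.
#' @param path FASTA file.
#' @return Named character vector, one element per contig, in file order.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm))
    stop_format("%s: duplicate contig name '%s'", path, nm[duplicated(nm)][1])
  out <- as.character(ss)
  names(out) <- nm
  out
}

#' Write a named character vector of sequences as FASTA
#'
#' Line wrapping is normalized to `width` columns.
#' @param sequences Named character vector.
#' @param path Output path.
#' @param width Wrap width (bp per line).
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  stopifnot(!is.null(names(sequences)), !anyDuplicated(names(sequences)))
  ss <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(ss, path, width = as.integer(width))
  invisible(path)
}

#' Read contig lengths from a two-column TSV or a FASTA .fai index
#' @param path TSV with columns `contig`, `length` (header optional when
#'   the extension is `.fai`, whose first two columns are used).
#' @return Named integer vector of contig lengths.
#' @export
read_contig_lengths <- function(path) {
  if (tolower(tools::file_ext(path)) == "fai") {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    out <- as.integer(df[[2]])
    names(out) <- as.character(df[[1]])
  } else {
    df <- read_tsv_skip_header(path)
    if (!all(c("contig", "length") %in% names(df)))
      stop_format("%s: need columns 'contig' and 'length'", path)
    out <- as.integer(df$length)
    names(out) <- as.character(df$contig)
  }
  if (any(out <= 0)) stop_format("%s: contig lengths must be positive", path)
  out
}

#' Analysis configuration
#'
#' Bundles the classification thresholds and resampling settings used by
#' the command-line entry points; serializable to YAML.
#'
#' @param spec A [category_spec()].
#' @param complete_fraction Fraction of a gene that a CNV must cover to
#'   count as a complete gene deletion/duplication. Default 0.95.
#' @param bootstrap_replicates Bootstrap replicates for rate CIs.
#' @param resampling_replicates Replicates for the gene-overlap null.
#' @param breakpoint_tolerance Breakpoint tolerance (bp) for indel call
#'   matching.
#' @param reciprocal_overlap Reciprocal-overlap fraction for long/CNV call
#'   matching.
#' @param seed Integer RNG seed recorded in every output header.
#' @return An `svcmr_config` list.
#' @export
svcmr_config <- function(spec = category_spec(), complete_fraction = 0.95,
                         bootstrap_replicates = 10000L,
                         resampling_replicates = 1000L,
                         breakpoint_tolerance = 10L,
                         reciprocal_overlap = 0.5, seed = 1L) {
  stopifnot(complete_fraction > 0, complete_fraction <= 1,
            bootstrap_replicates >= 1, resampling_replicates >= 1,
            breakpoint_tolerance >= 0,
            reciprocal_overlap > 0, reciprocal_overlap <= 1)
  structure(list(spec = spec, complete_fraction = complete_fraction,
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 resampling_replicates = as.integer(resampling_replicates),
                 breakpoint_tolerance = as.integer(breakpoint_tolerance),
                 reciprocal_overlap = reciprocal_overlap,
                 seed = as.integer(seed)),
            class = "svcmr_config")
}

#' Read / write an analysis configuration as YAML
#' @param path YAML file.
#' @return For `read_config`, an `svcmr_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  spec <- do.call(category_spec, y$spec %||% list())
  do.call(svcmr_config, c(list(spec = spec), y[setdiff(names(y), "spec")]))
}

#' @rdname read_config
#' @param config An `svcmr_config`.
#' @export
write_config <- function(config, path) {
  y <- unclass(config)
  y$spec <- unclass(y$spec)
  yaml::write_yaml(y, path)
  invisible(path)
}
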