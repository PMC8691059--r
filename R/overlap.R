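# Observed gene-overlap statistics and the positional resampling null
# testing whether events hit genes more or less often than chance.

events_granges <- function(events) {
  # insertions are points; represent as 1 bp at the insertion site
  width <- pmax(events$end - events$start, 1L)
  GenomicRanges::GRanges(events$contig,
                         IRanges::IRanges(start = events$start + 1L,
                                          width = width))
}

genes_granges <- function(genes) {
  GenomicRanges::GRanges(genes$contig,
                         IRanges::IRanges(start = genes$start + 1L,
                                          end = genes$end))
}

#' Observed gene overlap per line and category
#'
#' An event overlaps a gene iff their half-open intervals intersect in at
#' least 1 bp. A gene counts as completely deleted/duplicated when the
#' union of that line-and-category's events covers more than
#' `complete_fraction` of its length. Each gene is counted once per line
#' per category even when hit by several events. Events on contigs absent
#' from the annotation raise a warning and count as non-genic.
#'
#' @param events Classified events.
#' @param genes Gene annotation data frame (0-based half-open).
#' @param complete_fraction Complete-overlap threshold (default 0.95).
#' @return `list(per_line = <line x category overlap counts>,`
#'   `event_overlaps = <logical per event>)`. `per_line` columns:
#'   `line_id`, `category`, `n_events`, `n_events_overlapping_genes`,
#'   `genes_partial` (genes hit but not completely),
#'   `genes_complete`.
#' @export
overlap_events_genes <- function(events, genes, complete_fraction = 0.95) {
  if (nrow(events) == 0) {
    return(list(per_line = data.frame(line_id = character(0),
                                      category = character(0),
                                      n_events = integer(0),
                                      n_events_overlapping_genes = integer(0),
                                      genes_partial = integer(0),
                                      genes_complete = integer(0),
                                      stringsAsFactors = FALSE),
                event_overlaps = logical(0)))
  }
  unknown <- setdiff(unique(events$contig), unique(genes$contig))
  if (length(unknown) > 0 && nrow(genes) > 0)
    warning("event contig(s) absent from gene annotation, counted as non-genic: ",
            paste(unknown, collapse = ", "), call. = FALSE)

  ev_gr <- events_granges(events)
  gn_gr <- genes_granges(genes)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(ev_gr, gn_gr))
  ev_hit <- rep(FALSE, nrow(events))
  ev_hit[unique(S4Vectors::queryHits(hits))] <- TRUE

  key <- interaction(events$line_id, as.character(events$category), drop = FALSE)
  groups <- split(seq_len(nrow(events)), key, drop = TRUE)
  rows <- lapply(names(groups), function(gname) {
    idx <- groups[[gname]]
    h <- hits[S4Vectors::queryHits(hits) %in% idx]
    gene_ids <- unique(S4Vectors::subjectHits(h))
    complete <- 0L
    for (gi in gene_ids) {
      inter <- IRanges::intersect(
        IRanges::reduce(IRanges::ranges(ev_gr[S4Vectors::queryHits(h)[S4Vectors::subjectHits(h) == gi]])),
        IRanges::ranges(gn_gr[gi]))
      cov <- sum(IRanges::width(inter))
      if (cov > complete_fraction * IRanges::width(gn_gr[gi]))
        complete <- complete + 1L
    }
    data.frame(line_id = events$line_id[idx[1]],
               category = as.character(events$category[idx[1]]),
               n_events = length(idx),
               n_events_overlapping_genes = sum(ev_hit[idx]),
               genes_partial = length(gene_ids) - complete,
               genes_complete = complete,
               stringsAsFactors = FALSE)
  })
  per_line <- do.call(rbind, rows)
  per_line <- per_line[order(per_line$line_id, per_line$category), , drop = FALSE]
  rownames(per_line) <- NULL
  list(per_line = per_line, event_overlaps = ev_hit)
}

#' Resampling null for gene overlap
#'
#' Re-places every observed event uniformly at random on its original
#' contig with its original length (start uniform on
#' `[0, contig_length - length]`, so nothing runs off the contig),
#' `n_replicates` times, and counts events overlapping at least one gene
#' per replicate. The observed count is compared with the empirical
#' nearest-rank 5th and 95th percentiles; a tie with either bound counts
#' as "within". Deterministic under a fixed seed.
#'
#' @param events Events (any category mix) whose placement is randomized.
#' @param contig_lengths Named vector of contig lengths covering every
#'   event contig.
#' @param genes Gene annotation data frame.
#' @param n_replicates Number of resampling replicates (default 1000).
#' @param seed RNG seed.
#' @return `list(observed, counts, percentile_5, percentile_95, verdict)`
#'   with `verdict` one of `"below"`, `"within"`, `"above"`.
#' @export
resample_null <- function(events, contig_lengths, genes,
                          n_replicates = 1000L, seed = NULL) {
  stopifnot(n_replicates >= 1)
  n_ev <- nrow(events)
  missing_ctg <- setdiff(unique(events$contig), names(contig_lengths))
  if (length(missing_ctg) > 0)
    stop_format("no contig length for: %s", paste(missing_ctg, collapse = ", "))
  span <- pmax(events$end - events$start, 1L) # insertions probe 1 bp
  too_long <- which(span > contig_lengths[events$contig])
  if (length(too_long) > 0)
    stop_format("event row %d (%d bp) is longer than contig %s",
                too_long[1], span[too_long[1]], events$contig[too_long[1]])

  # merged gene intervals per contig for fast any-overlap tests
  gmerged <- lapply(split(genes, genes$contig), function(g) {
    red <- IRanges::reduce(IRanges::IRanges(g$start + 1L, g$end))
    list(start0 = IRanges::start(red) - 1L, end0 = IRanges::end(red))
  })

  overlaps_any <- function(ctg, s, len) {
    gm <- gmerged[[ctg]]
    if (is.null(gm)) return(rep(FALSE, length(s)))
    # [s, s+len) hits a merged gene iff #(gene starts < s+len) > #(gene ends <= s)
    findInterval(s + len - 0.5, gm$start0) > findInterval(s + 0.5, gm$end0)
  }

  observed <- sum(vapply(seq_len(n_ev), function(k) {
    overlaps_any(events$contig[k], events$start[k], span[k])
  }, logical(1)))

  counts <- with_rng_seed(seed, {
    tot <- integer(n_replicates)
    for (k in seq_len(n_ev)) {
      smax <- contig_lengths[[events$contig[k]]] - span[k]
      s <- floor(stats::runif(n_replicates, 0, smax + 1))
      tot <- tot + overlaps_any(events$contig[k], s, span[k])
    }
    tot
  })

  srt <- sort(counts)
  p5 <- srt[ceiling(0.05 * n_replicates)]
  p95 <- srt[ceiling(0.95 * n_replicates)]
  verdict <- if (observed < p5) "below" else if (observed > p95) "above" else "within"
  list(observed = observed, counts = counts,
       percentile_5 = p5, percentile_95 = p95, verdict = verdict)
}

#' Resampling-null report per category (and optionally per line)
#'
#' Runs [resample_null()] on each event subset and tabulates observed
#' counts, percentile bands and verdicts.
#'
#' @inheritParams resample_null
#' @param per `"category"` (default) randomizes each category's pooled
#'   events; `"line"` additionally splits by MA line.
#' @return Data frame with one row per subset.
#' @export
resample_null_report <- function(events, contig_lengths, genes,
                                 n_replicates = 1000L, seed = NULL,
                                 per = c("category", "line")) {
  per <- match.arg(per)
  key <- if (per == "line")
    interaction(events$line_id, as.character(events$category), drop = TRUE)
  else factor(as.character(events$category))
  groups <- split(seq_len(nrow(events)), key, drop = TRUE)
  rows <- lapply(seq_along(groups), function(i) {
    idx <- groups[[i]]
    nd <- resample_null(events[idx, , drop = FALSE], contig_lengths, genes,
                        n_replicates = n_replicates,
                        seed = seed_stream(seed, i))
    data.frame(subset = names(groups)[i], n_events = length(idx),
               observed = nd$observed, percentile_5 = nd$percentile_5,
               percentile_95 = nd$percentile_95, verdict = nd$verdict,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gene deletion/duplication rate report
#'
#' Per-gene per-generation rates w = y / (2 g m) for CNV deletions and
#' duplications, separately for partial+complete and complete-only gene
#' overlap, aggregated per genotype, per population, and species-wide
#' (zero-event lines included everywhere) with bootstrap CIs.
#'
#' @param events Classified events (only `cnv_*` categories contribute).
#' @param genes Gene annotation.
#' @param metadata Line metadata with `gene_count` (m).
#' @param complete_fraction Complete-overlap threshold.
#' @param n_boot,seed Bootstrap settings.
#' @return Tidy data frame of rate-estimate rows with `measure` in
#'   `partial_and_complete` / `complete_only` and `category` in
#'   `cnv_deletion` / `cnv_duplication` / `cnv_both`.
#' @export
gene_rate_report <- function(events, genes, metadata,
                             complete_fraction = 0.95, n_boot = 10000L,
                             seed = NULL) {
  ov <- overlap_events_genes(events, genes,
                             complete_fraction = complete_fraction)$per_line
  cats <- c("cnv_deletion", "cnv_duplication")
  # per-line gene-hit counts: partial+complete and complete-only
  y_all <- y_cmp <- matrix(0L, nrow(metadata), 3,
                           dimnames = list(metadata$line_id,
                                           c(cats, "cnv_both")))
  for (r in seq_len(nrow(ov))) {
    if (!ov$category[r] %in% cats) next
    i <- match(ov$line_id[r], metadata$line_id)
    if (is.na(i)) next
    tot <- ov$genes_partial[r] + ov$genes_complete[r]
    y_all[i, ov$category[r]] <- y_all[i, ov$category[r]] + tot
    y_cmp[i, ov$category[r]] <- y_cmp[i, ov$category[r]] + ov$genes_complete[r]
  }
  y_all[, "cnv_both"] <- y_all[, 1] + y_all[, 2]
  y_cmp[, "cnv_both"] <- y_cmp[, 1] + y_cmp[, 2]

  denom <- 2 * metadata$generations * metadata$gene_count
  groupings <- list(species = list(all = rep(TRUE, nrow(metadata))),
                    population = split_index(metadata$population),
                    genotype = split_index(metadata$genotype))
  out <- list(); k <- 0L
  for (measure in c("partial_and_complete", "complete_only")) {
    y <- if (measure == "partial_and_complete") y_all else y_cmp
    w <- y / denom
    for (level in names(groupings)) {
      for (label in names(groupings[[level]])) {
        sel <- groupings[[level]][[label]]
        for (cat in colnames(y)) {
          k <- k + 1L
          row <- aggregate_rates(w[sel, cat],
                                 level = if (level == "species") "species" else level,
                                 label = label, category = cat,
                                 n_events = sum(y[sel, cat]),
                                 n_boot = n_boot, seed = seed_stream(seed, k))
          row$measure <- measure
          out[[k]] <- row
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
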