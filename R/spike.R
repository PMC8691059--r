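# Spiking known events into a reference genome to build a truth set for
# caller validation. One mutated haplotype is emitted per line; diploidy
# enters the analysis only through the 2gn rate denominator.

#' Spike events into a reference to produce a truth set
#'
#' Edits per event type: deletions (including CNV deletions) remove
#' `[start, end)`; insertions insert `length` random seeded bases at
#' `start`; tandem and CNV duplications insert a copy of `[start, end)`
#' immediately after `end` (a CNV duplication's +50% of two diploid copies
#' is represented as one haplotype edit). Events on a contig must be
#' pairwise disjoint; they are applied right to left so coordinates
#' compose. A per-line, per-contig liftover table maps reference to
#' mutated coordinates.
#'
#' @param reference Named character vector of contig sequences.
#' @param events Classified event data frame (a `line_id` column groups
#'   events into lines; absent, all events form line `"line1"`).
#' @param seed RNG seed for inserted bases.
#' @return A `truth_set`: `list(events, sequences, liftover)` where
#'   `sequences[[line]]` is a named character vector over all contigs and
#'   `liftover[[line]][[contig]]` is a data frame of
#'   `(ref_start, ref_end, delta)` rows (cumulative shift applying to
#'   reference positions at or beyond `ref_end`).
#' @export
spike_events <- function(reference, events, seed = NULL) {
  stopifnot(!is.null(names(reference)))
  if (!"line_id" %in% names(events)) events$line_id <- "line1"
  if (!"category" %in% names(events)) events <- classify_events(events)
  ref_len <- nchar(reference)

  bad <- which(!events$contig %in% names(reference))
  if (length(bad) > 0)
    stop_format("event row %d: contig '%s' not in reference", bad[1],
                events$contig[bad[1]])
  bad <- which(events$end > ref_len[events$contig] |
                 events$start > ref_len[events$contig])
  if (length(bad) > 0)
    stop_format("event row %d: event at [%d,%d) extends beyond contig '%s' (%d bp)",
                bad[1], events$start[bad[1]], events$end[bad[1]],
                events$contig[bad[1]], ref_len[events$contig[bad[1]]])

  with_rng_seed(seed, {
    sequences <- list(); liftover <- list()
    for (line in unique(events$line_id)) {
      ev_line <- events[events$line_id == line, , drop = FALSE]
      seqs <- reference
      lifts <- list()
      for (ctg in unique(ev_line$contig)) {
        ev <- ev_line[ev_line$contig == ctg, , drop = FALSE]
        ev <- ev[order(ev$start, ev$end), , drop = FALSE]
        check_disjoint(ev, ctg)
        seqs[[ctg]] <- apply_edits(reference[[ctg]], ev)
        lifts[[ctg]] <- data.frame(
          ref_start = ev$start, ref_end = ev$end,
          delta = cumsum(ev$signed_length_change))
      }
      sequences[[line]] <- seqs
      liftover[[line]] <- lifts
    }
    structure(list(events = events, sequences = sequences, liftover = liftover),
              class = "truth_set")
  })
}

check_disjoint <- function(ev, ctg) {
  if (nrow(ev) < 2) return(invisible())
  # insertions are points; identical start positions still collide
  s <- ev$start; e <- pmax(ev$end, ev$start + 1L)
  for (i in seq_len(nrow(ev) - 1L)) {
    if (s[i + 1L] < e[i] || ev$start[i + 1L] == ev$start[i])
      stop_format("overlapping events on contig %s: [%d,%d) and [%d,%d)",
                  ctg, ev$start[i], ev$end[i], ev$start[i + 1L], ev$end[i + 1L])
  }
  invisible()
}

apply_edits <- function(seq, ev) {
  # right-to-left so earlier coordinates stay valid
  for (i in rev(seq_len(nrow(ev)))) {
    s <- ev$start[i]; e <- ev$end[i]
    seq <- switch(ev$sv_type[i],
      deletion = ,
      cnv_deletion = paste0(substr(seq, 1L, s), substring(seq, e + 1L)),
      insertion = paste0(substr(seq, 1L, s), random_bases(ev$length[i]),
                         substring(seq, s + 1L)),
      tandem_duplication = ,
      cnv_duplication = paste0(substr(seq, 1L, e), substr(seq, s + 1L, e),
                               substring(seq, e + 1L)),
      stop_format("unknown sv_type '%s'", ev$sv_type[i]))
  }
  seq
}

random_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Map a reference position to mutated-haplotype coordinates
#'
#' @param truth A `truth_set` from [spike_events()].
#' @param line,contig Which haplotype.
#' @param pos 0-based reference position(s).
#' @return Mutated 0-based position(s); `NA` for positions removed by a
#'   deletion (or inside a duplicated segment's second copy ambiguity,
#'   positions map to their first copy).
#' @export
lift_position <- function(truth, line, contig, pos) {
  lt <- truth$liftover[[line]][[contig]]
  if (is.null(lt)) return(pos)
  ev <- truth$events
  ev <- ev[ev$line_id == line & ev$contig == contig, , drop = FALSE]
  ev <- ev[order(ev$start, ev$end), , drop = FALSE]
  deleting <- ev$sv_type %in% c("deletion", "cnv_deletion")
  vapply(pos, function(p) {
    inside_del <- deleting & ev$start <= p & p < ev$end
    if (any(inside_del)) return(NA_real_)
    prior <- lt$ref_end <= p
    p + if (any(prior)) lt$delta[max(which(prior))] else 0
  }, numeric(1))
}
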