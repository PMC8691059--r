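#' The six structural-variation mutation categories
#'
#' Order is fixed and used everywhere counts or rates are tabulated:
#' short insertions and deletions (< 50 bp, split-read detected), long
#' deletions and tandem duplications (>= 50 bp, split-read detected), and
#' deletions and duplications at copy-number-variable (CNV) sites
#' (>= 2,000 bp, read-depth detected).
#' @export
SV_CATEGORIES <- c("short_insertion", "short_deletion",
                   "long_deletion", "long_tandem_duplication",
                   "cnv_deletion", "cnv_duplication")

SV_TYPES <- c("insertion", "deletion", "tandem_duplication",
              "cnv_deletion", "cnv_duplication")
SV_CHANNELS <- c("split_read", "read_depth")

#' Category thresholds for event classification
#'
#' @param short_max Largest length (bp) of a "short" indel. Default 49.
#' @param long_min Smallest length (bp) of a "long" split-read event.
#'   Default 50.
#' @param cnv_min Smallest length (bp) of a read-depth (CNV) event.
#'   Default 2000.
#' @return A `category_spec` list.
#' @export
category_spec <- function(short_max = 49L, long_min = 50L, cnv_min = 2000L) {
  short_max <- as.integer(short_max); long_min <- as.integer(long_min)
  cnv_min <- as.integer(cnv_min)
  if (!(short_max < long_min && long_min <= cnv_min))
    stop_format("category_spec requires short_max < long_min <= cnv_min")
  if (short_max < 1L) stop_format("thresholds must be positive")
  structure(list(short_max = short_max, long_min = long_min, cnv_min = cnv_min),
            class = "category_spec")
}

#' Validate an event table against its structural invariants
#'
#' Checks column presence, coordinate/length consistency (half-open
#' `end - start == length` for deletions and duplications, `end == start`
#' for insertions), positive lengths, and legal type/channel values.
#' Errors name the offending row.
#'
#' @param events Data frame of candidate events (see [read_event_table()]).
#' @return The validated data frame, invisibly usable downstream.
#' @export
validate_event_table <- function(events) {
  required <- c("line_id", "contig", "start", "end", "sv_type", "length", "channel")
  missing <- setdiff(required, names(events))
  if (length(missing) > 0)
    stop_format("event table is missing column(s): %s", paste(missing, collapse = ", "))
  if (!"copy_number_change" %in% names(events))
    events$copy_number_change <- rep(NA_real_, nrow(events))
  if (nrow(events) == 0) return(events)

  bad <- which(!events$sv_type %in% SV_TYPES)
  if (length(bad) > 0)
    stop_format("row %d: unknown sv_type '%s'", bad[1], events$sv_type[bad[1]])
  bad <- which(!events$channel %in% SV_CHANNELS)
  if (length(bad) > 0)
    stop_format("row %d: unknown channel '%s'", bad[1], events$channel[bad[1]])
  bad <- which(!is.finite(events$length) | events$length < 1)
  if (length(bad) > 0)
    stop_format("row %d: length must be >= 1 (got %s)", bad[1], events$length[bad[1]])
  bad <- which(events$start < 0)
  if (length(bad) > 0)
    stop_format("row %d: negative start coordinate", bad[1])

  ins <- events$sv_type == "insertion"
  bad <- which(ins & events$end != events$start)
  if (length(bad) > 0)
    stop_format("row %d: insertion must have end == start (point coordinate)", bad[1])
  bad <- which(!ins & events$end - events$start != events$length)
  if (length(bad) > 0)
    stop_format("row %d: end - start (%d) != length (%d)", bad[1],
                events$end[bad[1]] - events$start[bad[1]], events$length[bad[1]])
  events
}

#' Classify candidate events into the six mutation categories
#'
#' The detection channel is the category authority: read-depth events are
#' CNV deletions/duplications (and must be at least `spec$cnv_min` bp);
#' split-read events are short (< `spec$long_min`) or long (>=) indels and
#' tandem duplications. Length alone never decides, because long-deletion
#' and CNV-deletion length ranges overlap. A split-read tandem duplication
#' below the long threshold is recorded as a short insertion, since its
#' detectable signature is inserted sequence.
#'
#' Adds `category` and `signed_length_change` (+length for insertions and
#' duplications, -length for deletions) columns.
#'
#' @param events Validated event data frame.
#' @param spec A [category_spec()].
#' @return The data frame with `category` and `signed_length_change` added.
#' @export
classify_events <- function(events, spec = category_spec()) {
  events <- validate_event_table(events)
  n <- nrow(events)
  if (n == 0) {
    events$category <- character(0)
    events$signed_length_change <- numeric(0)
    return(events)
  }

  rd <- events$channel == "read_depth"
  bad <- which(rd & !events$sv_type %in% c("cnv_deletion", "cnv_duplication"))
  if (length(bad) > 0)
    stop_format("row %d: read_depth channel requires a cnv_* sv_type", bad[1])
  bad <- which(!rd & events$sv_type %in% c("cnv_deletion", "cnv_duplication"))
  if (length(bad) > 0)
    stop_format("row %d: cnv_* sv_type requires the read_depth channel", bad[1])
  bad <- which(rd & events$length < spec$cnv_min)
  if (length(bad) > 0)
    stop_format("row %d: read_depth event of %d bp is below the CNV minimum (%d bp)",
                bad[1], events$length[bad[1]], spec$cnv_min)

  category <- character(n)
  category[events$sv_type == "cnv_deletion"] <- "cnv_deletion"
  category[events$sv_type == "cnv_duplication"] <- "cnv_duplication"
  sr <- !rd
  short <- sr & events$length < spec$long_min
  long <- sr & !short
  category[short & events$sv_type %in% c("insertion", "tandem_duplication")] <- "short_insertion"
  category[short & events$sv_type == "deletion"] <- "short_deletion"
  category[long & events$sv_type == "deletion"] <- "long_deletion"
  category[long & events$sv_type == "tandem_duplication"] <- "long_tandem_duplication"
  bad <- which(long & events$sv_type == "insertion")
  if (length(bad) > 0)
    stop_format("row %d: split_read insertion of %d bp has no category (long events are deletions or tandem duplications)",
                bad[1], events$length[bad[1]])

  deleting <- events$sv_type %in% c("deletion", "cnv_deletion")
  events$category <- factor(category, levels = SV_CATEGORIES)
  events$signed_length_change <- ifelse(deleting, -1, 1) * events$length
  events
}

#' Count classified events per category
#'
#' @param events Classified event data frame (with a `category` column).
#' @param line_id Optional line identifier; if given, only that line's
#'   events are counted.
#' @return Named integer vector over all six categories (zeros included).
#' @export
count_by_category <- function(events, line_id = NULL) {
  if (!is.null(line_id)) events <- events[events$line_id == line_id, , drop = FALSE]
  cat <- factor(as.character(events$category), levels = SV_CATEGORIES)
  table_to_int(table(cat))
}

table_to_int <- function(tab) {
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Per-line x per-category event count matrix
#'
#' Rows follow `metadata$line_id` (lines without events get zero rows),
#' columns are the six categories.
#'
#' @param events Classified events.
#' @param metadata Line metadata data frame (see [read_line_metadata()]).
#' @return Integer matrix, `n_lines` x 6.
#' @export
category_count_matrix <- function(events, metadata) {
  lines <- metadata$line_id
  m <- matrix(0L, nrow = length(lines), ncol = length(SV_CATEGORIES),
              dimnames = list(lines, SV_CATEGORIES))
  if (nrow(events) > 0) {
    tab <- table(factor(events$line_id, levels = lines),
                 factor(as.character(events$category), levels = SV_CATEGORIES))
    m[] <- as.integer(tab)
  }
  m
}
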