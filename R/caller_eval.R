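# Caller evaluation: score a structural-variant call set against a truth
# set (false discovery and false negative rates), plus a diff-based
# perfect caller that closes the simulation loop without external tools.

sv_family <- function(sv_type) {
  fam <- c(insertion = "insertion", deletion = "deletion",
           cnv_deletion = "deletion", tandem_duplication = "duplication",
           cnv_duplication = "duplication")
  out <- unname(fam[sv_type])
  if (anyNA(out)) stop_format("unknown sv_type '%s'", sv_type[is.na(out)][1])
  out
}

# Reporting category for a bare call record (no channel information):
# length decides within the call's type family.
call_category <- function(sv_type, length, spec = category_spec()) {
  fam <- sv_family(sv_type)
  ifelse(fam == "insertion", "short_insertion",
    ifelse(fam == "deletion",
      ifelse(length < spec$long_min, "short_deletion",
        ifelse(length < spec$cnv_min, "long_deletion", "cnv_deletion")),
      ifelse(length < spec$cnv_min, "long_tandem_duplication",
             "cnv_duplication")))
}

#' Diff-based perfect caller for spiked haplotypes
#'
#' Recovers spiked events by anchored comparison of each mutated contig
#' against its reference: scan the common prefix, then at each divergence
#' find the smallest skip (in reference: deletion; in mutated: insertion)
#' that re-synchronizes an anchor of `anchor` identical bases. An inserted
#' segment of at least `dup_min` bp that equals the adjacent reference
#' window (left or right) is reported as a tandem duplication of that
#' window; shorter or non-matching insertions are reported as insertions.
#' Correct whenever events are pairwise separated by at least one
#' unmutated base and the sequence is not anchor-length periodic at the
#' breakpoints.
#'
#' @param reference Named character vector of contig sequences.
#' @param mutated Named character vector for one line (same contig names).
#' @param anchor Re-synchronization anchor length in bp.
#' @param dup_min Minimum inserted length eligible for tandem-duplication
#'   classification (default 50, the long-event threshold).
#' @return Call data frame: `contig`, `start`, `end` (0-based half-open
#'   reference coordinates; `end == start` for insertions), `sv_type`,
#'   `length`.
#' @export
oracle_caller <- function(reference, mutated, anchor = 30L, dup_min = 50L) {
  if (!all(names(mutated) %in% names(reference)))
    stop_format("mutated contig(s) not present in the reference: %s",
                paste(setdiff(names(mutated), names(reference)), collapse = ", "))
  calls <- lapply(names(mutated), function(ctg) {
    diff_contig(reference[[ctg]], mutated[[ctg]], ctg, anchor, dup_min)
  })
  out <- do.call(rbind, calls)
  if (is.null(out))
    out <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), sv_type = character(0),
                      length = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

diff_contig <- function(ref, mut, ctg, anchor, dup_min) {
  r <- charToRaw(ref); m <- charToRaw(mut)
  nr <- length(r); nm <- length(m)
  i <- 1L; j <- 1L
  calls <- list(); k <- 0L

  anchored_at <- function(ri, mj) {
    # TRUE when ref[ri..] and mut[mj..] agree over the anchor (or over the
    # whole remainder, provided the remainders have equal length)
    rem_r <- nr - ri + 1L; rem_m <- nm - mj + 1L
    a <- min(anchor, rem_r, rem_m)
    if (a < anchor && rem_r != rem_m) return(FALSE)
    if (a <= 0L) return(rem_r == rem_m) # both exhausted
    all(r[ri:(ri + a - 1L)] == m[mj:(mj + a - 1L)])
  }

  while (i <= nr || j <= nm) {
    # advance over the common prefix
    n_cmp <- min(nr - i, nm - j) + 1L
    if (n_cmp > 0L) {
      mism <- which(r[i:(i + n_cmp - 1L)] != m[j:(j + n_cmp - 1L)])
      adv <- if (length(mism) == 0L) n_cmp else mism[1L] - 1L
      i <- i + adv; j <- j + adv
    }
    if (i > nr && j > nm) break
    # divergence: smallest skip that re-anchors
    found <- FALSE
    max_d <- max(nr - i, nm - j) + 1L
    for (d in seq_len(max_d)) {
      # cheap first-byte prefilter before the full anchor comparison
      del_possible <- i + d <= nr + 1L &&
        (i + d > nr || j > nm || r[i + d] == m[j])
      if (del_possible && anchored_at(i + d, j)) { # deletion of d bp
        k <- k + 1L
        calls[[k]] <- data.frame(contig = ctg, start = i - 1L,
                                 end = i - 1L + d, sv_type = "deletion",
                                 length = d, stringsAsFactors = FALSE)
        i <- i + d
        found <- TRUE
        break
      }
      ins_possible <- j + d <= nm + 1L &&
        (j + d > nm || i > nr || m[j + d] == r[i])
      if (ins_possible && anchored_at(i, j + d)) { # insertion of d bp
        ins <- m[j:(j + d - 1L)]
        type <- "insertion"
        s0 <- i - 1L; e0 <- i - 1L
        if (d >= dup_min) {
          left_ok <- i - 1L >= d && all(r[(i - d):(i - 1L)] == ins)
          right_ok <- i + d - 1L <= nr && all(r[i:(i + d - 1L)] == ins)
          if (left_ok) { type <- "tandem_duplication"; s0 <- i - 1L - d; e0 <- i - 1L }
          else if (right_ok) { type <- "tandem_duplication"; s0 <- i - 1L; e0 <- i - 1L + d }
        }
        k <- k + 1L
        calls[[k]] <- data.frame(contig = ctg, start = s0, end = e0,
                                 sv_type = type, length = d,
                                 stringsAsFactors = FALSE)
        j <- j + d
        found <- TRUE
        break
      }
    }
    if (!found)
      stop_format("could not resolve divergence at %s:%d; sequences do not appear to derive from this reference", ctg, i - 1L)
  }
  if (k == 0L) return(NULL)
  do.call(rbind, calls)
}

#' Match a call set against truth and compute FDR / FNR
#'
#' A call matches a truth event iff they share contig and category family
#' (insertion / deletion / duplication) and either both breakpoints agree
#' within `tol` bp (events shorter than 50 bp) or the reciprocal overlap
#' is at least `reciprocal_overlap` (long and CNV events). Matching is
#' greedy one-to-one by ascending breakpoint distance, ties broken by the
#' leftmost truth event. Unmatched calls are false positives; unmatched
#' truth events false negatives. FDR = FP / (TP + FP) (NA when there are
#' no calls); FNR = FN / n_truth (NA when there is no truth).
#'
#' @param truth Classified truth events.
#' @param calls Call records (`contig`, `start`, `end`, `sv_type`,
#'   `length`).
#' @param tol Breakpoint tolerance in bp for short events.
#' @param reciprocal_overlap Minimum reciprocal overlap for long/CNV
#'   events.
#' @param spec A [category_spec()] used to bucket false-positive calls.
#' @return `list(summary = per-category + overall data frame,`
#'   `matches = data frame of matched pairs)`.
#' @export
match_calls <- function(truth, calls, tol = 10L, reciprocal_overlap = 0.5,
                        spec = category_spec()) {
  stopifnot(tol >= 0, reciprocal_overlap > 0, reciprocal_overlap <= 1)
  n_t <- nrow(truth); n_c <- nrow(calls)
  t_fam <- if (n_t) sv_family(truth$sv_type) else character(0)
  c_fam <- if (n_c) sv_family(calls$sv_type) else character(0)
  t_cat <- if ("category" %in% names(truth)) as.character(truth$category)
           else call_category(truth$sv_type, truth$length, spec)

  cand <- NULL
  if (n_t > 0 && n_c > 0) {
    pairs <- expand.grid(ti = seq_len(n_t), ci = seq_len(n_c))
    keep <- truth$contig[pairs$ti] == calls$contig[pairs$ci] &
      t_fam[pairs$ti] == c_fam[pairs$ci]
    pairs <- pairs[keep, , drop = FALSE]
    if (nrow(pairs) > 0) {
      ts <- truth$start[pairs$ti]; te <- truth$end[pairs$ti]
      tl <- truth$length[pairs$ti]
      cs <- calls$start[pairs$ci]; ce <- calls$end[pairs$ci]
      cl <- calls$length[pairs$ci]
      short <- tl < 50
      bp_dist <- abs(ts - cs) + abs(te - ce)
      inter <- pmax(0, pmin(te, ce) - pmax(ts, cs))
      ok_short <- short & abs(ts - cs) <= tol & abs(te - ce) <= tol &
        abs(tl - cl) <= tol
      ok_long <- !short & inter >= reciprocal_overlap * tl &
        inter >= reciprocal_overlap * cl
      keep2 <- ok_short | ok_long
      cand <- data.frame(ti = pairs$ti[keep2], ci = pairs$ci[keep2],
                         dist = bp_dist[keep2])
    }
  }

  matched_t <- integer(0); matched_c <- integer(0)
  if (!is.null(cand) && nrow(cand) > 0) {
    cand <- cand[order(cand$dist, truth$start[cand$ti]), , drop = FALSE]
    used_t <- rep(FALSE, n_t); used_c <- rep(FALSE, n_c)
    for (r in seq_len(nrow(cand))) {
      ti <- cand$ti[r]; ci <- cand$ci[r]
      if (!used_t[ti] && !used_c[ci]) {
        used_t[ti] <- TRUE; used_c[ci] <- TRUE
        matched_t <- c(matched_t, ti); matched_c <- c(matched_c, ci)
      }
    }
  }

  fp_idx <- setdiff(seq_len(n_c), matched_c)
  fp_cat <- if (length(fp_idx)) call_category(calls$sv_type[fp_idx],
                                              calls$length[fp_idx], spec)
            else character(0)
  rows <- lapply(c(SV_CATEGORIES, "overall"), function(cat) {
    if (cat == "overall") {
      in_t <- seq_len(n_t); tp <- length(matched_t); fp <- length(fp_idx)
    } else {
      in_t <- which(t_cat == cat)
      tp <- sum(matched_t %in% in_t)
      fp <- sum(fp_cat == cat)
    }
    nt <- length(in_t); fn <- nt - tp
    data.frame(category = cat, n_truth = nt, n_calls = tp + fp,
               true_positives = tp, false_positives = fp,
               false_negatives = fn,
               fdr = if (tp + fp > 0) fp / (tp + fp) else NA_real_,
               fnr = if (nt > 0) fn / nt else NA_real_,
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  matches <- data.frame(truth_index = matched_t, call_index = matched_c)
  list(summary = summary, matches = matches)
}

#' Read a call table (TSV)
#'
#' Minimal converter for external caller output normalized to TSV:
#' columns `contig`, `start`, `end`, `sv_type`, `length`.
#' @param path TSV path.
#' @return Call data frame.
#' @export
read_call_table <- function(path) {
  df <- read_tsv_skip_header(path)
  required <- c("contig", "start", "end", "sv_type", "length")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop_format("%s: missing required column(s): %s", path,
                paste(missing, collapse = ", "))
  df$contig <- as.character(df$contig)
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$length <- as.integer(df$length)
  df
}
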