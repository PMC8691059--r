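# Mutation-rate estimators and their aggregation. Per-line rates follow
# u_i = x_i / (2 g n) (events of category i per callable bp per
# generation), v_i = sum_j l_ij / (2 g n) (length-adjusted), and
# w_i = y_i / (2 g m) (genes hit per gene per generation). Group-level
# point estimates are unweighted means over MA lines (zero-event lines
# included) with seeded percentile-bootstrap confidence intervals.

#' Per-line count-based mutation rate u = x / (2 g n)
#'
#' @param x Event count(s) for one category.
#' @param g MA generations (>= 1).
#' @param n Callable sites in bp (> 0).
#' @return Rate per bp per generation; vectorized over equal-length inputs.
#' @export
line_rate <- function(x, g, n) {
  if (any(g < 1) || any(n <= 0))
    stop_format("line_rate requires g >= 1 and n > 0")
  if (any(x < 0)) stop_format("event counts must be >= 0")
  x / (2 * g * n)
}

#' Per-line length-adjusted rate v = sum(lengths) / (2 g n)
#'
#' Equals `line_rate(x, g, n) * mean(lengths)` for a single line; the
#' identity does not survive cross-line averaging.
#'
#' @param lengths Event lengths (bp) for one line and category.
#' @inheritParams line_rate
#' @return Rate in bp altered per bp per generation.
#' @export
line_length_adjusted_rate <- function(lengths, g, n) {
  if (g < 1 || n <= 0)
    stop_format("line_length_adjusted_rate requires g >= 1 and n > 0")
  sum(lengths) / (2 * g * n)
}

#' Per-line total-length and net-length rates
#'
#' Total-length rate is `sum_i v_i`; net-length rate is `sum_i c_i v_i`
#' with c = +1 for insertions/duplications and -1 for deletions, measuring
#' genome-size drift. Also reports the raw net bp change.
#'
#' @param events Classified events for one line (may be empty).
#' @inheritParams line_rate
#' @return One-row data frame: `total_length_rate`, `net_length_rate`,
#'   `net_bp_change`.
#' @export
line_net_rates <- function(events, g, n) {
  if (g < 1 || n <= 0) stop_format("line_net_rates requires g >= 1 and n > 0")
  total <- sum(events$length) / (2 * g * n)
  net_bp <- sum(events$signed_length_change)
  data.frame(total_length_rate = total,
             net_length_rate = net_bp / (2 * g * n),
             net_bp_change = net_bp)
}

#' Per-line per-gene rate w = y / (2 g m)
#'
#' @param y Number of genes overlapped by events of one category.
#' @param g MA generations.
#' @param m Total genes in the line's assembly (> 0).
#' @return Rate per gene per generation.
#' @export
line_gene_rate <- function(y, g, m) {
  if (any(m <= 0)) stop_format("line_gene_rate requires gene count m > 0")
  if (any(g < 1)) stop_format("line_gene_rate requires g >= 1")
  y / (2 * g * m)
}

# Seeded percentile bootstrap for a mean over lines.
bootstrap_ci_mean <- function(values, n_boot = 10000L, seed = NULL,
                              conf = 0.95) {
  values <- unname(values)
  n <- length(values)
  if (n == 0) stop_format("cannot bootstrap an empty group")
  if (n == 1 || all(values == values[1]))
    return(c(ci_low = values[1], ci_high = values[1]))
  means <- with_rng_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    rowMeans(matrix(values[idx], nrow = n_boot))
  })
  alpha <- (1 - conf) / 2
  q <- stats::quantile(means, c(alpha, 1 - alpha), names = FALSE)
  c(ci_low = q[1], ci_high = q[2])
}

#' Aggregate per-line rates to a group-level estimate with a bootstrap CI
#'
#' The point estimate is the unweighted mean of per-line rates, including
#' lines with zero events, matching the species-wide convention that all
#' MA lines contribute to the denominator even when no events were
#' observed in their population. The CI is a seeded nonparametric
#' percentile bootstrap over lines.
#'
#' @param values Per-line rates for one group (one value per line).
#' @param level One of `"line"`, `"genotype"`, `"population"`, `"species"`.
#' @param label Group label (genotype/population name, or species).
#' @param category Category (or aggregate) label.
#' @param n_events Total events behind the rates, for reporting.
#' @param n_boot Bootstrap replicates.
#' @param seed RNG seed.
#' @param conf Confidence level.
#' @return One-row data frame (a rate-estimate row).
#' @export
aggregate_rates <- function(values, level, label, category = NA_character_,
                            n_events = NA_integer_, n_boot = 10000L,
                            seed = NULL, conf = 0.95) {
  level <- match.arg(level, c("line", "genotype", "population", "species"))
  ci <- bootstrap_ci_mean(values, n_boot = n_boot, seed = seed, conf = conf)
  data.frame(level = level, group = label, category = category,
             rate = mean(values), ci_low = unname(ci["ci_low"]),
             ci_high = unname(ci["ci_high"]),
             n_lines = length(values), n_events = n_events,
             stringsAsFactors = FALSE)
}

# Pooled alternative estimator: summed counts over summed exposures.
pooled_rate <- function(x, g, n) sum(x) / sum(2 * g * n)

#' Full rate table across levels and categories
#'
#' Computes per-line count-based and length-adjusted rates for each of the
#' six categories, then aggregates to genotype, population, and
#' species-wide estimates with bootstrap CIs. Per-line denominators are
#' each line's own `2 g n`; lines never share denominators.
#'
#' @param events Classified events.
#' @param metadata Line metadata.
#' @param n_boot Bootstrap replicates per CI.
#' @param seed RNG seed for the bootstrap.
#' @param pooled Also emit pooled-count estimates
#'   (`measure = "count_pooled"`) for comparison.
#' @return Tidy data frame with one rate-estimate row per
#'   level x group x category x measure (`count` or `length_adjusted`).
#' @export
rate_table <- function(events, metadata, n_boot = 10000L, seed = NULL,
                       pooled = FALSE) {
  counts <- category_count_matrix(events, metadata)
  exposure <- 2 * metadata$generations * metadata$callable_sites
  urate <- counts / exposure

  lsum <- matrix(0, nrow(metadata), length(SV_CATEGORIES),
                 dimnames = dimnames(counts))
  if (nrow(events) > 0) {
    agg <- stats::aggregate(events$length,
                            by = list(line_id = events$line_id,
                                      category = as.character(events$category)),
                            FUN = sum)
    for (r in seq_len(nrow(agg))) {
      i <- match(agg$line_id[r], metadata$line_id)
      if (!is.na(i)) lsum[i, agg$category[r]] <- agg$x[r]
    }
  }
  vrate <- lsum / exposure

  groupings <- list(
    species = list(species = rep(TRUE, nrow(metadata))),
    population = split_index(metadata$population),
    genotype = split_index(metadata$genotype))

  out <- list(); k <- 0L
  for (measure in c("count", "length_adjusted")) {
    mat <- if (measure == "count") urate else vrate
    for (level in names(groupings)) {
      for (label in names(groupings[[level]])) {
        sel <- groupings[[level]][[label]]
        for (cat in SV_CATEGORIES) {
          k <- k + 1L
          row <- aggregate_rates(mat[sel, cat],
                                 level = if (level == "species") "species" else level,
                                 label = if (level == "species") "all" else label,
                                 category = cat,
                                 n_events = sum(counts[sel, cat]),
                                 n_boot = n_boot, seed = seed_stream(seed, k))
          row$measure <- measure
          out[[k]] <- row
        }
      }
    }
  }
  res <- do.call(rbind, out)
  if (pooled) {
    pooled_rows <- lapply(SV_CATEGORIES, function(cat) {
      data.frame(level = "species", group = "all", category = cat,
                 rate = pooled_rate(counts[, cat], metadata$generations,
                                    metadata$callable_sites),
                 ci_low = NA_real_, ci_high = NA_real_,
                 n_lines = nrow(metadata), n_events = sum(counts[, cat]),
                 measure = "count_pooled", stringsAsFactors = FALSE)
    })
    res <- rbind(res, do.call(rbind, pooled_rows))
  }
  rownames(res) <- NULL
  res
}

split_index <- function(f) {
  lapply(split(seq_along(f), f), function(i) seq_along(f) %in% i)
}

# Independent sub-seeds for the k-th bootstrap in a table, kept below 2^31.
seed_stream <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 7919 + k * 104729) %% 2147483647
}

#' Per-line total/net length rates for all lines
#'
#' @inheritParams rate_table
#' @return Data frame with one row per line: `line_id`,
#'   `total_length_rate`, `net_length_rate`, `net_bp_change`.
#' @export
net_rate_table <- function(events, metadata) {
  rows <- lapply(seq_len(nrow(metadata)), function(i) {
    ev <- events[events$line_id == metadata$line_id[i], , drop = FALSE]
    cbind(data.frame(line_id = metadata$line_id[i], stringsAsFactors = FALSE),
          line_net_rates(ev, metadata$generations[i],
                         metadata$callable_sites[i]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Coefficient of variation of rates across genotypes
#'
#' Sample standard deviation (n-1 denominator) over the mean. Undefined
#' (returned as `NA`) when the mean is not positive.
#' @param rates Per-genotype rate estimates.
#' @return CV, or `NA_real_` when undefined.
#' @export
coefficient_of_variation <- function(rates) {
  m <- mean(rates)
  if (!is.finite(m) || m <= 0) return(NA_real_)
  stats::sd(rates) / m
}

#' Insertion-to-deletion event-count ratio
#'
#' @param n_ins,n_del Category counts.
#' @param digits Reporting precision (default two decimals).
#' @return `n_ins / n_del` rounded; `NA` when no deletions were observed.
#' @export
insertion_deletion_ratio <- function(n_ins, n_del, digits = 2) {
  if (n_del == 0) return(NA_real_)
  round(n_ins / n_del, digits)
}

#' Fraction of events concentrated in the single most-mutated line
#'
#' @param events Event data frame with `line_id`.
#' @return Proportion in \[0, 1\] (`NA` for an empty set).
#' @export
top_line_fraction <- function(events) {
  if (nrow(events) == 0) return(NA_real_)
  max(table(events$line_id)) / nrow(events)
}
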