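# Forward simulation of a mutation-accumulation (MA) experiment: genomes,
# gene annotations, line pedigrees, and mutation events drawn under known
# per-category rates, so every downstream estimator can be checked against
# ground truth.

#' Default per-category mutation rates (per bp per generation)
#'
#' Species-wide point estimates for the six categories in a multi-genotype
#' Daphnia magna MA experiment (x 1e-10: insertions 2.72, deletions 10.68,
#' long deletions 0.98, tandem duplications 0.06, CNV deletions 3.05, CNV
#' duplications 3.48).
#' @export
default_category_rates <- function() {
  c(short_insertion = 2.72e-10, short_deletion = 1.068e-9,
    long_deletion = 9.8e-11, long_tandem_duplication = 6e-12,
    cnv_deletion = 3.05e-10, cnv_duplication = 3.48e-10)
}

#' Per-line generation counts emulating the study pedigree
#'
#' For 66 lines the pattern sums to 819 generations (mean 12.4 per line):
#' 12 generations per line with 27 lines at 13, spread evenly. For other
#' line counts a flat 12 generations is used.
#' @param n_lines Number of MA lines.
#' @return Integer vector of generation counts.
#' @export
default_generations <- function(n_lines) {
  g <- rep(12L, n_lines)
  if (n_lines == 66L) g[round(seq(1, n_lines, length.out = 27))] <- 13L
  g
}

#' Configuration for a synthetic MA experiment
#'
#' Defaults emulate a 9-genotype, 3-population design: 66 MA lines
#' (7/7/8 per genotype within each population), 819 total generations,
#' 60 Mb of callable genome (6 contigs of 10 Mb), and the default
#' per-category rates applied homogeneously across populations.
#'
#' Length models: short indels are geometric on 1..49 with mean ~3.7 bp;
#' long events log-uniform on [50, 6000] bp; CNVs multiples of 1,000 bp on
#' [2000, 10000]. CNV deletions carry a copy-number change of -0.5 or
#' -1.0 with equal probability; CNV duplications always +0.5.
#'
#' @param populations List of `list(name, n_genotypes, rates)` entries;
#'   `rates` is a named per-category vector (per bp per generation).
#' @param lines_per_genotype Integer vector recycled across each
#'   population's genotypes.
#' @param generations `NULL` (default pedigree), a scalar, or a per-line
#'   vector.
#' @param genome `list(n_contigs, contig_length, gc)`.
#' @param genes `list(count, length)` for [simulate_genome()].
#' @param callable_sites Callable bp per line (denominator n); defaults
#'   to the full genome length.
#' @param spec A [category_spec()].
#' @param seed Integer RNG seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(populations = NULL,
                              lines_per_genotype = c(7L, 7L, 8L),
                              generations = NULL,
                              genome = list(n_contigs = 6L,
                                            contig_length = 1e7, gc = 0.4),
                              genes = list(count = 200L, length = 2000L),
                              callable_sites = NULL,
                              spec = category_spec(),
                              seed = 1L) {
  if (is.null(populations)) {
    r <- default_category_rates()
    populations <- list(
      list(name = "Finland", n_genotypes = 3L, rates = r),
      list(name = "Germany", n_genotypes = 3L, rates = r),
      list(name = "Israel", n_genotypes = 3L, rates = r))
  }
  for (p in populations) {
    stopifnot(!is.null(p$name), !is.null(p$n_genotypes), !is.null(p$rates))
    if (!all(SV_CATEGORIES %in% names(p$rates)))
      stop_format("population '%s': rates must name all six categories", p$name)
    if (any(p$rates < 0)) stop_format("rates must be >= 0")
  }
  genome$n_contigs <- as.integer(genome$n_contigs)
  genome$contig_length <- as.numeric(genome$contig_length)
  genome$gc <- genome$gc %||% 0.4
  if (genome$contig_length < 10000)
    stop_format("contig_length must be at least the longest possible event (10 kb)")
  structure(list(populations = populations,
                 lines_per_genotype = as.integer(lines_per_genotype),
                 generations = generations, genome = genome, genes = genes,
                 callable_sites = callable_sites %||%
                   (genome$n_contigs * genome$contig_length),
                 spec = spec, seed = as.integer(seed)),
            class = "simulation_config")
}

length_model_means <- function(spec) {
  long_max <- 6000
  c(short_insertion = 3.7, short_deletion = 3.7,
    long_deletion = (long_max - spec$long_min) / log(long_max / spec$long_min),
    long_tandem_duplication = (long_max - spec$long_min) / log(long_max / spec$long_min),
    cnv_deletion = mean(seq(spec$cnv_min, 10000, by = 1000)),
    cnv_duplication = mean(seq(spec$cnv_min, 10000, by = 1000)))
}

draw_event_lengths <- function(category, n, spec) {
  if (n == 0) return(integer(0))
  switch(category,
    short_insertion = ,
    short_deletion = {
      # geometric on 1..short_max with mean ~3.7
      x <- 1L + stats::rgeom(n, prob = 1 / 3.7)
      while (any(x > spec$short_max))
        x[x > spec$short_max] <- 1L + stats::rgeom(sum(x > spec$short_max), prob = 1 / 3.7)
      x
    },
    long_deletion = ,
    long_tandem_duplication = {
      x <- round(exp(stats::runif(n, log(spec$long_min), log(6000))))
      pmin.int(pmax.int(as.integer(x), spec$long_min), 6000L)
    },
    cnv_deletion = ,
    cnv_duplication = {
      grid <- seq(spec$cnv_min, 10000L, by = 1000L)
      as.integer(sample(grid, n, replace = TRUE))
    },
    stop_format("unknown category '%s'", category))
}

category_to_type <- c(short_insertion = "insertion", short_deletion = "deletion",
                      long_deletion = "deletion",
                      long_tandem_duplication = "tandem_duplication",
                      cnv_deletion = "cnv_deletion",
                      cnv_duplication = "cnv_duplication")

#' Simulate an MA experiment: metadata plus true mutation events
#'
#' For each line and category i, the event count is Poisson with mean
#' `rate_i * 2 * g * n` (the diploid exposure), positions are uniform over
#' the genome contigs, and lengths follow the per-category length models.
#' Events on a line are rejection-sampled to be pairwise disjoint so they
#' can later be spiked into a reference. Deterministic under a fixed seed.
#'
#' @param config A [simulation_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return `list(metadata = <line metadata>, events = <classified events>)`.
#' @export
simulate_experiment <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  genome_len <- config$genome$n_contigs * config$genome$contig_length
  contig_names <- sprintf("ctg%02d", seq_len(config$genome$n_contigs))
  clen <- config$genome$contig_length

  # pedigree
  meta <- list(); k <- 0L
  for (p in config$populations) {
    for (gt in seq_len(p$n_genotypes)) {
      geno <- sprintf("%s%d", toupper(substr(p$name, 1, 2)), gt)
      n_l <- config$lines_per_genotype[(gt - 1L) %% length(config$lines_per_genotype) + 1L]
      for (l in seq_len(n_l)) {
        k <- k + 1L
        meta[[k]] <- data.frame(line_id = sprintf("%s_L%d", geno, l),
                                genotype = geno, population = p$name,
                                stringsAsFactors = FALSE)
      }
    }
  }
  metadata <- do.call(rbind, meta)
  n_lines <- nrow(metadata)
  gen <- config$generations
  metadata$generations <-
    if (is.null(gen)) default_generations(n_lines)
    else if (length(gen) == 1L) rep(as.integer(gen), n_lines)
    else { stopifnot(length(gen) == n_lines); as.integer(gen) }
  metadata$callable_sites <- config$callable_sites
  metadata$gene_count <- config$genes$count %||% 0L

  # sanity check: the disjoint-event model breaks when mutations are
  # expected to rewrite a large fraction of the genome
  mean_len <- length_model_means(config$spec)
  pop_of <- vapply(config$populations, `[[`, "", "name")
  exp_bp <- 0
  for (i in seq_len(n_lines)) {
    rates <- config$populations[[match(metadata$population[i], pop_of)]]$rates
    exp_bp <- exp_bp + sum(rates[SV_CATEGORIES] * 2 * metadata$generations[i] *
                             metadata$callable_sites[i] * mean_len[SV_CATEGORIES])
  }
  if (exp_bp > 0.1 * genome_len)
    stop_format("configured rates imply %.0f bp of expected events, over 10%% of the %.0f bp genome",
                exp_bp, genome_len)

  events <- with_rng_seed(seed, {
    rows <- vector("list", n_lines)
    for (i in seq_len(n_lines)) {
      rates <- config$populations[[match(metadata$population[i], pop_of)]]$rates
      exposure <- 2 * metadata$generations[i] * metadata$callable_sites[i]
      line_rows <- list()
      for (cat in SV_CATEGORIES) {
        x <- stats::rpois(1L, rates[[cat]] * exposure)
        if (x == 0L) next
        len <- draw_event_lengths(cat, x, config$spec)
        line_rows[[cat]] <- data.frame(
          line_id = metadata$line_id[i],
          contig = NA_character_, start = NA_integer_, end = NA_integer_,
          sv_type = unname(category_to_type[cat]), length = len,
          channel = if (grepl("^cnv", cat)) "read_depth" else "split_read",
          copy_number_change = switch(cat,
            cnv_duplication = rep(0.5, x),
            cnv_deletion = sample(c(-0.5, -1), x, replace = TRUE),
            rep(NA_real_, x)),
          stringsAsFactors = FALSE)
      }
      if (length(line_rows) == 0) next
      ev <- do.call(rbind, line_rows)
      rows[[i]] <- place_events_disjoint(ev, contig_names, clen)
    }
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows) == 0) {
      empty <- data.frame(line_id = character(0), contig = character(0),
                          start = integer(0), end = integer(0),
                          sv_type = character(0), length = integer(0),
                          channel = character(0), copy_number_change = numeric(0),
                          stringsAsFactors = FALSE)
      empty
    } else {
      out <- do.call(rbind, rows)
      rownames(out) <- NULL
      out
    }
  })
  list(metadata = metadata, events = classify_events(events, config$spec))
}

# Uniform placement of one line's events across contigs, rejection-sampled
# until pairwise disjoint (insertions are points; identical insertion
# positions also count as collisions). Cap 1000 attempts per event.
place_events_disjoint <- function(ev, contig_names, clen) {
  n <- nrow(ev)
  ord <- order(ev$length, decreasing = TRUE) # place big events first
  ev <- ev[ord, , drop = FALSE]
  placed_start <- numeric(0); placed_end <- numeric(0); placed_contig <- character(0)
  for (i in seq_len(n)) {
    len <- ev$length[i]
    is_ins <- ev$sv_type[i] == "insertion"
    span <- if (is_ins) 1 else len
    ok <- FALSE
    for (attempt in seq_len(1000L)) {
      ctg <- sample(contig_names, 1L)
      s <- floor(stats::runif(1, 0, clen - span + 1))
      e <- s + span
      same <- placed_contig == ctg
      if (!any(same & placed_start < e & placed_end > s)) { ok <- TRUE; break }
    }
    if (!ok)
      stop_format("could not place a %d bp event disjointly after 1000 attempts; lower the rates or enlarge the genome", len)
    placed_start <- c(placed_start, s); placed_end <- c(placed_end, e)
    placed_contig <- c(placed_contig, ctg)
    ev$contig[i] <- ctg
    ev$start[i] <- as.integer(s)
    ev$end[i] <- as.integer(if (is_ins) s else s + len)
  }
  ev[order(ev$contig, ev$start), , drop = FALSE]
}

#' Simulate a reference genome and a disjoint gene annotation
#'
#' Sequences are i.i.d. bases at the configured GC fraction; genes of the
#' configured length are distributed across contigs and placed uniformly
#' at random subject to being non-overlapping (exact uniform conditional
#' placement via the gap-composition construction, so no rejection loop is
#' needed).
#'
#' @param config A [simulation_config()]; `config$genes$count * length`
#'   must be at most 80% of the genome.
#' @param seed RNG seed; defaults to `config$seed`.
#' @return `list(sequences = named character, genes = data frame)`.
#' @export
simulate_genome <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  n_ctg <- config$genome$n_contigs
  clen <- as.integer(config$genome$contig_length)
  gc <- config$genome$gc
  m <- as.integer(config$genes$count %||% 0L)
  glen <- as.integer(config$genes$length %||% 2000L)
  if (m * as.numeric(glen) > 0.8 * n_ctg * as.numeric(clen))
    stop_format("infeasible gene packing: %d genes x %d bp exceed 80%% of the genome", m, glen)

  with_rng_seed(seed, {
    base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    sequences <- vapply(seq_len(n_ctg), function(i) {
      paste(sample(names(base_prob), clen, replace = TRUE, prob = base_prob),
            collapse = "")
    }, character(1))
    names(sequences) <- sprintf("ctg%02d", seq_len(n_ctg))

    genes <- NULL
    if (m > 0) {
      per_ctg <- tabulate(sample.int(n_ctg, m, replace = TRUE), nbins = n_ctg)
      parts <- list()
      gid <- 0L
      for (i in seq_len(n_ctg)) {
        k <- per_ctg[i]
        if (k == 0) next
        slack <- clen - k * glen
        if (slack < 0)
          stop_format("infeasible gene packing on contig %d", i)
        u <- sort(floor(stats::runif(k, 0, slack + 1)))
        starts <- u + (seq_len(k) - 1L) * glen
        parts[[i]] <- data.frame(
          gene_id = sprintf("gene_%04d", gid + seq_len(k)),
          contig = names(sequences)[i],
          start = as.integer(starts), end = as.integer(starts + glen),
          stringsAsFactors = FALSE)
        gid <- gid + k
      }
      genes <- do.call(rbind, parts)
      rownames(genes) <- NULL
    } else {
      genes <- data.frame(gene_id = character(0), contig = character(0),
                          start = integer(0), end = integer(0),
                          stringsAsFactors = FALSE)
    }
    list(sequences = sequences, genes = genes)
  })
}
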