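# Shared fixtures and independent brute-force oracles used across tests.

uniform_rates <- function(rate) stats::setNames(rep(rate, 6), SV_CATEGORIES)

three_pop_config <- function(rates_f, rates_g = rates_f, rates_i = rates_f,
                             ...) {
  simulation_config(populations = list(
    list(name = "Finland", n_genotypes = 3L, rates = rates_f),
    list(name = "Germany", n_genotypes = 3L, rates = rates_g),
    list(name = "Israel", n_genotypes = 3L, rates = rates_i)), ...)
}

make_event <- function(line_id = "L1", contig = "ctg01", start = 100L,
                       sv_type = "deletion", length = 10L,
                       channel = "split_read", copy_number_change = NA_real_) {
  end <- if (sv_type == "insertion") start else start + length
  data.frame(line_id = line_id, contig = contig, start = as.integer(start),
             end = as.integer(end), sv_type = sv_type,
             length = as.integer(length), channel = channel,
             copy_number_change = copy_number_change,
             stringsAsFactors = FALSE)
}

make_metadata <- function(line_id, genotype = line_id, population = "Germany",
                          generations = 12L, callable_sites = 6e7,
                          gene_count = 25000L) {
  data.frame(line_id = line_id, genotype = genotype, population = population,
             generations = generations, callable_sites = callable_sites,
             gene_count = gene_count, stringsAsFactors = FALSE)
}

# Event set mirroring the observed study spectrum: 23 short insertions,
# 39 short deletions, 6 long deletions, 1 tandem duplication, and 52 CNV
# events (10 deletions, 42 duplications) of which 39 sit in one line.
make_study_events <- function(seed = 402) {
  withr::local_seed(seed)
  ev <- list()
  lines <- sprintf("L%02d", 1:66)
  spread <- function(n) sample(lines[1:27], n, replace = TRUE)
  ev$ins <- do.call(rbind, lapply(seq_len(23), function(i)
    make_event(spread(1), start = 1000L * i, sv_type = "insertion",
               length = sample(1:24, 1))))
  ev$del <- do.call(rbind, lapply(seq_len(39), function(i)
    make_event(spread(1), start = 50000L + 1000L * i, sv_type = "deletion",
               length = sample(1:24, 1))))
  long_len <- c(417L, 800L, 1500L, 2500L, 4000L, 5508L)
  ev$ldel <- do.call(rbind, lapply(seq_len(6), function(i)
    make_event(spread(1), start = 120000L + 10000L * i, sv_type = "deletion",
               length = long_len[i])))
  ev$tdup <- make_event(spread(1), start = 200000L,
                        sv_type = "tandem_duplication", length = 1697L)
  cnv_line <- c(rep("GB1", 39), spread(13))
  cnv_type <- c(rep("cnv_duplication", 42), rep("cnv_deletion", 10))
  ev$cnv <- do.call(rbind, lapply(seq_len(52), function(i)
    make_event(cnv_line[i], start = 300000L + 12000L * i,
               sv_type = cnv_type[i],
               length = sample(seq(2000L, 10000L, 1000L), 1),
               channel = "read_depth",
               copy_number_change = if (cnv_type[i] == "cnv_duplication") 0.5 else -0.5)))
  classify_events(do.call(rbind, ev))
}

# Brute-force all-pairs interval overlap (0-based half-open), the oracle
# for the production GenomicRanges path.
brute_force_overlap <- function(events, genes) {
  span_end <- pmax(events$end, events$start + 1L)
  hit <- logical(nrow(events))
  pairs <- list(); k <- 0L
  for (i in seq_len(nrow(events))) {
    for (j in seq_len(nrow(genes))) {
      if (events$contig[i] == genes$contig[j] &&
          events$start[i] < genes$end[j] && span_end[i] > genes$start[j]) {
        hit[i] <- TRUE
        k <- k + 1L
        pairs[[k]] <- c(i, j)
      }
    }
  }
  list(hit = hit, pairs = do.call(rbind, pairs))
}

# Textbook tie-corrected Kruskal-Wallis H.
brute_force_kw <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2))
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Welch statistic and Satterthwaite df from first principles.
brute_force_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  c(t = t, df = df)
}

# Events guaranteed pairwise separated by >= gap unmutated bp on one
# contig, for the exact spike/call loop.
separated_events <- function(n, contig, contig_len, gap = 60L,
                             line_id = "line1") {
  types <- sample(c("insertion", "deletion", "tandem_duplication",
                    "cnv_duplication", "cnv_deletion"), n, replace = TRUE)
  len <- vapply(types, function(ty) switch(ty,
    insertion = sample(1:49, 1),
    deletion = sample(c(1:49, 50:3000), 1),
    tandem_duplication = sample(50:2000, 1),
    cnv_duplication = sample(seq(2000L, 5000L, 1000L), 1),
    cnv_deletion = sample(seq(2000L, 5000L, 1000L), 1)), integer(1))
  span <- ifelse(types == "insertion", 1L, len)
  slack <- contig_len - sum(span) - (n + 1L) * gap
  stopifnot(slack > 0)
  cuts <- sort(sample.int(slack, n))
  starts <- cuts + gap + c(0L, cumsum(span[-n] + gap))
  do.call(rbind, lapply(seq_len(n), function(i)
    make_event(line_id, contig, starts[i], types[i], len[i],
               channel = if (grepl("^cnv", types[i])) "read_depth" else "split_read",
               copy_number_change = switch(types[i], cnv_duplication = 0.5,
                                           cnv_deletion = -0.5, NA_real_))))
}
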