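test_that("zero rates produce metadata but no events", {
  cfg <- three_pop_config(uniform_rates(0),
                          genome = list(n_contigs = 2L, contig_length = 1e6,
                                        gc = 0.4), seed = 1L)
  sim <- simulate_experiment(cfg)
  expect_equal(nrow(sim$metadata), 66L)
  expect_equal(nrow(sim$events), 0L)
})

test_that("event counts are Poisson with mean rate * 2 g n", {
  # one category at rate 1e-8, g = 10, n = 10 Mb: mean 2 events per line
  rates <- uniform_rates(0); rates["short_deletion"] <- 1e-8
  cfg <- simulation_config(
    populations = list(list(name = "Pop", n_genotypes = 1L, rates = rates)),
    lines_per_genotype = 100L, generations = 10L,
    genome = list(n_contigs = 1L, contig_length = 1e7, gc = 0.4), seed = 21L)
  sim <- simulate_experiment(cfg)
  counts <- category_count_matrix(sim$events, sim$metadata)[, "short_deletion"]
  mu <- 1e-8 * 2 * 10 * 1e7
  se <- sqrt(mu / 100) # Poisson variance equals the mean
  expect_lt(abs(mean(counts) - mu), 3 * se)
  expect_lt(abs(var(counts) - mu), 6 * se) # loose variance sanity check
})

test_that("the default 66-line pedigree totals 819 generations", {
  g <- default_generations(66L)
  expect_equal(sum(g), 819L)
  expect_equal(round(mean(g), 1), 12.4)
  expect_true(all(g %in% c(12L, 13L)))
  cfg <- three_pop_config(uniform_rates(0),
                          genome = list(n_contigs = 1L, contig_length = 1e6,
                                        gc = 0.4), seed = 2L)
  sim <- simulate_experiment(cfg)
  expect_equal(sum(sim$metadata$generations), 819L)
  expect_equal(length(unique(sim$metadata$genotype)), 9L)
  expect_equal(length(unique(sim$metadata$population)), 3L)
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- three_pop_config(uniform_rates(3e-9),
                          genome = list(n_contigs = 2L, contig_length = 1e6,
                                        gc = 0.4), seed = 33L)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$events, b$events)
  c_ <- simulate_experiment(cfg, seed = 34L)
  expect_false(identical(a$events, c_$events))
})

test_that("events on a line are pairwise disjoint", {
  cfg <- three_pop_config(uniform_rates(4e-9),
                          genome = list(n_contigs = 2L, contig_length = 1e6,
                                        gc = 0.4), seed = 12L)
  ev <- simulate_experiment(cfg)$events
  for (key in split(seq_len(nrow(ev)),
                    interaction(ev$line_id, ev$contig, drop = TRUE))) {
    e <- ev[key, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) < 2) next
    span_end <- pmax(e$end, e$start + 1L)
    expect_true(all(e$start[-1] >= span_end[-nrow(e)]))
  }
})

test_that("infeasible configurations are rejected", {
  expect_error(three_pop_config(uniform_rates(1e-6),
                                genome = list(n_contigs = 1L,
                                              contig_length = 1e5, gc = 0.4),
                                seed = 1L) |> simulate_experiment(),
               "10%")
  expect_error(simulation_config(genome = list(n_contigs = 1L,
                                               contig_length = 5000,
                                               gc = 0.4)),
               "longest possible event")
})

test_that("simulate_genome places disjoint genes and honors GC", {
  cfg <- simulation_config(genome = list(n_contigs = 3L, contig_length = 5e4,
                                         gc = 1.0),
                           genes = list(count = 30L, length = 1000L),
                           seed = 9L)
  g <- simulate_genome(cfg)
  expect_equal(length(g$sequences), 3L)
  expect_true(all(nchar(g$sequences) == 5e4))
  expect_false(any(grepl("[AT]", g$sequences)))
  expect_equal(nrow(g$genes), 30L)
  for (ctg in unique(g$genes$contig)) {
    gg <- g$genes[g$genes$contig == ctg, , drop = FALSE]
    gg <- gg[order(gg$start), , drop = FALSE]
    if (nrow(gg) > 1) expect_true(all(gg$start[-1] >= gg$end[-nrow(gg)]))
    expect_true(all(gg$end <= 5e4))
  }
  expect_identical(simulate_genome(cfg), g)
  expect_error(simulate_genome(
    simulation_config(genome = list(n_contigs = 1L, contig_length = 1e4,
                                    gc = 0.4),
                      genes = list(count = 10L, length = 1000L))),
    "packing")
})

test_that("spike_events applies each edit type with exact arithmetic", {
  ref <- c(ctg1 = paste(rep("ACGTT", 2000), collapse = "")) # 10 kb
  del <- classify_events(make_event("L1", "ctg1", 4000L, "deletion", 417L))
  ts <- spike_events(ref, del)
  expect_equal(nchar(ts$sequences$L1[["ctg1"]]), 9583L)

  dup <- classify_events(make_event("L1", "ctg1", 2000L,
                                    "tandem_duplication", 1697L))
  ts2 <- spike_events(ref, dup)
  mut <- ts2$sequences$L1[["ctg1"]]
  expect_equal(nchar(mut), 10000L + 1697L)
  # the copy sits immediately after the duplicated segment
  expect_equal(substr(mut, 3697L + 1L, 3697L + 1697L),
               substr(ref[["ctg1"]], 2000L + 1L, 3697L))

  ins <- classify_events(make_event("L1", "ctg1", 500L, "insertion", 7L))
  ts3 <- spike_events(ref, ins, seed = 4)
  expect_equal(nchar(ts3$sequences$L1[["ctg1"]]), 10007L)
  expect_equal(substr(ts3$sequences$L1[["ctg1"]], 508L, 10007L),
               substr(ref[["ctg1"]], 501L, 10000L))

  none <- spike_events(ref, del[0, ])
  expect_length(none$sequences, 0L)
})

test_that("spike_events rejects collisions and out-of-bounds events", {
  ref <- c(ctg1 = strrep("ACGT", 2500))
  ev <- rbind(make_event("L1", "ctg1", 100L, "deletion", 500L),
              make_event("L1", "ctg1", 400L, "deletion", 100L))
  expect_error(spike_events(ref, classify_events(ev)), "overlapping")
  far <- make_event("L1", "ctg1", 9900L, "deletion", 500L)
  expect_error(spike_events(ref, classify_events(far)), "beyond contig")
  off <- make_event("L1", "ctg2", 100L, "deletion", 10L)
  expect_error(spike_events(ref, classify_events(off)), "not in reference")
})

test_that("spiked length changes equal the summed signed length changes", {
  withr::local_seed(77)
  ref <- c(ctg1 = paste(sample(c("A", "C", "G", "T"), 60000, TRUE),
                        collapse = ""),
           ctg2 = paste(sample(c("A", "C", "G", "T"), 60000, TRUE),
                        collapse = ""))
  for (s in 1:5) {
    withr::local_seed(100 + s)
    ev <- rbind(separated_events(8, "ctg1", 60000L),
                separated_events(5, "ctg2", 60000L))
    ev <- classify_events(ev)
    ts <- spike_events(ref, ev, seed = s)
    for (ctg in c("ctg1", "ctg2")) {
      delta <- nchar(ts$sequences$line1[[ctg]]) - nchar(ref[[ctg]])
      expect_equal(delta,
                   sum(ev$signed_length_change[ev$contig == ctg]))
    }
  }
})

test_that("liftover maps reference positions through the edits", {
  ref <- c(ctg1 = strrep("ACGT", 5000)) # 20 kb
  ev <- classify_events(rbind(
    make_event("L1", "ctg1", 1000L, "deletion", 200L),
    make_event("L1", "ctg1", 5000L, "insertion", 30L),
    make_event("L1", "ctg1", 9000L, "tandem_duplication", 400L)))
  ts <- spike_events(ref, ev, seed = 1)
  expect_equal(lift_position(ts, "L1", "ctg1", 500), 500)
  expect_true(is.na(lift_position(ts, "L1", "ctg1", 1100))) # deleted
  expect_equal(lift_position(ts, "L1", "ctg1", 2000), 1800) # after -200
  expect_equal(lift_position(ts, "L1", "ctg1", 6000), 5830) # -200 + 30
  expect_equal(lift_position(ts, "L1", "ctg1", 8000), 7830) # before the dup
  expect_equal(lift_position(ts, "L1", "ctg1", 9500), 9730) # past the copy
  # a lifted unmutated base is the same character in both sequences
  mut <- ts$sequences$L1[["ctg1"]]
  for (p in c(500, 2000, 6000, 15000)) {
    q <- lift_position(ts, "L1", "ctg1", p)
    expect_equal(substr(mut, q + 1, q + 1), substr(ref[["ctg1"]], p + 1, p + 1))
  }
})
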