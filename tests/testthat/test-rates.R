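test_that("per-line count rate is x / (2 g n)", {
  expect_equal(line_rate(0, 12, 6e7), 0)
  expect_equal(line_rate(1, 10, 5e7), 1e-9)
  expect_equal(line_rate(3, 12, 6e7), 3 / (2 * 12 * 6e7))
  expect_error(line_rate(1, 0, 5e7), "g >= 1")
  expect_error(line_rate(1, 10, 0), "n > 0")
  expect_error(line_rate(-1, 10, 5e7), ">= 0")
})

test_that("length-adjusted rate is summed length over 2 g n", {
  expect_equal(line_length_adjusted_rate(integer(0), 10, 5e7), 0)
  expect_equal(line_length_adjusted_rate(100, 10, 5e7), 1e-7)
  expect_equal(line_length_adjusted_rate(c(417, 5508), 12, 6e7),
               5925 / 1.44e9)
})

test_that("length-adjusted equals count rate times mean length per line, but not across lines", {
  lens <- c(5, 40, 300)
  g <- 12; n <- 6e7
  expect_equal(line_length_adjusted_rate(lens, g, n),
               line_rate(length(lens), g, n) * mean(lens))
  # two lines with different exposures and event sizes: averaging the
  # per-line v is not mean(u) * mean(length) pooled across lines
  u <- c(line_rate(1, 10, n), line_rate(2, 40, n))
  v <- c(line_length_adjusted_rate(1000, 10, n),
         line_length_adjusted_rate(c(5, 5), 40, n))
  pooled_mean_len <- mean(c(1000, 5, 5))
  expect_false(isTRUE(all.equal(mean(v), mean(u) * pooled_mean_len)))
})

test_that("net rates cancel, flip sign, and track bp change", {
  g <- 10; n <- 5e7
  ev <- classify_events(rbind(
    make_event("L1", start = 100L, sv_type = "tandem_duplication",
               length = 100L),
    make_event("L1", start = 500L, sv_type = "deletion", length = 100L)))
  nr <- line_net_rates(ev, g, n)
  expect_equal(nr$net_length_rate, 0)
  expect_gt(nr$total_length_rate, 0)

  dels <- classify_events(rbind(
    make_event("L1", start = 100L, sv_type = "deletion", length = 40L),
    make_event("L1", start = 500L, sv_type = "deletion", length = 10L)))
  nr2 <- line_net_rates(dels, g, n)
  expect_equal(nr2$net_length_rate, -nr2$total_length_rate)

  big <- classify_events(rbind(
    make_event("L1", start = 1000L, sv_type = "cnv_duplication",
               length = 100000L, channel = "read_depth",
               copy_number_change = 0.5),
    make_event("L1", start = 400000L, sv_type = "tandem_duplication",
               length = 4000L),
    make_event("L1", start = 600000L, sv_type = "deletion", length = 2000L)))
  expect_equal(line_net_rates(big, g, n)$net_bp_change, 102000)
})

test_that("per-gene rate is y / (2 g m)", {
  expect_equal(line_gene_rate(0, 12, 25000), 0)
  expect_equal(line_gene_rate(2, 12, 25000), 2 / (2 * 12 * 25000))
  expect_equal(line_gene_rate(25000, 12, 25000), 1 / (2 * 12))
  expect_error(line_gene_rate(1, 12, 0), "m > 0")
})

test_that("aggregation is the unweighted line mean with a percentile bootstrap", {
  r <- 2.5e-9
  same <- aggregate_rates(rep(r, 10), "genotype", "GA", n_boot = 200, seed = 1)
  expect_equal(same$rate, r)
  expect_equal(same$ci_low, r)
  expect_equal(same$ci_high, r)

  mixed <- aggregate_rates(c(0, 0, 2 * r), "genotype", "GB",
                           n_boot = 2000, seed = 1)
  expect_equal(mixed$rate, 2 * r / 3)
  expect_true(mixed$ci_low <= mixed$rate && mixed$rate <= mixed$ci_high)
  # same seed reproduces the CI
  again <- aggregate_rates(c(0, 0, 2 * r), "genotype", "GB",
                           n_boot = 2000, seed = 1)
  expect_identical(mixed, again)
})

test_that("zeros from unaffected populations dilute the species mean", {
  # CNV-style data: events only in German lines; the species mean over all
  # lines must fall below the German-only mean
  meta <- make_metadata(sprintf("L%02d", 1:66),
                        genotype = rep(sprintf("G%d", 1:9), c(7, 7, 8, 7, 7, 8, 7, 7, 8)),
                        population = rep(c("Finland", "Germany", "Israel"),
                                         c(22, 22, 22)))
  german <- meta$line_id[meta$population == "Germany"]
  ev <- classify_events(do.call(rbind, lapply(1:10, function(i)
    make_event(german[i], start = 5000L * i, sv_type = "cnv_deletion",
               length = 2000L, channel = "read_depth",
               copy_number_change = -0.5))))
  tab <- rate_table(ev, meta, n_boot = 200, seed = 2)
  sp <- tab[tab$level == "species" & tab$category == "cnv_deletion" &
              tab$measure == "count", ]
  de <- tab[tab$level == "population" & tab$group == "Germany" &
              tab$category == "cnv_deletion" & tab$measure == "count", ]
  expect_lt(sp$rate, de$rate)
  expect_equal(sp$rate, de$rate * 22 / 66)
})

test_that("count rates scale linearly in the event counts", {
  meta <- make_metadata(c("A", "B", "C"))
  x <- c(1L, 4L, 0L)
  u1 <- line_rate(x, meta$generations, meta$callable_sites)
  u2 <- line_rate(2L * x, meta$generations, meta$callable_sites)
  expect_equal(u2, 2 * u1)
})

test_that("pooled estimator differs from the line mean under unequal exposure", {
  meta <- make_metadata(c("A", "B"), generations = c(10L, 40L))
  ev <- classify_events(rbind(
    make_event("A", start = 10L, sv_type = "deletion", length = 5L),
    make_event("B", start = 10L, sv_type = "deletion", length = 5L)))
  tab <- rate_table(ev, meta, n_boot = 100, seed = 1, pooled = TRUE)
  mean_row <- tab[tab$measure == "count" & tab$level == "species" &
                    tab$category == "short_deletion", ]
  pooled_row <- tab[tab$measure == "count_pooled" &
                      tab$category == "short_deletion", ]
  n <- meta$callable_sites[1]
  expect_equal(mean_row$rate, mean(c(1 / (2 * 10 * n), 1 / (2 * 40 * n))))
  expect_equal(pooled_row$rate, 2 / (2 * 50 * n))
  # the unweighted line mean up-weights the low-exposure line
  expect_gt(mean_row$rate, pooled_row$rate * 1.5)
})

test_that("net-rate table covers every line including event-free ones", {
  meta <- make_metadata(c("A", "B"))
  ev <- classify_events(make_event("A", start = 10L, sv_type = "deletion",
                                   length = 100L))
  nets <- net_rate_table(ev, meta)
  expect_equal(nets$line_id, c("A", "B"))
  expect_equal(nets$net_bp_change, c(-100, 0))
})

test_that("coefficient of variation uses the sample standard deviation", {
  expect_equal(coefficient_of_variation(rep(3, 5)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), sqrt(2) / 2)
  onehot <- c(rep(0, 8), 5)
  expect_equal(coefficient_of_variation(onehot),
               sd(onehot) / mean(onehot))
  expect_equal(coefficient_of_variation(onehot), 3)
  expect_true(is.na(coefficient_of_variation(rep(0, 9))))
})

test_that("insertion:deletion ratio reports to two decimals", {
  expect_equal(insertion_deletion_ratio(23, 39), 0.59)
  expect_equal(insertion_deletion_ratio(10, 10), 1.00)
  expect_equal(insertion_deletion_ratio(0, 5), 0.00)
  expect_true(is.na(insertion_deletion_ratio(5, 0)))
})

test_that("bootstrap CIs cover the true rate at nominal-ish frequency", {
  # 200 replicates of a one-category experiment with a known rate; the
  # 95% percentile CI over 66 lines should cover truth in 90-98% of them
  rate <- 4e-8
  g <- default_generations(66L)
  expo <- 2 * g * 1e6
  cover <- 0L
  withr::local_seed(515)
  for (r in 1:200) {
    x <- rpois(66, rate * expo)
    est <- aggregate_rates(x / expo, "species", "all", n_boot = 1000,
                           seed = 9000 + r)
    if (est$ci_low <= rate && rate <= est$ci_high) cover <- cover + 1L
  }
  expect_gte(cover, 180L)
  expect_lte(cover, 196L)
})
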