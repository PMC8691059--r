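# Inferential layer: population-effect tests on per-line rates,
# insertion-vs-deletion comparisons, cross-category rate correlations,
# and a binomial-GLM surrogate (with parametric-bootstrap LRT) for the
# population effect on event counts.

test_result <- function(test, statistic, df, p_value, groups = NULL,
                        degenerate = FALSE, posthoc = NULL, extra = NULL) {
  structure(c(list(test = test, statistic = unname(statistic),
                   df = unname(df), p_value = unname(p_value),
                   groups = groups, degenerate = degenerate,
                   posthoc = posthoc), extra),
            class = "svcmr_test")
}

#' @export
print.svcmr_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g%s\n", x$test,
              x$statistic, paste(signif(x$df, 4), collapse = ", "),
              x$p_value, if (x$degenerate) " (degenerate)" else ""))
  if (!is.null(x$posthoc)) {
    cat("post hoc:\n")
    print(x$posthoc, ...)
  }
  invisible(x)
}

check_groups <- function(values, groups, min_groups = 2L) {
  if (!is.factor(groups)) groups <- factor(groups)
  if (nlevels(groups) < min_groups)
    stop_format("need at least %d groups", min_groups)
  cnt <- table(groups)
  if (any(cnt == 0)) stop_format("group '%s' has no observations",
                                 names(cnt)[cnt == 0][1])
  groups
}

#' Kruskal-Wallis rank-sum test on per-line rates
#'
#' Tie-corrected H statistic with a chi-square p-value on k - 1 degrees of
#' freedom (via [stats::kruskal.test()]). All-identical values are a
#' degenerate case reported as H = 0, p = 1.
#'
#' @param values Per-line rates.
#' @param groups Population (or other) labels, same length.
#' @return An `svcmr_test`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- check_groups(values, groups)
  if (length(unique(values)) == 1L)
    return(test_result("kruskal_wallis", 0, nlevels(groups) - 1L, 1,
                       groups = levels(groups), degenerate = TRUE))
  kt <- stats::kruskal.test(values, groups)
  test_result("kruskal_wallis", kt$statistic, kt$parameter, kt$p.value,
              groups = levels(groups))
}

#' Dunn post hoc test on mean ranks
#'
#' Pairwise z statistics on mean ranks with tie-corrected variance,
#' two-sided p-values, Holm-adjusted by default. Run after a significant
#' Kruskal-Wallis omnibus.
#'
#' @inheritParams kruskal_wallis
#' @param p_adjust Adjustment method passed to [stats::p.adjust()].
#' @return Data frame with one row per group pair: `group_a`, `group_b`,
#'   `z`, `p_value`, `p_adjusted`.
#' @export
dunn_posthoc <- function(values, groups, p_adjust = "holm") {
  groups <- check_groups(values, groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  sigma2 <- N * (N + 1) / 12 - tie_term

  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  rows <- apply(pairs, 2, function(pr) {
    a <- pr[1]; b <- pr[2]
    se <- sqrt(sigma2 * (1 / n[[a]] + 1 / n[[b]]))
    z <- if (se == 0) 0 else (rbar[[a]] - rbar[[b]]) / se
    data.frame(group_a = a, group_b = b, z = z,
               p_value = if (se == 0) 1 else 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  rownames(out) <- NULL
  out
}

#' Paired t test on per-line rates
#'
#' df = n - 1. A zero-variance difference vector is a degenerate case
#' reported as t = 0, p = 1.
#' @param a,b Paired per-line values (equal length >= 2).
#' @return An `svcmr_test`.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) == 0)
    return(test_result("paired_t", 0, length(a) - 1L, 1, degenerate = TRUE))
  tt <- stats::t.test(a, b, paired = TRUE)
  test_result("paired_t", tt$statistic, tt$parameter, tt$p.value)
}

#' Welch two-sample t test (unequal variances)
#'
#' Welch-Satterthwaite degrees of freedom. Degenerate when both samples
#' have zero variance.
#' @param a,b Samples (each length >= 2).
#' @return An `svcmr_test`.
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(test_result("welch_t", 0, length(a) + length(b) - 2L, 1,
                       degenerate = TRUE))
  tt <- stats::t.test(a, b, var.equal = FALSE)
  test_result("welch_t", tt$statistic, tt$parameter, tt$p.value)
}

#' Pairwise Pearson correlations among per-genotype category rates
#'
#' For a genotypes x categories rate matrix, computes every pairwise
#' Pearson r with its t test on n - 2 degrees of freedom. Zero-variance
#' categories yield `NA` correlations (flagged). Raw p-values are
#' reported alongside Holm-adjusted ones.
#'
#' @param rate_matrix Numeric matrix, genotypes in rows, categories in
#'   columns (>= 3 rows).
#' @return `list(r = matrix, p = matrix, pairs = data frame)`.
#' @export
rate_correlations <- function(rate_matrix) {
  rate_matrix <- as.matrix(rate_matrix)
  stopifnot(nrow(rate_matrix) >= 3)
  k <- ncol(rate_matrix)
  cats <- colnames(rate_matrix) %||% paste0("cat", seq_len(k))
  r <- p <- matrix(NA_real_, k, k, dimnames = list(cats, cats))
  diag(r) <- 1
  rows <- list(); idx <- 0L
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      xi <- rate_matrix[, i]; xj <- rate_matrix[, j]
      degenerate <- stats::sd(xi) == 0 || stats::sd(xj) == 0
      if (!degenerate) {
        ct <- stats::cor.test(xi, xj, method = "pearson")
        r[i, j] <- r[j, i] <- unname(ct$estimate)
        p[i, j] <- p[j, i] <- ct$p.value
      }
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        category_a = cats[i], category_b = cats[j],
        r = r[i, j], df = nrow(rate_matrix) - 2L, p_value = p[i, j],
        degenerate = degenerate, stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  pairs$p_adjusted <- stats::p.adjust(pairs$p_value, method = "holm")
  list(r = r, p = p, pairs = pairs)
}

fit_binomial_lrt <- function(x, exposure, populations) {
  f1 <- suppressWarnings(stats::glm(cbind(x, exposure - x) ~ populations,
                                    family = stats::binomial()))
  f0 <- suppressWarnings(stats::glm(cbind(x, exposure - x) ~ 1,
                                    family = stats::binomial()))
  max(f0$deviance - f1$deviance, 0)
}

#' Population effect on event counts: binomial GLM with bootstrap LRT
#'
#' Fits a binomial GLM of per-line event counts on the per-line exposure
#' (2 g n "trials") with population as a fixed effect, and tests the
#' population effect with a likelihood-ratio chi-square on
#' k - 1 degrees of freedom. Because lines cluster within genotypes, the
#' asymptotic p-value is complemented by a seeded parametric-bootstrap
#' p-value: counts are re-simulated from the fitted null (common-rate)
#' model and the LRT distribution is built empirically,
#' p = (1 + #(LRT* >= LRT)) / (B + 1).
#'
#' @param counts Per-line event counts.
#' @param exposures Per-line exposures (2 g n).
#' @param populations Population labels.
#' @param genotypes Optional genotype labels, recorded for provenance.
#' @param n_boot Parametric-bootstrap replicates (default 199).
#' @param seed RNG seed.
#' @return An `svcmr_test` with `p_value` = bootstrap p and extra fields
#'   `p_asymptotic` and `n_boot`.
#' @export
population_effect_binomial <- function(counts, exposures, populations,
                                       genotypes = NULL, n_boot = 199L,
                                       seed = NULL) {
  populations <- check_groups(counts, populations)
  stopifnot(length(counts) == length(exposures),
            length(counts) == length(populations))
  if (!is_count(counts)) stop_format("counts must be non-negative integers")
  df <- nlevels(populations) - 1L
  if (all(counts == 0))
    return(test_result("population_effect_binomial", 0, df, 1,
                       groups = levels(populations), degenerate = TRUE,
                       extra = list(p_asymptotic = 1, n_boot = 0L)))

  lrt <- fit_binomial_lrt(counts, exposures, populations)
  p_asym <- stats::pchisq(lrt, df = df, lower.tail = FALSE)
  p0 <- sum(counts) / sum(exposures)
  boot <- with_rng_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      xb <- stats::rbinom(length(exposures), size = round(exposures), prob = p0)
      fit_binomial_lrt(xb, exposures, populations)
    }, numeric(1))
  })
  p_boot <- (1 + sum(boot >= lrt)) / (n_boot + 1)
  test_result("population_effect_binomial", lrt, df, p_boot,
              groups = levels(populations),
              extra = list(p_asymptotic = p_asym, n_boot = n_boot))
}
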