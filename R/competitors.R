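#' Direct logistic interaction test for one pair
#'
#' The likelihood-ratio test of the additive-on-logit model (H4, logit
#' link) against the saturated two-locus model, df 4 — the conventional
#' logistic-regression interaction test.
#'
#' @param table A [pair_table()].
#' @return The p-value.
#' @export
direct_logistic_test <- function(table) {
  table <- as_pair_table(table)
  lrt(fit_pair_model(table, "H4", link = "logit"), fit_pair_model(table, "HA"))$pvalue
}

#' Marginal screen over variants
#'
#' Tests each variant's marginal effect by a 2-df likelihood-ratio test of
#' the saturated single-variant penetrance model against the intercept-only
#' model, at an optimistic screening level. A variant pair is screened in
#' iff both of its variants pass. Monomorphic variants get p = 1 by
#' convention.
#'
#' @param genotypes Individuals x variants 0/1/2 matrix (NA allowed).
#' @param phenotype Binary 0/1 vector.
#' @param alpha_screen Screening level (default 0.1).
#' @return Tibble with `variant`, `p`, `pass`.
#' @export
marginal_screen <- function(genotypes, phenotype, alpha_screen = 0.1) {
  G <- as.matrix(genotypes)
  if (is.null(colnames(G))) colnames(G) <- paste0("v", seq_len(ncol(G)))
  stopifnot(all(phenotype %in% 0:1))
  p <- vapply(seq_len(ncol(G)), function(j) marginal_lrt_p(G[, j], phenotype),
              numeric(1))
  tibble::tibble(variant = colnames(G), p = p, pass = p < alpha_screen)
}

marginal_lrt_p <- function(g, y) {
  keep <- !is.na(g)
  g <- g[keep]; y <- y[keep]
  n1 <- tabulate(g[y == 1] + 1L, 3)
  n0 <- tabulate(g[y == 0] + 1L, 3)
  if (sum((n1 + n0) > 0) < 2) return(1)  # monomorphic
  ll_sat <- sum(xlogx(n1) + xlogx(n0) - xlogx(n1 + n0))
  ll_null <- xlogx(sum(n1)) + xlogx(sum(n0)) - xlogx(sum(n1) + sum(n0))
  stat <- max(0, 2 * (ll_sat - ll_null))
  pchisq(stat, 2, lower.tail = FALSE)
}

# composite-LD machinery on 0/1/2 (or 0/1) genotype scores: covariance of
# scores within a group, and the variance of the per-individual
# cross-product deviations (delta-method variance of the covariance).
ld_group_stats <- function(g1, g2) {
  n <- length(g1)
  m1 <- mean(g1); m2 <- mean(g2)
  d <- (g1 - m1) * (g2 - m2)
  list(cov = mean(d), v = mean((d - mean(d))^2), n = n)
}

#' LD-contrast interaction test
#'
#' Compares composite linkage disequilibrium (the covariance of unphased
#' genotype scores) between cases and controls:
#' `stat = (cov_cases - cov_controls)^2 / (V_cases/n_cases + V_controls/n_controls)`
#' with `V_g` the sample variance of per-individual cross-product
#' deviations in group `g`, referred to chi-square with 1 df.
#'
#' @param g1,g2 Genotype score vectors.
#' @param y Binary phenotype.
#' @return List with `statistic`, `pvalue`, `degenerate` flag.
#' @export
ld_contrast_test <- function(g1, g2, y) {
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]; y <- y[keep]
  sc <- ld_group_stats(g1[y == 1], g2[y == 1])
  sk <- ld_group_stats(g1[y == 0], g2[y == 0])
  se2 <- sc$v / sc$n + sk$v / sk$n
  if (se2 <= 0) {
    return(list(statistic = 0, pvalue = 1, degenerate = TRUE))
  }
  stat <- (sc$cov - sk$cov)^2 / se2
  list(statistic = stat, pvalue = pchisq(stat, 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Pooled-cohort LD screen (CSS and R-squared variants)
#'
#' The pooled-sample composite-LD chi-square `n * r^2` of the two variants'
#' genotype scores (cases and controls combined), df 1. The `css` variant
#' passes at `statistic >= 3`; the `r2` variant at `p <= 1e-4`.
#'
#' @param g1,g2 Genotype score vectors (pooled cohort).
#' @param variant `"css"` or `"r2"`.
#' @return List with `statistic`, `pvalue`, `pass`.
#' @export
ld_cohort_screen <- function(g1, g2, variant = c("css", "r2")) {
  variant <- match.arg(variant)
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  if (var(g1) == 0 || var(g2) == 0) {
    return(list(statistic = 0, pvalue = 1, pass = FALSE, degenerate = TRUE))
  }
  r <- suppressWarnings(stats::cor(g1, g2))
  stat <- length(g1) * r^2
  p <- pchisq(stat, 1, lower.tail = FALSE)
  pass <- if (variant == "css") stat >= 3 else p <= 1e-4
  list(statistic = stat, pvalue = p, pass = pass, degenerate = FALSE)
}

#' Sixpac-style dominant/recessive recoded LD test
#'
#' Recodes both variants into dominant (`x >= 1`) and recessive (`x == 2`)
#' binary variables and, for each of the four coding combinations, applies
#' a within-cases LD screen (z-test on the case covariance) followed by a
#' binary-variable LD-contrast main test. The pair's p-value is the minimum
#' main-test p over passing codings, Bonferroni-multiplied by the number of
#' codings tested. Codings that collapse a variable to a constant are
#' skipped.
#'
#' @param g1,g2 0/1/2 genotype vectors.
#' @param y Binary phenotype.
#' @param screen_alpha Within-cases screening level (default 0.01).
#' @return List with `pvalue`, `screen_pass` (any coding passed),
#'   `n_codings` tested.
#' @export
sixpac_style_test <- function(g1, g2, y, screen_alpha = 0.01) {
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]; y <- y[keep]
  codings <- list(dom = function(x) as.numeric(x >= 1),
                  rec = function(x) as.numeric(x == 2))
  tested <- 0L
  passed <- FALSE
  best <- Inf
  for (c1 in names(codings)) {
    for (c2 in names(codings)) {
      b1 <- codings[[c1]](g1); b2 <- codings[[c2]](g2)
      if (var(b1) == 0 || var(b2) == 0) next
      tested <- tested + 1L
      sc <- ld_group_stats(b1[y == 1], b2[y == 1])
      if (sc$v <= 0) next
      z2 <- sc$cov^2 / (sc$v / sc$n)
      p_screen <- pchisq(z2, 1, lower.tail = FALSE)
      if (p_screen >= screen_alpha) next
      passed <- TRUE
      best <- min(best, ld_contrast_test(b1, b2, y)$pvalue)
    }
  }
  p <- if (is.finite(best)) min(1, best * tested) else 1
  list(pvalue = p, screen_pass = passed, n_codings = tested)
}

#' Holm-Bonferroni step-down adjustment against a larger family
#'
#' Standard Holm step-down adjusted p-values, generalized to a family of
#' `m_total` hypotheses of which only some were actually computed (the
#' remainder implicitly have p = 1, which never alters the step-down path
#' through the supplied values).
#'
#' @param pvalues Numeric vector of raw p-values.
#' @param m_total Family size (>= `length(pvalues)`).
#' @return Adjusted p-values in the input order (monotone, capped at 1).
#' @export
holm_bonferroni <- function(pvalues, m_total = length(pvalues)) {
  k <- length(pvalues)
  if (m_total < k) abort("m_total must be at least the number of p-values")
  if (!k) return(numeric())
  o <- order(pvalues)
  mult <- m_total - seq_len(k) + 1
  adj <- pmin(cummax(mult * pvalues[o]), 1)
  out <- numeric(k)
  out[o] <- adj
  out
}

#' Expected number of tests surviving a screen
#'
#' Converts a screening threshold into the effective number of tests used
#' for the main-test correction: `per_pair` mode multiplies the threshold
#' by the total pair count (pair-level screens such as the pooled-LD CSS
#' and R-squared screens); `pairwise_product` mode takes
#' `choose(threshold * n_variants, 2)` (variant-level screens such as the
#' marginal screen).
#'
#' @param screen_threshold Screening p-value threshold in (0, 1\].
#' @param total_pairs Total number of variant pairs (per_pair mode).
#' @param mode `"per_pair"` or `"pairwise_product"`.
#' @param n_variants Total variant count (pairwise_product mode).
#' @return The effective test count.
#' @examples
#' effective_tests_after_screen(0.39, 1e12)                  # CSS
#' effective_tests_after_screen(0.1, mode = "pairwise_product", n_variants = 1e6)
#' @export
effective_tests_after_screen <- function(screen_threshold, total_pairs = NULL,
                                         mode = c("per_pair", "pairwise_product"),
                                         n_variants = NULL) {
  mode <- match.arg(mode)
  if (screen_threshold <= 0 || screen_threshold > 1) {
    abort("screen_threshold must lie in (0, 1]")
  }
  if (mode == "per_pair") {
    if (is.null(total_pairs) || total_pairs <= 0) abort("total_pairs must be positive")
    screen_threshold * total_pairs
  } else {
    if (is.null(n_variants) || n_variants <= 0) abort("n_variants must be positive")
    k <- screen_threshold * n_variants
    k * (k - 1) / 2
  }
}
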