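#' Bonferroni significance threshold
#'
#' @param n_tests Number of tests.
#' @param alpha Overall level (default 0.05).
#' @return `alpha / n_tests`; e.g. all pairs of 500,000 variants give
#'   `0.05 / (5e5 * (5e5 - 1) / 2)` = 4.0e-13.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (n_tests <= 0) abort("n_tests must be positive")
  alpha / n_tests
}

fwer_methods <- c("static", "adaptive", "logistic", "marginal_logistic",
                  "css_logistic", "r2_logistic", "ld_contrast", "sixpac")

#' Estimate the family-wise error rate of a method under a null model
#'
#' Generates replicate null cohorts (see [simulate_null_cohort()]) and, for
#' each requested method, records whether at least one variant pair is
#' declared significant among all pairs — every rejection is false, since
#' all ten null kinds are null for interaction. Cohorts are shared across
#' the requested methods, so contrasts between methods are paired.
#'
#' @param null_kind Null-cohort kind, e.g. `"none"`, `"double:odds"`,
#'   `"multi:10"`.
#' @param methods Character vector from `"static"`, `"adaptive"`,
#'   `"logistic"`, `"marginal_logistic"`, `"css_logistic"`,
#'   `"r2_logistic"`, `"ld_contrast"`, `"sixpac"`.
#' @param n_reps Number of replicate cohorts (default 100).
#' @param alpha Nominal family-wise level (default 0.05).
#' @param weights,links Stage-wise settings.
#' @param n_cases,n_controls,n_variants Cohort dimensions.
#' @param M Assumed associated-variant count for the static corrections;
#'   default `max(L, 2)` where `L` is the null model's associated count.
#' @param seed Root seed; replicate r uses a seed derived from it, so runs
#'   are reproducible and parallelizable by replicate.
#' @param screen_alpha_sixpac Within-cases screen level for the
#'   sixpac-style method.
#' @return Tibble with one row per method: `null_kind`, `method`,
#'   `estimate` (fraction of replicates with >= 1 rejection), `n_reps`,
#'   `se` (binomial Monte-Carlo standard error).
#' @export
estimate_fwer <- function(null_kind, methods = c("static", "adaptive"),
                          n_reps = 100, alpha = 0.05,
                          weights = stage_weights(), links = all_links(),
                          n_cases = 4000, n_controls = 4000, n_variants = 500,
                          M = NULL, seed = 1L, screen_alpha_sixpac = 0.01) {
  methods <- match.arg(methods, fwer_methods, several.ok = TRUE)
  stopifnot(n_reps >= 1)
  L <- parse_null_kind(null_kind)$L
  if (is.null(M)) M <- max(L, 2L)
  K_static <- static_corrections(n_variants, M)$K
  hits <- matrix(FALSE, n_reps, length(methods), dimnames = list(NULL, methods))
  for (r in seq_len(n_reps)) {
    coh <- simulate_null_cohort(null_kind, n_cases, n_controls, n_variants,
                                seed = derive_seed(seed, r))
    hits[r, ] <- cohort_any_rejection(coh$genotypes, coh$phenotype, methods,
                                      alpha, weights, links, K_static,
                                      screen_alpha_sixpac)[methods]
  }
  est <- colMeans(hits)
  tibble::tibble(null_kind = null_kind, method = methods,
                 estimate = unname(est), n_reps = n_reps,
                 se = sqrt(unname(est) * (1 - unname(est)) / n_reps))
}

derive_seed <- function(root, counter) {
  # double arithmetic: exact below 2^53, result always a valid 32-bit seed
  as.integer((as.numeric(root) * 48271 + as.numeric(counter) * 16807) %% 2147483647)
}

# One cohort, all requested methods: does each make >= 1 rejection?
# Stage p-values, pair tables and count blocks are shared across methods.
cohort_any_rejection <- function(G, y, methods, alpha, weights, links,
                                 K_static, screen_alpha_sixpac = 0.01) {
  m <- ncol(G)
  n_pairs <- m * (m - 1) / 2
  out <- setNames(rep(FALSE, length(fwer_methods)), fwer_methods)
  need_counts <- any(methods %in% c("static", "adaptive", "logistic",
                                    "marginal_logistic", "css_logistic",
                                    "r2_logistic"))
  if (need_counts) {
    cc <- cohort_counts(G, y)
    s1 <- stage1_matrix(cc)
    ut <- upper.tri(s1$stat)
    idx <- which(ut, arr.ind = TRUE)
    p1 <- s1$p[ut]
    stat1 <- s1$stat[ut]
    tab_cache <- new.env(parent = emptyenv())
    get_tab <- function(k) {
      key <- as.character(k)
      if (is.null(tab_cache[[key]])) {
        tab_cache[[key]] <- extract_pair_table(cc, idx[k, 1], idx[k, 2])
      }
      tab_cache[[key]]
    }
    pcache <- new.env(parent = emptyenv())
    stage_p <- function(k, s) {
      if (s == 1) return(p1[k])
      key <- paste0(k, ":", s)
      if (!is.null(pcache[[key]])) return(pcache[[key]])
      tab <- get_tab(k)
      ha <- fit_pair_model(tab, "HA")
      val <- if (s == 2) {
        lrt(fit_pair_model(tab, "H2"), ha)$pvalue
      } else if (s == 3) {
        lrt(fit_pair_model(tab, "H3"), ha)$pvalue
      } else {
        scale_invariant_p(vapply(links, function(lk) {
          lrt(fit_h4(tab, lk), ha)$pvalue
        }, numeric(1)))
      }
      pcache[[key]] <- val
      val
    }
    for (mth in intersect(methods, c("static", "adaptive"))) {
      res <- run_stagewise(stage_p, n_pairs, weights, alpha, mth,
                           K = if (mth == "static") K_static else NULL)
      out[mth] <- any(res$significant)
    }
    # logistic-family methods: >=1 Holm rejection over family size m_eff is
    # equivalent to min p < alpha/m_eff, and stat_H4 <= stat_H1 exactly, so
    # H4 is fitted only where the stage-1 statistic clears the bound.
    logit_min_hit <- function(candidates, thr) {
      q4 <- qchisq(thr, 4, lower.tail = FALSE)
      for (k in candidates[stat1[candidates] > q4]) {
        if (direct_logistic_test(get_tab(k)) < thr) return(TRUE)
      }
      FALSE
    }
    if ("logistic" %in% methods) {
      out["logistic"] <- logit_min_hit(seq_len(n_pairs), alpha / n_pairs)
    }
    if ("marginal_logistic" %in% methods) {
      sc <- marginal_screen(G, y, alpha_screen = 0.1)
      pass <- sc$pass
      cand <- which(pass[idx[, 1]] & pass[idx[, 2]])
      m_eff <- max(1, effective_tests_after_screen(0.1, mode = "pairwise_product",
                                                   n_variants = m))
      out["marginal_logistic"] <- logit_min_hit(cand, alpha / m_eff)
    }
    if (any(methods %in% c("css_logistic", "r2_logistic"))) {
      pooled_stat <- pooled_ld_stats(G)[ut]
      if ("css_logistic" %in% methods) {
        m_eff <- effective_tests_after_screen(0.39, n_pairs)
        out["css_logistic"] <- logit_min_hit(which(pooled_stat >= 3), alpha / m_eff)
      }
      if ("r2_logistic" %in% methods) {
        m_eff <- max(1, effective_tests_after_screen(1e-4, n_pairs))
        cand <- which(pooled_stat >= qchisq(1e-4, 1, lower.tail = FALSE))
        out["r2_logistic"] <- logit_min_hit(cand, alpha / m_eff)
      }
    }
  }
  if ("ld_contrast" %in% methods) {
    stats <- ld_contrast_stats(G, y)
    thr_stat <- qchisq(alpha / n_pairs, 1, lower.tail = FALSE)
    out["ld_contrast"] <- any(stats[upper.tri(stats)] > thr_stat, na.rm = TRUE)
  }
  if ("sixpac" %in% methods) {
    pmin_pair <- sixpac_scan(G, y, screen_alpha_sixpac)
    out["sixpac"] <- any(pmin_pair[upper.tri(pmin_pair)] < alpha / n_pairs,
                         na.rm = TRUE)
  }
  out
}

# pooled-cohort composite-LD chi-square (n * r^2) for all pairs
pooled_ld_stats <- function(G) {
  n <- nrow(G)
  X <- scale(G, center = TRUE, scale = FALSE)
  C <- crossprod(X) / n
  v <- diag(C)
  v[v == 0] <- NA
  r2 <- C^2 / outer(v, v)
  n * r2
}

# LD-contrast chi-square statistics for all pairs (df 1)
ld_contrast_stats <- function(G, y) {
  grp <- function(rows) {
    X <- G[rows, , drop = FALSE]
    n <- nrow(X)
    Xc <- scale(X, center = TRUE, scale = FALSE)
    C <- crossprod(Xc) / n
    S <- crossprod(Xc^2) / n
    list(C = C, V = S - C^2, n = n)
  }
  g1 <- grp(y == 1); g0 <- grp(y == 0)
  se2 <- g1$V / g1$n + g0$V / g0$n
  se2[se2 <= 0] <- NA
  (g1$C - g0$C)^2 / se2
}

# sixpac-style minimum coding p-value (Bonferroni over tested codings) for
# all pairs, vectorized over the four dom/rec coding combinations
sixpac_scan <- function(G, y, screen_alpha = 0.01) {
  m <- ncol(G)
  Dm <- matrix(as.numeric(G >= 1), nrow(G), m)
  Rm <- matrix(as.numeric(G == 2), nrow(G), m)
  grp <- function(M, rows) {
    X <- M[rows, , drop = FALSE]
    n <- nrow(X)
    Xc <- scale(X, center = TRUE, scale = FALSE)
    list(Xc = Xc, n = n)
  }
  cases <- y == 1; ctrls <- y == 0
  blocks <- list(D = list(ca = grp(Dm, cases), co = grp(Dm, ctrls)),
                 R = list(ca = grp(Rm, cases), co = grp(Rm, ctrls)))
  const <- list(D = apply(Dm, 2, var) == 0, R = apply(Rm, 2, var) == 0)
  best <- matrix(Inf, m, m)
  tested <- matrix(0, m, m)
  for (a in c("D", "R")) {
    for (b in c("D", "R")) {
      ok <- outer(!const[[a]], !const[[b]])
      tested <- tested + ok
      covv <- function(g1, g2) {
        n <- g1$n
        C <- crossprod(g1$Xc, g2$Xc) / n
        S <- crossprod(g1$Xc^2, g2$Xc^2) / n
        list(C = C, V = S - C^2, n = n)
      }
      ca <- covv(blocks[[a]]$ca, blocks[[b]]$ca)
      co <- covv(blocks[[a]]$co, blocks[[b]]$co)
      vca <- ca$V / ca$n
      vca[vca <= 0] <- NA
      z2 <- ca$C^2 / vca
      pass <- ok & !is.na(z2) &
        pchisq(z2, 1, lower.tail = FALSE) < screen_alpha
      se2 <- ca$V / ca$n + co$V / co$n
      se2[se2 <= 0] <- NA
      stat <- (ca$C - co$C)^2 / se2
      pmain <- pchisq(stat, 1, lower.tail = FALSE)
      pmain[!pass | is.na(pmain)] <- Inf
      best <- pmin(best, pmain)
    }
  }
  out <- best * tested
  out[!is.finite(best)] <- 1
  pmin(out, 1)
}

#' Default multiple-testing accounting for chip-scale power studies
#'
#' The assumed totals used in the power experiments: `1e6` variants and
#' `1e12` variant pairs on the chip, one interacting pair present; static
#' stage corrections for an assumed `M = 100` associated variants are
#' `1e12, 1e8, 1e8, 4950`.
#'
#' @param n_variants,total_pairs Assumed chip totals.
#' @param M Assumed associated-variant count for the static corrections.
#' @return List with `n_variants`, `total_pairs` and `static_K`.
#' @export
power_corrections <- function(n_variants = 1e6, total_pairs = 1e12, M = 100) {
  list(n_variants = n_variants, total_pairs = total_pairs,
       static_K = c(total_pairs, M * n_variants, M * n_variants, M * (M - 1) / 2))
}

#' Estimate power to detect one interacting pair
#'
#' Simulates replicate case-control samples of a single variant pair from a
#' two-locus interaction model and records how often the configured method
#' declares the pair significant under chip-scale multiple-testing
#' accounting ([power_corrections()]). Screened methods succeed only when
#' the pair passes both its screen and the corrected main test.
#'
#' Besides the comparison methods of [estimate_fwer()], the pseudo-methods
#' `"h1"` and `"h4"` report the uncorrected power of the stage-1
#' (no-association, df 8) and last-stage (logit interaction, df 4) tests at
#' the nominal level — the building blocks of the stage-wise procedure.
#'
#' @param model A [two_locus_model()].
#' @param method Method id.
#' @param n_reps Replicates (default 200).
#' @param n_cases,n_controls Group sizes (default 3000 + 3000).
#' @param alpha Nominal level.
#' @param corrections See [power_corrections()].
#' @param weights,links Stage-wise settings.
#' @param seed Root seed.
#' @return One-row tibble: `method`, `estimate`, `n_reps`, `se`.
#' @export
estimate_power <- function(model, method = "static", n_reps = 200,
                           n_cases = 3000, n_controls = 3000, alpha = 0.05,
                           corrections = power_corrections(),
                           weights = stage_weights(), links = all_links(),
                           seed = 1L) {
  stopifnot(inherits(model, "two_locus_model"))
  method <- match.arg(method, c(fwer_methods, "h1", "h4"))
  hit <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(derive_seed(seed, r))
    hit[r] <- power_replicate(model, method, n_cases, n_controls, alpha,
                              corrections, weights, links)
  }
  est <- mean(hit)
  tibble::tibble(method = method, estimate = est, n_reps = n_reps,
                 se = sqrt(est * (1 - est) / n_reps))
}

power_replicate <- function(model, method, n_cases, n_controls, alpha,
                            corrections, weights, links) {
  needs_geno <- method %in% c("marginal_logistic", "css_logistic", "r2_logistic",
                              "ld_contrast", "sixpac")
  samp <- sample_case_control(model, n_cases, n_controls, genotypes = needs_geno)
  tab <- if (needs_geno) samp$table else samp
  np <- corrections$total_pairs
  switch(method,
    h1 = lrt(fit_pair_model(tab, "H1"), fit_pair_model(tab, "HA"))$pvalue < alpha,
    h4 = direct_logistic_test(tab) < alpha,
    logistic = direct_logistic_test(tab) < alpha / np,
    static = {
      sp <- stage_pvalues(tab, links)
      ps <- c(sp$p1, sp$p2, sp$p3, sp$q)
      all(ps < stage_weights(weights) * alpha / corrections$static_K)
    },
    adaptive = {
      # single embedded pair: every |R_{s-1}| is 1 while the pair is alive
      sp <- stage_pvalues(tab, links)
      ps <- c(sp$p1, sp$p2, sp$p3, sp$q)
      all(ps < stage_weights(weights) * alpha)
    },
    marginal_logistic = {
      p1 <- marginal_lrt_p(samp$g1, samp$y)
      p2 <- marginal_lrt_p(samp$g2, samp$y)
      m_eff <- effective_tests_after_screen(0.1, mode = "pairwise_product",
                                            n_variants = corrections$n_variants)
      p1 < 0.1 && p2 < 0.1 && direct_logistic_test(tab) < alpha / m_eff
    },
    css_logistic = {
      sc <- ld_cohort_screen(samp$g1, samp$g2, "css")
      sc$pass && direct_logistic_test(tab) <
        alpha / effective_tests_after_screen(0.39, np)
    },
    r2_logistic = {
      sc <- ld_cohort_screen(samp$g1, samp$g2, "r2")
      sc$pass && direct_logistic_test(tab) <
        alpha / effective_tests_after_screen(1e-4, np)
    },
    ld_contrast = ld_contrast_test(samp$g1, samp$g2, samp$y)$pvalue < alpha / np,
    sixpac = {
      sx <- sixpac_style_test(samp$g1, samp$g2, samp$y)
      sx$screen_pass && sx$pvalue < alpha / np
    }
  )
}

#' Exceedence curve of a set of power estimates
#'
#' For power values of a collection of models, the exceedence curve maps a
#' threshold `t` to the fraction of models whose power is at least `t` — a
#' non-increasing step function with value 1 at `t = 0`.
#'
#' @param powers Nonempty numeric vector of power estimates in \[0, 1\].
#' @return A function `f(t)`; `tidy()` returns the step coordinates.
#' @export
exceedence_curve <- function(powers) {
  powers <- as.numeric(powers)
  if (!length(powers) || anyNA(powers)) abort("powers must be a nonempty numeric vector")
  f <- function(t) vapply(t, function(tt) mean(powers >= tt), numeric(1))
  structure(f, powers = powers, class = c("exceedence_curve", "function"))
}

#' @exportS3Method generics::tidy
tidy.exceedence_curve <- function(x, ...) {
  p <- sort(unique(c(0, attr(x, "powers"), 1)))
  tibble::tibble(threshold = p, fraction = x(p))
}

#' @exportS3Method ggplot2::autoplot
autoplot.exceedence_curve <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$threshold, .data$fraction)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "power threshold t", y = "fraction of models with power ≥ t")
}

#' Enumerate the stage-weight grid
#'
#' All weight 4-tuples on the `precision` grid summing to 1 (exact rational
#' arithmetic on grid steps). With `allow_zero = FALSE` (default) every
#' weight is at least one grid step.
#'
#' @param precision Grid step (must divide 1; default 0.1).
#' @param allow_zero Allow zero weights in the enumeration.
#' @return Tibble with columns `w1`..`w4`.
#' @export
weight_grid <- function(precision = 0.1, allow_zero = FALSE) {
  steps <- round(1 / precision)
  if (abs(steps * precision - 1) > 1e-9) abort("precision must divide 1")
  lo <- if (allow_zero) 0L else 1L
  combos <- expand.grid(i = lo:steps, j = lo:steps, k = lo:steps)
  combos$l <- steps - combos$i - combos$j - combos$k
  combos <- combos[combos$l >= lo, ]
  tibble::tibble(w1 = combos$i / steps, w2 = combos$j / steps,
                 w3 = combos$k / steps, w4 = combos$l / steps)
}

#' Grid search over stage weights
#'
#' Estimates the static procedure's power for every weight combination on
#' the grid, re-using one set of simulated stage p-value quadruples across
#' all combinations (the weights only move the per-stage thresholds).
#'
#' @param model A [two_locus_model()] to simulate from.
#' @param alpha Nominal level.
#' @param n_reps Replicates shared by all weight tuples.
#' @param n_cases,n_controls Group sizes.
#' @param corrections See [power_corrections()].
#' @param precision,allow_zero Grid settings, see [weight_grid()].
#' @param links Stage-4 links.
#' @param seed Root seed.
#' @return Tibble `w1`..`w4`, `power`, ranked by decreasing power.
#' @export
weight_grid_search <- function(model, alpha = 0.05, n_reps = 100,
                               n_cases = 3000, n_controls = 3000,
                               corrections = power_corrections(),
                               precision = 0.1, allow_zero = FALSE,
                               links = all_links(), seed = 1L) {
  grid <- weight_grid(precision, allow_zero)
  sp <- matrix(NA_real_, n_reps, 4)
  for (r in seq_len(n_reps)) {
    set.seed(derive_seed(seed, r))
    tab <- sample_case_control(model, n_cases, n_controls)
    s <- stage_pvalues(tab, links)
    sp[r, ] <- c(s$p1, s$p2, s$p3, s$q)
  }
  K <- corrections$static_K
  grid$power <- vapply(seq_len(nrow(grid)), function(i) {
    w <- unlist(grid[i, 1:4])
    if (any(w == 0)) return(0)  # a zero-weight stage can never be passed
    thr <- w * alpha / K
    mean(apply(sp, 1, function(ps) all(ps < thr)))
  }, numeric(1))
  dplyr::arrange(grid, dplyr::desc(.data$power))
}
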