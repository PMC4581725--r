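test_that("static procedure matches a hand-executed transcript on 3 pairs", {
  # thresholds at w = 0.25 each, K = (3, 2, 2, 1), alpha = 0.05:
  # 0.0041667, 0.00625, 0.00625, 0.0125
  pm <- rbind(A = c(0.001, 0.002, 0.003, 0.004),
              B = c(0.002, 0.010, 0.001, 0.001),
              C = c(0.500, 0.001, 0.001, 0.001))
  df <- as.data.frame(pm)
  names(df) <- c("p1", "p2", "p3", "p4")
  df$pair <- rownames(pm)
  res <- run_static(df, weights = rep(0.25, 4),
                    scheme = correction_scheme(c(3, 2, 2, 1)), alpha = 0.05)
  out <- tidy(res)
  expect_equal(out$significant, c(TRUE, FALSE, FALSE))
  # hand-computed adjusted p-values: max_s K_s p_is / w_s
  expect_equal(out$adjusted_p, c(0.024, 0.08, 1), tolerance = 1e-12)
  expect_equal(out$stage_reached, c(4L, 2L, 1L))
})

test_that("static output equals the pseudocode transcript on enumerated inputs", {
  set.seed(21)
  w <- stage_weights()
  K <- c(10, 5, 5, 2)
  for (r in 1:20) {
    pm <- matrix(runif(20, 0, 0.2)^2, 5, 4)
    df <- as.data.frame(pm); names(df) <- c("p1", "p2", "p3", "p4")
    res <- tidy(run_static(df, w, correction_scheme(K), alpha = 0.05))
    oracle <- static_pseudocode_oracle(pm, w, K, 0.05)
    expect_equal(res$significant, oracle$significant)
    expect_equal(res$adjusted_p, oracle$adjusted)
    # adjusted-p consistency: significant at alpha iff adjusted p < alpha
    expect_equal(res$significant, res$adjusted_p < 0.05)
    # adaptive agrees with its transcript too
    resa <- tidy(run_adaptive(df, w, alpha = 0.05))
    expect_equal(resa$significant, adaptive_pseudocode_oracle(pm, w, 0.05))
    # conservative direction: adjusted < alpha implies significance
    expect_true(all(resa$significant[resa$adjusted_p < 0.05]))
  }
})

test_that("single pair edge cases behave as the formulas dictate", {
  df <- data.frame(p1 = 0, p2 = 0, p3 = 0, p4 = 0)
  res <- tidy(run_static(df, scheme = correction_scheme(c(1, 1, 1, 1))))
  expect_true(res$significant)
  expect_equal(res$adjusted_p, 0)
  # adaptive on one pair: every threshold is w_s * alpha
  w <- stage_weights()
  ps <- w * 0.05 * 0.99
  dfa <- data.frame(p1 = ps[1], p2 = ps[2], p3 = ps[3], p4 = ps[4])
  expect_true(tidy(run_adaptive(dfa))$significant)
  ps2 <- ps; ps2[3] <- w[3] * 0.05 * 1.01
  dfb <- data.frame(p1 = ps2[1], p2 = ps2[2], p3 = ps2[3], p4 = ps2[4])
  expect_false(tidy(run_adaptive(dfb))$significant)
  # strict inequality: p exactly at the threshold does not pass
  dfc <- data.frame(p1 = w[1] * 0.05, p2 = 0, p3 = 0, p4 = 0)
  expect_false(tidy(run_adaptive(dfc))$significant)
})

test_that("adaptive rejects a superset of static when its corrections are smaller", {
  set.seed(22)
  for (r in 1:20) {
    pm <- matrix(runif(40, 0, 0.1)^3, 10, 4)
    df <- as.data.frame(pm); names(df) <- c("p1", "p2", "p3", "p4")
    # static K with stage-2..4 corrections at least the adaptive |R| bound
    K <- c(10, 50, 50, 50)
    st <- tidy(run_static(df, scheme = correction_scheme(K)))
    ad <- tidy(run_adaptive(df))
    expect_true(all(ad$significant[st$significant]))
  }
})

test_that("rejections are monotone in alpha", {
  set.seed(23)
  pm <- matrix(runif(80, 0, 0.05)^2, 20, 4)
  df <- as.data.frame(pm); names(df) <- c("p1", "p2", "p3", "p4")
  K <- correction_scheme(c(20, 8, 8, 3))
  for (pairs_alpha in list(c(0.01, 0.05), c(0.05, 0.2))) {
    s_lo <- tidy(run_static(df, scheme = K, alpha = pairs_alpha[1]))$significant
    s_hi <- tidy(run_static(df, scheme = K, alpha = pairs_alpha[2]))$significant
    expect_true(all(s_hi[s_lo]))
    a_lo <- tidy(run_adaptive(df, alpha = pairs_alpha[1]))$significant
    a_hi <- tidy(run_adaptive(df, alpha = pairs_alpha[2]))$significant
    expect_true(all(a_hi[a_lo]))
  }
})

test_that("static corrections validate and compute the stage counts", {
  expect_equal(static_corrections(2, 2)$K, c(1, 4, 4, 1))
  expect_error(static_corrections(500, 1), "M must be at least 2")
  expect_error(correction_scheme(c(1, 0, 1, 1)), "positive")
  expect_error(stage_weights(c(0.5, 0.5, 0, 0)), "positive")
  expect_error(stage_weights(c(0.5, 0.2, 0.2, 0.2)), "sum to 1")
})

test_that("stage p-values respect the pair-swap symmetry and degeneracy", {
  set.seed(24)
  g1 <- rbinom(600, 2, 0.3); g2 <- rbinom(600, 2, 0.4)
  y <- rbinom(600, 1, plogis(-0.5 + 0.4 * g1))
  a <- stage_pvalues(pair_table(g1, g2, y))
  b <- stage_pvalues(pair_table(g2, g1, y))
  expect_equal(a$p1, b$p1, tolerance = 1e-9)
  expect_equal(a$p2, b$p3, tolerance = 1e-9)  # H2/H3 swap with the variants
  expect_equal(a$p3, b$p2, tolerance = 1e-9)
  expect_equal(a$q, b$q, tolerance = 1e-6)
  # a constant second variant collapses the stratification: the single-main
  # model for it is already saturated and the scale-invariance stage is
  # degenerate (saturated-equivalent), so those p-values are 1
  g2c <- rep(0L, 600)
  d <- stage_pvalues(pair_table(g1, g2c, y))
  expect_equal(d$p2, 1)
  expect_equal(d$q, 1)
})

test_that("stage p-values are marginally uniform under no association", {
  set.seed(25)
  reps <- 500
  f <- outer(hwe_genotype_freqs(0.35), hwe_genotype_freqs(0.35))
  probs <- c(as.vector(f) * 0.5, as.vector(f) * 0.5)  # y independent of (a, b)
  pm <- t(replicate(reps, {
    tab <- as_pair_table(array(rmultinom(1, 8000, probs), c(3, 3, 2)))
    s <- stage_pvalues(tab, links = "logit")
    c(s$p1, s$p2, s$p3, s$q)
  }))
  for (s in 1:4) {
    ks <- suppressWarnings(stats::ks.test(pm[, s], "punif"))
    expect_gt(ks$p.value, 0.005, label = paste("stage", s))
  }
})

test_that("strong pure-interaction signal is seen most strongly at stage 1", {
  set.seed(26)
  model <- double_dominant_model(0.05, 0.3)
  for (r in 1:10) {
    tab <- sample_case_control(model, 3000, 3000)
    s <- stage_pvalues(tab)
    expect_lte(s$p1, max(s$p4_logit, 1e-300))
  }
})

test_that("scan results are written as a TSV with the documented schema", {
  set.seed(27)
  coh <- simulate_null_cohort("none", 300, 300, n_variants = 12)
  res <- epistasis_scan(coh$genotypes, coh$phenotype, method = "adaptive")
  expect_s3_class(res, "stage_result")
  expect_equal(nrow(tidy(res)), choose(12, 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(res, path)
  back <- utils::read.delim(path)
  expect_true(all(c("variant1", "variant2", "p_stage1", "q_combined",
                    "stage_reached", "adjusted_p", "significant") %in% names(back)))
  expect_equal(nrow(back), choose(12, 2))
})
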