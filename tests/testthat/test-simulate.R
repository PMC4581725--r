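test_that("Hardy-Weinberg frequencies are exact and normalized", {
  expect_equal(hwe_genotype_freqs(0.5), c(0.25, 0.5, 0.25))
  expect_equal(hwe_genotype_freqs(0.3), c(0.49, 0.42, 0.09))
  set.seed(31)
  for (q in runif(200, 1e-6, 0.5)) {
    expect_equal(sum(hwe_genotype_freqs(q)), 1, tolerance = 1e-12)
  }
  expect_error(hwe_genotype_freqs(0))
  expect_error(hwe_genotype_freqs(0.7))
})

test_that("Risch decomposability matches an independent brute-force oracle", {
  # oracle written independently: explicit row-constant and column-constant
  # matrices combined by logical OR, compared cell by cell
  oracle <- function(P) {
    for (ri in 0:7) for (ci in 0:7) {
      r <- c(bitwAnd(ri, 1), bitwAnd(bitwShiftR(ri, 1), 1), bitwAnd(bitwShiftR(ri, 2), 1))
      ccol <- c(bitwAnd(ci, 1), bitwAnd(bitwShiftR(ci, 1), 1), bitwAnd(bitwShiftR(ci, 2), 1))
      R <- rbind(r, r, r)                 # identical rows
      C <- cbind(ccol, ccol, ccol)        # identical columns
      ok <- TRUE
      for (a in 1:3) for (b in 1:3) {
        if ((R[a, b] | C[a, b]) != (P[a, b] == 1)) { ok <- FALSE; break }
      }
      if (ok) return(TRUE)
    }
    FALSE
  }
  expect_true(risch_decomposable(matrix(1, 3, 3)))
  first_col <- matrix(0, 3, 3); first_col[, 1] <- 1
  expect_true(risch_decomposable(first_col))
  n_dec <- 0
  for (k in 0:511) {
    P <- matrix(bitwAnd(bitwShiftR(k, 0:8), 1L), 3, 3, byrow = TRUE)
    d <- risch_decomposable(P)
    expect_identical(d, oracle(P), info = paste("pattern", k))
    n_dec <- n_dec + d
  }
  models <- enumerate_interaction_models()
  expect_equal(attr(models, "scanned"), 512L)
  expect_equal(length(models) + n_dec, 512L)     # exact partition
  expect_equal(length(models), 462L)             # regression constant (oracle-derived)
  # all-zero and all-one patterns are decomposable, hence excluded
  expect_false(0L %in% attr(models, "index"))
  expect_false(511L %in% attr(models, "index"))
})

test_that("heritability follows its variance-decomposition definition", {
  # constant penetrance: no genotype-attributable variance
  expect_equal(heritability(two_locus_model(matrix(0.3, 3, 3))), 0)
  set.seed(32)
  for (r in 1:10) {
    pen <- matrix(runif(9, 0.05, 0.6), 3, 3)
    model <- two_locus_model(pen, 0.25, 0.4)
    f <- outer(hwe_genotype_freqs(0.25), hwe_genotype_freqs(0.4))
    K <- sum(pen * f)
    expect_equal(heritability(model),
                 sum((K - pen)^2 * f) / (K * (1 - K)), tolerance = 1e-12)
  }
  # shrinking the effect drives heritability to zero monotonically
  P <- matrix(c(0, 0, 0, 0, 1, 1, 0, 1, 1), 3, 3)
  h <- vapply(c(0.4, 0.2, 0.1, 0.05), function(b1) {
    heritability(two_locus_model(0.05 + b1 * P))
  }, numeric(1))
  expect_true(all(diff(h) < 0))
  expect_error(heritability(two_locus_model(matrix(0, 3, 3))), "degenerate")
})

test_that("effect calibration hits the target and is monotone", {
  P <- matrix(c(0, 0, 0, 0, 1, 1, 0, 1, 1), 3, 3)
  expect_equal(calibrate_effect(P, target_h2 = 0), 0)
  b <- vapply(c(0.005, 0.010, 0.015), function(h2) {
    calibrate_effect(P, beta0 = 0.05, target_h2 = h2)
  }, numeric(1))
  expect_true(all(diff(b) > 0))
  for (i in seq_along(b)) {
    m <- two_locus_model(0.05 + b[i] * P)
    expect_lt(abs(heritability(m) - c(0.005, 0.010, 0.015)[i]), 1e-8)
  }
  expect_error(calibrate_effect(P, beta0 = 0.05, target_h2 = 0.9), "unachievable")
  expect_error(calibrate_effect(matrix(1, 3, 3), target_h2 = 0.01), "constant")
})

test_that("Bayes case-control sampler draws from the exact conditionals", {
  # constant penetrance: case genotypes are just the HWE product
  set.seed(33)
  model <- two_locus_model(matrix(0.2, 3, 3), 0.3, 0.4)
  tab <- sample_case_control(model, 1e6, 10)
  f <- outer(hwe_genotype_freqs(0.3), hwe_genotype_freqs(0.4))
  obs <- unclass(tab)[, , 2] / 1e6
  se <- sqrt(f * (1 - f) / 1e6)
  expect_true(all(abs(obs - f) < 4 * se + 1e-9))
  # non-constant model: cells match the Bayes conditional at n = 1e6
  pen <- matrix(c(0.02, 0.02, 0.3, 0.02, 0.25, 0.3, 0.3, 0.3, 0.5), 3, 3)
  model <- two_locus_model(pen, 0.3, 0.3)
  fj <- outer(hwe_genotype_freqs(0.3), hwe_genotype_freqs(0.3))
  wc <- pen * fj / sum(pen * fj)
  wk <- (1 - pen) * fj / sum((1 - pen) * fj)
  expect_equal(sum(wc), 1, tolerance = 1e-12)
  expect_equal(sum(wk), 1, tolerance = 1e-12)
  tab <- sample_case_control(model, 1e6, 1e6)
  for (side in 1:2) {
    th <- if (side == 2) wc else wk
    obs <- unclass(tab)[, , side] / 1e6
    se <- sqrt(th * (1 - th) / 1e6)
    expect_true(all(abs(obs - th) < 4 * se + 1e-9))
  }
  # determinism under a fixed seed
  set.seed(99); t1 <- sample_case_control(model, 500, 500)
  set.seed(99); t2 <- sample_case_control(model, 500, 500)
  expect_identical(t1, t2)
  expect_error(sample_case_control(two_locus_model(matrix(0, 3, 3)), 10, 10),
               "all-zero")
})

test_that("the double-dominant model calibrates and has the stated structure", {
  m0 <- double_dominant_model(0)
  expect_equal(heritability(m0), 0)
  m <- double_dominant_model(0.02, 0.3)
  expect_lt(abs(heritability(m) - 0.02), 1e-8)
  # delta block structure: baseline cells at g_inverse(alpha0), the four
  # double-carrier cells sharing one elevated penetrance
  expect_equal(unname(m$penetrance[1, ]), rep(0.5, 3))
  expect_equal(unname(m$penetrance[, 1]), rep(0.5, 3))
  expect_equal(length(unique(as.vector(round(m$penetrance[2:3, 2:3], 12)))), 1L)
  xs <- vapply(c(0.01, 0.02, 0.03), function(h2) {
    attr(double_dominant_model(h2, 0.3), "x")
  }, numeric(1))
  expect_true(all(diff(xs) > 0))
})

test_that("null cohorts are reproducible and correctly wired", {
  c1 <- simulate_null_cohort("multi:10", 300, 300, n_variants = 40, seed = 42)
  c2 <- simulate_null_cohort("multi:10", 300, 300, n_variants = 40, seed = 42)
  expect_identical(c1$genotypes, c2$genotypes)
  expect_equal(dim(c1$genotypes), c(600L, 40L))
  expect_equal(sum(c1$phenotype), 300)
  expect_equal(c1$associated, 1:10)
  # intercept wiring: implied population disease probability is rare
  p_mean <- plogis(c1$params$intercept +
                     sum(c1$params$beta * 2 * c1$maf[1:10]))
  expect_lt(p_mean, 0.01)
  expect_error(simulate_null_cohort("double:probit"), "unknown")
  expect_error(simulate_null_cohort("multi:0"), "positive L")
})

test_that("exact-Bayes and rejection-sampling cohort paths agree in distribution", {
  ce <- simulate_null_cohort("double:logit", 1500, 1500, n_variants = 4, seed = 7)
  cr <- simulate_null_cohort("double:logit", 1500, 1500, n_variants = 4, seed = 8,
                             method = "rejection")
  # theoretical case allele frequency from the exact Bayes conditional
  theory_caf <- function(coh) {
    grid <- as.matrix(expand.grid(0:2, 0:2))
    f <- hwe_genotype_freqs(coh$maf[1])[grid[, 1] + 1] *
      hwe_genotype_freqs(coh$maf[2])[grid[, 2] + 1]
    p <- plogis(coh$params$a0 + coh$params$theta * rowSums(grid))
    w <- p * f / sum(p * f)
    c(sum(grid[, 1] * w), sum(grid[, 2] * w)) / 2
  }
  for (coh in list(ce, cr)) {
    caf <- variant_maf(coh$genotypes[coh$phenotype == 1, 1:2, drop = FALSE])
    kaf <- variant_maf(coh$genotypes[coh$phenotype == 0, 1:2, drop = FALSE])
    expect_true(all(caf > kaf))  # risk alleles enriched in cases
    th <- theory_caf(coh)
    expect_true(all(abs(unname(caf) - th) < 4 * sqrt(0.25 / 3000)))
  }
})

test_that("unachievable double-main effects on raw scales are rejected", {
  expect_error(
    simulate_null_cohort("double:identity", 100, 100, n_variants = 3,
                         effects = list(a0 = 0.5, theta = 0.2), seed = 1),
    "outside \\[0, 1\\]"
  )
})

test_that("saturated fits recover the generating penetrance at large n", {
  set.seed(34)
  models <- enumerate_interaction_models()
  for (k in c(5, 200, 400)) {
    b1 <- calibrate_effect(models[[k]], beta0 = 0.05, target_h2 = 0.01)
    model <- two_locus_model(0.05 + b1 * models[[k]])
    samp <- sample_case_control(model, 1e5, 1e5)
    fit <- fit_pair_model(samp, "HA")
    # expected sample-conditional penetrance per cell
    f <- outer(hwe_genotype_freqs(0.3), hwe_genotype_freqs(0.3))
    wc <- model$penetrance * f / sum(model$penetrance * f) * 1e5
    wk <- (1 - model$penetrance) * f / sum((1 - model$penetrance) * f) * 1e5
    pi_ab <- wc / (wc + wk)
    n_ab <- wc + wk
    se <- sqrt(pi_ab * (1 - pi_ab) / n_ab)
    expect_true(all(abs(fit$fitted_penetrance - pi_ab) < 3 * se + 1e-6))
  }
})
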