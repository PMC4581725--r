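test_that("binomial loglik follows the cell-sum definition", {
  set.seed(11)
  tab <- random_pair_table(1, 40)
  half <- matrix(0.5, 3, 3)
  expect_equal(loglik_binomial(tab, half), sum(tab) * log(0.5))
  # empty cell contributes nothing whatever its penetrance
  arr <- unclass(random_pair_table())
  arr[2, 2, ] <- 0L
  tab0 <- as_pair_table(arr)
  pen1 <- matrix(runif(9), 3, 3); pen2 <- pen1; pen2[2, 2] <- 0.999
  expect_equal(loglik_binomial(tab0, pen1), loglik_binomial(tab0, pen2))
  # agreement with an independent term-by-term oracle
  for (r in 1:20) {
    tab <- random_pair_table()
    pen <- matrix(runif(9, 0.05, 0.95), 3, 3)
    expect_equal(loglik_binomial(tab, pen), loglik_oracle(tab, pen),
                 tolerance = 1e-10)
  }
  # -Inf when positive counts meet boundary penetrance
  expect_identical(loglik_binomial(tab, matrix(0, 3, 3)), -Inf)
  expect_error(loglik_binomial(tab, matrix(2, 3, 3)), "\\[0, 1\\]")
})

test_that("saturated fits are closed-form maximum likelihood", {
  # 50% cases in every cell: H1 fit is flat 0.5 and already saturated
  arr <- array(7L, c(3, 3, 2))
  tab <- as_pair_table(arr)
  f1 <- fit_pair_model(tab, "H1")
  expect_equal(unname(f1$fitted_penetrance[1, 1]), 0.5)
  expect_equal(f1$loglik, fit_pair_model(tab, "HA")$loglik)
  set.seed(12)
  for (r in 1:10) {
    tab <- random_pair_table()
    for (m in c("H1", "H2", "H3", "HA")) {
      expect_equal(fit_pair_model(tab, m)$loglik,
                   saturated_loglik_oracle(tab, m), tolerance = 1e-6,
                   info = paste(m, r))
    }
  }
})

test_that("loglik is monotone along the nesting chains", {
  set.seed(13)
  for (r in 1:15) {
    tab <- random_pair_table()
    ll <- sapply(c("H1", "H2", "H3", "HA"), function(m) fit_pair_model(tab, m)$loglik)
    expect_true(ll["H1"] <= ll["H2"] + 1e-9 && ll["H2"] <= ll["HA"] + 1e-9)
    expect_true(ll["H1"] <= ll["H3"] + 1e-9 && ll["H3"] <= ll["HA"] + 1e-9)
    for (lk in all_links()) {
      ll4 <- fit_pair_model(tab, "H4", lk)$loglik
      expect_gte(ll4, ll["H1"] - 1e-6)
      expect_lte(ll4, ll["HA"] + 1e-6)
    }
  }
})

test_that("saturated logliks are invariant to transforming through any link", {
  set.seed(14)
  for (r in 1:10) {
    tab <- random_pair_table(1, 50)
    for (m in c("H1", "H2", "H3", "HA")) {
      fit <- fit_pair_model(tab, m)
      direct <- fit$loglik
      for (lk in all_links()) {
        phat <- fit$fitted_penetrance
        nz <- rowSums(unclass(tab), dims = 2) > 0
        phat[nz] <- lk$g_inverse(lk$g(pmin(pmax(phat[nz], 1e-9), 1 - 1e-9)))
        phat[!nz] <- 0
        expect_equal(loglik_binomial(tab, phat), direct, tolerance = 1e-10 * abs(direct),
                     info = paste(m, lk$name))
      }
    }
  }
})

test_that("H4 logit fit matches an off-the-shelf IRLS oracle", {
  set.seed(15)
  for (r in 1:15) {
    tab <- dense_pair_table(2000)
    ours <- fit_pair_model(tab, "H4", "logit")
    u <- unclass(tab)
    df <- data.frame(a = factor(rep(0:2, 3)), b = factor(rep(0:2, each = 3)),
                     n1 = as.vector(u[, , 2]), n0 = as.vector(u[, , 1]))
    gfit <- stats::glm(cbind(n1, n0) ~ a + b, family = binomial(), data = df)
    p <- stats::fitted(gfit)
    ll_glm <- sum(df$n1 * log(p) + df$n0 * log(1 - p))
    expect_equal(ours$loglik, ll_glm, tolerance = 1e-6)
  }
})

test_that("H4 fits match a generic bounded numerical optimizer", {
  set.seed(16)
  for (lk in all_links()) {
    worst <- 0
    for (r in 1:100) {
      tab <- dense_pair_table(800)
      ours <- fit_pair_model(tab, "H4", lk)
      u <- unclass(tab)
      n1 <- as.vector(u[, , 2]); n0 <- as.vector(u[, , 1])
      D <- cbind(1, rep(0:2, 3) == 1, rep(0:2, 3) == 2,
                 rep(0:2, each = 3) == 1, rep(0:2, each = 3) == 2)
      nll <- function(th) {
        p <- lk$g_inverse(drop(D %*% th))
        -sum(n1 * log(p) + n0 * log(1 - p))
      }
      start <- c(lk$g(sum(n1) / sum(n1 + n0)), 0, 0, 0, 0)
      o <- optim(start, nll, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-12))
      worst <- max(worst, -o$value - ours$loglik)
    }
    expect_lt(worst, 1e-5, label = paste("H4 deficit on", lk$name))
  }
})

test_that("H4 recovers generating parameters on exactly-additive data", {
  # prospective sampling: the observed conditional equals the generating
  # penetrance, so additivity on the chosen link is preserved in-sample
  # (retrospective quota sampling preserves it only for the logit link)
  set.seed(17)
  D <- cbind(1, rep(0:2, 3) == 1, rep(0:2, 3) == 2,
             rep(0:2, each = 3) == 1, rep(0:2, each = 3) == 2)
  for (nm in c("logit", "identity", "odds")) {
    lk <- link_spec(nm)
    theta <- switch(nm, logit = c(-1.2, 0.3, 0.5, -0.2, -0.4),
                    identity = c(0.2, 0.05, 0.1, 0.04, 0.08),
                    odds = c(0.25, 0.1, 0.2, 0.05, 0.15))
    pen <- matrix(lk$g_inverse(drop(D %*% theta)), 3, 3)
    f <- outer(hwe_genotype_freqs(0.4), hwe_genotype_freqs(0.4))
    probs <- c(as.vector(f * (1 - pen)), as.vector(f * pen))
    cnt <- rmultinom(1, 4e5, probs)
    tab <- as_pair_table(array(cnt, c(3, 3, 2)))
    fit <- fit_pair_model(tab, "H4", lk)
    lr <- lrt(fit, fit_pair_model(tab, "HA"))
    expect_gt(lr$pvalue, 1e-4)  # no spurious interaction at n = 4e5
    expect_true(fit$converged)
    expect_equal(unname(fit$params), theta, tolerance = 0.15)
  }
})

test_that("H4 on a table with fewer than five strata is saturated-equivalent", {
  arr <- array(0L, c(3, 3, 2))
  arr[1:2, 1, 1] <- 5L; arr[1:2, 1, 2] <- c(3L, 8L)
  tab <- as_pair_table(arr)
  fit <- fit_pair_model(tab, "H4", "logit")
  expect_true(fit$saturated_equivalent)
  expect_equal(fit$loglik, fit_pair_model(tab, "HA")$loglik)
})

test_that("likelihood-ratio tests carry the right degrees of freedom", {
  set.seed(18)
  tab <- dense_pair_table(1000)
  ha <- fit_pair_model(tab, "HA")
  expect_equal(lrt(fit_pair_model(tab, "H1"), ha)$df, 8)
  expect_equal(lrt(fit_pair_model(tab, "H2"), ha)$df, 6)
  expect_equal(lrt(fit_pair_model(tab, "H4", "logit"), ha)$df, 4)
  expect_error(lrt(fit_pair_model(tab, "H2"), fit_pair_model(tab, "H3")),
               "not nested")
  expect_error(lrt(ha, fit_pair_model(tab, "H1")), "not nested")
  # equal logliks: statistic 0, p 1
  f1 <- fit_pair_model(tab, "H1")
  fake <- f1; fake$loglik <- ha$loglik
  out <- lrt(fake, ha)
  expect_equal(out$statistic, 0)
  expect_equal(out$pvalue, 1)
})

test_that("scale-invariant combination is the maximum over links", {
  expect_equal(scale_invariant_p(c(logit = 0.01, log = 0.04, identity = 0.2)), 0.2)
  expect_equal(scale_invariant_p(c(odds = 0.73)), 0.73)
  expect_error(scale_invariant_p(numeric()), "at least one")
  expect_error(scale_invariant_p(c(0.5, 1.2)))
})

test_that("H4-vs-saturated p-values are uniform under the additive null", {
  set.seed(19)
  n_rep <- 1000
  f <- outer(hwe_genotype_freqs(0.3), hwe_genotype_freqs(0.3))
  for (nm in c("logit", "odds")) {
    lk <- link_spec(nm)
    pen <- matrix(lk$g_inverse(outer(c(0, 0.15, 0.3), c(0, 0.1, 0.2), "+") +
                                 lk$g(0.3)), 3, 3)
    probs <- c(as.vector(f * (1 - pen)), as.vector(f * pen))
    p <- replicate(n_rep, {
      tab <- as_pair_table(array(rmultinom(1, 8000, probs), c(3, 3, 2)))
      lrt(fit_pair_model(tab, "H4", lk), fit_pair_model(tab, "HA"))$pvalue
    })
    ks <- suppressWarnings(stats::ks.test(p, "punif"))
    expect_gt(ks$p.value, 0.01, label = paste("KS uniformity on", nm))
  }
})
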