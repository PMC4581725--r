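#' Hardy-Weinberg genotype frequencies
#'
#' @param maf Minor-allele frequency in (0, 0.5].
#' @return Numeric vector `((1-q)^2, 2q(1-q), q^2)` of genotype
#'   frequencies for minor-allele counts 0, 1, 2.
#' @export
hwe_genotype_freqs <- function(maf) {
  if (!is.numeric(maf) || length(maf) != 1 || is.na(maf) ||
      maf <= 0 || maf > 0.5) {
    abort("maf must lie in (0, 0.5]")
  }
  q <- maf
  c((1 - q)^2, 2 * q * (1 - q), q^2)
}

#' Two-locus penetrance model
#'
#' The generative unit for power simulations: a 3 x 3 matrix of penetrances
#' `Pr(Y = 1 | X1 = a, X2 = b)` together with the two loci's minor-allele
#' frequencies. Loci are independent (no LD) with Hardy-Weinberg genotype
#' frequencies.
#'
#' @param penetrance 3 x 3 matrix with entries in \[0, 1\].
#' @param maf1,maf2 Minor-allele frequencies in (0, 0.5].
#' @return A `two_locus_model`.
#' @export
two_locus_model <- function(penetrance, maf1 = 0.3, maf2 = maf1) {
  penetrance <- as.matrix(penetrance)
  if (!identical(dim(penetrance), c(3L, 3L)) || anyNA(penetrance) ||
      any(penetrance < 0) || any(penetrance > 1)) {
    abort("penetrance must be a 3 x 3 matrix with entries in [0, 1]")
  }
  hwe_genotype_freqs(maf1); hwe_genotype_freqs(maf2)
  structure(list(penetrance = penetrance, maf1 = maf1, maf2 = maf2),
            class = "two_locus_model")
}

#' @export
print.two_locus_model <- function(x, ...) {
  cat("<two_locus_model> maf =", x$maf1, "/", x$maf2, "\n")
  print(round(x$penetrance, 4))
  invisible(x)
}

# joint genotype frequencies Pr(X1 = a, X2 = b)
joint_geno_freqs <- function(model) {
  outer(hwe_genotype_freqs(model$maf1), hwe_genotype_freqs(model$maf2))
}

#' Risch heterogeneity decomposability of a binary penetrance pattern
#'
#' A 3 x 3 binary penetrance matrix `P` is decomposable in the genetic
#' heterogeneity sense if it can be written as the element-wise OR of a
#' matrix with identical rows and a matrix with identical columns — i.e.
#' `P[a, b] = u[a] | v[b]` for some binary vectors `u`, `v`. Patterns that
#' can NOT be decomposed this way are retained as genuine interactions. The
#' check exhausts all 8 x 8 (row-pattern, column-pattern) combinations.
#'
#' @param P 3 x 3 matrix over \{0, 1\}.
#' @return `TRUE` if decomposable (not an interaction), `FALSE` otherwise.
#' @export
risch_decomposable <- function(P) {
  P <- as.matrix(P)
  if (!identical(dim(P), c(3L, 3L)) || !all(P %in% c(0, 1))) {
    abort("P must be a 3 x 3 binary matrix")
  }
  pats <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  for (i in 1:8) {
    for (j in 1:8) {
      u <- pats[i, ]; v <- pats[j, ]   # u: column-constant part, v: row part
      if (all(P == pmax(matrix(u, 3, 3), matrix(v, 3, 3, byrow = TRUE)))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Enumerate complete-penetrance two-locus interaction models
#'
#' Scans all `2^9 = 512` binary 3 x 3 penetrance matrices and retains those
#' that are not Risch-decomposable (see [risch_decomposable()]), i.e. the
#' patterns displaying genuine two-locus interaction. The enumeration order
#' is deterministic: pattern `k` (0..511) sets cell `(a, b)` to bit
#' `3 * a + b` of `k` (row-major, least-significant bit first).
#'
#' @return A list of 3 x 3 binary matrices; attribute `scanned` records the
#'   512 patterns visited, attribute `index` the retained pattern indices.
#' @export
enumerate_interaction_models <- function() {
  kept <- list()
  index <- integer()
  for (k in 0:511) {
    P <- matrix(bitwAnd(bitwShiftR(k, 0:8), 1L), 3, 3, byrow = TRUE)
    if (!risch_decomposable(P)) {
      kept[[length(kept) + 1L]] <- P
      index <- c(index, k)
    }
  }
  attr(kept, "scanned") <- 512L
  attr(kept, "index") <- index
  kept
}

#' Broad-sense heritability of a two-locus model
#'
#' `H^2 = sum_ab (K - p_ab)^2 f_ab / (K (1 - K))` where `p_ab` is the
#' penetrance, `f_ab` the joint genotype frequency and
#' `K = sum_ab p_ab f_ab` the disease prevalence: the genotype-attributable
#' variance of the binary trait, normalized by its total variance.
#'
#' @param model A [two_locus_model()].
#' @return Heritability in \[0, 1\].
#' @export
heritability <- function(model) {
  stopifnot(inherits(model, "two_locus_model"))
  f <- joint_geno_freqs(model)
  K <- sum(model$penetrance * f)
  if (K <= 0 || K >= 1) abort("degenerate model: Pr(Y = 1) must lie in (0, 1)")
  sum((K - model$penetrance)^2 * f) / (K * (1 - K))
}

#' Calibrate a binary pattern's effect size to a target heritability
#'
#' Given a binary pattern `P`, the continuous model `beta0 + beta1 * P` has
#' heritability continuous and increasing in `beta1`; this solves for the
#' `beta1` achieving the target by bisection on `[0, 1 - beta0]`.
#'
#' @param pattern 3 x 3 binary matrix (not constant).
#' @param beta0 Base risk in \[0, 1).
#' @param mafs Length-2 vector of minor-allele frequencies.
#' @param target_h2 Target heritability (>= 0).
#' @param tol Bisection tolerance on the achieved heritability.
#' @return `beta1` such that the calibrated model's heritability is within
#'   `tol` of the target.
#' @export
calibrate_effect <- function(pattern, beta0 = 0.05, mafs = c(0.3, 0.3),
                             target_h2, tol = 1e-8) {
  pattern <- as.matrix(pattern)
  if (all(pattern == pattern[1, 1])) abort("pattern must not be constant")
  h2_of <- function(b1) {
    heritability(two_locus_model(beta0 + b1 * pattern, mafs[1], mafs[2]))
  }
  if (target_h2 == 0) return(0)
  hi <- 1 - beta0
  if (h2_of(hi) < target_h2 - tol) {
    abort(sprintf("target heritability %.4g unachievable (max %.4g)",
                  target_h2, h2_of(hi)))
  }
  lo <- 0
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (h2_of(mid) < target_h2) lo <- mid else hi <- mid
    if (abs(h2_of(mid) - target_h2) < tol) return(mid)
  }
  (lo + hi) / 2
}

#' Sample a case-control cohort from a two-locus model
#'
#' Case genotypes are drawn from the multinomial with
#' `Pr(X1 = a, X2 = b | Y = 1)` proportional to `p_ab * f_ab` (Bayes'
#' theorem), controls analogously with `1 - p_ab`, i.e. exactly the
#' retrospective sampling scheme of a case-control design.
#'
#' @param model A [two_locus_model()].
#' @param n_cases,n_controls Group sizes.
#' @param genotypes If `TRUE`, also return per-individual genotype vectors.
#' @return A [pair_table()]; with `genotypes = TRUE`, a list with `table`,
#'   `g1`, `g2`, `y`.
#' @export
sample_case_control <- function(model, n_cases, n_controls, genotypes = FALSE) {
  stopifnot(inherits(model, "two_locus_model"), n_cases > 0, n_controls > 0)
  f <- joint_geno_freqs(model)
  wc <- model$penetrance * f
  wk <- (1 - model$penetrance) * f
  if (sum(wc) <= 0) abort("all-zero penetrance: cases cannot be sampled")
  if (sum(wk) <= 0) abort("all-one penetrance: controls cannot be sampled")
  case_counts <- matrix(rmultinom(1, n_cases, as.vector(wc / sum(wc))), 3, 3)
  ctrl_counts <- matrix(rmultinom(1, n_controls, as.vector(wk / sum(wk))), 3, 3)
  arr <- array(0L, c(3, 3, 2))
  arr[, , 1] <- ctrl_counts; arr[, , 2] <- case_counts
  tab <- as_pair_table(arr)
  if (!genotypes) return(tab)
  expand <- function(counts) {
    cells <- which(counts > 0, arr.ind = TRUE)
    g <- cbind(rep(cells[, 1] - 1L, counts[cells]),
               rep(cells[, 2] - 1L, counts[cells]))
    g[sample.int(nrow(g)), , drop = FALSE]
  }
  gc <- expand(case_counts); gk <- expand(ctrl_counts)
  list(table = tab, g1 = c(gk[, 1], gc[, 1]), g2 = c(gk[, 2], gc[, 2]),
       y = rep(0:1, c(n_controls, n_cases)))
}

#' Double-dominant interaction model at a target heritability
#'
#' A pure-interaction model on the logit scale: the linear predictor is
#' `alpha0 + x * [a >= 1][b >= 1]` (all main effects zero, all four
#' interaction cells sharing the effect `x`), with `x` solved by bisection
#' so the model's heritability matches the target.
#'
#' @param target_h2 Target heritability.
#' @param maf Minor-allele frequency at both loci.
#' @param alpha0 Baseline linear predictor (default 0, i.e. baseline
#'   penetrance 0.5 on the logit scale).
#' @param link Link function; the logit link is the one this model is
#'   defined on.
#' @return A [two_locus_model()]; attribute `x` records the solved effect.
#' @export
double_dominant_model <- function(target_h2, maf = 0.3, alpha0 = 0,
                                  link = link_spec("logit")) {
  if (is.character(link)) link <- link_spec(link)
  dd <- outer(0:2 >= 1, 0:2 >= 1) * 1
  pen_of <- function(x) {
    p <- link$g_inverse(alpha0 + x * dd)
    two_locus_model(p, maf, maf)
  }
  if (target_h2 == 0) {
    out <- pen_of(0); attr(out, "x") <- 0; return(out)
  }
  h2_of <- function(x) heritability(pen_of(x))
  hi <- 1
  while (h2_of(hi) < target_h2 && hi < 64) hi <- hi * 2
  if (h2_of(hi) < target_h2) {
    abort(sprintf("target heritability %.4g unachievable for the double-dominant model",
                  target_h2))
  }
  lo <- 0
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (h2_of(mid) < target_h2) lo <- mid else hi <- mid
    if (abs(h2_of(mid) - target_h2) < 1e-8) break
  }
  out <- pen_of(mid)
  attr(out, "x") <- mid
  out
}

#' Default effect sizes for the single/double-main null cohorts
#'
#' Per-allele additive effects on each link scale used by
#' [simulate_null_cohort()] for the `single` and `double:<link>` null
#' models: a baseline intercept `a0` on the link scale and a per-genotype
#' increment `theta` (linear predictor `a0 + theta * a + theta * b`).
#' Chosen so each variant's marginal association is detected essentially
#' always at cohort scale while the identity/odds scales deviate strongly
#' from logit-additivity; see the methods vignette.
#'
#' @param link Link name.
#' @return List with `a0` and `theta`.
#' @export
double_main_defaults <- function(link) {
  switch(link,
    identity = list(a0 = 0.05, theta = 0.10),
    log = list(a0 = log(0.08), theta = log(1.35)),
    log_complement = list(a0 = log(0.92), theta = log(0.90)),
    odds = list(a0 = 0.10, theta = 0.35),
    logit = list(a0 = qlogis(0.10), theta = 0.35),
    abort(paste("unknown link:", link))
  )
}

#' Simulate a null-model case-control cohort
#'
#' Generates a cohort of `n_variants` variants (minor-allele frequencies
#' uniform on `maf_range`) and a binary phenotype under one of the null
#' models used in family-wise error rate studies — all of which are null
#' for interaction:
#'
#' * `"none"` — phenotype independent of every genotype;
#' * `"single"` — one variant with a main effect (logit scale by default);
#' * `"double:<link>"` — two variants with additive main effects on the
#'   named link (`identity`, `log`, `log_complement`, `odds`, `logit`) and
#'   no interaction term;
#' * `"multi:<L>"` — an additive logistic model on `L` variants with
#'   `beta_i ~ N(0.15, 0.01)` (variance 0.01) and intercept -9.0.
#'
#' Sampling targets exact case/control quotas. Associated-variant genotypes
#' are drawn from the exact Bayes conditional `Pr(x | Y)` (enumerating all
#' genotype combinations when `3^L` is small), which is distributionally
#' identical to rejection-sampling individuals until the quotas fill;
#' `method = "rejection"` forces literal chunked rejection sampling (capped
#' at 1e9 draws). Unassociated variants are independent of the phenotype
#' and drawn from Hardy-Weinberg frequencies directly.
#'
#' @param kind Null-model kind (see above).
#' @param n_cases,n_controls Quotas (defaults 4000 + 4000).
#' @param n_variants Total variant count (default 500).
#' @param maf_range Range for the uniform MAF draw (default (0.2, 0.4)).
#' @param beta_mean,beta_var Mean and variance of the multivariate model's
#'   per-allele effects.
#' @param intercept Intercept of the multivariate logistic model.
#' @param effects Optional override for single/double kinds: list with
#'   `a0`, `theta` (see [double_main_defaults()]).
#' @param link_single Link for the `single` kind (default logit).
#' @param method `"auto"` (exact Bayes enumeration when feasible) or
#'   `"rejection"`.
#' @param seed Optional integer; if given, seeds the RNG for a reproducible
#'   cohort.
#' @return List of class `null_cohort`: `genotypes` (n x m integer matrix),
#'   `phenotype` (0/1), `maf`, `kind`, `associated` (indices of associated
#'   variants) and the model parameters used.
#' @export
simulate_null_cohort <- function(kind = "none", n_cases = 4000, n_controls = 4000,
                                 n_variants = 500, maf_range = c(0.2, 0.4),
                                 beta_mean = 0.15, beta_var = 0.01,
                                 intercept = -9.0, effects = NULL,
                                 link_single = "logit",
                                 method = c("auto", "rejection"), seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_cases > 0, n_controls > 0, n_variants >= 2)
  if (any(maf_range <= 0) || any(maf_range >= 0.5) || maf_range[1] > maf_range[2]) {
    abort("maf_range must lie within (0, 0.5)")
  }
  parsed <- parse_null_kind(kind)
  L <- parsed$L
  if (L > n_variants) abort("more associated variants than variants")
  n <- n_cases + n_controls
  maf <- runif(n_variants, maf_range[1], maf_range[2])
  G <- matrix(0L, n, n_variants)
  # unassociated variants: independent of Y, straight HWE draws
  null_idx <- setdiff(seq_len(n_variants), seq_len(L))
  for (j in null_idx) G[, j] <- sample(0:2, n, replace = TRUE,
                                       prob = hwe_genotype_freqs(maf[j]))
  params <- list()
  if (L > 0) {
    if (parsed$type == "multi") {
      beta <- rnorm(L, beta_mean, sqrt(beta_var))
      eta_fun <- function(X) intercept + drop(X %*% beta)
      p_fun <- function(X) plogis(eta_fun(X))
      params <- list(beta = beta, intercept = intercept)
    } else {
      eff <- effects %||%
        double_main_defaults(if (parsed$type == "single") link_single else parsed$link)
      lk <- link_spec(if (parsed$type == "single") link_single else parsed$link)
      p_fun <- function(X) {
        eta <- eff$a0 + rowSums(X) * eff$theta
        p <- lk$g_inverse(eta)
        p
      }
      # validate: no genotype combination may escape [0, 1] on raw scale
      grid <- as.matrix(expand.grid(rep(list(0:2), L)))
      raw <- eff$a0 + rowSums(grid) * eff$theta
      praw <- switch(lk$name,
        identity = raw, log = exp(raw), log_complement = 1 - exp(raw),
        odds = raw / (1 + raw), logit = plogis(raw))
      if (any(praw < 0) || any(praw > 1) ||
          (lk$name == "odds" && any(raw < 0))) {
        abort("effect sizes drive the phenotype probability outside [0, 1]")
      }
      params <- list(a0 = eff$a0, theta = eff$theta,
                     link = lk$name)
    }
    Gl <- sample_assoc_genotypes(L, maf[seq_len(L)], p_fun, n_cases, n_controls,
                                 method)
    G[, seq_len(L)] <- Gl
  }
  y <- rep(c(1L, 0L), c(n_cases, n_controls))
  colnames(G) <- sprintf("v%03d", seq_len(n_variants))
  structure(list(genotypes = G, phenotype = y, maf = maf, kind = kind,
                 associated = seq_len(L), params = params),
            class = "null_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_null_kind <- function(kind) {
  if (kind == "none") return(list(type = "none", L = 0L))
  if (kind == "single") return(list(type = "single", L = 1L))
  if (grepl("^double:", kind)) {
    link <- sub("^double:", "", kind)
    if (!link %in% c("identity", "log", "log_complement", "odds", "logit")) {
      abort(paste("unknown double-main link:", link))
    }
    return(list(type = "double", L = 2L, link = link))
  }
  if (grepl("^multi:", kind)) {
    L <- as.integer(sub("^multi:", "", kind))
    if (is.na(L) || L < 1) abort("multi:<L> needs a positive L")
    return(list(type = "multi", L = L))
  }
  abort(paste("unknown null-cohort kind:", kind))
}

# Associated-variant genotypes to exact case/control quotas. Cases first,
# then controls (matching the phenotype layout of the caller).
sample_assoc_genotypes <- function(L, mafs, p_fun, n_cases, n_controls, method) {
  if (method == "auto" && 3^L <= 2e5) {
    grid <- as.matrix(expand.grid(rep(list(0:2), L)))
    fg <- rep(1, nrow(grid))
    for (j in seq_len(L)) fg <- fg * hwe_genotype_freqs(mafs[j])[grid[, j] + 1]
    p <- p_fun(grid)
    wc <- p * fg; wk <- (1 - p) * fg
    if (sum(wc) <= 0 || sum(wk) <= 0) abort("degenerate null model: empty stratum")
    ic <- sample.int(nrow(grid), n_cases, replace = TRUE, prob = wc)
    ik <- sample.int(nrow(grid), n_controls, replace = TRUE, prob = wk)
    rbind(grid[ic, , drop = FALSE], grid[ik, , drop = FALSE])
  } else {
    cases <- matrix(0L, 0, L); ctrls <- matrix(0L, 0, L)
    draws <- 0
    chunk <- 200000L
    while (nrow(cases) < n_cases || nrow(ctrls) < n_controls) {
      if (draws >= 1e9) abort("rejection sampling exceeded the 1e9-draw cap")
      X <- vapply(seq_len(L), function(j) {
        sample(0:2, chunk, replace = TRUE, prob = hwe_genotype_freqs(mafs[j]))
      }, integer(chunk))
      p <- p_fun(X)
      yy <- rbinom(chunk, 1, p)
      draws <- draws + chunk
      if (nrow(cases) < n_cases) {
        cases <- rbind(cases, X[yy == 1, , drop = FALSE])
      }
      if (nrow(ctrls) < n_controls) {
        ctrls <- rbind(ctrls, X[yy == 0, , drop = FALSE])
      }
    }
    rbind(cases[seq_len(n_cases), , drop = FALSE],
          ctrls[seq_len(n_controls), , drop = FALSE])
  }
}
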