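# shared fixtures: all built in code at test time

random_pair_table <- function(n_min = 0, n_max = 60) {
  as_pair_table(array(sample(n_min:n_max, 18, replace = TRUE), c(3, 3, 2)))
}

# a dense table with every cell populated (avoids degenerate strata)
dense_pair_table <- function(total = 4000, maf = 0.3, case_frac = 0.5) {
  f <- outer(hwe_genotype_freqs(maf), hwe_genotype_freqs(maf))
  n1 <- rmultinom(1, round(total * case_frac), as.vector(f)) + 1L
  n0 <- rmultinom(1, round(total * (1 - case_frac)), as.vector(f)) + 1L
  arr <- array(0L, c(3, 3, 2))
  arr[, , 1] <- matrix(n0, 3, 3); arr[, , 2] <- matrix(n1, 3, 3)
  as_pair_table(arr)
}

# independent term-by-term loglik oracle (plain loops, no vectorization)
loglik_oracle <- function(tab, pen) {
  ll <- 0
  for (a in 1:3) for (b in 1:3) for (y in 1:2) {
    n <- unclass(tab)[a, b, y]
    if (n == 0) next
    p <- if (y == 2) pen[a, b] else 1 - pen[a, b]
    ll <- ll + n * log(p)
  }
  ll
}

# independent per-stratum numerical maximizer for the saturated models
saturated_loglik_oracle <- function(tab, model) {
  u <- unclass(tab)
  strata <- switch(model,
    H1 = list(cbind(rep(1:3, 3), rep(1:3, each = 3))),
    H2 = lapply(1:3, function(a) cbind(a, 1:3)),
    H3 = lapply(1:3, function(b) cbind(1:3, b)),
    HA = lapply(1:9, function(k) cbind((k - 1) %% 3 + 1, (k - 1) %/% 3 + 1))
  )
  ll <- 0
  for (s in strata) {
    n1 <- sum(u[cbind(s, 2)]); n0 <- sum(u[cbind(s, 1)])
    if (n1 + n0 == 0) next
    f <- function(p) n1 * log(p) + n0 * log(1 - p)
    opt <- stats::optimize(f, c(1e-12, 1 - 1e-12), maximum = TRUE)
    ll <- ll + max(opt$objective, f(1e-12), f(1 - 1e-12))
  }
  ll
}

# literal transcription of the static stage-wise pseudocode: R_0 = all
# pairs; at stage j, threshold w_j * alpha / K_j; R_j = pairs of R_{j-1}
# with p_ij below it; significant = R_4
static_pseudocode_oracle <- function(pmat, w, K, alpha) {
  R <- seq_len(nrow(pmat))
  for (j in 1:4) {
    R <- R[pmat[R, j] < w[j] * alpha / K[j]]
  }
  sig <- logical(nrow(pmat))
  sig[R] <- TRUE
  adj <- apply(pmat, 1, function(ps) min(1, max(K * ps / w)))
  list(significant = sig, adjusted = adj)
}

# adaptive transcript: K_j = |R_{j-1}|
adaptive_pseudocode_oracle <- function(pmat, w, alpha) {
  R <- seq_len(nrow(pmat))
  for (j in 1:4) {
    if (!length(R)) break
    R <- R[pmat[R, j] < w[j] * alpha / length(R)]
  }
  sig <- logical(nrow(pmat))
  sig[R] <- TRUE
  sig
}
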