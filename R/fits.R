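#' Binomial log-likelihood of a penetrance matrix on a pair table
#'
#' Each genotype cell contributes `n1 * log(p) + n0 * log(1 - p)` where `p`
#' is the cell penetrance (here the sample-conditional probability of being
#' a case). The convention `0 * log(0) = 0` applies, so empty cells
#' contribute exactly 0; a cell with positive case count and penetrance 0
#' (or controls and penetrance 1) yields `-Inf`.
#'
#' @param table A [pair_table()].
#' @param penetrance 3 x 3 numeric matrix with entries in \[0, 1\].
#' @return The log-likelihood (scalar; possibly `-Inf`).
#' @export
loglik_binomial <- function(table, penetrance) {
  table <- as_pair_table(table)
  penetrance <- as.matrix(penetrance)
  if (!identical(dim(penetrance), c(3L, 3L))) abort("penetrance must be 3 x 3")
  if (anyNA(penetrance) || any(penetrance < 0) || any(penetrance > 1)) {
    abort("penetrance entries must lie in [0, 1]")
  }
  h <- table_halves(table)
  sum(xlogy(h$n1, penetrance)) + sum(xlogy(h$n0, 1 - penetrance))
}

# x * log(y) with the 0 * log(0) = 0 convention
xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))

# n * log(n) with 0 -> 0; used for closed-form saturated logliks
xlogx <- function(n) ifelse(n <= 0, 0, n * log(n))

#' Fit a two-locus penetrance model to a pair table
#'
#' Fits one of the nested penetrance models on a 3 x 3 genotype table:
#'
#' * `H1` — no association, constant penetrance (1 free parameter);
#' * `H2` — main effect of variant 1 only (3 parameters);
#' * `H3` — main effect of variant 2 only (3 parameters);
#' * `H4` — both main effects, no interaction, on a given link scale
#'   (5 parameters);
#' * `HA` — saturated cell-wise model (9 parameters).
#'
#' `H1`–`H3` and `HA` are saturated within their genotype stratification, so
#' their maximum likelihood is attained in closed form and does not depend
#' on any link function. `H4` is fitted by maximizing the aggregated
#' binomial log-likelihood over (alpha, beta1, beta2, gamma1, gamma2) with
#' the penetrance `g_inverse(alpha + beta_a + gamma_b)` box-constrained to
#' `[1e-10, 1 - 1e-10]`; the logit link uses a dedicated
#' iteratively-reweighted least-squares path, other links a quasi-Newton
#' iteration started from the marginal fits. Identifiability constraints fix
#' `beta_0 = gamma_0 = 0` (and all `delta_0b`, `delta_a0` at 0 in the
#' saturated parameterization).
#'
#' Empty genotype strata contribute nothing to any log-likelihood; their
#' fitted penetrance is reported as 0. An `H4` fit on a table with fewer
#' than 5 nondegenerate strata is reported as saturated-equivalent (it can
#' match the saturated likelihood exactly).
#'
#' @param table A [pair_table()].
#' @param model One of `"H1"`, `"H2"`, `"H3"`, `"H4"`, `"HA"`.
#' @param link A [link_spec()] (or link name); required for `"H4"`, ignored
#'   otherwise.
#' @return A `pair_model_fit`: list with `model_id`, `link` (name or `NA`),
#'   `params` (named vector for `H4`, `NULL` for link-free models),
#'   `fitted_penetrance`, `loglik`, `n_free`, `converged` and
#'   `saturated_equivalent` flags.
#' @examples
#' set.seed(1)
#' tab <- pair_table(rbinom(400, 2, 0.3), rbinom(400, 2, 0.3), rbinom(400, 1, 0.5))
#' fit_pair_model(tab, "H4", link = "logit")$loglik
#' @export
fit_pair_model <- function(table, model = c("H1", "H2", "H3", "H4", "HA"),
                           link = NULL) {
  model <- match.arg(model)
  table <- as_pair_table(table)
  if (model == "H4") {
    if (is.null(link)) abort("H4 requires a link function")
    if (is.character(link)) link <- link_spec(link)
    fit_h4(table, link)
  } else {
    fit_saturated(table, model)
  }
}

# closed-form fits for the models that are saturated within a stratification
fit_saturated <- function(table, model) {
  h <- table_halves(table)
  n1 <- h$n1; n0 <- h$n0; n <- n1 + n0
  phat <- switch(model,
    H1 = matrix(sum(n1) / sum(n), 3, 3),
    H2 = matrix(ifelse(rowSums(n) > 0, rowSums(n1) / pmax(rowSums(n), 1), 0),
                3, 3, byrow = FALSE),
    H3 = matrix(ifelse(colSums(n) > 0, colSums(n1) / pmax(colSums(n), 1), 0),
                3, 3, byrow = TRUE),
    HA = ifelse(n > 0, n1 / pmax(n, 1), 0)
  )
  phat[n == 0] <- 0  # empty strata: defined as 0, contribute nothing
  ll <- sum(xlogy(n1, phat)) + sum(xlogy(n0, 1 - phat))
  new_pair_fit(model, link = NULL, params = NULL, phat = phat, loglik = ll,
               n_free = c(H1 = 1L, H2 = 3L, H3 = 3L, HA = 9L)[[model]])
}

h4_design <- local({
  ab <- expand.grid(a = 0:2, b = 0:2)
  D <- cbind(alpha = 1, beta1 = as.numeric(ab$a == 1), beta2 = as.numeric(ab$a == 2),
             gamma1 = as.numeric(ab$b == 1), gamma2 = as.numeric(ab$b == 2))
  function() D
})

fit_h4 <- function(table, link) {
  h <- table_halves(table)
  n1 <- as.vector(h$n1); n0 <- as.vector(h$n0); n <- n1 + n0
  info <- n > 0
  ha <- fit_saturated(table, "HA")
  if (sum(info) < 5) {
    out <- new_pair_fit("H4", link, params = NULL, phat = ha$fitted_penetrance,
                        loglik = ha$loglik, n_free = 5L)
    out$saturated_equivalent <- TRUE
    return(out)
  }
  D <- h4_design()
  nll <- function(theta) {
    p <- link$g_inverse(drop(D %*% theta))
    -(sum(xlogy(n1, p)) + sum(xlogy(n0, 1 - p)))
  }
  gr <- function(theta) {
    eta <- drop(D %*% theta)
    p <- link$g_inverse(eta)
    s <- (ifelse(n1 > 0, n1 / p, 0) - ifelse(n0 > 0, n0 / (1 - p), 0)) * link$mu_eta(eta)
    -drop(crossprod(D, s))
  }
  theta0 <- h4_start(table, link)
  cand <- list()
  if (link$name == "logit") cand$irls <- h4_irls(n1, n0, D, theta0)
  o <- optim(if (!is.null(cand$irls)) cand$irls$theta else theta0, nll, gr,
             method = "BFGS", control = list(maxit = 200, reltol = 1e-10))
  if (o$convergence != 0) {
    o2 <- optim(o$par, nll, gr, method = "BFGS",
                control = list(maxit = 200, reltol = 1e-10))
    if (o2$value <= o$value) o <- o2
  }
  best <- list(theta = o$par, loglik = -o$value, converged = o$convergence == 0)
  if (!is.null(cand$irls) && cand$irls$loglik > best$loglik) {
    best <- cand$irls
  }
  p <- link$g_inverse(drop(D %*% best$theta))
  phat <- matrix(p, 3, 3)
  phat[matrix(!info, 3, 3)] <- 0
  new_pair_fit("H4", link, params = setNames(best$theta, colnames(D)),
               phat = phat, loglik = min(best$loglik, ha$loglik),
               n_free = 5L, converged = isTRUE(best$converged))
}

# deterministic start: marginal fits pushed through the link
h4_start <- function(table, link) {
  h <- table_halves(table)
  n1 <- h$n1; n0 <- h$n0; n <- n1 + n0
  squeeze <- function(p) pmin(pmax(p, 1e-6), 1 - 1e-6)
  p_all <- squeeze(sum(n1) / sum(n))
  p_row <- ifelse(rowSums(n) > 0, rowSums(n1) / pmax(rowSums(n), 1), p_all)
  p_col <- ifelse(colSums(n) > 0, colSums(n1) / pmax(colSums(n), 1), p_all)
  a0 <- link$g(p_all)
  c(a0, link$g(squeeze(p_row[2:3])) - a0, link$g(squeeze(p_col[2:3])) - a0)
}

# hand-written IRLS on the 9 aggregated binomial cells (logit link)
h4_irls <- function(n1, n0, D, theta) {
  n <- n1 + n0
  keep <- n > 0
  Dk <- D[keep, , drop = FALSE]
  y <- n1[keep]; m <- n[keep]
  ll_of <- function(th) {
    p <- plogis(drop(Dk %*% th))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum(y * log(p) + (m - y) * log(1 - p))
  }
  ll <- ll_of(theta)
  for (it in seq_len(100)) {
    eta <- drop(Dk %*% theta)
    p <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
    w <- m * p * (1 - p)
    z <- eta + (y - m * p) / w
    th_new <- tryCatch(
      drop(solve(crossprod(Dk, Dk * w), crossprod(Dk, w * z))),
      error = function(e) NULL
    )
    if (is.null(th_new) || any(!is.finite(th_new))) break
    ll_new <- ll_of(th_new)
    if (ll_new < ll - 1e-8) { # step-halving for rare overshoot
      for (half in 1:20) {
        th_new <- (theta + th_new) / 2
        ll_new <- ll_of(th_new)
        if (ll_new >= ll - 1e-8) break
      }
    }
    done <- abs(ll_new - ll) < 1e-12 * (abs(ll) + 1)
    theta <- th_new; ll <- ll_new
    if (done || max(abs(theta)) > 40) break
  }
  list(theta = theta, loglik = ll, converged = TRUE)
}

new_pair_fit <- function(model, link, params, phat, loglik, n_free,
                         converged = TRUE) {
  structure(
    list(model_id = model,
         link = if (is.null(link)) NA_character_ else link$name,
         params = params, fitted_penetrance = phat, loglik = loglik,
         n_free = n_free, converged = converged, saturated_equivalent = FALSE),
    class = "pair_model_fit"
  )
}

#' @export
print.pair_model_fit <- function(x, ...) {
  cat("<pair_model_fit> ", x$model_id,
      if (!is.na(x$link)) paste0(" [", x$link, "]"),
      "  loglik = ", format(x$loglik), "  df = ", x$n_free,
      if (!x$converged) "  (not converged)", "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pair_model_fit <- function(x, ...) {
  if (is.null(x$params)) {
    tibble::tibble(term = character(), estimate = numeric())
  } else {
    tibble::tibble(term = names(x$params), estimate = unname(x$params))
  }
}

#' @exportS3Method generics::glance
glance.pair_model_fit <- function(x, ...) {
  tibble::tibble(model = x$model_id, link = x$link, loglik = x$loglik,
                 n_free = x$n_free, converged = x$converged,
                 saturated_equivalent = x$saturated_equivalent)
}

#' Likelihood-ratio test between two nested pair-model fits
#'
#' The statistic is `max(0, 2 * (loglik_alt - loglik_null))`, compared
#' against a chi-square distribution whose degrees of freedom equal the
#' difference in free-parameter counts (e.g. 8 for H1 vs the saturated
#' model, 4 for H4 vs saturated).
#'
#' @param null_fit,alt_fit `pair_model_fit` objects on the same table, with
#'   the null model nested in the alternative.
#' @return An `lrt_result`: list with `statistic`, `df`, `pvalue`.
#' @export
lrt <- function(null_fit, alt_fit) {
  stopifnot(inherits(null_fit, "pair_model_fit"), inherits(alt_fit, "pair_model_fit"))
  nested <- list(H1 = c("H2", "H3", "H4", "HA"), H2 = c("H4", "HA"),
                 H3 = c("H4", "HA"), H4 = "HA", HA = character())
  if (!alt_fit$model_id %in% nested[[null_fit$model_id]]) {
    abort(paste0(null_fit$model_id, " is not nested in ", alt_fit$model_id))
  }
  stat <- max(0, 2 * (alt_fit$loglik - null_fit$loglik))
  df <- alt_fit$n_free - null_fit$n_free
  structure(
    list(statistic = stat, df = df,
         pvalue = pchisq(stat, df, lower.tail = FALSE)),
    class = "lrt_result"
  )
}

#' @export
print.lrt_result <- function(x, ...) {
  cat("<lrt_result> chi2 =", format(x$statistic), " df =", x$df,
      " p =", format(x$pvalue), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.lrt_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$pvalue)
}

#' Scale-invariant combination of per-link interaction p-values
#'
#' Combines the H4-vs-saturated p-values obtained on a set of link
#' functions by the intersection-union rule: the combined p-value is the
#' maximum over links, so significance requires significance on every
#' scale.
#'
#' @param pvalues_per_link Named numeric vector (or list) of p-values, one
#'   per link; all in \[0, 1\].
#' @return The combined p-value `q = max(p)`.
#' @examples
#' scale_invariant_p(c(logit = 0.01, log = 0.04, identity = 0.2))
#' @export
scale_invariant_p <- function(pvalues_per_link) {
  p <- unlist(pvalues_per_link, use.names = FALSE)
  if (!length(p)) abort("at least one per-link p-value is required")
  if (anyNA(p) || any(p < 0) || any(p > 1)) abort("p-values must lie in [0, 1]")
  max(p)
}
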