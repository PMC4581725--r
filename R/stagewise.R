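#' Stage weights for the stage-wise procedure
#'
#' The four stages share the significance level through positive weights
#' summing to 1; the stage-s threshold is `w_s * alpha / K_s`. The default
#' `c(0.1, 0.3, 0.3, 0.3)` is the combination that performed best in a grid
#' search over the 0.1-step simplex (see [weight_grid_search()]).
#'
#' @param w Numeric vector of four positive weights summing to 1.
#' @return The validated weight vector.
#' @export
stage_weights <- function(w = c(0.1, 0.3, 0.3, 0.3)) {
  w <- as.numeric(w)
  if (length(w) != 4 || anyNA(w)) abort("weights must be four numbers")
  if (any(w <= 0)) abort("all stage weights must be positive")
  if (abs(sum(w) - 1) > 1e-12) abort("stage weights must sum to 1")
  w
}

#' Static multiple-testing corrections from variant counts
#'
#' With `N` genotyped variants and `M` (assumed) marginally associated
#' variants, the numbers of hypotheses belonging to the four stages are
#' `N(N-1)/2` (all pairs), `N * M` (twice, for the two single-main stages)
#' and `M(M-1)/2` (double-main pairs).
#'
#' @param N Total variant count (>= 2).
#' @param M Assumed number of marginally associated variants (>= 2, so that
#'   every stage has a positive hypothesis count).
#' @return A `correction_scheme` list with `mode = "static"` and `K`, the
#'   four per-stage counts.
#' @examples
#' static_corrections(500, 10)$K
#' @export
static_corrections <- function(N, M) {
  if (N < 2) abort("N must be at least 2")
  if (M < 2) abort("M must be at least 2 so that K4 = M(M-1)/2 is positive")
  structure(list(mode = "static",
                 K = c(N * (N - 1) / 2, N * M, N * M, M * (M - 1) / 2)),
            class = "correction_scheme")
}

#' @rdname static_corrections
#' @param K Four positive finite per-stage hypothesis counts, given
#'   directly.
#' @export
correction_scheme <- function(K) {
  K <- as.numeric(K)
  if (length(K) != 4 || anyNA(K) || any(!is.finite(K)) || any(K <= 0)) {
    abort("K must be four positive finite per-stage counts")
  }
  structure(list(mode = "static", K = K), class = "correction_scheme")
}

#' Per-stage p-values for one variant pair
#'
#' Stages 1-3 test the link-free null models H1 (no association), H2 and H3
#' (single main effect) against the saturated model (df 8, 6, 6). Stage 4
#' is the scale-invariance test: H4 (double main, no interaction) is tested
#' against the saturated model on each configured link (df 4), and the
#' per-link p-values are combined by their maximum.
#'
#' @param table A [pair_table()].
#' @param links Links for stage 4: a list of [link_spec()], link names, or
#'   the default [all_links()].
#' @return One-row tibble with `p1`, `p2`, `p3`, one `p4_<link>` column per
#'   link, and the combined `q` (= `p4`).
#' @export
stage_pvalues <- function(table, links = all_links()) {
  links <- as_link_list(links)
  table <- as_pair_table(table)
  ha <- fit_pair_model(table, "HA")
  p123 <- vapply(c("H1", "H2", "H3"), function(m) {
    lrt(fit_pair_model(table, m), ha)$pvalue
  }, numeric(1))
  p4 <- vapply(links, function(lk) lrt(fit_h4(table, lk), ha)$pvalue, numeric(1))
  out <- tibble::tibble(p1 = p123[[1]], p2 = p123[[2]], p3 = p123[[3]])
  for (nm in names(p4)) out[[paste0("p4_", nm)]] <- p4[[nm]]
  out$q <- scale_invariant_p(p4)
  out
}

# ---- stage-wise runner ------------------------------------------------------

# provider(i, s) -> p-value of stage s for pair i (memoised by the caller if
# expensive); mode "static" uses fixed K, "adaptive" uses |R_{s-1}|.
run_stagewise <- function(provider, n_pairs, weights, alpha, mode,
                          K = NULL, have_all = FALSE) {
  weights <- stage_weights(weights)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (mode == "static") {
    if (is.null(K)) abort("static mode requires a correction scheme")
    if (any(K <= 0) || any(!is.finite(K))) abort("K entries must be positive and finite")
  }
  pmat <- matrix(NA_real_, n_pairs, 4)
  alive <- rep(TRUE, n_pairs)
  stage_info <- vector("list", 4)
  stage_of_death <- rep(NA_integer_, n_pairs)
  r_prev <- n_pairs
  for (s in 1:4) {
    Ks <- if (mode == "static") K[s] else r_prev
    if (Ks == 0) { # adaptive with no survivors: halt
      stage_info[[s]] <- list(stage = s, K = 0, threshold = NA_real_,
                              n_alive = 0L, n_rejected = 0L)
      next
    }
    thr <- weights[s] * alpha / Ks
    idx <- which(alive)
    if (length(idx)) pmat[idx, s] <- vapply(idx, provider, numeric(1), s = s)
    rej <- alive & !is.na(pmat[, s]) & pmat[, s] < thr
    stage_of_death[alive & !rej] <- s
    stage_info[[s]] <- list(stage = s, K = Ks, threshold = thr,
                            n_alive = length(idx), n_rejected = sum(rej))
    alive <- rej
    r_prev <- sum(rej)
  }
  # adjusted p-values: max over stages with a computed p-value, using the
  # correction actually applied at that stage; eliminated pairs report 1
  # unless all four stage p-values are available.
  Ks_used <- vapply(stage_info, function(z) if (is.na(z$threshold)) NA_real_ else z$K,
                    numeric(1))
  adj <- vapply(seq_len(n_pairs), function(i) {
    ps <- pmat[i, ]
    if (have_all && anyNA(ps)) {
      # fill from the provider so the max runs over all four stages
      for (s in which(is.na(ps))) ps[s] <- provider(i, s)
      pmat[i, ] <<- ps
    }
    if (anyNA(ps) || anyNA(Ks_used)) {
      if (is.na(stage_of_death[i])) {
        s_ok <- which(!is.na(ps) & !is.na(Ks_used))
      } else {
        return(1)
      }
    } else {
      s_ok <- 1:4
    }
    if (!length(s_ok)) return(1)
    min(1, max(Ks_used[s_ok] * ps[s_ok] / weights[s_ok]))
  }, numeric(1))
  list(p = pmat, significant = alive, adjusted_p = adj,
       stage_reached = ifelse(is.na(stage_of_death), 4L, stage_of_death),
       stages = dplyr::bind_rows(lapply(stage_info, tibble::as_tibble)))
}

#' Run the static stage-wise procedure over a set of pairs
#'
#' Applies the four-stage closed-testing procedure with a-priori hypothesis
#' counts `K_s`: a pair survives stage s iff its stage-s p-value is strictly
#' below `w_s * alpha / K_s`, and is declared significant iff it survives
#' all four stages. Adjusted p-values are `min(1, max_s K_s p_is / w_s)`
#' over the stages reached; a pair eliminated before stage 4 reports 1
#' unless all four of its stage p-values are available (precomputed input),
#' in which case the maximum over all four is reported.
#'
#' @param pairs Either a data frame with columns `p1`..`p4` of per-stage
#'   p-values (`p4` being the combined scale-invariance p-value), or a list
#'   of [pair_table()] objects (stage p-values are then computed lazily).
#' @param weights Stage weights, see [stage_weights()].
#' @param scheme A [static_corrections()] / [correction_scheme()] object.
#' @param alpha Overall significance level in (0, 1).
#' @param links Links for stage 4 when `pairs` is a list of tables.
#' @return A `stage_result`; see [tidy.stage_result()].
#' @export
run_static <- function(pairs, weights = stage_weights(), scheme, alpha = 0.05,
                       links = all_links()) {
  pp <- as_stage_provider(pairs, links)
  res <- run_stagewise(pp$provider, pp$n, weights, alpha, "static",
                       K = scheme$K, have_all = pp$have_all)
  new_stage_result(res, pp, method = "static", alpha = alpha, weights = weights)
}

#' Run the adaptive stage-wise procedure over a set of pairs
#'
#' Identical to [run_static()] except that the stage-s hypothesis count is
#' the number of rejections in the previous stage, `|R_{s-1}|`, with `R_0`
#' the full input set. If a stage rejects nothing the procedure halts with
#' an empty significant set. The adjusted p-values
#' `min(1, max_s |R_{s-1}| p_is / w_s)` are conservative.
#'
#' @inheritParams run_static
#' @return A `stage_result`.
#' @export
run_adaptive <- function(pairs, weights = stage_weights(), alpha = 0.05,
                         links = all_links()) {
  pp <- as_stage_provider(pairs, links)
  res <- run_stagewise(pp$provider, pp$n, weights, alpha, "adaptive",
                       have_all = pp$have_all)
  new_stage_result(res, pp, method = "adaptive", alpha = alpha, weights = weights)
}

as_stage_provider <- function(pairs, links) {
  if (is.data.frame(pairs)) {
    need <- c("p1", "p2", "p3", "p4")
    if (!all(need %in% names(pairs))) {
      abort("precomputed pairs need columns p1, p2, p3, p4")
    }
    pm <- as.matrix(pairs[, need])
    ids <- if ("pair" %in% names(pairs)) as.character(pairs$pair) else
      as.character(seq_len(nrow(pairs)))
    list(provider = function(i, s) pm[i, s], n = nrow(pairs),
         have_all = TRUE, ids = ids, extra = NULL)
  } else if (is.list(pairs)) {
    links <- as_link_list(links)
    tabs <- lapply(pairs, as_pair_table)
    cache <- vector("list", length(tabs))
    provider <- function(i, s) {
      if (is.null(cache[[i]])) cache[[i]] <<- stage_pvalues(tabs[[i]], links)
      unlist(cache[[i]][1, c("p1", "p2", "p3", "q")])[[s]]
    }
    ids <- names(tabs)
    if (is.null(ids)) ids <- as.character(seq_along(tabs))
    list(provider = provider, n = length(tabs), have_all = FALSE, ids = ids,
         extra = function() cache)
  } else {
    abort("pairs must be a data frame of p-values or a list of pair tables")
  }
}

new_stage_result <- function(res, pp, method, alpha, weights) {
  results <- tibble::tibble(
    pair = pp$ids,
    p1 = res$p[, 1], p2 = res$p[, 2], p3 = res$p[, 3], p4 = res$p[, 4],
    stage_reached = res$stage_reached,
    adjusted_p = res$adjusted_p,
    significant = res$significant
  )
  structure(list(results = results, stages = res$stages, method = method,
                 alpha = alpha, weights = weights),
            class = "stage_result")
}

#' @export
print.stage_result <- function(x, ...) {
  cat("<stage_result> ", x$method, " procedure, alpha = ", x$alpha,
      ", weights = ", paste(x$weights, collapse = "/"), "\n", sep = "")
  print(x$stages)
  cat(sum(x$results$significant), "of", nrow(x$results),
      "pairs significant\n")
  invisible(x)
}

#' Tidy a stage-wise result
#'
#' @param x A `stage_result` from [run_static()], [run_adaptive()] or
#'   [epistasis_scan()].
#' @param ... Unused.
#' @return Per-pair tibble: stage p-values, stage reached, adjusted p-value
#'   and significance flag.
#' @exportS3Method generics::tidy
tidy.stage_result <- function(x, ...) x$results

#' @exportS3Method generics::glance
glance.stage_result <- function(x, ...) {
  tibble::tibble(method = x$method, alpha = x$alpha,
                 n_pairs = nrow(x$results),
                 n_significant = sum(x$results$significant),
                 n_stage4_tested = x$stages$n_alive[4])
}

#' @exportS3Method ggplot2::autoplot
autoplot.stage_result <- function(object, ...) {
  df <- object$stages
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$stage), y = .data$n_alive)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_rejected), vjust = -0.4) +
    ggplot2::labs(x = "stage", y = "pairs tested",
                  title = paste(object$method, "stage-wise procedure"),
                  subtitle = "bar = pairs entering the stage; label = rejections")
}
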