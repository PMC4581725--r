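# Vectorized all-pairs machinery: pair-cell counts for every variant pair
# are obtained from crossproducts of genotype indicator matrices, giving the
# closed-form saturated loglikelihoods (and hence all stage-1 statistics)
# without per-pair loops.

# Per-phenotype-group cell-count blocks. For groups y = 0, 1 returns, for
# a, b in {1, 2}, the m x m matrices N_ab[i, j] = #{g_i = a, g_j = b} among
# jointly observed individuals, plus per-variant marginal counts. Handles
# missing genotypes via an observed-indicator block.
cohort_counts <- function(G, y) {
  stopifnot(is.matrix(G), nrow(G) == length(y))
  if (!all(y %in% 0:1)) abort("phenotype must be coded 0/1")
  m <- ncol(G)
  has_na <- anyNA(G)
  grp <- function(rows) {
    Gg <- G[rows, , drop = FALSE]
    E1 <- matrix(as.double(!is.na(Gg) & Gg == 1L), nrow(Gg), m)
    E2 <- matrix(as.double(!is.na(Gg) & Gg == 2L), nrow(Gg), m)
    if (has_na) {
      O <- matrix(as.double(!is.na(Gg)), nrow(Gg), m)
      CC <- crossprod(cbind(E1, E2, O))
      i1 <- seq_len(m); i2 <- m + i1; i3 <- 2 * m + i1
      list(N11 = CC[i1, i1], N12 = CC[i1, i2], N22 = CC[i2, i2],
           N1O = CC[i1, i3], N2O = CC[i2, i3], NOO = CC[i3, i3])
    } else {
      CC <- crossprod(cbind(E1, E2))
      i1 <- seq_len(m); i2 <- m + i1
      c1 <- colSums(E1); c2 <- colSums(E2)
      n <- nrow(Gg)
      list(N11 = CC[i1, i1], N12 = CC[i1, i2], N22 = CC[i2, i2],
           c1 = c1, c2 = c2, n = n)
    }
  }
  out <- list(g0 = grp(y == 0), g1 = grp(y == 1), m = m, has_na = has_na)
  out
}

# All nine cell-count matrices for one group's blocks
group_cells <- function(B, m, has_na) {
  N11 <- B$N11; N12 <- B$N12; N21 <- t(B$N12); N22 <- B$N22
  if (has_na) {
    r1 <- B$N1O; r2 <- B$N2O          # m x m: #{g_i = a, g_j observed}
    c1 <- t(B$N1O); c2 <- t(B$N2O)
    tot <- B$NOO
  } else {
    r1 <- matrix(B$c1, m, m); r2 <- matrix(B$c2, m, m)
    c1 <- matrix(B$c1, m, m, byrow = TRUE); c2 <- matrix(B$c2, m, m, byrow = TRUE)
    tot <- matrix(B$n, m, m)
  }
  N10 <- r1 - N11 - N12; N20 <- r2 - N21 - N22
  N01 <- c1 - N11 - N21; N02 <- c2 - N12 - N22
  N00 <- tot - N11 - N12 - N21 - N22 - N10 - N20 - N01 - N02
  list(N00 = N00, N01 = N01, N02 = N02, N10 = N10, N11 = N11, N12 = N12,
       N20 = N20, N21 = N21, N22 = N22, tot = tot)
}

# xlogx elementwise on matrices, guarding small negative rounding noise
mxlogx <- function(n) {
  n <- pmax(n, 0)
  out <- n * log(pmax(n, 1))
  out
}

# Stage-1 LRT p-values (H1 vs saturated, df 8) for all pairs, as an m x m
# matrix; also returns the per-pair saturated loglik and case totals.
stage1_matrix <- function(cc) {
  c0 <- group_cells(cc$g0, cc$m, cc$has_na)
  c1 <- group_cells(cc$g1, cc$m, cc$has_na)
  llHA <- 0
  for (cell in c("N00", "N01", "N02", "N10", "N11", "N12", "N20", "N21", "N22")) {
    a <- c1[[cell]]; b <- c0[[cell]]
    llHA <- llHA + mxlogx(a) + mxlogx(b) - mxlogx(a + b)
  }
  Tcase <- c1$tot; Tctrl <- c0$tot
  llH1 <- mxlogx(Tcase) + mxlogx(Tctrl) - mxlogx(Tcase + Tctrl)
  stat <- pmax(2 * (llHA - llH1), 0)
  list(stat = stat, p = pchisq(stat, 8, lower.tail = FALSE), llHA = llHA)
}

# Pair table for variants (i, j) reconstructed from the count blocks
extract_pair_table <- function(cc, i, j) {
  c0 <- group_cells_ij(cc$g0, cc$m, cc$has_na, i, j)
  c1 <- group_cells_ij(cc$g1, cc$m, cc$has_na, i, j)
  arr <- array(0L, c(3, 3, 2))
  arr[, , 1] <- round(c0)
  arr[, , 2] <- round(c1)
  as_pair_table(arr)
}

# scalar version of group_cells for a single (i, j)
group_cells_ij <- function(B, m, has_na, i, j) {
  n11 <- B$N11[i, j]; n12 <- B$N12[i, j]; n21 <- B$N12[j, i]; n22 <- B$N22[i, j]
  if (has_na) {
    r1 <- B$N1O[i, j]; r2 <- B$N2O[i, j]
    cc1 <- B$N1O[j, i]; cc2 <- B$N2O[j, i]
    tot <- B$NOO[i, j]
  } else {
    r1 <- B$c1[i]; r2 <- B$c2[i]; cc1 <- B$c1[j]; cc2 <- B$c2[j]; tot <- B$n
  }
  n10 <- r1 - n11 - n12; n20 <- r2 - n21 - n22
  n01 <- cc1 - n11 - n21; n02 <- cc2 - n12 - n22
  n00 <- tot - n11 - n12 - n21 - n22 - n10 - n20 - n01 - n02
  matrix(c(n00, n01, n02, n10, n11, n12, n20, n21, n22), 3, 3, byrow = TRUE)
}

#' Stage-wise interaction scan over a genotype matrix
#'
#' Runs the full stage-wise closed-testing procedure over variant pairs of
#' a case-control cohort. Stage 1 (no-association vs saturated, df 8) is
#' computed for every pair at once from genotype-indicator crossproducts;
#' later stages are evaluated lazily only for the pairs still alive, with
#' the scale-invariance test (H4 vs saturated on each link, combined by
#' their maximum) as stage 4.
#'
#' @param genotypes Integer matrix, individuals x variants, of 0/1/2
#'   minor-allele counts (NA = missing; individuals missing either variant
#'   of a pair are dropped pairwise). Column names are used as variant IDs.
#' @param phenotype Binary vector, 0 = control, 1 = case.
#' @param method `"adaptive"` (default) or `"static"`.
#' @param weights Stage weights, see [stage_weights()].
#' @param alpha Overall significance level.
#' @param links Stage-4 link set (default all five).
#' @param scheme For the static method: a [static_corrections()] object; if
#'   `NULL`, derived from `N = ncol(genotypes)` and `M`.
#' @param M Assumed marginally associated variant count used when `scheme`
#'   is `NULL` (static method only).
#' @param pairs Optional two-column data frame (`variant1`, `variant2`) of
#'   variant IDs restricting the scan; default all pairs.
#' @return A `stage_result` whose `results` tibble has one row per tested
#'   pair (columns `variant1`, `variant2`, stage p-values, per-link stage-4
#'   p-values for pairs that reached stage 4, combined `q`, stage reached,
#'   adjusted p-value, significance flag).
#' @export
epistasis_scan <- function(genotypes, phenotype,
                           method = c("adaptive", "static"),
                           weights = stage_weights(), alpha = 0.05,
                           links = all_links(), scheme = NULL, M = NULL,
                           pairs = NULL) {
  method <- match.arg(method)
  links <- as_link_list(links)
  genotypes <- as.matrix(genotypes)
  if (is.null(colnames(genotypes))) {
    colnames(genotypes) <- paste0("v", seq_len(ncol(genotypes)))
  }
  if (method == "static" && is.null(scheme)) {
    if (is.null(M)) abort("static method needs `scheme` or `M`")
    scheme <- static_corrections(ncol(genotypes), M)
  }
  cc <- cohort_counts(genotypes, phenotype)
  s1 <- stage1_matrix(cc)
  ids <- colnames(genotypes)
  if (is.null(pairs)) {
    idx <- which(upper.tri(s1$p), arr.ind = TRUE)
  } else {
    i1 <- match(pairs[[1]], ids); i2 <- match(pairs[[2]], ids)
    if (anyNA(i1) || anyNA(i2)) abort("pair list contains unknown variant IDs")
    idx <- cbind(pmin(i1, i2), pmax(i1, i2))
  }
  n_pairs <- nrow(idx)
  p1 <- s1$p[idx]
  link_p <- matrix(NA_real_, n_pairs, length(links),
                   dimnames = list(NULL, names(links)))
  tab_cache <- vector("list", n_pairs)
  get_tab <- function(k) {
    if (is.null(tab_cache[[k]])) {
      tab_cache[[k]] <<- extract_pair_table(cc, idx[k, 1], idx[k, 2])
    }
    tab_cache[[k]]
  }
  provider <- function(k, s) {
    if (s == 1) return(p1[k])
    tab <- get_tab(k)
    ha <- fit_pair_model(tab, "HA")
    if (s == 2) return(lrt(fit_pair_model(tab, "H2"), ha)$pvalue)
    if (s == 3) return(lrt(fit_pair_model(tab, "H3"), ha)$pvalue)
    pl <- vapply(links, function(lk) lrt(fit_h4(tab, lk), ha)$pvalue, numeric(1))
    link_p[k, ] <<- pl
    scale_invariant_p(pl)
  }
  res <- run_stagewise(provider, n_pairs, weights, alpha, method,
                       K = scheme$K, have_all = FALSE)
  results <- tibble::tibble(
    variant1 = ids[idx[, 1]], variant2 = ids[idx[, 2]],
    p_stage1 = res$p[, 1], p_stage2 = res$p[, 2], p_stage3 = res$p[, 3]
  )
  for (nm in names(links)) results[[paste0("p4_", nm)]] <- link_p[, nm]
  results$q_combined <- res$p[, 4]
  results$stage_reached <- res$stage_reached
  results$adjusted_p <- res$adjusted_p
  results$significant <- res$significant
  structure(list(results = results, stages = res$stages, method = method,
                 alpha = alpha, weights = stage_weights(weights)),
            class = "stage_result")
}

#' Write a stage-wise result table as TSV
#'
#' @param x A `stage_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  df <- tidy(x)
  df$significant <- as.integer(df$significant)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
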