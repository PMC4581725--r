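#' Genotype-by-phenotype count table for one variant pair
#'
#' The 3 x 3 x 2 table of counts `n[a, b, y]` — minor-allele counts
#' `a, b` in 0..2 at the two variants, phenotype `y` in 0 (control) /
#' 1 (case) — is the sufficient statistic for every per-pair test in the
#' package.
#'
#' @param g1,g2 Integer vectors of 0/1/2 minor-allele counts (NA allowed;
#'   individuals missing either genotype are dropped pairwise).
#' @param y Binary phenotype vector (0 = control, 1 = case).
#' @return A `pair_table`: a 3 x 3 x 2 integer array with dimnames
#'   `a`, `b`, `y`.
#' @examples
#' set.seed(1)
#' tab <- pair_table(rbinom(100, 2, 0.3), rbinom(100, 2, 0.3), rbinom(100, 1, 0.5))
#' margin.table(tab, 3)
#' @export
pair_table <- function(g1, g2, y) {
  stopifnot(length(g1) == length(g2), length(g1) == length(y))
  keep <- !is.na(g1) & !is.na(g2) & !is.na(y)
  g1 <- g1[keep]; g2 <- g2[keep]; y <- y[keep]
  if (!all(g1 %in% 0:2) || !all(g2 %in% 0:2)) {
    abort("genotypes must be minor-allele counts in {0, 1, 2}")
  }
  if (!all(y %in% 0:1)) abort("phenotype must be coded 0 (control) / 1 (case)")
  counts <- table(factor(g1, 0:2), factor(g2, 0:2), factor(y, 0:1))
  as_pair_table(array(as.integer(counts), dim = c(3, 3, 2)))
}

#' Coerce a 3 x 3 x 2 count array to a pair table
#'
#' @param x A 3 x 3 x 2 array of nonnegative counts; `x[, , 1]` holds
#'   control counts, `x[, , 2]` case counts.
#' @return A validated `pair_table`.
#' @export
as_pair_table <- function(x) {
  if (inherits(x, "pair_table")) return(x)
  x <- as.array(x)
  if (!identical(dim(x), c(3L, 3L, 2L))) abort("expected a 3 x 3 x 2 array")
  if (any(x < 0) || any(x != round(x)) || anyNA(x)) {
    abort("pair table entries must be nonnegative integers")
  }
  if (sum(x) == 0) abort("pair table has zero total count")
  storage.mode(x) <- "integer"
  dimnames(x) <- list(a = 0:2, b = 0:2, y = 0:1)
  class(x) <- c("pair_table", "array")
  x
}

#' @export
print.pair_table <- function(x, ...) {
  cat("<pair_table> n =", sum(x), " (", sum(x[, , 2]), "cases /",
      sum(x[, , 1]), "controls )\n")
  print(unclass(x)[, , 2] + unclass(x)[, , 1])
  invisible(x)
}

#' @describeIn pair_table Tidy a pair table into one row per cell.
#' @param x A `pair_table`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.pair_table <- function(x, ...) {
  tibble::tibble(
    a = rep(0:2, 6), b = rep(rep(0:2, each = 3), 2),
    y = rep(0:1, each = 9), n = as.integer(x)
  )
}

# counts split into case/control 3x3 matrices
table_halves <- function(tab) {
  u <- unclass(tab)
  list(n0 = u[, , 1], n1 = u[, , 2])
}
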