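#' Quality-control filter for variants
#'
#' Removes variants with minor-allele frequency below `min_maf`, variants
#' deviating from Hardy-Weinberg equilibrium (1-df goodness-of-fit
#' chi-square on the full-sample genotype counts) at `p < hwe_p`, and
#' (optionally) X-chromosome variants. Criteria are evaluated on the input
#' set, so the per-criterion counts in the report may overlap.
#'
#' @param g A [genotype_matrix()].
#' @param min_maf MAF threshold (default 0.05).
#' @param hwe_p Hardy-Weinberg p-value threshold (default 1e-6).
#' @param drop_x Drop chromosome X (coded `"X"` or `"23"`) variants.
#' @return List with `genotypes` (the filtered [genotype_matrix()]) and
#'   `report` (tibble of per-criterion removal counts).
#' @export
qc_filter <- function(g, min_maf = 0.05, hwe_p = 1e-6, drop_x = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  maf <- variant_maf(g)
  maf <- pmin(maf, 1 - maf)
  fail_maf <- !is.na(maf) & maf < min_maf
  hp <- apply(g$genotypes, 2, hwe_test_p)
  fail_hwe <- !is.na(hp) & hp < hwe_p
  fail_x <- if (drop_x) !is.na(g$variants$chrom) &
    toupper(g$variants$chrom) %in% c("X", "23") else rep(FALSE, ncol(g$genotypes))
  drop <- fail_maf | fail_hwe | fail_x
  keep <- which(!drop)
  out <- genotype_matrix(g$genotypes[, keep, drop = FALSE],
                         g$variants[keep, ], g$individuals)
  report <- tibble::tibble(
    criterion = c("maf", "hwe", "chrX", "total_removed", "retained"),
    count = c(sum(fail_maf), sum(fail_hwe), sum(fail_x), sum(drop), sum(!drop))
  )
  list(genotypes = out, report = report)
}

#' Hardy-Weinberg goodness-of-fit p-value for one variant
#'
#' 1-df chi-square comparing observed genotype counts to the counts
#' expected from the sample allele frequency.
#'
#' @param geno 0/1/2 genotype vector (NA allowed).
#' @return The p-value (1 for monomorphic or empty variants).
#' @export
hwe_test_p <- function(geno) {
  obs <- tabulate(geno[!is.na(geno)] + 1L, 3)
  n <- sum(obs)
  if (n == 0) return(1)
  q <- (obs[2] + 2 * obs[3]) / (2 * n)
  if (q == 0 || q == 1) return(1)
  expd <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  stat <- sum((obs - expd)^2 / expd)
  pchisq(stat, 1, lower.tail = FALSE)
}

#' Build the variant-pair list to test
#'
#' Applies the pair-selection strategy and the pair-level filters: minimum
#' MAF product (likelihood-ratio approximations are unstable for rare
#' pairs) and minimum inter-variant distance on the same chromosome (to
#' avoid pairs in LD); pairs on different chromosomes — or with unknown
#' positions — always pass the distance rule.
#'
#' @param g A [genotype_matrix()].
#' @param strategy `"all"` (every unordered pair), `"anchored"` (each
#'   anchor variant against everything) or `"pairfile"` (explicit list).
#' @param anchors Anchor variant IDs (anchored strategy).
#' @param pair_list Tibble `variant1`/`variant2` or a pair-file path
#'   (pairfile strategy).
#' @param min_maf_product MAF-product threshold (default 0.04).
#' @param min_distance_bp Same-chromosome distance threshold (default 1e6).
#' @return Tibble `variant1`, `variant2`; attribute `report` holds filter
#'   counts and any unknown IDs (reported, not fatal).
#' @export
build_pairs <- function(g, strategy = c("all", "anchored", "pairfile"),
                        anchors = NULL, pair_list = NULL,
                        min_maf_product = 0.04, min_distance_bp = 1e6) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(g, "genotype_matrix"))
  ids <- g$variants$id
  unknown <- character()
  pairs <- switch(strategy,
    all = {
      cmb <- combn(ids, 2)
      tibble::tibble(variant1 = cmb[1, ], variant2 = cmb[2, ])
    },
    anchored = {
      if (is.null(anchors)) abort("anchored strategy requires `anchors`")
      unknown <- setdiff(anchors, ids)
      anchors <- intersect(anchors, ids)
      df <- tidyr::expand_grid(variant1 = anchors, variant2 = ids)
      df <- df[df$variant1 != df$variant2, ]
      # de-duplicate unordered pairs
      key <- paste(pmin(df$variant1, df$variant2), pmax(df$variant1, df$variant2))
      df[!duplicated(key), ]
    },
    pairfile = {
      if (is.null(pair_list)) abort("pairfile strategy requires `pair_list`")
      df <- if (is.character(pair_list)) read_pair_file(pair_list) else
        tibble::as_tibble(pair_list)
      unknown <- setdiff(c(df$variant1, df$variant2), ids)
      df[df$variant1 %in% ids & df$variant2 %in% ids & df$variant1 != df$variant2, ]
    }
  )
  n_input <- nrow(pairs)
  maf <- pmin(variant_maf(g), 1 - variant_maf(g))
  names(maf) <- ids
  mp <- maf[pairs$variant1] * maf[pairs$variant2]
  pass_maf <- mp >= min_maf_product
  chrom <- setNames(g$variants$chrom, ids)
  pos <- setNames(g$variants$pos, ids)
  same_chr <- !is.na(chrom[pairs$variant1]) & !is.na(chrom[pairs$variant2]) &
    chrom[pairs$variant1] == chrom[pairs$variant2]
  dist <- abs(pos[pairs$variant1] - pos[pairs$variant2])
  pass_dist <- !(same_chr & !is.na(dist) & dist < min_distance_bp)
  keep <- pass_maf & pass_dist
  out <- pairs[keep, ]
  attr(out, "report") <- tibble::tibble(
    n_input = n_input,
    removed_maf_product = sum(!pass_maf),
    removed_distance = sum(pass_maf & !pass_dist),
    retained = sum(keep),
    unknown_ids = list(unknown)
  )
  out
}
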