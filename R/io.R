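#' Genotype matrix container
#'
#' Couples an individuals x variants matrix of 0/1/2 minor-allele counts
#' (NA = missing, never silently 0) with per-variant metadata (ID,
#' chromosome, base-pair position, allele coding) and individual IDs.
#'
#' @param genotypes Integer matrix, individuals x variants.
#' @param variants Tibble with at least `id`; optional `chrom`, `pos`
#'   (1-based), `a1`, `a2`, `flipped`.
#' @param individuals Character vector of individual IDs.
#' @return A `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, variants = NULL, individuals = NULL) {
  genotypes <- as.matrix(genotypes)
  m <- ncol(genotypes)
  if (is.null(variants)) {
    ids <- colnames(genotypes) %||% paste0("v", seq_len(m))
    variants <- tibble::tibble(id = ids, chrom = NA_character_,
                               pos = NA_integer_)
  }
  variants <- tibble::as_tibble(variants)
  if (!"id" %in% names(variants)) abort("variants needs an `id` column")
  if (!"chrom" %in% names(variants)) variants$chrom <- NA_character_
  if (!"pos" %in% names(variants)) variants$pos <- NA_integer_
  if (nrow(variants) != m) abort("variant metadata does not match genotype columns")
  if (any(!is.na(variants$pos) & variants$pos < 0)) abort("positions must be nonnegative")
  if (is.null(individuals)) {
    individuals <- rownames(genotypes) %||% paste0("i", seq_len(nrow(genotypes)))
  }
  if (length(individuals) != nrow(genotypes)) {
    abort("individual IDs do not match genotype rows")
  }
  vals <- genotypes[!is.na(genotypes)]
  if (length(vals) && !all(vals %in% 0:2)) {
    abort("genotype values must be 0/1/2 minor-allele counts or NA")
  }
  storage.mode(genotypes) <- "integer"
  colnames(genotypes) <- variants$id
  rownames(genotypes) <- individuals
  structure(list(genotypes = genotypes, variants = variants,
                 individuals = individuals),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix>", length(x$individuals), "individuals x",
      nrow(x$variants), "variants;",
      sum(is.na(x$genotypes)), "missing calls\n")
  invisible(x)
}

#' Minor-allele frequencies of a genotype matrix
#'
#' @param g A `genotype_matrix` (or plain 0/1/2 matrix).
#' @return Per-variant allele frequency of the counted allele (missing
#'   genotypes excluded).
#' @export
variant_maf <- function(g) {
  G <- if (inherits(g, "genotype_matrix")) g$genotypes else as.matrix(g)
  colMeans(G, na.rm = TRUE) / 2
}

#' Read genotypes from PLINK binary or TSV
#'
#' `plink_bed` reads a PLINK 1 `.bed/.bim/.fam` triple (variant-major
#' layout). The counted (minor) allele is recomputed from the loaded
#' sample: variants whose A1 frequency exceeds 0.5 are flipped so values
#' are always minor-allele counts, with the flip recorded in the variant
#' table. `tsv` reads the package's plain-text dialect: a header row of
#' variant IDs, an `id` first column, one individual per row, values 0/1/2
#' with empty or `NA` cells as missing.
#'
#' @param path For `plink_bed`: the file-set prefix (or the `.bed` path);
#'   for `tsv`: the file path.
#' @param format `"plink_bed"` or `"tsv"`.
#' @return A [genotype_matrix()]; for PLINK input the `.fam` phenotype is
#'   attached as attribute `phenotype` when it is interpretable as binary.
#' @export
read_genotypes <- function(path, format = c("plink_bed", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") read_genotypes_tsv(path) else read_plink(path)
}

read_genotypes_tsv <- function(path) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (!ncol(df) || names(df)[1] != "id") {
    abort("TSV dialect requires an `id` first column and variant-ID header")
  }
  ids <- df$id
  G <- as.matrix(df[, -1, drop = FALSE])
  G[G == "" | G == "NA"] <- NA
  suppressWarnings(storage.mode(G) <- "integer")
  bad <- which(!is.na(G) & !(G %in% 0:2), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf("invalid genotype value at individual %s, variant %s",
                  ids[bad[1, 1]], colnames(G)[bad[1, 2]]))
  }
  genotype_matrix(G, individuals = ids)
}

#' Write genotypes in the TSV dialect
#'
#' @param g A [genotype_matrix()] (or plain matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(g, path) {
  if (!inherits(g, "genotype_matrix")) g <- genotype_matrix(g)
  df <- data.frame(id = g$individuals, g$genotypes, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column phenotype file
#'
#' Whitespace-separated `id status` lines; status coded 0/1, or PLINK-style
#' 1/2 which is auto-detected and converted (with a warning).
#'
#' @param path File path.
#' @param ids Optional individual IDs to align the phenotype to.
#' @return Named integer vector of 0/1 statuses.
#' @export
read_phenotype <- function(path, ids = NULL) {
  df <- utils::read.table(path, header = FALSE, col.names = c("id", "status"),
                          colClasses = c("character", "integer"))
  st <- df$status
  if (all(st %in% 1:2) && any(st == 2)) {
    warn("phenotype looks PLINK-coded (1/2); converting to 0/1")
    st <- st - 1L
  }
  if (!all(st %in% 0:1)) abort("phenotype statuses must be 0/1 (or PLINK 1/2)")
  names(st) <- df$id
  if (!is.null(ids)) {
    miss <- setdiff(ids, df$id)
    if (length(miss)) abort(paste("phenotype missing for:", miss[1]))
    st <- st[ids]
  }
  st
}

# ---- PLINK 1 binary ---------------------------------------------------------

plink_prefix <- function(path) sub("\\.bed$", "", path)

read_plink <- function(path) {
  prefix <- plink_prefix(path)
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) abort(paste("no such file:", f))
  bimdf <- utils::read.table(bim, header = FALSE, colClasses = "character",
                             col.names = c("chrom", "id", "cm", "pos", "a1", "a2"))
  famdf <- utils::read.table(fam, header = FALSE, colClasses = "character",
                             col.names = c("fid", "iid", "pid", "mid", "sex", "pheno"))
  n <- nrow(famdf); m <- nrow(bimdf)
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    abort(paste("not a PLINK .bed file:", bed))
  }
  if (raw[3] != as.raw(0x01)) abort("only variant-major .bed files are supported")
  bpv <- ceiling(n / 4)
  expected <- 3 + bpv * m
  if (length(raw) != expected) {
    abort(sprintf(".bed size %d does not match %d variants x %d individuals (expected %d)",
                  length(raw), m, n, expected))
  }
  body <- as.integer(raw[-(1:3)])
  # decode 2-bit codes, LSB first: 00 hom A1, 01 missing, 10 het, 11 hom A2
  codes <- matrix(0L, 4 * bpv, m)
  for (s in 0:3) {
    codes[seq(s + 1, 4 * bpv, by = 4), ] <- bitwAnd(bitwShiftR(
      matrix(body, bpv, m), 2L * s), 3L)
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  G <- matrix(NA_integer_, n, m)
  G[codes == 0L] <- 2L  # two copies of A1
  G[codes == 2L] <- 1L
  G[codes == 3L] <- 0L
  # recompute the minor allele from the sample
  freq_a1 <- colMeans(G, na.rm = TRUE) / 2
  flip <- !is.na(freq_a1) & freq_a1 > 0.5
  if (any(flip)) G[, flip] <- 2L - G[, flip]
  variants <- tibble::tibble(
    id = bimdf$id, chrom = bimdf$chrom, pos = as.integer(bimdf$pos),
    a1 = bimdf$a1, a2 = bimdf$a2, flipped = flip,
    minor_allele = ifelse(flip, bimdf$a2, bimdf$a1)
  )
  colnames(G) <- variants$id
  out <- genotype_matrix(G, variants, famdf$iid)
  ph <- suppressWarnings(as.integer(famdf$pheno))
  if (all(ph %in% 1:2) && !anyNA(ph)) {
    attr(out, "phenotype") <- setNames(ph - 1L, famdf$iid)
  } else if (all(ph %in% 0:1) && !anyNA(ph)) {
    attr(out, "phenotype") <- setNames(ph, famdf$iid)
  }
  out
}

#' Write a PLINK 1 .bed/.bim/.fam file set
#'
#' Variant-major layout with A1 = the counted (minor) allele, so values
#' round-trip exactly through [read_genotypes()]. Phenotypes are written in
#' PLINK 1/2 coding.
#'
#' @param g A [genotype_matrix()] (or plain 0/1/2 matrix).
#' @param prefix Output prefix (writes `<prefix>.bed`, `.bim`, `.fam`).
#' @param phenotype Optional 0/1 vector.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix, phenotype = NULL) {
  if (!inherits(g, "genotype_matrix")) g <- genotype_matrix(g)
  G <- g$genotypes
  n <- nrow(G); m <- ncol(G)
  v <- g$variants
  a1 <- if ("a1" %in% names(v)) v$a1 else rep("A", m)
  a2 <- if ("a2" %in% names(v)) v$a2 else rep("B", m)
  chrom <- ifelse(is.na(v$chrom), "0", v$chrom)
  pos <- ifelse(is.na(v$pos), 0L, v$pos)
  utils::write.table(data.frame(chrom, v$id, 0, pos, a1, a2),
                     paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ph <- if (is.null(phenotype)) rep(-9L, n) else as.integer(phenotype) + 1L
  utils::write.table(data.frame(g$individuals, g$individuals, 0, 0, 0, ph),
                     paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bpv <- ceiling(n / 4)
  code <- matrix(1L, 4 * bpv, m)      # 01 = missing
  gg <- rbind(G, matrix(NA_integer_, 4 * bpv - n, m))
  code[!is.na(gg) & gg == 2L] <- 0L
  code[!is.na(gg) & gg == 1L] <- 2L
  code[!is.na(gg) & gg == 0L] <- 3L
  if (4 * bpv > n) code[(n + 1):(4 * bpv), ] <- 0L  # zero padding bits
  idx <- seq(1, 4 * bpv, by = 4)
  bytes <- code[idx, , drop = FALSE] +
    4L * code[idx + 1, , drop = FALSE] +
    16L * code[idx + 2, , drop = FALSE] +
    64L * code[idx + 3, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}

#' Read a variant-pair list file
#'
#' Two whitespace-separated variant IDs per line; `#` starts a comment.
#'
#' @param path File path.
#' @return Tibble with `variant1`, `variant2`.
#' @export
read_pair_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\\s+")
  bad <- which(lengths(parts) != 2)
  if (length(bad)) abort(sprintf("malformed pair line %d: %s", bad[1], lines[bad[1]]))
  tibble::tibble(variant1 = vapply(parts, `[`, "", 1),
                 variant2 = vapply(parts, `[`, "", 2))
}
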