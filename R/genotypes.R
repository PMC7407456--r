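#' Marker matrix container
#'
#' Bundles a line x marker matrix of minor-allele counts (0/1/2, `NA` for
#' missing) with per-marker minor allele frequency and missingness, the two
#' quantities marker quality control filters on.
#'
#' @param calls Numeric matrix, lines in rows, markers in columns, entries in
#'   `{0, 1, 2, NA}`. Row and column names are used as line and marker
#'   identifiers; defaults (`L1..`, `M1..`) are supplied when absent.
#' @return An object of class `marker_matrix`: a list with elements `calls`,
#'   `line_ids`, `marker_ids`, `maf`, `missing_rate`.
#' @export
marker_matrix <- function(calls) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "double"
  if (!all(calls %in% c(0, 1, 2) | is.na(calls)))
    stop("marker calls must be allele counts in {0, 1, 2} or NA")
  if (is.null(rownames(calls))) rownames(calls) <- paste0("L", seq_len(nrow(calls)))
  if (is.null(colnames(calls))) colnames(calls) <- paste0("M", seq_len(ncol(calls)))
  if (anyDuplicated(rownames(calls))) stop("duplicate line identifiers")
  if (anyDuplicated(colnames(calls))) stop("duplicate marker identifiers")
  obj <- structure(
    list(calls = calls,
         line_ids = rownames(calls),
         marker_ids = colnames(calls),
         maf = .marker_maf(calls),
         missing_rate = colMeans(is.na(calls))),
    class = "marker_matrix")
  het <- mean(calls == 1, na.rm = TRUE)
  if (is.finite(het) && het > 0.05)
    warning(sprintf("heterozygosity %.1f%% exceeds 5%%; data may not be inbred",
                    100 * het))
  obj
}

# allele frequency of the counted allele, folded to [0, 0.5]
.marker_maf <- function(calls) {
  f <- colMeans(calls, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d lines x %d markers\n",
              length(x$line_ids), length(x$marker_ids)))
  cat(sprintf("  MAF range [%.3f, %.3f]; missing rate mean %.3f\n",
              min(x$maf), max(x$maf), mean(x$missing_rate)))
  invisible(x)
}

#' @export
dim.marker_matrix <- function(x) dim(x$calls)

# Flip marker coding so the counted allele is the minor allele.
.orient_minor <- function(calls) {
  f <- colMeans(calls, na.rm = TRUE) / 2
  flip <- which(!is.na(f) & f > 0.5)
  if (length(flip)) calls[, flip] <- 2 - calls[, flip]
  calls
}

#' Read genotypes from CSV, HapMap-dialect text, or VCF
#'
#' All formats are normalised to minor-allele counts: heterozygotes become 1
#' and each marker is oriented so the counted allele is the minor allele.
#' Non-biallelic VCF sites are skipped with a message giving the count.
#'
#' @param path Path to the genotype file.
#' @param format One of `"csv"` (numeric, lines as rows, header = marker IDs,
#'   first column = line IDs), `"hapmap"` (tab-separated: rs, alleles, chrom,
#'   pos, then one call column per line, calls like `AA`/`AC`/`NN`), or
#'   `"vcf"` (biallelic SNPs, GT field).
#' @return A [marker_matrix()].
#' @export
read_genotypes <- function(path, format = c("csv", "hapmap", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  calls <- switch(format,
                  csv = .read_geno_csv(path),
                  hapmap = .read_geno_hapmap(path),
                  vcf = .read_geno_vcf(path))
  marker_matrix(.orient_minor(calls))
}

.read_geno_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  bad <- which(!(m %in% c(0, 1, 2) | is.na(m)), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("unparseable genotype at data line %d (value %s)",
                 bad[1, 1], m[bad[1, 1], bad[1, 2]]))
  m
}

.read_geno_hapmap <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 5)
    stop("hapmap dialect needs columns rs, alleles, chrom, pos, then calls")
  rs <- df[[1]]
  alleles <- strsplit(df[[2]], "/", fixed = TRUE)
  geno <- as.matrix(df[, -(1:4), drop = FALSE])
  calls <- matrix(NA_real_, nrow = ncol(geno), ncol = nrow(geno),
                  dimnames = list(colnames(geno), rs))
  for (i in seq_len(nrow(geno))) {
    a <- alleles[[i]]
    if (length(a) != 2)
      stop(sprintf("unparseable alleles field at line %d: %s", i + 1, df[[2]][i]))
    g <- geno[i, ]
    cnt <- ifelse(g == "NN" | g == "--", NA_real_,
                  vapply(strsplit(g, ""), function(ch) {
                    if (any(!ch %in% a)) return(NA_real_)
                    sum(ch == a[2])
                  }, numeric(1)))
    calls[, i] <- cnt
  }
  calls
}

.read_geno_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt) | is.na(alt) | alt == ""
  if (any(multi))
    message(sprintf("skipped %d non-biallelic site(s)", sum(multi)))
  v <- v[!multi, ]
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- rownames(gt)
  if (is.null(ids) || anyDuplicated(ids))
    ids <- paste0("M", seq_len(nrow(gt)))
  counts <- apply(gt, 2, function(col) {
    col <- gsub("|", "/", col, fixed = TRUE)
    vapply(strsplit(col, "/", fixed = TRUE), function(a) {
      if (any(is.na(a)) || any(a == ".")) return(NA_real_)
      sum(a == "1")
    }, numeric(1))
  })
  t(matrix(counts, nrow = nrow(gt), dimnames = list(ids, colnames(gt))))
}

#' Filter markers on minor allele frequency and missingness
#'
#' Retains markers with `maf >= maf_min` and `missing_rate <= missing_max`
#' (defaults are the usual GBS quality-control thresholds). Lines and marker
#' order are preserved.
#'
#' @param m A [marker_matrix()].
#' @param maf_min Minimum minor allele frequency, in `[0, 0.5]`.
#' @param missing_max Maximum per-marker missing fraction, in `[0, 1]`.
#' @return A filtered [marker_matrix()].
#' @export
filter_markers <- function(m, maf_min = 0.05, missing_max = 0.10) {
  stopifnot(inherits(m, "marker_matrix"),
            maf_min >= 0, maf_min <= 0.5,
            missing_max >= 0, missing_max <= 1)
  keep <- !is.na(m$maf) & m$maf >= maf_min & m$missing_rate <= missing_max
  if (!any(keep)) stop("all markers removed by filtering")
  marker_matrix(m$calls[, keep, drop = FALSE])
}

#' Mean-impute missing genotype calls
#'
#' Missing cells are replaced by the per-marker mean of the observed calls,
#' the standard preparation step before building a genomic relationship
#' matrix. Markers with no observed calls are an error.
#'
#' @param m A [marker_matrix()].
#' @return A [marker_matrix()] with no missing values (imputed calls are
#'   fractional, so MAF metadata is recomputed from rounded dosage only for
#'   display; calls are kept as-is).
#' @export
impute_missing <- function(m) {
  stopifnot(inherits(m, "marker_matrix"))
  calls <- m$calls
  if (!anyNA(calls)) return(m)
  allmiss <- colSums(!is.na(calls)) == 0
  if (any(allmiss))
    stop("marker(s) with all calls missing: ",
         paste(m$marker_ids[allmiss], collapse = ", "))
  mu <- colMeans(calls, na.rm = TRUE)
  idx <- which(is.na(calls), arr.ind = TRUE)
  calls[idx] <- mu[idx[, 2]]
  out <- m
  out$calls <- calls
  out$maf <- .marker_maf(calls)
  out$missing_rate <- rep(0, ncol(calls))
  out
}

#' Genomic relationship matrix G = WW'/p
#'
#' Columns of the call matrix are centred by their mean (the `center`
#' default; uncentred Gram matrices conflate allele frequency with
#' relatedness) and the cross-product is divided by the marker count p.
#' VanRaden-style per-marker scaling by 2*p_k*q_k is available but off by
#' default.
#'
#' @param m A [marker_matrix()] without missing values (see
#'   [impute_missing()]).
#' @param center Centre marker columns by their mean before the
#'   cross-product. Default `TRUE`.
#' @param vanraden Additionally divide by `sum(2 p_k q_k)` instead of `p`
#'   (VanRaden scaling). Default `FALSE`.
#' @return A `genomic_relationship`: a symmetric line x line matrix with line
#'   IDs as dimnames.
#' @export
compute_grm <- function(m, center = TRUE, vanraden = FALSE) {
  stopifnot(inherits(m, "marker_matrix"))
  if (anyNA(m$calls)) stop("missing calls: impute before computing the GRM")
  p <- ncol(m$calls)
  if (p < 1) stop("no markers")
  W <- m$calls
  if (center) W <- sweep(W, 2, colMeans(W), "-")
  denom <- if (vanraden) {
    fr <- colMeans(m$calls) / 2
    s <- sum(2 * fr * (1 - fr))
    if (s <= 0) stop("vanraden scaling undefined: all markers monomorphic")
    s
  } else p
  G <- tcrossprod(W) / denom
  G <- (G + t(G)) / 2
  structure(G, class = c("genomic_relationship", class(G)))
}

#' @export
print.genomic_relationship <- function(x, ...) {
  cat(sprintf("genomic_relationship: %d lines, mean diagonal %.3f\n",
              nrow(x), mean(diag(x))))
  invisible(x)
}

#' Eigenvalue spectrum summary of a relationship matrix
#'
#' Principal-component style diversity summary: eigenvalues (clipped at 0),
#' their variance shares, the number of components needed to reach a
#' cumulative share threshold, and loadings of the first two components.
#'
#' @param g A symmetric PSD matrix ([compute_grm()] output).
#' @param threshold Cumulative variance share to reach, in `(0, 1]`.
#' @return List with `eigenvalues`, `shares`, `cumulative`, `n_components`,
#'   `loadings` (first two eigenvectors).
#' @export
pca_variance_summary <- function(g, threshold = 0.8) {
  stopifnot(threshold > 0, threshold <= 1)
  g <- unclass(as.matrix(g))
  if (!all(is.finite(g))) stop("non-finite entries in relationship matrix")
  eg <- eigen(g, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  if (sum(ev) <= 0) stop("matrix has no positive eigenvalues")
  shares <- ev / sum(ev)
  cum <- cumsum(shares)
  k <- which(cum >= threshold - 1e-9)[1]
  list(eigenvalues = ev,
       shares = shares,
       cumulative = cum,
       n_components = k,
       loadings = eg$vectors[, 1:2, drop = FALSE])
}

#' Write genotypes as numeric CSV
#'
#' @param m A [marker_matrix()].
#' @param path Output path; lines as rows, header = marker IDs.
#' @export
write_genotypes_csv <- function(m, path) {
  stopifnot(inherits(m, "marker_matrix"))
  df <- data.frame(line = m$line_ids, m$calls, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write genotypes as a minimal biallelic VCF (GT only)
#'
#' Markers are placed on a single dummy chromosome at consecutive positions;
#' phase is not meaningful for inbred dosage data and is written unphased.
#'
#' @param m A [marker_matrix()] with integer calls (0/1/2 or missing).
#' @param path Output path.
#' @export
write_genotypes_vcf <- function(m, path) {
  stopifnot(inherits(m, "marker_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", m$line_ids), collapse = "\t")), con)
  gtmap <- c("0/0", "0/1", "1/1")
  for (j in seq_along(m$marker_ids)) {
    calls <- m$calls[, j]
    gt <- ifelse(is.na(calls), "./.", gtmap[round(calls) + 1])
    writeLines(paste(c("1", j, m$marker_ids[j], "A", "C", ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}
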