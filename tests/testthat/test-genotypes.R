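test_that("CSV genotypes are read with minor-allele orientation and MAF", {
  calls <- matrix(c(0, 2, 1,
                    1, 1, 1,
                    2, 0, 1), nrow = 3, byrow = TRUE,
                  dimnames = list(c("A", "B", "C"), c("m1", "m2", "m3")))
  # heterozygote-rich toy data triggers the inbred-heterozygosity warning
  expect_warning(m <- read_genotypes(write_temp_csv(calls), "csv"),
                 "heterozygosity")
  expect_equal(dim(m), c(3L, 3L))
  expect_equal(unname(m$maf), c(0.5, 0.5, 0.5))
  expect_equal(m$line_ids, c("A", "B", "C"))

  # major-allele coding gets flipped: column mean frequency > 0.5
  calls2 <- matrix(c(2, 2, 2, 2, 2, 0), ncol = 1,
                   dimnames = list(paste0("L", 1:6), "m1"))
  m2 <- read_genotypes(write_temp_csv(calls2), "csv")
  expect_equal(unname(m2$calls[, 1]), c(0, 0, 0, 0, 0, 2))
})

test_that("HapMap-dialect rows parse calls, heterozygotes and NN missing", {
  path <- tempfile(fileext = ".txt")
  writeLines(c(paste(c("rs", "alleles", "chrom", "pos", "L1", "L2", "L3"),
                     collapse = "\t"),
               paste(c("m1", "A/C", "1", "100", "AA", "AC", "CC"),
                     collapse = "\t"),
               paste(c("m2", "G/T", "1", "200", "NN", "GG", "TT"),
                     collapse = "\t")), path)
  m <- suppressWarnings(read_genotypes(path, "hapmap"))
  expect_equal(unname(m$calls[, "m1"]), c(0, 1, 2))
  expect_true(is.na(m$calls["L1", "m2"]))
  expect_equal(unname(m$calls[c("L2", "L3"), "m2"]), c(0, 2))
})

test_that("VCF reading skips non-biallelic sites and maps GT to dosage", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"G\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "L1", "L2", "L3"), collapse = "\t"),
               paste(c("1", "1", "s1", "A", "C", ".", "PASS", ".", "GT",
                       "0/0", "0/1", "1/1"), collapse = "\t"),
               paste(c("1", "2", "s2", "A", "C,G", ".", "PASS", ".", "GT",
                       "0/0", "1/2", "2/2"), collapse = "\t"),
               paste(c("1", "3", "s3", "G", "T", ".", "PASS", ".", "GT",
                       "./.", "0/0", "1/1"), collapse = "\t"),
               paste(c("1", "4", "s4", "G", "T", ".", "PASS", ".", "GT",
                       "0|0", "0|0", "1|1"), collapse = "\t"),
               paste(c("1", "5", "s5", "G", "T", ".", "PASS", ".", "GT",
                       "0/0", "0/0", "0/1"), collapse = "\t"),
               paste(c("1", "6", "s6", "G", "T", ".", "PASS", ".", "GT",
                       "0/0", "1/1", "0/1"), collapse = "\t")), path)
  expect_message(m <- suppressWarnings(read_genotypes(path, "vcf")),
                 "1 non-biallelic")
  expect_equal(length(m$marker_ids), 5L)
  expect_false("s2" %in% m$marker_ids)
  expect_equal(unname(m$calls[, "s1"]), c(0, 1, 2))
  expect_true(is.na(m$calls["L1", "s3"]))
})

test_that("round-trip through the minimal VCF writer preserves calls", {
  m <- random_inbred_markers(6, 5, seed = 42)
  path <- tempfile(fileext = ".vcf")
  write_genotypes_vcf(m, path)
  m2 <- read_genotypes(path, "vcf")
  # reading normalises to minor-allele orientation, so compare against the
  # minor-oriented version of what was written
  expected <- gxeblup:::.orient_minor(m$calls)
  expect_equal(unname(m2$calls[m$line_ids, m$marker_ids]), unname(expected))
})

test_that("marker filtering keeps exactly the hand-enumerated survivor set", {
  set.seed(7)
  n <- 100
  mafs <- c(0.01, 0.04, 0.05, 0.10, 0.20, 0.30, 0.40, 0.50, 0.0, 0.25)
  miss <- c(0.00, 0.00, 0.00, 0.05, 0.11, 0.00, 0.20, 0.05, 0.00, 0.09)
  calls <- sapply(seq_along(mafs), function(j) {
    v <- c(rep(2, round(mafs[j] * n)), rep(0, n - round(mafs[j] * n)))
    v[seq_len(round(miss[j] * n))] <- NA
    sample(v)
  })
  colnames(calls) <- paste0("m", seq_along(mafs))
  # recompute realized maf/missingness, then enumerate survivors by hand
  m <- marker_matrix(calls)
  expected <- m$marker_ids[m$maf >= 0.05 & m$missing_rate <= 0.10]
  f <- filter_markers(m, 0.05, 0.10)
  expect_identical(f$marker_ids, expected)
  expect_true(all(c("m3", "m4", "m6", "m8", "m10") %in% f$marker_ids))
  expect_false(any(c("m1", "m2", "m5", "m7", "m9") %in% f$marker_ids))
  expect_identical(f$line_ids, m$line_ids)
  # monomorphic marker removed at the MAF boundary
  expect_false("m9" %in% f$marker_ids)
  # removing everything is an explicit error
  expect_error(filter_markers(m, 0.5, 0), "all markers removed")
})

test_that("mean imputation reproduces observed column means", {
  m0 <- marker_matrix(matrix(c(0, 2, NA), ncol = 1))
  expect_equal(unname(impute_missing(m0)$calls[3, 1]), 1.0)

  complete <- random_inbred_markers(10, 6, seed = 3)
  expect_identical(impute_missing(complete), complete)

  set.seed(11)
  calls <- complete$calls
  mask <- matrix(runif(length(calls)) < 0.2, nrow(calls))
  calls[mask] <- NA
  keep <- colSums(!is.na(calls)) > 0
  calls <- calls[, keep, drop = FALSE]
  imp <- impute_missing(marker_matrix(calls))
  for (j in seq_len(ncol(calls))) {
    mu_j <- mean(calls[, j], na.rm = TRUE)
    expect_equal(unname(imp$calls[is.na(calls[, j]), j]),
                 rep(mu_j, sum(is.na(calls[, j]))))
  }
  all_na <- calls
  all_na[, 1] <- NA
  expect_error(impute_missing(marker_matrix(all_na)), "all calls missing")
})

test_that("GRM matches hand arithmetic and degenerate cases", {
  m <- suppressWarnings(
    marker_matrix(matrix(c(0, 2, 1,
                           2, 0, 1), ncol = 2,
                         dimnames = list(c("a", "b", "c"), c("m1", "m2")))))
  G <- compute_grm(m)
  expect_equal(unname(unclass(G)),
               matrix(c(1, -1, 0, -1, 1, 0, 0, 0, 0), 3), tolerance = 1e-12)
  # identical lines give a constant matrix equal to its diagonal
  same <- marker_matrix(matrix(2, nrow = 3, ncol = 4))
  Gs <- compute_grm(same)
  expect_true(all(abs(Gs - Gs[1, 1]) < 1e-12))
})

test_that("GRM invariants: PSD, permutation, duplication, zero sum", {
  m <- random_inbred_markers(25, 60, seed = 5)
  G <- compute_grm(m)
  expect_lt(max(abs(G - t(G))), 1e-10)
  ev <- eigen(unclass(G), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  # algebraic identity: centered columns sum to zero so sum(G) == 0
  expect_lt(abs(sum(G)), 1e-8)
  # marker permutation leaves G unchanged
  perm <- sample(ncol(m$calls))
  Gp <- compute_grm(marker_matrix(m$calls[, perm]))
  expect_equal(unclass(G), unclass(Gp), tolerance = 1e-12)
  # duplicating every marker column leaves G unchanged (p cancels)
  dup <- cbind(m$calls, m$calls)
  colnames(dup) <- paste0("d", seq_len(ncol(dup)))
  Gd <- compute_grm(marker_matrix(dup))
  expect_equal(unclass(G), unclass(Gd), tolerance = 1e-12)
  # line reordering permutes rows and columns together
  lp <- sample(nrow(m$calls))
  Gl <- compute_grm(marker_matrix(m$calls[lp, ]))
  expect_equal(unclass(Gl), unclass(G)[lp, lp], tolerance = 1e-12)
})

test_that("eigen spectrum summary matches flat, rank-1 and dense oracles", {
  s <- pca_variance_summary(diag(10), threshold = 0.8)
  expect_equal(s$n_components, 8L)
  expect_equal(sum(s$shares), 1)

  v <- 1:5
  r1 <- tcrossprod(v)
  s1 <- pca_variance_summary(r1, threshold = 0.99)
  expect_equal(s1$n_components, 1L)
  expect_equal(s1$shares[1], 1)

  G <- compute_grm(random_inbred_markers(50, 200, seed = 9))
  s50 <- pca_variance_summary(G, threshold = 0.8)
  ev <- pmax(eigen(unclass(G), symmetric = TRUE, only.values = TRUE)$values, 0)
  expect_equal(s50$eigenvalues, ev, tolerance = 1e-10)
  expect_equal(s50$n_components,
               which(cumsum(ev / sum(ev)) >= 0.8 - 1e-9)[1])
  expect_error(pca_variance_summary(matrix(c(1, NA, NA, 1), 2)),
               "non-finite")
})
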