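test_that("covariance structures reduce correctly in small designs", {
  # single environment: interaction kernel equals the genomic kernel
  t1 <- cell_table(matrix(1:4, ncol = 1))
  G <- compute_grm(random_inbred_markers(4, 30, seed = 1))
  rownames(G) <- colnames(G) <- unique(t1$line)
  cov1 <- build_covariances(t1, G, model = "M3")
  expect_equal(cov1$kernels$gE, cov1$kernels$g, tolerance = 1e-12)

  # 2 lines x 2 environments sorted by environment: block diagonal with G
  t2 <- cell_table(matrix(1:4, ncol = 2))
  G2 <- compute_grm(random_inbred_markers(2, 30, seed = 2))
  rownames(G2) <- colnames(G2) <- unique(t2$line)
  cov2 <- build_covariances(t2, G2, model = "M3")
  expected <- rbind(cbind(unclass(G2), matrix(0, 2, 2)),
                    cbind(matrix(0, 2, 2), unclass(G2)))
  expect_equal(unname(cov2$kernels$gE), unname(expected), tolerance = 1e-12)

  # lines missing from G are reported by name
  bad_G <- G2[1, 1, drop = FALSE]
  expect_error(build_covariances(t2, bad_G, model = "M2"), "L2")
})

test_that("interaction kernels are PSD for random PSD genomic matrices", {
  # Schur product theorem, checked over random instances
  set.seed(42)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    A <- matrix(rnorm(n * n), n)
    G <- tcrossprod(A) / n
    dimnames(G) <- list(paste0("L", 1:n), paste0("L", 1:n))
    t <- cell_table(matrix(rnorm(n * 3), ncol = 3),
                    lines = rownames(G))
    cov <- build_covariances(t, G, model = "M3")
    ev <- eigen(cov$kernels$gE, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
  }
})

test_that("variance percentages reproduce the within-environment split", {
  p1 <- variance_percentages(c(L = 12.09, e = 7.01))
  expect_equal(unname(p1$percent), c(63, 37))
  p3 <- variance_percentages(c(L = 2.47, g = 10.03, gE = 2.13, e = 4.92))
  expect_equal(unname(p3$percent[c("L", "g", "gE", "e")]), c(13, 51, 11, 25))
  # environment variance never enters the base
  p3b <- variance_percentages(c(E = 8.11, L = 2.47, g = 10.03, gE = 2.13,
                                e = 4.92))
  expect_equal(p3$percent, p3b$percent)
  expect_equal(sum(p3$unrounded), 100)
  expect_equal(unname(variance_percentages(c(g = 3))$percent), 100)
  expect_error(variance_percentages(c(L = 0, e = 0)), "zero")
})

test_that("closed-form BLUP matches scalar shrinkage and vanishing-variance limits", {
  # single line observed twice in one environment: the combined line-level
  # variance shrinks the mean by s2_u / (s2_u + s2_e / 2)
  t <- phenotype_table(data.frame(line = c("A", "A", "B"),
                                  environment = "E1",
                                  replicate = c(1, 2, 1),
                                  value = c(30, 32, NA)))
  cov <- build_covariances(t, model = "M1", terms = "L")
  s2_u <- 4; s2_e <- 2
  bl <- closed_form_blup(t, cov, c(L = s2_u, e = s2_e))
  ybar_A <- 31
  shrunk <- s2_u / (s2_u + s2_e / 2) * (ybar_A - bl$mu)
  expect_equal(bl$gebv$gebv[bl$gebv$line == "A"][1], shrunk, tolerance = 1e-10)

  # genomic variance -> 0: GEBVs vanish
  t2 <- cell_table(matrix(rnorm(12, 25), ncol = 2))
  G <- compute_grm(random_inbred_markers(6, 40, seed = 3))
  rownames(G) <- colnames(G) <- unique(t2$line)
  cov2 <- build_covariances(t2, G, model = "M1", terms = "g")
  bl2 <- closed_form_blup(t2, cov2, c(g = 1e-10, e = 1))
  expect_lt(max(abs(bl2$gebv$gebv)), 1e-6)
})

test_that("GBLUP equals ridge regression on markers with lambda = p s2e/s2g", {
  set.seed(4)
  n <- 20; p <- 50
  m <- random_inbred_markers(n, p, seed = 4)
  X <- sweep(m$calls, 2, colMeans(m$calls))
  y <- 25 + X %*% rnorm(p, 0, 0.2) + rnorm(n)
  t <- cell_table(matrix(y, ncol = 1), lines = m$line_ids)
  G <- compute_grm(m)
  cov <- build_covariances(t, G, model = "M2", terms = "g")
  s2g <- 3; s2e <- 1.5
  bl <- closed_form_blup(t, cov, c(g = s2g, e = s2e))
  lambda <- p * s2e / s2g
  bhat <- solve(crossprod(X) + lambda * diag(p), crossprod(X, y - bl$mu))
  expect_equal(bl$gebv$gebv, as.vector(X %*% bhat), tolerance = 1e-8)
})

test_that("record order only permutes closed-form results", {
  t <- cell_table(matrix(rnorm(18, 25), ncol = 3))
  G <- compute_grm(random_inbred_markers(6, 40, seed = 5))
  rownames(G) <- colnames(G) <- unique(t$line)
  cov <- build_covariances(t, G, model = "M3")
  comp <- c(E = 2, L = 1, g = 3, gE = 1, e = 1)
  bl <- closed_form_blup(t, cov, comp)
  perm <- sample(nrow(t))
  tp <- phenotype_table(as.data.frame(t)[perm, ])
  covp <- build_covariances(tp, G, model = "M3")
  blp <- closed_form_blup(tp, covp, comp)
  key <- function(g) g[order(g$line, g$environment), "gebv"]
  expect_equal(key(blp$gebv), key(bl$gebv), tolerance = 1e-10)
})

test_that("Gibbs sampler at fixed components agrees with closed-form BLUP", {
  m <- random_inbred_markers(20, 50, seed = 6)
  ph <- simulate_phenotypes(m, true_parameters(), n_env = 3, seed = 7)
  G <- compute_grm(m)
  cov <- build_covariances(ph, G, model = "M3")
  comp <- c(E = 8.11, L = 2.47, g = 10.03, gE = 2.13, e = 4.92)
  bl <- closed_form_blup(ph, cov, comp)
  fit <- fit_gibbs(ph, cov, n_iter = 6000, burn_in = 1000, thin = 2,
                   fix_components = comp, seed = 8, store_gebv = TRUE)
  # per-cell Monte-Carlo SE of the posterior-mean GEBV
  gs <- fit$gebv_samples[, fit$cells, drop = FALSE]
  se <- apply(gs, 2, function(x) sd(x) / sqrt(gxeblup:::.ess(x)))
  z <- abs(fit$gebv$gebv - bl$gebv$gebv) / se
  expect_gt(mean(z <= 2), 0.93)
  expect_true(all(z <= 4.5))
})

test_that("a constant phenotype collapses onto its mean with zero GEBVs", {
  t <- cell_table(matrix(26.9, nrow = 6, ncol = 2))
  G <- compute_grm(random_inbred_markers(6, 40, seed = 9))
  rownames(G) <- colnames(G) <- unique(t$line)
  cov <- build_covariances(t, G, model = "M2")
  fit <- fit_gibbs(t, cov, n_iter = 2000, burn_in = 500, thin = 2, seed = 10)
  expect_equal(fit$mu, 26.9, tolerance = 0.05)
  expect_lt(max(abs(fit$gebv$gebv)), 0.1)
})

test_that("two chains with different seeds agree within Monte-Carlo error", {
  m <- random_inbred_markers(30, 60, seed = 11)
  ph <- simulate_phenotypes(m, true_parameters(), n_env = 3, seed = 12)
  G <- compute_grm(m)
  cov <- build_covariances(ph, G, model = "M2")
  f1 <- fit_gibbs(ph, cov, n_iter = 8000, burn_in = 2000, thin = 2, seed = 13)
  f2 <- fit_gibbs(ph, cov, n_iter = 8000, burn_in = 2000, thin = 2, seed = 14)
  for (k in seq_len(nrow(f1$components))) {
    se <- sqrt(f1$components$sd[k]^2 / f1$components$ess[k] +
                 f2$components$sd[k]^2 / f2$components$ess[k])
    expect_lt(abs(f1$components$mean[k] - f2$components$mean[k]), 3 * se + 1e-8)
  }
})

test_that("M3 with the interaction variance pinned near zero reproduces M2", {
  m <- random_inbred_markers(25, 60, seed = 15)
  params <- true_parameters(var_gE = 0)
  ph <- simulate_phenotypes(m, params, n_env = 3, seed = 16)
  G <- compute_grm(m)
  comp2 <- c(E = 8.11, L = 2.47, g = 10.03, e = 4.92)
  cov2 <- build_covariances(ph, G, model = "M2")
  cov3 <- build_covariances(ph, G, model = "M3")
  bl2 <- closed_form_blup(ph, cov2, comp2)
  bl3 <- closed_form_blup(ph, cov3, c(comp2, gE = 1e-9))
  expect_equal(bl3$gebv$gebv, bl2$gebv$gebv, tolerance = 1e-5)
})

test_that("masked design cells receive GEBV predictions", {
  t <- cell_table(matrix(rnorm(30, 25, 2), ncol = 3))
  t$value[c(2, 17, 25)] <- NA
  G <- compute_grm(random_inbred_markers(10, 50, seed = 17))
  rownames(G) <- colnames(G) <- unique(t$line)
  cov <- build_covariances(t, G, model = "M3")
  fit <- fit_gibbs(t, cov, n_iter = 1200, burn_in = 300, thin = 2, seed = 18)
  expect_equal(nrow(fit$gebv), 30)
  expect_true(all(is.finite(fit$gebv$gebv)))
})
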