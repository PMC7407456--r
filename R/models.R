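#' Record-level covariance structures for models M1/M2/M3
#'
#' Builds the random-effect covariance kernels over the records of a
#' phenotype table: environment (`Z_E Z_E'`), line (`Z_L Z_L'`), genomic
#' (`Z_g G Z_g'`, M2/M3) and the genomic-by-environment interaction
#' (`(Z_g G Z_g') # (Z_E Z_E')`, the Hadamard product, M3 only). With a
#' single environment the interaction kernel equals the genomic kernel
#' exactly.
#'
#' @param t A [phenotype_table()]; rows with `NA` values are design cells
#'   kept in the kernels but excluded from any likelihood.
#' @param g A `genomic_relationship` ([compute_grm()]); required for M2/M3.
#' @param model `"M1"` (environment + line), `"M2"` (+ genomic) or `"M3"`
#'   (+ genomic-by-environment).
#' @param terms Optional character subset of `c("E", "L", "g", "gE")`
#'   overriding the model preset (used for stripped-down oracles).
#' @return A `covariance_set`: list with `records`, `terms`, `kernels`
#'   (named list of n x n matrices), `model`, `cells` (row indices of the
#'   first record of each (line, environment) cell).
#' @export
build_covariances <- function(t, g = NULL, model = c("M1", "M2", "M3"),
                              terms = NULL) {
  stopifnot(inherits(t, "phenotype_table"))
  model <- match.arg(model)
  if (is.null(terms))
    terms <- switch(model, M1 = c("E", "L"), M2 = c("E", "L", "g"),
                    M3 = c("E", "L", "g", "gE"))
  records <- as.data.frame(t)
  n <- nrow(records)
  env_f <- factor(records$environment, levels = unique(records$environment))
  line_f <- factor(records$line, levels = unique(records$line))
  K_E <- outer(env_f, env_f, "==") * 1
  K_L <- outer(line_f, line_f, "==") * 1
  kernels <- list()
  if ("E" %in% terms) kernels$E <- K_E
  if ("L" %in% terms) kernels$L <- K_L
  if (any(c("g", "gE") %in% terms)) {
    if (is.null(g)) stop("a genomic relationship matrix is required for ", model)
    g <- as.matrix(g)
    missing_lines <- setdiff(levels(line_f), rownames(g))
    if (length(missing_lines))
      stop("lines missing from the genomic relationship matrix: ",
           paste(missing_lines, collapse = ", "))
    idx <- match(as.character(records$line), rownames(g))
    K_g <- g[idx, idx]
    if ("g" %in% terms) kernels$g <- K_g
    if ("gE" %in% terms) kernels$gE <- K_g * K_E
  }
  cell_key <- paste(records$line, records$environment)
  structure(list(records = records,
                 terms = names(kernels),
                 kernels = kernels,
                 model = model,
                 cells = which(!duplicated(cell_key))),
            class = "covariance_set")
}

#' @export
print.covariance_set <- function(x, ...) {
  cat(sprintf("covariance_set (%s): %d records, terms %s\n", x$model,
              nrow(x$records), paste(x$terms, collapse = " + ")))
  invisible(x)
}

# eigen factor Phi = U sqrt(D) of a PSD kernel, dropping null directions
.eigen_factor <- function(K, jitter = 1e-8) {
  eg <- eigen(K + diag(jitter, nrow(K)), symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-10
  d <- eg$values[keep]
  list(Phi = eg$vectors[, keep, drop = FALSE] %*% diag(sqrt(d), length(d)),
       d = d)
}

# effective sample size from the initial positive autocorrelation sequence
.ess <- function(x) {
  n <- length(x)
  if (n < 10 || stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(200, n - 1), plot = FALSE)$acf[-1]
  s <- 0
  for (r in ac) {
    if (r <= 0) break
    s <- s + r
  }
  min(n, n / (1 + 2 * s))
}

#' Fit a reaction-norm GBLUP model by Gibbs sampling
#'
#' Bayesian mixed model `y = mu + sum_k u_k + e` where each random-effect
#' block has covariance `sigma2_k K_k` for a kernel from
#' [build_covariances()]. Each kernel is eigen-decomposed once; blocks are
#' then sampled jointly in the eigenbasis (diagonal full-conditional
#' precision), variances get scaled-inverse-chi-square updates with prior
#' degrees of freedom `df0` and scales derived from the phenotypic variance
#' split equally among the active terms, and masked (`NA`) records are
#' imputed by data augmentation so they never inform the fit.
#'
#' @param t A [phenotype_table()]; `NA` values mark masked cells to predict.
#' @param cov A `covariance_set` built on the same records.
#' @param n_iter,burn_in,thin MCMC settings (defaults 12000 / 2000 / 5).
#' @param df0 Prior degrees of freedom for every variance. The default 2 is
#'   weakly informative: with several near-confounded variance components
#'   (line vs genomic, interaction vs residual under single replication)
#'   stronger priors visibly pull the posterior means along the ridge.
#' @param r2 Prior variance partition: the residual prior scale corresponds
#'   to `(1 - r2)` of the phenotypic variance and each random term to
#'   `r2 / K` of it (K active terms), each divided by the mean diagonal of
#'   its kernel. Default 0.5.
#' @param fix_components Optional named numeric vector (names = active
#'   terms plus `"e"`): variances are held fixed at these values and only
#'   effects are sampled (used to check the sampler against closed-form
#'   BLUP).
#' @param seed Optional integer seed.
#' @param store_gebv Keep per-sample genetic values (needed for Monte-Carlo
#'   SEs of GEBVs). Default `FALSE`.
#' @return A `fit_result`: `components` (posterior mean, SD and effective
#'   sample size per variance), `mu`, `gebv` (per (line, environment) cell:
#'   predicted genetic value, the sum of line, genomic and interaction
#'   effects present in the model), `fitted` (posterior mean record means),
#'   `samples` (variance and mu draws), `effects` (posterior-mean record
#'   effects per term), and the settings used.
#' @export
fit_gibbs <- function(t, cov, n_iter = 12000, burn_in = 2000, thin = 5,
                      df0 = 2, r2 = 0.5, fix_components = NULL, seed = NULL,
                      store_gebv = FALSE) {
  stopifnot(inherits(t, "phenotype_table"), inherits(cov, "covariance_set"))
  if (nrow(t) != nrow(cov$records))
    stop("phenotype table and covariance set differ in record count")
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (length(unique(t$line[!is.na(t$value)])) < 2)
    stop("need at least 2 distinct observed lines")
  if (!is.null(seed)) set.seed(seed)

  y <- t$value
  is_obs <- as.integer(!is.na(y))
  y[is.na(y)] <- 0
  terms <- cov$terms
  K <- length(terms)
  facs <- lapply(cov$kernels, .eigen_factor)
  Phi <- lapply(facs, `[[`, "Phi")
  d <- lapply(facs, `[[`, "d")

  update_var <- is.null(fix_components)
  vy <- stats::var(t$value[!is.na(t$value)])
  if (!is.finite(vy) || vy == 0) vy <- 1
  stopifnot(r2 > 0, r2 < 1)
  meandiag <- vapply(cov$kernels, function(k) mean(diag(k)), numeric(1))
  S0 <- vy * (r2 / K) * (df0 + 2) / df0 / meandiag
  S0e <- vy * (1 - r2) * (df0 + 2) / df0
  if (update_var) {
    init_var <- S0
    init_var_e <- S0e
  } else {
    miss <- setdiff(c(terms, "e"), names(fix_components))
    if (length(miss))
      stop("fix_components must name all of: ",
           paste(c(terms, "e"), collapse = ", "))
    if (any(fix_components <= 0)) stop("fixed components must be > 0")
    init_var <- unname(fix_components[terms])
    init_var_e <- unname(fix_components[["e"]])
  }

  genetic <- as.integer(terms %in% c("L", "g", "gE"))
  raw <- .gibbs_core(y, is_obs, Phi, d, df0, S0, S0e,
                     as.integer(n_iter), as.integer(burn_in),
                     as.integer(thin), update_var, init_var, init_var_e,
                     genetic, store_gebv)

  samples <- raw$samples
  colnames(samples) <- c(paste0("var_", terms), "var_e", "mu")
  comp_cols <- seq_len(K + 1)
  components <- data.frame(
    term = c(terms, "e"),
    mean = colMeans(samples[, comp_cols, drop = FALSE]),
    sd = apply(samples[, comp_cols, drop = FALSE], 2, stats::sd),
    ess = apply(samples[, comp_cols, drop = FALSE], 2, .ess),
    row.names = NULL)

  effects <- raw$u_mean
  colnames(effects) <- terms
  gebv_rec <- rowSums(effects[, genetic == 1, drop = FALSE])
  cells <- cov$cells
  gebv <- data.frame(line = cov$records$line[cells],
                     environment = cov$records$environment[cells],
                     gebv = gebv_rec[cells],
                     stringsAsFactors = FALSE)

  structure(list(model = cov$model,
                 terms = terms,
                 components = components,
                 mu = mean(samples[, "mu"]),
                 gebv = gebv,
                 fitted = raw$eta_mean,
                 effects = effects,
                 samples = samples,
                 gebv_samples = raw$gebv_samples,
                 cells = cells,
                 settings = list(n_iter = n_iter, burn_in = burn_in,
                                 thin = thin, df0 = df0,
                                 update_var = update_var)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("reaction-norm GBLUP fit (%s), mu = %.3f\n", x$model, x$mu))
  comp <- x$components
  comp$mean <- round(comp$mean, 2)
  comp$sd <- round(comp$sd, 2)
  comp$ess <- round(comp$ess)
  print(comp, row.names = FALSE)
  invisible(x)
}

#' Closed-form mixed-model BLUP at fixed variance components
#'
#' Solves `y ~ N(mu 1, sum_k sigma2_k K_k + sigma2_e I)` exactly over the
#' observed records: GLS estimate of `mu`, then conditional means
#' `u_k = sigma2_k K_k[, obs] V^{-1} (y - mu)` for every record including
#' masked ones. Serves as the deterministic oracle for the Gibbs sampler.
#'
#' @param t A [phenotype_table()] (masked cells `NA`).
#' @param cov A `covariance_set` on the same records.
#' @param components Named numeric vector: one strictly positive variance
#'   per active term plus `"e"`.
#' @return List with `mu`, `effects` (record x term matrix), `gebv` (per
#'   cell, as in [fit_gibbs()]), `fitted`.
#' @export
closed_form_blup <- function(t, cov, components) {
  stopifnot(inherits(t, "phenotype_table"), inherits(cov, "covariance_set"))
  terms <- cov$terms
  need <- c(terms, "e")
  if (!all(need %in% names(components)))
    stop("components must name all of: ", paste(need, collapse = ", "))
  if (any(components[need] <= 0)) stop("components must be strictly positive")
  obs <- which(!is.na(t$value))
  if (length(obs) < 2) stop("need at least 2 observed records")
  y <- t$value[obs]
  n <- nrow(cov$records)

  V <- diag(components[["e"]], length(obs))
  for (k in terms)
    V <- V + components[[k]] * cov$kernels[[k]][obs, obs]
  Vi_y <- tryCatch(solve(V, cbind(y, 1)),
                   error = function(e) stop("singular mixed-model system: ",
                                            conditionMessage(e)))
  mu <- sum(Vi_y[, 1]) / sum(Vi_y[, 2])
  r <- solve(V, y - mu)

  effects <- matrix(0, n, length(terms), dimnames = list(NULL, terms))
  for (k in terms)
    effects[, k] <- components[[k]] * (cov$kernels[[k]][, obs] %*% r)

  genetic <- terms %in% c("L", "g", "gE")
  gebv_rec <- rowSums(effects[, genetic, drop = FALSE])
  cells <- cov$cells
  list(mu = mu,
       effects = effects,
       gebv = data.frame(line = cov$records$line[cells],
                         environment = cov$records$environment[cells],
                         gebv = gebv_rec[cells],
                         stringsAsFactors = FALSE),
       fitted = mu + rowSums(effects))
}

#' Percentages of within-environment variance
#'
#' Each of the line, genomic, genomic-by-environment and residual variances
#' divided by their sum — the environment variance is excluded — times 100.
#' Reported percentages are rounded to the nearest integer; unrounded
#' values are retained.
#'
#' @param components A named numeric vector with any of `L`, `g`, `gE`, `e`
#'   (an `E` entry is ignored), or a `fit_result`.
#' @return List with `percent` (rounded integers) and `unrounded`.
#' @export
variance_percentages <- function(components) {
  if (inherits(components, "fit_result"))
    components <- stats::setNames(components$components$mean,
                                  components$components$term)
  keep <- intersect(names(components), c("L", "g", "gE", "e"))
  if (!length(keep)) stop("no within-environment components among L, g, gE, e")
  v <- components[keep]
  if (any(v < 0)) stop("negative variance component")
  total <- sum(v)
  if (total == 0) stop("all within-environment components are zero")
  un <- 100 * v / total
  list(percent = round(un), unrounded = un)
}
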