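#' Genetic map for meiosis simulation
#'
#' Uniformly spaced marker positions on a configurable number of chromosomes.
#' Maize has 10 chromosomes; the default map uses 10 chromosomes of 1.5
#' Morgans each.
#'
#' @param n_markers Total marker count, split as evenly as possible across
#'   chromosomes.
#' @param n_chromosomes Number of chromosomes (default 10).
#' @param lengths Chromosome lengths in Morgans; recycled to
#'   `n_chromosomes`. Default 1.5 M.
#' @return A `genetic_map`: data.frame with columns `chrom`, `marker`,
#'   `pos` (Morgans), plus a `lengths` attribute.
#' @export
genetic_map <- function(n_markers, n_chromosomes = 10, lengths = 1.5) {
  stopifnot(n_markers >= 1, n_chromosomes >= 1)
  lengths <- rep_len(lengths, n_chromosomes)
  if (any(lengths <= 0)) stop("chromosome lengths must be > 0")
  per <- diff(round(seq(0, n_markers, length.out = n_chromosomes + 1)))
  rows <- lapply(seq_len(n_chromosomes), function(c) {
    k <- per[c]
    if (k == 0) return(NULL)
    pos <- lengths[c] * (seq_len(k) - 0.5) / k
    data.frame(chrom = c, pos = pos)
  })
  map <- do.call(rbind, rows)
  map$marker <- paste0("M", seq_len(nrow(map)))
  map <- map[, c("chrom", "marker", "pos")]
  structure(map, lengths = lengths, class = c("genetic_map", "data.frame"))
}

#' True simulation parameters
#'
#' Variance components and mean on the observed trait scale of kernel zinc
#' concentration (ug/g). Defaults are the full-data G-by-E model estimates
#' for a diverse tropical maize panel: mean 26.94 ug/g, environment 8.11,
#' line 2.47, genomic 10.03, genomic-by-environment 2.13, residual 4.92
#' (ug/g)^2.
#'
#' @param mu Overall trait mean (ug/g).
#' @param var_E,var_L,var_g,var_gE,var_e Variances of the environment, line,
#'   genomic, genomic-by-environment and residual terms, (ug/g)^2.
#' @param env_effects Optional fixed environment effects (numeric vector,
#'   one per environment); when `NULL` they are drawn `N(0, var_E)`.
#' @return A `true_parameters` list.
#' @export
true_parameters <- function(mu = 26.94, var_E = 8.11, var_L = 2.47,
                            var_g = 10.03, var_gE = 2.13, var_e = 4.92,
                            env_effects = NULL) {
  v <- c(var_E = var_E, var_L = var_L, var_g = var_g,
         var_gE = var_gE, var_e = var_e)
  if (any(v < 0)) stop("variances must be >= 0")
  structure(list(mu = mu, var_E = var_E, var_L = var_L, var_g = var_g,
                 var_gE = var_gE, var_e = var_e, env_effects = env_effects),
            class = "true_parameters")
}

#' Simulate genotypes for a structured inbred panel
#'
#' Balding-Nichols style model: each marker draws an ancestral frequency
#' from Uniform(0.05, 0.5); each subpopulation perturbs it through a Beta
#' distribution with divergence parameter `fst`; each inbred line is a
#' single haplotype doubled (calls 0/2), as for fully homozygous maize
#' inbreds.
#'
#' @param n_lines Number of inbred lines.
#' @param n_markers Number of markers.
#' @param n_subpop Number of subpopulations (default 5).
#' @param fst Divergence parameter in `[0, 1)`; 0 collapses all
#'   subpopulations onto the ancestral frequency. The default 0.2 gives a
#'   diffuse eigenvalue spectrum (about half the components are needed for
#'   80% of the genomic variance) while keeping enough relatedness
#'   structure that line, genomic and interaction variances are separable.
#' @param maf_range Range of the ancestral allele-frequency draw.
#' @param seed Optional integer seed.
#' @return A [marker_matrix()] with a `subpop` attribute giving each line's
#'   subpopulation label.
#' @export
simulate_panel_genotypes <- function(n_lines, n_markers, n_subpop = 5,
                                     fst = 0.2, maf_range = c(0.05, 0.5),
                                     seed = NULL) {
  if (n_lines < 1 || n_markers < 1 || n_subpop < 1)
    stop("n_lines, n_markers and n_subpop must be positive")
  if (fst < 0 || fst >= 1) stop("fst must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  p_anc <- stats::runif(n_markers, maf_range[1], maf_range[2])
  pops <- rep_len(seq_len(n_subpop), n_lines)
  freqs <- matrix(p_anc, nrow = n_subpop, ncol = n_markers, byrow = TRUE)
  if (fst > 0 && n_subpop > 1) {
    a <- (1 - fst) / fst
    for (s in seq_len(n_subpop))
      freqs[s, ] <- stats::rbeta(n_markers, p_anc * a, (1 - p_anc) * a)
  }
  hap <- matrix(stats::rbinom(n_lines * n_markers, 1, freqs[pops, ]),
                nrow = n_lines)
  calls <- 2 * hap
  dimnames(calls) <- list(paste0("L", seq_len(n_lines)),
                          paste0("M", seq_len(n_markers)))
  out <- marker_matrix(calls)
  attr(out, "subpop") <- pops
  out
}

# one gamete from an F1, Haldane model: crossovers ~ Poisson(length),
# uniform positions, alternating parental origin from a fair start
.f1_gamete <- function(map) {
  lens <- attr(map, "lengths")
  origin <- integer(nrow(map))
  for (c in unique(map$chrom)) {
    idx <- which(map$chrom == c)
    n_co <- stats::rpois(1, lens[c])
    start <- stats::rbinom(1, 1, 0.5)
    if (n_co == 0) {
      origin[idx] <- start
    } else {
      xo <- sort(stats::runif(n_co, 0, lens[c]))
      seg <- findInterval(map$pos[idx], xo)
      origin[idx] <- (start + seg) %% 2
    }
  }
  origin
}

#' Simulate a bi-parental doubled-haploid population
#'
#' Each DH line is a doubled F1 gamete: every chromosome is a mosaic of the
#' two parental haplotypes with crossover count Poisson in the chromosome
#' length (Haldane, no interference), then made fully homozygous. Parents
#' default to opposite homozygotes at every marker (calls 0 and 2).
#'
#' @param n_lines Number of DH lines (e.g. 112 and 143 for the two maize
#'   populations this generator emulates).
#' @param map A [genetic_map()]; its marker count fixes the marker count.
#' @param parents Optional 2 x n_markers matrix of parental calls; both rows
#'   must be homozygous (0 or 2).
#' @param seed Optional integer seed.
#' @return A [marker_matrix()] (calls 0/2 only) with a `parent_share`
#'   attribute: per-line fraction of alleles inherited from parent 2.
#' @export
simulate_dh_genotypes <- function(n_lines, map, parents = NULL, seed = NULL) {
  stopifnot(inherits(map, "genetic_map"), n_lines >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- nrow(map)
  if (is.null(parents))
    parents <- rbind(rep(0, p), rep(2, p))
  parents <- as.matrix(parents)
  if (nrow(parents) != 2 || ncol(parents) != p)
    stop("parents must be a 2 x n_markers matrix")
  if (!all(parents %in% c(0, 2)))
    stop("parents must be fully homozygous (calls 0 or 2)")
  calls <- matrix(0, n_lines, p,
                  dimnames = list(paste0("DH", seq_len(n_lines)), map$marker))
  share <- numeric(n_lines)
  for (i in seq_len(n_lines)) {
    origin <- .f1_gamete(map)
    calls[i, ] <- ifelse(origin == 1, parents[2, ], parents[1, ])
    share[i] <- mean(origin)
  }
  out <- marker_matrix(calls)
  attr(out, "parent_share") <- share
  out
}

#' Simulate multi-environment phenotypes from the reaction-norm model
#'
#' Draws records `y_ijr = mu + E_i + L_j + g_j + gE_ji + e_ijr` with
#' `E_i ~ N(0, var_E)` (or fixed effects if supplied), `L_j ~ N(0, var_L)`,
#' genomic values `g = X b` for centred calls X and marker effects
#' `b ~ N(0, var_g / p)` (so `Cov(g) = G var_g` for `G = XX'/p`), the
#' interaction drawn exactly from its model covariance — independent
#' `N(0, G var_gE)` vectors per environment, via an eigen factor of G with
#' 1e-8 diagonal jitter — and iid residuals. Replicates within a cell share
#' every term except the residual.
#'
#' @param markers A complete (no missing) [marker_matrix()].
#' @param params A [true_parameters()] object.
#' @param n_env Number of environments (default 3).
#' @param n_reps Replicates per environment; recycled to `n_env`. Default 1.
#' @param seed Optional integer seed.
#' @return A [phenotype_table()] with attribute `truth`: list of the drawn
#'   `env_effects`, `line_effects`, `genomic_values`, `gxe` (line x env
#'   matrix), and the `grm` used.
#' @export
simulate_phenotypes <- function(markers, params = true_parameters(),
                                n_env = 3, n_reps = 1, seed = NULL) {
  stopifnot(inherits(markers, "marker_matrix"),
            inherits(params, "true_parameters"))
  if (anyNA(markers$calls)) stop("markers must be complete (no missing calls)")
  if (n_env < 1) stop("n_env must be positive")
  n_reps <- rep_len(n_reps, n_env)
  if (any(n_reps < 1)) stop("n_reps must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(markers$calls)
  p <- ncol(markers$calls)
  lines <- markers$line_ids
  envs <- paste0("Env", seq_len(n_env))

  E <- if (!is.null(params$env_effects)) {
    if (length(params$env_effects) != n_env)
      stop("env_effects length must equal n_env")
    params$env_effects
  } else stats::rnorm(n_env, 0, sqrt(params$var_E))
  L <- stats::rnorm(n, 0, sqrt(params$var_L))

  X <- sweep(markers$calls, 2, colMeans(markers$calls), "-")
  b <- stats::rnorm(p, 0, sqrt(params$var_g / p))
  g <- as.vector(X %*% b)

  G <- tcrossprod(X) / p
  gE <- matrix(0, n, n_env)
  if (params$var_gE > 0) {
    eg <- eigen(G + diag(1e-8, n), symmetric = TRUE)
    fac <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), n)
    for (i in seq_len(n_env))
      gE[, i] <- sqrt(params$var_gE) * as.vector(fac %*% stats::rnorm(n))
  }

  rows <- vector("list", n_env)
  for (i in seq_len(n_env)) {
    cell <- params$mu + E[i] + L + g + gE[, i]
    reps <- lapply(seq_len(n_reps[i]), function(r)
      data.frame(line = lines, environment = envs[i], replicate = r,
                 value = cell + stats::rnorm(n, 0, sqrt(params$var_e)),
                 stringsAsFactors = FALSE))
    rows[[i]] <- do.call(rbind, reps)
  }
  tab <- phenotype_table(do.call(rbind, rows))
  attr(tab, "truth") <- list(env_effects = stats::setNames(E, envs),
                             line_effects = stats::setNames(L, lines),
                             genomic_values = stats::setNames(g, lines),
                             gxe = `dimnames<-`(gE, list(lines, envs)),
                             grm = G)
  tab
}
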