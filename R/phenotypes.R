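#' Long-format phenotype table
#'
#' Trial records of one trait value per (line, environment, replicate).
#' Values are on the observed trait scale (ug/g for kernel zinc).
#'
#' @param records data.frame with columns `line`, `environment`,
#'   `replicate`, `value`. Masked records may carry `NA` values; duplicate
#'   (line, environment, replicate) keys are an error.
#' @return A `phenotype_table` (data.frame subclass).
#' @export
phenotype_table <- function(records) {
  need <- c("line", "environment", "replicate", "value")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  records <- as.data.frame(records)[, need]
  records$line <- as.character(records$line)
  records$environment <- as.character(records$environment)
  key <- paste(records$line, records$environment, records$replicate)
  if (anyDuplicated(key)) stop("duplicate (line, environment, replicate) keys")
  if (any(!is.finite(records$value) & !is.na(records$value)))
    stop("non-finite trait values")
  class(records) <- c("phenotype_table", "data.frame")
  records
}

#' Read a phenotype CSV (columns line, environment, replicate, value)
#' @param path Input path.
#' @return A [phenotype_table()].
#' @export
read_phenotypes <- function(path) {
  phenotype_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a phenotype table to CSV
#' @param t A [phenotype_table()].
#' @param path Output path.
#' @export
write_phenotypes <- function(t, path) {
  utils::write.csv(as.data.frame(t), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Adjusted line means (BLUEs) per environment
#'
#' Within each environment, line means adjusted for a random replicate
#' effect: a mixed model with fixed line effects and a random intercept per
#' replicate (replications nested within environment). With a single
#' replicate, or perfectly balanced data, the BLUE reduces to the arithmetic
#' cell mean; the mixed model is only fitted for unbalanced multi-replicate
#' environments.
#'
#' @param t A [phenotype_table()].
#' @return data.frame `line`, `environment`, `value` (one BLUE per observed
#'   cell).
#' @export
compute_blues <- function(t) {
  stopifnot(inherits(t, "phenotype_table"))
  t <- t[!is.na(t$value), ]
  out <- lapply(unique(t$environment), function(env) {
    d <- t[t$environment == env, ]
    if (nrow(d) == 0) {
      warning("environment with zero records skipped: ", env)
      return(NULL)
    }
    reps_per_cell <- table(d$line)
    balanced <- length(unique(d$replicate)) == 1 ||
      (length(unique(reps_per_cell)) == 1 &&
         nrow(d) == length(unique(d$line)) * length(unique(d$replicate)))
    if (balanced) {
      mu <- tapply(d$value, d$line, mean)
      data.frame(line = names(mu), environment = env, value = as.vector(mu),
                 stringsAsFactors = FALSE)
    } else {
      fit <- suppressMessages(suppressWarnings(
        lme4::lmer(value ~ 0 + line + (1 | replicate), data = d,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))))
      be <- lme4::fixef(fit)
      data.frame(line = sub("^line", "", names(be)), environment = env,
                 value = as.vector(be), stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Between-environment phenotypic correlations
#'
#' Pearson correlation of per-line means between each pair of environments,
#' over lines observed in both. Pairs sharing fewer than 3 lines are
#' undefined (`NA`) and flagged.
#'
#' @param means data.frame with columns `line`, `environment`, `value`
#'   ([compute_blues()] output, or any per-cell means).
#' @return Environment x environment correlation matrix with unit diagonal
#'   and an attribute `flagged` listing undefined pairs.
#' @export
env_correlations <- function(means) {
  envs <- unique(means$environment)
  wide <- stats::reshape(means[, c("line", "environment", "value")],
                         idvar = "line", timevar = "environment",
                         direction = "wide")
  colnames(wide) <- sub("^value\\.", "", colnames(wide))
  m <- as.matrix(wide[, envs, drop = FALSE])
  out <- diag(1, length(envs))
  dimnames(out) <- list(envs, envs)
  flagged <- character(0)
  for (i in seq_along(envs)) for (j in seq_along(envs)) {
    if (i >= j) next
    ok <- stats::complete.cases(m[, c(i, j)])
    if (sum(ok) < 3) {
      out[i, j] <- out[j, i] <- NA
      flagged <- c(flagged, paste(envs[i], envs[j], sep = ":"))
    } else {
      out[i, j] <- out[j, i] <- stats::cor(m[ok, i], m[ok, j])
    }
  }
  attr(out, "flagged") <- flagged
  out
}

#' Broad-sense heritability across environments
#'
#' `H^2 = var_G / (var_G + var_GE / l + var_e / (l r))` for `l`
#' environments and `r` replications.
#'
#' @param var_G,var_GE,var_e Genotypic, genotype-by-environment and residual
#'   variances (>= 0).
#' @param l Number of environments.
#' @param r Number of replications.
#' @return A `heritability` list (`kind`, `value`, `components`, `l`, `r`).
#' @export
broad_sense_h2 <- function(var_G, var_GE, var_e, l, r) {
  stopifnot(var_G >= 0, var_GE >= 0, var_e >= 0, l >= 1, r >= 1)
  denom <- var_G + var_GE / l + var_e / (l * r)
  if (denom == 0) stop("all variance components are zero")
  structure(list(kind = "broad", value = var_G / denom,
                 components = c(var_G = var_G, var_GE = var_GE, var_e = var_e),
                 l = l, r = r),
            class = "heritability")
}

#' Narrow-sense heritability from genomic components
#'
#' `h^2 = var_g / (var_g + var_e)` with `var_g` the additive (genomic)
#' variance and `var_e` the residual variance.
#'
#' @param var_g Additive genetic variance (>= 0).
#' @param var_e Residual variance (>= 0).
#' @return A `heritability` list.
#' @export
narrow_sense_h2 <- function(var_g, var_e) {
  stopifnot(var_g >= 0, var_e >= 0)
  if (var_g + var_e == 0) stop("var_g and var_e cannot both be zero")
  structure(list(kind = "narrow", value = var_g / (var_g + var_e),
                 components = c(var_g = var_g, var_e = var_e)),
            class = "heritability")
}

#' @export
print.heritability <- function(x, ...) {
  cat(sprintf("%s-sense heritability: %.3f\n", x$kind, x$value))
  invisible(x)
}

#' Descriptive statistics per environment and across environments
#'
#' Mean, standard error (SD/sqrt(n)), minimum, maximum and record count per
#' environment, plus an `Across` row over all records. Single-record groups
#' report SE 0 with `se_defined = FALSE`.
#'
#' @param t A [phenotype_table()].
#' @return data.frame with columns `environment`, `n`, `mean`, `se`, `min`,
#'   `max`, `se_defined`.
#' @export
descriptive_stats <- function(t) {
  stopifnot(inherits(t, "phenotype_table"))
  t <- t[!is.na(t$value), ]
  if (nrow(t) == 0) stop("empty phenotype table")
  one <- function(v, label) {
    n <- length(v)
    data.frame(environment = label, n = n, mean = mean(v),
               se = if (n > 1) stats::sd(v) / sqrt(n) else 0,
               min = min(v), max = max(v), se_defined = n > 1,
               stringsAsFactors = FALSE)
  }
  sp <- split(t$value, t$environment)
  per <- do.call(rbind, Map(one, sp, names(sp)))
  out <- rbind(per, one(t$value, "Across"))
  rownames(out) <- NULL
  out
}

#' Box plot of trait values by environment
#'
#' @param t A [phenotype_table()].
#' @param path Optional PNG path; when given the plot is written there.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot_phenotypes <- function(t, path = NULL, ...) {
  stopifnot(inherits(t, "phenotype_table"))
  draw <- function() graphics::boxplot(value ~ environment, data = t,
                                       ylab = "trait value", ...)
  if (!is.null(path)) {
    grDevices::png(path, width = 720, height = 480)
    on.exit(grDevices::dev.off())
    draw()
    invisible(path)
  } else draw()
}
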