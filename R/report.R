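#' Standardised selection intensity for truncation selection
#'
#' `i = phi(z_p) / p` where `z_p` is the standard-normal truncation point
#' leaving the top fraction `p` selected.
#'
#' @param p Selected proportion, in (0, 1).
#' @return Selection intensity (standardised selection differential).
#' @export
selection_intensity <- function(p) {
  if (any(p <= 0 | p >= 1)) stop("selected proportion must be in (0, 1)")
  stats::dnorm(stats::qnorm(p, lower.tail = FALSE)) / p
}

#' Expected mean of the selected fraction after genomic selection
#'
#' Breeder's-equation projection: `population_mean + i * r * sqrt(var_g)`
#' with selection intensity `i` from the selected proportion, prediction
#' accuracy `r`, and genetic variance `var_g`.
#'
#' @param population_mean Trait mean of the candidate population (ug/g).
#' @param var_g Genetic variance of the candidates, (ug/g)^2.
#' @param accuracy Prediction accuracy (correlation), in `[-1, 1]`.
#' @param selected_proportion Fraction selected, in (0, 1).
#' @return Expected trait mean of the selected fraction (ug/g).
#' @export
expected_selected_mean <- function(population_mean, var_g, accuracy,
                                   selected_proportion) {
  if (var_g < 0) stop("var_g must be >= 0")
  population_mean +
    selection_intensity(selected_proportion) * accuracy * sqrt(var_g)
}

.fmt_pm <- function(m, s, digits = 2) sprintf("%.*f ± %.*f", digits, m,
                                              digits, s)

#' Render a variance-component table
#'
#' One column of `estimate ± SD` per fitted model plus integer percentage
#' columns of the within-environment variance (environment excluded from
#' the percentage base). Unrounded values are attached for round-tripping.
#'
#' @param fits Named list of `fit_result` objects (names become column
#'   labels, e.g. `list(M1 = ..., M3 = ...)`).
#' @return data.frame with a `source` column (E, L, g, gE, e) and, per
#'   model, `<name>` and `<name>_pct` columns; attribute `unrounded` holds
#'   the raw numbers.
#' @export
render_variance_table <- function(fits) {
  if (!length(fits)) stop("no fits supplied")
  if (is.null(names(fits))) names(fits) <- paste0("fit", seq_along(fits))
  sources <- c("E", "L", "g", "gE", "e")
  out <- data.frame(source = sources, stringsAsFactors = FALSE)
  un <- list()
  for (nm in names(fits)) {
    f <- fits[[nm]]
    comp <- stats::setNames(f$components$mean, f$components$term)
    sds <- stats::setNames(f$components$sd, f$components$term)
    pct <- variance_percentages(comp)
    est_col <- pct_col <- rep("—", length(sources))
    for (i in seq_along(sources)) {
      s <- sources[i]
      if (s %in% names(comp)) {
        est_col[i] <- .fmt_pm(comp[[s]], sds[[s]])
        if (s %in% names(pct$percent)) pct_col[i] <- as.character(pct$percent[[s]])
      }
    }
    out[[nm]] <- est_col
    out[[paste0(nm, "_pct")]] <- pct_col
    un[[nm]] <- list(mean = comp, sd = sds, pct = pct$unrounded)
  }
  attr(out, "unrounded") <- un
  out
}

#' Render a prediction-ability table
#'
#' Per-environment rows of `mean ± SD` correlations with a bold `Average`
#' row, one column per (model, scheme) result.
#'
#' @param cvs Named list of `cv_result` objects.
#' @return data.frame with `environment` plus one formatted column per
#'   result; attribute `unrounded` holds the summary numbers.
#' @export
render_cv_table <- function(cvs) {
  if (!length(cvs)) stop("no cross-validation results supplied")
  if (is.null(names(cvs)))
    names(cvs) <- vapply(cvs, function(x) paste(x$model, x$scheme, sep = "_"),
                         character(1))
  sums <- lapply(cvs, summarize_rmp)
  envs <- unique(unlist(lapply(sums, function(s) s$environment)))
  envs <- c(setdiff(envs, "Average"), "Average")
  out <- data.frame(environment = ifelse(envs == "Average", "**Average**",
                                         envs),
                    stringsAsFactors = FALSE)
  for (nm in names(sums)) {
    s <- sums[[nm]]
    col <- vapply(envs, function(e) {
      row <- s[s$environment == e, ]
      if (!nrow(row)) return("—")
      v <- .fmt_pm(row$r_mean, row$r_sd)
      if (e == "Average") paste0("**", v, "**") else v
    }, character(1))
    out[[nm]] <- col
  }
  attr(out, "unrounded") <- sums
  out
}

#' Parse `estimate ± SD` cells back to numbers
#'
#' @param x Character vector of `m ± s` strings (em dashes give `NA`).
#' @return data.frame with columns `mean` and `sd`.
#' @export
parse_pm <- function(x) {
  x <- gsub("\\*", "", x)
  parts <- strsplit(x, "±", fixed = TRUE)
  data.frame(mean = vapply(parts, function(p)
    suppressWarnings(as.numeric(trimws(p[1]))), numeric(1)),
    sd = vapply(parts, function(p)
      if (length(p) > 1) suppressWarnings(as.numeric(trimws(p[2])))
      else NA_real_, numeric(1)))
}

#' Write a data.frame as a Markdown pipe table
#'
#' @param df data.frame of display values.
#' @param path Output path.
#' @export
write_markdown_table <- function(df, path) {
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                          " |"))
  writeLines(c(header, sep, body), path)
  invisible(path)
}

#' Run a full pipeline from a YAML (or list) configuration
#'
#' Orchestrates the stages: `simulate` (panel or DH genotypes plus
#' phenotypes), `grm` (filter, impute, relationship matrix), `fit` (full-data
#' Gibbs fits per model), `cv` (CV1/CV2 prediction ability) and `report`
#' (rendered tables, selection projection). Every stage is optional; outputs
#' are written under `output_dir` when it is set.
#'
#' @param config Path to a YAML file or a named list. Recognised blocks:
#'   `simulate: {population_kind, n_lines, n_markers, n_environments,
#'   n_replicates, variances: {E, L, g, gE, e}, mu, seed}`,
#'   `grm: {maf_min, missing_max}`, `fit: {models, mcmc: {n_iter, burn_in,
#'   thin, seed}}`, `cv: {schemes, models, n_folds, n_repeats, seed, mcmc}`,
#'   `report: {selected_proportion}`, `output_dir`.
#' @return List with the objects produced per stage.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  out <- list()
  dir_out <- cfg$output_dir
  if (!is.null(dir_out) && !dir.exists(dir_out))
    dir.create(dir_out, recursive = TRUE)

  if (!is.null(cfg$simulate)) {
    s <- cfg$simulate
    kind <- if (is.null(s$population_kind)) "panel" else s$population_kind
    markers <- if (kind == "panel")
      simulate_panel_genotypes(s$n_lines, s$n_markers,
                               n_subpop = s$n_subpop %||% 3,
                               fst = s$fst %||% 0.05, seed = s$seed)
    else
      simulate_dh_genotypes(s$n_lines, genetic_map(s$n_markers),
                            seed = s$seed)
    v <- s$variances %||% list()
    params <- true_parameters(mu = s$mu %||% 26.94,
                              var_E = v$E %||% 8.11, var_L = v$L %||% 2.47,
                              var_g = v$g %||% 10.03,
                              var_gE = v$gE %||% 2.13,
                              var_e = v$e %||% 4.92)
    phen <- simulate_phenotypes(markers, params,
                                n_env = s$n_environments %||% 3,
                                n_reps = s$n_replicates %||% 1,
                                seed = (s$seed %||% 1) + 1L)
    out$markers <- markers
    out$phenotypes <- phen
    if (!is.null(dir_out)) {
      write_genotypes_csv(markers, file.path(dir_out, "genotypes.csv"))
      write_phenotypes(phen, file.path(dir_out, "phenotypes.csv"))
    }
  }

  if (!is.null(cfg$grm) || !is.null(out$markers)) {
    gcf <- cfg$grm %||% list()
    m <- out$markers
    if (!is.null(gcf$path)) m <- read_genotypes(gcf$path,
                                                gcf$format %||% "csv")
    m <- filter_markers(m, gcf$maf_min %||% 0.05, gcf$missing_max %||% 0.10)
    m <- impute_missing(m)
    out$grm <- compute_grm(m)
    if (!is.null(dir_out))
      utils::write.csv(as.data.frame(unclass(out$grm)),
                       file.path(dir_out, "grm.csv"))
  }

  if (!is.null(cfg$fit)) {
    f <- cfg$fit
    mc <- f$mcmc %||% list()
    cov_by_model <- list()
    out$fits <- list()
    for (mod in (f$models %||% "M3")) {
      cov_by_model[[mod]] <- build_covariances(out$phenotypes, out$grm,
                                               model = mod)
      out$fits[[mod]] <- fit_gibbs(out$phenotypes, cov_by_model[[mod]],
                                   n_iter = mc$n_iter %||% 12000,
                                   burn_in = mc$burn_in %||% 2000,
                                   thin = mc$thin %||% 5,
                                   seed = mc$seed %||% 1)
    }
    out$covariances <- cov_by_model
  }

  if (!is.null(cfg$cv)) {
    cvc <- cfg$cv
    mc <- cvc$mcmc %||% list()
    out$cv <- list()
    for (mod in (cvc$models %||% "M3")) {
      cov <- out$covariances[[mod]] %||%
        build_covariances(out$phenotypes, out$grm, model = mod)
      for (sch in (cvc$schemes %||% c("CV1", "CV2"))) {
        plan <- cv_plan(sch, cvc$n_folds %||% 5, cvc$n_repeats %||% 20,
                        cvc$seed %||% 1)
        out$cv[[paste(mod, sch, sep = "_")]] <-
          run_cross_validation(out$phenotypes, cov, plan,
                               n_iter = mc$n_iter %||% 4000,
                               burn_in = mc$burn_in %||% 1000)
      }
    }
  }

  if (!is.null(cfg$report)) {
    rp <- cfg$report %||% list()
    if (!is.null(out$fits)) {
      out$variance_table <- render_variance_table(out$fits)
      if (!is.null(dir_out))
        utils::write.csv(out$variance_table,
                         file.path(dir_out, "variance_components.csv"),
                         row.names = FALSE)
    }
    if (!is.null(out$cv) && length(out$cv)) {
      out$cv_table <- render_cv_table(out$cv)
      if (!is.null(dir_out))
        utils::write.csv(out$cv_table,
                         file.path(dir_out, "prediction_ability.csv"),
                         row.names = FALSE)
    }
    if (!is.null(out$fits) && !is.null(out$phenotypes)) {
      fit <- out$fits[[length(out$fits)]]
      comp <- stats::setNames(fit$components$mean, fit$components$term)
      var_g <- sum(comp[intersect(c("L", "g"), names(comp))])
      acc <- if (!is.null(out$cv) && length(out$cv)) {
        s <- summarize_rmp(out$cv[[length(out$cv)]])
        s$r_mean[s$environment == "Average"]
      } else NA_real_
      if (is.finite(acc))
        out$selection <- data.frame(
          population_mean = mean(out$phenotypes$value, na.rm = TRUE),
          var_g = var_g, accuracy = acc,
          selected_proportion = rp$selected_proportion %||% 0.10,
          expected_mean = expected_selected_mean(
            mean(out$phenotypes$value, na.rm = TRUE), var_g, acc,
            rp$selected_proportion %||% 0.10))
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
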