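#' Cross-validation plan
#'
#' @param scheme `"CV1"` (validation lines unobserved in every environment)
#'   or `"CV2"` (sparse testing: each validation line missing in exactly one
#'   environment).
#' @param n_folds Folds per repeat (default 5, i.e. 80/20 splits).
#' @param n_repeats Number of repeats (default 20, so 100 runs).
#' @param seed Integer seed; run `r` uses `seed + r` so any single run can
#'   be replayed.
#' @return A `cv_plan` list.
#' @export
cv_plan <- function(scheme = c("CV1", "CV2"), n_folds = 5, n_repeats = 20,
                    seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(n_folds >= 2, n_repeats >= 1)
  structure(list(scheme = scheme, n_folds = n_folds, n_repeats = n_repeats,
                 seed = as.integer(seed)),
            class = "cv_plan")
}

# partition of lines into near-equal folds for one repeat
.fold_lines <- function(lines, n_folds) {
  perm <- sample(lines)
  split(perm, rep_len(seq_len(n_folds), length(perm)))
}

#' CV1 masks: whole lines hidden from training
#'
#' Per repeat, lines are randomly partitioned into `n_folds` near-equal
#' subsets; each subset in turn is the validation set and all of its
#' (line, environment) cells are masked.
#'
#' @param lines Character vector of line identifiers.
#' @param plan A [cv_plan()] (scheme `"CV1"`).
#' @param environments Environment identifiers used to enumerate masked
#'   cells.
#' @return List of masks; each has `run`, `repeat_id`, `fold`, `lines`
#'   (validation lines) and `cells` (data.frame line, environment).
#' @export
make_cv1_folds <- function(lines, plan, environments) {
  lines <- unique(as.character(lines))
  if (length(lines) < plan$n_folds)
    stop("fewer lines than folds")
  masks <- list()
  run <- 0L
  for (r in seq_len(plan$n_repeats)) {
    set.seed(plan$seed + r)
    folds <- .fold_lines(lines, plan$n_folds)
    for (f in seq_len(plan$n_folds)) {
      run <- run + 1L
      val <- folds[[f]]
      masks[[run]] <- list(run = run, repeat_id = r, fold = f, lines = val,
                           cells = expand.grid(line = val,
                                               environment = environments,
                                               stringsAsFactors = FALSE))
    }
  }
  masks
}

#' CV2 masks: each validation line missing in exactly one environment
#'
#' Validation folds are drawn as in CV1, but each validation line keeps all
#' of its observed environments except one; the masked environment is
#' allocated round-robin so every environment is missing for about
#' `1/n_env` of the validation lines. Lines observed in fewer than two
#' environments are excluded with a warning.
#'
#' @param cells data.frame of observed (line, environment) pairs.
#' @param plan A [cv_plan()] (scheme `"CV2"`).
#' @return List of masks as in [make_cv1_folds()], with one masked cell per
#'   validation line.
#' @export
make_cv2_masks <- function(cells, plan) {
  envs <- unique(cells$environment)
  per_line <- split(as.character(cells$environment), as.character(cells$line))
  eligible <- names(per_line)[lengths(per_line) >= 2]
  dropped <- setdiff(names(per_line), eligible)
  if (length(dropped))
    warning("lines observed in a single environment excluded: ",
            paste(dropped, collapse = ", "))
  if (length(eligible) < plan$n_folds) stop("fewer eligible lines than folds")
  masks <- list()
  run <- 0L
  for (r in seq_len(plan$n_repeats)) {
    set.seed(plan$seed + r)
    folds <- .fold_lines(eligible, plan$n_folds)
    for (f in seq_len(plan$n_folds)) {
      run <- run + 1L
      val <- folds[[f]]
      masked_env <- character(length(val))
      for (i in seq_along(val)) {
        # rotate the round-robin start by fold so the allocation is also
        # balanced across the folds of a repeat
        pref <- envs[(i + f - 2) %% length(envs) + 1]
        avail <- per_line[[val[i]]]
        masked_env[i] <- if (pref %in% avail) pref else
          avail[(i + f - 2) %% length(avail) + 1]
      }
      masks[[run]] <- list(run = run, repeat_id = r, fold = f, lines = val,
                           cells = data.frame(line = val,
                                              environment = masked_env,
                                              stringsAsFactors = FALSE))
    }
  }
  masks
}

# set masked cells' values to NA
.apply_mask <- function(t, cells) {
  key <- paste(t$line, t$environment)
  t$value[key %in% paste(cells$line, cells$environment)] <- NA
  t
}

#' Run a CV1/CV2 cross-validation experiment
#'
#' For each run, masked cells are removed from the likelihood (set `NA`),
#' the model is refitted on the remaining records, masked cells are
#' predicted, and the Pearson correlation between observed values and
#' predicted genetic values is computed within each environment over that
#' run's masked cells — the prediction ability r_MP once averaged over
#' runs.
#'
#' @param t A [phenotype_table()] (per-environment BLUEs for a panel, raw
#'   records for DH populations).
#' @param cov A `covariance_set` built on `t` ([build_covariances()]).
#' @param plan A [cv_plan()].
#' @param engine `"gibbs"` refits the Bayesian model each run (reduced
#'   default budget `n_iter` 4000 / `burn_in` 1000); `"blup"` uses the
#'   exact mixed-model solution at fixed variance components (`components`
#'   required), which is deterministic and fast.
#' @param components Named variances for `engine = "blup"`.
#' @param n_iter,burn_in,thin Sampler budget per run for `engine = "gibbs"`.
#' @param min_cells Minimum masked cells per (run, environment) for a
#'   correlation; sparser combinations are skipped with a message.
#' @return A `cv_result`: data.frame `runs` with one row per
#'   (run, environment): `run`, `repeat_id`, `fold`, `environment`, `r`,
#'   `n_cells`, plus attributes `scheme` and `model`.
#' @export
run_cross_validation <- function(t, cov, plan, engine = c("gibbs", "blup"),
                                 components = NULL, n_iter = 4000,
                                 burn_in = 1000, thin = 5, min_cells = 3) {
  stopifnot(inherits(t, "phenotype_table"), inherits(cov, "covariance_set"),
            inherits(plan, "cv_plan"))
  engine <- match.arg(engine)
  if (engine == "blup" && is.null(components))
    stop("engine = 'blup' needs fixed variance components")
  observed <- t[!is.na(t$value), ]
  cell_means <- stats::aggregate(value ~ line + environment, observed, mean)
  masks <- if (plan$scheme == "CV1")
    make_cv1_folds(unique(observed$line), plan,
                   environments = unique(observed$environment))
  else
    make_cv2_masks(unique(cell_means[, c("line", "environment")]), plan)

  rows <- list()
  for (m in masks) {
    tm <- .apply_mask(t, m$cells)
    gebv <- if (engine == "gibbs")
      fit_gibbs(tm, cov, n_iter = n_iter, burn_in = burn_in, thin = thin,
                seed = plan$seed + 1000L * m$run)$gebv
    else
      closed_form_blup(tm, cov, components)$gebv
    pred <- merge(m$cells, gebv, by = c("line", "environment"))
    pred <- merge(pred, cell_means, by = c("line", "environment"))
    for (env in unique(pred$environment)) {
      d <- pred[pred$environment == env, ]
      if (nrow(d) < min_cells) {
        message(sprintf("run %d, %s: %d masked cells (< %d), skipped",
                        m$run, env, nrow(d), min_cells))
        next
      }
      rows[[length(rows) + 1]] <-
        data.frame(run = m$run, repeat_id = m$repeat_id, fold = m$fold,
                   environment = env, r = stats::cor(d$value, d$gebv),
                   n_cells = nrow(d), stringsAsFactors = FALSE)
    }
  }
  runs <- do.call(rbind, rows)
  structure(list(runs = runs, scheme = plan$scheme, model = cov$model,
                 plan = plan),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cross-validation %s, model %s: %d runs\n", x$scheme, x$model,
              length(unique(x$runs$run))))
  print(summarize_rmp(x), row.names = FALSE)
  invisible(x)
}

#' Summarise prediction ability r_MP
#'
#' Mean and SD of the per-run within-environment correlations, one row per
#' environment plus an `Average` row (the mean over runs of the per-run
#' environment average, matching how multi-environment prediction tables
#' report their bold average line).
#'
#' @param result A `cv_result`, or a data.frame of runs with columns
#'   `environment`, `run`, `r`.
#' @return data.frame `environment`, `r_mean`, `r_sd`, `n_runs`.
#' @export
summarize_rmp <- function(result) {
  runs <- if (inherits(result, "cv_result")) result$runs else result
  per_env <- do.call(rbind, lapply(split(runs, runs$environment), function(d)
    data.frame(environment = d$environment[1], r_mean = mean(d$r),
               r_sd = if (nrow(d) > 1) stats::sd(d$r) else 0,
               n_runs = nrow(d), stringsAsFactors = FALSE)))
  run_avg <- tapply(runs$r, runs$run, mean)
  avg <- data.frame(environment = "Average", r_mean = mean(run_avg),
                    r_sd = if (length(run_avg) > 1) stats::sd(run_avg) else 0,
                    n_runs = length(run_avg), stringsAsFactors = FALSE)
  out <- rbind(per_env, avg)
  rownames(out) <- NULL
  out
}
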