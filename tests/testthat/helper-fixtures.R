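# small programmatic fixtures shared across test files

# phenotype table with one record per (line, environment)
cell_table <- function(values, lines = NULL, envs = NULL) {
  values <- as.matrix(values)
  if (is.null(lines)) lines <- paste0("L", seq_len(nrow(values)))
  if (is.null(envs)) envs <- paste0("Env", seq_len(ncol(values)))
  phenotype_table(data.frame(
    line = rep(lines, times = ncol(values)),
    environment = rep(envs, each = nrow(values)),
    replicate = 1L,
    value = as.vector(values)))
}

# small complete marker matrix with given dimensions, codes 0/2
random_inbred_markers <- function(n_lines, n_markers, seed = 1) {
  set.seed(seed)
  marker_matrix(matrix(2 * rbinom(n_lines * n_markers, 1, 0.4),
                       n_lines, n_markers))
}

# writes a temporary genotype CSV and returns its path
write_temp_csv <- function(calls) {
  path <- tempfile(fileext = ".csv")
  df <- data.frame(line = rownames(calls), calls, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
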