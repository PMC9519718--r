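#' Assemble a multi-environment trial dataset from plot-level phenotypes
#'
#' Validates and indexes a plot-level phenotype table for downstream model
#' fitting. Each row is one field plot identified by environment, trial within
#' environment, replicate block within trial and genotype, with a numeric trait
#' value (`NA` for a missing plot). Missing plots are retained and flagged, so
#' per-environment plot counts mirror the usual MET summary tables.
#'
#' Factor levels are indexed in first-appearance order unless an explicit order
#' is supplied; all loading and score vectors produced downstream are
#' order-sensitive, so the level order is stored on the returned object.
#'
#' @param plots A data frame with columns `env`, `trial`, `block`, `genotype`
#'   and `value` (numeric trait value, `NA` allowed).
#' @param env_levels,genotype_levels Optional character vectors fixing the
#'   level order of environments and genotypes. Must cover all ids present.
#'
#' @return A `met_data` object: a list with `plots` (a tibble with index
#'   columns and a `missing` flag), `p`, `v`, `n` (non-missing plots), `n_j`
#'   (named per-environment non-missing counts), `envs`, `genotypes`, and
#'   `blocks` (the unique env/trial/block combinations).
#' @export
#' @examples
#' plots <- expand.grid(env = c("E1", "E2"), trial = "T1", block = c("B1", "B2"),
#'                      genotype = paste0("G", 1:3), stringsAsFactors = FALSE)
#' plots$value <- rnorm(nrow(plots))
#' met <- load_met_dataset(plots)
#' met$n_j
load_met_dataset <- function(plots, env_levels = NULL, genotype_levels = NULL) {
  required <- c("env", "trial", "block", "genotype", "value")
  missing_cols <- setdiff(required, names(plots))
  assert_that(length(missing_cols) == 0L,
              paste0("phenotype table lacks column(s): ",
                     paste(missing_cols, collapse = ", ")),
              class = "metfa_input_error")
  plots <- tibble::as_tibble(plots)[required]
  assert_that(is.numeric(plots$value) || all(is.na(plots$value)),
              "trait values must be numeric or missing",
              class = "metfa_input_error")
  plots$value <- as.numeric(plots$value)
  for (cc in c("env", "trial", "block", "genotype")) {
    plots[[cc]] <- as.character(plots[[cc]])
    assert_that(!anyNA(plots[[cc]]),
                paste0("column '", cc, "' contains missing ids"),
                class = "metfa_input_error")
  }

  key <- paste(plots$env, plots$trial, plots$block, plots$genotype, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    first_dup <- plots[which(dup)[1L], c("env", "trial", "block", "genotype")]
    stop_metfa(paste0("duplicated plot row for (env=", first_dup$env,
                      ", trial=", first_dup$trial, ", block=", first_dup$block,
                      ", genotype=", first_dup$genotype, ")"),
               class = "metfa_duplicate_error")
  }

  envs <- resolve_levels(plots$env, env_levels, "environment")
  genotypes <- resolve_levels(plots$genotype, genotype_levels, "genotype")

  plots$env_idx <- match(plots$env, envs)
  plots$geno_idx <- match(plots$genotype, genotypes)
  block_key <- paste(plots$env, plots$trial, plots$block, sep = "\r")
  blocks_tbl <- tibble::tibble(key = unique(block_key))
  parts <- strsplit(blocks_tbl$key, "\r", fixed = TRUE)
  blocks_tbl$env <- vapply(parts, `[[`, character(1L), 1L)
  blocks_tbl$trial <- vapply(parts, `[[`, character(1L), 2L)
  blocks_tbl$block <- vapply(parts, `[[`, character(1L), 3L)
  blocks_tbl$env_idx <- match(blocks_tbl$env, envs)
  blocks_tbl <- blocks_tbl[order(blocks_tbl$env_idx, blocks_tbl$trial, blocks_tbl$block), ]
  blocks_tbl$block_idx <- seq_len(nrow(blocks_tbl))
  plots$block_idx <- blocks_tbl$block_idx[match(block_key, blocks_tbl$key)]
  blocks_tbl$key <- NULL
  plots$missing <- is.na(plots$value)

  n_j <- vapply(seq_along(envs), function(j) {
    sum(plots$env_idx == j & !plots$missing)
  }, integer(1L))
  names(n_j) <- envs
  assert_that(all(n_j > 0L),
              paste0("environment(s) with no non-missing plots: ",
                     paste(envs[n_j == 0L], collapse = ", ")),
              class = "metfa_input_error")

  structure(list(
    plots = plots,
    p = length(envs),
    v = length(genotypes),
    n = sum(!plots$missing),
    n_j = n_j,
    envs = envs,
    genotypes = genotypes,
    blocks = blocks_tbl
  ), class = "met_data")
}

resolve_levels <- function(x, levels, what) {
  if (is.null(levels)) return(unique(x))
  levels <- as.character(levels)
  unknown <- setdiff(unique(x), levels)
  assert_that(length(unknown) == 0L,
              paste0(what, " id(s) not in declared level order: ",
                     paste(unknown, collapse = ", ")),
              class = "metfa_input_error")
  levels
}

#' @export
print.met_data <- function(x, ...) {
  cat("<met_data> ", x$n, " non-missing plots (", sum(x$plots$missing),
      " missing), p = ", x$p, " environments, v = ", x$v, " genotypes, ",
      nrow(x$blocks), " blocks\n", sep = "")
  invisible(x)
}

#' Read and write MET phenotype tables
#'
#' Plot-level phenotypes travel as delimited text with header
#' `env,trial,block,genotype,value`; an empty `value` field is a missing plot.
#'
#' @param path File path.
#' @param ... Passed to [load_met_dataset()] (e.g. level orders).
#' @return `read_met_phenotypes()` returns a `met_data` object;
#'   `write_met_phenotypes()` returns `path` invisibly.
#' @export
read_met_phenotypes <- function(path, ...) {
  tab <- utils::read.csv(path, colClasses = c(env = "character", trial = "character",
                                              block = "character", genotype = "character"))
  load_met_dataset(tab, ...)
}

#' @rdname read_met_phenotypes
#' @param data A `met_data` object or a plain phenotype data frame.
#' @export
write_met_phenotypes <- function(data, path) {
  tab <- if (inherits(data, "met_data")) {
    data$plots[c("env", "trial", "block", "genotype", "value")]
  } else {
    data[c("env", "trial", "block", "genotype", "value")]
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Link a genomic relationship matrix to a MET dataset
#'
#' Checks that every genotype in the phenotype table has a row in the
#' relationship matrix, and returns the matrix subset and re-ordered to the
#' dataset's genotype levels.
#'
#' @param data A `met_data` object.
#' @param grm A `genomic_relationship` object or a square matrix with genotype
#'   dimnames.
#' @return A `v x v` matrix aligned with `data$genotypes`.
#' @export
align_grm <- function(data, grm) {
  G <- if (inherits(grm, "genomic_relationship")) grm$G else grm
  assert_that(is_square_numeric(G) && !is.null(rownames(G)),
              "grm must be a square matrix with genotype dimnames",
              class = "metfa_input_error")
  unknown <- setdiff(data$genotypes, rownames(G))
  assert_that(length(unknown) == 0L,
              paste0("genotype(s) missing from relationship matrix: ",
                     paste(unknown, collapse = ", ")),
              class = "metfa_linkage_error")
  G[data$genotypes, data$genotypes, drop = FALSE]
}
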