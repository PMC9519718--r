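#' Centre and scale known environmental covariates
#'
#' Prepares a raw environment-by-covariate table for modelling. Each covariate
#' column is centred to zero mean across environments and divided by its
#' Euclidean norm, so every prepared column `s_i` satisfies `sum(s_i) = 0` and
#' `s_i' s_i = 1`. The centring offsets and scale divisors are stored so the
#' identical transform can be applied to new (e.g. future) environments.
#'
#' @param covariates A data frame with an `env` id column and one numeric
#'   column per covariate, one row per environment; or a numeric matrix with
#'   environment rownames.
#' @param env_levels Optional environment order (defaults to row order).
#' @return A `covariate_matrix` object: list with `S` (p x q matrix of
#'   prepared scores, environments in rows), `center` and `scale` (named
#'   numeric vectors), `covariates` (names) and `envs`.
#' @export
prepare_covariates <- function(covariates, env_levels = NULL) {
  if (is.matrix(covariates)) {
    raw <- covariates
    assert_that(!is.null(rownames(raw)), "covariate matrix needs environment rownames",
                class = "metfa_input_error")
  } else {
    covariates <- as.data.frame(covariates)
    assert_that("env" %in% names(covariates),
                "covariate table needs an 'env' column", class = "metfa_input_error")
    raw <- as.matrix(covariates[setdiff(names(covariates), "env")])
    rownames(raw) <- as.character(covariates$env)
  }
  assert_that(is.numeric(raw), "covariates must be numeric", class = "metfa_input_error")
  assert_that(!anyNA(raw), "covariate table contains missing values",
              class = "metfa_input_error")
  if (!is.null(env_levels)) {
    unknown <- setdiff(env_levels, rownames(raw))
    assert_that(length(unknown) == 0L,
                paste0("covariates missing for environment(s): ",
                       paste(unknown, collapse = ", ")),
                class = "metfa_input_error")
    raw <- raw[env_levels, , drop = FALSE]
  }
  p <- nrow(raw); q <- ncol(raw)
  assert_that(q < p, "need fewer covariates than environments (q < p)",
              class = "metfa_input_error")

  ctr <- colMeans(raw)
  centred <- sweep(raw, 2L, ctr, `-`)
  scl <- sqrt(colSums(centred^2))
  zero <- scl <= 1e-12 * (1 + abs(ctr))
  if (any(zero)) {
    stop_metfa(paste0("constant covariate column(s) (zero norm after centring): ",
                      paste(colnames(raw)[zero], collapse = ", ")),
               class = "metfa_constant_covariate_error")
  }
  S <- sweep(centred, 2L, scl, `/`)

  structure(list(S = S, center = ctr, scale = scl,
                 covariates = colnames(raw), envs = rownames(raw)),
            class = "covariate_matrix")
}

#' Apply a stored covariate transform to new environments
#'
#' Centres and scales raw covariate values for new environments with the
#' offsets and divisors learned on the training set, as required when
#' predicting into future environments on the training scale.
#'
#' @param object A `covariate_matrix` from [prepare_covariates()].
#' @param newdata Data frame with `env` plus the same covariate columns, or a
#'   matrix with matching column names and environment rownames.
#' @return Matrix of transformed covariate scores, new environments in rows.
#' @export
apply_covariate_transform <- function(object, newdata) {
  if (inherits(object, "covariate_basis")) {
    assert_that(!is.null(object$transform),
                "basis carries no covariate transform; build it from prepare_covariates()",
                class = "metfa_input_error")
    object <- structure(c(object$transform, list(S = object$S)),
                        class = "covariate_matrix")
  }
  assert_that(inherits(object, "covariate_matrix"), "object must be a covariate_matrix")
  if (is.matrix(newdata)) {
    raw <- newdata
  } else {
    newdata <- as.data.frame(newdata)
    assert_that("env" %in% names(newdata), "newdata needs an 'env' column",
                class = "metfa_input_error")
    raw <- as.matrix(newdata[setdiff(names(newdata), "env")])
    rownames(raw) <- as.character(newdata$env)
  }
  missing_cov <- setdiff(object$covariates, colnames(raw))
  assert_that(length(missing_cov) == 0L,
              paste0("covariate(s) missing for new environment(s): ",
                     paste(missing_cov, collapse = ", ")),
              class = "metfa_input_error")
  raw <- raw[, object$covariates, drop = FALSE]
  assert_that(!anyNA(raw), "new covariate values contain missing entries",
              class = "metfa_input_error")
  sweep(sweep(raw, 2L, object$center, `-`), 2L, object$scale, `/`)
}

#' @export
print.covariate_matrix <- function(x, ...) {
  cat("<covariate_matrix> ", length(x$envs), " environments x ",
      length(x$covariates), " covariates (centred, unit length)\n", sep = "")
  invisible(x)
}

#' Read a raw environment-by-covariate table
#'
#' @param path Delimited text file: first column `env`, remaining columns named
#'   covariates.
#' @return A tibble with the raw (untransformed) values.
#' @export
read_covariates <- function(path) {
  tibble::as_tibble(utils::read.csv(path, colClasses = c(env = "character")))
}
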