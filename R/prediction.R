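# Prediction into current (leave-one-environment-out) and future
# environments, with accuracy summaries.

# predicted GE effects for one environment given its transformed covariates
# (1 x q) and a trained model; p_train is the environment count of the
# training fit (the latent mean-loading divisor follows it)
predict_env_effects <- function(fit, S_row) {
  fam <- fit$family
  p_train <- fit$p
  if (fam %in% c("far", "ifa")) {
    rot <- rotate_solution(fit)
    pred_load <- if (fam == "ifa") {
      lb_r <- colSums(rot$Lambda_r) / p_train
      as.numeric(S_row %*% rot$Lambda_s) + lb_r
    } else {
      as.numeric(rot$Lambda_g) / sqrt(p_train) +
        as.numeric(S_row %*% rot$Lambda_s)
    }
    return(as.numeric(rot$scores %*% pred_load))
  }
  if (fam %in% c("rreg1", "rreg2")) {
    return(fit$intercepts / sqrt(p_train) +
             as.numeric(fit$slopes %*% as.numeric(S_row)))
  }
  if (fam %in% c("comp", "mdiag")) {
    return(fit$intercepts / sqrt(p_train))
  }
  stop_metfa(paste0("family '", fam, "' cannot predict unseen environments ",
                    "(its factors are purely latent)"),
             class = "metfa_predict_error")
}

genotype_env_means <- function(data, j) {
  obs <- data$plots[!data$plots$missing & data$plots$env_idx == j, ]
  if (nrow(obs) == 0L) return(tibble::tibble(genotype = character(), mean = numeric()))
  agg <- rowsum(obs$value, group = obs$genotype)
  cnt <- rowsum(rep(1, nrow(obs)), group = obs$genotype)
  tibble::tibble(genotype = rownames(agg), mean = as.numeric(agg / cnt))
}

#' Leave-one-environment-out cross-validation
#'
#' For each environment `j`, refits the model on the remaining `p - 1`
#' environments (covariates re-centred and scaled on the training set and
#' the latent basis rebuilt, so nothing from the left-out environment enters
#' the fit), predicts the left-out GE effects from the environment's known
#' covariates and the training genotype scores, and correlates the
#' predictions with the observed genotype mean yields.
#'
#' @param data A `met_data` with at least 3 environments.
#' @param spec A [vm_spec()] for a family with known covariates (`far`,
#'   `ifa`, `rreg1`, `rreg2`) or main effects (`comp`, `mdiag`).
#' @param covariates Raw environment-by-covariate table (data frame with
#'   `env`, as read by [read_covariates()]).
#' @param grm Optional relationship matrix.
#' @param options A [fit_options()] list.
#' @param n_latent Latent columns requested for `ifa` (capped at
#'   `p - 1 - q` per training fit).
#' @return A `met_cv` object: tibble-like list with `accuracy` (env,
#'   n_genotypes, r, converged), `predictions` (per-environment tibbles of
#'   predicted effects and observed means) and `mode = "current"`.
#' @export
loeo_cv <- function(data, spec, covariates, grm = NULL,
                    options = fit_options(), n_latent = NULL) {
  assert_that(inherits(data, "met_data"), "data must be a met_data")
  assert_that(data$p >= 3L, "leave-one-environment-out needs p >= 3",
              class = "metfa_input_error")
  covariates <- as.data.frame(covariates)
  envs <- data$envs
  acc <- vector("list", data$p)
  preds <- vector("list", data$p)
  for (j in seq_len(data$p)) {
    train_envs <- envs[-j]
    plots_tr <- data$plots[data$plots$env != envs[j],
                           c("env", "trial", "block", "genotype", "value")]
    train <- load_met_dataset(plots_tr, env_levels = train_envs,
                              genotype_levels = data$genotypes)
    cov_tr <- prepare_covariates(covariates[covariates$env %in% train_envs, ,
                                            drop = FALSE],
                                 env_levels = train_envs)
    basis_tr <- if (spec$family %in% c("rreg1", "rreg2", "far", "ifa")) {
      q_tr <- ncol(cov_tr$S)
      nl <- if (spec$family == "ifa") {
        min(n_latent %||% (train$p - q_tr), train$p - q_tr)
      } else NULL
      build_projection(cov_tr, n_latent = nl)
    }
    fit <- fit_met(train, spec, grm = grm, basis = basis_tr, options = options)
    S_row <- apply_covariate_transform(cov_tr,
                                       covariates[covariates$env == envs[j], ,
                                                  drop = FALSE])
    u_hat <- predict_env_effects(fit, S_row)
    obs <- genotype_env_means(data, j)
    pred_tbl <- tibble::tibble(genotype = data$genotypes, predicted = u_hat)
    pred_tbl <- dplyr::left_join(pred_tbl, obs, by = "genotype")
    with_data <- !is.na(pred_tbl$mean)
    r_j <- if (sum(with_data) >= 3L) {
      stats::cor(pred_tbl$mean[with_data], pred_tbl$predicted[with_data])
    } else NA_real_
    acc[[j]] <- tibble::tibble(env = envs[j], n_genotypes = sum(with_data),
                               accuracy = r_j, converged = fit$converged)
    preds[[j]] <- pred_tbl
  }
  structure(list(accuracy = dplyr::bind_rows(acc),
                 predictions = setNames(preds, envs),
                 mode = "current", spec = spec),
            class = "met_cv")
}

#' Predict GE effects for future environments from their covariates
#'
#' Applies the training covariate transform to the new environments'
#' raw covariates and predicts per-genotype GE effects as
#' `(S*_j Lambda_s + lambda_bar_r) f` (latent mean loadings divided by the
#' training `p`). When validation phenotypes are supplied, the accuracy
#' `r_j = cor(ybar_j, u*_j)` is computed per environment.
#'
#' @param fit A `met_fit` trained on all current environments with a basis
#'   built from [prepare_covariates()].
#' @param new_covariates Raw covariate table for the future environments
#'   (data frame with `env` and the training covariate columns).
#' @param validation Optional `met_data` holding future-environment
#'   phenotypes for the same genotype ids.
#' @return A `met_cv` object with `mode = "future"`.
#' @export
predict_future <- function(fit, new_covariates, validation = NULL) {
  assert_that(inherits(fit, "met_fit"), "fit must be a met_fit")
  new_covariates <- as.data.frame(new_covariates)
  assert_that("env" %in% names(new_covariates),
              "new_covariates needs an 'env' column", class = "metfa_input_error")
  Sstar <- apply_covariate_transform(fit$basis, new_covariates)
  envs_new <- rownames(Sstar)
  acc <- vector("list", length(envs_new))
  preds <- vector("list", length(envs_new))
  for (j in seq_along(envs_new)) {
    u_hat <- predict_env_effects(fit, Sstar[j, , drop = FALSE])
    pred_tbl <- tibble::tibble(genotype = fit$genotypes, predicted = u_hat)
    r_j <- NA_real_
    n_g <- 0L
    if (!is.null(validation)) {
      jj <- match(envs_new[j], validation$envs)
      if (!is.na(jj)) {
        obs <- genotype_env_means(validation, jj)
        pred_tbl <- dplyr::left_join(pred_tbl, obs, by = "genotype")
        with_data <- !is.na(pred_tbl$mean)
        n_g <- sum(with_data)
        if (n_g >= 3L) {
          r_j <- stats::cor(pred_tbl$mean[with_data], pred_tbl$predicted[with_data])
        }
      }
    }
    acc[[j]] <- tibble::tibble(env = envs_new[j], n_genotypes = n_g,
                               accuracy = r_j, converged = fit$converged)
    preds[[j]] <- pred_tbl
  }
  structure(list(accuracy = dplyr::bind_rows(acc),
                 predictions = setNames(preds, envs_new),
                 mode = "future", spec = fit$spec),
            class = "met_cv")
}

#' @export
print.met_cv <- function(x, ...) {
  r <- x$accuracy$accuracy
  cat("<met_cv> ", x$mode, "-environment prediction, ", nrow(x$accuracy),
      " environments; accuracy mean ",
      sprintf("%.3f", mean(r, na.rm = TRUE)),
      " [", sprintf("%.3f", suppressWarnings(min(r, na.rm = TRUE))), ", ",
      sprintf("%.3f", suppressWarnings(max(r, na.rm = TRUE))), "]\n", sep = "")
  invisible(x)
}

#' Min/mean/max accuracy by region
#'
#' @param x A `met_cv` or a data frame with `env` and `accuracy` columns.
#' @param regions Optional named character vector mapping environment ids to
#'   region labels (default: one overall region).
#' @return Tibble with one row per region plus an overall row: `region`,
#'   `n`, `n_undefined`, `min`, `mean`, `max`. Undefined accuracies are
#'   excluded from the order statistics and counted.
#' @export
accuracy_summary <- function(x, regions = NULL) {
  tab <- if (inherits(x, "met_cv")) x$accuracy else tibble::as_tibble(x)
  assert_that(all(c("env", "accuracy") %in% names(tab)),
              "need env and accuracy columns", class = "metfa_input_error")
  assert_that(any(!is.na(tab$accuracy)), "no defined accuracies",
              class = "metfa_input_error")
  tab$region <- if (is.null(regions)) "overall" else
    unname(regions[tab$env]) %||% "overall"
  one <- function(d, label) {
    ok <- !is.na(d$accuracy)
    tibble::tibble(region = label, n = sum(ok), n_undefined = sum(!ok),
                   min = min(d$accuracy[ok]), mean = mean(d$accuracy[ok]),
                   max = max(d$accuracy[ok]))
  }
  out <- dplyr::bind_rows(lapply(split(tab, tab$region), function(d)
    one(d, d$region[1L])))
  if (!is.null(regions)) out <- dplyr::bind_rows(out, one(tab, "overall"))
  out
}
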