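as_rotation <- function(x) {
  if (inherits(x, "met_rotation")) return(x)
  if (inherits(x, "met_fit")) return(rotate_solution(x))
  stop_metfa("expected a met_fit or met_rotation")
}

# total GE effects implied by a rotated solution (v x p)
rotation_U <- function(rot) {
  U <- tcrossprod(rot$scores, rot$Lambda)
  if (!is.null(rot$deviations)) U <- U + rot$deviations
  if (!is.null(rot$intercepts)) {
    U <- U + tcrossprod(rot$intercepts, rep(1 / sqrt(rot$p), rot$p))
  }
  U
}

# family-wise decomposition of G_e into common, known-covariate and specific
# parts, on the rotated scale
ge_parts <- function(x) {
  if (inherits(x, "met_fit") && !x$family %in% c("fa", "fam", "far", "ifa")) {
    p <- x$p
    Jp <- matrix(1, p, p)
    vars <- x$params$vars
    S <- if (!is.null(x$basis)) x$basis$S
    known <- switch(x$family,
                    rreg1 = vars[2L] * tcrossprod(S),
                    rreg2 = S %*% (vars[-1L] * t(S)),
                    NULL)
    common <- switch(x$family,
                     id = NULL,
                     diag = NULL,
                     comp = vars[1L] * Jp,
                     mdiag = vars[1L] * Jp,
                     rreg1 = vars[1L] * Jp + known,
                     rreg2 = vars[1L] * Jp + known)
    return(list(Ge = x$Ge, common = common, known = known,
                d = NULL, Lambda = NULL, Lambda_s = NULL, S = S,
                envs = x$envs, p = p, family = x$family))
  }
  rot <- as_rotation(x)
  p <- rot$p
  common <- rot$Lambda %*% (rot$d * t(rot$Lambda))
  if (rot$family == "fam") common <- common + rot$sigma2_1 * matrix(1, p, p)
  S <- if (!is.null(rot$basis)) rot$basis$S
  Lambda_s <- switch(rot$family, far = , ifa = rot$Lambda_s, NULL)
  known <- if (!is.null(Lambda_s)) {
    SL <- S %*% Lambda_s
    SL %*% (rot$d * t(SL))
  }
  list(Ge = rot$Ge, common = common, known = known, d = rot$d,
       Lambda = rot$Lambda, Lambda_s = Lambda_s, S = S,
       envs = rot$envs, p = p, family = rot$family, rot = rot)
}

#' Genotype main effects
#'
#' Computes per-genotype main effects from a fitted model. *Simple* main
#' effects are simple averages across environments (families with explicit
#' intercepts: `fam`, `far`, `comp`, `mdiag`, `rreg1`, `rreg2`); for `fam`
#' they equal `gamma_1 + sqrt(p) * sum_l mean(lambda_l) f_l`. *Generalised*
#' main effects are first-factor weighted averages capturing non-crossover
#' GEI: `mean(lambda_1) * f_1` for `fa`, and for `ifa`
#' `lambda_bar_r1 * f_1` with `lambda_bar_r1 = sum(lambda_r1) / p`.
#'
#' @param x A `met_fit` or `met_rotation`.
#' @param kind `"generalised"` or `"simple"`.
#' @return Tibble with `genotype` and `effect`, with attributes `variance`
#'   (the effect variance on the `G_g` scale) and `lambda_bar`.
#' @export
main_effects <- function(x, kind = c("generalised", "simple")) {
  kind <- match.arg(kind)
  fam <- if (inherits(x, "met_fit")) x$family else x$family
  if (kind == "generalised") {
    assert_that(fam %in% c("fa", "ifa"),
                paste0("family '", fam, "' has no generalised main effects ",
                       "(no positive first factor)"),
                class = "metfa_main_effect_error")
    rot <- as_rotation(x)
    lb <- if (fam == "ifa") sum(rot$Lambda_r[, 1L]) / rot$p else mean(rot$Lambda[, 1L])
    eff <- lb * rot$scores[, 1L]
    out <- tibble::tibble(genotype = rot$genotypes, effect = as.numeric(eff))
    attr(out, "variance") <- rot$d[1L] * lb^2
    attr(out, "lambda_bar") <- lb
    return(out)
  }
  # simple main effects
  if (fam == "fam") {
    rot <- as_rotation(x)
    lb <- colMeans(rot$Lambda)
    eff <- rot$intercepts + sqrt(rot$p) * as.numeric(rot$scores %*% lb)
    sigma2_g <- rot$sigma2_1 + sum(rot$d * lb^2)
    out <- tibble::tibble(genotype = rot$genotypes, effect = eff)
    attr(out, "variance") <- rot$p * sigma2_g
    attr(out, "lambda_bar") <- lb
    return(out)
  }
  if (fam == "far") {
    rot <- as_rotation(x)
    eff <- as.numeric(rot$scores %*% as.numeric(rot$Lambda_g))
    out <- tibble::tibble(genotype = rot$genotypes, effect = eff)
    attr(out, "variance") <- sum(rot$d * as.numeric(rot$Lambda_g)^2)
    attr(out, "lambda_bar") <- as.numeric(rot$Lambda_g)
    return(out)
  }
  assert_that(inherits(x, "met_fit") && !is.null(x$intercepts),
              paste0("family '", fam, "' has no simple main effects"),
              class = "metfa_main_effect_error")
  out <- tibble::tibble(genotype = x$genotypes, effect = x$intercepts)
  attr(out, "variance") <- x$p * x$params$vars[1L]
  out
}

#' Variance-explained summaries
#'
#' Percentage of additive genetic variance explained by the known covariates
#' and overall by the common factors, overall and per environment, per
#' factor, and per covariate:
#' `vbar = 100 tr(D) / tr(G_e)` (for `fam`, the simple-main-effect term is
#' included in the common part),
#' `vbar_s = 100 tr(S Lambda_s D Lambda_s' S') / tr(G_e)`,
#' per-environment ratios from the diagonals of the corresponding quadratic
#' forms (no clipping: `v_sj` may exceed `v_j` since known and latent
#' covariates are not orthogonal environment-wise), per-factor
#' `v_l = 100 d_l / tr(G_e)` and `v_sl = 100 d_l ||S lambda_sl||^2 / tr(G_e)`,
#' per-covariate `v_si` (squared projection of the known part onto covariate
#' `i`, which need not sum to `vbar_s` since covariates are correlated), and
#' the factor-by-covariate decomposition `v_li = 100 (s_i' lambda_l)^2` with
#' `v_l. = v_sl / v_l` the share of joint factor `l` explained by all known
#' covariates.
#'
#' @param x A `met_fit` or `met_rotation`.
#' @return A `met_varexp` object: list of tibbles `overall`, `env`,
#'   `factors`, `covariates`, `factor_covariate` (components absent where
#'   the family does not define them).
#' @export
variance_explained <- function(x) {
  parts <- ge_parts(x)
  trG <- sum(diag(parts$Ge))
  assert_that(trG > 0, "total genetic variance is zero",
              class = "metfa_varexp_error")
  pct <- function(num) 100 * num / trG
  vbar <- if (!is.null(parts$d)) pct(sum(parts$d)) else
    if (!is.null(parts$common)) pct(sum(diag(parts$common))) else NA_real_
  if (identical(parts$family, "fam")) {
    vbar <- pct(sum(parts$d) + parts$p * parts$rot$sigma2_1)
  }
  vbar_s <- if (!is.null(parts$known)) pct(sum(diag(parts$known))) else NA_real_
  overall <- tibble::tibble(vbar_s = vbar_s, vbar = vbar)

  dGe <- diag(parts$Ge)
  env <- tibble::tibble(
    env = parts$envs,
    variance = dGe,
    v_sj = if (!is.null(parts$known)) {
      ifelse(dGe > 0, 100 * diag(parts$known) / dGe, NA_real_)
    } else NA_real_,
    v_j = if (!is.null(parts$common)) {
      ifelse(dGe > 0, 100 * diag(parts$common) / dGe, NA_real_)
    } else NA_real_)

  factors <- covariates <- factor_covariate <- NULL
  if (!is.null(parts$d)) {
    k <- length(parts$d)
    v_l <- pct(parts$d)
    v_sl <- if (!is.null(parts$Lambda_s)) {
      pct(parts$d * colSums((parts$S %*% parts$Lambda_s)^2))
    } else rep(NA_real_, k)
    factors <- tibble::tibble(factor = seq_len(k), v_l = v_l, v_sl = v_sl,
                              v_ldot = 100 * v_sl / v_l)
    if (!is.null(parts$Lambda_s)) {
      S <- parts$S
      Ls <- parts$Lambda_s
      D <- diag(parts$d, k)
      q <- ncol(S)
      v_si <- vapply(seq_len(q), function(i) {
        a_i <- Ls[i, ]                              # row: covariate i over factors
        num <- as.numeric(S[, i] %*% S %*% Ls %*% D %*% a_i)^2
        den <- as.numeric(a_i %*% D %*% a_i) * trG
        if (den <= 0) return(NA_real_)
        100 * num / den
      }, numeric(1))
      covariates <- tibble::tibble(covariate = colnames(S), v_si = v_si)
      # factor-by-covariate shares of the (unit-norm) joint loadings
      v_li <- 100 * crossprod(S, parts$Lambda)^2
      factor_covariate <- tibble::as_tibble(expand.grid(
        covariate = colnames(S), factor = seq_len(k),
        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
      factor_covariate$v_li <- as.numeric(v_li)
    }
  }
  structure(list(overall = overall, env = env, factors = factors,
                 covariates = covariates, factor_covariate = factor_covariate),
            class = "met_varexp")
}

#' @export
print.met_varexp <- function(x, ...) {
  cat("<met_varexp> overall: vbar_s = ",
      if (is.na(x$overall$vbar_s)) "-" else sprintf("%.1f%%", x$overall$vbar_s),
      ", vbar = ",
      if (is.na(x$overall$vbar)) "-" else sprintf("%.1f%%", x$overall$vbar),
      "\n", sep = "")
  invisible(x)
}

#' Additive genetic correlations between environments
#'
#' Correlation matrix of the regression (common-factor) part of `G_e`,
#' either in terms of the known covariates only or of the known and latent
#' covariates jointly. Specific variances are excluded by default so the two
#' parts are comparable; `include_psi = TRUE` adds them. Environments with
#' zero variance under the requested part get `NA` correlations rather than
#' fabricated values. An agglomerative (average-linkage on 1 - r) clustering
#' order is returned for heatmap display.
#'
#' @param x A `met_fit` or `met_rotation`.
#' @param parts `"full"` (known + latent) or `"known"`.
#' @param include_psi Add the specific variances to the diagonal.
#' @return A `met_corr` object: list with `correlation` (p x p), `order`
#'   (display order), `parts`, `envs`.
#' @export
env_correlation <- function(x, parts = c("full", "known"), include_psi = FALSE) {
  parts <- match.arg(parts)
  gp <- ge_parts(x)
  C <- if (parts == "known") gp$known else gp$common
  assert_that(!is.null(C),
              paste0("family '", gp$family, "' has no ", parts, " part"),
              class = "metfa_varexp_error")
  if (include_psi) {
    psi <- diag(gp$Ge - gp$common)
    C <- C + diag(pmax(psi, 0), gp$p)
  }
  dd <- diag(C)
  ok <- dd > 1e-12 * max(dd, 1e-300)
  R <- matrix(NA_real_, gp$p, gp$p, dimnames = list(gp$envs, gp$envs))
  if (any(ok)) {
    R[ok, ok] <- stats::cov2cor(C[ok, ok, drop = FALSE])
  }
  diag(R)[ok] <- 1
  ord <- seq_len(gp$p)
  if (all(ok) && gp$p > 2L) {
    hc <- stats::hclust(stats::as.dist(1 - R), method = "average")
    ord <- hc$order
  }
  structure(list(correlation = R, order = ord, parts = parts, envs = gp$envs),
            class = "met_corr")
}

#' @export
print.met_corr <- function(x, ...) {
  off <- x$correlation[upper.tri(x$correlation)]
  cat("<met_corr> ", x$parts, "-part correlations over ", length(x$envs),
      " environments; mean off-diagonal ",
      sprintf("%.2f", mean(off, na.rm = TRUE)), "\n", sep = "")
  invisible(x)
}

#' Data for genotype regression plots
#'
#' For each factor `l` and requested genotype, returns the composite
#' loadings as abscissa, a fitted line through the origin with slope equal
#' to the genotype's rotated score, and the GE effects adjusted for the
#' preceding factors as points (deviations included in the points, not the
#' line). The generalised main effect marker sits at the mean first-factor
#' loading.
#'
#' @param x A `met_fit` or `met_rotation` of a factor family.
#' @param genotypes Character vector of genotype ids (default: first two).
#' @return Tibble with `factor`, `genotype`, `env`, `loading`, `effect`,
#'   `fitted` and `slope`; attribute `markers` holds the main-effect points
#'   when the family defines them.
#' @export
regression_plot_data <- function(x, genotypes = NULL) {
  rot <- as_rotation(x)
  genotypes <- genotypes %||% utils::head(rot$genotypes, 2L)
  unknown <- setdiff(genotypes, rot$genotypes)
  assert_that(length(unknown) == 0L,
              paste0("unknown genotype id(s): ", paste(unknown, collapse = ", ")),
              class = "metfa_input_error")
  gi <- match(genotypes, rot$genotypes)
  U <- rotation_U(rot)
  k <- length(rot$d)
  rows <- list()
  for (l in seq_len(k)) {
    lam <- rot$Lambda[, l]
    for (g in seq_along(gi)) {
      u_adj <- U[gi[g], ]
      if (l > 1L) {
        prev <- seq_len(l - 1L)
        u_adj <- u_adj - as.numeric(rot$Lambda[, prev, drop = FALSE] %*%
                                      rot$scores[gi[g], prev])
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        factor = l, genotype = genotypes[g], env = rot$envs,
        loading = lam, effect = as.numeric(u_adj),
        fitted = lam * rot$scores[gi[g], l],
        slope = rot$scores[gi[g], l])
    }
  }
  out <- dplyr::bind_rows(rows)
  if (rot$family %in% c("fa", "ifa")) {
    lb <- if (rot$family == "ifa") sum(rot$Lambda_r[, 1L]) / rot$p else
      mean(rot$Lambda[, 1L])
    attr(out, "markers") <- tibble::tibble(
      factor = 1L, genotype = genotypes,
      loading = lb, effect = lb * rot$scores[gi, 1L])
  }
  out
}
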