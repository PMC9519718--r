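#' Options controlling the REML fit
#'
#' @param max_iter Maximum average-information iterations.
#' @param tol_par Convergence tolerance on the maximum relative parameter
#'   change (default `1e-6`).
#' @param tol_ll Convergence tolerance on the relative change in residual
#'   log-likelihood (default `1e-8`).
#' @param psi_floor Lower bound for specific variances (default `1e-8`),
#'   keeping `G_e` invertible.
#' @param grm_ridge Diagonal ridge added to the relationship matrix inside
#'   the solves. `NULL` (default) applies `1e-6 * mean(diag(G_g))` when
#'   `G_g` is rank deficient, else 0; the value used is reported on the fit.
#' @param fixed_covariates Replace the per-environment fixed means by an
#'   overall mean plus a fixed regression on the known covariates, with a
#'   random residual environment effect (variance `sigma2_omega`). Default
#'   `FALSE`.
#' @param evaluator `"auto"` picks the balanced-design evaluator when the
#'   layout allows it, otherwise the general dense evaluator; `"dense"` or
#'   `"balanced"` force a choice.
#' @param start Optional full starting vector of variance parameters.
#' @param verbose Print the iteration trace.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(max_iter = 100L, tol_par = 1e-6, tol_ll = 1e-8,
                        psi_floor = 1e-8, grm_ridge = NULL,
                        fixed_covariates = FALSE,
                        evaluator = c("auto", "dense", "balanced"),
                        start = NULL, verbose = FALSE) {
  assert_that(tol_par > 0 && tol_ll > 0, "tolerances must be positive")
  assert_that(max_iter >= 1L, "max_iter must be at least 1")
  structure(list(max_iter = as.integer(max_iter), tol_par = tol_par,
                 tol_ll = tol_ll, psi_floor = psi_floor,
                 grm_ridge = grm_ridge, fixed_covariates = fixed_covariates,
                 evaluator = match.arg(evaluator), start = start,
                 verbose = isTRUE(verbose)), class = "fit_options")
}

# Deterministic starting values: per-environment moment estimates for the
# nuisance components, then the genetic structure seeded from the leading
# eigenvectors of a regularised sample genetic covariance matrix computed on
# genotype means (the "fit a diagonal model first" strategy in closed form).
starting_theta <- function(frame) {
  p <- frame$p; v <- frame$v
  layout <- frame$layout
  y <- frame$y; env <- frame$env; geno <- frame$geno

  var_j <- vapply(seq_len(p), function(j) {
    vv <- stats::var(y[env == j])
    if (!is.finite(vv) || vv <= 0) frame$vy else vv
  }, numeric(1))

  # sweep block means (shared by all genotypes in balanced blocks) before
  # forming genotype means, so the sample genetic covariance is not inflated
  env_mean <- as.numeric(tapply(y, env, mean))[env]
  block_mean <- as.numeric(tapply(y, frame$block, mean))[frame$block]
  y_adj <- y - (block_mean - env_mean)
  Ymeans <- matrix(NA_real_, v, p)
  agg <- rowsum(y_adj, group = (env - 1L) * v + geno)
  cnt <- rowsum(rep(1, length(y_adj)), group = (env - 1L) * v + geno)
  Ymeans[as.integer(rownames(agg))] <- agg / cnt
  resid <- y_adj - Ymeans[cbind(geno, env)]
  se0 <- vapply(seq_len(p), function(j) {
    r <- resid[env == j]
    dof <- max(frame$n_j[j] - sum(!is.na(Ymeans[, j])) - frame$nb_j[j] + 1, 1)
    max(sum(r^2) / dof, 1e-6 * frame$vy)
  }, numeric(1))
  sb0 <- vapply(seq_len(p), function(j) {
    bm <- as.numeric(tapply(y[env == j], frame$block[env == j], mean))
    vb <- if (length(bm) > 1) stats::var(bm) else 0.1 * var_j[j]
    max(vb - se0[j] / max(frame$n_j[j] / frame$nb_j[j], 1), 1e-4 * var_j[j])
  }, numeric(1))
  reps <- frame$n_j / pmax(colSums(!is.na(Ymeans)), 1)
  Cg <- suppressWarnings(stats::cov(Ymeans, use = "pairwise.complete.obs"))
  Cg[!is.finite(Cg)] <- 0
  dg <- pmax(diag(Cg) - se0 / pmax(reps, 1), 0.05 * var_j)
  diag(Cg) <- dg
  # symmetrise + eigenvalue floor
  Cg <- (Cg + t(Cg)) / 2
  ee <- eigen(Cg, symmetric = TRUE)
  ee$values <- pmax(ee$values, 1e-4 * mean(dg))
  Cg <- ee$vectors %*% (ee$values * t(ee$vectors))

  f <- layout$spec$family
  k <- layout$k
  psi_fl <- max(layout$lower[layout$ranges$psi %||% 1], 1e-8)
  off_mean <- if (p > 1) mean(Cg[upper.tri(Cg)]) else 0
  sg0 <- max(off_mean, 0.05 * mean(dg))

  th_g <- switch(f,
    id = mean(dg),
    diag = dg,
    comp = c(sg0, max(mean(dg) - sg0, 0.05 * mean(dg))),
    mdiag = c(sg0, pmax(dg - sg0, 0.05 * dg)),
    rreg1 = c(sg0, max(mean(dg) - sg0, 0.05 * mean(dg)) * p / (2 * frame$basis$q),
              pmax(0.5 * dg, psi_fl)),
    rreg2 = c(sg0, rep(max(mean(dg) - sg0, 0.05 * mean(dg)) * p / (2 * frame$basis$q),
                       frame$basis$q),
              pmax(0.5 * dg, psi_fl)),
    fam = , fa = , far = , ifa = {
      Cg_f <- Cg
      extra <- numeric(0)
      if (f == "fam") {
        s1 <- max(sg0, 1e-3 * mean(dg))
        Cg_f <- Cg - s1 * matrix(1, p, p)
        extra <- s1
      }
      ee <- eigen((Cg_f + t(Cg_f)) / 2, symmetric = TRUE)
      ev <- pmax(ee$values[seq_len(k)], 1e-3 * mean(dg))
      L0 <- ee$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(ev), k)
      Lc <- composite_to_constrained(L0, layout)
      psi0 <- pmax(dg - rowSums((layout$Phi %*% Lc)^2), pmax(0.05 * dg, psi_fl))
      c(extra, Lc[layout$mask], psi0)
    })
  sw0 <- if (frame$use_omega) {
    max(0.1 * stats::var(as.numeric(tapply(y, env, mean))), 1e-4 * frame$vy)
  } else NULL
  pmax(c(th_g, sb0, se0, sw0), frame$lower)
}

# Map a composite p x k loadings start onto the constrained stacked
# parameterisation: express in the family basis, rotate so the upper-right
# identification zeros hold, then blank structurally zero entries.
composite_to_constrained <- function(L0, layout) {
  Phi <- layout$Phi
  k <- ncol(L0)
  Lc <- if (ncol(Phi) == nrow(Phi)) solve(Phi, L0) else qr.solve(Phi, L0)
  if (k > 1L) {
    r <- min(k - 1L, nrow(Lc))
    Atop <- Lc[seq_len(r), , drop = FALSE]
    qrA <- qr(t(Atop))
    V <- qr.Q(qrA, complete = TRUE)
    Lc <- Lc %*% V
    # fix signs for determinism: leading diagonal entries non-negative
    for (l in seq_len(k)) {
      piv <- if (l <= nrow(Lc)) Lc[l, l] else Lc[nrow(Lc), l]
      if (is.finite(piv) && piv < 0) Lc[, l] <- -Lc[, l]
    }
  }
  Lc[!layout$mask] <- 0
  Lc
}

#' Deterministic REML starting values
#'
#' @param data A `met_data`.
#' @param spec A [vm_spec()].
#' @param grm Optional relationship matrix.
#' @param basis Optional [build_projection()] result.
#' @param options A [fit_options()] list.
#' @return Named numeric vector of starting variance parameters (genetic,
#'   block, residual).
#' @export
starting_values <- function(data, spec, grm = NULL, basis = NULL,
                            options = fit_options()) {
  frame <- build_model_frame(data, grm, basis, spec, options)
  th <- starting_theta(frame)
  names(th) <- frame$par_names
  th
}

#' Fit a GE variance model to a MET dataset by average-information REML
#'
#' Fits the linear mixed model `y = X tau + Z u + Z_p u_p + e` with
#' `var(u) = G_e(theta) x G_g`, per-environment random block effects and
#' per-environment residual variances, maximising the residual log-likelihood
#' by average-information updates with step halving. Factor models are
#' estimated under the identification constraints (score variances fixed at
#' one, upper-right loadings zero); use [rotate_solution()] for the
#' principal-axis form.
#'
#' @param data A `met_data` from [load_met_dataset()] or [simulate_met()].
#' @param spec A [vm_spec()].
#' @param grm A `genomic_relationship`, a matrix with genotype dimnames, or
#'   `NULL` for an identity relationship.
#' @param basis A [build_projection()] result (required for covariate
#'   families).
#' @param options A [fit_options()] list.
#' @return A `met_fit` object; see [tidy.met_fit()], [glance.met_fit()],
#'   [rotate_solution()], [variance_explained()].
#' @export
fit_met <- function(data, spec, grm = NULL, basis = NULL,
                    options = fit_options()) {
  frame <- build_model_frame(data, grm, basis, spec, options)
  use_fast <- switch(options$evaluator,
                     auto = frame$balanced,
                     dense = FALSE,
                     balanced = {
                       assert_that(frame$balanced,
                                   "design is not balanced complete-block; use the dense evaluator",
                                   class = "metfa_input_error")
                       TRUE
                     })
  evalr <- if (use_fast) evaluator_balanced(frame) else evaluator_dense(frame)

  theta <- options$start %||% starting_theta(frame)
  assert_that(length(theta) == frame$n_par,
              paste0("starting vector must have length ", frame$n_par),
              class = "metfa_input_error")
  theta <- pmax(theta, frame$lower)

  ev <- evalr(theta, derivs = TRUE)
  assert_that(isTRUE(ev$ok),
              "likelihood could not be evaluated at the starting values",
              class = "metfa_fit_error")
  trace <- list(tibble::tibble(iteration = 0L, loglik = ev$ll, step = 1,
                               max_rel_change = NA_real_))
  converged <- FALSE
  msg <- "maximum iterations reached"
  it <- 0L
  while (it < options$max_iter) {
    it <- it + 1L
    # active-set handling: parameters pinned at their bound with a negative
    # score have no feasible ascent direction and are held fixed this round
    at_bound <- theta - frame$lower < 1e-10 * (1 + abs(frame$lower))
    free <- !(at_bound & ev$score < 0)
    if (!any(free)) {
      converged <- TRUE
      msg <- "all parameters at bounds with no ascent direction"
      break
    }
    delta <- numeric(frame$n_par)
    delta[free] <- ai_direction(ev$AI[free, free, drop = FALSE], ev$score[free])
    step <- 1
    accepted <- FALSE
    for (h in seq_len(15L)) {
      th_new <- pmax(theta + step * delta, frame$lower)
      ev_new <- evalr(th_new, derivs = FALSE)
      if (isTRUE(ev_new$ok) && ev_new$ll >= ev$ll - 1e-9) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) {
      converged <- max(abs(ev$score[free])) < 1e-3 * (1 + abs(ev$ll))
      msg <- if (converged) "score negligible; no further improvement" else
        "step halving failed to improve the log-likelihood"
      break
    }
    rel <- max(abs(th_new - theta) / (abs(theta) + 1e-8))
    dll <- ev_new$ll - ev$ll
    theta <- th_new
    ev <- evalr(theta, derivs = TRUE)
    if (!isTRUE(ev$ok)) {
      msg <- "likelihood evaluation failed after an accepted step"
      break
    }
    trace[[length(trace) + 1L]] <-
      tibble::tibble(iteration = it, loglik = ev$ll, step = step,
                     max_rel_change = rel)
    if (options$verbose) {
      cat(sprintf("iter %3d  ll %.6f  step %.3g  max-rel %.3g\n",
                  it, ev$ll, step, rel))
    }
    if (rel < options$tol_par && abs(dll) / (abs(ev$ll) + 1) < options$tol_ll) {
      converged <- TRUE
      msg <- "converged"
      break
    }
  }

  build_met_fit(frame, theta, ev, do.call(rbind, trace), it, converged, msg,
                options)
}

# Levenberg-style regularised solve of the average-information system
ai_direction <- function(AI, score) {
  lam <- 0
  base <- mean(diag(AI))
  if (!is.finite(base) || base <= 0) base <- 1
  for (tries in 1:8) {
    M <- AI + diag(lam * base, nrow(AI))
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (!is.null(ch)) {
      return(backsolve(ch, backsolve(ch, score, transpose = TRUE)))
    }
    lam <- if (lam == 0) 1e-8 else lam * 100
  }
  score / base
}

build_met_fit <- function(frame, theta, ev, trace, iterations, converged, msg,
                          options) {
  layout <- frame$layout
  th <- split_theta(frame, theta)
  pr <- layout$unpack(th$g)
  p <- frame$p; v <- frame$v
  Ge <- ev$Ge; Ge_inv <- ev$Ge_inv
  Umat <- ev$Umat
  rownames(Umat) <- frame$genotypes
  colnames(Umat) <- frame$envs
  one_star <- rep(1 / sqrt(p), p)
  f <- frame$spec$family

  scores <- deviations <- intercepts <- slopes <- NULL
  if (f %in% c("fa", "fam", "far", "ifa")) {
    lam_comp <- layout$Phi %*% pr$Lambda
    scores <- Umat %*% Ge_inv %*% lam_comp
    colnames(scores) <- paste0("f", seq_len(layout$k))
    deviations <- Umat - tcrossprod(scores, lam_comp)
    if (f == "fam") {
      s1 <- pr$vars[1L]
      intercepts <- as.numeric(p * s1 * (Umat %*% Ge_inv %*% one_star))
      deviations <- deviations - tcrossprod(intercepts, one_star)
    }
  } else if (f %in% c("comp", "mdiag", "rreg1", "rreg2")) {
    sg2 <- pr$vars[1L]
    intercepts <- as.numeric(p * sg2 * (Umat %*% Ge_inv %*% one_star))
    if (f %in% c("rreg1", "rreg2")) {
      svar <- if (f == "rreg1") rep(pr$vars[2L], frame$basis$q) else pr$vars[-1L]
      slopes <- Umat %*% Ge_inv %*% frame$basis$S %*% diag(svar, frame$basis$q)
      colnames(slopes) <- frame$basis$covariates
      deviations <- Umat - tcrossprod(intercepts, one_star) -
        tcrossprod(slopes, frame$basis$S)
    }
  }

  params <- list(vars = pr$vars, Lambda = pr$Lambda, psi = pr$psi)
  m_total <- frame$n_par
  ll <- ev$ll
  tau <- ev$tau
  names(tau) <- colnames(frame$Xe)
  names(theta) <- frame$par_names

  structure(list(
    spec = frame$spec, family = f, theta = theta, params = params,
    Ge = Ge, Ge_inv = Ge_inv,
    sigma2_block = th$sb2, sigma2_resid = th$se2, sigma2_omega = th$sw2,
    tau = tau, Umat = Umat,
    scores = scores, deviations = deviations,
    intercepts = intercepts, slopes = slopes,
    loglik = ll, m_genetic = length(frame$idx_g), m_total = m_total,
    aic = -2 * ll + 2 * m_total,
    iterations = iterations, converged = converged, message = msg,
    trace = tibble::as_tibble(trace),
    grm_ridge = frame$ridge, Gg = frame$Gg,
    basis = frame$basis, layout = layout,
    n = frame$n, p = p, v = v,
    envs = frame$envs, genotypes = frame$genotypes,
    options = options), class = "met_fit")
}

#' @export
print.met_fit <- function(x, ...) {
  cat("<met_fit> ", vm_label(x$spec), " model: ", x$v, " genotypes x ", x$p,
      " environments, n = ", x$n, "\n", sep = "")
  cat("  residual log-likelihood ", format(x$loglik, nsmall = 2),
      ", AIC ", format(x$aic, nsmall = 2),
      " (", x$m_genetic, " genetic + ", x$m_total - x$m_genetic,
      " other variance parameters)\n", sep = "")
  cat("  ", if (x$converged) "converged" else paste0("NOT converged (", x$message, ")"),
      " in ", x$iterations, " iterations",
      if (x$grm_ridge > 0) paste0("; GRM ridge ", format(x$grm_ridge)), "\n", sep = "")
  invisible(x)
}

#' Residual log-likelihood and AIC of a fitted model
#'
#' The AIC convention counts estimated variance parameters only (genetic plus
#' non-genetic plus residual); fixed effects are not counted.
#'
#' @param object A `met_fit`.
#' @param ... Unused.
#' @return `logLik()` returns an object of class `logLik` with `df` set to
#'   the variance parameter count; `AIC` then gives `-2 ll + 2 df`.
#' @export
logLik.met_fit <- function(object, ...) {
  structure(object$loglik, df = object$m_total, nobs = object$n,
            class = "logLik")
}

#' AIC from a residual log-likelihood and a variance parameter count
#'
#' @param loglik Residual log-likelihood.
#' @param m_total Number of estimated variance parameters (genetic +
#'   non-genetic + residual).
#' @return `-2 * loglik + 2 * m_total`.
#' @export
met_aic <- function(loglik, m_total) {
  -2 * loglik + 2 * m_total
}
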