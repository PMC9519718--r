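#' Build the known-plus-latent covariate basis
#'
#' Constructs the orthogonal complement `Gamma` to the column space of the
#' prepared covariates `S`, so that integrated factor models can regress on
#' `B = [S Gamma]` with `S' Gamma = 0`. `Gamma` is taken as the first
#' `p - q` columns of the projector `I - S (S'S)^-1 S'` and then
#' orthonormalised (QR) for a stable, full-column-rank basis spanning the same
#' subspace. When the number of environments is large it can be desirable to
#' keep fewer latent columns; `n_latent` selects the leading columns after
#' orthonormalisation, deterministically.
#'
#' @param covariates A `covariate_matrix` from [prepare_covariates()], or a
#'   numeric `p x q` matrix of prepared scores.
#' @param n_latent Number of latent basis columns to keep, between 1 and
#'   `p - q` (default `p - q`).
#' @return A `covariate_basis` object: list with `S` (p x q), `Gamma`
#'   (p x n_latent, orthonormal, `S' Gamma = 0`), `B = [S Gamma]`,
#'   `A = [1_p/sqrt(p), S]`, `q`, `p`, `n_latent`, `envs` and `covariates`.
#' @export
build_projection <- function(covariates, n_latent = NULL) {
  transform <- NULL
  if (inherits(covariates, "covariate_matrix")) {
    S <- covariates$S
    envs <- covariates$envs
    covs <- covariates$covariates
    transform <- covariates[c("center", "scale", "covariates")]
  } else {
    S <- as.matrix(covariates)
    envs <- rownames(S)
    covs <- colnames(S)
  }
  p <- nrow(S); q <- ncol(S)
  assert_that(q < p, "projection requires q < p", class = "metfa_basis_error")
  n_latent <- n_latent %||% (p - q)
  assert_that(n_latent >= 1L && n_latent <= p - q,
              "n_latent must lie in [1, p - q]", class = "metfa_basis_error")

  sv <- svd(S, nu = 0L, nv = 0L)$d
  kappa <- sv[1L] / sv[q]
  if (!is.finite(kappa) || sv[q] < 1e-10 * sv[1L]) {
    stop_metfa(sprintf("covariate matrix is numerically rank deficient (condition number %.3g)",
                       kappa),
               class = "metfa_basis_error")
  }

  proj <- diag(p) - S %*% solve(crossprod(S), t(S))
  G0 <- proj[, seq_len(p - q), drop = FALSE]
  qrd <- qr(G0)
  assert_that(qrd$rank == p - q,
              "leading projector columns are rank deficient; cannot build Gamma",
              class = "metfa_basis_error")
  Gamma <- qr.Q(qrd)[, seq_len(p - q), drop = FALSE]
  # span check: Gamma must be invariant under the projector
  assert_that(max(abs(proj %*% Gamma - Gamma)) < 1e-8,
              "orthonormalised Gamma left the orthogonal complement of col(S)")
  # deterministic column signs: largest-magnitude entry positive
  for (l in seq_len(ncol(Gamma))) {
    i <- which.max(abs(Gamma[, l]))
    if (Gamma[i, l] < 0) Gamma[, l] <- -Gamma[, l]
  }
  Gamma <- Gamma[, seq_len(n_latent), drop = FALSE]
  colnames(Gamma) <- paste0("latent", seq_len(n_latent))

  B <- cbind(S, Gamma)
  A <- cbind(`(main)` = rep(1 / sqrt(p), p), S)
  structure(list(S = S, Gamma = Gamma, B = B, A = A,
                 p = p, q = q, n_latent = n_latent,
                 envs = envs, covariates = covs, transform = transform),
            class = "covariate_basis")
}

#' @export
print.covariate_basis <- function(x, ...) {
  cat("<covariate_basis> p = ", x$p, ", q = ", x$q, " known covariates, ",
      x$n_latent, " latent columns (S'Gamma = 0)\n", sep = "")
  invisible(x)
}
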