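#' Rotate constrained factor estimates to principal axes
#'
#' REML estimation of the factor families uses identification constraints
#' (score variances fixed at one, upper-right loadings zero). This rotation
#' recovers the interpretable principal-axis form through the singular value
#' decomposition of the composite loadings `B Lambda* = U D^(1/2) V'`:
#' rotated composite loadings are the orthonormal `U`, score variances are
#' the squared singular values in decreasing order, and scores rotate in
#' tandem (`f = (D^(1/2) V' x I) f*`) so fitted GE effects and `G_e` are
#' unchanged. A sign convention is then applied: the first factor is oriented
#' so its mean composite loading is positive (all-positive loadings define
#' generalised main effects; a warning lists environments with negative
#' loadings when signs are mixed), and higher factors so their mean loading
#' is non-negative.
#'
#' @param x A `met_fit` for a factor family (`fa`, `fam`, `far`, `ifa`).
#' @return A `met_rotation` object: list with `Lambda` (p x k rotated
#'   composite loadings, orthonormal columns), `d` (decreasing score
#'   variances), `Lambda_s`/`Lambda_r`/`Lambda_g` (rotated blocks, family
#'   dependent), `scores` (v x k rotated scores), `deviations`, `psi`,
#'   `sigma2_1` (fam), `Ge`, `U`, `V`, `family`, `spec`, `basis`, `envs`,
#'   `genotypes`.
#' @export
rotate_solution <- function(x) {
  assert_that(inherits(x, "met_fit"), "x must be a met_fit")
  assert_that(x$family %in% c("fa", "fam", "far", "ifa"),
              "rotation applies to factor families only",
              class = "metfa_rotation_error")
  Bmat <- x$layout$Phi
  rot <- rotate_loadings(x$params$Lambda, x$scores, Bmat)
  rot <- sign_convention(rot, generalised = x$family %in% c("fa", "ifa"),
                         envs = x$envs)

  k <- x$spec$k
  q <- if (!is.null(x$basis)) x$basis$q else 0L
  stacked <- rot$stacked
  blocks <- switch(x$family,
                   fa = , fam = list(),
                   far = list(Lambda_g = stacked[1L, , drop = FALSE],
                              Lambda_s = stacked[-1L, , drop = FALSE]),
                   ifa = list(Lambda_s = stacked[seq_len(q), , drop = FALSE],
                              Lambda_r = stacked[-seq_len(q), , drop = FALSE]))

  out <- c(list(Lambda = rot$Lambda, d = rot$d, stacked = stacked,
                scores = rot$scores, U = rot$Lambda, V = rot$V,
                deviations = x$deviations, psi = x$params$psi,
                sigma2_1 = if (x$family == "fam") x$params$vars[1L],
                intercepts = x$intercepts,
                Ge = x$Ge, family = x$family, spec = x$spec, basis = x$basis,
                envs = x$envs, genotypes = x$genotypes, p = x$p, v = x$v),
           blocks)
  structure(out, class = "met_rotation")
}

#' Low-level SVD rotation of loadings and scores
#'
#' @param Lambda Constrained stacked loadings (m x k; `m = p` for latent
#'   families, `q + 1` for `far`, `q + n_latent` for `ifa`).
#' @param scores Constrained scores (v x k) or `NULL`.
#' @param B Basis matrix (p x m) mapping stacked loadings to composite
#'   environment loadings (identity for latent families).
#' @return List with `Lambda` (p x k orthonormal composite loadings `U`),
#'   `stacked` (rotated stacked loadings, `B`-solve of `U`), `d` (squared
#'   singular values, decreasing), `V`, `scores` (rotated).
#' @export
rotate_loadings <- function(Lambda, scores = NULL, B = NULL) {
  Lambda <- as.matrix(Lambda)
  k <- ncol(Lambda)
  if (is.null(B)) B <- diag(nrow(Lambda))
  BL <- B %*% Lambda
  sv <- svd(BL)
  if (sv$d[k] < 1e-10 * max(sv$d[1L], 1)) {
    stop_metfa(paste0("collapsed factor: singular value ", k,
                      " is numerically zero"),
               class = "metfa_rotation_error")
  }
  U <- sv$u[, seq_len(k), drop = FALSE]
  V <- sv$v[, seq_len(k), drop = FALSE]
  d <- sv$d[seq_len(k)]^2
  stacked <- if (nrow(B) == ncol(B)) solve(B, U) else qr.solve(B, U)
  rot_scores <- if (!is.null(scores)) {
    as.matrix(scores) %*% V %*% diag(sv$d[seq_len(k)], k)
  }
  rownames(U) <- rownames(B)
  list(Lambda = U, stacked = stacked, d = d, V = V, scores = rot_scores)
}

#' Apply the sign convention to a rotated solution
#'
#' Factor one is flipped so the mean composite loading is positive (with a
#' warning naming negative-loading environments when the family defines
#' generalised main effects and signs are mixed); higher factors are flipped
#' so their mean loading is non-negative, with exact zeros left unchanged.
#' Scores flip in tandem, so fitted GE effects are invariant.
#'
#' @param rot A list as returned by [rotate_loadings()] (or a
#'   `met_rotation`).
#' @param generalised Does the family interpret factor one as generalised
#'   main effects (all-positive loadings assumed)?
#' @param envs Optional environment names for the warning.
#' @return The input with signs normalised.
#' @export
sign_convention <- function(rot, generalised = TRUE, envs = NULL) {
  Lam <- rot$Lambda
  k <- ncol(Lam)
  flip <- rep(1, k)
  for (l in seq_len(k)) {
    m <- mean(Lam[, l])
    if (l == 1L) {
      if (m < 0) flip[l] <- -1
    } else if (m < 0) flip[l] <- -1
  }
  rot$Lambda <- sweep(Lam, 2L, flip, `*`)
  if (!is.null(rot$stacked)) rot$stacked <- sweep(rot$stacked, 2L, flip, `*`)
  if (!is.null(rot$scores)) rot$scores <- sweep(rot$scores, 2L, flip, `*`)
  if (!is.null(rot$V)) rot$V <- sweep(rot$V, 2L, flip, `*`)
  if (generalised && any(rot$Lambda[, 1L] < 0)) {
    neg <- which(rot$Lambda[, 1L] < 0)
    labs <- if (!is.null(envs)) envs[neg] else as.character(neg)
    warn(paste0("first-factor loadings are not all positive; ",
                "generalised main effects are approximate. Negative in: ",
                paste(labs, collapse = ", ")))
  }
  rot
}

#' @export
print.met_rotation <- function(x, ...) {
  cat("<met_rotation> ", vm_label(x$spec), ": ", length(x$d),
      " factors, score variances ",
      paste(signif(x$d, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}
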