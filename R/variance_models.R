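#' Variance model specifications for the additive GE effects
#'
#' Declarative descriptions of the between-environment genetic variance
#' structures `G_e` supported by the package. The families are:
#'
#' * `id` — `sigma2_ge * I_p`;
#' * `diag` — a separate variance per environment;
#' * `comp` — compound symmetry `sigma2_g J_p + sigma2_ge I_p`;
#' * `mdiag` — main effects plus diagonal `sigma2_g J_p + Sigma_ge`;
#' * `fam` — factor analytic with explicit simple main effects,
#'   `sigma2_1 J_p + Lambda D Lambda' + Psi`;
#' * `fa` — conventional factor analytic `Lambda D Lambda' + Psi`;
#' * `rreg1` — random regression on known covariates with a single slope
#'   variance, `sigma2_g J_p + sigma2_s S S' + Psi`;
#' * `rreg2` — as `rreg1` but one slope variance per covariate;
#' * `far` — factor analytic regression: a reduced-rank factor model across
#'   the main effect and the known-covariate slopes,
#'   `A Lambda_a D Lambda_a' A' + Psi` with `A = [1_p/sqrt(p), S]`;
#' * `ifa` — integrated factor analytic: factors are linear combinations of
#'   known covariates and latent directions orthogonal to them,
#'   `B Lambda_b D Lambda_b' B' + Psi` with `B = [S Gamma]`. `k_r < k` keeps
#'   only the first `k_r` latent columns of the loadings (the remaining
#'   latent columns are structurally zero).
#'
#' @param family One of `"id"`, `"diag"`, `"comp"`, `"mdiag"`, `"fam"`,
#'   `"fa"`, `"rreg1"`, `"rreg2"`, `"far"`, `"ifa"`.
#' @param k Number of factors (factor families only).
#' @param k_r Number of latent factors with non-zero loadings (`ifa` only;
#'   defaults to `k`).
#' @return A `vm_spec` object with fields `family`, `k`, `k_s`, `k_r`.
#' @export
#' @examples
#' vm_spec("ifa", k = 4, k_r = 3)
#' count_parameters(vm_spec("fa", k = 4), p = 24)           # 114
#' count_parameters(vm_spec("ifa", k = 4, k_r = 3), 24, 18) # 108
vm_spec <- function(family, k = NULL, k_r = NULL) {
  family <- match.arg(family, c("id", "diag", "comp", "mdiag", "fam", "fa",
                                "rreg1", "rreg2", "far", "ifa"))
  factor_family <- family %in% c("fam", "fa", "far", "ifa")
  if (factor_family) {
    assert_that(!is.null(k) && k >= 1L && k == round(k),
                paste0("family '", family, "' needs an integer k >= 1"),
                class = "metfa_spec_error")
    k <- as.integer(k)
  } else {
    assert_that(is.null(k) || identical(as.integer(k), 0L),
                paste0("family '", family, "' takes no factors"),
                class = "metfa_spec_error")
    k <- 0L
  }
  if (family == "ifa") {
    k_r <- as.integer(k_r %||% k)
    assert_that(k_r >= 1L && k_r <= k, "ifa requires 1 <= k_r <= k",
                class = "metfa_spec_error")
  } else {
    assert_that(is.null(k_r), "k_r only applies to the ifa family",
                class = "metfa_spec_error")
    k_r <- k
  }
  structure(list(family = family, k = k, k_s = k, k_r = k_r), class = "vm_spec")
}

#' @export
print.vm_spec <- function(x, ...) {
  lab <- vm_label(x)
  cat("<vm_spec> ", lab, "\n", sep = "")
  invisible(x)
}

vm_label <- function(spec) {
  switch(spec$family,
         ifa = if (spec$k_r < spec$k) paste0("IFA", spec$k, "-", spec$k_r) else paste0("IFA", spec$k),
         fa = paste0("FA", spec$k),
         fam = paste0("FAM", spec$k),
         far = paste0("FAR", spec$k),
         spec$family)
}

validate_spec_dims <- function(spec, p, q, n_latent = p - q) {
  f <- spec$family
  if (f %in% c("rreg1", "rreg2", "far", "ifa")) {
    assert_that(q >= 1L, paste0("family '", f, "' needs known covariates"),
                class = "metfa_spec_error")
  }
  switch(f,
         fa = ,
         fam = assert_that(spec$k <= p, "fa/fam require k <= p", class = "metfa_spec_error"),
         far = assert_that(spec$k <= q + 1L, "far requires k <= q + 1",
                           class = "metfa_spec_error"),
         ifa = {
           assert_that(q < p, "ifa requires q < p", class = "metfa_spec_error")
           assert_that(spec$k <= q + 1L, "ifa requires k <= q + 1",
                       class = "metfa_spec_error")
           assert_that(spec$k_r <= n_latent,
                       "ifa requires k_r <= number of latent basis columns",
                       class = "metfa_spec_error")
         })
  invisible(TRUE)
}

# free-entry mask for an m x k loadings matrix under the estimation
# constraints: zeros in the upper-right (row r has zeros in columns > r for
# r < k); for ifa, latent rows additionally have zero columns beyond k_r.
loadings_mask <- function(spec, p, q, n_latent = p - q) {
  k <- spec$k
  m <- switch(spec$family,
              fa = , fam = p,
              far = q + 1L,
              ifa = q + n_latent)
  mask <- matrix(TRUE, m, k)
  if (k > 1L) {
    for (r in seq_len(min(k - 1L, m))) mask[r, seq_len(k)[-seq_len(r)]] <- FALSE
  }
  if (spec$family == "ifa" && spec$k_r < k) {
    latent_rows <- q + seq_len(n_latent)
    mask[latent_rows, (spec$k_r + 1L):k] <- FALSE
  }
  mask
}

#' Number of estimated genetic variance parameters
#'
#' Counts the free parameters of a variance structure at `p` environments and
#' `q` known covariates, by enumerating the free entries of the constrained
#' parameterisation (loadings with the upper-right identification zeros, plus
#' variance components). For the `ifa` family with `k_r < k` the latent
#' loading block has structurally zero columns beyond `k_r`.
#'
#' @param spec A [vm_spec()].
#' @param p Number of environments.
#' @param q Number of known covariates (0 for latent-only families).
#' @param n_latent Latent basis columns for `ifa` (default `p - q`).
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec, p, q = 0L, n_latent = p - q) {
  assert_that(inherits(spec, "vm_spec"), "spec must be a vm_spec")
  p <- as.integer(p); q <- as.integer(q)
  assert_that(p >= 2L, "need p >= 2 environments", class = "metfa_spec_error")
  validate_spec_dims(spec, p, q, n_latent)
  switch(spec$family,
         id = 1L,
         diag = p,
         comp = 2L,
         mdiag = p + 1L,
         rreg1 = p + 2L,
         rreg2 = p + q + 1L,
         fam = sum(loadings_mask(spec, p, q)) + p + 1L,
         fa = sum(loadings_mask(spec, p, q)) + p,
         far = sum(loadings_mask(spec, p, q)) + p,
         ifa = sum(loadings_mask(spec, p, q, n_latent)) + p)
}

#' Assemble the between-environment genetic variance matrix
#'
#' Evaluates the algebraic form of `G_e` for a variance family from a named
#' parameter list. Factor families take loadings, score variances `d`
#' (default all 1, the estimation constraint) and specific variances `psi`.
#'
#' @param spec A [vm_spec()].
#' @param params Named list; relevant entries by family:
#'   `sigma2_ge` (`id`: scalar; `diag`/`mdiag`: length-p vector),
#'   `sigma2_g`, `sigma2_1`, `sigma2_s` (scalar), `sigma2_si` (length-q),
#'   `Lambda` (`fa`/`fam`: p x k), `Lambda_a` (`far`: (q+1) x k),
#'   `Lambda_s` (`ifa`: q x k), `Lambda_r` (`ifa`: n_latent x k),
#'   `d` (length k), `psi` (length p).
#' @param basis A [build_projection()] result (needed for `rreg*`, `far`,
#'   `ifa`).
#' @param p Number of environments (taken from `basis` when supplied).
#' @return Symmetric `p x p` matrix.
#' @export
assemble_Ge <- function(spec, params, basis = NULL, p = NULL) {
  assert_that(inherits(spec, "vm_spec"), "spec must be a vm_spec")
  if (!is.null(basis)) p <- basis$p
  assert_that(!is.null(p), "supply p or a covariate_basis", class = "metfa_spec_error")
  f <- spec$family
  needs_basis <- f %in% c("rreg1", "rreg2", "far", "ifa")
  assert_that(!needs_basis || !is.null(basis),
              paste0("family '", f, "' needs a covariate_basis"),
              class = "metfa_spec_error")
  chk_var <- function(x, nm) {
    assert_that(!is.null(x), paste0("missing parameter '", nm, "'"),
                class = "metfa_spec_error")
    assert_that(all(x >= 0), paste0("negative variance in '", nm, "'"),
                class = "metfa_negative_variance_error")
    x
  }
  Jp <- matrix(1, p, p)
  k <- spec$k
  d <- if (k > 0L) params$d %||% rep(1, k) else numeric(0)
  if (k > 0L) chk_var(d, "d")
  psi_mat <- function() diag(chk_var(params$psi, "psi"), p)

  Ge <- switch(f,
    id = diag(rep(chk_var(params$sigma2_ge, "sigma2_ge"), p), p),
    diag = diag(chk_var(rep_len_ok(params$sigma2_ge, p, "sigma2_ge"), "sigma2_ge"), p),
    comp = chk_var(params$sigma2_g, "sigma2_g") * Jp +
      diag(rep(chk_var(params$sigma2_ge, "sigma2_ge"), p), p),
    mdiag = chk_var(params$sigma2_g, "sigma2_g") * Jp +
      diag(chk_var(rep_len_ok(params$sigma2_ge, p, "sigma2_ge"), "sigma2_ge"), p),
    rreg1 = chk_var(params$sigma2_g, "sigma2_g") * Jp +
      chk_var(params$sigma2_s, "sigma2_s") * tcrossprod(basis$S) + psi_mat(),
    rreg2 = chk_var(params$sigma2_g, "sigma2_g") * Jp +
      basis$S %*% diag(chk_var(rep_len_ok(params$sigma2_si, basis$q, "sigma2_si"),
                               "sigma2_si"), basis$q) %*% t(basis$S) + psi_mat(),
    fam = {
      L <- as_loadings(params$Lambda, p, k, "Lambda")
      chk_var(params$sigma2_1, "sigma2_1") * Jp +
        L %*% diag(d, k) %*% t(L) + psi_mat()
    },
    fa = {
      L <- as_loadings(params$Lambda, p, k, "Lambda")
      L %*% diag(d, k) %*% t(L) + psi_mat()
    },
    far = {
      La <- as_loadings(params$Lambda_a, basis$q + 1L, k, "Lambda_a")
      AL <- basis$A %*% La
      AL %*% diag(d, k) %*% t(AL) + psi_mat()
    },
    ifa = {
      Ls <- as_loadings(params$Lambda_s, basis$q, k, "Lambda_s")
      Lr <- as_loadings(params$Lambda_r, basis$n_latent, k, "Lambda_r")
      BL <- basis$S %*% Ls + basis$Gamma %*% Lr
      BL %*% diag(d, k) %*% t(BL) + psi_mat()
    })
  (Ge + t(Ge)) / 2
}

rep_len_ok <- function(x, n, nm) {
  assert_that(!is.null(x) && (length(x) == n || length(x) == 1L),
              paste0("parameter '", nm, "' must have length ", n),
              class = "metfa_spec_error")
  rep_len(x, n)
}

as_loadings <- function(L, m, k, nm) {
  assert_that(!is.null(L), paste0("missing parameter '", nm, "'"),
              class = "metfa_spec_error")
  L <- as.matrix(L)
  assert_that(nrow(L) == m && ncol(L) == k,
              paste0("'", nm, "' must be ", m, " x ", k),
              class = "metfa_spec_error")
  L
}

#' Re-express a FAM model as a special FA(k+1) structure
#'
#' A factor analytic model with explicit genotype intercepts is equivalent to
#' a factor model on the basis `[1_p/sqrt(p), Lambda_star]` where the first
#' "factor" has equal loadings and the remaining columns are Gram-Schmidt
#' centred (`Lambda_star' 1 = 0`), with a dense (k+1) x (k+1) score
#' covariance. The induced simple-main-effect variance is
#' `sigma2_g = sigma2_1 + sum_l d_l * mean(lambda_l)^2`.
#'
#' @param params Named list with `sigma2_1`, `Lambda` (p x k), optional `d`
#'   (default 1s), `psi` (p).
#' @return List with `basis` (`p x (k+1)`, first column `1/sqrt(p)`),
#'   `Lambda_star` (centred loadings), `D` (the (k+1) x (k+1) score
#'   covariance), `sigma2_g` and `lambda_bar` (mean loadings).
#' @export
fam_as_special_fa <- function(params) {
  L <- as.matrix(params$Lambda)
  p <- nrow(L); k <- ncol(L)
  d <- params$d %||% rep(1, k)
  sigma2_1 <- params$sigma2_1 %||% 0
  one_star <- rep(1 / sqrt(p), p)
  cvec <- as.numeric(crossprod(one_star, L))        # sqrt(p) * lambda_bar
  Lstar <- L - tcrossprod(one_star, cvec)
  lambda_bar <- cvec / sqrt(p)
  D <- matrix(0, k + 1L, k + 1L)
  D[1L, 1L] <- p * sigma2_1 + sum(d * cvec^2)
  D[1L, -1L] <- cvec * d
  D[-1L, 1L] <- cvec * d
  D[-1L, -1L] <- diag(d, k)
  list(basis = cbind(one_star, Lstar),
       Lambda_star = Lstar,
       D = D,
       sigma2_g = sigma2_1 + sum(d * lambda_bar^2),
       lambda_bar = lambda_bar)
}

# ---- internal estimation layout -------------------------------------------
#
# Maps a vm_spec to the constrained parameter vector used during REML
# (score variances fixed at 1, upper-right loadings zero) and provides G_e,
# its derivatives, bounds and names. `basis` may be NULL for latent-only
# families.
vm_layout <- function(spec, p, basis = NULL, psi_floor = 1e-8) {
  f <- spec$family
  q <- if (is.null(basis)) 0L else basis$q
  n_latent <- if (is.null(basis)) p - q else basis$n_latent
  validate_spec_dims(spec, p, q, n_latent)
  k <- spec$k

  Phi <- switch(f,
                fa = , fam = diag(p),
                far = basis$A,
                ifa = cbind(basis$S, basis$Gamma),
                NULL)
  mask <- if (f %in% c("fa", "fam", "far", "ifa")) loadings_mask(spec, p, q, n_latent) else NULL

  nm_psi <- paste0("psi[", seq_len(p), "]")
  pieces <- switch(f,
    id = list(vars = "sigma2_ge"),
    diag = list(vars = paste0("sigma2_ge[", seq_len(p), "]")),
    comp = list(vars = c("sigma2_g", "sigma2_ge")),
    mdiag = list(vars = c("sigma2_g", paste0("sigma2_ge[", seq_len(p), "]"))),
    rreg1 = list(vars = c("sigma2_g", "sigma2_s", nm_psi)),
    rreg2 = list(vars = c("sigma2_g", paste0("sigma2_s[", seq_len(q), "]"), nm_psi)),
    fam = list(vars = c("sigma2_1",
                        paste0("lambda[", which(mask, arr.ind = TRUE)[, 1L], ",",
                               which(mask, arr.ind = TRUE)[, 2L], "]"), nm_psi)),
    fa = , far = , ifa = list(vars = c(
      paste0("lambda[", which(mask, arr.ind = TRUE)[, 1L], ",",
             which(mask, arr.ind = TRUE)[, 2L], "]"), nm_psi)))
  nms <- pieces$vars
  n_par <- length(nms)

  free_idx <- if (!is.null(mask)) which(mask) else integer(0)
  n_load <- length(free_idx)
  # index ranges within theta
  ranges <- switch(f,
    id = list(var = 1L),
    diag = list(var = seq_len(p)),
    comp = list(var = 1:2),
    mdiag = list(var = seq_len(p + 1L)),
    rreg1 = list(var = 1:2, psi = 2L + seq_len(p)),
    rreg2 = list(var = seq_len(q + 1L), psi = q + 1L + seq_len(p)),
    fam = list(var = 1L, load = 1L + seq_len(n_load), psi = 1L + n_load + seq_len(p)),
    fa = , far = , ifa = list(load = seq_len(n_load), psi = n_load + seq_len(p)))

  lower <- rep(-Inf, n_par)
  is_var <- rep(FALSE, n_par)
  if (!is.null(ranges$var)) { lower[ranges$var] <- 0; is_var[ranges$var] <- TRUE }
  if (!is.null(ranges$psi)) { lower[ranges$psi] <- psi_floor; is_var[ranges$psi] <- TRUE }
  # variances that form the diagonal of G_e must stay strictly positive, or
  # G_e turns semidefinite and the solves break down
  diag_essential <- switch(f,
                           id = 1L,
                           diag = seq_len(p),
                           comp = 2L,
                           mdiag = 1L + seq_len(p),
                           integer(0))
  lower[diag_essential] <- pmax(lower[diag_essential], psi_floor)

  unpack <- function(theta) {
    out <- list()
    if (!is.null(ranges$var)) out$vars <- theta[ranges$var]
    if (!is.null(ranges$load)) {
      L <- matrix(0, nrow(mask), k)
      L[free_idx] <- theta[ranges$load]
      out$Lambda <- L
    }
    if (!is.null(ranges$psi)) out$psi <- theta[ranges$psi]
    out
  }

  Ge_fun <- function(theta) {
    pr <- unpack(theta)
    Jp <- matrix(1, p, p)
    switch(f,
      id = diag(rep(pr$vars[1L], p), p),
      diag = diag(pr$vars, p),
      comp = pr$vars[1L] * Jp + diag(rep(pr$vars[2L], p), p),
      mdiag = pr$vars[1L] * Jp + diag(pr$vars[-1L], p),
      rreg1 = pr$vars[1L] * Jp + pr$vars[2L] * tcrossprod(basis$S) + diag(pr$psi, p),
      rreg2 = pr$vars[1L] * Jp +
        basis$S %*% (pr$vars[-1L] * t(basis$S)) + diag(pr$psi, p),
      fam = pr$vars[1L] * Jp + tcrossprod(pr$Lambda) + diag(pr$psi, p),
      fa = tcrossprod(pr$Lambda) + diag(pr$psi, p),
      far = , ifa = {
        PL <- Phi %*% pr$Lambda
        tcrossprod(PL) + diag(pr$psi, p)
      })
  }

  # derivative of G_e wrt each theta element, as a list of closures evaluated
  # lazily at theta (returns list of p x p matrices)
  dGe_fun <- function(theta) {
    pr <- unpack(theta)
    Jp <- matrix(1, p, p)
    outs <- vector("list", n_par)
    ei <- function(j) { m <- matrix(0, p, p); m[j, j] <- 1; m }
    if (f == "id") outs[[1L]] <- diag(p)
    if (f == "diag") for (j in seq_len(p)) outs[[j]] <- ei(j)
    if (f == "comp") { outs[[1L]] <- Jp; outs[[2L]] <- diag(p) }
    if (f == "mdiag") { outs[[1L]] <- Jp; for (j in seq_len(p)) outs[[1L + j]] <- ei(j) }
    if (f == "rreg1") {
      outs[[1L]] <- Jp; outs[[2L]] <- tcrossprod(basis$S)
      for (j in seq_len(p)) outs[[ranges$psi[j]]] <- ei(j)
    }
    if (f == "rreg2") {
      outs[[1L]] <- Jp
      for (i in seq_len(q)) outs[[1L + i]] <- tcrossprod(basis$S[, i])
      for (j in seq_len(p)) outs[[ranges$psi[j]]] <- ei(j)
    }
    if (f %in% c("fam", "fa", "far", "ifa")) {
      if (f == "fam") outs[[1L]] <- Jp
      PhiL <- if (f %in% c("far", "ifa")) Phi %*% pr$Lambda else pr$Lambda
      Phi_cols <- if (f %in% c("far", "ifa")) Phi else diag(p)
      rc <- which(mask, arr.ind = TRUE)
      for (ii in seq_len(nrow(rc))) {
        a <- rc[ii, 1L]; l <- rc[ii, 2L]
        g <- PhiL[, l]
        phi_a <- Phi_cols[, a]
        m <- tcrossprod(phi_a, g)
        outs[[ranges$load[ii]]] <- m + t(m)
      }
      for (j in seq_len(p)) outs[[ranges$psi[j]]] <- ei(j)
    }
    outs
  }

  list(spec = spec, p = p, q = q, n_latent = n_latent, k = k,
       Phi = Phi, mask = mask, names = nms, n_par = n_par,
       lower = lower, is_var = is_var, ranges = ranges,
       unpack = unpack, Ge = Ge_fun, dGe = dGe_fun)
}
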