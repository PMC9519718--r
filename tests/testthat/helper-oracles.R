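# Independent oracles used across the suite. These deliberately use direct,
# textbook formulations (explicit dense matrices, brute-force loops) so they
# share no code path with the package internals they check.

# Dense textbook REML residual log-likelihood: builds V = Z G Z' + ...
# explicitly at the observation level and evaluates
# -0.5 [log|V| + log|X'V^-1 X| + y'Py + (n - p_x) log 2pi].
oracle_reml_ll <- function(data, Ge, Gg, sigma2_block, sigma2_resid,
                           Xe = NULL, sigma2_omega = NULL) {
  obs <- data$plots[!data$plots$missing, ]
  n <- nrow(obs)
  env <- obs$env_idx; geno <- obs$geno_idx
  blk <- obs$block_idx
  blks <- sort(unique(blk)); block <- match(blk, blks)
  benv <- data$blocks$env_idx[blks]
  p <- data$p
  if (is.null(Xe)) Xe <- diag(p)
  X <- Xe[env, , drop = FALSE]
  V <- Ge[env, env] * Gg[geno, geno]
  Zb <- diag(length(blks))[block, , drop = FALSE]
  V <- V + Zb %*% (sigma2_block[benv] * t(Zb))
  if (!is.null(sigma2_omega)) {
    Zw <- diag(p)[env, , drop = FALSE]
    V <- V + sigma2_omega * tcrossprod(Zw)
  }
  V <- V + diag(sigma2_resid[env], n)
  y <- obs$value
  Vi <- solve(V)
  XVX <- crossprod(X, Vi %*% X)
  Pm <- Vi - Vi %*% X %*% solve(XVX, crossprod(X, Vi))
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XVX)$modulus +
                       t(y) %*% Pm %*% y + (n - ncol(X)) * log(2 * pi)))
}

# evaluate the engine's own log-likelihood oracle-style for a met_fit
oracle_ll_of_fit <- function(fit, data) {
  Xe <- if (isTRUE(fit$options$fixed_covariates)) cbind(1, fit$basis$S)
  oracle_reml_ll(data, fit$Ge, fit$Gg, fit$sigma2_block, fit$sigma2_resid,
                 Xe = Xe, sigma2_omega = fit$sigma2_omega)
}

# Brute-force kNN imputation mirroring the documented definition: root mean
# squared difference over mutually observed markers, unweighted mean of the
# k nearest donors observed for the target marker, ties by row order.
oracle_knn_impute <- function(M, k) {
  v <- nrow(M)
  out <- M
  for (g in seq_len(v)) {
    for (j in seq_len(ncol(M))) {
      if (!is.na(M[g, j])) next
      d <- rep(Inf, v)
      for (h in seq_len(v)) {
        if (h == g) next
        shared <- which(!is.na(M[g, ]) & !is.na(M[h, ]))
        if (length(shared) == 0L) next
        d[h] <- mean((M[g, shared] - M[h, shared])^2)
      }
      cand <- order(d, seq_len(v))
      cand <- cand[!is.na(M[cand, j]) & is.finite(d[cand])]
      if (length(cand) == 0L) cand <- which(!is.na(M[, j]))
      use <- cand[seq_len(min(k, length(cand)))]
      out[g, j] <- mean(M[use, j])
    }
  }
  out
}

# per-column marker filter recomputation
oracle_filter_keep <- function(M, maf_min, missing_max) {
  keep <- logical(ncol(M))
  for (i in seq_len(ncol(M))) {
    x <- M[, i]
    miss <- mean(is.na(x))
    xo <- x[!is.na(x)]
    if (length(xo) == 0L || miss >= missing_max) { keep[i] <- FALSE; next }
    if (length(unique(xo)) <= 1L) { keep[i] <- FALSE; next }
    af <- mean((xo + 1) / 2)
    keep[i] <- min(af, 1 - af) > maf_min
  }
  keep
}

# naive triple-loop GRM
oracle_grm <- function(M) {
  Mc <- sweep(M, 2, colMeans(M))
  v <- nrow(M); m <- ncol(M)
  G <- matrix(0, v, v)
  for (a in seq_len(v)) for (b in seq_len(v)) {
    s <- 0
    for (i in seq_len(m)) s <- s + Mc[a, i] * Mc[b, i]
    G[a, b] <- s / m
  }
  G
}

# closed-form REML (= balanced ANOVA) for a single-environment complete
# two-way layout: y_{gb} = mu + block_b + geno_g + e
oracle_oneway_anova <- function(Y) {
  v <- nrow(Y); b <- ncol(Y)
  gm <- mean(Y)
  geno_m <- rowMeans(Y); block_m <- colMeans(Y)
  ss_g <- b * sum((geno_m - gm)^2)
  ss_b <- v * sum((block_m - gm)^2)
  ss_e <- sum((Y - outer(geno_m, rep(1, b)) -
                 outer(rep(1, v), block_m) + gm)^2)
  ms_g <- ss_g / (v - 1); ms_b <- ss_b / (b - 1)
  ms_e <- ss_e / ((v - 1) * (b - 1))
  list(sigma2_g = (ms_g - ms_e) / b,
       sigma2_b = (ms_b - ms_e) / v,
       sigma2_e = ms_e)
}

# largest principal angle (degrees) between the column spaces of A and B
principal_angle <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  sv <- svd(crossprod(qa, qb))$d
  acos(min(pmin(pmax(sv, -1), 1))) * 180 / pi
}

# small phenotype table builder
toy_plots <- function(p = 2, trials = 1, blocks = 2, v = 6, missing = 0) {
  g <- expand.grid(genotype = paste0("G", seq_len(v)),
                   block = paste0("B", seq_len(blocks)),
                   trial = paste0("T", seq_len(trials)),
                   env = paste0("E", seq_len(p)),
                   stringsAsFactors = FALSE)
  g <- g[, c("env", "trial", "block", "genotype")]
  g$value <- rnorm(nrow(g))
  if (missing > 0) g$value[seq_len(missing)] <- NA
  g
}

quiet_fit <- function(...) suppressWarnings(fit_met(...))
quiet_rot <- function(...) suppressWarnings(rotate_solution(...))
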