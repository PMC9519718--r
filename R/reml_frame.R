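# Internal model frame: observation indices, designs and variance layout
# shared by the likelihood evaluators.

build_model_frame <- function(data, Gg = NULL, basis = NULL, spec, options) {
  assert_that(inherits(data, "met_data"), "data must be a met_data")
  assert_that(inherits(spec, "vm_spec"), "spec must be a vm_spec")
  p <- data$p; v <- data$v

  if (is.null(Gg)) {
    Gg_raw <- diag(v)
    dimnames(Gg_raw) <- list(data$genotypes, data$genotypes)
  } else {
    Gg_raw <- align_grm(data, Gg)
  }
  ridge <- options$grm_ridge
  if (is.null(ridge)) {
    mineig <- min_eigenvalue(Gg_raw)
    ridge <- if (mineig < 1e-8 * mean(diag(Gg_raw))) 1e-6 * mean(diag(Gg_raw)) else 0
  }
  Gg_use <- Gg_raw + diag(rep(ridge, v), v)
  cg <- tryCatch(chol(Gg_use), error = function(e) NULL)
  assert_that(!is.null(cg),
              "relationship matrix not positive definite even after ridge; increase grm_ridge",
              class = "metfa_grm_error")
  Gg_inv <- chol2inv(cg)
  logdet_Gg <- 2 * sum(log(diag(cg)))

  if (!is.null(basis)) {
    assert_that(inherits(basis, "covariate_basis"), "basis must be a covariate_basis")
    assert_that(basis$p == p, "basis environments must match the dataset",
                class = "metfa_input_error")
    if (!is.null(basis$envs)) {
      assert_that(identical(basis$envs, data$envs),
                  "basis environment order must match the dataset",
                  class = "metfa_input_error")
    }
  }
  layout <- vm_layout(spec, p, basis, psi_floor = options$psi_floor)

  obs <- data$plots[!data$plots$missing, , drop = FALSE]
  n <- nrow(obs)
  env <- obs$env_idx
  geno <- obs$geno_idx
  # re-index observed blocks compactly
  blk_raw <- obs$block_idx
  blk_levels <- sort(unique(blk_raw))
  block <- match(blk_raw, blk_levels)
  NB <- length(blk_levels)
  block_env <- data$blocks$env_idx[blk_levels]
  nb_j <- tabulate(block_env, p)

  use_omega <- isTRUE(options$fixed_covariates)
  if (use_omega) {
    assert_that(!is.null(basis),
                "fixed-effect covariate regression needs a covariate_basis",
                class = "metfa_input_error")
    Xe <- cbind(`(mu)` = 1, basis$S)
  } else {
    Xe <- diag(p)
    colnames(Xe) <- data$envs
  }
  px <- ncol(Xe)

  # variance parameter bookkeeping: genetic, block, residual (+ omega)
  ng <- layout$n_par
  idx_g <- seq_len(ng)
  idx_b <- ng + seq_len(p)
  idx_e <- ng + p + seq_len(p)
  idx_w <- if (use_omega) ng + 2L * p + 1L else integer(0)
  n_par <- ng + 2L * p + length(idx_w)

  vy <- stats::var(obs$value)
  lower <- c(layout$lower, rep(1e-10 * vy, p), rep(1e-8 * vy, p),
             if (use_omega) 1e-10 * vy)
  par_names <- c(layout$names, paste0("sigma2_block[", seq_len(p), "]"),
                 paste0("sigma2_resid[", seq_len(p), "]"),
                 if (use_omega) "sigma2_omega")

  balanced <- n == NB * v &&
    all(tabulate(block, NB) == v) &&
    !anyNA(obs$value) && {
      # each block holds each genotype exactly once
      key <- (block - 1L) * v + geno
      !anyDuplicated(key)
    }

  list(y = obs$value, env = env, geno = geno, block = block,
       n = n, p = p, v = v, NB = NB, block_env = block_env, nb_j = nb_j,
       n_j = tabulate(env, p),
       Xe = Xe, px = px, use_omega = use_omega,
       Gg = Gg_use, Gg_inv = Gg_inv, logdet_Gg = logdet_Gg, ridge = ridge,
       layout = layout, basis = basis, spec = spec,
       idx_g = idx_g, idx_b = idx_b, idx_e = idx_e, idx_w = idx_w,
       n_par = n_par, lower = lower, par_names = par_names,
       balanced = balanced, vy = vy,
       envs = data$envs, genotypes = data$genotypes)
}

split_theta <- function(frame, theta) {
  list(g = theta[frame$idx_g],
       sb2 = theta[frame$idx_b],
       se2 = theta[frame$idx_e],
       sw2 = if (frame$use_omega) theta[frame$idx_w] else NULL)
}
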