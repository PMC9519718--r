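# Synthetic MET generation: markers, covariates and phenotypes with the exact
# generative structure the variance models assume, plus a truth record.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Simulate a genotype-by-marker matrix
#'
#' Markers are coded -1/0/1 (homozygous minor, heterozygous, homozygous
#' major). Each marker draws an allele frequency uniformly from `af_range`
#' and genotype dosages from Binomial(2, f).
#'
#' @param v Number of genotypes.
#' @param r Number of markers.
#' @param af_range Allele-frequency range (default `c(0.05, 0.5)`).
#' @param missing_rate Fraction of entries set missing (default 0).
#' @param seed Integer seed; the draw is fully reproducible per seed.
#' @return Numeric `v x r` matrix with genotype rownames `G1..Gv`.
#' @export
simulate_markers <- function(v, r, af_range = c(0.05, 0.5), missing_rate = 0,
                             seed = NULL) {
  assert_that(v >= 2L && r >= 1L, "need v >= 2 genotypes and r >= 1 markers",
              class = "metfa_input_error")
  with_seed(seed, {
    af <- runif(r, af_range[1L], af_range[2L])
    M <- vapply(af, function(f) rbinom(v, 2L, f) - 1L, integer(v))
    M <- matrix(as.numeric(M), v, r)
    if (missing_rate > 0) {
      drop <- runif(v * r) < missing_rate
      M[drop] <- NA_real_
    }
    dimnames(M) <- list(paste0("G", seq_len(v)), paste0("m", seq_len(r)))
    M
  })
}

#' Simulate raw environmental covariates
#'
#' Draws `q` correlated covariates for `p` environments from a multivariate
#' normal with exchangeable correlation `rho`, then maps them onto arbitrary
#' raw scales (random offsets and spreads), emulating the heterogeneous units
#' of real weather and soil summaries. Prepare with [prepare_covariates()].
#'
#' @param p Number of environments.
#' @param q Number of covariates (must satisfy `q < p`).
#' @param rho Common between-covariate correlation (default 0.3).
#' @param seed Integer seed.
#' @return Tibble with `env` plus `cov1..covq` raw columns.
#' @export
simulate_covariates <- function(p, q, rho = 0.3, seed = NULL) {
  assert_that(q >= 1L && q < p, "need 1 <= q < p", class = "metfa_input_error")
  assert_that(rho > -1 / max(1, q - 1) && rho < 1, "invalid correlation level",
              class = "metfa_input_error")
  with_seed(seed, {
    Sigma <- matrix(rho, q, q); diag(Sigma) <- 1
    Z <- matrix(rnorm(p * q), p, q) %*% chol(Sigma)
    offs <- runif(q, -5, 25)
    sprd <- runif(q, 0.5, 10)
    raw <- sweep(sweep(Z, 2L, sprd, `*`), 2L, offs, `+`)
    colnames(raw) <- paste0("cov", seq_len(q))
    tibble::tibble(env = paste0("E", seq_len(p)), !!!as.data.frame(raw))
  })
}

#' Simulate a multi-environment trial dataset with known truth
#'
#' Generates plot-level phenotypes with the generative structure the variance
#' models assume: GE effects `u = (Lambda x I) f + delta` with
#' `f ~ N(0, D x G_g)` and `delta ~ N(0, Psi x G_g)` (or the appropriate
#' analogue for non-factor families), environment means, random complete
#' replicate blocks within trials, and per-environment residual noise, with a
#' configurable missing-plot rate. The returned truth record holds every
#' generating parameter for parameter-recovery studies.
#'
#' Default magnitudes emulate a late-stage row-crop MET: environment mean
#' yields around 1.7 (sd 0.4), mean per-environment additive genetic variance
#' about 0.03 of which roughly three quarters sits in the common factors,
#' block variance 0.02 and plot residual variances 0.04-0.10.
#'
#' @param spec A [vm_spec()] describing the true `G_e` family.
#' @param v,p,q Genotypes, environments, known covariates.
#' @param n_trials,n_blocks Trials per environment and complete replicate
#'   blocks per trial.
#' @param missing_rate Fraction of plots masked missing (default 0.0654).
#'   Masking never removes a genotype from all environments.
#' @param Gg Genotype relationship: `NULL` for identity, `"markers"` to
#'   simulate markers and build the GRM, or a matrix /
#'   `genomic_relationship`.
#' @param covariates Optional raw covariate table (simulated when `NULL` and
#'   the family uses covariates).
#' @param n_latent Latent basis columns for `ifa` (default `p - q`).
#' @param params Optional list of true `G_e` parameters (as in
#'   [assemble_Ge()]); generated when `NULL`.
#' @param var_common Target mean per-environment common-factor variance.
#' @param var_specific Range of specific variances `psi_j`.
#' @param var_block Block variance (recycled to `p`).
#' @param var_resid Range of residual variances.
#' @param env_mean_sd Mean and sd of environment means.
#' @param tau_s Optional q-vector of mean responses to the covariates added to
#'   the environment means (covariate regression of the fixed effects).
#' @param n_markers Markers when `Gg = "markers"`.
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @return List of class `met_sim` with `data` (a `met_data`), `truth`
#'   (true parameters, scores, deviations, `G_e`, `G_g`, basis, seed),
#'   `covariates` (raw tibble or `NULL`), `markers` (or `NULL`) and `Gg`.
#' @export
simulate_met <- function(spec, v = 200L, p = 24L, q = 18L,
                         n_trials = 1L, n_blocks = 2L,
                         missing_rate = 0.0654,
                         Gg = NULL, covariates = NULL, n_latent = NULL,
                         params = NULL,
                         var_common = 0.0225,
                         var_specific = c(0.005, 0.01),
                         var_block = 0.02,
                         var_resid = c(0.04, 0.10),
                         env_mean_sd = c(1.7, 0.4),
                         tau_s = NULL,
                         n_markers = 1000L,
                         seed = NULL) {
  assert_that(inherits(spec, "vm_spec"), "spec must be a vm_spec")
  f <- spec$family
  needs_cov <- f %in% c("rreg1", "rreg2", "far", "ifa")
  with_seed(seed, {
    # genotype relationship ---------------------------------------------------
    markers <- NULL
    if (is.null(Gg)) {
      Ggm <- diag(v)
      dimnames(Ggm) <- list(paste0("G", seq_len(v)), paste0("G", seq_len(v)))
    } else if (identical(Gg, "markers")) {
      markers <- simulate_markers(v, n_markers)
      Ggm <- compute_grm(markers)$G
    } else {
      Ggm <- if (inherits(Gg, "genomic_relationship")) Gg$G else Gg
      assert_that(is_square_numeric(Ggm) && nrow(Ggm) == v,
                  "Gg must be v x v", class = "metfa_input_error")
      if (is.null(rownames(Ggm)))
        dimnames(Ggm) <- list(paste0("G", seq_len(v)), paste0("G", seq_len(v)))
    }
    genotypes <- rownames(Ggm)
    eps <- 1e-8 * mean(diag(Ggm))
    Lg <- t(chol(Ggm + diag(eps, v)))

    # covariates and basis ----------------------------------------------------
    basis <- NULL
    if (needs_cov) {
      if (is.null(covariates)) covariates <- simulate_covariates(p, q)
      cov_prep <- prepare_covariates(covariates)
      basis <- build_projection(cov_prep, n_latent = n_latent)
      assert_that(basis$p == p, "covariate table rows must match p",
                  class = "metfa_input_error")
    }
    envs <- if (!is.null(basis)) basis$envs else paste0("E", seq_len(p))

    # true G_e parameters ------------------------------------------------------
    if (is.null(params)) {
      params <- default_truth_params(spec, p, q, basis, var_common, var_specific)
    }
    Ge <- assemble_Ge(spec, params, basis = basis, p = p)

    # GE effects with component records ----------------------------------------
    k <- spec$k
    comp <- draw_ge_effects(spec, params, basis, p, v, Lg)
    Umat <- comp$Umat

    sb2 <- rep_len(var_block, p)
    se2 <- runif(p, var_resid[1L], var_resid[2L])
    mu_env <- rnorm(p, env_mean_sd[1L], env_mean_sd[2L])
    if (!is.null(tau_s)) {
      assert_that(needs_cov, "tau_s requires a covariate-using family",
                  class = "metfa_input_error")
      mu_env <- mu_env + as.numeric(basis$S %*% tau_s)
    }

    # assemble plots ------------------------------------------------------------
    rows <- vector("list", p * n_trials * n_blocks)
    ri <- 0L
    for (j in seq_len(p)) {
      for (tt in seq_len(n_trials)) {
        for (b in seq_len(n_blocks)) {
          beta <- rnorm(1L, 0, sqrt(sb2[j]))
          e <- rnorm(v, 0, sqrt(se2[j]))
          ri <- ri + 1L
          rows[[ri]] <- tibble::tibble(
            env = envs[j], trial = paste0("T", tt), block = paste0("B", b),
            genotype = genotypes,
            value = mu_env[j] + beta + Umat[, j] + e)
        }
      }
    }
    plots <- dplyr::bind_rows(rows)

    if (missing_rate > 0) {
      drop <- runif(nrow(plots)) < missing_rate
      # keep every genotype observed somewhere and every environment non-empty
      for (g in genotypes) {
        gi <- which(plots$genotype == g)
        if (all(drop[gi])) drop[gi[1L]] <- FALSE
      }
      for (ee in envs) {
        eidx <- which(plots$env == ee)
        if (all(drop[eidx])) drop[eidx[1L]] <- FALSE
      }
      plots$value[drop] <- NA_real_
    }

    data <- load_met_dataset(plots, env_levels = envs, genotype_levels = genotypes)
    truth <- structure(list(
      spec = spec, params = params, Ge = Ge, Gg = Ggm,
      scores = comp$scores, deviations = comp$deviations,
      intercepts = comp$intercepts, slopes = comp$slopes,
      U = Umat, basis = basis,
      mu_env = mu_env, sigma2_block = sb2, sigma2_resid = se2,
      seed = seed), class = "met_truth")
    structure(list(data = data, truth = truth, covariates = covariates,
                   markers = markers, Gg = Ggm, basis = basis),
              class = "met_sim")
  })
}

# family-specific true parameter generation
default_truth_params <- function(spec, p, q, basis, var_common, var_specific) {
  f <- spec$family
  k <- spec$k
  psi <- runif(p, var_specific[1L], var_specific[2L])
  tr_target <- p * var_common
  dec <- function(k) {
    w <- 0.55^(seq_len(k) - 1L)
    tr_target * w / sum(w)
  }
  if (f == "id") return(list(sigma2_ge = var_common + mean(psi)))
  if (f == "diag") return(list(sigma2_ge = var_common + psi))
  if (f == "comp") return(list(sigma2_g = var_common / 2,
                               sigma2_ge = var_common / 2 + mean(psi)))
  if (f == "mdiag") return(list(sigma2_g = var_common / 2,
                                sigma2_ge = var_common / 2 + psi))
  if (f == "rreg1") return(list(sigma2_g = var_common * p / (2 * p),
                                sigma2_s = tr_target / (2 * q),
                                psi = psi))
  if (f == "rreg2") return(list(sigma2_g = var_common / 2,
                                sigma2_si = runif(q, 0.5, 1.5) * tr_target / (2 * q),
                                psi = psi))
  # first factor all-positive (non-crossover GEI), higher factors orthogonal
  # to it and mean-balanced (predominately crossover GEI)
  positive_first <- function() {
    l1 <- abs(rnorm(p, 1, 0.3))
    l1 / sqrt(sum(l1^2))
  }
  if (f %in% c("fa", "fam")) {
    l1 <- positive_first()
    L0 <- cbind(l1, if (k > 1L) {
      Zr <- matrix(rnorm(p * (k - 1L)), p, k - 1L)
      Zr <- Zr - l1 %*% crossprod(l1, Zr)
      qr.Q(qr(Zr))[, seq_len(k - 1L), drop = FALSE]
    })
    d <- dec(k)
    out <- list(Lambda = unname(L0), d = d, psi = psi)
    if (f == "fam") { out$sigma2_1 <- var_common / 4; }
    return(out)
  }
  if (f == "far") {
    targ1 <- positive_first()
    La <- cbind(qr.solve(basis$A, targ1),
                if (k > 1L) matrix(rnorm((q + 1L) * (k - 1L)), q + 1L, k - 1L))
    AL <- basis$A %*% La
    La <- sweep(La, 2L, sqrt(colSums(AL^2)), `/`)
    return(list(Lambda_a = unname(La), d = dec(k), psi = psi))
  }
  # ifa: latent columns beyond k_r structurally zero. The generating
  # structure mirrors fitted MET analyses: the first factor is predominantly
  # latent with all-positive loadings (non-crossover GEI; known share ~20%),
  # higher factors are predominantly known-covariate-driven (crossover GEI;
  # known share ~90%, or 100% beyond k_r). Composite columns have unit norm.
  known_share <- c(0.2, rep(0.9, k - 1L))
  if (spec$k_r < k) known_share[(spec$k_r + 1L):k] <- 1
  unit <- function(x) x / sqrt(sum(x^2))
  Ls <- matrix(0, q, k)
  Lr <- matrix(0, basis$n_latent, k)
  for (l in seq_len(k)) {
    s_part <- unit(rnorm(q))
    Ls[, l] <- sqrt(known_share[l]) * s_part
    if (l <= spec$k_r) {
      r_part <- if (l == 1L) {
        # latent part of factor 1: positive vector expressed in the latent
        # basis (the centred-covariate complement contains the unit vector)
        unit(as.numeric(crossprod(basis$Gamma, positive_first())))
      } else unit(rnorm(basis$n_latent))
      Lr[, l] <- sqrt(1 - known_share[l]) * r_part
    }
  }
  BL <- basis$S %*% Ls + basis$Gamma %*% Lr
  nrm <- sqrt(colSums(BL^2))
  Ls <- sweep(Ls, 2L, nrm, `/`); Lr <- sweep(Lr, 2L, nrm, `/`)
  if (mean(BL[, 1L] / nrm[1L]) < 0) { Ls[, 1L] <- -Ls[, 1L]; Lr[, 1L] <- -Lr[, 1L] }
  list(Lambda_s = unname(Ls), Lambda_r = unname(Lr), d = dec(k), psi = psi)
}

# draw the GE effect components for a family; returns v x p matrix plus records
draw_ge_effects <- function(spec, params, basis, p, v, Lg) {
  f <- spec$family
  k <- spec$k
  one_star <- rep(1 / sqrt(p), p)
  scores <- deviations <- intercepts <- slopes <- NULL
  rn <- function(n) matrix(rnorm(v * n), v, n)
  if (f %in% c("fa", "fam", "far", "ifa")) {
    Lam <- switch(f,
                  fa = , fam = as.matrix(params$Lambda),
                  far = basis$A %*% params$Lambda_a,
                  ifa = basis$S %*% params$Lambda_s + basis$Gamma %*% params$Lambda_r)
    d <- params$d %||% rep(1, k)
    scores <- Lg %*% sweep(rn(k), 2L, sqrt(d), `*`)
    deviations <- Lg %*% sweep(rn(p), 2L, sqrt(params$psi), `*`)
    Umat <- tcrossprod(scores, Lam) + deviations
    if (f == "fam") {
      intercepts <- as.numeric(Lg %*% rnorm(v, 0, sqrt(p * params$sigma2_1)))
      Umat <- Umat + tcrossprod(intercepts, one_star)
    }
  } else if (f %in% c("rreg1", "rreg2")) {
    intercepts <- as.numeric(Lg %*% rnorm(v, 0, sqrt(p * params$sigma2_g)))
    svar <- if (f == "rreg1") rep(params$sigma2_s, basis$q) else params$sigma2_si
    slopes <- Lg %*% sweep(rn(basis$q), 2L, sqrt(svar), `*`)
    deviations <- Lg %*% sweep(rn(p), 2L, sqrt(params$psi), `*`)
    Umat <- tcrossprod(intercepts, one_star) + tcrossprod(slopes, basis$S) + deviations
  } else {
    # id/diag/comp/mdiag via the assembled G_e directly
    Ge <- assemble_Ge(spec, params, basis = basis, p = p)
    ce <- chol(Ge + diag(1e-12, p))
    Umat <- Lg %*% rn(p) %*% ce
    if (f %in% c("comp", "mdiag")) {
      # not separable into intercepts/deviations without extra draws; record total
    }
  }
  list(Umat = Umat, scores = scores, deviations = deviations,
       intercepts = intercepts, slopes = slopes)
}

#' Write a simulated MET to the standard delimited files
#'
#' Emits the same three files the loaders read (`phenotypes.csv`,
#' `covariates.csv`, `markers.csv` when present) plus `truth.json` with the
#' generating parameters.
#'
#' @param sim A `met_sim` from [simulate_met()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_met_files <- function(sim, dir) {
  assert_that(inherits(sim, "met_sim"), "sim must be a met_sim")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(phenotypes = file.path(dir, "phenotypes.csv"))
  write_met_phenotypes(sim$data, paths[["phenotypes"]])
  if (!is.null(sim$covariates)) {
    paths[["covariates"]] <- file.path(dir, "covariates.csv")
    utils::write.csv(sim$covariates, paths[["covariates"]], row.names = FALSE,
                     quote = FALSE)
  }
  if (!is.null(sim$markers)) {
    paths[["markers"]] <- file.path(dir, "markers.csv")
    write_markers(sim$markers, paths[["markers"]])
  }
  paths[["truth"]] <- file.path(dir, "truth.json")
  tr <- sim$truth
  jsonlite::write_json(list(
    family = tr$spec$family, k = tr$spec$k, k_r = tr$spec$k_r,
    params = lapply(tr$params, unclass),
    mu_env = tr$mu_env, sigma2_block = tr$sigma2_block,
    sigma2_resid = tr$sigma2_resid, seed = tr$seed),
    paths[["truth"]], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
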