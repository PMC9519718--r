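# build a synthetic rotated solution directly (principal axes, unit-norm
# composite loadings) for identity checks that need no model fit
synthetic_rotation <- function(p, q, k, seed, family = "ifa") {
  set.seed(seed)
  cov <- simulate_covariates(p, q, seed = seed)
  basis <- build_projection(prepare_covariates(cov))
  raw <- matrix(rnorm(p * k), p, k)
  raw[, 1] <- abs(raw[, 1])
  U <- qr.Q(qr(raw))
  if (mean(U[, 1]) < 0) U[, 1] <- -U[, 1]
  d <- sort(runif(k, 0.5, 2), decreasing = TRUE)
  psi <- runif(p, 0.05, 0.3)
  stacked <- solve(basis$B, U)
  Ge <- U %*% (d * t(U)) + diag(psi)
  structure(list(Lambda = U, d = d, stacked = stacked,
                 Lambda_s = stacked[seq_len(q), , drop = FALSE],
                 Lambda_r = stacked[-seq_len(q), , drop = FALSE],
                 scores = matrix(rnorm(20 * k), 20, k),
                 deviations = matrix(0, 20, p),
                 psi = psi, Ge = Ge, family = family,
                 spec = vm_spec(family, k), basis = basis,
                 envs = paste0("E", seq_len(p)),
                 genotypes = paste0("G", 1:20), p = p, v = 20),
            class = "met_rotation")
}

test_that("variance-explained identities hold on random rotated solutions", {
  for (seed in 1:25) {
    p <- sample(6:10, 1); q <- sample(2:4, 1); k <- sample(1:3, 1)
    rot <- synthetic_rotation(p, q, k, seed)
    ve <- variance_explained(rot)
    expect_equal(ve$overall$vbar, sum(ve$factors$v_l), tolerance = 1e-10)
    expect_equal(ve$overall$vbar_s, sum(ve$factors$v_sl), tolerance = 1e-10)
    expect_lte(ve$overall$vbar_s, ve$overall$vbar + 1e-10)
    expect_lte(ve$overall$vbar, 100 + 1e-10)
    # per-covariate shares against an element-wise recomputation
    trG <- sum(diag(rot$Ge))
    S <- rot$basis$S
    for (i in seq_len(q)) {
      a_i <- rot$Lambda_s[i, ]
      num <- 0
      for (l in seq_len(k)) {
        num <- num + sum(S[, i] * (S %*% rot$Lambda_s[, l])) *
          rot$d[l] * a_i[l]
      }
      den <- sum(a_i^2 * rot$d) * trG
      expect_equal(ve$covariates$v_si[i], unname(100 * num^2 / den),
                   tolerance = 1e-10)
    }
    # v_l. = 100 * v_sl / v_l and the v_li decomposition sums to it
    expect_equal(ve$factors$v_ldot, 100 * ve$factors$v_sl / ve$factors$v_l,
                 tolerance = 1e-8)
  }
})

test_that("full-span factors explain everything; zero latent block makes known = overall", {
  p <- 6; q <- 2
  rot <- synthetic_rotation(p, q, 2, 99)
  rot$psi <- rep(0, p)
  rot$Ge <- rot$Lambda %*% (rot$d * t(rot$Lambda))
  ve0 <- variance_explained(rot)
  expect_equal(ve0$overall$vbar, 100, tolerance = 1e-10)

  rot2 <- synthetic_rotation(p, q, 1, 100)
  rot2$Lambda_r[] <- 0
  nrm <- sqrt(sum((rot2$basis$S %*% rot2$Lambda_s)^2))
  rot2$Lambda_s <- rot2$Lambda_s / nrm
  rot2$Lambda <- rot2$basis$S %*% rot2$Lambda_s
  rot2$stacked <- rbind(rot2$Lambda_s, rot2$Lambda_r)
  rot2$Ge <- rot2$Lambda %*% (rot2$d * t(rot2$Lambda)) + diag(rot2$psi)
  ve2 <- variance_explained(rot2)
  expect_equal(ve2$overall$vbar_s, ve2$overall$vbar, tolerance = 1e-6)
  expect_equal(ve2$factors$v_ldot[1], 100, tolerance = 1e-6)
})

test_that("percentage summaries are invariant to phenotype rescaling", {
  sim <- simulate_met(vm_spec("ifa", 2), v = 25, p = 6, q = 2, n_blocks = 2,
                      missing_rate = 0, seed = 63)
  opts <- fit_options(max_iter = 150)
  f1 <- quiet_fit(sim$data, vm_spec("ifa", 2), basis = sim$basis,
                  options = opts)
  scaled <- sim$data$plots
  scaled$value <- scaled$value * 3
  d2 <- load_met_dataset(scaled[, c("env", "trial", "block", "genotype",
                                    "value")],
                         env_levels = sim$data$envs,
                         genotype_levels = sim$data$genotypes)
  # warm-start the rescaled fit from the rescaled solution so both runs sit
  # on the (exactly rescaled) optimum
  th_scaled <- f1$theta
  is_load <- grepl("^lambda", names(th_scaled))
  th_scaled[is_load] <- th_scaled[is_load] * 3
  th_scaled[!is_load] <- th_scaled[!is_load] * 9
  opts2 <- fit_options(max_iter = 150, start = unname(th_scaled))
  f2 <- quiet_fit(d2, vm_spec("ifa", 2), basis = sim$basis, options = opts2)
  v1 <- variance_explained(f1); v2 <- variance_explained(f2)
  expect_equal(v1$overall$vbar, v2$overall$vbar, tolerance = 1e-3)
  expect_equal(v1$overall$vbar_s, v2$overall$vbar_s, tolerance = 1e-3)
})

test_that("main effects follow the family formulas", {
  # FA with lambda_1 = 1/sqrt(p): lambda_bar = 1/sqrt(p), gamma* = f1/sqrt(p)
  p <- 5
  rot <- synthetic_rotation(p, 2, 1, 64, family = "fa")
  rot$Lambda <- matrix(rep(1 / sqrt(p), p), p, 1)
  rot$stacked <- rot$Lambda
  me <- main_effects(rot, "generalised")
  expect_equal(attr(me, "lambda_bar"), 1 / sqrt(p))
  expect_equal(me$effect, rot$scores[, 1] / sqrt(p))

  # IFA: var(gamma*) / var(f1) = lambda_bar_r1^2
  rot2 <- synthetic_rotation(7, 3, 2, 65)
  me2 <- main_effects(rot2, "generalised")
  lb <- sum(rot2$Lambda_r[, 1]) / rot2$p
  expect_equal(var(me2$effect) / var(rot2$scores[, 1]), lb^2,
               tolerance = 1e-10)
  expect_equal(attr(me2, "variance"), rot2$d[1] * lb^2)

  # FAM with centred loadings: simple main effects collapse to intercepts
  simf <- simulate_met(vm_spec("fam", 1), v = 20, p = 5, q = 2, n_blocks = 2,
                       missing_rate = 0, seed = 66)
  fitf <- quiet_fit(simf$data, vm_spec("fam", 1),
                    options = fit_options(max_iter = 100))
  rotf <- quiet_rot(fitf)
  mef <- main_effects(rotf, "simple")
  manual <- rotf$intercepts + sqrt(5) *
    as.numeric(rotf$scores %*% colMeans(rotf$Lambda))
  expect_equal(mef$effect, manual, tolerance = 1e-10)
  expect_error(main_effects(rotf, "generalised"),
               class = "metfa_main_effect_error")
})

test_that("environment correlations match brute-force conversion and rank-1 structure", {
  rot <- synthetic_rotation(6, 2, 1, 67)
  ec <- env_correlation(rot, parts = "full")
  expect_true(all(abs(abs(ec$correlation[upper.tri(ec$correlation)]) - 1) < 1e-10))

  rot2 <- synthetic_rotation(7, 3, 3, 68)
  for (parts in c("full", "known")) {
    ec2 <- env_correlation(rot2, parts = parts)
    C <- if (parts == "full") {
      rot2$Lambda %*% (rot2$d * t(rot2$Lambda))
    } else {
      SL <- rot2$basis$S %*% rot2$Lambda_s
      SL %*% (rot2$d * t(SL))
    }
    brute <- C / sqrt(outer(diag(C), diag(C)))
    expect_lt(max(abs(ec2$correlation - brute)), 1e-10)
    expect_true(all(diag(ec2$correlation) == 1))
    expect_true(all(abs(ec2$correlation) <= 1 + 1e-12))
    expect_setequal(ec2$order, 1:7)
  }

  # zero-variance environment under the known part flags NA
  rot3 <- synthetic_rotation(6, 2, 1, 69)
  rot3$Lambda_s[] <- 0
  ec3 <- env_correlation(rot3, parts = "known")
  expect_true(all(is.na(ec3$correlation[upper.tri(ec3$correlation)])))
})

test_that("regression plot data has exact slopes and factor-adjusted points", {
  rot <- synthetic_rotation(6, 2, 2, 70)
  # no deviations: points sit on the fitted lines for factor 1... k? factor 1
  df <- regression_plot_data(rot, c("G1", "G3"))
  d1 <- df[df$factor == 1 & df$genotype == "G1", ]
  resid1 <- d1$effect - d1$fitted
  # after removing factor 1, what remains is factor 2 only
  lam2 <- rot$Lambda[, 2]
  expect_equal(resid1, lam2 * rot$scores[1, 2], tolerance = 1e-10)
  expect_equal(unique(d1$slope), rot$scores[1, 1])
  # adjusted factor-2 points have zero projection on the factor-1 loadings
  d2 <- df[df$factor == 2 & df$genotype == "G1", ]
  expect_lt(abs(sum(d2$effect * rot$Lambda[, 1])), 1e-10)
  expect_equal(d2$effect, d2$fitted, tolerance = 1e-10)
  err <- expect_error(regression_plot_data(rot, "nope"),
                      class = "metfa_input_error")
  expect_match(conditionMessage(err), "nope")
  mk <- attr(df, "markers")
  expect_equal(nrow(mk), 2L)
})

test_that("Eq-consistency: FA first-factor share equals the generalised main-effect share", {
  rot <- synthetic_rotation(8, 3, 2, 71, family = "fa")
  rot$basis <- NULL; rot$Lambda_s <- NULL; rot$Lambda_r <- NULL
  rot$stacked <- rot$Lambda
  ve <- variance_explained(rot)
  expect_equal(ve$factors$v_l[1], 100 * rot$d[1] / sum(diag(rot$Ge)),
               tolerance = 1e-12)
})
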