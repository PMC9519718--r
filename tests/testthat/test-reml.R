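test_that("balanced and dense evaluators agree on likelihood, score and AI", {
  sim <- simulate_met(vm_spec("ifa", 2), v = 20, p = 5, q = 2, n_blocks = 2,
                      missing_rate = 0, seed = 51)
  opts <- fit_options()
  frame <- metfa:::build_model_frame(sim$data, NULL, sim$basis,
                                     vm_spec("ifa", 2), opts)
  expect_true(frame$balanced)
  th <- metfa:::starting_theta(frame)
  ed <- metfa:::evaluator_dense(frame)(th, derivs = TRUE)
  eb <- metfa:::evaluator_balanced(frame)(th, derivs = TRUE)
  expect_equal(ed$ll, eb$ll, tolerance = 1e-10)
  expect_lt(max(abs(ed$score - eb$score)), 1e-6)
  expect_lt(max(abs(ed$AI - eb$AI)) / max(abs(ed$AI)), 1e-8)
  expect_lt(max(abs(ed$Umat - eb$Umat)), 1e-10)
})

test_that("the analytic score matches a numerical gradient", {
  sim <- simulate_met(vm_spec("far", 1), v = 12, p = 4, q = 2, n_blocks = 2,
                      missing_rate = 0.1, seed = 52)
  opts <- fit_options()
  frame <- metfa:::build_model_frame(sim$data, NULL, sim$basis,
                                     vm_spec("far", 1), opts)
  evalr <- metfa:::evaluator_dense(frame)
  th <- metfa:::starting_theta(frame)
  ev <- evalr(th, derivs = TRUE)
  num <- vapply(seq_along(th), function(a) {
    h <- 1e-6 * (abs(th[a]) + 1e-6)
    tp <- th; tp[a] <- tp[a] + h
    tm <- th; tm[a] <- tm[a] - h
    (evalr(tp, derivs = FALSE)$ll - evalr(tm, derivs = FALSE)$ll) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(ev$score - num)), 1e-3 * max(1, max(abs(num))))
})

test_that("a balanced single-environment fit recovers closed-form ANOVA REML", {
  set.seed(53)
  v <- 40; b <- 4
  Y <- outer(rnorm(v, 0, sqrt(0.3)), rep(1, b)) +
    outer(rep(1, v), rnorm(b, 0, sqrt(0.15))) +
    matrix(rnorm(v * b, 0, sqrt(0.2)), v, b) + 2
  plots <- expand.grid(genotype = paste0("G", 1:v), block = paste0("B", 1:b),
                       stringsAsFactors = FALSE)
  plots$env <- "E1"; plots$trial <- "T1"
  plots$value <- Y[cbind(match(plots$genotype, paste0("G", 1:v)),
                         match(plots$block, paste0("B", 1:b)))]
  met <- load_met_dataset(plots)
  fit <- quiet_fit(met, vm_spec("id"))
  an <- oracle_oneway_anova(Y)
  expect_equal(unname(fit$theta[1]), an$sigma2_g, tolerance = 1e-4)
  expect_equal(unname(fit$sigma2_block), an$sigma2_b, tolerance = 1e-4)
  expect_equal(unname(fit$sigma2_resid), an$sigma2_e, tolerance = 1e-4)
})

test_that("converged log-likelihoods respect model nesting", {
  sim <- simulate_met(vm_spec("fa", 2), v = 30, p = 5, q = 2, n_blocks = 2,
                      missing_rate = 0, seed = 54)
  opts <- fit_options(max_iter = 200)
  ll <- function(spec) quiet_fit(sim$data, spec, basis = sim$basis,
                                 options = opts)$loglik
  expect_gte(ll(vm_spec("mdiag")), ll(vm_spec("comp")) - 1e-6)
  expect_gte(ll(vm_spec("fa", 2)), ll(vm_spec("fa", 1)) - 1e-6)
  expect_gte(ll(vm_spec("fam", 1)), ll(vm_spec("fa", 1)) - 1e-6)
})

test_that("FAR and IFA fits are translationally invariant", {
  sim <- simulate_met(vm_spec("far", 1), v = 20, p = 5, q = 2, n_blocks = 2,
                      missing_rate = 0, seed = 55)
  opts <- fit_options(max_iter = 200)
  for (spec in list(vm_spec("far", 1), vm_spec("ifa", 1))) {
    f0 <- quiet_fit(sim$data, spec, basis = sim$basis, options = opts)
    shifted <- sim$data$plots
    shifted$value <- shifted$value + 5
    data2 <- load_met_dataset(shifted[, c("env", "trial", "block", "genotype",
                                          "value")],
                              env_levels = sim$data$envs,
                              genotype_levels = sim$data$genotypes)
    f5 <- quiet_fit(data2, spec, basis = sim$basis, options = opts)
    expect_lt(max(abs(f0$Ge - f5$Ge)), 1e-5)
    expect_equal(unname(f5$tau - f0$tau), rep(5, sim$data$p), tolerance = 1e-4)
  }
})

test_that("accepted iterations never decrease the log-likelihood", {
  sim <- simulate_met(vm_spec("fa", 1), v = 20, p = 4, q = 2, n_blocks = 2,
                      missing_rate = 0.05, seed = 56)
  fit <- quiet_fit(sim$data, vm_spec("fa", 1))
  expect_true(all(diff(fit$trace$loglik) >= -1e-8))
  expect_true(fit$converged)
})

test_that("starting values are deterministic and strictly positive on variances", {
  sim <- simulate_met(vm_spec("fa", 1), v = 15, p = 4, q = 2, n_blocks = 2,
                      seed = 57)
  s1 <- starting_values(sim$data, vm_spec("diag"))
  s2 <- starting_values(sim$data, vm_spec("diag"))
  expect_identical(s1, s2)
  expect_true(all(s1 > 0))
  s3 <- starting_values(sim$data, vm_spec("fa", 1))
  expect_true(all(s3[grepl("psi", names(s3))] > 0))
})

test_that("eigen-seeded factor starts sit close to the converged fit on one-factor data", {
  p <- 5
  lam <- matrix(seq(0.8, 1.2, length.out = p) / sqrt(p), p, 1)
  sim <- simulate_met(vm_spec("fa", 1), v = 60, p = p, q = 2, n_blocks = 2,
                      missing_rate = 0,
                      params = list(Lambda = lam, d = 0.2,
                                    psi = rep(0.002, p)),
                      seed = 58)
  opts <- fit_options(max_iter = 200)
  frame <- metfa:::build_model_frame(sim$data, NULL, NULL, vm_spec("fa", 1),
                                     opts)
  th0 <- metfa:::starting_theta(frame)
  ll0 <- metfa:::evaluator_balanced(frame)(th0, derivs = FALSE)$ll
  fit_diag <- quiet_fit(sim$data, vm_spec("diag"), options = opts)
  fit_fa <- quiet_fit(sim$data, vm_spec("fa", 1), options = opts)
  gap <- fit_fa$loglik - fit_diag$loglik
  expect_gt(gap, 0)
  # the start recovers most of the diag -> FA1 gap on strongly 1-factor data
  expect_gt(ll0, fit_fa$loglik - 0.05 * gap)
})

test_that("AIC uses the variance-parameter count and logLik carries df", {
  sim <- simulate_met(vm_spec("comp"), v = 15, p = 4, q = 2, n_blocks = 2,
                      seed = 59)
  fit <- quiet_fit(sim$data, vm_spec("comp"))
  expect_equal(fit$m_total, 2 + 4 + 4)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$m_total)
  expect_equal(AIC(fit), fit$aic)
  expect_equal(met_aic(0, 0), 0)
})

test_that("fixed-effect covariate regression adds the random env term", {
  sim <- simulate_met(vm_spec("rreg1"), v = 20, p = 6, q = 2, n_blocks = 2,
                      missing_rate = 0, seed = 60)
  opts <- fit_options(fixed_covariates = TRUE, max_iter = 60)
  fit <- quiet_fit(sim$data, vm_spec("rreg1"), basis = sim$basis,
                   options = opts)
  expect_named(fit$tau, c("(mu)", "cov1", "cov2"))
  expect_false(is.null(fit$sigma2_omega))
  expect_equal(oracle_ll_of_fit(fit, sim$data), fit$loglik, tolerance = 1e-6)
})
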