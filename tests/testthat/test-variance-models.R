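# closed forms for the genetic parameter counts, recomputed independently of
# the package's free-entry enumeration
closed_form_count <- function(family, p, q = 0, k = 0, k_r = k) {
  switch(family,
         id = 1, diag = p, comp = 2, mdiag = p + 1,
         rreg1 = p + 2, rreg2 = p + q + 1,
         fam = p * (k + 1) - k * (k - 1) / 2 + 1,
         fa = p * (k + 1) - k * (k - 1) / 2,
         far = p + k * (2 * q - k + 3) / 2,
         ifa = q * k + (p - q) * k_r - k * (k - 1) / 2 + p)
}

test_that("parameter counts reproduce the closed forms across a grid", {
  for (p in c(4, 9, 17, 24, 30)) {
    for (fam in c("id", "diag", "comp", "mdiag")) {
      expect_equal(count_parameters(vm_spec(fam), p), closed_form_count(fam, p))
    }
    for (q in unique(pmin(c(1, 3, p - 1), p - 1))) {
      expect_equal(count_parameters(vm_spec("rreg1"), p, q),
                   closed_form_count("rreg1", p, q))
      expect_equal(count_parameters(vm_spec("rreg2"), p, q),
                   closed_form_count("rreg2", p, q))
      for (k in 1:min(5, q)) {
        expect_equal(count_parameters(vm_spec("far", k), p, q),
                     closed_form_count("far", p, q, k))
        if (q < p) {
          if (k <= p - q) {
            expect_equal(count_parameters(vm_spec("ifa", k), p, q),
                         closed_form_count("ifa", p, q, k))
          }
          for (kr in seq_len(k)) {
            if (kr <= p - q) {
              expect_equal(count_parameters(vm_spec("ifa", k, k_r = kr), p, q),
                           closed_form_count("ifa", p, q, k, kr))
            }
          }
        }
      }
    }
    for (k in 1:min(5, p)) {
      expect_equal(count_parameters(vm_spec("fa", k), p),
                   closed_form_count("fa", p, k = k))
      expect_equal(count_parameters(vm_spec("fam", k), p),
                   closed_form_count("fam", p, k = k))
    }
  }
  expect_error(count_parameters(vm_spec("fa", 10), p = 4),
               class = "metfa_spec_error")
  expect_error(count_parameters(vm_spec("far", 4), p = 8, q = 2),
               class = "metfa_spec_error")
})

test_that("G_e assembly matches the family algebra on hand-checkable cases", {
  expect_equal(assemble_Ge(vm_spec("comp"),
                           list(sigma2_g = 1, sigma2_ge = 0.5), p = 2),
               matrix(c(1.5, 1, 1, 1.5), 2))
  L <- matrix(c(1, 1) / sqrt(2), 2, 1)
  expect_equal(assemble_Ge(vm_spec("fa", 1),
                           list(Lambda = L, d = 2, psi = c(0.1, 0.1)), p = 2),
               matrix(c(1.1, 1, 1, 1.1), 2))
  expect_error(assemble_Ge(vm_spec("fa", 1),
                           list(Lambda = L, d = -1, psi = c(0.1, 0.1)), p = 2),
               class = "metfa_negative_variance_error")
})

test_that("ifa assembly with a square basis equals fa assembly at Lambda = B Lambda_b", {
  set.seed(21)
  cov <- simulate_covariates(p = 7, q = 3, seed = 21)
  basis <- build_projection(prepare_covariates(cov))
  k <- 2
  Ls <- matrix(rnorm(3 * k), 3, k)
  Lr <- matrix(rnorm(4 * k), 4, k)
  d <- c(2, 1); psi <- runif(7, 0.1, 0.3)
  Ge_ifa <- assemble_Ge(vm_spec("ifa", k), list(Lambda_s = Ls, Lambda_r = Lr,
                                                d = d, psi = psi), basis)
  Lam <- basis$B %*% rbind(Ls, Lr)
  Ge_fa <- assemble_Ge(vm_spec("fa", k), list(Lambda = Lam, d = d, psi = psi),
                       p = 7)
  expect_lt(max(abs(Ge_ifa - Ge_fa)), 1e-10)
})

test_that("rreg1 equals rreg2 with equal slope variances; psi never lowers eigenvalues", {
  set.seed(22)
  cov <- simulate_covariates(p = 6, q = 3, seed = 22)
  basis <- build_projection(prepare_covariates(cov))
  psi <- runif(6, 0.05, 0.2)
  g1 <- assemble_Ge(vm_spec("rreg1"),
                    list(sigma2_g = 0.4, sigma2_s = 0.7, psi = psi), basis)
  g2 <- assemble_Ge(vm_spec("rreg2"),
                    list(sigma2_g = 0.4, sigma2_si = rep(0.7, 3), psi = psi),
                    basis)
  expect_lt(max(abs(g1 - g2)), 1e-12)
  expect_lt(max(abs(g1 - t(g1))), 1e-12)
  g0 <- assemble_Ge(vm_spec("rreg1"),
                    list(sigma2_g = 0.4, sigma2_s = 0.7, psi = rep(0, 6)),
                    basis)
  e_with <- eigen(g1, symmetric = TRUE, only.values = TRUE)$values
  e_without <- eigen(g0, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(e_with >= e_without - 1e-10))
  expect_gt(min(e_with), -1e-8)
})

test_that("a FAM model re-expresses as a special FA(k+1) with centred loadings", {
  # lambda_bar = 0.2, d = 1, sigma2_1 = 0.5, k = 1 -> sigma2_g = 0.54
  p <- 5
  L <- matrix(0.2 + c(-0.2, -0.1, 0, 0.1, 0.2), p, 1)
  out <- fam_as_special_fa(list(sigma2_1 = 0.5, Lambda = L, d = 1,
                                psi = rep(0.1, p)))
  expect_equal(out$sigma2_g, 0.54)
  expect_lt(max(abs(crossprod(out$Lambda_star, rep(1 / sqrt(p), p)))), 1e-12)

  # already-centred loadings: sigma2_g = sigma2_1 and Lambda unchanged
  Lc <- matrix(c(-1, 0, 1, 0, 0), p, 1)
  outc <- fam_as_special_fa(list(sigma2_1 = 0.3, Lambda = Lc, d = 2,
                                 psi = rep(0.1, p)))
  expect_equal(outc$sigma2_g, 0.3)
  expect_equal(outc$Lambda_star, Lc)

  # random FAM parameters: reassembled G_e identical
  set.seed(23)
  L2 <- matrix(rnorm(12), 6, 2)
  pars <- list(sigma2_1 = 0.4, Lambda = L2, d = c(1.5, 0.7),
               psi = runif(6, 0.05, 0.2))
  Ge <- assemble_Ge(vm_spec("fam", 2), pars, p = 6)
  sp <- fam_as_special_fa(pars)
  Ge2 <- sp$basis %*% sp$D %*% t(sp$basis) + diag(pars$psi)
  expect_lt(max(abs(Ge - Ge2)), 1e-10)
  # Eq-8-style identity through the simple-main-effect variance
  expect_equal(sp$sigma2_g,
               pars$sigma2_1 + sum(pars$d * colMeans(L2)^2))
})
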