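# random constrained solutions in a given family geometry
random_constrained <- function(p, q, k, seed) {
  set.seed(seed)
  cov <- simulate_covariates(p, q, seed = seed)
  basis <- build_projection(prepare_covariates(cov))
  mask <- metfa:::loadings_mask(vm_spec("ifa", k), p, q)
  L <- matrix(rnorm(p * k), p, k)
  L[!mask] <- 0
  scores <- matrix(rnorm(30 * k), 30, k)
  list(basis = basis, Lambda = L, scores = scores)
}

test_that("rotation yields orthonormal loadings, ordered variances and an unchanged G_e", {
  for (seed in 1:100) {
    p <- sample(5:9, 1)
    q <- sample(2:(p - 2), 1)
    k <- sample(1:3, 1)
    rc <- random_constrained(p, q, k, seed)
    B <- rc$basis$B
    rot <- suppressWarnings(
      sign_convention(rotate_loadings(rc$Lambda, rc$scores, B)))
    expect_lt(max(abs(crossprod(rot$Lambda) - diag(k))), 1e-10)
    if (k > 1) expect_true(all(diff(rot$d) < 1e-12))
    Ge_pre <- tcrossprod(B %*% rc$Lambda)
    Ge_post <- rot$Lambda %*% (rot$d * t(rot$Lambda))
    expect_lt(max(abs(Ge_pre - Ge_post)), 1e-10)
    # fitted GE effects are invariant
    U_pre <- tcrossprod(rc$scores, B %*% rc$Lambda)
    U_post <- tcrossprod(rot$scores, rot$Lambda)
    expect_lt(max(abs(U_pre - U_post)), 1e-8)
  }
})

test_that("k = 1 rotation reduces to scaling plus a sign flip", {
  set.seed(7)
  lam <- -abs(rnorm(6))           # all-negative loadings
  scores <- matrix(rnorm(10), 10, 1)
  rot <- sign_convention(rotate_loadings(matrix(lam, 6, 1), scores))
  expect_equal(unname(rot$Lambda[, 1]), -lam / sqrt(sum(lam^2)))
  expect_true(all(rot$Lambda[, 1] > 0))
  expect_equal(rot$d[1], sum(lam^2))
  expect_lt(max(abs(tcrossprod(rot$scores, rot$Lambda) -
                      tcrossprod(scores, matrix(lam, 6, 1)))), 1e-12)
})

test_that("rotation is idempotent on principal-axis input", {
  set.seed(8)
  rc <- random_constrained(7, 3, 2, 8)
  rot1 <- suppressWarnings(
    sign_convention(rotate_loadings(rc$Lambda, rc$scores, rc$basis$B)))
  # principal-axis input: composite loadings already U D^(1/2)
  stacked_scaled <- rot1$stacked %*% diag(sqrt(rot1$d))
  rot2 <- suppressWarnings(
    sign_convention(rotate_loadings(stacked_scaled, NULL, rc$basis$B)))
  expect_lt(max(abs(abs(rot2$Lambda) - abs(rot1$Lambda))), 1e-8)
  expect_equal(rot2$d, rot1$d, tolerance = 1e-10)
})

test_that("collapsed factors are rejected with the factor index", {
  L <- cbind(c(1, 2, 1), c(2, 4, 2))   # rank 1
  err <- expect_error(rotate_loadings(L), class = "metfa_rotation_error")
  expect_match(conditionMessage(err), "2")
})

test_that("the sign convention preserves fitted effects and handles zero means", {
  set.seed(9)
  rot <- rotate_loadings(matrix(rnorm(12), 6, 2), matrix(rnorm(8), 4, 2))
  U_before <- tcrossprod(rot$scores, rot$Lambda)
  flipped <- suppressWarnings(sign_convention(rot))
  expect_lt(max(abs(tcrossprod(flipped$scores, flipped$Lambda) - U_before)),
            1e-12)
  # mean-zero column is left untouched
  lam <- cbind(c(1, 1, 1, 1) / 2, c(-0.5, 0.5, -0.5, 0.5))
  rot2 <- list(Lambda = lam, scores = matrix(1, 2, 2))
  out <- sign_convention(rot2, generalised = FALSE)
  expect_equal(out$Lambda[, 2], lam[, 2])
})

test_that("rotated score variances track the score-variance matrix D", {
  # empirical variance of rotated scores over simulator replicates follows d
  spec <- vm_spec("fa", 2)
  p <- 6
  base <- simulate_met(spec, v = 500, p = p, q = 2, n_blocks = 1,
                       missing_rate = 0, seed = 61)
  d_true <- base$truth$params$d
  emp <- apply(base$truth$scores, 2, var)
  expect_lt(max(abs(emp - d_true) / d_true), 0.35)
})
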