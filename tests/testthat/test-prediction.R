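test_that("left-out environment phenotypes never influence their prediction", {
  sim <- simulate_met(vm_spec("ifa", 1), v = 18, p = 4, q = 2, n_blocks = 2,
                      missing_rate = 0, seed = 81)
  opts <- fit_options(max_iter = 60)
  cv1 <- suppressWarnings(loeo_cv(sim$data, vm_spec("ifa", 1),
                                  sim$covariates, options = opts))
  plots2 <- sim$data$plots
  sel <- plots2$env == sim$data$envs[1]
  plots2$value[sel] <- rev(plots2$value[sel]) * -2  # sentinel corruption
  d2 <- load_met_dataset(plots2[, c("env", "trial", "block", "genotype",
                                    "value")],
                         env_levels = sim$data$envs,
                         genotype_levels = sim$data$genotypes)
  cv2 <- suppressWarnings(loeo_cv(d2, vm_spec("ifa", 1), sim$covariates,
                                  options = opts))
  expect_equal(cv1$predictions[[1]]$predicted, cv2$predictions[[1]]$predicted,
               tolerance = 1e-10)
  expect_false(isTRUE(all.equal(cv1$accuracy$accuracy[1],
                                cv2$accuracy$accuracy[1])))
})

test_that("accuracy summaries compute exact order statistics by region", {
  tab <- tibble::tibble(env = c("A", "B", "C"),
                        accuracy = c(0.2, 0.4, 0.6))
  s <- accuracy_summary(tab)
  expect_equal(s$min, 0.2); expect_equal(s$mean, 0.4); expect_equal(s$max, 0.6)

  tab2 <- tibble::tibble(env = c("A", "B", "C", "D"),
                         accuracy = c(0.2, 0.4, NA, 0.9))
  regions <- c(A = "south", B = "south", C = "north", D = "north")
  s2 <- accuracy_summary(tab2, regions)
  expect_equal(s2$n_undefined[s2$region == "north"], 1L)
  # brute-force group-by check
  south <- s2[s2$region == "south", ]
  expect_equal(south$mean, mean(c(0.2, 0.4)))
  north <- s2[s2$region == "north", ]
  expect_equal(north$min, 0.9)
  overall <- s2[s2$region == "overall", ]
  expect_equal(overall$mean, mean(c(0.2, 0.4, 0.9)))
  expect_error(accuracy_summary(tibble::tibble(env = "A", accuracy = NA)),
               class = "metfa_input_error")
})

test_that("future environments matching a training environment reproduce its known component", {
  sim <- simulate_met(vm_spec("ifa", 1), v = 20, p = 5, q = 2, n_blocks = 2,
                      missing_rate = 0, seed = 82)
  fit <- quiet_fit(sim$data, vm_spec("ifa", 1), basis = sim$basis,
                   options = fit_options(max_iter = 80))
  rot <- quiet_rot(fit)
  cov_raw <- as.data.frame(sim$covariates)
  newcov <- cov_raw[3, , drop = FALSE]
  newcov$env <- "FUT1"
  pr <- predict_future(fit, newcov)
  # manual Eq-34-style prediction with the training env's S row
  S3 <- fit$basis$S[3, , drop = FALSE]
  lb_r <- colSums(rot$Lambda_r) / fit$p
  manual <- as.numeric(rot$scores %*%
                         (as.numeric(S3 %*% rot$Lambda_s) + lb_r))
  expect_equal(pr$predictions[["FUT1"]]$predicted, manual, tolerance = 1e-10)

  # all-zero covariates reduce to the latent mean-loading term
  newcov0 <- newcov
  newcov0[names(newcov0) != "env"] <-
    as.list(fit$basis$transform$center)
  pr0 <- predict_future(fit, newcov0)
  expect_equal(pr0$predictions[[1]]$predicted,
               as.numeric(rot$scores %*% lb_r), tolerance = 1e-10)

  # missing covariate for the new environment is rejected by name
  err <- expect_error(predict_future(fit, newcov[, 1:2]),
                      class = "metfa_input_error")
  expect_match(conditionMessage(err), "cov2")
})

test_that("validation phenotypes give per-environment future accuracies", {
  spec <- vm_spec("ifa", 1)
  sim <- simulate_met(spec, v = 25, p = 6, q = 2, n_blocks = 2,
                      missing_rate = 0, seed = 83)
  fit <- quiet_fit(sim$data, spec, basis = sim$basis,
                   options = fit_options(max_iter = 80))
  # reuse two training environments as pseudo-future with their own data
  cov_raw <- as.data.frame(sim$covariates)[1:2, ]
  val_plots <- sim$data$plots[sim$data$plots$env %in% cov_raw$env,
                              c("env", "trial", "block", "genotype", "value")]
  val <- load_met_dataset(val_plots, genotype_levels = sim$data$genotypes)
  pr <- suppressWarnings(predict_future(fit, cov_raw, validation = val))
  expect_equal(nrow(pr$accuracy), 2L)
  expect_true(all(is.finite(pr$accuracy$accuracy)))
  expect_true(all(abs(pr$accuracy$accuracy) <= 1))
})

test_that("the integrated model out-predicts the simple random regression into future environments", {
  # paired simulation study: integrated truth, future environments drawn
  # from the training covariate distribution with latent components around
  # the training mean latent loading; one-sided sign test on the mean
  # accuracy difference
  n_rep <- 50
  diffs <- numeric(n_rep)
  safe_cor <- function(a, b) if (stats::sd(b) < 1e-12) 0 else cor(a, b)
  for (r in seq_len(n_rep)) {
    spec <- vm_spec("ifa", 2)
    sim <- simulate_met(spec, v = 25, p = 6, q = 2, n_blocks = 2,
                        missing_rate = 0, seed = 7000 + r)
    opts <- fit_options(max_iter = 40)
    f_ifa <- quiet_fit(sim$data, spec, basis = sim$basis, options = opts)
    f_rr <- quiet_fit(sim$data, vm_spec("rreg1"), basis = sim$basis,
                      options = opts)
    tr <- sim$truth
    Lat <- sim$basis$Gamma %*% tr$params$Lambda_r
    lat_mean <- colMeans(Lat)
    lat_sd <- apply(Lat, 2, sd)
    raw_fut <- simulate_covariates(6, 2, seed = 8000 + r)
    raw_fut$env <- paste0("F", 1:6)
    Sstar <- apply_covariate_transform(f_ifa$basis, raw_fut)
    pr_i <- suppressWarnings(predict_future(f_ifa, raw_fut))
    pr_r <- suppressWarnings(predict_future(f_rr, raw_fut))
    set.seed(9000 + r)
    acc <- matrix(NA_real_, 6, 2)
    for (j in 1:6) {
      a_j <- lat_mean + rnorm(2, 0, lat_sd)
      load_j <- as.numeric(Sstar[j, ] %*% tr$params$Lambda_s) + a_j
      u_star <- as.numeric(tr$scores %*% load_j)
      ybar <- u_star + rnorm(25, 0, sqrt(mean(tr$params$psi) + 0.06 / 2))
      acc[j, 1] <- safe_cor(ybar, pr_i$predictions[[j]]$predicted)
      acc[j, 2] <- safe_cor(ybar, pr_r$predictions[[j]]$predicted)
    }
    diffs[r] <- mean(acc[, 1]) - mean(acc[, 2])
  }
  expect_gt(mean(diffs), 0)
  p_sign <- binom.test(sum(diffs > 0), n_rep, alternative = "greater")$p.value
  expect_lt(p_sign, 0.05)
})

test_that("families without covariates or intercepts cannot predict unseen environments", {
  sim <- simulate_met(vm_spec("fa", 1), v = 15, p = 4, q = 2, n_blocks = 2,
                      missing_rate = 0, seed = 84)
  cov_df <- simulate_covariates(p = 4, q = 2, seed = 84)
  cov_df$env <- sim$data$envs
  expect_error(
    suppressWarnings(loeo_cv(sim$data, vm_spec("fa", 1), cov_df,
                             options = fit_options(max_iter = 30))),
    class = "metfa_predict_error")
})
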