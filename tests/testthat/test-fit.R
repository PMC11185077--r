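test_that("quadratic latent conditional matches the closed-form posterior", {
  # One animal, hyperparameters frozen: the sampler draws theta_i iid from
  # its exact conjugate conditional. Compare against a direct-formula
  # oracle: precision = X'R^-1 X + Sigma_e^-1 (all on the model's raw age
  # scale).
  ds <- tiny_dataset(n = 1, seed = 51, ages = seq(70, 500, 20))
  se <- quadratic_latent_covariance(ds$config$sigma_e, ds$config$mu,
                                    ds$config$ages)
  fit <- fit_growth_model(ds$records, ds$genotypes[, 0, drop = FALSE],
                          model = "quadratic", sigma_e = se,
                          sigma_alpha = se,
                          mcmc = mcmc_config(n_iter = 21000, burn_in = 1000,
                                             thin = 1, seed = 52),
                          update_hyper = FALSE)
  draws <- t(fit$theta[1, , ])  # S x 3

  ri <- ds$records
  X <- cbind(1, ri$age, ri$age^2)
  Rinv <- diag(1 / residual_sd(ri$age, ds$config$residual_bands)^2,
               nrow(ri))
  prior_mean <- colMeans(fit$mu)  # frozen at the LS initialization
  prec <- t(X) %*% Rinv %*% X + solve(se)
  mean_or <- solve(prec, t(X) %*% Rinv %*% ri$weight + solve(se, prior_mean))
  cov_or <- solve(prec)

  expect_true(all(apply(fit$mu, 2, sd) == 0))  # hyper frozen
  mc_se <- sqrt(diag(cov_or) / nrow(draws))
  expect_true(all(abs(colMeans(draws) - mean_or) < 4 * mc_se))
  scale_mat <- sqrt(outer(diag(cov_or), diag(cov_or)))
  expect_lt(max(abs(cov(draws) - cov_or) / scale_mat), 0.05)
})

test_that("conjugate sampler recovers the GLS oracle for (mu, alpha)", {
  ds <- tiny_dataset(n = 12, seed = 53, ages = seq(70, 500, 40))
  keep <- c(1, 3, 5)  # 3 QTL
  G <- ds$genotypes[, keep, drop = FALSE]
  se <- quadratic_latent_covariance(ds$config$sigma_e, ds$config$mu,
                                    ds$config$ages)
  sa <- quadratic_latent_covariance(ds$config$sigma_alpha, ds$config$mu,
                                    ds$config$ages)
  fit <- fit_growth_model(ds$records, G, model = "quadratic", sigma_e = se,
                          sigma_alpha = sa,
                          mcmc = mcmc_config(n_iter = 22000, burn_in = 2000,
                                             thin = 2, seed = 54))
  beta_or <- quad_gls_oracle(ds$records, G, se, sa,
                             ds$config$residual_bands)
  mu_got <- colMeans(fit$mu)
  al_got <- apply(fit$alpha, c(1, 2), mean)
  want_mu <- beta_or[1:3]
  want_al <- t(matrix(beta_or[-(1:3)], 3, 3))  # locus x trait
  mu_sd <- apply(fit$mu, 2, sd)
  al_sd <- apply(fit$alpha, c(1, 2), sd)
  expect_true(all(abs(mu_got - want_mu) / mu_sd < 0.2))
  expect_true(all(abs(al_got - want_al) / al_sd < 0.2))
})

test_that("noise-free Gompertz data pin the latents to their true values", {
  cfg <- sim_config(n_animals = 20, scale = "desk",
                    sigma_e = default_sigma_e() * 1e-4,
                    residual_bands = tibble::tibble(
                      age_lo = c(70, 168, 335), age_hi = c(167, 334, 500),
                      variance = c(0.01, 0.01, 0.01)))
  ds <- simulate_growth(cfg, seed = 55)
  fit <- fit_growth_model(ds$records, ds$genotypes, model = "gompertz",
                          sigma_e = cfg$sigma_e,
                          sigma_alpha = cfg$sigma_alpha,
                          residual_bands = cfg$residual_bands,
                          mcmc = mcmc_config(n_iter = 4000, burn_in = 2000,
                                             thin = 2,
                                             proposal_scales =
                                               c(0.05, 2e-5, 0.02),
                                             seed = 56))
  post_mean <- apply(fit$theta, c(1, 2), mean)
  rel <- abs(post_mean / ds$theta - 1)
  expect_lt(max(rel), 0.01)
})

test_that("null QTL effects shrink posterior marker effects toward zero", {
  cfg <- sim_config(n_animals = 25, scale = "desk")
  ds <- simulate_growth(cfg, seed = 57)
  ds$effects[] <- 0  # rebuild truth with null effects
  ds$theta_g <- genetic_latents(ds$genotypes, ds$effects, cfg$mu)
  ds$theta <- sample_latents(ds$theta_g, cfg$sigma_e, seed = 58)
  w <- t(vapply(seq_len(25), function(i) {
    gompertz_weight(cfg$ages, ds$theta[i, 1], ds$theta[i, 2], ds$theta[i, 3])
  }, numeric(length(cfg$ages))))
  set.seed(59)
  ds$records$weight <- as.numeric(t(w)) +
    rnorm(length(cfg$ages) * 25,
          sd = rep(residual_sd(cfg$ages, cfg$residual_bands), 25))
  fit <- fit_growth_model(ds$records, ds$genotypes, model = "gompertz",
                          sigma_e = cfg$sigma_e,
                          sigma_alpha = cfg$sigma_alpha,
                          mcmc = mcmc_config(n_iter = 1500, burn_in = 500,
                                             thin = 2, seed = 60))
  am <- apply(fit$alpha, c(1, 2), mean)
  asd <- apply(fit$alpha, c(1, 2), sd)
  expect_true(all(abs(am) < 3 * asd + 1e-12))
})

test_that("chains are seed-deterministic", {
  ds <- tiny_dataset(n = 6, seed = 61, ages = seq(70, 500, 60))
  mc <- mcmc_config(n_iter = 300, burn_in = 100, thin = 1, seed = 62)
  f1 <- fit_growth_model(ds$records, ds$genotypes, "gompertz",
                         sigma_e = ds$config$sigma_e,
                         sigma_alpha = ds$config$sigma_alpha, mcmc = mc)
  f2 <- fit_growth_model(ds$records, ds$genotypes, "gompertz",
                         sigma_e = ds$config$sigma_e,
                         sigma_alpha = ds$config$sigma_alpha, mcmc = mc)
  expect_identical(f1$mu, f2$mu)
  expect_identical(f1$theta, f2$theta)
})

test_that("EBV surfaces are per-draw curve averages, not curves of means", {
  ds <- tiny_dataset(n = 5, seed = 63, ages = seq(70, 500, 60))
  fit <- fit_growth_model(ds$records, ds$genotypes, "gompertz",
                          sigma_e = ds$config$sigma_e,
                          sigma_alpha = ds$config$sigma_alpha,
                          mcmc = mcmc_config(n_iter = 202, burn_in = 200,
                                             thin = 1, seed = 64))
  expect_identical(nrow(fit$mu), 2L)
  ages <- c(100, 400)
  ebv <- posterior_ebv(fit, "2", ages)
  # manual two-draw average of the genetic curves
  manual <- sapply(1:2, function(s) {
    thg <- fit$mu[s, ] + as.numeric(ds$genotypes["2", ] %*%
                                      fit$alpha[, , s])
    gompertz_weight(ages, thg[1], thg[2], thg[3])
  })
  expect_equal(as.numeric(ebv), rowMeans(manual))

  # single retained draw: the surface is exactly that draw's curve
  fit1 <- fit_growth_model(ds$records, ds$genotypes, "gompertz",
                           sigma_e = ds$config$sigma_e,
                           sigma_alpha = ds$config$sigma_alpha,
                           mcmc = mcmc_config(n_iter = 201, burn_in = 200,
                                              thin = 1, seed = 65))
  ebv1 <- posterior_ebv(fit1, "2", ages)
  thg <- fit1$mu[1, ] + as.numeric(ds$genotypes["2", ] %*%
                                     fit1$alpha[, , 1])
  expect_equal(as.numeric(ebv1),
               gompertz_weight(ages, thg[1], thg[2], thg[3]))
})

test_that("Gibbs genetic-variance estimator obeys its defining formula", {
  ds <- tiny_dataset(n = 4, seed = 66, ages = seq(70, 500, 60))
  fit <- fit_growth_model(ds$records, ds$genotypes, "gompertz",
                          sigma_e = ds$config$sigma_e,
                          sigma_alpha = ds$config$sigma_alpha,
                          mcmc = mcmc_config(n_iter = 201, burn_in = 200,
                                             thin = 1, seed = 67))
  ages <- c(150, 350)
  vu <- estimate_genetic_variance(fit, ages)
  # single draw, by hand: population variance (divisor n) of the curves
  thg <- sweep(ds$genotypes %*% fit$alpha[, , 1], 2, fit$mu[1, ], `+`)
  u <- sapply(ages, function(a) {
    vapply(1:4, function(i) {
      gompertz_weight(a, thg[i, 1], thg[i, 2], thg[i, 3])
    }, numeric(1))
  })
  expect_equal(vu$var_u, apply(u, 2, function(x) mean(x^2) - mean(x)^2))

  # identical genotypes: no genetic variance
  G1 <- ds$genotypes
  G1[] <- rep(G1[1, ], each = 4)
  fit2 <- fit_growth_model(ds$records, G1, "gompertz",
                           sigma_e = ds$config$sigma_e,
                           sigma_alpha = ds$config$sigma_alpha,
                           mcmc = mcmc_config(n_iter = 300, burn_in = 200,
                                              thin = 1, seed = 68))
  vu2 <- estimate_genetic_variance(fit2, ages)
  expect_lt(max(abs(vu2$var_u)), 1e-6)
})

test_that("tidy and glance expose posterior summaries", {
  ds <- tiny_dataset(n = 5, seed = 69, ages = seq(70, 500, 60))
  fit <- fit_growth_model(ds$records, ds$genotypes, "quadratic",
                          sigma_e = quadratic_latent_covariance(
                            ds$config$sigma_e, ds$config$mu, ds$config$ages),
                          mcmc = mcmc_config(n_iter = 300, burn_in = 100,
                                             thin = 1, seed = 70))
  td <- tidy(fit)
  expect_identical(nrow(td), 3L + 3L * ncol(ds$genotypes))
  expect_true(all(td$std.error > 0))
  gl <- glance(fit)
  expect_identical(gl$n_draws, 200L)
  expect_identical(gl$model, "quadratic")
})
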