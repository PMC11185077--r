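test_that("genotype sampling follows the Hardy-Weinberg binomial law", {
  g <- sample_genotypes(1500, 30, runif(30, 0.1, 0.9), seed = 7)
  expect_identical(dim(g), c(1500L, 30L))
  expect_true(all(g %in% 0:2))

  g1 <- sample_genotypes(1e5, 1, 0.5, seed = 8)
  obs <- tabulate(g1 + 1L, 3)
  chi <- sum((obs - 1e5 * c(0.25, 0.5, 0.25))^2 / (1e5 * c(0.25, 0.5, 0.25)))
  expect_lt(chi, qchisq(0.99, df = 2))

  # degenerate frequency limit: nearly all homozygous reference
  g2 <- sample_genotypes(1000, 1, 1 - 1e-12, seed = 9)
  expect_true(all(g2 == 2L))
  expect_error(sample_genotypes(10, 1, 1.2), "frequencies")
})

test_that("QTL effects reproduce their covariance and scale", {
  cfg <- sim_config()
  expect_equal(cfg$sigma_alpha, cfg$sigma_e / 30)
  eff <- sample_qtl_effects(cfg$sigma_alpha, 1e5, seed = 10)
  emp <- cov(eff)
  # 3 Monte-Carlo standard errors, elementwise: se(cov) ~ sqrt((s_ii s_jj +
  # s_ij^2)/n)
  for (a in 1:3) for (b in 1:3) {
    se <- sqrt((cfg$sigma_alpha[a, a] * cfg$sigma_alpha[b, b] +
                  cfg$sigma_alpha[a, b]^2) / 1e5)
    expect_lt(abs(emp[a, b] - cfg$sigma_alpha[a, b]), 3 * se)
  }
  expect_identical(nrow(sample_qtl_effects(cfg$sigma_alpha, 0)), 0L)
  expect_error(sample_qtl_effects(matrix(1, 3, 3), 5), "positive-definite")
})

test_that("genetic latents equal the explicit double-loop sum", {
  set.seed(12)
  G <- sample_genotypes(5, 4, c(0.2, 0.5, 0.7, 0.4))
  eff <- sample_qtl_effects(default_sigma_e() / 30, 4)
  mu <- c(160, 0.012, 24)
  got <- genetic_latents(G, eff, mu)
  want <- matrix(NA_real_, 5, 3)
  for (i in 1:5) {
    acc <- mu
    for (j in 1:4) acc <- acc + G[i, j] * eff[j, ]
    want[i, ] <- acc
  }
  expect_equal(unname(got), want)
  # trivial cases
  expect_equal(unname(genetic_latents(matrix(0L, 3, 4), eff, mu)),
               matrix(mu, 3, 3, byrow = TRUE))
  expect_equal(unname(genetic_latents(matrix(2L, 1, 1),
                                      eff[1, , drop = FALSE], mu)),
               matrix(mu + 2 * eff[1, ], 1))
})

test_that("latent sampling adds the configured environmental covariance", {
  mu <- c(160, 0.012, 24)
  theta_g <- matrix(mu, 1e5, 3, byrow = TRUE)
  se <- default_sigma_e(mu)
  theta <- sample_latents(theta_g, se, seed = 13)
  emp <- cov(theta - theta_g)
  for (a in 1:3) for (b in 1:3) {
    mc_se <- sqrt((se[a, a] * se[b, b] + se[a, b]^2) / 1e5)
    expect_lt(abs(emp[a, b] - se[a, b]), 3 * mc_se)
  }
  expect_true(attr(theta, "n_resampled") < 50)  # violations are rare

  # vanishing covariance limit: theta collapses onto theta_g
  theta0 <- sample_latents(theta_g[1:10, ], se * 1e-18, seed = 14)
  expect_equal(unname(theta0), unname(theta_g[1:10, ]), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("residual bands return the printed heterogeneous variances", {
  b <- default_residual_bands()
  expect_equal(residual_sd(70, b), sqrt(3))
  expect_equal(residual_sd(167, b), sqrt(3))
  expect_equal(residual_sd(168, b), 2)
  expect_equal(residual_sd(334, b), 2)
  expect_equal(residual_sd(335, b), sqrt(8))
  expect_equal(residual_sd(500, b), sqrt(8))
  expect_error(residual_sd(69, b), "outside")
  expect_error(residual_sd(501, b), "outside")
})

test_that("simulated datasets have the advertised structure and truth", {
  cfg <- sim_config(n_animals = 40, scale = "desk")
  ds <- simulate_growth(cfg, seed = 15)
  expect_identical(nrow(ds$records), 40L * length(cfg$ages))
  expect_identical(dim(ds$bv), c(40L, length(cfg$ages)))
  expect_true(all(is.finite(ds$records$weight)))
  expect_identical(anyDuplicated(ds$records[c("animal", "age")]), 0L)

  # noise-free limit: weights equal the genetic curves exactly
  cfg0 <- sim_config(n_animals = 10, scale = "desk",
                     sigma_e = default_sigma_e() * 1e-18,
                     residual_bands = tibble::tibble(
                       age_lo = c(70, 168, 335), age_hi = c(167, 334, 500),
                       variance = c(1e-18, 1e-18, 1e-18)))
  ds0 <- simulate_growth(cfg0, seed = 16)
  w <- matrix(ds0$records$weight, nrow = 10, byrow = TRUE)
  expect_equal(unname(w), unname(ds0$bv), tolerance = 1e-6)

  # the true-BV surface is the curve of the genetic latents, elementwise
  i <- 7
  expect_equal(ds$bv[i, "300"],
               gompertz_weight(300, ds$theta_g[i, 1], ds$theta_g[i, 2],
                               ds$theta_g[i, 3]),
               ignore_attr = TRUE)
  expect_gt(var(ds$bv[, "300"]), 0)
})

test_that("empirical residual variance matches the configured bands", {
  cfg <- sim_config(n_animals = 200, scale = "desk")
  bands <- cfg$residual_bands
  rel_err <- matrix(NA_real_, 5, 3)
  for (r in 1:5) {
    ds <- simulate_growth(cfg, seed = 500 + r)
    mean_w <- t(vapply(seq_len(200), function(i) {
      gompertz_weight(cfg$ages, ds$theta[i, 1], ds$theta[i, 2],
                      ds$theta[i, 3])
    }, numeric(length(cfg$ages))))
    resid <- matrix(ds$records$weight, 200, byrow = TRUE) - mean_w
    band_of <- findInterval(cfg$ages, bands$age_lo)
    for (k in 1:3) {
      rel_err[r, k] <- var(as.numeric(resid[, band_of == k])) /
        bands$variance[k] - 1
    }
  }
  expect_lt(max(abs(colMeans(rel_err))), 0.05)
})

test_that("simulation is bit-reproducible and config round-trips", {
  cfg <- sim_config(n_animals = 15, scale = "desk")
  a <- simulate_growth(cfg, seed = 20)
  b <- simulate_growth(cfg, seed = 20)
  expect_identical(a$records, b$records)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$theta, b$theta)

  dir <- withr::local_tempdir()
  write_growth_dataset(a, dir)
  expect_true(all(file.exists(file.path(dir, c("phenotypes.csv",
                                               "genotypes.csv",
                                               "truth_latents.csv",
                                               "truth_bv.csv",
                                               "config.txt")))))
  cfg2 <- read_sim_config(file.path(dir, "config.txt"))
  expect_equal(cfg2$sigma_e, cfg$sigma_e, ignore_attr = TRUE)
  expect_identical(cfg2$ages, cfg$ages)
  expect_equal(simulate_growth(cfg2, seed = 20)$records, a$records)
})

test_that("per-day phenotypic variance decomposes into curve and residual", {
  cfg <- sim_config(n_animals = 1000, ages = c(100L, 250L, 450L),
                    scale = "desk")
  ds <- simulate_growth(cfg, seed = 21)
  for (k in seq_along(cfg$ages)) {
    w <- ds$records$weight[ds$records$age == cfg$ages[k]]
    curve <- vapply(seq_len(1000), function(i) {
      gompertz_weight(cfg$ages[k], ds$theta[i, 1], ds$theta[i, 2],
                      ds$theta[i, 3])
    }, numeric(1))
    expected <- var(curve) + residual_sd(cfg$ages[k], cfg$residual_bands)^2
    expect_equal(var(w), expected, tolerance = 0.12)
  }
})
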