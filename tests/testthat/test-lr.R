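# Hand-built surfaces: 5 animals x 2 days.
mk_surface <- function(x) {
  m <- matrix(x, 5, 2)
  dimnames(m) <- list(as.character(1:5), c("100", "200"))
  m
}
vu1 <- tibble::tibble(age = c(100, 200), var_u = 1)

test_that("LR day statistics collapse correctly on identical surfaces", {
  up <- mk_surface(c(1, 2, 3, 4, 5, 2, 4, 6, 8, 10))
  d <- lr_day_stats(up, up, up, vu1)
  expect_equal(d$delta_hat, c(0, 0))
  expect_equal(d$slope_hat, c(1, 1))
  expect_equal(d$cov_hat, c(var(up[, 1]), var(up[, 2])))
  expect_equal(d$acc_true, c(1, 1))

  shifted <- up + 3
  d2 <- lr_day_stats(up, up, shifted, vu1)
  expect_equal(d2$delta_hat, c(-3, -3))
  expect_equal(d2$slope_hat, c(1, 1))
})

test_that("LR slope and covariance match hand arithmetic", {
  up <- mk_surface(rep(c(1, 2, 3, 4, 5), 2))
  uw <- mk_surface(rep(c(2, 4, 6, 8, 10), 2))
  u <- mk_surface(rep(c(5, 4, 3, 2, 1), 2))
  d <- lr_day_stats(u, up, uw, vu1)
  expect_equal(d$slope_hat, c(2, 2))          # cov(2x, x)/var(x)
  expect_equal(d$slope_true, c(-1, -1))       # perfectly anti-correlated
  expect_equal(d$cov_hat, c(5, 5))            # var(1:5) = 2.5, cov = 5
  expect_equal(d$acc_true, c(-1, -1))
  expect_equal(d$delta_true, c(0, 0))
  # accuracy denominator: var(u)hat = 1, var(up) = 2.5
  expect_equal(d$acc_hat, rep(5 / sqrt(2.5), 2))
})

test_that("degenerate partial EBV flags missing, not an error", {
  up <- mk_surface(rep(1, 10))
  uw <- mk_surface(rep(c(1, 2, 3, 4, 5), 2))
  d <- lr_day_stats(uw, up, uw, vu1)
  expect_true(all(is.na(d$slope_hat)))
  expect_true(all(is.na(d$acc_hat)))
  expect_equal(d$delta_hat, colMeans(up) - colMeans(uw), ignore_attr = TRUE)
})

test_that("replicate summaries are plain across-day means", {
  up <- mk_surface(c(1, 2, 3, 4, 5, 2, 4, 6, 8, 10))
  uw <- up + rep(c(0, 2), each = 5)  # delta_hat 0 on day 1, -2 on day 2
  d <- lr_day_stats(up, up, uw, vu1)
  s <- lr_summarize(d)
  expect_equal(s$delta_hat, -1)
  # brute-force mean oracle over a random day table
  set.seed(41)
  dd <- d[rep(1:2, 5), ]
  dd[2:9] <- matrix(rnorm(8 * 10), 10)
  s2 <- lr_summarize(dd)
  for (cc in names(dd)[-1]) expect_equal(s2[[cc]], sum(dd[[cc]]) / 10)
})

test_that("one-sample t-test matches the textbook computation", {
  v <- c(0.1, 0.2, 0.3, 0.4)
  rep_t <- lr_t_test(v, 0, "delta")
  t_hand <- mean(v) / (sd(v) / sqrt(4))
  expect_equal(rep_t$t, t_hand)
  expect_equal(rep_t$df, 3)
  expect_equal(rep_t$p.value, 2 * pt(-abs(t_hand), df = 3))

  # symmetric about the null: t = 0, p = 1
  sym <- lr_t_test(c(0.9, 1.1, 0.95, 1.05), 1)
  expect_equal(sym$t, 0)
  expect_equal(sym$p.value, 1)

  # overwhelming shift
  expect_lt(lr_t_test(rnorm(20, 50, 0.1), 0)$p.value, 1e-6)

  # zero variance is degenerate, flagged
  degen <- lr_t_test(rep(2, 5), 0)
  expect_true(degen$degenerate)
  expect_true(is.na(degen$p.value))
})

test_that("covariance-gap test is the t-test of per-replicate differences", {
  set.seed(42)
  rs <- tibble::tibble(cov_hat = rnorm(20, 1.5), cov_true = rnorm(20, 1.2))
  got <- lr_covariance_gap_test(rs)
  want <- t.test(rs$cov_hat - rs$cov_true, mu = 0)
  expect_equal(got$t, unname(want$statistic))
  expect_equal(got$p.value, want$p.value)
  expect_identical(got$statistic, "cov_gap")

  same <- tibble::tibble(cov_hat = 1:5, cov_true = 1:5)
  expect_true(lr_covariance_gap_test(same)$degenerate)
})

test_that("true accuracy is scale-free and delta flips sign on role swap", {
  set.seed(43)
  up <- mk_surface(rnorm(10))
  uw <- mk_surface(rnorm(10))
  u <- mk_surface(rnorm(10))
  d1 <- lr_day_stats(u, up, uw, vu1)
  d2 <- lr_day_stats(u, 3 * up + 7, uw, vu1)
  expect_equal(abs(d2$acc_true), abs(d1$acc_true))
  swap <- lr_day_stats(u, uw, up, vu1)
  expect_equal(swap$delta_hat, -d1$delta_hat)
})
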