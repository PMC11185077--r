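# Independent oracles used across test files.

# Root-finding construction of the boundary-constrained Gompertz curve: fix
# (A, I) of the standard form A * exp(-exp(-k (t - I))) from y(65) = bw65 and
# y(a115) = 115, without using the package's closed form.
gompertz_oracle <- function(t, a115, shape, bw65) {
  f <- function(I) {
    log(115 / bw65) - exp(-shape * (65 - I)) + exp(-shape * (a115 - I))
  }
  I <- stats::uniroot(f, c(-4000, 4000), extendInt = "yes",
                      tol = 1e-14)$root
  A <- 115 * exp(exp(-shape * (a115 - I)))
  A * exp(-exp(-shape * (t - I)))
}

# Random valid latent triples around the default intercepts.
random_triples <- function(n) {
  tibble::tibble(
    age115 = stats::runif(n, 100, 260),
    shape = stats::runif(n, 0.004, 0.04),
    bw65 = stats::runif(n, 5, 80))
}

# Small simulated dataset shared by fitting tests.
tiny_dataset <- function(n = 30, seed = 11, ages = seq(70, 500, 10)) {
  simulate_growth(sim_config(n_animals = n, ages = ages, scale = "desk"),
                  seed = seed)
}

# Direct generalized-least-squares solution of the fully conjugate
# (quadratic-curve) hierarchical model: marginal posterior mean of
# beta = (mu, alpha_1, ..., alpha_p) after integrating out theta and e.
quad_gls_oracle <- function(records, genotypes, sigma_e, sigma_alpha,
                            residual_bands) {
  animals <- rownames(genotypes)
  p <- ncol(genotypes)
  prec <- matrix(0, 3 * (p + 1), 3 * (p + 1))
  rhs <- numeric(3 * (p + 1))
  for (i in seq_along(animals)) {
    ri <- records[as.character(records$animal) == animals[i], ]
    if (nrow(ri) == 0) next
    X <- cbind(1, ri$age, ri$age^2)
    R <- diag(residual_sd(ri$age, residual_bands)^2, nrow(ri))
    V <- X %*% sigma_e %*% t(X) + R
    W <- do.call(cbind, c(list(X), lapply(seq_len(p), function(j) {
      genotypes[i, j] * X
    })))
    Vi <- solve(V)
    prec <- prec + t(W) %*% Vi %*% W
    rhs <- rhs + t(W) %*% Vi %*% ri$weight
  }
  for (j in seq_len(p)) {
    idx <- 3 * j + 1:3
    prec[idx, idx] <- prec[idx, idx] + solve(sigma_alpha)
  }
  solve(prec, rhs)
}
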