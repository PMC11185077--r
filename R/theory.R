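#' Tractable toy models for the conditional-mean identities
#'
#' The LR method rests on identities that hold whenever the predictor is a
#' conditional mean \eqn{\hat u = E(u \mid y)}: \eqn{Cov(\hat u_w, \hat u_p)
#' = Var(\hat u_p)}, unbiasedness \eqn{E(\hat u_p) = E(\hat u_w) = E(u)},
#' and the tower property \eqn{E_{y_r \mid y_p}(\hat u_w \mid y_p) = \hat
#' u_p}. These constructors define small models in which both conditional
#' means are independently computable, so the identities can be checked
#' empirically — including for a genuinely non-linear predictor.
#'
#' `toy_gaussian()` is a scalar breeding value \eqn{u \sim N(0,
#' \sigma^2_u)} observed through `n_p` partial and `n_r` additional
#' phenotypes \eqn{y = u + e} with residual variances `var_p`, `var_r`; the
#' conditional means are the usual linear shrinkage predictors.
#' `toy_probit()` observes binary threshold indicators \eqn{z = 1\{u + e >
#' 0\}}, making \eqn{E(u \mid z)} a non-linear function of the data,
#' computed by adaptive quadrature.
#'
#' @param sigma2_u Prior (genetic) variance of `u`.
#' @param n_p,n_r Number of partial and additional observations.
#' @param var_p,var_r Residual variances of the partial and additional
#'   observations (`var_obs` for the probit toy, shared).
#' @param var_obs Residual variance of the probit threshold observations.
#' @return An object of class `toy_gaussian` or `toy_probit`.
#' @name lr_toys
#' @export
toy_gaussian <- function(sigma2_u = 1, n_p = 2, var_p = 1, n_r = 2,
                         var_r = 2) {
  stopifnot(sigma2_u > 0, var_p > 0, var_r > 0, n_p >= 1, n_r >= 0)
  structure(list(sigma2_u = sigma2_u, n_p = as.integer(n_p), var_p = var_p,
                 n_r = as.integer(n_r), var_r = var_r),
            class = "toy_gaussian")
}

#' @rdname lr_toys
#' @export
toy_probit <- function(sigma2_u = 1, n_p = 2, n_r = 2, var_obs = 1) {
  stopifnot(sigma2_u > 0, var_obs > 0, n_p >= 1, n_r >= 0)
  structure(list(sigma2_u = sigma2_u, n_p = as.integer(n_p),
                 n_r = as.integer(n_r), var_obs = var_obs),
            class = "toy_probit")
}

#' Closed-form Gaussian conditional-mean predictors
#'
#' Exact \eqn{\hat u_p = E(u \mid y_p)} and \eqn{\hat u_w = E(u \mid y_p,
#' y_r)} for the Gaussian toy: with iid observations the conditional mean is
#' precision-weighted shrinkage,
#' \eqn{E(u \mid y) = (\sum_k y_k / v_k) / (1/\sigma^2_u + \sum_k 1/v_k)}.
#' `prior_var_scale_p` deliberately mis-scales the prior variance used for
#' the partial predictor only (a wrong-shrinkage negative control; 1 = the
#' true conditional mean).
#'
#' @param model A [toy_gaussian()].
#' @param y_p Matrix (replicates x `n_p`) or vector of partial phenotypes.
#' @param y_r Matrix/vector of additional phenotypes, or `NULL` for none
#'   (then \eqn{\hat u_w = \hat u_p}).
#' @param prior_var_scale_p Multiplier on `sigma2_u` used in \eqn{\hat u_p}.
#' @return A tibble with columns `u_p_hat`, `u_w_hat`, one row per
#'   replicate.
#' @export
conditional_means_gaussian <- function(model, y_p, y_r = NULL,
                                       prior_var_scale_p = 1) {
  stopifnot(inherits(model, "toy_gaussian"))
  y_p <- rbind(y_p)
  if (!is.null(y_r) && length(y_r)) y_r <- rbind(y_r) else y_r <- NULL
  stopifnot(ncol(y_p) == model$n_p)
  prec_p <- model$n_p / model$var_p
  u_p <- (rowSums(y_p) / model$var_p) /
    (1 / (model$sigma2_u * prior_var_scale_p) + prec_p)
  if (is.null(y_r)) {
    u_w <- (rowSums(y_p) / model$var_p) / (1 / model$sigma2_u + prec_p)
  } else {
    stopifnot(ncol(y_r) == model$n_r, nrow(y_r) == nrow(y_p))
    u_w <- (rowSums(y_p) / model$var_p + rowSums(y_r) / model$var_r) /
      (1 / model$sigma2_u + prec_p + model$n_r / model$var_r)
  }
  tibble::tibble(u_p_hat = as.numeric(u_p), u_w_hat = as.numeric(u_w))
}

#' Non-linear conditional mean for threshold observations
#'
#' \eqn{E(u \mid z)} for the probit toy by adaptive quadrature:
#' \eqn{p(u \mid z) \propto \phi(u; 0, \sigma^2_u) \prod_k \Phi((2 z_k - 1)
#' u / \sigma_{obs})}. With no observations the prior mean (0) is returned.
#'
#' @param model A [toy_probit()].
#' @param z Integer/logical vector of 0/1 threshold observations.
#' @param sigma2_u Prior variance to condition under (defaults to the
#'   model's; override for misspecified-predictor controls).
#' @return Scalar conditional mean.
#' @export
conditional_mean_probit <- function(model, z, sigma2_u = model$sigma2_u) {
  stopifnot(inherits(model, "toy_probit"))
  if (!length(z)) return(0)
  z <- as.integer(z)
  stopifnot(all(z %in% c(0L, 1L)))
  so <- sqrt(model$var_obs)
  su <- sqrt(sigma2_u)
  lik <- function(u) {
    out <- rep(1, length(u))
    for (k in seq_along(z)) {
      out <- out * stats::pnorm((2 * z[k] - 1) * u / so)
    }
    out
  }
  num <- stats::integrate(function(u) u * lik(u) * stats::dnorm(u, 0, su),
                          -Inf, Inf, subdivisions = 200L,
                          rel.tol = 1e-10)
  den <- stats::integrate(function(u) lik(u) * stats::dnorm(u, 0, su),
                          -Inf, Inf, subdivisions = 200L, rel.tol = 1e-10)
  if (den$value <= 0) stop("quadrature failed.", call. = FALSE)
  num$value / den$value
}

# Conditional means for every 0/1 pattern of `m` observations, cached once
# so that Monte-Carlo loops are table lookups.
.probit_pattern_means <- function(model, m, sigma2_u = model$sigma2_u) {
  if (m == 0) return(matrix(0, 1, 0))
  pats <- as.matrix(expand.grid(rep(list(0:1), m)))
  means <- apply(pats, 1, function(z) {
    conditional_mean_probit(model, z, sigma2_u = sigma2_u)
  })
  list(patterns = pats, means = means)
}

.pattern_index <- function(z) {
  # Rows of expand.grid(rep(list(0:1), m)) enumerate in base-2 with the
  # first column fastest.
  as.integer(z %*% 2^(seq_along(z[1, ]) - 1)) + 1L
}

#' Empirically verify the LR conditional-mean identities
#'
#' Simulates `n_mc` independent realizations of `(u, y_p, y_r)` from a toy
#' model, computes the conditional-mean predictors for each, and estimates
#' the deviations whose theoretical value is exactly zero:
#'
#' * `cov_gap`: \eqn{Cov(\hat u_w, \hat u_p) - Var(\hat u_p)};
#' * `bias_p`, `bias_w`: \eqn{E(\hat u_p) - E(u)}, \eqn{E(\hat u_w) - E(u)};
#' * `tower_dev`: the deviation of the Monte-Carlo average of \eqn{\hat u_w}
#'   over \eqn{y_r \mid y_p} from \eqn{\hat u_p}, reported at the
#'   conditioning value where the standardized deviation is largest.
#'
#' Each row carries its Monte-Carlo standard error; under the theory every
#' estimate should lie within ~3 standard errors of zero. Setting
#' `misspecify_partial = TRUE` replaces \eqn{\hat u_p} by a wrong-shrinkage
#' predictor (prior variance inflated fourfold), a negative control under
#' which `cov_gap` must deviate.
#'
#' @param model A [toy_gaussian()] or [toy_probit()].
#' @param n_mc Number of Monte-Carlo replicates (>= 1e4 recommended).
#' @param seed Integer seed.
#' @param misspecify_partial Use the deliberately wrong partial predictor.
#' @param tower_k Number of conditioning values for the tower check.
#' @param tower_n_mc Monte-Carlo draws of `y_r | y_p` per conditioning
#'   value.
#' @return A tibble with columns `identity`, `estimate`, `mc_se`, `n_mc`.
#' @export
verify_lr_identities <- function(model, n_mc = 1e4, seed = 1L,
                                 misspecify_partial = FALSE, tower_k = 20,
                                 tower_n_mc = 2000) {
  set.seed(seed)
  scale_p <- if (misspecify_partial) 4 else 1
  if (inherits(model, "toy_gaussian")) {
    u <- stats::rnorm(n_mc, 0, sqrt(model$sigma2_u))
    y_p <- u + matrix(stats::rnorm(n_mc * model$n_p, 0, sqrt(model$var_p)),
                      n_mc)
    y_r <- if (model$n_r > 0) {
      u + matrix(stats::rnorm(n_mc * model$n_r, 0, sqrt(model$var_r)), n_mc)
    } else NULL
    cm <- conditional_means_gaussian(model, y_p, y_r,
                                     prior_var_scale_p = scale_p)
    tower <- .tower_gaussian(model, tower_k, tower_n_mc, scale_p)
  } else if (inherits(model, "toy_probit")) {
    so <- sqrt(model$var_obs)
    u <- stats::rnorm(n_mc, 0, sqrt(model$sigma2_u))
    z_p <- matrix(stats::rnorm(n_mc * model$n_p, 0, so), n_mc) + u > 0
    z_p <- matrix(as.integer(z_p), n_mc)
    z_r <- matrix(as.integer(matrix(stats::rnorm(n_mc * model$n_r, 0, so),
                                    n_mc) + u > 0), n_mc)
    lut_p <- .probit_pattern_means(model, model$n_p,
                                   sigma2_u = model$sigma2_u * scale_p)
    lut_w <- .probit_pattern_means(model, model$n_p + model$n_r)
    cm <- tibble::tibble(
      u_p_hat = lut_p$means[.pattern_index(z_p)],
      u_w_hat = lut_w$means[.pattern_index(cbind(z_p, z_r))])
    tower <- .tower_probit(model, tower_k, tower_n_mc, scale_p)
  } else {
    stop("`model` must be a toy_gaussian or toy_probit.", call. = FALSE)
  }
  d <- (cm$u_w_hat - cm$u_p_hat) * (cm$u_p_hat - mean(cm$u_p_hat))
  bp <- cm$u_p_hat - u
  bw <- cm$u_w_hat - u
  mc_row <- function(id, x) {
    tibble::tibble(identity = id, estimate = mean(x),
                   mc_se = stats::sd(x) / sqrt(length(x)),
                   n_mc = length(x))
  }
  dplyr::bind_rows(mc_row("cov_gap", d), mc_row("bias_p", bp),
                   mc_row("bias_w", bw), tower)
}

# Tower check, Gaussian: for fixed y_p, draw u | y_p then fresh y_r, and
# compare the Monte-Carlo mean of u_w_hat with u_p_hat.
.tower_gaussian <- function(model, k, m, scale_p) {
  u0 <- stats::rnorm(k, 0, sqrt(model$sigma2_u))
  y_p <- u0 + matrix(stats::rnorm(k * model$n_p, 0, sqrt(model$var_p)), k)
  prec_post <- 1 / model$sigma2_u + model$n_p / model$var_p
  u_p_true <- (rowSums(y_p) / model$var_p) / prec_post  # true conditional
  u_p_used <- conditional_means_gaussian(model, y_p,
                                         prior_var_scale_p = scale_p)$u_p_hat
  pv <- 1 / prec_post
  dev <- se <- numeric(k)
  for (i in seq_len(k)) {
    uu <- stats::rnorm(m, u_p_true[i], sqrt(pv))
    yr <- uu + matrix(stats::rnorm(m * model$n_r, 0, sqrt(model$var_r)), m)
    uw <- conditional_means_gaussian(
      model, matrix(y_p[i, ], m, model$n_p, byrow = TRUE), yr)$u_w_hat
    dev[i] <- mean(uw) - u_p_used[i]
    se[i] <- stats::sd(uw) / sqrt(m)
  }
  worst <- which.max(abs(dev) / se)
  tibble::tibble(identity = "tower_dev", estimate = dev[worst],
                 mc_se = se[worst], n_mc = m)
}

# Tower check, probit: rejection-sample u | z_p, then fresh z_r.
.tower_probit <- function(model, k, m, scale_p) {
  so <- sqrt(model$var_obs)
  su <- sqrt(model$sigma2_u)
  u0 <- stats::rnorm(k, 0, su)
  z_p <- matrix(as.integer(matrix(stats::rnorm(k * model$n_p, 0, so), k) +
                             u0 > 0), k)
  lut_p <- .probit_pattern_means(model, model$n_p,
                                 sigma2_u = model$sigma2_u * scale_p)
  lut_w <- .probit_pattern_means(model, model$n_p + model$n_r)
  dev <- se <- numeric(k)
  for (i in seq_len(k)) {
    zi <- z_p[i, , drop = FALSE]
    acc <- matrix(NA_real_, 0, 1)
    us <- numeric(0)
    while (length(us) < m) {  # rejection: accept u with prob P(z_p | u)
      cand <- stats::rnorm(2 * m, 0, su)
      pr <- rep(1, length(cand))
      for (kk in seq_len(model$n_p)) {
        pr <- pr * stats::pnorm((2 * zi[1, kk] - 1) * cand / so)
      }
      us <- c(us, cand[stats::runif(length(cand)) < pr])
    }
    us <- us[seq_len(m)]
    zr <- matrix(as.integer(matrix(stats::rnorm(m * model$n_r, 0, so), m) +
                              us > 0), m)
    zp_rep <- matrix(zi, m, model$n_p, byrow = TRUE)
    uw <- lut_w$means[.pattern_index(cbind(zp_rep, zr))]
    dev[i] <- mean(uw) - lut_p$means[.pattern_index(zi)]
    se[i] <- stats::sd(uw) / sqrt(m)
  }
  worst <- which.max(abs(dev) / se)
  tibble::tibble(identity = "tower_dev", estimate = dev[worst],
                 mc_se = se[worst], n_mc = m)
}
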