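#' MCMC settings for the hierarchical growth samplers
#'
#' @param n_iter Total Gibbs iterations.
#' @param burn_in Discarded initial iterations (`< n_iter`).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param proposal_scales Initial random-walk standard deviations for the
#'   three Gompertz latent components (age115 days, shape 1/day, bw65 kg);
#'   ignored by the conjugate quadratic sampler.
#' @param adapt Adapt proposal scales toward `target_acc` during burn-in
#'   (Robbins-Monro on the log scale); the post-burn-in chain is left
#'   Markov-homogeneous.
#' @param target_acc Target Metropolis acceptance rate.
#' @param seed Integer seed for the chain.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 5000, burn_in = 1000, thin = 4,
                        proposal_scales = c(1, 2.5e-4, 0.4), adapt = TRUE,
                        target_acc = 0.35, seed = 1L) {
  stopifnot(burn_in < n_iter, thin >= 1, all(proposal_scales > 0),
            target_acc > 0, target_acc < 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin),
                 proposal_scales = as.numeric(proposal_scales),
                 adapt = isTRUE(adapt), target_acc = target_acc,
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

# Internal age rescaling for the quadratic model: fitting on age/100 keeps
# the (1, t, t^2) cross-product well conditioned; the linear map
# theta' = D theta with D = diag(1, 100, 1e4) is applied to the latents and
# both covariance matrices and inverted on the stored draws, so the model
# itself is unchanged.
.QUAD_D <- c(1, 100, 1e4)

#' Fit a Bayesian hierarchical growth model
#'
#' Metropolis-within-Gibbs sampler for the hierarchical model
#' \deqn{BW_{it} = c(t; \theta_i) + \epsilon_{it}, \qquad
#'       \theta_i \sim MVN(\mu + \textstyle\sum_j m_{ij}\alpha_j, \Sigma_e),}
#' with flat prior on \eqn{\mu}, \eqn{\alpha_j \sim MVN(0, \Sigma_\alpha)},
#' age-banded residual variances, and all variance components held fixed
#' (the study design fixes them at their simulation values). The curve
#' \eqn{c} is the reparameterized Gompertz function (`model = "gompertz"`,
#' the true model) or a quadratic in age (`model = "quadratic"`, the wrong
#' model).
#'
#' Latent updates are componentwise Gaussian random-walk Metropolis for the
#' Gompertz model and exact trivariate-Gaussian conjugate draws for the
#' quadratic model; \eqn{\mu} and each \eqn{\alpha_j} have exact
#' multivariate-normal conditionals. Genotyped animals without phenotype
#' records in the supplied view (validation animals of a between-animal
#' partition) still carry latent draws from the marker-informed prior, which
#' leaves the posterior of \eqn{(\mu, \alpha)} unchanged. Latents are
#' initialized at per-animal least-squares curve fits (record-less animals
#' at the mean of those fits).
#'
#' @param records Long tibble/data frame with columns `animal`, `age`,
#'   `weight` (e.g. `dataset$records` or `partition$partial_records`).
#' @param genotypes Integer matrix of allele counts with animal ids as
#'   rownames; must cover every animal in `records` and may include
#'   additional (validation) animals.
#' @param model `"gompertz"` or `"quadratic"`.
#' @param sigma_e,sigma_alpha Fixed 3x3 latent and per-QTL covariances.
#' @param residual_bands Fixed residual bands, see
#'   [default_residual_bands()].
#' @param mcmc An [mcmc_config()].
#' @param update_hyper Update `mu` and `alpha` (default). `FALSE` freezes
#'   them at their initial values (`mu` at the mean of the least-squares
#'   latent fits, `alpha` at zero) so the latent conditionals can be
#'   examined in isolation; intended for sampler validation.
#' @return An object of class `growth_fit` holding posterior draws `mu`
#'   (S x 3), `alpha` (p x 3 x S), `theta` (n x 3 x S), the genotype matrix,
#'   animal ids, training-animal ids, Metropolis acceptance rates and the
#'   settings used.
#' @seealso [posterior_ebv()], [estimate_genetic_variance()]
#' @export
fit_growth_model <- function(records, genotypes,
                             model = c("gompertz", "quadratic"),
                             sigma_e = default_sigma_e(),
                             sigma_alpha = sigma_e / 30,
                             residual_bands = default_residual_bands(),
                             mcmc = mcmc_config(), update_hyper = TRUE) {
  model <- match.arg(model)
  stopifnot(inherits(mcmc, "mcmc_config"))
  .check_spd(sigma_e, "sigma_e")
  .check_spd(sigma_alpha, "sigma_alpha")
  records <- tibble::as_tibble(records)
  stopifnot(all(c("animal", "age", "weight") %in% names(records)))
  animals <- rownames(genotypes)
  if (is.null(animals)) animals <- as.character(seq_len(nrow(genotypes)))
  rec_animal <- as.character(records$animal)
  if (!all(rec_animal %in% animals)) {
    stop("every animal in `records` must have a genotype row.", call. = FALSE)
  }

  ord <- order(match(rec_animal, animals), records$age)
  y <- records$weight[ord]
  age <- as.numeric(records$age[ord])
  rvar <- residual_sd(age, residual_bands)^2
  idx <- match(rec_animal[ord], animals)
  rec_count <- tabulate(idx, nbins = length(animals))
  rec_start <- cumsum(c(0L, rec_count[-length(rec_count)]))

  theta0 <- .init_latents(y, age, rec_start, rec_count, model)
  mu0 <- colMeans(theta0[rec_count > 0, , drop = FALSE])
  if (any(rec_count == 0)) {
    theta0[rec_count == 0, ] <- matrix(mu0, sum(rec_count == 0), 3,
                                       byrow = TRUE)
  }

  G <- matrix(as.numeric(genotypes), nrow(genotypes), ncol(genotypes))
  p <- ncol(G)
  se_fit <- sigma_e
  sa_fit <- sigma_alpha
  age_fit <- age
  if (model == "quadratic") {
    D <- diag(.QUAD_D)
    se_fit <- D %*% sigma_e %*% D
    sa_fit <- D %*% sigma_alpha %*% D
    age_fit <- age / 100
    theta0 <- theta0 %*% D
    mu0 <- as.numeric(mu0 %*% D)
  }

  set.seed(mcmc$seed)
  out <- mcmc_growth_cpp(y, age_fit, rvar, rec_start, rec_count, G, se_fit,
                         sa_fit, if (model == "gompertz") 0L else 1L,
                         mcmc$n_iter, mcmc$burn_in, mcmc$thin,
                         mcmc$proposal_scales, mcmc$adapt, mcmc$target_acc,
                         theta0, mu0, matrix(0, max(p, 1L), 3)[seq_len(p), ,
                                                               drop = FALSE],
                         update_hyper)

  mu_draws <- out$mu
  alpha_draws <- out$alpha
  theta_draws <- out$theta
  if (model == "quadratic") {
    # Map draws back from the age/100 fitting scale to raw coefficients.
    for (k in 1:3) {
      mu_draws[, k] <- mu_draws[, k] / .QUAD_D[k]
      alpha_draws[, k, ] <- alpha_draws[, k, , drop = FALSE] / .QUAD_D[k]
      theta_draws[, k, ] <- theta_draws[, k, , drop = FALSE] / .QUAD_D[k]
    }
  }
  acc <- as.numeric(out$acceptance)
  if (model == "gompertz" &&
      any(!is.na(acc) & (acc < 0.05 | acc > 0.95))) {
    warning("Metropolis acceptance rate outside (0.05, 0.95) after ",
            "adaptation: ", paste(round(acc, 3), collapse = ", "),
            call. = FALSE)
  }
  colnames(mu_draws) <- c("age115", "shape", "bw65")
  trn <- animals[rec_count > 0]
  structure(list(model = model, mu = mu_draws, alpha = alpha_draws,
                 theta = theta_draws, genotypes = G, animals = animals,
                 trn_animals = trn, n_trn = length(trn),
                 acceptance = acc, prop_scales = as.numeric(out$prop_scales),
                 sigma_e = sigma_e, sigma_alpha = sigma_alpha,
                 residual_bands = residual_bands, mcmc = mcmc,
                 n_records = length(y)),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit> ", x$model, " model: ", nrow(x$mu), " retained draws, ",
      length(x$animals), " animals (", x$n_trn, " with records, ",
      x$n_records, " records)\n", sep = "")
  if (x$model == "gompertz") {
    cat("  Metropolis acceptance: ",
        paste(sprintf("%.2f", x$acceptance), collapse = " / "), "\n", sep = "")
  }
  invisible(x)
}

#' Posterior-mean EBV surface
#'
#' Estimated breeding values for body weight: for each retained draw the
#' genetic latents \eqn{\theta_g^{(s)} = \mu^{(s)} + \sum_j m_{ij}
#' \alpha_j^{(s)}} are pushed through the fitted model's growth curve, and
#' the per-draw curves are averaged. This is the Monte-Carlo conditional
#' mean \eqn{E(u \mid y)} — not the curve at the posterior-mean parameters,
#' which would differ for a non-linear curve.
#'
#' @param fit A `growth_fit`.
#' @param animals Character/integer vector of animal ids (default: all
#'   genotyped animals in the fit).
#' @param ages Ages (days) at which to evaluate the EBV surface.
#' @return Numeric matrix `animals x ages` with an attached `model`
#'   attribute.
#' @export
posterior_ebv <- function(fit, animals = NULL, ages) {
  stopifnot(inherits(fit, "growth_fit"), nrow(fit$mu) >= 1)
  if (is.null(animals)) animals <- fit$animals
  animals <- as.character(animals)
  ridx <- match(animals, fit$animals)
  if (anyNA(ridx)) stop("unknown animal id(s).", call. = FALSE)
  p <- dim(fit$alpha)[1]
  has_alpha <- ncol(fit$genotypes) > 0
  G <- fit$genotypes[ridx, , drop = FALSE]
  out <- ebv_surface_cpp(fit$mu, fit$alpha, G, as.numeric(ages),
                         if (fit$model == "gompertz") 0L else 1L, has_alpha)
  dimnames(out) <- list(animals, as.character(ages))
  attr(out, "model") <- fit$model
  out
}

#' Gibbs estimator of the per-day genetic variance
#'
#' For each retained draw \eqn{s} and day \eqn{t}, the population variance
#' (divisor \eqn{n_{trn}}) of the genetic body-weight curves over the
#' training animals,
#' \eqn{v_s(t) = \frac{1}{n_{trn}}\sum_j u_{j,s}(t)^2 -
#' (\frac{1}{n_{trn}}\sum_j u_{j,s}(t))^2}, averaged across draws
#' (Rao-Blackwellized across the chain). This is the \eqn{\widehat{var(u)}}
#' entering the denominator of the LR population-accuracy estimator.
#'
#' @param fit A `growth_fit` with at least two training animals.
#' @param ages Ages (days) at which to estimate the variance.
#' @return A tibble with columns `age`, `var_u`.
#' @export
estimate_genetic_variance <- function(fit, ages) {
  stopifnot(inherits(fit, "growth_fit"))
  if (fit$n_trn < 2) {
    stop("need at least two training animals.", call. = FALSE)
  }
  ridx <- match(fit$trn_animals, fit$animals)
  G <- fit$genotypes[ridx, , drop = FALSE]
  v <- genetic_variance_cpp(fit$mu, fit$alpha, G, as.numeric(ages),
                            if (fit$model == "gompertz") 0L else 1L,
                            ncol(fit$genotypes) > 0)
  tibble::tibble(age = as.numeric(ages), var_u = as.numeric(v))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of a growth-model fit
#'
#' One row per intercept component and per QTL-by-trait substitution
#' effect, with posterior means and standard deviations.
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `locus`, `trait`, `estimate`,
#'   `std.error`.
#' @export
tidy.growth_fit <- function(x, ...) {
  traits <- c("age115", "shape", "bw65")
  if (x$model == "quadratic") traits <- c("b0", "b1", "b2")
  mu_tb <- tibble::tibble(parameter = "mu", locus = NA_integer_,
                          trait = traits, estimate = colMeans(x$mu),
                          std.error = apply(x$mu, 2, stats::sd))
  p <- ncol(x$genotypes)
  if (p == 0) return(mu_tb)
  am <- apply(x$alpha, c(1, 2), mean)
  as_ <- apply(x$alpha, c(1, 2), stats::sd)
  al_tb <- tibble::tibble(parameter = "alpha",
                          locus = rep(seq_len(p), times = 3),
                          trait = rep(traits, each = p),
                          estimate = as.numeric(am),
                          std.error = as.numeric(as_))
  dplyr::bind_rows(mu_tb, al_tb)
}

#' One-row summary of a growth-model fit
#'
#' @param x A `growth_fit`.
#' @param ... Unused.
#' @return A tibble with the model tag, chain dimensions and Metropolis
#'   acceptance rates.
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(model = x$model, n_draws = nrow(x$mu),
                 n_animals = length(x$animals), n_trn = x$n_trn,
                 n_records = x$n_records,
                 acc_1 = x$acceptance[1], acc_2 = x$acceptance[2],
                 acc_3 = x$acceptance[3])
}

#' Express latent covariances on the quadratic model's scale
#'
#' The study fixes variance components at their simulation values in both
#' the true and the wrong model. The simulation values live on the Gompertz
#' latent scale (Age115, Shape, BW65); the wrong model's latents are
#' quadratic coefficients (b0, b1, b2) in very different units. This helper
#' carries a Gompertz-latent covariance into the quadratic basis by the
#' linearized least-squares projection of the growth curve:
#' \deqn{\Sigma_Q = J \Sigma J', \qquad
#'       J = (X'X)^{-1} X' \left.\frac{\partial g}{\partial \theta}
#'       \right|_{\mu},}
#' where \eqn{X} is the quadratic design over the recording ages. A small
#' perturbation of the Gompertz latents moves the curve by
#' \eqn{\partial g/\partial\theta \, d\theta}; \eqn{J d\theta} is the
#' corresponding move of its best-fitting quadratic coefficients, so
#' \eqn{\Sigma_Q} is the same dispersion information expressed in the wrong
#' model's units.
#'
#' @param sigma 3x3 covariance on the Gompertz latent scale (`sigma_e` or
#'   `sigma_alpha`).
#' @param mu Gompertz latent intercepts around which to linearize.
#' @param ages Recording ages (days) defining the projection grid.
#' @return A 3x3 SPD covariance for (b0, b1, b2).
#' @export
quadratic_latent_covariance <- function(sigma, mu, ages) {
  .check_spd(sigma, "sigma")
  ages <- as.numeric(ages)
  X <- cbind(1, ages, ages^2)
  jac <- vapply(1:3, function(k) {
    h <- abs(mu[k]) * 1e-6
    up <- dn <- as.numeric(mu)
    up[k] <- up[k] + h
    dn[k] <- dn[k] - h
    (.gompertz(ages, up[1], up[2], up[3]) -
        .gompertz(ages, dn[1], dn[2], dn[3])) / (2 * h)
  }, numeric(length(ages)))
  J <- solve(crossprod(X), crossprod(X, jac))
  out <- J %*% sigma %*% t(J)
  (out + t(out)) / 2
}

# Per-animal least-squares initialization of the latent triples.
.init_latents <- function(y, age, rec_start, rec_count, model) {
  n <- length(rec_count)
  theta0 <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (rec_count[i] == 0) next
    sel <- (rec_start[i] + 1):(rec_start[i] + rec_count[i])
    ti <- age[sel]
    yi <- y[sel]
    if (model == "quadratic") {
      if (rec_count[i] >= 3) {
        theta0[i, ] <- stats::lm.fit(cbind(1, ti, ti^2), yi)$coefficients
      } else {
        theta0[i, ] <- c(mean(yi), 0, 0)
      }
    } else {
      theta0[i, ] <- .gomp_ls(ti, yi)
    }
  }
  theta0
}

# Moment-based Gompertz start: anchor bw65 and age115 from the record path,
# then 1-D least squares over the shape parameter.
.gomp_ls <- function(ti, yi) {
  o <- order(ti)
  ti <- ti[o]
  yi <- yi[o]
  slope <- if (length(ti) > 1) {
    max((yi[length(yi)] - yi[1]) / (ti[length(ti)] - ti[1]), 1e-3)
  } else 0.8
  bw65 <- min(max(yi[1] - slope * (ti[1] - 65), 1), 110)
  if (any(yi >= 115)) {
    k <- which(yi >= 115)[1]
    a115 <- if (k == 1) ti[1] else {
      ti[k - 1] + (115 - yi[k - 1]) / max(yi[k] - yi[k - 1], 1e-6) *
        (ti[k] - ti[k - 1])
    }
  } else {
    a115 <- ti[length(ti)] + (115 - yi[length(yi)]) / slope
  }
  a115 <- max(a115, 70)
  sse <- function(s) sum((yi - .gompertz(ti, a115, s, bw65))^2)
  s_hat <- stats::optimize(sse, c(1e-4, 0.1))$minimum
  c(a115, s_hat, bw65)
}
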