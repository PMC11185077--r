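#' Default latent (co)variance of the growth parameters
#'
#' Environmental (co)variance matrix of the latent triple
#' (Age115 in days, Shape in 1/day, BW65 in kg). The package's calibration
#' stores the latent dispersion as a relative (proportional-to-mean) matrix —
#' its diagonal entries are squared coefficients of variation — and rescales
#' it to the natural units of the latents around the population intercepts
#' `mu`: \eqn{\Sigma_e = D \Sigma_{rel} D} with \eqn{D = diag(\mu)}. At the
#' default `mu = (160, 0.012, 24)` this gives latent standard deviations of
#' about 9.7 days, 0.0023 /day and 4.2 kg, with correlations
#' (+0.09, -0.52, -0.44) — a slow-growing pig is lighter at 65 days and
#' reaches 115 kg later.
#'
#' @param mu Numeric 3-vector of latent intercepts (Age115, Shape, BW65).
#' @param relative Logical; if `TRUE` return the relative-scale matrix
#'   itself instead of rescaling by `mu`.
#' @return A symmetric positive-definite 3x3 matrix.
#' @export
default_sigma_e <- function(mu = c(160, 0.012, 24), relative = FALSE) {
  s_rel <- matrix(c(3.65e-3, 1.05e-3, -5.51e-3,
                    1.05e-3, 3.52e-2, -1.44e-2,
                   -5.51e-3, -1.44e-2, 3.05e-2),
                  nrow = 3, byrow = TRUE,
                  dimnames = list(c("age115", "shape", "bw65"),
                                  c("age115", "shape", "bw65")))
  if (relative) return(s_rel)
  d <- diag(as.numeric(mu))
  out <- d %*% s_rel %*% d
  dimnames(out) <- dimnames(s_rel)
  out
}

#' Default age-banded residual variances
#'
#' Heterogeneous residual variances of daily body-weight records, mimicking
#' real pig growth data: 3.0 kg^2 for days 70-167, 4.0 kg^2 for days
#' 168-334 and 8.0 kg^2 for days 335-500. Bands are closed on both
#' endpoints.
#'
#' @return A tibble with columns `age_lo`, `age_hi`, `variance`.
#' @export
default_residual_bands <- function() {
  tibble::tibble(age_lo = c(70, 168, 335),
                 age_hi = c(167, 334, 500),
                 variance = c(3.0, 4.0, 8.0))
}

#' Simulation configuration
#'
#' Bundles every knob of the generative model: population size, QTL panel,
#' recording ages, latent intercepts and (co)variances, residual bands and
#' allele-frequency range. `scale = "full"` is the full study design
#' (1,500 individuals, daily records 70-500 days); `scale = "desk"` is the
#' reduced design used for replicated desk experiments (300 individuals,
#' records every 5 days), which preserves the age range and all variance
#' components.
#'
#' @param n_animals Number of individuals.
#' @param n_qtl Number of independent bi-allelic QTL.
#' @param ages Integer vector of recording ages (days), increasing.
#' @param mu Latent intercepts `c(age115, shape, bw65)` in (days, 1/day, kg).
#' @param sigma_e 3x3 environmental covariance of the latent triple;
#'   defaults to [default_sigma_e()] at `mu`.
#' @param sigma_alpha 3x3 per-QTL substitution-effect covariance; defaults
#'   to `sigma_e / n_qtl`.
#' @param residual_bands Tibble of residual bands, see
#'   [default_residual_bands()].
#' @param allele_freq_range Range of the per-locus uniform allele-frequency
#'   draw.
#' @param max_resample Per-individual cap on rejection resampling of latent
#'   triples that violate their biological bounds.
#' @param scale `"full"` or `"desk"`; presets for `n_animals` and `ages`
#'   applied only where those arguments are left at their defaults.
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(scale = "desk")
#' cfg$n_animals
#' @export
sim_config <- function(n_animals = NULL, n_qtl = 30, ages = NULL,
                       mu = c(age115 = 160, shape = 0.012, bw65 = 24),
                       sigma_e = NULL, sigma_alpha = NULL,
                       residual_bands = default_residual_bands(),
                       allele_freq_range = c(0.1, 0.9),
                       max_resample = 100,
                       scale = c("full", "desk")) {
  scale <- match.arg(scale)
  if (is.null(n_animals)) n_animals <- if (scale == "desk") 300L else 1500L
  if (is.null(ages)) {
    ages <- if (scale == "desk") seq(70L, 500L, by = 5L) else seq(70L, 500L, by = 1L)
  }
  mu <- as.numeric(mu)
  stopifnot(length(mu) == 3, all(is.finite(mu)), mu[1] > 65, mu[2] > 0,
            mu[3] > 0, mu[3] < 115)
  if (is.null(sigma_e)) sigma_e <- default_sigma_e(mu)
  if (is.null(sigma_alpha)) sigma_alpha <- sigma_e / n_qtl
  .check_spd(sigma_e, "sigma_e")
  .check_spd(sigma_alpha, "sigma_alpha")
  bands <- tibble::as_tibble(residual_bands)
  stopifnot(all(c("age_lo", "age_hi", "variance") %in% names(bands)),
            all(bands$variance > 0))
  if (any(bands$age_lo[-1] != bands$age_hi[-nrow(bands)] + 1)) {
    stop("residual bands must partition the age range with no gaps/overlaps.",
         call. = FALSE)
  }
  ages <- as.integer(ages)
  stopifnot(length(ages) >= 2, !is.unsorted(ages, strictly = TRUE),
            min(ages) >= min(bands$age_lo), max(ages) <= max(bands$age_hi))
  stopifnot(length(allele_freq_range) == 2, allele_freq_range[1] > 0,
            allele_freq_range[2] < 1,
            allele_freq_range[1] <= allele_freq_range[2])
  structure(list(n_animals = as.integer(n_animals), n_qtl = as.integer(n_qtl),
                 ages = ages, mu = mu, sigma_e = sigma_e,
                 sigma_alpha = sigma_alpha, residual_bands = bands,
                 allele_freq_range = as.numeric(allele_freq_range),
                 max_resample = as.integer(max_resample), scale = scale),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_animals, " animals, ", x$n_qtl, " QTL, ages ",
      min(x$ages), "-", max(x$ages), " (", length(x$ages), " days, scale '",
      x$scale, "')\n", sep = "")
  invisible(x)
}

.check_spd <- function(m, name) {
  if (!is.matrix(m) || !identical(dim(m), c(3L, 3L)) ||
      max(abs(m - t(m))) > 1e-8 * max(abs(m)) ||
      min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("`", name, "` must be a symmetric positive-definite 3x3 matrix.",
         call. = FALSE)
  }
  invisible(m)
}

#' Sample bi-allelic QTL genotypes
#'
#' Draws an `n x p` genotype matrix of reference-allele counts (0/1/2) under
#' Hardy-Weinberg equilibrium with mutually independent loci: each entry is
#' the sum of two independent Bernoulli draws at the locus frequency.
#'
#' @param n Number of individuals.
#' @param p Number of loci.
#' @param freqs Per-locus allele frequencies in (0, 1), recycled to length
#'   `p`.
#' @param seed Optional integer seed.
#' @return Integer matrix `n x p` with rownames `1..n`.
#' @export
sample_genotypes <- function(n, p, freqs = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  freqs <- rep_len(as.numeric(freqs), p)
  if (any(freqs <= 0) || any(freqs >= 1)) {
    stop("allele frequencies must lie strictly in (0, 1).", call. = FALSE)
  }
  g <- vapply(freqs, function(f) stats::rbinom(n, 2L, f), integer(n))
  g <- matrix(as.integer(g), nrow = n, ncol = p)
  rownames(g) <- as.character(seq_len(n))
  g
}

#' Sample multivariate QTL substitution effects
#'
#' Draws `p` independent zero-mean trivariate Gaussian effect vectors, one
#' per locus, with covariance `sigma_alpha` across the three latent growth
#' parameters. The study's default is `sigma_alpha = sigma_e / n_qtl`.
#'
#' @param sigma_alpha 3x3 SPD effect covariance.
#' @param p Number of loci.
#' @param seed Optional integer seed.
#' @return Numeric `p x 3` matrix (columns age115, shape, bw65).
#' @export
sample_qtl_effects <- function(sigma_alpha, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .check_spd(sigma_alpha, "sigma_alpha")
  z <- matrix(stats::rnorm(p * 3), nrow = p, ncol = 3)
  eff <- z %*% chol(sigma_alpha)
  colnames(eff) <- c("age115", "shape", "bw65")
  eff
}

#' Genetic values of the latent growth parameters
#'
#' Marker-transmitted part of each individual's latent triple:
#' `theta_g[i, ] = mu + sum_j counts[i, j] * effects[j, ]`.
#'
#' @param genotypes Integer `n x p` genotype matrix (0/1/2).
#' @param effects Numeric `p x 3` QTL effect matrix.
#' @param mu Latent intercept 3-vector.
#' @return Numeric `n x 3` matrix of genetic latents.
#' @export
genetic_latents <- function(genotypes, effects, mu) {
  if (ncol(genotypes) != nrow(effects)) {
    stop("genotype columns must match effect rows.", call. = FALSE)
  }
  stopifnot(ncol(effects) == 3 || nrow(effects) == 0, length(mu) == 3)
  out <- matrix(rep(as.numeric(mu), each = nrow(genotypes)),
                nrow = nrow(genotypes))
  if (ncol(genotypes) > 0) out <- out + genotypes %*% effects
  colnames(out) <- c("age115", "shape", "bw65")
  rownames(out) <- rownames(genotypes)
  out
}

#' Sample total latent triples
#'
#' Adds individual environmental deviations `e_i ~ MVN(0, sigma_e)` to the
#' genetic latents. Rows violating the biological bounds of the triple
#' (age115 > 65, shape > 0, 0 < bw65 < 115) are rejected and resampled; the
#' number of resampled draws is recorded in the `"n_resampled"` attribute.
#'
#' @param theta_g Numeric `n x 3` matrix of genetic latents.
#' @param sigma_e 3x3 SPD environmental covariance.
#' @param max_resample Per-individual resampling cap (simulation error if
#'   exceeded).
#' @param seed Optional integer seed.
#' @return Numeric `n x 3` matrix of total latents with attribute
#'   `n_resampled`.
#' @export
sample_latents <- function(theta_g, sigma_e, max_resample = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .check_spd(sigma_e, "sigma_e")
  n <- nrow(theta_g)
  cl <- chol(sigma_e)
  theta <- theta_g + matrix(stats::rnorm(n * 3), n, 3) %*% cl
  bad <- which(!.valid_triple(theta))
  n_res <- 0L
  for (i in bad) {
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > max_resample) {
        stop("latent resampling cap exceeded for individual ", i, call. = FALSE)
      }
      theta[i, ] <- theta_g[i, ] + as.numeric(crossprod(cl, stats::rnorm(3)))
      if (.valid_triple(theta[i, , drop = FALSE])) break
    }
    n_res <- n_res + tries
  }
  dimnames(theta) <- dimnames(theta_g)
  attr(theta, "n_resampled") <- n_res
  theta
}

.valid_triple <- function(theta) {
  theta[, 1] > 65 & theta[, 2] > 0 & theta[, 3] > 0 & theta[, 3] < 115
}

#' Residual standard deviation at an age
#'
#' Looks up the age band containing `t` (bands closed on both endpoints) and
#' returns the square root of its variance.
#'
#' @param t Age(s) in days.
#' @param bands Residual-band tibble (`age_lo`, `age_hi`, `variance`).
#' @return Numeric vector of residual standard deviations (kg).
#' @examples
#' residual_sd(168, default_residual_bands())  # sqrt(4) = 2
#' @export
residual_sd <- function(t, bands = default_residual_bands()) {
  idx <- findInterval(t, c(bands$age_lo, max(bands$age_hi) + 1L))
  if (any(idx < 1 | idx > nrow(bands)) || any(t < bands$age_lo[1])) {
    stop("age outside all residual bands.", call. = FALSE)
  }
  sqrt(bands$variance[idx])
}

#' Simulate a longitudinal growth dataset
#'
#' End-to-end generative model of the study: QTL genotypes, multivariate
#' substitution effects, correlated latent growth triples, body weights
#' `BW_it = g(t; theta_i) + eps_it` with age-banded residual noise, and the
#' sealed truth (genetic latents and the true breeding-value surface
#' `u[i, t] = g(t; theta_g_i)`).
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; the whole dataset is bit-reproducible given
#'   `(config, seed)`.
#' @return An object of class `growth_dataset`: a list with `records` (long
#'   tibble `animal`, `age`, `weight`), `genotypes`, `effects`, `mu`,
#'   `theta_g`, `theta`, `bv` (n x ages true-BV matrix), `allele_freqs`,
#'   `config`, `seed`, `n_resampled`.
#' @examples
#' ds <- simulate_growth(sim_config(n_animals = 20, scale = "desk"), seed = 1)
#' dplyr::glimpse(ds$records)
#' @export
simulate_growth <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  n <- config$n_animals
  p <- config$n_qtl
  freqs <- stats::runif(p, config$allele_freq_range[1], config$allele_freq_range[2])
  genotypes <- sample_genotypes(n, p, freqs)
  effects <- sample_qtl_effects(config$sigma_alpha, p)
  theta_g <- genetic_latents(genotypes, effects, config$mu)
  if (!all(.valid_triple(theta_g))) {
    stop("genetic latents violate biological bounds; check mu/sigma_alpha.",
         call. = FALSE)
  }
  theta <- sample_latents(theta_g, config$sigma_e, config$max_resample)
  ages <- config$ages
  sds <- residual_sd(ages, config$residual_bands)
  mean_w <- t(vapply(seq_len(n), function(i) {
    .gompertz(ages, theta[i, 1], theta[i, 2], theta[i, 3])
  }, numeric(length(ages))))
  eps <- matrix(stats::rnorm(n * length(ages)), n, length(ages)) *
    rep(sds, each = n)
  records <- tibble::tibble(
    animal = rep(seq_len(n), each = length(ages)),
    age = rep(ages, times = n),
    weight = as.numeric(t(mean_w + eps)))
  bv <- true_breeding_values(theta_g, ages)
  structure(list(records = records, genotypes = genotypes, effects = effects,
                 mu = config$mu, theta_g = theta_g, theta = theta, bv = bv,
                 allele_freqs = freqs, config = config, seed = seed,
                 n_resampled = attr(theta, "n_resampled")),
            class = "growth_dataset")
}

#' @export
print.growth_dataset <- function(x, ...) {
  cat("<growth_dataset> ", nrow(x$genotypes), " animals x ",
      length(x$config$ages), " ages (", nrow(x$records), " records), ",
      ncol(x$genotypes), " QTL, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' True breeding-value surface
#'
#' Genetic body-weight trajectory of each individual: the growth curve
#' evaluated at its genetic latents, excluding both the environmental latent
#' deviation and the record-level residual.
#'
#' @param theta_g Numeric `n x 3` matrix of genetic latents (valid triples).
#' @param ages Ages (days) at which to evaluate.
#' @return Numeric `n x length(ages)` matrix; rownames from `theta_g`,
#'   colnames the ages.
#' @export
true_breeding_values <- function(theta_g, ages) {
  if (!all(.valid_triple(theta_g))) {
    stop("invalid genetic latent rows.", call. = FALSE)
  }
  u <- t(vapply(seq_len(nrow(theta_g)), function(i) {
    .gompertz(ages, theta_g[i, 1], theta_g[i, 2], theta_g[i, 3])
  }, numeric(length(ages))))
  rownames(u) <- rownames(theta_g)
  colnames(u) <- as.character(ages)
  u
}

#' Write a growth dataset to plain-text files
#'
#' Serializes the phenotypes (`phenotypes.csv`: animal, age, weight), the
#' genotypes (`genotypes.csv`), the sealed truth (`truth_latents.csv` with
#' genetic and total latents, `truth_bv.csv` long-format true BV) and the
#' configuration (`config.txt`, key = value) into `dir`.
#'
#' @param dataset A `growth_dataset`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_growth_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "growth_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(dir, c("phenotypes.csv", "genotypes.csv", "truth_latents.csv",
                        "truth_bv.csv", "config.txt"))
  utils::write.csv(dataset$records, f[1], row.names = FALSE)
  gt <- data.frame(animal = rownames(dataset$genotypes), dataset$genotypes,
                   check.names = FALSE)
  colnames(gt)[-1] <- paste0("qtl", seq_len(ncol(dataset$genotypes)))
  utils::write.csv(gt, f[2], row.names = FALSE)
  lat <- data.frame(animal = rownames(dataset$genotypes),
                    theta_g = dataset$theta_g, theta = dataset$theta)
  utils::write.csv(lat, f[3], row.names = FALSE)
  bv_long <- tibble::as_tibble(as.data.frame.table(dataset$bv,
                                                   responseName = "bv"))
  names(bv_long)[1:2] <- c("animal", "age")
  utils::write.csv(bv_long, f[4], row.names = FALSE)
  writeLines(.serialize_config(dataset$config), f[5])
  invisible(f)
}

.serialize_config <- function(cfg) {
  c(paste0("n_animals = ", cfg$n_animals),
    paste0("n_qtl = ", cfg$n_qtl),
    paste0("ages = ", paste(cfg$ages, collapse = ",")),
    paste0("mu = ", paste(format(cfg$mu, digits = 17), collapse = ",")),
    paste0("sigma_e = ", paste(format(as.numeric(cfg$sigma_e), digits = 17),
                               collapse = ",")),
    paste0("sigma_alpha = ", paste(format(as.numeric(cfg$sigma_alpha),
                                          digits = 17), collapse = ",")),
    paste0("residual_bands = ",
           paste(apply(cfg$residual_bands, 1, paste, collapse = ":"),
                 collapse = ";")),
    paste0("allele_freq_range = ", paste(cfg$allele_freq_range, collapse = ",")),
    paste0("max_resample = ", cfg$max_resample),
    paste0("scale = ", cfg$scale))
}

#' Read a simulation configuration from a plain-text file
#'
#' Parses the `key = value` format written by [write_growth_dataset()].
#'
#' @param path Path to a config file.
#' @return A [sim_config()] object.
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  names(vals) <- keys
  num <- function(k) as.numeric(strsplit(vals[[k]], ",")[[1]])
  bands <- do.call(rbind, lapply(strsplit(vals[["residual_bands"]], ";")[[1]],
                                 function(s) as.numeric(strsplit(s, ":")[[1]])))
  sim_config(
    n_animals = as.integer(vals[["n_animals"]]),
    n_qtl = as.integer(vals[["n_qtl"]]),
    ages = as.integer(num("ages")),
    mu = num("mu"),
    sigma_e = matrix(num("sigma_e"), 3, 3),
    sigma_alpha = matrix(num("sigma_alpha"), 3, 3),
    residual_bands = tibble::tibble(age_lo = bands[, 1], age_hi = bands[, 2],
                                    variance = bands[, 3]),
    allele_freq_range = num("allele_freq_range"),
    max_resample = as.integer(vals[["max_resample"]]),
    scale = vals[["scale"]])
}
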