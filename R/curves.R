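#' Reparameterized Gompertz growth curve
#'
#' Body weight at age `t` for the Gompertz growth family reparameterized in
#' terms of three interpretable latent growth parameters: the age (days) at
#' which the animal reaches 115 kg (`age115`), a growth-rate shape parameter
#' (`shape`, per day), and the body weight at 65 days (`bw65`, kg).
#'
#' The curve is the unique member of the standard Gompertz family
#' \eqn{y(t) = A \exp(-\exp(-k(t - I)))} with rate \eqn{k = } `shape` that
#' satisfies the two boundary constraints \eqn{y(65) = } `bw65` and
#' \eqn{y(}`age115`\eqn{) = 115}. In closed form,
#' \deqn{g(t) = 115 \, (115/\mathrm{BW65})^{E(t)}, \quad
#'   E(t) = \frac{e^{-s(\mathrm{A115}-65)} - e^{-s(t-65)}}
#'              {1 - e^{-s(\mathrm{A115}-65)}},}
#' so that \eqn{E(65) = -1} and \eqn{E(\mathrm{A115}) = 0}. The curve is
#' strictly increasing in `t` and bounded above by the implied mature-weight
#' asymptote.
#'
#' Inner exponents are clamped at 50 in absolute value so that evaluation is
#' numerically safe for `shape * (age115 - 65)` up to ~50; beyond the clamp
#' the curve has saturated to machine precision anyway.
#'
#' @param t Age in days (numeric vector, `>= 0`).
#' @param age115 Age at 115 kg, days (`> 65`).
#' @param shape Growth-rate parameter, per day (`> 0`).
#' @param bw65 Body weight at 65 days, kg (in `(0, 115)`).
#' @return Numeric vector of body weights (kg), recycled over the longest
#'   argument.
#' @examples
#' gompertz_weight(65, 160, 0.012, 24)   # boundary: 24 kg
#' gompertz_weight(160, 160, 0.012, 24)  # boundary: 115 kg
#' @seealso [quadratic_weight()]
#' @export
gompertz_weight <- function(t, age115, shape, bw65) {
  n <- max(length(t), length(age115), length(shape), length(bw65))
  t <- rep_len(as.numeric(t), n)
  age115 <- rep_len(as.numeric(age115), n)
  shape <- rep_len(as.numeric(shape), n)
  bw65 <- rep_len(as.numeric(bw65), n)
  if (anyNA(t) || any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be finite and non-negative.", call. = FALSE)
  }
  ok <- is.finite(age115) & is.finite(shape) & is.finite(bw65) &
    age115 > 65 & shape > 0 & bw65 > 0 & bw65 < 115
  if (any(!ok)) {
    stop("invalid latent triple: need age115 > 65, shape > 0, 0 < bw65 < 115.",
         call. = FALSE)
  }
  sd115 <- shape * (age115 - 65)
  if (any(sd115 < 1e-10)) {
    stop("degenerate latent triple: age115 too close to 65 days.", call. = FALSE)
  }
  .gompertz(t, age115, shape, bw65)
}

# Unchecked vectorized evaluator shared with simulation internals. Exponents
# clamped at +-50: e^-50 below relative machine precision of the leading term.
.gompertz <- function(t, age115, shape, bw65) {
  clamp <- function(x) pmin(pmax(x, -50), 50)
  eD <- exp(-clamp(shape * (age115 - 65)))
  Et <- (eD - exp(-clamp(shape * (t - 65)))) / (1 - eD)
  115 * exp(Et * log(115 / bw65))
}

#' Quadratic growth curve
#'
#' Evaluates the quadratic age-weight function
#' \eqn{f(t) = b_0 + b_1 t + b_2 t^2} used as the deliberately misspecified
#' ("wrong") growth model in the model-adequacy experiments.
#'
#' @param t Age in days (numeric vector, finite).
#' @param b0 Intercept (kg).
#' @param b1 Linear coefficient (kg/day).
#' @param b2 Quadratic coefficient (kg/day^2).
#' @return Numeric vector of body weights (kg).
#' @examples
#' quadratic_weight(100, 5, 0.5, 0.001)  # 65
#' @export
quadratic_weight <- function(t, b0, b1, b2) {
  n <- max(length(t), length(b0), length(b1), length(b2))
  t <- rep_len(as.numeric(t), n)
  b0 <- rep_len(as.numeric(b0), n)
  b1 <- rep_len(as.numeric(b1), n)
  b2 <- rep_len(as.numeric(b2), n)
  if (any(!is.finite(t)) || any(!is.finite(b0)) || any(!is.finite(b1)) ||
      any(!is.finite(b2))) {
    stop("all arguments must be finite.", call. = FALSE)
  }
  b0 + b1 * t + b2 * t^2
}
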