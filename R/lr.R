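#' Per-day LR statistics over the validation set
#'
#' For each validation day, compares three vectors over the validation
#' animals — the EBV from the partial data \eqn{\hat u_p}, the EBV from the
#' whole data \eqn{\hat u_w}, and the true BV \eqn{u} — and returns the LR
#' method's statistics together with their true counterparts:
#'
#' * bias: \eqn{\hat\Delta = \overline{\hat u_p} - \overline{\hat u_w}}
#'   (estimating \eqn{\Delta = \overline{\hat u_p} - \bar u});
#' * dispersion: \eqn{\hat b_{wp} = cov(\hat u_w, \hat u_p)/var(\hat u_p)}
#'   (estimating \eqn{b_{up} = cov(u, \hat u_p)/var(\hat u_p)});
#' * population accuracy: \eqn{\hat\rho_p = cov(\hat u_w, \hat u_p) /
#'   \sqrt{\widehat{var(u)} \, var(\hat u_p)}} (estimating
#'   \eqn{\rho_p = cor(u, \hat u_p)});
#' * the two covariances themselves, whose gap is the Table-style
#'   adequacy test.
#'
#' Sample statistics use the (n-1) divisor throughout. When
#' \eqn{var(\hat u_p) = 0} the slope and accuracy fields are `NA` (flagged,
#' not an error). \eqn{\hat\rho_p} can legitimately exceed 1 in noisy
#' replicates; it is never clipped.
#'
#' @param u True-BV matrix (validation animals x ages; rownames animal ids,
#'   colnames ages).
#' @param ebv_p,ebv_w EBV surfaces from [posterior_ebv()] on the partial and
#'   whole fits, with the same rows/columns.
#' @param var_u_hat Tibble `age`, `var_u` from [estimate_genetic_variance()]
#'   on the partial fit, covering every validation age.
#' @param animals Validation animal ids (default: rownames of `u`).
#' @param ages Validation ages (default: colnames of `u`).
#' @return A tibble with one row per age and columns `age`, `delta_hat`,
#'   `delta_true`, `slope_hat`, `slope_true`, `acc_hat`, `acc_true`,
#'   `cov_hat`, `cov_true`.
#' @export
lr_day_stats <- function(u, ebv_p, ebv_w, var_u_hat, animals = NULL,
                         ages = NULL) {
  if (is.null(animals)) animals <- rownames(u)
  if (is.null(ages)) ages <- colnames(u)
  animals <- as.character(animals)
  ages_chr <- as.character(ages)
  if (length(animals) < 3) {
    stop("need at least three validation animals.", call. = FALSE)
  }
  u <- u[animals, ages_chr, drop = FALSE]
  ebv_p <- ebv_p[animals, ages_chr, drop = FALSE]
  ebv_w <- ebv_w[animals, ages_chr, drop = FALSE]
  vu <- tibble::as_tibble(var_u_hat)
  vmap <- vu$var_u[match(as.numeric(ages_chr), vu$age)]
  if (anyNA(vmap)) {
    stop("`var_u_hat` must cover every validation age.", call. = FALSE)
  }
  purrr::map_dfr(seq_along(ages_chr), function(k) {
    up <- ebv_p[, k]
    uw <- ebv_w[, k]
    ut <- u[, k]
    vp <- stats::var(up)
    cw <- stats::cov(uw, up)
    ct <- stats::cov(ut, up)
    ok <- is.finite(vp) && vp > 0
    tibble::tibble(
      age = as.numeric(ages_chr[k]),
      delta_hat = mean(up) - mean(uw),
      delta_true = mean(up) - mean(ut),
      slope_hat = if (ok) cw / vp else NA_real_,
      slope_true = if (ok) ct / vp else NA_real_,
      acc_hat = if (ok && vmap[k] > 0) cw / sqrt(vmap[k] * vp) else NA_real_,
      acc_true = if (ok) stats::cor(ut, up) else NA_real_,
      cov_hat = cw,
      cov_true = ct)
  })
}

#' Average LR day statistics across the validation ages of one replicate
#'
#' Unweighted mean across days of every statistic column, one row out.
#'
#' @param day_stats A tibble from [lr_day_stats()] (optionally already
#'   carrying id columns such as `replicate`, `scenario`, `model`, which are
#'   preserved if constant).
#' @return A one-row tibble of across-day means.
#' @export
lr_summarize <- function(day_stats) {
  stat_cols <- c("delta_hat", "delta_true", "slope_hat", "slope_true",
                 "acc_hat", "acc_true", "cov_hat", "cov_true")
  stopifnot(all(stat_cols %in% names(day_stats)))
  id_cols <- setdiff(names(day_stats), c(stat_cols, "age"))
  keep <- id_cols[vapply(id_cols, function(cc) {
    dplyr::n_distinct(day_stats[[cc]]) == 1
  }, logical(1))]
  out <- dplyr::summarise(day_stats,
                          dplyr::across(dplyr::all_of(stat_cols),
                                        ~ mean(.x)))
  if (length(keep)) {
    out <- dplyr::bind_cols(dplyr::distinct(day_stats[keep]), out)
  }
  out
}

#' One-sample t-test of per-replicate LR means against a null value
#'
#' The across-replicate significance machinery: each replicate contributes
#' its across-day mean of a statistic, and the 20 (or however many) means
#' are tested two-sided against the null value implied by an adequate model
#' (0 for the bias statistics, 1 for the dispersion statistics).
#'
#' @param values Numeric vector of per-replicate means (length >= 2).
#' @param null Null value (0 or 1).
#' @param statistic Label carried into the report.
#' @return A one-row tibble: `statistic`, `null`, `n`, `mean`, `t`, `df`,
#'   `p.value`. With zero variance across replicates the test is degenerate
#'   and `t`/`p.value` are `NA` (flagged via `degenerate = TRUE`).
#' @export
lr_t_test <- function(values, null, statistic = "stat") {
  values <- as.numeric(values)
  stopifnot(length(values) >= 2, all(is.finite(values)))
  degen <- stats::sd(values) == 0
  if (degen) {
    return(tibble::tibble(statistic = statistic, null = null,
                          n = length(values), mean = mean(values),
                          t = NA_real_, df = length(values) - 1L,
                          p.value = NA_real_, degenerate = TRUE))
  }
  tt <- stats::t.test(values, mu = null, alternative = "two.sided")
  tibble::tibble(statistic = statistic, null = null, n = length(values),
                 mean = mean(values), t = unname(tt$statistic),
                 df = unname(tt$parameter), p.value = tt$p.value,
                 degenerate = FALSE)
}

#' Covariance-gap adequacy test
#'
#' Tests whether \eqn{cov(\hat u_w, \hat u_p)} differs from
#' \eqn{cov(u, \hat u_p)}: per replicate the mean across validation days of
#' `cov_hat - cov_true`, then a two-sided one-sample t-test of the
#' per-replicate differences against 0. Under an adequate conditional-mean
#' model the two covariances share the same expectation, so a significant
#' gap flags model inadequacy.
#'
#' @param replicate_summary Tibble of per-replicate summaries (from
#'   [lr_summarize()] rows) containing `cov_hat` and `cov_true`.
#' @return A one-row tibble as from [lr_t_test()].
#' @export
lr_covariance_gap_test <- function(replicate_summary) {
  stopifnot(all(c("cov_hat", "cov_true") %in% names(replicate_summary)))
  lr_t_test(replicate_summary$cov_hat - replicate_summary$cov_true, 0,
            statistic = "cov_gap")
}
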