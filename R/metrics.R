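#' Accuracy metrics
#'
#' Mean absolute error and root mean square error of predicted means against
#' observed values.
#'
#' @param preds,targets Equal-length numeric vectors.
#' @return A single number.
#' @export
mae <- function(preds, targets) {
  check_equal_length(preds, targets)
  mean(abs(preds - targets))
}

#' @rdname mae
#' @export
rmse <- function(preds, targets) {
  check_equal_length(preds, targets)
  sqrt(mean((preds - targets)^2))
}

check_equal_length <- function(a, b) {
  if (length(a) != length(b) || length(a) < 1) {
    rlang::abort("inputs must be non-empty vectors of equal length")
  }
  invisible(TRUE)
}

#' Confidence-based calibration curve and ECE
#'
#' For each confidence level the central two-sided Gaussian interval
#' `mu +/- z((1 + CL) / 2) * sigma` is formed and the empirical fraction of
#' observations falling inside is recorded. The expected calibration error
#' (ECE) is the mean absolute gap between the nominal levels and the
#' empirical fractions.
#'
#' @param mu,sigma2,y Predictive means, predictive variances (strictly
#'   positive) and observed values.
#' @param levels Confidence levels in (0, 1); default 1%..99% in 1% steps.
#' @return An object of class `confidence_curve`: list with `curve` (tibble
#'   of `level`, `fraction`), `ece`, and `n`.
#' @export
confidence_curve <- function(mu, sigma2, y, levels = seq(0.01, 0.99, by = 0.01)) {
  check_equal_length(mu, y)
  check_equal_length(sigma2, y)
  if (any(sigma2 <= 0)) rlang::abort("sigma2 must be strictly positive")
  stopifnot(all(levels > 0), all(levels < 1))
  z_abs <- abs(y - mu) / sqrt(sigma2)
  fraction <- vapply(levels, function(cl) {
    mean(z_abs <= stats::qnorm((1 + cl) / 2))
  }, numeric(1))
  structure(list(
    curve = tibble::tibble(level = levels, fraction = fraction),
    ece = mean(abs(levels - fraction)),
    n = length(y)
  ), class = "confidence_curve")
}

#' @export
print.confidence_curve <- function(x, ...) {
  cat(sprintf("<confidence_curve> %d levels, n = %d, ECE = %.4f\n",
              nrow(x$curve), x$n, x$ece))
  invisible(x)
}

#' Error-based calibration curve and ENCE
#'
#' Sorts the data by predicted variance (stable, ties kept in input order),
#' splits it into `bins` near-equal bins (any remainder spread over the
#' first bins), and compares each bin's empirical RMSE with its root mean
#' uncertainty `RMU = sqrt(mean(sigma2))`. The expected normalized
#' calibration error (ENCE) is the mean of `|RMSE - RMU| / RMU` over bins.
#'
#' @inheritParams confidence_curve
#' @param bins Number of bins `B` (default 10); must not exceed the number
#'   of observations.
#' @return An object of class `error_curve`: list with `curve` (tibble of
#'   `bin`, `n`, `rmse`, `rmu`), `ence`, and `n`.
#' @export
error_curve <- function(mu, sigma2, y, bins = 10) {
  check_equal_length(mu, y)
  check_equal_length(sigma2, y)
  n <- length(y)
  if (bins < 1 || bins > n) rlang::abort("bins must satisfy 1 <= bins <= length(y)")
  ord <- order(sigma2)   # radix sort: stable, input-order tie-breaking
  sizes <- rep(n %/% bins, bins)
  if (n %% bins > 0) sizes[seq_len(n %% bins)] <- sizes[seq_len(n %% bins)] + 1L
  stop_at <- cumsum(sizes)
  start_at <- c(1L, utils::head(stop_at, -1) + 1L)
  curve <- purrr::map_dfr(seq_len(bins), function(b) {
    idx <- ord[start_at[b]:stop_at[b]]
    tibble::tibble(
      bin = b, n = length(idx),
      rmse = sqrt(mean((mu[idx] - y[idx])^2)),
      rmu = sqrt(mean(sigma2[idx]))
    )
  })
  structure(list(
    curve = curve,
    ence = mean(abs(curve$rmse - curve$rmu) / curve$rmu),
    n = n
  ), class = "error_curve")
}

#' @export
print.error_curve <- function(x, ...) {
  cat(sprintf("<error_curve> %d bins, n = %d, ENCE = %.4f\n",
              nrow(x$curve), x$n, x$ence))
  invisible(x)
}

#' Scalar calibration errors
#'
#' Convenience wrappers returning only the ECE of [confidence_curve()] or
#' the ENCE of [error_curve()].
#'
#' @inheritParams confidence_curve
#' @inheritParams error_curve
#' @return A single number.
#' @export
ece <- function(mu, sigma2, y, levels = seq(0.01, 0.99, by = 0.01)) {
  confidence_curve(mu, sigma2, y, levels)$ece
}

#' @rdname ece
#' @export
ence <- function(mu, sigma2, y, bins = 10) {
  error_curve(mu, sigma2, y, bins)$ence
}

#' Evaluate ensemble predictions against targets
#'
#' Computes MAE and RMSE of the ensemble mean, and ECE/ENCE separately for
#' the aleatoric and epistemic variance components (callers choose which
#' variance to trust; both are reported side by side).
#'
#' @param preds Tibble from [ensemble_predict()] (columns `mu_ens`,
#'   `sigma2_ale`, `sigma2_epi`).
#' @param y Observed values aligned with `preds`.
#' @param levels Confidence levels for the ECE.
#' @param bins Bin count for the ENCE.
#' @return A one-row tibble with `mae`, `rmse`, `ece_ale`, `ece_epi`,
#'   `ence_ale`, `ence_epi`, `n`.
#' @export
evaluate_predictions <- function(preds, y, levels = seq(0.01, 0.99, by = 0.01),
                                 bins = 10) {
  epi <- pmax(preds$sigma2_epi, .var_floor)
  tibble::tibble(
    mae = mae(preds$mu_ens, y),
    rmse = rmse(preds$mu_ens, y),
    ece_ale = ece(preds$mu_ens, preds$sigma2_ale, y, levels),
    ece_epi = ece(preds$mu_ens, epi, y, levels),
    ence_ale = ence(preds$mu_ens, preds$sigma2_ale, y, bins),
    ence_epi = ence(preds$mu_ens, epi, y, bins),
    n = length(y)
  )
}
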