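#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a trained model's history
#'
#' @param x An `atomuq_model`.
#' @param ... Unused.
#' @return The per-epoch training history tibble.
#' @method tidy atomuq_model
#' @export
tidy.atomuq_model <- function(x, ...) x$history

#' @rdname tidy.atomuq_model
#' @method glance atomuq_model
#' @export
glance.atomuq_model <- function(x, ...) {
  tibble::tibble(
    mode = x$meta$mode,
    hidden_dim = x$meta$hidden_dim,
    depth = x$meta$depth,
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    valid_nll = x$valid_nll
  )
}

#' Tidy an ensemble
#'
#' @param x An `atomuq_ensemble`.
#' @param ... Unused.
#' @return One row per member with its seed, best epoch and validation NLL.
#' @method tidy atomuq_ensemble
#' @export
tidy.atomuq_ensemble <- function(x, ...) {
  purrr::map_dfr(seq_along(x$members), function(j) {
    m <- x$members[[j]]
    tibble::tibble(member = j, seed = m$config$seed,
                   best_epoch = m$best_epoch, valid_nll = m$valid_nll)
  })
}

#' @rdname tidy.atomuq_ensemble
#' @method glance atomuq_ensemble
#' @export
glance.atomuq_ensemble <- function(x, ...) {
  tibble::tibble(
    M = x$M, mode = x$mode, calibrated = x$calibrated,
    mean_valid_nll = mean(vapply(x$members, function(m) m$valid_nll, numeric(1)))
  )
}

#' @method tidy confidence_curve
#' @export
tidy.confidence_curve <- function(x, ...) x$curve

#' @method glance confidence_curve
#' @export
glance.confidence_curve <- function(x, ...) tibble::tibble(ece = x$ece, n = x$n)

#' @method tidy error_curve
#' @export
tidy.error_curve <- function(x, ...) x$curve

#' @method glance error_curve
#' @export
glance.error_curve <- function(x, ...) tibble::tibble(ence = x$ence, n = x$n)
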