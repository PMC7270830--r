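#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the seasonal DMY fit
#'
#' One row per model term with estimate, standard error, statistic and
#' p-value (delegates to the underlying `lm`).
#'
#' @param x a `season_fit` from [fit_seasonal_model()].
#' @param ... passed on.
#' @return tibble.
#' @export
tidy.season_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' Glance at the seasonal DMY fit
#' @inheritParams tidy.season_fit
#' @return one-row tibble with `r.squared`, `sigma`, `nobs`, `n_seasons`.
#' @export
glance.season_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
                 sigma = s$sigma, nobs = x$n,
                 n_seasons = length(x$seasons))
}

#' Tidy a predicted-vs-measured validation
#'
#' @param x a `dmy_validation` from [validate_predictions()].
#' @param ... unused.
#' @return one-row tibble of the validation metrics.
#' @export
tidy.dmy_validation <- function(x, ...) {
  tibble::tibble(n = x$n, slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, rmse_raw = x$rmse_raw,
                 rmse_resid = x$rmse_resid)
}

#' @export
glance.dmy_validation <- function(x, ...) tidy.dmy_validation(x)
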