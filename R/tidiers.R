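#' @importFrom generics tidy glance augment
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
generics::augment

#' Tidy a decay fit
#'
#' @param x A `decay_fit` from [fit_decay()].
#' @param ... Unused.
#' @return One row per fitted quantity (`term`, `estimate`).
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(
    term = c("rate_k", "half_life_h", "intercept"),
    estimate = c(x$rate_k, x$half_life_h, x$intercept)
  )
}

#' @rdname tidy.decay_fit
#' @return `glance()`: a one-row model summary.
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(
    rate_k = x$rate_k, half_life_h = x$half_life_h,
    intercept = x$intercept, residual_sd = x$residual_sd,
    n_points = nrow(x$fitted), method = x$method, infinite = x$infinite
  )
}

#' @rdname tidy.decay_fit
#' @return `augment()`: the per-point data with fitted values and residuals.
#' @export
augment.decay_fit <- function(x, ...) {
  x$fitted
}

#' Tidy a segregation chi-square result
#'
#' @param x A `mendel_chisq` from [mendelian_chisq()].
#' @param ... Unused.
#' @return One row per genotype class with observed and expected counts.
#' @export
tidy.mendel_chisq <- function(x, ...) {
  k <- length(x$observed_counts)
  tibble(
    class = if (k == 3L) c("wt", "het", "hom") else paste0("class", seq_len(k)),
    observed = x$observed_counts,
    expected = x$expected_counts
  )
}

#' @rdname tidy.mendel_chisq
#' @return `glance()`: a one-row test summary.
#' @export
glance.mendel_chisq <- function(x, ...) {
  tibble(chi2 = x$chi2, df = x$df, p_value = x$p,
         p_exact = x$p_exact %||% NA_real_)
}
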