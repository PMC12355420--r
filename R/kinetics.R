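#' Normalize a chase course to its pre-treatment point
#'
#' Scales each replicate so its `time_h == 0` ("pre", before the
#' translation block) value equals 100%.
#'
#' @param course Decay course tibble with `replicate`, `time_h`, `value`
#'   (see [read_decay_course()]).
#' @return The course with `value` rescaled per replicate.
#' @export
normalize_pre <- function(course) {
  pre <- course |>
    filter(.data$time_h == 0) |>
    group_by(.data$replicate) |>
    summarise(n_pre = dplyr::n(), pre = .data$value[1L], .groups = "drop")
  if (!all(sort(unique(course$replicate)) %in% pre$replicate) ||
      any(pre$n_pre != 1L)) {
    abort("each replicate needs exactly one pre (time_h == 0) point")
  }
  if (any(pre$pre <= 0)) abort("pre value must be > 0")
  course |>
    left_join(select(pre, "replicate", "pre"), by = "replicate") |>
    mutate(value = .data$value / .data$pre * 100) |>
    select(-"pre")
}

#' Fit a single-exponential decay and estimate the half-life
#'
#' Fits `value = A * exp(-k * t)` to a (pre-normalized) chase course.
#' `"loglinear"` (default) is the closed-form least-squares fit of
#' `log(value)` on time; `"nonlinear"` is a one-parameter nonlinear
#' least-squares fit with the intercept fixed at 100%. The half-life is
#' `ln(2) / k`. Non-decaying data (`k <= 0`) return a fit with the
#' half-life flagged infinite rather than an error.
#'
#' @param course Decay course tibble with `time_h` and `value`; replicates
#'   are pooled into one fit.
#' @param method `"loglinear"` or `"nonlinear"`.
#' @return A `decay_fit` object: `rate_k` (per hour), `half_life_h`,
#'   `intercept` (% at t = 0), `residual_sd`, `fitted` (per-point tibble),
#'   `method`, `infinite` flag.
#' @export
#' @examples
#' course <- tibble::tibble(replicate = 1, time_h = c(0, 24, 48),
#'                          value = c(100, 50, 25))
#' fit_decay(course)$half_life_h # exactly 24
fit_decay <- function(course, method = c("loglinear", "nonlinear")) {
  method <- match.arg(method)
  if (length(unique(course$time_h)) < 3L) {
    abort("need >= 3 distinct timepoints to fit a decay")
  }
  t <- course$time_h
  v <- course$value

  if (method == "loglinear") {
    if (any(v <= 0)) abort("log-linear fit requires strictly positive values")
    fit <- lm(log(v) ~ t)
    k <- -unname(coef(fit)[2L])
    intercept <- exp(unname(coef(fit)[1L]))
    fitted_v <- exp(unname(fit$fitted.values))
  } else {
    k0 <- {
      lf <- lm(log(pmax(v, .Machine$double.eps)) ~ t)
      max(-unname(coef(lf)[2L]), 1e-6)
    }
    # scaleOffset keeps the convergence test meaningful on zero-residual data
    fit <- nls(v ~ 100 * exp(-k * t), start = list(k = k0),
               control = stats::nls.control(maxiter = 200, scaleOffset = 1))
    k <- unname(coef(fit)[["k"]])
    intercept <- 100
    fitted_v <- as.numeric(predict(fit))
  }

  # a slope indistinguishable from zero at double precision is non-decaying
  infinite <- k <= sqrt(.Machine$double.eps)
  res <- v - fitted_v
  structure(
    list(
      rate_k = k,
      half_life_h = if (infinite) Inf else log(2) / k,
      intercept = intercept,
      residual_sd = if (length(res) > 2L) sd(res) else NA_real_,
      fitted = tibble(time_h = t, value = v, fitted = fitted_v,
                      residual = res),
      method = method,
      infinite = infinite
    ),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Exponential decay fit (%s)\n", x$method))
  cat(sprintf("  rate k      : %.5f /h\n", x$rate_k))
  cat(sprintf("  half-life   : %s h\n",
              if (x$infinite) "Inf (non-decaying)" else sprintf("%.2f", x$half_life_h)))
  cat(sprintf("  intercept   : %.1f %%\n", x$intercept))
  invisible(x)
}

#' Predicted remaining fraction at a time point
#'
#' `100 * exp(-k * t)`: the percentage of the initial protein pool the
#' fitted decay predicts to remain after `t` hours.
#'
#' @param fit A [fit_decay()] result.
#' @param t Hours. Vectorized.
#' @return Percent remaining.
#' @export
remaining_fraction <- function(fit, t) {
  stopifnot(inherits(fit, "decay_fit"))
  100 * exp(-fit$rate_k * t)
}

#' Mendelian segregation chi-square test
#'
#' Pearson goodness-of-fit of observed genotype counts against an expected
#' segregation ratio (default 1:2:1 for a heterozygote intercross), with no
#' continuity correction. For sensitivity when expected cell counts are
#' small, an exact multinomial test is available.
#'
#' @param counts Either a genotype-count tibble with `n_wt`, `n_het`,
#'   `n_hom` (first row used) or a numeric vector of counts.
#' @param ratio Expected segregation ratio (default `c(1, 2, 1)`).
#' @param exact If `TRUE`, also compute the exact multinomial p-value
#'   (sum of probabilities of all outcomes at most as probable as the
#'   observed one); enumeration, practical for totals up to a few hundred.
#' @return A `mendel_chisq` object with `chi2`, `df`, `p`,
#'   `expected_counts`, `observed_counts` and optionally `p_exact`.
#' @export
#' @examples
#' mendelian_chisq(c(15, 28, 4)) # deviates from 1:2:1 (p < 0.05)
mendelian_chisq <- function(counts, ratio = c(1, 2, 1), exact = FALSE) {
  if (is.data.frame(counts)) {
    counts <- as.numeric(counts[1L, c("n_wt", "n_het", "n_hom")])
  }
  if (length(counts) != length(ratio)) {
    abort("counts and ratio must have the same length")
  }
  if (any(counts < 0) || sum(counts) < 1) {
    abort("counts must be non-negative with total >= 1")
  }
  if (any(ratio <= 0)) abort("ratio entries must be > 0 (expected count of 0)")
  p_exp <- ratio / sum(ratio)
  ht <- suppressWarnings(chisq.test(counts, p = p_exp, correct = FALSE))
  out <- list(
    chi2 = unname(ht$statistic),
    df = unname(ht$parameter),
    p = ht$p.value,
    expected_counts = unname(ht$expected),
    observed_counts = as.numeric(counts)
  )
  if (exact) {
    out$p_exact <- exact_multinomial_p(as.integer(round(counts)), p_exp)
  }
  structure(out, class = "mendel_chisq")
}

# exact multinomial GOF p: total probability of outcomes no more likely
# than the observed one; full enumeration over the 3-class simplex
exact_multinomial_p <- function(counts, p) {
  n <- sum(counts)
  if (length(counts) != 3L) abort("exact test implemented for 3 classes")
  if (n > 500L) abort("exact multinomial enumeration limited to n <= 500")
  p_obs <- stats::dmultinom(counts, prob = p)
  total <- 0
  for (a in 0:n) {
    for (b in 0:(n - a)) {
      pr <- stats::dmultinom(c(a, b, n - a - b), prob = p)
      if (pr <= p_obs * (1 + 1e-10)) total <- total + pr
    }
  }
  min(total, 1)
}

#' @export
print.mendel_chisq <- function(x, ...) {
  cat("Segregation chi-square (goodness of fit)\n")
  cat(sprintf("  observed : %s\n", paste(x$observed_counts, collapse = " / ")))
  cat(sprintf("  expected : %s\n",
              paste(sprintf("%.2f", x$expected_counts), collapse = " / ")))
  cat(sprintf("  chi2 = %.4f, df = %d, p = %.5g %s\n",
              x$chi2, x$df, x$p, p_stars(x$p)))
  if (!is.null(x$p_exact)) cat(sprintf("  exact multinomial p = %.5g\n", x$p_exact))
  invisible(x)
}

#' Standard-curve relative quantification for qPCR
#'
#' Fits the least-squares line of Ct on log10(relative quantity) through a
#' serial dilution of a reference sample, inverts unknown Ct values through
#' the line, and reports the implied amplification efficiency
#' `10^(-1/slope) - 1` (1.0 = perfect doubling per cycle).
#'
#' @param standards Tibble with columns `dilution` (relative quantity) and
#'   `ct`; needs >= 3 points spanning >= 2 distinct dilutions. A
#'   non-monotone series warns but is still fitted.
#' @param unknowns Numeric Ct values (or a tibble with a `ct` column).
#' @return A list: `quantities` tibble (`ct`, `quantity`), `slope`,
#'   `intercept`, `efficiency`, `r_squared`.
#' @export
#' @examples
#' std <- tibble::tibble(dilution = c(1, 0.5, 0.25), ct = c(20, 21, 22))
#' standard_curve_quant(std, 21)$quantities$quantity # 0.5
standard_curve_quant <- function(standards, unknowns) {
  if (is.data.frame(unknowns)) unknowns <- unknowns$ct
  if (nrow(standards) < 3L) abort("need >= 3 standard points")
  if (length(unique(standards$dilution)) < 2L) {
    abort("standards must span >= 2 distinct dilutions")
  }
  if (any(standards$dilution <= 0)) abort("dilutions must be > 0")
  ord <- order(standards$dilution)
  cts <- standards$ct[ord]
  if (is.unsorted(rev(cts)) && is.unsorted(cts)) {
    warn("standard series is not monotone in Ct; fitting anyway")
  }
  lx <- log10(standards$dilution)
  fit <- lm(standards$ct ~ lx)
  intercept <- unname(coef(fit)[1L])
  slope <- unname(coef(fit)[2L])
  quantities <- tibble(
    ct = as.numeric(unknowns),
    quantity = 10^((as.numeric(unknowns) - intercept) / slope)
  )
  list(
    quantities = quantities,
    slope = slope,
    intercept = intercept,
    efficiency = 10^(-1 / slope) - 1,
    # direct R^2: summary.lm warns on the perfect-dilution case
    r_squared = {
      ss_tot <- sum((standards$ct - mean(standards$ct))^2)
      if (ss_tot == 0) NA_real_ else 1 - sum(fit$residuals^2) / ss_tot
    }
  )
}

#' Two-group comparison
#'
#' Thin wrapper over [stats::t.test()] covering the comparisons used
#' throughout the pipeline: Student's t (equal variances), Welch's t
#' (unequal variances), and a one-sided Student's t. With zero pooled
#' variance and equal means the test is degenerate; p = 1 is returned and
#' logged rather than erroring.
#'
#' @param a,b Numeric vectors, >= 2 values each.
#' @param test `"student"`, `"welch"` or `"student_one_sided"` (alternative:
#'   mean of `a` greater than mean of `b`).
#' @return A one-row tibble: `estimate` (mean difference), `statistic`,
#'   `df`, `p_value`, `method`, `stars`.
#' @export
compare_groups <- function(a, b, test = c("student", "welch", "student_one_sided")) {
  test <- match.arg(test)
  if (length(a) < 2L || length(b) < 2L) abort("need >= 2 values per group")
  var_equal <- test != "welch"
  alternative <- if (test == "student_one_sided") "greater" else "two.sided"
  tt <- tryCatch(
    t.test(a, b, var.equal = var_equal, alternative = alternative),
    error = function(e) NULL
  )
  if (is.null(tt)) {
    # constant data: identical groups get p = 1, anything else is undefined
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    fs_log("degenerate variance in compare_groups; %s",
           if (eq) "identical groups, p = 1" else "means differ, p undefined")
    return(tibble(estimate = mean(a) - mean(b),
                  statistic = if (eq) 0 else NA_real_, df = NA_real_,
                  p_value = if (eq) 1 else NA_real_, method = test,
                  stars = p_stars(if (eq) 1 else NA_real_)))
  }
  tibble(
    estimate = unname(diff(rev(tt$estimate))),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    method = test,
    stars = p_stars(tt$p.value)
  )
}

#' Family-wise pairwise comparisons against a reference group
#'
#' Runs [compare_groups()] of every non-reference group against the
#' reference and optionally applies the Holm step-down adjustment across
#' that declared family.
#'
#' @param data Tibble in long format.
#' @param value,group Column names (strings) of the measurement and the
#'   grouping factor.
#' @param reference Reference group label (default: first group).
#' @param test Passed to [compare_groups()].
#' @param adjust `"none"` or `"holm"`.
#' @return A tibble with one row per comparison (`group`, `estimate`,
#'   `statistic`, `p_value`, `p_adjusted`, `stars`).
#' @export
compare_pairwise <- function(data, value, group, reference = NULL,
                             test = c("student", "welch", "student_one_sided"),
                             adjust = c("none", "holm")) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  groups <- unique(data[[group]])
  if (is.null(reference)) reference <- groups[1L]
  if (!reference %in% groups) abort("reference group not found")
  ref_vals <- data[[value]][data[[group]] == reference]
  res <- purrr::map_dfr(setdiff(groups, reference), function(g) {
    cg <- compare_groups(data[[value]][data[[group]] == g], ref_vals, test)
    mutate(cg, group = g, .before = 1L)
  })
  res$p_adjusted <- p.adjust(res$p_value,
                             method = if (adjust == "holm") "holm" else "none")
  mutate(res, stars = p_stars(.data$p_adjusted))
}

#' Multi-group comparisons
#'
#' Pass-throughs to the standard multi-group routines used around the
#' pipeline: one-way ANOVA with Tukey HSD post hoc for normal data, or
#' Kruskal-Wallis with Holm-adjusted pairwise Mann-Whitney tests otherwise.
#'
#' @param data Tibble in long format.
#' @param value,group Column names (strings).
#' @param method `"anova_tukey"` or `"kruskal_mw_holm"`.
#' @return A list with `omnibus` (one-row tibble: statistic, p) and
#'   `pairwise` (tibble of pairwise p-values).
#' @export
compare_multigroup <- function(data, value, group,
                               method = c("anova_tukey", "kruskal_mw_holm")) {
  method <- match.arg(method)
  df <- data.frame(y = data[[value]], g = factor(data[[group]]))
  if (method == "anova_tukey") {
    fit <- aov(y ~ g, data = df)
    s <- summary(fit)[[1L]]
    tuk <- as.data.frame(TukeyHSD(fit)$g)
    pairwise <- tibble(
      comparison = rownames(tuk),
      estimate = tuk$diff,
      p_value = tuk$`p adj`
    )
    omnibus <- tibble(statistic = s[["F value"]][1L],
                      p_value = s[["Pr(>F)"]][1L], method = "anova")
  } else {
    kw <- kruskal.test(y ~ g, data = df)
    pw <- pairwise.wilcox.test(df$y, df$g, p.adjust.method = "holm",
                               exact = FALSE)
    m <- pw$p.value
    pairwise <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
      tibble(comparison = paste(rownames(m)[i], colnames(m), sep = "-"),
             p_value = m[i, ])
    }) |> filter(!is.na(.data$p_value))
    pairwise$estimate <- NA_real_
    omnibus <- tibble(statistic = unname(kw$statistic),
                      p_value = kw$p.value, method = "kruskal_wallis")
  }
  list(omnibus = omnibus, pairwise = pairwise)
}
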