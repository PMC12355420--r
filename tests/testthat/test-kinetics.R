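test_that("pre-normalization scales each replicate to 100% independently", {
  course <- tibble::tibble(
    series_id = "s", replicate = c(1L, 1L, 2L, 2L),
    time_h = c(0, 24, 0, 24), value = c(200, 100, 50, 40)
  )
  norm <- normalize_pre(course)
  expect_equal(norm$value, c(100, 50, 100, 80))
  # already-normalized series is the identity
  expect_equal(normalize_pre(norm)$value, norm$value)
  # missing pre point errors
  expect_error(normalize_pre(dplyr::filter(course, time_h > 0)), "pre")
})

test_that("noiseless two-fold decay gives exactly 24 h by both methods", {
  course <- tibble::tibble(series_id = "s", replicate = 1L,
                           time_h = c(0, 24, 48), value = c(100, 50, 25))
  for (m in c("loglinear", "nonlinear")) {
    fit <- fit_decay(course, m)
    expect_equal(fit$half_life_h, 24, tolerance = 1e-6)
    expect_equal(fit$rate_k, log(2) / 24, tolerance = 1e-6)
    expect_equal(fit$half_life_h * fit$rate_k, log(2), tolerance = 1e-12)
    # remaining_fraction round-trips the input points
    expect_equal(remaining_fraction(fit, course$time_h), course$value,
                 tolerance = 1e-6)
  }
})

test_that("a constant series is flagged as non-decaying", {
  course <- tibble::tibble(series_id = "s", replicate = 1L,
                           time_h = c(0, 24, 48), value = c(100, 100, 100))
  fit <- fit_decay(course)
  expect_true(fit$infinite)
  expect_identical(fit$half_life_h, Inf)
  expect_error(fit_decay(course[1:2, ]), "3 distinct timepoints")
})

test_that("half-life is recovered from a noisy synthetic chase", {
  course <- gen_decay_course(24, cv = 0.05, n_replicates = 3L, seed = 1)
  fit <- fit_decay(course, "loglinear")
  expect_lt(abs(fit$half_life_h - 24), 2)
  nl <- fit_decay(course, "nonlinear")
  expect_lt(abs(nl$half_life_h - 24), 2)
})

test_that("remaining fraction matches its closed form, incl. the 20%-at-12h bound", {
  course <- tibble::tibble(series_id = "s", replicate = 1L,
                           time_h = c(0, 24, 48), value = c(100, 50, 25))
  fit <- fit_decay(course)
  expect_equal(remaining_fraction(fit, 24), 50, tolerance = 1e-6)
  expect_equal(remaining_fraction(fit, 0), 100)
  # a protein down to <20% within 12 h must have t1/2 below 12*ln2/ln5
  t_crit <- 12 * log(2) / log(5)
  fast <- fit_decay(tibble::tibble(
    series_id = "s", replicate = 1L, time_h = c(0, 12, 24),
    value = 100 * exp(-log(2) / (t_crit * 0.999) * c(0, 12, 24))
  ))
  expect_lt(remaining_fraction(fast, 12), 20)
})

test_that("segregation chi-square matches the df-2 closed form and chisq.test", {
  m <- mendelian_chisq(c(15, 28, 4))
  expect_equal(m$chi2, 6.872340, tolerance = 1e-6)
  expect_equal(m$df, 2)
  expect_equal(m$p, exp(-m$chi2 / 2), tolerance = 1e-12) # df-2 closed form
  expect_lt(m$p, 0.05)
  expect_equal(sum(m$expected_counts), sum(m$observed_counts))

  perfect <- mendelian_chisq(c(1, 2, 1))
  expect_equal(perfect$chi2, 0)
  expect_equal(perfect$p, 1)
  expect_equal(mendelian_chisq(c(25, 50, 25))$chi2, 0)
  expect_error(mendelian_chisq(c(1, 2, 1), ratio = c(1, 0, 1)), "ratio")
})

test_that("exact multinomial p agrees with a simulation oracle", {
  m <- mendelian_chisq(c(15, 28, 4), exact = TRUE)
  # Monte-Carlo oracle: P(dmultinom(outcome) <= dmultinom(observed))
  set.seed(99)
  draws <- rmultinom(20000, 47, prob = c(1, 2, 1) / 4)
  p_obs <- dmultinom(c(15, 28, 4), prob = c(1, 2, 1) / 4)
  p_mc <- mean(apply(draws, 2, function(x) {
    dmultinom(x, prob = c(1, 2, 1) / 4)
  }) <= p_obs * (1 + 1e-10))
  expect_lt(abs(m$p_exact - p_mc), 4 * sqrt(p_mc * (1 - p_mc) / 20000))
})

test_that("standard-curve quantification inverts a perfect 2-fold series", {
  std <- tibble::tibble(dilution = c(1, 0.5, 0.25), ct = c(20, 21, 22))
  sq <- standard_curve_quant(std, c(21, 20, 23))
  expect_equal(sq$quantities$quantity, c(0.5, 1.0, 0.125), tolerance = 1e-10)
  expect_equal(sq$efficiency, 1.0, tolerance = 1e-10)
  expect_error(standard_curve_quant(std[1:2, ], 21), "3 standard")
  expect_warning(
    standard_curve_quant(
      tibble::tibble(dilution = c(1, 0.5, 0.25), ct = c(20, 22, 21)), 21
    ),
    "monotone"
  )
})

test_that("standard-curve inversion is exact for any log-linear series", {
  # arbitrary efficiency (slope), intercept: inversion must still be exact
  for (slope in c(-3.1, -3.6)) {
    qty <- c(1, 0.2, 0.04, 0.008)
    std <- tibble::tibble(dilution = qty, ct = 18 + slope * log10(qty))
    truth <- 0.1
    ct_u <- 18 + slope * log10(truth)
    sq <- standard_curve_quant(std, ct_u)
    expect_equal(sq$quantities$quantity, truth, tolerance = 1e-9)
    expect_equal(sq$efficiency, 10^(-1 / slope) - 1, tolerance = 1e-9)
  }
})

test_that("two-group comparisons delegate correctly and handle degeneracy", {
  a <- c(1.0, 1.1, 0.9)
  expect_equal(compare_groups(a, a)$statistic, 0)
  # identical constant groups: p = 1, logged fall-through
  expect_equal(compare_groups(c(1, 1), c(1, 1))$p_value, 1)

  set.seed(7)
  x <- c(0, 0, 0) + rnorm(3, sd = 1e-3)
  y <- c(1, 1, 1) + rnorm(3, sd = 1e-3)
  expect_lt(compare_groups(y, x, "welch")$p_value, 0.01)
  # one-sided p is half the two-sided p when the effect is in-direction
  two <- compare_groups(y, x, "student")$p_value
  one <- compare_groups(y, x, "student_one_sided")$p_value
  expect_equal(one, two / 2, tolerance = 1e-12)
  # cross-check against stats::t.test directly
  expect_equal(compare_groups(y, x, "welch")$p_value,
               t.test(y, x)$p.value, tolerance = 1e-12)
})

test_that("family-wise Holm adjustment is applied across declared comparisons", {
  set.seed(11)
  d <- tibble::tibble(
    g = rep(c("ref", "a", "b"), each = 4),
    y = c(rnorm(4), rnorm(4, 2), rnorm(4, 0.1))
  )
  res <- compare_pairwise(d, "y", "g", reference = "ref", adjust = "holm")
  raw <- compare_pairwise(d, "y", "g", reference = "ref", adjust = "none")
  expect_equal(res$p_adjusted, p.adjust(raw$p_value, "holm"))
})

test_that("multi-group pass-throughs agree with the base routines", {
  set.seed(13)
  d <- tibble::tibble(g = rep(c("a", "b", "c"), each = 5),
                      y = c(rnorm(5), rnorm(5, 3), rnorm(5)))
  an <- compare_multigroup(d, "y", "g", "anova_tukey")
  ref <- summary(aov(y ~ factor(g), data = d))[[1]]
  expect_equal(an$omnibus$p_value, ref[["Pr(>F)"]][1])
  expect_equal(nrow(an$pairwise), 3L)
  kw <- compare_multigroup(d, "y", "g", "kruskal_mw_holm")
  expect_equal(kw$omnibus$p_value, kruskal.test(y ~ factor(g), data = d)$p.value)
})

test_that("decay and chi-square tidiers expose broom-style summaries", {
  fit <- fit_decay(tibble::tibble(series_id = "s", replicate = 1L,
                                  time_h = c(0, 24, 48),
                                  value = c(100, 50, 25)))
  expect_equal(glance(fit)$half_life_h, 24, tolerance = 1e-6)
  expect_equal(nrow(tidy(fit)), 3L)
  expect_named(augment(fit), c("time_h", "value", "fitted", "residual"))
  m <- mendelian_chisq(c(15, 28, 4))
  expect_equal(glance(m)$chi2, m$chi2)
  expect_equal(tidy(m)$observed, c(15, 28, 4))
})
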