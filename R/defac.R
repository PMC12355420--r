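#' Gating configuration for expression-binned flux analysis
#'
#' Defines the dead-cell threshold and the four GFP boundaries cutting the
#' expression axis into five levels (Level 0, the GFP-negative population,
#' through Level 4, the highest expressors).
#'
#' @param gfp_boundaries Strictly increasing numeric vector of 4 intensities
#'   (a.u.) separating Levels 0-4.
#' @param viability_threshold Viability-dye intensity (a.u.) at or above
#'   which an event is counted as dead. Instrument-dependent; there is no
#'   default.
#' @param min_events_per_level Minimum events required in a level before its
#'   MFI (and hence flux) is reported rather than flagged; default 100.
#' @return A `gate_config` list.
#' @seealso [auto_gate()] for a data-driven default.
#' @export
gate_config <- function(gfp_boundaries, viability_threshold,
                        min_events_per_level = 100L) {
  if (length(gfp_boundaries) != 4L || any(diff(gfp_boundaries) <= 0)) {
    abort("gfp_boundaries must be 4 strictly increasing intensities",
          class = "fluxscreen_config_error")
  }
  if (!is.numeric(viability_threshold) || length(viability_threshold) != 1L) {
    abort("viability_threshold must be a single intensity",
          class = "fluxscreen_config_error")
  }
  if (min_events_per_level < 1L) {
    abort("min_events_per_level must be >= 1", class = "fluxscreen_config_error")
  }
  structure(
    list(
      gfp_boundaries = as.numeric(gfp_boundaries),
      viability_threshold = as.numeric(viability_threshold),
      min_events_per_level = as.integer(min_events_per_level)
    ),
    class = "gate_config"
  )
}

#' Derive a gate from a GFP-negative reference sample
#'
#' Data-driven default gate: the Level 0 upper boundary is the `q` quantile
#' (default 99.5%) of the GFP channel in a mock/untransfected reference
#' sample, and Levels 1-4 split the range up to the analyte sample's maximum
#' GFP into equal log-width bins.
#'
#' @param events Analyte event table (defines the upper end of the
#'   expression range).
#' @param reference Mock/untransfected event table (defines autofluorescence).
#' @param viability_threshold Dead-cell threshold passed through to
#'   [gate_config()].
#' @param min_events_per_level Passed through to [gate_config()].
#' @param q Reference quantile for the Level 0 boundary; default 0.995.
#' @return A `gate_config`.
#' @export
auto_gate <- function(events, reference, viability_threshold,
                      min_events_per_level = 100L, q = 0.995) {
  b1 <- unname(quantile(reference$gfp, q, names = FALSE))
  top <- max(events$gfp)
  if (top <= b1) abort("analyte GFP range does not exceed the reference boundary")
  r <- (top / b1)^(1 / 4)
  gate_config(b1 * r^(0:3), viability_threshold, min_events_per_level)
}

#' Exclude dead cells from an event table
#'
#' Removes viability-dye-positive events (intensity at or above `threshold`)
#' before any flux computation; the removed count is logged to stderr when
#' `options(fluxscreen.verbose = TRUE)`.
#'
#' @param events Event table with a `viability` column.
#' @param threshold Viability intensity at or above which events are dropped.
#' @return The viable subset of `events`.
#' @export
exclude_dead <- function(events, threshold) {
  if (!"viability" %in% names(events)) {
    abort("missing required channel(s): viability",
          class = "fluxscreen_channel_error")
  }
  keep <- events$viability < threshold
  if (!any(keep)) abort("no viable events", class = "fluxscreen_gate_error")
  fs_log("excluded %d / %d dead events", sum(!keep), length(keep))
  events[keep, , drop = FALSE]
}

#' Assign GFP expression levels
#'
#' Labels each event with the expression level 0-4 implied by the gate
#' boundaries. Bins are left-closed, right-open: an event whose GFP
#' intensity equals boundary *k* falls into level *k* (the higher side).
#'
#' @param events Event table with a `gfp` column.
#' @param gate A [gate_config()] or a strictly increasing numeric vector of
#'   4 boundaries.
#' @return `events` with an integer `level` column added.
#' @export
assign_levels <- function(events, gate) {
  boundaries <- if (inherits(gate, "gate_config")) gate$gfp_boundaries else gate
  if (length(boundaries) != 4L || any(diff(boundaries) <= 0)) {
    abort("gfp_boundaries must be 4 strictly increasing intensities",
          class = "fluxscreen_config_error")
  }
  if (!"gfp" %in% names(events)) {
    abort("missing required channel(s): gfp", class = "fluxscreen_channel_error")
  }
  mutate(events, level = findInterval(.data$gfp, boundaries))
}

#' Geometric mean fluorescence intensity
#'
#' `exp(mean(log(x)))`, the cytometry-standard population summary for
#' log-normally distributed fluorescence. Requires strictly positive input
#' (guaranteed by the `"floor"` or `"arcsinh"` transform policies).
#'
#' @param x Numeric intensities.
#' @param arithmetic If `TRUE`, return the arithmetic mean instead (kept as
#'   a sensitivity-analysis switch).
#' @return A scalar; `NA_real_` for empty input (undefined, not an error).
#' @export
#' @examples
#' geometric_mfi(c(10, 1000)) # 100
geometric_mfi <- function(x, arithmetic = FALSE) {
  if (length(x) == 0L) return(NA_real_)
  if (any(x <= 0)) {
    abort(paste("non-positive intensity: apply a transform policy",
                "('floor' or 'arcsinh') before computing geometric MFIs"))
  }
  if (arithmetic) mean(x) else exp(mean(log(x)))
}

#' Per-level LC3 flux statistic
#'
#' The fraction of the lysosome-arrested LC3 pool that is degraded in
#' untreated cells, as a percentage:
#' `(MFI_bafa1 - MFI_untreated) / MFI_bafa1 * 100`. 100% means complete
#' degradation of the arrested pool; 0% means none. Negative values
#' (accumulation apparently exceeding the arrested signal, i.e. noise or a
#' quench artifact) are reported, not clipped.
#'
#' The identical formula applies to western-blot LC3-II densitometry pairs
#' (inhibitor-treated vs untreated band intensities) - one statistic, two
#' data sources.
#'
#' @param mfi_bafa1 LC3 MFI (or band intensity) under bafilomycin A1;
#'   must be > 0.
#' @param mfi_untreated LC3 MFI (or band intensity) untreated.
#' @return Flux in percent, in (-Inf, 100]. Vectorized.
#' @export
#' @examples
#' compute_flux(200, 150) # 25
compute_flux <- function(mfi_bafa1, mfi_untreated) {
  if (any(mfi_bafa1 <= 0, na.rm = TRUE)) {
    abort("mfi_bafa1 must be > 0")
  }
  (mfi_bafa1 - mfi_untreated) / mfi_bafa1 * 100
}

#' Expression-binned autophagic flux analysis (DEFAC)
#'
#' Runs the full per-expression-level flux pipeline on a matched pair of
#' event tables (untreated and bafilomycin-A1-treated cells carrying the
#' same rescue construct): dead-cell exclusion, GFP level assignment with a
#' common gate, per-level geometric LC3 MFIs, and the per-level flux
#' statistic. Replicate-wise fluxes are aggregated to mean and SD; the
#' pooled (all replicates) MFIs and flux are reported alongside.
#'
#' @param untreated,bafa1 Event tables (see [read_events()] /
#'   [gen_defac_events()]) with identical replicate sets.
#' @param gate A [gate_config()].
#' @param mean_type `"geometric"` (default) or `"arithmetic"` population
#'   summary.
#' @param baseline_subtract If `TRUE`, subtract the GFP-negative baseline
#'   LC3 MFI from both arms' MFIs before forming the flux ratio. Default
#'   `FALSE`: the flux is computed on the plain MFIs.
#' @return A `defac_tbl` tibble with one row per level 0-4: event counts and
#'   LC3 MFIs per arm (pooled across replicates), the pooled `flux_pct`,
#'   per-replicate fluxes (`flux_reps` list-column), their `flux_mean` and
#'   `flux_sd`, and a `flagged` column marking levels with fewer than
#'   `min_events_per_level` events in either arm. The GFP-negative baseline
#'   LC3 MFI (untreated Level 0) is stored in the `baseline_lc3` attribute
#'   and column.
#' @export
defac_analysis <- function(untreated, bafa1, gate,
                           mean_type = c("geometric", "arithmetic"),
                           baseline_subtract = FALSE) {
  mean_type <- match.arg(mean_type)
  stopifnot(inherits(gate, "gate_config"))
  arith <- mean_type == "arithmetic"

  reps_u <- sort(unique(untreated$replicate))
  reps_b <- sort(unique(bafa1$replicate))
  if (!identical(reps_u, reps_b)) {
    abort(sprintf(
      "replicate mismatch between arms (untreated: %s; bafa1: %s)",
      paste(reps_u, collapse = ","), paste(reps_b, collapse = ",")
    ))
  }

  prep <- function(ev) {
    ev |>
      exclude_dead(gate$viability_threshold) |>
      assign_levels(gate)
  }
  u <- prep(untreated)
  b <- prep(bafa1)

  per_level <- function(ev) {
    ev |>
      group_by(.data$replicate, .data$level) |>
      summarise(n = dplyr::n(), mfi = geometric_mfi(.data$lc3, arith),
                .groups = "drop")
  }
  lu <- per_level(u)
  lb <- per_level(b)

  baseline_lc3 <- geometric_mfi(u$lc3[u$level == 0L], arith)
  offset <- if (baseline_subtract) baseline_lc3 else 0

  grid <- tidyr::expand_grid(replicate = reps_u, level = 0:4) |>
    left_join(rename(lu, n_untreated = "n", mfi_untreated = "mfi"),
              by = c("replicate", "level")) |>
    left_join(rename(lb, n_bafa1 = "n", mfi_bafa1 = "mfi"),
              by = c("replicate", "level")) |>
    mutate(
      n_untreated = dplyr::coalesce(.data$n_untreated, 0L),
      n_bafa1 = dplyr::coalesce(.data$n_bafa1, 0L),
      ok = .data$n_untreated >= gate$min_events_per_level &
        .data$n_bafa1 >= gate$min_events_per_level &
        (.data$mfi_bafa1 - offset) > 0,
      flux = ifelse(.data$ok,
        (.data$mfi_bafa1 - .data$mfi_untreated) / (.data$mfi_bafa1 - offset) * 100,
        NA_real_
      )
    )

  pooled_level <- function(ev, suffix) {
    ev |>
      group_by(.data$level) |>
      summarise(n = dplyr::n(), mfi = geometric_mfi(.data$lc3, arith),
                .groups = "drop") |>
      setNames(c("level", paste0("n_", suffix), paste0("mfi_lc3_", suffix)))
  }

  out <- tibble(level = 0:4) |>
    left_join(pooled_level(u, "untreated"), by = "level") |>
    left_join(pooled_level(b, "bafa1"), by = "level") |>
    mutate(
      n_untreated = dplyr::coalesce(.data$n_untreated, 0L),
      n_bafa1 = dplyr::coalesce(.data$n_bafa1, 0L)
    )

  rep_summ <- grid |>
    group_by(.data$level) |>
    summarise(
      flux_reps = list(setNames(.data$flux, .data$replicate)),
      flux_mean = mean(.data$flux[!is.na(.data$flux)]),
      flux_sd = sd(.data$flux[!is.na(.data$flux)]),
      .groups = "drop"
    )

  out <- out |>
    left_join(rep_summ, by = "level") |>
    mutate(
      flagged = .data$n_untreated < gate$min_events_per_level |
        .data$n_bafa1 < gate$min_events_per_level,
      flux_pct = ifelse(!.data$flagged & (.data$mfi_lc3_bafa1 - offset) > 0,
        (.data$mfi_lc3_bafa1 - .data$mfi_lc3_untreated) /
          (.data$mfi_lc3_bafa1 - offset) * 100,
        NA_real_
      ),
      baseline_lc3 = baseline_lc3
    ) |>
    select("level", "n_untreated", "n_bafa1", "mfi_lc3_untreated",
           "mfi_lc3_bafa1", "flux_pct", "flux_reps", "flux_mean", "flux_sd",
           "flagged", "baseline_lc3")

  structure(out,
    baseline_lc3 = baseline_lc3, gate = gate, mean_type = mean_type,
    baseline_subtract = baseline_subtract,
    class = c("defac_tbl", class(out))
  )
}

#' Reporter-quench control
#'
#' Checks that the lysosome inhibitor does not itself alter the expression
#' reporter: the ratio of the gross GFP MFI (all events, both arms) should
#' be ~1. A failing control invalidates the flux readout.
#'
#' @param untreated,bafa1 Event tables with a `gfp` column.
#' @param tolerance Maximum allowed deviation of the ratio from 1
#'   (default 0.1).
#' @return A one-row tibble with `ratio`, `tolerance` and `pass`.
#' @export
quench_control <- function(untreated, bafa1, tolerance = 0.1) {
  if (nrow(untreated) == 0L || nrow(bafa1) == 0L) abort("empty event table")
  for (ev in list(untreated, bafa1)) {
    if (!"gfp" %in% names(ev)) {
      abort("missing required channel(s): gfp", class = "fluxscreen_channel_error")
    }
  }
  ratio <- geometric_mfi(bafa1$gfp) / geometric_mfi(untreated$gfp)
  tibble(ratio = ratio, tolerance = tolerance,
         pass = abs(ratio - 1) <= tolerance)
}

#' Per-level two-group comparison of flux
#'
#' Compares two flux tables level by level with a two-sided Student's
#' t test on the per-replicate flux values (the published per-level
#' reporting convention: unadjusted p-values, significance stars at
#' 0.05/0.01/0.001). Holm adjustment across the five levels is available
#' as an option.
#'
#' @param table_a,table_b `defac_tbl` objects from [defac_analysis()].
#' @param adjust `"none"` (default, matching per-level reporting) or
#'   `"holm"` across levels.
#' @return A tibble with one row per level: replicate counts, means,
#'   t statistic, p-value, stars, and `testable` (FALSE where either side
#'   has fewer than 2 usable replicates).
#' @export
compare_levels <- function(table_a, table_b, adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(table_a, "defac_tbl"), inherits(table_b, "defac_tbl"))
  res <- purrr::map_dfr(0:4, function(lv) {
    fa <- table_a$flux_reps[[which(table_a$level == lv)]]
    fb <- table_b$flux_reps[[which(table_b$level == lv)]]
    fa <- fa[!is.na(fa)]
    fb <- fb[!is.na(fb)]
    if (length(fa) < 2L || length(fb) < 2L) {
      return(tibble(level = lv, n_a = length(fa), n_b = length(fb),
                    mean_a = mean(fa), mean_b = mean(fb),
                    statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                    testable = FALSE))
    }
    tt <- tryCatch(
      t.test(fa, fb, var.equal = TRUE),
      error = function(e) NULL # constant data with zero spread
    )
    if (is.null(tt)) {
      eq <- isTRUE(all.equal(mean(fa), mean(fb)))
      return(tibble(level = lv, n_a = length(fa), n_b = length(fb),
                    mean_a = mean(fa), mean_b = mean(fb),
                    statistic = if (eq) 0 else NA_real_, df = NA_real_,
                    p_value = if (eq) 1 else NA_real_, testable = eq))
    }
    tibble(level = lv, n_a = length(fa), n_b = length(fb),
           mean_a = mean(fa), mean_b = mean(fb),
           statistic = unname(tt$statistic), df = unname(tt$parameter),
           p_value = tt$p.value, testable = TRUE)
  })
  if (adjust == "holm") {
    res$p_value <- p.adjust(res$p_value, method = "holm")
  }
  mutate(res, stars = p_stars(.data$p_value))
}
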