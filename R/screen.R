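#' Screening triage configuration
#'
#' Thresholds and exclusion lists for the dual-criterion library triage.
#' Defaults are the published operating point: drugs dropping viability
#' below 50% of vehicle are toxic; a hit must push the cell-number-adjusted
#' GAG reporter below 0.5 of vehicle while keeping the mutant-protein
#' stability reporter above 2-fold of vehicle. All three thresholds are
#' strict inequalities; an exact-boundary value falls on the
#' retained / non-hit side.
#'
#' @param viability_min Viability ratio below which a drug is excluded as
#'   cytotoxic (strict; default 0.5).
#' @param gag_max GAG reporter ratio a hit must fall strictly below
#'   (default 0.5).
#' @param vps33a_min Stability reporter fold a hit must exceed strictly
#'   (default 2.0).
#' @param excluded_categories Category tags removed from the hit list
#'   (default `c("anticancer", "topical")` - drugs unsuitable for pregnant
#'   mothers or newborns).
#' @param named_exclusions Drug names removed at the second stage (e.g.
#'   drugs toxic to patient-derived cells); default none. Purely
#'   configuration - the package hard-codes no drug names.
#' @param gag_cell_normalize If `TRUE` (default) the quadrant's GAG axis is
#'   the cell-number-adjusted ratio ([cell_normalize_sdc1()]); `FALSE` uses
#'   the raw vehicle ratio.
#' @return A `screen_config` list.
#' @export
screen_config <- function(viability_min = 0.5,
                          gag_max = 0.5,
                          vps33a_min = 2.0,
                          excluded_categories = c("anticancer", "topical"),
                          named_exclusions = character(),
                          gag_cell_normalize = TRUE) {
  for (v in c(viability_min, gag_max, vps33a_min)) {
    if (!is.numeric(v) || length(v) != 1L || v <= 0) {
      abort("screen thresholds must be single positive ratios",
            class = "fluxscreen_config_error")
    }
  }
  structure(
    list(viability_min = viability_min, gag_max = gag_max,
         vps33a_min = vps33a_min,
         excluded_categories = as.character(excluded_categories),
         named_exclusions = as.character(named_exclusions),
         gag_cell_normalize = isTRUE(gag_cell_normalize)),
    class = "screen_config"
  )
}

#' Normalize a raw plate signal to the vehicle wells
#'
#' Percent-of-control normalization: each well's signal is divided by the
#' mean signal of the vehicle (DMSO) wells of the *same plate*, so the
#' vehicle sits at 1 by construction.
#'
#' @param records Screen records (see [read_screen_table()]).
#' @param signal `"cellmask"` (whole-cell stain, mapped to
#'   `viability_ratio`), `"sdc1"` (GAG reporter, `sdc1_ratio`) or `"nluc"`
#'   (stability reporter, `vps33a_ratio`).
#' @return `records` with the corresponding ratio column added.
#' @export
normalize_to_vehicle <- function(records, signal = c("cellmask", "sdc1", "nluc")) {
  signal <- match.arg(signal)
  raw_col <- paste0(signal, "_raw")
  ratio_col <- c(cellmask = "viability_ratio", sdc1 = "sdc1_ratio",
                 nluc = "vps33a_ratio")[[signal]]
  if (!raw_col %in% names(records)) {
    abort(sprintf("records lack column '%s'", raw_col))
  }
  veh <- records |>
    filter(.data$is_vehicle) |>
    group_by(.data$plate) |>
    summarise(vehicle_mean = mean(.data[[raw_col]]), .groups = "drop")
  plates <- unique(records$plate)
  if (!all(plates %in% veh$plate)) {
    abort(sprintf("no vehicle wells on plate(s): %s",
                  paste(setdiff(plates, veh$plate), collapse = ", ")))
  }
  if (any(is.na(veh$vehicle_mean) | veh$vehicle_mean <= 0)) {
    abort("vehicle mean signal must be > 0")
  }
  records |>
    left_join(veh, by = "plate") |>
    mutate(!!ratio_col := .data[[raw_col]] / .data$vehicle_mean) |>
    select(-"vehicle_mean")
}

#' Cell-number-adjusted GAG ratio
#'
#' Divides the GAG reporter ratio by the cell-number (viability) ratio so
#' that GAG loss attributable purely to cell loss normalizes back to 1.
#'
#' @param sdc1_ratio Vehicle-normalized GAG reporter ratio.
#' @param viability_ratio Vehicle-normalized cell-number ratio; must be > 0.
#' @return The adjusted ratio. Vectorized.
#' @export
#' @examples
#' cell_normalize_sdc1(0.5, 0.5) # 1: GAG loss fully explained by cell loss
cell_normalize_sdc1 <- function(sdc1_ratio, viability_ratio) {
  if (any(viability_ratio <= 0, na.rm = TRUE)) {
    abort("viability_ratio must be > 0")
  }
  sdc1_ratio / viability_ratio
}

#' Normalize a whole screen table
#'
#' Applies [normalize_to_vehicle()] for all three signals, adds the
#' cell-number-adjusted GAG ratio, and drops the vehicle rows, yielding one
#' result row per drug.
#'
#' @param records Screen records.
#' @return A tibble of per-drug screen results with `viability_ratio`,
#'   `sdc1_ratio`, `sdc1_cellnorm`, `vps33a_ratio`.
#' @export
screen_normalize <- function(records) {
  records |>
    normalize_to_vehicle("cellmask") |>
    normalize_to_vehicle("sdc1") |>
    normalize_to_vehicle("nluc") |>
    filter(!.data$is_vehicle) |>
    mutate(sdc1_cellnorm = cell_normalize_sdc1(.data$sdc1_ratio,
                                               .data$viability_ratio))
}

#' Cytotoxicity filter
#'
#' Splits screen results into retained and excluded sets on the viability
#' ratio. Exclusion is strict: a drug is dropped iff
#' `viability_ratio < min_ratio`; a ratio exactly at the threshold is
#' retained.
#'
#' @param results Normalized screen results (see [screen_normalize()]).
#' @param min_ratio Viability threshold (default 0.5).
#' @return A list with tibbles `retained` and `excluded`.
#' @export
viability_filter <- function(results, min_ratio = 0.5) {
  toxic <- results$viability_ratio < min_ratio
  list(retained = results[!toxic, , drop = FALSE],
       excluded = results[toxic, , drop = FALSE])
}

#' Dual-criterion quadrant hit selection
#'
#' Selects hits in the lower-right quadrant of the stability-vs-GAG plane:
#' GAG reporter strictly below `gag_max` *and* stability reporter strictly
#' above `vps33a_min`. Run this on viability-filtered results. Drugs
#' lacking the stability reporter signal are flagged unevaluable and are
#' never hits.
#'
#' @param results Viability-filtered screen results.
#' @param gag_max GAG threshold (strict `<`; default 0.5).
#' @param vps33a_min Stability threshold (strict `>`; default 2.0).
#' @param use_cell_normalized Use the cell-number-adjusted GAG ratio
#'   (default) or the raw vehicle ratio for the GAG axis.
#' @return A list: `results` (input with logical flags `gag_hit`,
#'   `stabilizer`, `dual_hit`, `unevaluable`), and the three selections
#'   `gag_hits`, `stabilizers`, `dual_hits`.
#' @export
quadrant_select <- function(results, gag_max = 0.5, vps33a_min = 2.0,
                            use_cell_normalized = TRUE) {
  gag_axis <- if (use_cell_normalized) results$sdc1_cellnorm else results$sdc1_ratio
  unevaluable <- is.na(results$vps33a_ratio)
  flagged <- results |>
    mutate(
      gag_hit = gag_axis < gag_max,
      stabilizer = !unevaluable & .data$vps33a_ratio > vps33a_min,
      unevaluable = unevaluable,
      dual_hit = .data$gag_hit & .data$stabilizer
    )
  list(
    results = flagged,
    gag_hits = filter(flagged, .data$gag_hit),
    stabilizers = filter(flagged, .data$stabilizer),
    dual_hits = filter(flagged, .data$dual_hit)
  )
}

#' Remove hits by category tag or by name
#'
#' Drops any hit carrying one of the excluded category tags (e.g.
#' anticancer, topical) or whose name appears in the named exclusion list
#' (e.g. drugs toxic to patient-derived cells at the second stage), and
#' returns the removed set with reasons.
#'
#' @param hits Hit tibble with `drug_name` and a `category_tags`
#'   list-column.
#' @param excluded_categories Character vector of category tags to remove.
#' @param named_exclusions Character vector of drug names to remove.
#' @return A list with tibbles `candidates` and `removed` (the latter with
#'   a `reason` column).
#' @export
apply_exclusions <- function(hits, excluded_categories = character(),
                             named_exclusions = character()) {
  tags <- hits$category_tags %||% vector("list", nrow(hits))
  by_cat <- purrr::map_lgl(tags, function(tg) {
    length(intersect(tg %||% character(), excluded_categories)) > 0L
  })
  by_name <- hits$drug_name %in% named_exclusions
  removed <- hits[by_cat | by_name, , drop = FALSE]
  if (nrow(removed)) {
    removed$reason <- dplyr::case_when(
      by_cat[by_cat | by_name] & by_name[by_cat | by_name] ~ "category+named",
      by_cat[by_cat | by_name] ~ "category",
      TRUE ~ "named"
    )
  } else {
    removed$reason <- character(0)
  }
  list(candidates = hits[!(by_cat | by_name), , drop = FALSE],
       removed = removed)
}

#' Run the full screening funnel
#'
#' Executes the published triage order on a raw screen table:
#' vehicle normalization (all signals, per plate), cytotoxicity filter,
#' cell-number adjustment, dual-criterion quadrant selection, category
#' exclusions, then named (second-stage) exclusions. Emits a
#' [funnel_report()] whose stage counts satisfy conservation and chaining,
#' with the single-criterion hit counts carried as annotations.
#'
#' The stage order is load-bearing: the toxicity filter precedes quadrant
#' selection, so cytotoxic drugs can never surface as hits even when their
#' reporter ratios would qualify.
#'
#' @param records Raw screen records (see [read_screen_table()] or
#'   [gen_screen_table()]).
#' @param config A [screen_config()].
#' @return A `screen_funnel` list: `report` (the [funnel_report()]),
#'   `results` (all drugs with ratios and flags) and `candidates`
#'   (the final hit tibble).
#' @export
run_funnel <- function(records, config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  results <- screen_normalize(records)

  vf <- viability_filter(results, config$viability_min)
  qs <- quadrant_select(vf$retained, config$gag_max, config$vps33a_min,
                        use_cell_normalized = config$gag_cell_normalize)
  cat_ex <- apply_exclusions(qs$dual_hits,
                             excluded_categories = config$excluded_categories)
  named_ex <- apply_exclusions(cat_ex$candidates,
                               named_exclusions = config$named_exclusions)

  ids <- function(x) as.character(x$drug_id)
  stages <- tibble(
    stage_name = c("viability", "dual_criterion", "category_exclusion",
                   "second_stage_exclusion"),
    n_in = c(nrow(results), nrow(vf$retained), nrow(qs$dual_hits),
             nrow(cat_ex$candidates)),
    n_retained = c(nrow(vf$retained), nrow(qs$dual_hits),
                   nrow(cat_ex$candidates), nrow(named_ex$candidates)),
    n_excluded = c(nrow(vf$excluded),
                   nrow(vf$retained) - nrow(qs$dual_hits),
                   nrow(cat_ex$removed), nrow(named_ex$removed)),
    retained_ids = list(ids(vf$retained), ids(qs$dual_hits),
                        ids(cat_ex$candidates), ids(named_ex$candidates)),
    excluded_ids = list(ids(vf$excluded),
                        setdiff(ids(vf$retained), ids(qs$dual_hits)),
                        ids(cat_ex$removed), ids(named_ex$removed))
  )
  report <- funnel_report(stages, annotations = list(
    n_library = nrow(results),
    n_gag_hits = nrow(qs$gag_hits),
    n_stabilizers = nrow(qs$stabilizers),
    n_unevaluable = sum(qs$results$unevaluable)
  ))

  flagged_all <- qs$results |>
    mutate(toxic = FALSE) |>
    bind_rows(mutate(vf$excluded, toxic = TRUE, gag_hit = NA, stabilizer = NA,
                     dual_hit = FALSE, unevaluable = is.na(.data$vps33a_ratio))) |>
    mutate(
      excluded_by_category = .data$drug_id %in% ids(cat_ex$removed),
      second_stage_excluded = .data$drug_id %in% ids(named_ex$removed),
      candidate = .data$drug_id %in% ids(named_ex$candidates)
    )

  structure(
    list(report = report, results = flagged_all,
         candidates = named_ex$candidates, config = config),
    class = "screen_funnel"
  )
}

#' @export
print.screen_funnel <- function(x, ...) {
  cat("Screening funnel\n")
  ann <- attr(x$report, "annotations")
  cat(sprintf("  library: %d drugs; GAG hits %s, stabilizers %s\n",
              ann$n_library %||% NA, ann$n_gag_hits %||% NA,
              ann$n_stabilizers %||% NA))
  for (i in seq_len(nrow(x$report))) {
    cat(sprintf("  %-24s %5d -> %5d (excluded %d)\n",
                x$report$stage_name[i], x$report$n_in[i],
                x$report$n_retained[i], x$report$n_excluded[i]))
  }
  invisible(x)
}
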