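# small hand-built screen table: 2 plates with different vehicle means
mini_screen <- function() {
  tibble::tibble(
    drug_id = c("D1", "D2", "D3", "V1", "V2"),
    drug_name = c("alpha", "beta", "gamma", "DMSO", "DMSO"),
    plate = c("p1", "p1", "p2", "p1", "p2"),
    well = c("w1", "w2", "w1", "v1", "v1"),
    is_vehicle = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    category = c("", "anticancer", "", "", ""),
    category_tags = list(character(0), "anticancer", character(0),
                         character(0), character(0)),
    cellmask_raw = c(80, 40, 100, 80, 200),
    sdc1_raw = c(50, 20, 60, 50, 120),
    nluc_raw = c(20, 60, 45, 20, 15)
  )
}

test_that("vehicle normalization is per plate and puts vehicle at 1", {
  rec <- normalize_to_vehicle(mini_screen(), "cellmask")
  # drug equal to vehicle mean -> 1; plate 2 uses its own vehicle mean
  expect_equal(rec$viability_ratio[rec$drug_id == "D1"], 1.0)
  expect_equal(rec$viability_ratio[rec$drug_id == "D2"], 0.5)
  expect_equal(rec$viability_ratio[rec$drug_id == "D3"], 0.5)
  expect_equal(rec$viability_ratio[rec$is_vehicle], c(1, 1))
  # no vehicle wells -> error
  expect_error(
    normalize_to_vehicle(dplyr::filter(mini_screen(), !is_vehicle), "cellmask"),
    "vehicle"
  )
})

test_that("cell-number adjustment divides out viability", {
  expect_equal(cell_normalize_sdc1(0.5, 0.5), 1.0)
  expect_equal(cell_normalize_sdc1(0.4, 1.0), 0.4)
  expect_equal(cell_normalize_sdc1(1.0, 2.0), 0.5)
  expect_error(cell_normalize_sdc1(0.5, 0), "viability_ratio")
})

test_that("viability filter is strict below the threshold", {
  res <- tibble::tibble(drug_id = c("a", "b", "c"),
                        viability_ratio = c(0.49, 0.50, 1.0))
  vf <- viability_filter(res, 0.5)
  expect_equal(vf$excluded$drug_id, "a") # 0.49 out
  expect_setequal(vf$retained$drug_id, c("b", "c")) # 0.50 exactly stays
})

test_that("quadrant selection is strict on both axes and handles missing reporter", {
  res <- tibble::tibble(
    drug_id = c("hit", "boundary", "vehicle_like", "no_nluc"),
    sdc1_cellnorm = c(0.4, 0.5, 1.0, 0.3),
    sdc1_ratio = c(0.4, 0.5, 1.0, 0.3),
    vps33a_ratio = c(2.5, 2.0, 1.0, NA)
  )
  qs <- quadrant_select(res, 0.5, 2.0)
  expect_equal(qs$dual_hits$drug_id, "hit")
  expect_false("boundary" %in% qs$dual_hits$drug_id) # both exactly at threshold
  expect_false("vehicle_like" %in% qs$dual_hits$drug_id) # (1,1) is no hit
  expect_true(qs$results$unevaluable[qs$results$drug_id == "no_nluc"])
  expect_false(qs$results$dual_hit[qs$results$drug_id == "no_nluc"])
})

test_that("threshold strictness flips membership only across the strict side", {
  ulp_down <- function(x) x * (1 - .Machine$double.eps)
  ulp_up <- function(x) x * (1 + .Machine$double.eps)
  # viability: exactly 0.5 retained, one ulp below excluded
  res <- tibble::tibble(drug_id = "d", viability_ratio = 0.5)
  expect_equal(nrow(viability_filter(res, 0.5)$excluded), 0L)
  res$viability_ratio <- ulp_down(0.5)
  expect_equal(nrow(viability_filter(res, 0.5)$excluded), 1L)
  # quadrant: at (0.5, 2.0) not a hit; one ulp inside on both axes is
  q <- tibble::tibble(drug_id = "d", sdc1_cellnorm = 0.5, sdc1_ratio = 0.5,
                      vps33a_ratio = 2.0)
  expect_equal(nrow(quadrant_select(q, 0.5, 2.0)$dual_hits), 0L)
  q$sdc1_cellnorm <- ulp_down(0.5)
  q$vps33a_ratio <- ulp_up(2.0)
  expect_equal(nrow(quadrant_select(q, 0.5, 2.0)$dual_hits), 1L)
})

test_that("exclusions remove tagged and named hits with reasons", {
  hits <- tibble::tibble(
    drug_id = sprintf("H%02d", 1:18),
    drug_name = c(sprintf("tagged_%d", 1:7), paper_named_exclusions,
                  sprintf("keeper_%d", 1:7)),
    category_tags = c(
      as.list(c(rep("anticancer", 4), rep("topical", 3))),
      rep(list(character(0)), 11)
    )
  )
  first <- apply_exclusions(hits, excluded_categories = c("anticancer", "topical"))
  expect_equal(nrow(first$candidates), 11L)
  expect_equal(nrow(first$removed), 7L)
  expect_true(all(first$removed$reason == "category"))
  second <- apply_exclusions(first$candidates,
                             named_exclusions = paper_named_exclusions)
  expect_equal(nrow(second$candidates), 7L)
  expect_true(all(second$removed$reason == "named"))
  # empty exclusion sets are the identity
  none <- apply_exclusions(hits)
  expect_equal(none$candidates, hits)
})

test_that("funnel conservation, chaining and idempotence hold on synthetic screens", {
  for (seed in c(101, 202)) {
    rec <- gen_screen_table(screen_sim_spec(n_drugs = 400L), seed = seed)
    fun <- run_funnel(rec, screen_config())
    rep <- fun$report
    expect_true(all(rep$n_retained + rep$n_excluded == rep$n_in))
    expect_true(all(rep$n_in[-1] == rep$n_retained[-nrow(rep)]))
    expect_true(all(diff(c(rep$n_in[1], rep$n_retained)) <= 0)) # monotone
    # idempotence: re-filtering retained sets changes nothing
    vf <- viability_filter(fun$results |> dplyr::filter(!toxic), 0.5)
    expect_equal(nrow(vf$excluded), 0L)
    qs <- quadrant_select(dplyr::filter(fun$results, dual_hit))
    expect_equal(nrow(qs$dual_hits), sum(fun$results$dual_hit, na.rm = TRUE))
  }
})

test_that("degenerate thresholds give zero hits", {
  rec <- gen_screen_table(screen_sim_spec(n_drugs = 200L), seed = 5)
  fun <- run_funnel(rec, screen_config(gag_max = 1e-12))
  expect_equal(fun$report$n_retained[fun$report$stage_name == "dual_criterion"], 0L)
})

test_that("filter order is load-bearing: toxicity before quadrant selection", {
  # a cytotoxic drug whose reporter ratios would qualify as a dual hit
  rec <- tibble::tibble(
    drug_id = c("toxic_hit", "clean_hit", "V1"),
    drug_name = c("toxic_hit", "clean_hit", "DMSO"),
    plate = "p1", well = c("w1", "w2", "v1"),
    is_vehicle = c(FALSE, FALSE, TRUE),
    category = "", category_tags = rep(list(character(0)), 3),
    cellmask_raw = c(30, 100, 100), # toxic: viability 0.3
    sdc1_raw = c(9, 40, 100),       # cellnorm 0.3 and 0.4
    nluc_raw = c(300, 300, 100)     # both stabilize 3-fold
  )
  correct <- run_funnel(rec, screen_config())
  expect_equal(correct$candidates$drug_id, "clean_hit")
  # reversed order would admit the toxic drug as a hit
  results <- screen_normalize(rec)
  reversed_hits <- quadrant_select(results)$dual_hits
  expect_setequal(reversed_hits$drug_id, c("toxic_hit", "clean_hit"))
  expect_false(setequal(reversed_hits$drug_id, correct$candidates$drug_id))
})

test_that("the synthetic reconstruction reproduces the published funnel", {
  rec <- gen_screen_reference()
  fun <- run_funnel(rec, screen_config(named_exclusions = paper_named_exclusions))
  rep <- fun$report
  ann <- attr(rep, "annotations")
  expect_equal(ann$n_library, 1968L)
  expect_equal(rep$n_excluded[rep$stage_name == "viability"], 346L)
  expect_equal(rep$n_retained[rep$stage_name == "viability"], 1622L)
  expect_equal(ann$n_gag_hits, 129L)
  expect_equal(ann$n_stabilizers, 52L)
  expect_equal(rep$n_retained[rep$stage_name == "dual_criterion"], 18L)
  expect_equal(rep$n_retained[rep$stage_name == "category_exclusion"], 11L)
  expect_equal(rep$n_retained[rep$stage_name == "second_stage_exclusion"], 7L)
  expect_setequal(fun$candidates$drug_name,
                  c("acitretin", "dimethyl fumarate", "entacapone",
                    "nifedipine", "rifaximin", "triclabendazole", "vitamin A"))
})
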