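#' Simulation specification for expression-binned flux cytometry
#'
#' Parameters of the event-table generator: a mixture of an untransfected
#' (autofluorescent) population and a transfected population whose
#' expression-reporter signal spans several decades, a per-level true flux
#' vector, a dead-cell fraction with elevated viability-dye signal, and
#' multiplicative log-normal measurement noise. The defaults emulate the
#' conditions of a transient-rescue flux experiment: 20,000 events, 3
#' replicates, 10% dead cells, a transfected fraction of 0.6, and gate
#' boundaries enclosing well-populated levels.
#'
#' @param n_events Events per arm per replicate (default 20000).
#' @param transfected_fraction Fraction of cells expressing the construct
#'   (default 0.6).
#' @param gfp_neg_meanlog,gfp_neg_sdlog Log-normal parameters of the
#'   autofluorescence GFP signal (defaults `log(50)`, 0.4).
#' @param gfp_pos_meanlog,gfp_pos_sdlog Log-normal parameters of the
#'   transfected GFP signal (defaults `log(3000)`, 1.3 - several decades).
#' @param lc3_meanlog,lc3_sdlog Log-normal parameters of the arrested
#'   (inhibitor-treated) LC3 baseline (defaults `log(500)`, 0.5).
#' @param true_flux_by_level True flux percentages for levels 0-4.
#' @param dead_fraction Fraction of dead events (default 0.1).
#' @param noise_sdlog SD of the multiplicative log-normal measurement noise
#'   on LC3 (meanlog 0, so the geometric mean is unbiased; default 0.15).
#' @param gfp_boundaries Level boundaries used by the generator to decide
#'   which flux applies to an event (default `c(160, 800, 4000, 20000)`,
#'   matched to the GFP mixture above).
#' @param viability_live_meanlog,viability_dead_meanlog,viability_sdlog
#'   Log-normal parameters of the viability dye for live and dead cells
#'   (defaults `log(50)`, `log(5000)`, 0.3; threshold 1000 separates them).
#' @param viability_threshold Dead-cell gate consistent with the above
#'   (default 1000).
#' @param n_replicates Number of replicates (default 3).
#' @return A `defac_sim_spec` list.
#' @export
defac_sim_spec <- function(n_events = 20000L,
                           transfected_fraction = 0.6,
                           gfp_neg_meanlog = log(50), gfp_neg_sdlog = 0.4,
                           gfp_pos_meanlog = log(3000), gfp_pos_sdlog = 1.3,
                           lc3_meanlog = log(500), lc3_sdlog = 0.5,
                           true_flux_by_level = c(0, 40, 60, 60, 60),
                           dead_fraction = 0.1,
                           noise_sdlog = 0.15,
                           gfp_boundaries = c(160, 800, 4000, 20000),
                           viability_live_meanlog = log(50),
                           viability_dead_meanlog = log(5000),
                           viability_sdlog = 0.3,
                           viability_threshold = 1000,
                           n_replicates = 3L) {
  stopifnot(
    n_events >= 1L, n_replicates >= 1L,
    transfected_fraction >= 0, transfected_fraction <= 1,
    dead_fraction >= 0, dead_fraction <= 1,
    gfp_neg_sdlog > 0, gfp_pos_sdlog > 0, lc3_sdlog > 0, noise_sdlog >= 0,
    length(true_flux_by_level) == 5L, all(true_flux_by_level <= 100),
    length(gfp_boundaries) == 4L, all(diff(gfp_boundaries) > 0)
  )
  structure(as.list(environment()), class = "defac_sim_spec")
}

#' Generate paired flux-cytometry event tables
#'
#' Draws untreated and inhibitor-treated event tables per replicate from a
#' [defac_sim_spec()]. Each arm's cells draw a GFP signal from the
#' untransfected or transfected mixture component; the arrested LC3 signal
#' is the log-normal baseline, and the untreated LC3 signal is the baseline
#' times `(1 - flux(level)/100)` - i.e. degradation removes signal from the
#' untreated arm, which is algebraically equivalent (for the flux ratio) to
#' accumulation in the inhibited arm. Both arms carry independent
#' multiplicative noise with geometric mean 1, so the per-level geometric
#' MFIs recover the true flux in expectation. Dead events draw an elevated
#' viability-dye signal.
#'
#' @param spec A [defac_sim_spec()].
#' @param seed Integer seed (required; the generator seeds the global RNG
#'   once per call and is fully reproducible).
#' @param construct Construct label recorded in metadata (default "WT").
#' @return A single tidy event tibble covering both arms and all
#'   replicates, with columns `sample_id`, `construct`, `treatment`,
#'   `replicate`, `gfp`, `lc3`, `viability` and a generator-truth `level`
#'   attribute-free design (levels are re-derived by the analysis).
#' @export
gen_defac_events <- function(spec = defac_sim_spec(), seed, construct = "WT") {
  stopifnot(inherits(spec, "defac_sim_spec"))
  if (missing(seed)) abort("seed is required")
  set.seed(seed)

  one_arm <- function(treatment, replicate) {
    n <- spec$n_events
    transfected <- runif(n) < spec$transfected_fraction
    gfp <- ifelse(transfected,
      rlnorm(n, spec$gfp_pos_meanlog, spec$gfp_pos_sdlog),
      rlnorm(n, spec$gfp_neg_meanlog, spec$gfp_neg_sdlog)
    )
    level <- findInterval(gfp, spec$gfp_boundaries)
    baseline <- rlnorm(n, spec$lc3_meanlog, spec$lc3_sdlog)
    noise <- rlnorm(n, 0, spec$noise_sdlog)
    flux <- spec$true_flux_by_level[level + 1L]
    lc3 <- if (treatment == "bafa1") {
      baseline * noise
    } else {
      baseline * (1 - flux / 100) * noise
    }
    dead <- runif(n) < spec$dead_fraction
    viability <- ifelse(dead,
      rlnorm(n, spec$viability_dead_meanlog, spec$viability_sdlog),
      rlnorm(n, spec$viability_live_meanlog, spec$viability_sdlog)
    )
    tibble(
      sample_id = sprintf("%s_%s_rep%d", construct, treatment, replicate),
      construct = construct, treatment = treatment,
      replicate = as.integer(replicate),
      gfp = gfp, lc3 = pmax(lc3, .Machine$double.xmin), viability = viability
    )
  }

  purrr::map_dfr(seq_len(spec$n_replicates), function(r) {
    bind_rows(one_arm("untreated", r), one_arm("bafa1", r))
  })
}

#' The gate implied by a simulation spec
#'
#' Convenience constructor returning the [gate_config()] matching a
#' [defac_sim_spec()]'s boundaries and viability threshold, for analyzing
#' generated events with the generator's own gate.
#'
#' @param spec A [defac_sim_spec()].
#' @param min_events_per_level Passed to [gate_config()].
#' @return A `gate_config`.
#' @export
sim_gate <- function(spec, min_events_per_level = 100L) {
  gate_config(spec$gfp_boundaries, spec$viability_threshold,
              min_events_per_level)
}

#' Simulation specification for a screening plate library
#'
#' Parameters of the synthetic drug-library generator. Per-drug latent
#' effects come from a four-class mixture (toxic, GAG-reducing,
#' protein-stabilizing, dual-action); observed signals are vehicle mean
#' times effect times multiplicative log-normal noise. The default class
#' probabilities are calibrated so that the expected stage counts of a
#' 1968-drug screen match the published proportions (346/1968 toxic;
#' 129, 52 and 18 of the remaining 1622 as GAG hits, stabilizers and dual
#' hits). The dual-class probability exceeding the product of the marginal
#' hit probabilities is what correlates the two effects.
#'
#' @param n_drugs Library size (default 1968).
#' @param toxic_fraction P(toxic) (default 346/1968).
#' @param gag_only_fraction,stabilizer_only_fraction,dual_fraction
#'   Class probabilities among non-toxic drugs (defaults 111/1622, 34/1622,
#'   18/1622, so marginal GAG and stabilizer rates are 129/1622 and
#'   52/1622).
#' @param noise_cv Log-normal measurement CV on every raw signal
#'   (default 0.05).
#' @param plate_size Drug wells per plate (default 88).
#' @param n_vehicle_wells Vehicle (DMSO) wells per plate (default 8).
#' @param tag_hit_fraction Fraction of dual-action drugs annotated with an
#'   excludable category tag, to exercise category exclusions
#'   (default 7/18).
#' @return A `screen_sim_spec` list.
#' @export
screen_sim_spec <- function(n_drugs = 1968L,
                            toxic_fraction = 346 / 1968,
                            gag_only_fraction = 111 / 1622,
                            stabilizer_only_fraction = 34 / 1622,
                            dual_fraction = 18 / 1622,
                            noise_cv = 0.05,
                            plate_size = 88L,
                            n_vehicle_wells = 8L,
                            tag_hit_fraction = 7 / 18) {
  stopifnot(
    n_drugs >= 1L,
    toxic_fraction >= 0, toxic_fraction <= 1,
    gag_only_fraction >= 0, stabilizer_only_fraction >= 0,
    dual_fraction >= 0,
    gag_only_fraction + stabilizer_only_fraction + dual_fraction <= 1,
    noise_cv >= 0, n_vehicle_wells >= 1L
  )
  structure(as.list(environment()), class = "screen_sim_spec")
}

#' Generate a synthetic screening plate table
#'
#' Draws a raw screen table (drug wells plus per-plate vehicle wells) from
#' a [screen_sim_spec()]. Latent effect sizes are kept well away from the
#' decision thresholds relative to the measurement noise (toxic viability
#' 0.10-0.42, GAG effect 0.15-0.42, stabilization 2.3-3.8, null effects
#' ~1), so realized stage counts are binomial in the class probabilities.
#'
#' @param spec A [screen_sim_spec()].
#' @param seed Integer seed (required).
#' @return A raw screen-record tibble in [read_screen_table()] layout.
#' @export
gen_screen_table <- function(spec = screen_sim_spec(), seed) {
  stopifnot(inherits(spec, "screen_sim_spec"))
  if (missing(seed)) abort("seed is required")
  set.seed(seed)

  n <- spec$n_drugs
  u <- runif(n)
  toxic <- u < spec$toxic_fraction
  # class draw among non-toxic drugs
  v <- runif(n)
  p1 <- spec$dual_fraction
  p2 <- p1 + spec$gag_only_fraction
  p3 <- p2 + spec$stabilizer_only_fraction
  class <- dplyr::case_when(
    toxic ~ "toxic",
    v < p1 ~ "dual",
    v < p2 ~ "gag",
    v < p3 ~ "stabilizer",
    TRUE ~ "null"
  )

  viab_eff <- ifelse(class == "toxic", runif(n, 0.10, 0.42), 1)
  gag_eff <- ifelse(class %in% c("gag", "dual"), runif(n, 0.15, 0.42), 1)
  stab_eff <- ifelse(class %in% c("stabilizer", "dual"), runif(n, 2.3, 3.8), 1)

  base <- c(cellmask = 10000, sdc1 = 5000, nluc = 2000)
  sdlog <- sqrt(log(1 + spec$noise_cv^2))
  noise <- function(n) rlnorm(n, -sdlog^2 / 2, sdlog) # mean-1 noise

  plate_of <- ceiling(seq_len(n) / spec$plate_size)
  drugs <- tibble(
    drug_id = sprintf("D%04d", seq_len(n)),
    drug_name = sprintf("compound_%04d", seq_len(n)),
    plate = sprintf("plate%02d", plate_of),
    well = sprintf("w%02d", (seq_len(n) - 1L) %% spec$plate_size + 1L),
    is_vehicle = FALSE,
    category = ifelse(class == "dual" & runif(n) < spec$tag_hit_fraction,
                      sample(c("anticancer", "topical"), n, replace = TRUE),
                      ""),
    cellmask_raw = base["cellmask"] * viab_eff * noise(n),
    # observed GAG signal scales with both the GAG effect and cell number
    sdc1_raw = base["sdc1"] * gag_eff * viab_eff * noise(n),
    nluc_raw = base["nluc"] * stab_eff * noise(n),
    latent_class = class
  )

  n_plates <- max(plate_of)
  vehicles <- purrr::map_dfr(seq_len(n_plates), function(p) {
    m <- spec$n_vehicle_wells
    tibble(
      drug_id = sprintf("VEH_p%02d_%d", p, seq_len(m)),
      drug_name = "DMSO",
      plate = sprintf("plate%02d", p),
      well = sprintf("v%02d", seq_len(m)),
      is_vehicle = TRUE,
      category = "",
      cellmask_raw = base["cellmask"] * noise(m),
      sdc1_raw = base["sdc1"] * noise(m),
      nluc_raw = base["nluc"] * noise(m),
      latent_class = "vehicle"
    )
  })

  validate_screen_records(
    mutate(bind_rows(drugs, vehicles),
           category_tags = strsplit(.data$category, ";", fixed = TRUE))
  )
}

#' Deterministic synthetic reconstruction of the published screen
#'
#' Builds a 1968-drug raw screen table engineered so that the triage
#' funnel reproduces the published stage counts exactly: 346 drugs fail
#' the 50% viability filter; among the 1622 survivors 129 suppress the GAG
#' reporter below 0.5, 52 keep the stability reporter above 2-fold, and 18
#' do both; 7 of the 18 carry anticancer/topical tags, and 4 of the
#' remaining 11 are the named drugs excluded for patient-cell toxicity at
#' the second stage, leaving the 7 published candidates. This is a
#' synthetic stand-in for the supplementary raw screening table (which is
#' available only on request from the study authors): the marginal counts
#' and the named drugs are taken from the publication, every per-well
#' signal is invented.
#'
#' @return A raw screen-record tibble in [read_screen_table()] layout.
#'   Fully deterministic; no RNG is used.
#' @export
gen_screen_reference <- function() {
  n <- 1968L
  n_toxic <- 346L
  n_dual <- 18L
  n_gag_only <- 111L # 129 GAG hits total
  n_stab_only <- 34L # 52 stabilizers total

  final_candidates <- c("acitretin", "dimethyl fumarate", "entacapone",
                        "nifedipine", "rifaximin", "triclabendazole",
                        "vitamin A")
  second_stage_excluded <- c("Andrographolide", "Apigenin",
                             "Berberine sulfate", "Harmine hydrochloride")
  category_excluded <- tibble(
    drug_name = c("cisplatin", "carboplatin", "oxaliplatin", "doxorubicin",
                  "topical_agent_1", "topical_agent_2", "topical_agent_3"),
    category = c(rep("anticancer", 4L), rep("topical", 3L))
  )

  spread <- function(lo, hi, k) if (k == 1L) (lo + hi) / 2 else seq(lo, hi, length.out = k)

  dual <- tibble(
    drug_name = c(category_excluded$drug_name, second_stage_excluded,
                  final_candidates),
    category = c(category_excluded$category, rep("", 11L)),
    viab = spread(0.8, 1.2, n_dual),
    gag = spread(0.20, 0.45, n_dual),
    stab = spread(2.2, 3.6, n_dual)
  )
  gag_only <- tibble(
    drug_name = sprintf("gag_reducer_%03d", seq_len(n_gag_only)),
    category = "",
    viab = spread(0.7, 1.3, n_gag_only),
    gag = spread(0.15, 0.45, n_gag_only),
    stab = spread(0.8, 1.8, n_gag_only)
  )
  stab_only <- tibble(
    drug_name = sprintf("stabilizer_%03d", seq_len(n_stab_only)),
    category = "",
    viab = spread(0.7, 1.3, n_stab_only),
    gag = spread(0.6, 1.4, n_stab_only),
    stab = spread(2.2, 4.0, n_stab_only)
  )
  toxic <- tibble(
    drug_name = sprintf("toxic_%03d", seq_len(n_toxic)),
    category = "",
    viab = spread(0.05, 0.45, n_toxic),
    gag = spread(0.6, 1.4, n_toxic),
    stab = spread(0.6, 1.8, n_toxic)
  )
  n_null <- n - n_toxic - n_dual - n_gag_only - n_stab_only
  null <- tibble(
    drug_name = sprintf("inactive_%04d", seq_len(n_null)),
    category = "",
    viab = spread(0.55, 1.45, n_null),
    gag = spread(0.55, 1.45, n_null),
    stab = spread(0.55, 1.95, n_null)
  )

  drugs <- bind_rows(dual, gag_only, stab_only, toxic, null)
  base <- c(cellmask = 10000, sdc1 = 5000, nluc = 2000)
  plate_size <- 88L
  plate_of <- ceiling(seq_len(n) / plate_size)
  drugs <- drugs |>
    mutate(
      drug_id = sprintf("R%04d", row_number()),
      plate = sprintf("plate%02d", plate_of),
      well = sprintf("w%02d", (row_number() - 1L) %% plate_size + 1L),
      is_vehicle = FALSE,
      cellmask_raw = base["cellmask"] * .data$viab,
      sdc1_raw = base["sdc1"] * .data$gag * .data$viab,
      nluc_raw = base["nluc"] * .data$stab
    ) |>
    select(-"viab", -"gag", -"stab")

  vehicles <- purrr::map_dfr(seq_len(max(plate_of)), function(p) {
    tibble(
      drug_id = sprintf("VEH_p%02d_%d", p, 1:8),
      drug_name = "DMSO", category = "",
      plate = sprintf("plate%02d", p),
      well = sprintf("v%02d", 1:8), is_vehicle = TRUE,
      cellmask_raw = base["cellmask"], sdc1_raw = base["sdc1"],
      nluc_raw = base["nluc"]
    )
  })

  validate_screen_records(
    mutate(bind_rows(drugs, vehicles),
           category_tags = strsplit(.data$category, ";", fixed = TRUE))
  )
}

#' Generate a noisy protein-decay chase course
#'
#' Single-exponential decay with multiplicative log-normal noise:
#' `value = 100 * exp(-ln(2) * t / t_half) * lognormal(cv)` per replicate,
#' with the pre (t = 0) point fixed exactly at 100.
#'
#' @param true_half_life_h True half-life in hours (> 0).
#' @param timepoints Chase times in hours, including 0 (default
#'   `c(0, 6, 12, 24, 48)`).
#' @param cv Coefficient of variation of the multiplicative noise
#'   (default 0.05).
#' @param n_replicates Number of replicates (default 3).
#' @param seed Integer seed (required).
#' @return A decay-course tibble (`series_id`, `replicate`, `time_h`,
#'   `value`).
#' @export
gen_decay_course <- function(true_half_life_h, timepoints = c(0, 6, 12, 24, 48),
                             cv = 0.05, n_replicates = 3L, seed) {
  if (missing(seed)) abort("seed is required")
  stopifnot(true_half_life_h > 0, cv >= 0, n_replicates >= 1L,
            all(timepoints >= 0), 0 %in% timepoints)
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  purrr::map_dfr(seq_len(n_replicates), function(r) {
    mu <- 100 * exp(-log(2) * timepoints / true_half_life_h)
    noise <- rlnorm(length(timepoints), 0, sdlog)
    noise[timepoints == 0] <- 1 # pre point is the normalization anchor
    tibble(series_id = "synthetic_chase", replicate = as.integer(r),
           time_h = timepoints, value = mu * noise)
  })
}

#' Simulation specification for intercross litters
#'
#' @param n_dams Number of pooled litters (default 6).
#' @param litter_size_lambda Poisson mean litter size (zero-truncated;
#'   default 8, giving ~47 pooled conceptuses over 6 dams at the published
#'   scale).
#' @param hom_survival_prob Probability that a homozygous conceptus
#'   survives to genotyping (1 = full Mendelian survival, 0 = fully
#'   embryonic-lethal).
#' @param total_n If non-`NULL`, generate exactly this many pooled
#'   conceptuses instead of drawing litter sizes (used for calibration
#'   studies at a fixed sample size).
#' @return A `litter_sim_spec` list.
#' @export
litter_sim_spec <- function(n_dams = 6L, litter_size_lambda = 8,
                            hom_survival_prob = 1, total_n = NULL) {
  stopifnot(n_dams >= 1L, litter_size_lambda > 0,
            hom_survival_prob >= 0, hom_survival_prob <= 1)
  structure(list(n_dams = n_dams, litter_size_lambda = litter_size_lambda,
                 hom_survival_prob = hom_survival_prob, total_n = total_n),
            class = "litter_sim_spec")
}

#' Generate pooled genotype counts from an intercross
#'
#' Each conceptus draws a genotype from the Mendelian 1:2:1 ratio;
#' homozygotes survive to genotyping with `hom_survival_prob` (lost
#' homozygotes are resorbed and never counted). Counts are pooled across
#' dams.
#'
#' @param spec A [litter_sim_spec()].
#' @param seed Integer seed (required).
#' @param group_label Label recorded on the output row.
#' @return A one-row genotype-count tibble (`n_wt`, `n_het`, `n_hom`,
#'   `group_label`).
#' @export
gen_litters <- function(spec = litter_sim_spec(), seed, group_label = "pooled") {
  stopifnot(inherits(spec, "litter_sim_spec"))
  if (missing(seed)) abort("seed is required")
  set.seed(seed)
  n_total <- if (!is.null(spec$total_n)) {
    as.integer(spec$total_n)
  } else {
    sizes <- rpois(spec$n_dams, spec$litter_size_lambda)
    sizes[sizes == 0L] <- 1L
    sum(sizes)
  }
  g <- rmultinom(1L, n_total, prob = c(1, 2, 1) / 4)[, 1L]
  hom_seen <- rbinom(1L, g[3L], spec$hom_survival_prob)
  tibble(n_wt = g[1L], n_het = g[2L], n_hom = hom_seen,
         group_label = group_label)
}
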