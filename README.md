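# fluxscreen

Quantitative tools for two linked problems in rare-disease drug
repurposing, built for analysts working with flow-cytometry rescue
experiments and phenotypic plate screens:

1. **Expression-binned autophagic flux (DEFAC).** In a knock-out cell line
   transiently rescued with a GFP-tagged construct, expression varies over
   several decades from cell to cell. Binning cells by GFP level
   (Levels 0–4) and measuring the LC3 flux inside each bin asks whether the
   protein *per molecule* is functional, independent of how much of it a
   cell happens to make. The per-level statistic is

   ```
   flux (%) = (MFI_LC3^BafA1 − MFI_LC3^untreated) / MFI_LC3^BafA1 × 100
   ```

   where MFI is the geometric mean fluorescence intensity of the LC3
   immunostain in that GFP level, with and without the lysosomal inhibitor
   bafilomycin A1. 100% means the whole inhibitor-arrested LC3 pool is
   normally degraded; 0% means autophagic degradation is blocked.

2. **Dual-criterion screening triage.** A ~2,000-drug FDA-approved library
   is triaged per plate against vehicle (DMSO) wells: drugs dropping the
   whole-cell stain below 50% of vehicle are removed as cytotoxic; among
   the survivors, a hit must push the cell-number-adjusted GAG reporter
   (SDC1 in-cell western) strictly below 0.5 *and* keep the mutant-protein
   stability reporter (NanoLuc) strictly above 2-fold. Category and named
   exclusions follow, and every stage is accounted for in a conservation-
   checked funnel report.

Supporting statistics round out the pipeline: cycloheximide-chase
single-exponential decay fits with half-life `ln(2)/k`, Mendelian
segregation chi-square tests, qPCR standard-curve relative quantification,
and the usual two-/multi-group comparisons. Seeded generators produce
synthetic event tables, plate libraries, decay courses and litters with the
statistical structure each analysis assumes, so the entire pipeline runs
and is testable offline.

## Worked example

```r
library(fluxscreen)
library(dplyr)

# --- DEFAC on a synthetic rescue experiment ------------------------------
spec <- defac_sim_spec()              # 20,000 events, 3 replicates,
                                      # true flux (0, 40, 60, 60, 60)%
ev   <- gen_defac_events(spec, seed = 42)
res  <- defac_analysis(filter(ev, treatment == "untreated"),
                       filter(ev, treatment == "bafa1"),
                       sim_gate(spec))
res[, c("level", "n_untreated", "flux_pct", "flux_mean", "flux_sd")]
#>   level n_untreated    flux_pct   flux_mean   flux_sd
#> 1     0       21967  0.03521799  0.04331483 0.1748865
#> 2     1        4597 40.22005361 40.21611876 0.5258871
#> 3     2       14097 59.90681770 59.90291626 0.9066648
#> 4     3       11019 60.28254794 60.28190958 0.3030576
#> 5     4        2309 60.11899167 60.11324788 0.9261941
```

Each row is one GFP expression level; `flux_pct` is the flux computed from
the pooled MFIs and `flux_mean ± flux_sd` aggregates the per-replicate
fluxes. The generator's true per-level flux (0, 40, 60, 60, 60)% is
recovered to well within a percentage point at this event count.

```r
# --- screening funnel on the synthetic reconstruction of the screen ------
fun <- run_funnel(
  gen_screen_reference(),
  screen_config(named_exclusions = c("Andrographolide", "Apigenin",
                                     "Berberine sulfate",
                                     "Harmine hydrochloride"))
)
fun
#> Screening funnel
#>   library: 1968 drugs; GAG hits 129, stabilizers 52
#>   viability                 1968 ->  1622 (excluded 346)
#>   dual_criterion            1622 ->    18 (excluded 1604)
#>   category_exclusion          18 ->    11 (excluded 7)
#>   second_stage_exclusion      11 ->     7 (excluded 4)
```

346 of 1,968 drugs fail the 50% viability filter; 18 of the 1,622
survivors satisfy both reporter criteria; 7 carry excluded category tags
(anticancer/topical) and 4 more are removed by name, leaving 7 candidates.

```r
# --- kinetics and genetics ----------------------------------------------
fit_decay(gen_decay_course(24, cv = 0.05, n_replicates = 3, seed = 1))
#> Exponential decay fit (loglinear)
#>   rate k      : 0.02858 /h
#>   half-life   : 24.25 h
#>   intercept   : 100.4 %

mendelian_chisq(c(15, 28, 4))
#> Segregation chi-square (goodness of fit)
#>   observed : 15 / 28 / 4
#>   expected : 11.75 / 23.50 / 11.75
#>   chi2 = 6.8723, df = 2, p = 0.032188 *
```

The chase fit recovers the 24 h half-life it was generated with; the
genotype counts deviate significantly from the 1:2:1 intercross
expectation (a deficit of homozygotes).

`autoplot()` methods exist for flux tables, funnels and decay fits, plus
`plot_defac_dotplot()` and `plot_screen_scatter()` for the two classic
diagnostic views.

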