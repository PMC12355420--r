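---
title: "Methods: expression-binned flux cytometry and screen triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression-binned flux cytometry and screen triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models behind `fluxscreen`, the
assumptions they rest on, the tunable parameters and why their defaults
are what they are, what the synthetic generators do and do not emulate,
and the design decisions taken where more than one reasonable choice
existed.

## The per-level flux model

A knock-out cell line is transiently rescued with a GFP-tagged construct;
expression spans several decades across cells. Cells are binned into five
GFP levels and, within each bin, autophagy activity is read out as the LC3
flux

$$\mathrm{flux} \;=\; \frac{\mathrm{MFI}^{\mathrm{BafA1}}_{\mathrm{LC3}}
 - \mathrm{MFI}^{\mathrm{untr}}_{\mathrm{LC3}}}
 {\mathrm{MFI}^{\mathrm{BafA1}}_{\mathrm{LC3}}} \times 100\,(\%)$$

where the MFIs are geometric means of the LC3 immunostain intensity in the
inhibitor-treated and untreated arms. The statistic is a ratio, so it is
invariant under any common positive rescaling of the LC3 channel
(instrument gain, staining batch) applied to both arms — a property the
test suite asserts. It is bounded above by 100% (complete degradation of
the arrested pool) and unbounded below; negative values indicate the
untreated signal exceeding the arrested one, which is sampling noise or a
reporter artifact, and are *reported, not clipped*, because clipping would
hide exactly the artifacts the quench control exists to catch.

Assumptions:

- fluorescence intensities are approximately log-normal within a bin,
  which is why the geometric mean is the population summary (the
  arithmetic mean is available via `mean_type = "arithmetic"` for
  sensitivity analysis only);
- the inhibitor fully arrests lysosomal LC3 turnover during the treatment
  window, so the treated arm measures production plus the standing pool;
- the inhibitor does not alter the GFP reporter itself. This is checked,
  not assumed: `quench_control()` compares gross GFP geometric MFIs across
  arms and passes iff the ratio is within `tolerance` (default 0.1) of 1;
- binning by GFP is binning by construct abundance; within a bin the two
  arms are exchangeable populations of equivalent expressors. Single cells
  are not matched across arms — this is a population method, and per-cell
  flux is deliberately out of scope.

### Gating parameters

- `viability_threshold` (a.u.): events at or above this viability-dye
  intensity are dead and excluded first. The value is
  instrument-dependent, so it is required configuration with *no default*;
  a wrong magic constant here silently corrupts every downstream MFI.
- `gfp_boundaries` (4 intensities, a.u.): the level cuts. Published gates
  of this kind are typically drawn on the instrument, so boundaries are
  config-first. `auto_gate()` provides a data-driven default: Level 0 ends
  at the 99.5th percentile of a mock/untransfected reference sample (the
  autofluorescence ceiling), and Levels 1–4 split the remaining range up
  to the analyte maximum into equal log-width bins, matching the
  log-scaled axis such gates are drawn on.
- Boundary ties: bins are left-closed, right-open — an event exactly on
  boundary *k* belongs to level *k*. Some convention is needed for exact
  float equality; going up keeps the highest bin closed at the top.
- `min_events_per_level` (default 100): below this count a level's MFI is
  statistically meaningless, so the level is flagged and its flux withheld
  rather than silently reported. 100 events bounds the geometric-mean
  log-SE at roughly sdlog/10.

Level 0 (GFP-negative) flux is computed and reported like any other level
rather than suppressed as "untransfected background": the user decides its
interpretation, and its untreated LC3 MFI doubles as the reported
`baseline_lc3` (the classic dashed line in two-channel dot plots).

The flux denominator uses the plain arrested MFI, exactly as the formula
above reads. An optional `baseline_subtract` mode subtracts the
GFP-negative baseline from both arms before forming the ratio, for users
who prefer background-corrected MFIs; it is off by default because the
uncorrected form is the formula as conventionally stated.

Per-level two-group comparisons (`compare_levels()`) use Student's t on
the per-replicate flux values, two-sided, and report *unadjusted*
p-values: each level is conventionally reported as its own comparison in
this assay family. A Holm option across the five levels exists for users
who want family-wise control.

## The screening triage model

Each plate is normalized to its own vehicle (DMSO) wells — percent-of-
control, no spatial or plate-effect correction (B-scores etc.), matching
standard practice for this assay design where every plate carries its own
vehicle set. Per-plate (rather than global) vehicle means are the default
because they absorb plate-to-plate gain drift; this is the main reason
normalization happens before any pooling.

The triage order is: toxicity filter → cell-number adjustment → quadrant
selection → category exclusions → named (second-stage) exclusions. The
order is load-bearing — a cytotoxic drug can trivially "reduce GAG" by
killing cells — and a dedicated test shows that reversing the first two
stages changes hit membership on a crafted fixture.

Decision rules, all strict inequalities (exact-boundary values fall on the
retained / non-hit side, mirroring how the operating points are stated:
"less than 50%", "<0.5", "above 2-fold"):

| parameter | default | meaning |
|---|---|---|
| `viability_min` | 0.5 | cytotoxicity exclusion: `viability_ratio < 0.5` |
| `gag_max` | 0.5 | hit needs GAG reporter `< 0.5` |
| `vps33a_min` | 2.0 | hit needs stability reporter `> 2.0` |

The quadrant's GAG axis is the cell-number-adjusted ratio
(`sdc1_ratio / viability_ratio`) by default — a drug that halves both the
GAG signal and the cell count has done nothing to GAG *per cell* — with a
config switch (`gag_cell_normalize = FALSE`) for the raw vehicle ratio.
Drugs lacking the stability reporter are flagged unevaluable and can never
be hits. Category and named exclusion lists are pure configuration: the
package hard-codes no drug identities (the deterministic reference
generator, a test fixture, is the only place names appear).

Every stage emits counts and identifier lists into a `funnel_report`,
which enforces conservation (`retained + excluded = in`) and chaining at
construction *and* again after deserialization, so a corrupted report file
cannot silently enter an analysis.

## Kinetics and genetics statistics

**Decay fitting.** `fit_decay()` fits a single exponential. The default
`"loglinear"` method is ordinary least squares of `log(value)` on time —
closed-form, no starting values, robust for the 3–5-timepoint courses
this assay produces; `"nonlinear"` (one-parameter NLS with the intercept
pinned at 100%) is available when the pre-point normalization is to be
trusted exactly. On noiseless exponentials both methods agree to solver
tolerance (tested). Half-life is `ln(2)/k`. A fitted slope within
`sqrt(.Machine$double.eps)` of zero is flagged as non-decaying with an
infinite half-life rather than reporting an astronomically large number.
Multiplicative (log-normal) noise is the assumed error model — band
densitometry and luminescence are scale-positive — which is also why the
log-linear fit is the default: it is maximum likelihood under exactly that
model.

**Segregation chi-square.** `mendelian_chisq()` is Pearson's goodness of
fit against an expected ratio (default 1:2:1), two degrees of freedom, no
continuity correction: the classical expected-count rule of thumb (≥5)
holds for every class at the sample sizes of interest (at n = 47 the
smallest expected count is 11.75 — the *observed* 4 is irrelevant to
validity). At df = 2 the p-value has the closed form `exp(-chi2/2)`, which
the tests use as an independent oracle. An exact multinomial test
(enumeration of the 3-class simplex, practical to n = 500) is provided for
sensitivity; it is expectedly more conservative-or-liberal depending on
the tail geometry and is cross-checked against a Monte-Carlo oracle in the
suite. The test's finite-sample calibration at n = 47 is verified by full
enumeration (exact size 0.0517 at nominal 0.05 — discreteness, not error)
and by 10,000 simulated litter pools.

**qPCR standard curves.** Ct is regressed on log10(relative quantity) of
a serial dilution; unknowns are inverted through the line and the implied
amplification efficiency `10^(-1/slope) − 1` is reported. Inversion is
exact on any log-linear series regardless of efficiency (tested), which is
the reason to prefer standard curves over ΔΔCt when efficiencies are not
guaranteed to be 100%.

**Group comparisons** are thin pass-throughs to the standard routines
(`t.test`, `aov`/`TukeyHSD`, `kruskal.test`/`pairwise.wilcox.test`,
`p.adjust`); the package adds only the degenerate-variance convention
(identical constant groups get p = 1, logged) and one-sided tests are used
only where an analysis explicitly declares that direction.

## What the generators emulate — and what they do not

`gen_defac_events()` draws a two-component log-normal GFP mixture
(autofluorescent vs transfected cells), a log-normal arrested LC3 pool,
and applies the per-level true flux to the *untreated* arm
(`baseline × (1 − flux/100)`). Degradation-removes-signal is algebraically
equivalent, for the flux ratio, to accumulation-adds-signal in the treated
arm, and calibrates more simply. Measurement noise is multiplicative
log-normal with geometric mean 1 on every channel, so per-level geometric
MFIs recover the true flux without bias. Dead cells draw an elevated
viability signal. Defaults (20,000 events, 3 replicates, 10% dead, 60%
transfected, flux (0, 40, 60, 60, 60)%) reflect a realistic transient
rescue: no expression effect at Level 0, partial rescue at the lowest
expressed level, saturation from Level 2 up.

Not emulated: spectral spillover/compensation, doublets, acquisition-time
drift, cell-cycle-correlated autofluorescence, or any coupling between
expression level and viability. Passing recovery tests therefore shows the
*estimator* is correct under the stated noise model — not that a real
instrument's artifacts are handled; the quench control and the
config-first gate are the hooks for those.

`gen_screen_table()` draws per-drug latent classes (toxic / GAG-reducing /
stabilizing / dual-action / inactive) with class probabilities calibrated
to the published stage proportions (346/1968; 129, 52, 18 of 1622), and
the dual-class probability exceeding the product of the marginals is what
correlates the two effects. Effect-size ranges are kept several noise-SDs
away from the decision thresholds so realized counts are binomial in the
class probabilities — deliberately: the calibration check then has a known
sampling distribution. Real libraries have continuous, threshold-straddling
effect distributions; only the four stage proportions are calibrated, not
per-drug realism. `gen_screen_reference()` is the deterministic cousin:
a synthetic reconstruction that carries the published marginal counts and
named drugs exactly, used to exercise the funnel end to end (the original
per-well raw table is distributed only on request by its authors).

`gen_decay_course()` and `gen_litters()` are direct implementations of
their models (exponential decay with log-normal noise and an exact
pre-point; multinomial 1:2:1 conceptuses with thinned homozygote
survival). Litter effects (dam-level correlation) are not modeled; counts
are pooled exactly as the downstream test pools them.

All generators take a mandatory integer seed and seed the global RNG once
per call; identical (spec, seed) pairs are bit-identical.

## Numerical conventions and problem sizes

- Intensity transform default is floor-at-epsilon (epsilon = smallest
  positive recorded value / 10), the minimal intervention that makes
  geometric means well-defined on instrument exports containing zeros or
  baseline-subtracted negatives; arcsinh (cofactor 150) is available where
  analysts prefer it, and plain MFIs are reported either way.
- Empty-input MFIs are `NA` with a flag, not errors; non-positive inputs
  to a geometric mean are an error naming the transform policy, because
  they indicate the policy was skipped.
- The test suite runs its simulations at 20,000 events × 3 replicates × 2
  arms for flux recovery, 1,968 drugs for screen calibration, 600-drug
  libraries for funnel properties, and 10,000 pools of 47 conceptuses for
  chi-square calibration — sizes chosen so binomial/Monte-Carlo tolerances
  (4 SD bands) are tight enough to catch real defects while the whole
  suite stays interactive (~20 s).

## Known limitations

- No spillover compensation, automated gating, or FCS writing; FCS
  reading covers list-mode float/integer data, the dominant export format,
  but not ASCII or correlated-mode files.
- The flux statistic is a population contrast; it cannot resolve
  cell-to-cell heterogeneity within a level.
- Screening assumes every plate carries usable vehicle wells; there is no
  rescue path for vehicle-free plates by design (failing loudly beats
  imputing a control).
- The exact multinomial option enumerates a 3-class simplex only, and the
  decay models are single-exponential: two-phase decays will show
  structured residuals (inspect `augment()` output) rather than a warning.
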