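---
title: "Length-based stock assessment with lfqassess: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Length-based stock assessment with lfqassess}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfqassess)
```

# The problem

For many exploited crustacean stocks — deep-water spiny lobsters are a
canonical case — no age data, no tagging series and no reliable
catch-effort history exist. What a survey can deliver is a table of
individually measured animals: date, depth, sex, carapace length (CL,
mm), wet weight (g). `lfqassess` implements the standard length-based
assessment chain on exactly that input: growth from modal progression in
monthly length frequencies, total mortality from a length-converted
catch curve, natural mortality from empirical life-history rules, gear
selectivity from the catch curve's ascending limb, and exploitation
reference points from Beverton–Holt per-recruit theory.

# Growth model

We use the von Bertalanffy growth function with the theoretical age at
length zero removed, so length is anchored at birth:

$$L(t) = L_\infty\,(1 - e^{-k t}), \qquad L(0)=0 .$$

* `linf_mm` ($L_\infty$): asymptotic carapace length, mm.
* `k_per_year` ($k$): growth coefficient, year$^{-1}$.
* `t_anchor`: fraction of the calendar year at which annual cohorts are
  born; it positions the cohort trajectory family in real time.

Derived: growth performance index $\phi' = \log_{10}k +
2\log_{10}L_\infty$ (mm units, base-10 logs) and lifespan
$t_{max} = 3/k$, the age of ~95% asymptotic size. No seasonal
oscillation is modelled: the assessment targets an 8-month survey
window in a deep, thermally stable habitat.

# ELEFAN: restructuring and scoring

Raw monthly counts are *restructured* so that a growth curve can be
rewarded for passing through modes ([restructure()]):

1. a centred moving average over `window` bins (default 5; at the grid
   edges the window shrinks to the available bins, so a uniform column
   scores exactly zero);
2. quotients $q_i = N_i/MA_i$ (zero where $MA_i=0$);
3. scores $r_i = q_i/\bar q - 1$;
4. positive scores divided by $(nz_i+1)$, where $nz_i$ counts
   zero-count immediate neighbours (out-of-grid neighbours count as
   zero), de-emphasizing isolated spikes;
5. negative scores rescaled by one per-column factor so each column
   sums to zero (skipped when a column has a single sign).

Scoring a candidate $(L_\infty, k, t_\mathrm{anchor})$
([elefan_score()]): one trajectory per birth year whose curve
intersects the observed lengths during the sampling window (ages capped
at $\min(3/k, 60)$ years — 60 being the oldest lifespan estimate
published for the species, which prevents degenerate hundreds-of-cohort
families at very small $k$). ASP sums, per column, the maximum score of
each maximal positive run; ESP sums the scores of bins crossed by the
family at each sample date, crediting each positive run at most once
per column and, symmetrically, charging each crossed *negative* run its
minimum score exactly once per column. The fit score is
$R_n = 10^{ESP/ASP}/10 \le 1$.

The symmetric run-level treatment of troughs is a deliberate design
choice. Charging every crossed negative *bin* — a common dialect —
penalizes slow-growth candidates simply for having more, more closely
spaced cohort trajectories, and in our calibration experiments it
biased the optimizer toward fast-growth aliases. With the symmetric
dialect, recovery on the package's own cohort-mixture fixtures
(8 monthly samples, n = 5000, 5% individual variability in $L_\infty$)
improves to median errors of about 1% in $L_\infty$ and 3% in $k$
across seeds.

# Optimization and uncertainty

`elefan_ga()` maximizes $R_n$ with a generational genetic algorithm:
tournament selection (size 3), uniform crossover, Gaussian mutation
(probability 0.1 per gene, SD = 0.1 of the search span), elitism (2).
Population 50, 30 generations by default; all settings sit in
`ga_control()`. Two robustness devices bracket the GA: a deterministic
coarse screen over a $(L_\infty, \log k, t_\mathrm{anchor})$ lattice
seeds half the initial population, and a Nelder–Mead polish refines the
final optimum. Default search bounds: $L_\infty \in [0.9, 1.3]\cdot
L_{max}$ (largest occupied bin edge), $k \in [0.01, 1]$,
$t_\mathrm{anchor} \in [0,1)$. Everything is deterministic given
`seed`.

`elefan_ga_boot()` resamples each monthly column as a multinomial with
its observed total (months are fixed design points, so per-month sample
sizes are preserved), refits each replicate, and reports means with
2.5/97.5 percentile intervals. Production analyses conventionally use
1000 resamples; the bundled demo and tests use 50 or fewer to stay
fast.

# Mortality

The pooled length frequency enters the linearized length-converted
catch curve: bin midpoints map to relative ages through the inverse
VBGF, residence times are
$\Delta t_i = \frac1k\ln\frac{L_\infty - L_{i,low}}{L_\infty - L_{i,up}}$,
and OLS of $\ln(N_i/\Delta t_i)$ on $t_i$ over the descending limb
gives $Z = -$slope with a normal-theory 0.95 CI. Automatic limb
selection starts one bin after the response maximum and stops at the
last occupied bin below $0.95\,L_\infty$; an explicit index range
overrides it. On noiseless exponential-decay input the estimator is
exact by construction.

Natural mortality uses thirteen empirical estimators
(`empirical_m_suite()`), each implemented exactly as published, and
their arithmetic mean. Unit conventions matter and are fixed per row:
Pauly's temperature formula takes $L_\infty$ in cm with base-10 logs;
Then's growth formula takes $L_\infty$ in mm. Two caveats are worth
stating plainly: the exponential-decay form
$3k/(e^{0.38\,t_{max}k}-1)$ algebraically reduces to $\approx 1.41k$
whenever $t_{max}=3/k$, and the Pauly form evaluates to values well
below some figures quoted in the applied literature for this species;
this package reports the formula-faithful numbers. With
$t_{max}=3/k$ ten of the thirteen rows are proportional to $k$, so the
mean M inherits any error in $k$ almost linearly — see the
identifiability section.

Then $F = Z - \bar M$ and $E = F/(F+\bar M)$, with
$F = E\bar M/(1-E)$ as the exact inverse.

# Selectivity

Back-extrapolating the catch-curve regression over the ascending limb
predicts fully selected counts $\hat N_i$; capture probabilities are
$P_i = \min(N_i/\hat N_i, 1)$ (descending-limb bins are set to 1). Bins
with $P \in \{0, 1\}$ are excluded from the logit regression
$\ln(1/P_i - 1) = s_1 - s_2 L_i$, which yields $L_{50} = s_1/s_2$,
$L_{25/75} = (s_1 \mp \ln 3)/s_2$ and, through the inverse VBGF with
the same growth parameters as the catch curve, the age at first capture
$t_c$. The ogive is symmetric on the logit scale by construction.

# Per-recruit analysis

Knife-edge selection at $L_c$ gives the Beverton–Holt relative yield
per recruit, with $U = 1 - L_c/L_\infty$ and $m = (1-E)/(M/k)$:

$$Y'/R = E\,U^{M/k}\left[1 - \frac{3U}{1+m} + \frac{3U^2}{1+2m}
  - \frac{U^3}{1+3m}\right]$$

and the relative biomass ratio
$B(E)/B(0) = (1-E)\,\mathrm{bracket}(E)/\mathrm{bracket}(0)$ — the
bracket is the cubic factor above; this is $Y'/(RF)$ normalized to its
unfished limit, and it decreases strictly from 1. Reference points:
$E_{max}$ by grid search (step $10^{-3}$) refined with golden-section
optimization; $E_{10}$ as the smallest root of
$dY'/dE = 0.1\,(dY'/dE)|_0$ (forward difference at the origin, central
differences elsewhere, $h = 10^{-5}$); $E_{50}$ as the unique root of
the biomass ratio at one half (tolerance $10^{-6}$). Fishing
mortalities follow from $F = E M/(1-E)$.

Because a trap ogive is not knife-edged, a length-structured mode
integrates the full ogive: classes of width 0.5 mm carry residence
times $\Delta t_i$, mortality $Z_i = M + F s_i$, survivorship
$N_{i+1} = N_i e^{-Z_i \Delta t_i}$, catch
$(F s_i/Z_i)N_i(1-e^{-Z_i\Delta t_i})$ and weight $aL^b$; the terminal
class absorbs survivors with infinite residence. With a step ogive and
fine classes this recursion reproduces the closed form to better than
1%, which the test suite asserts.

A note on direction: under knife-edge selection all three reference
points *increase* with $L_c$ (delaying first capture always permits
more exploitation in this model). Published Lc-sensitivity tables
produced with ogive-based software can show the opposite ordering for
$E_{10}$; the two model modes are both exposed here so the comparison
can be made explicitly.

# The trap-survey simulator

`sim_config()` encodes the study conditions the package is tested
against: an 8-month (July–February) survey of 550 fifteen-trap sets
(34 invalidated) over 40–222 m, with relative density by 20-m stratum
peaking at 80–120 m; growth $L_\infty = 176.76$ mm, $k = 0.07$,
individual $L_\infty$ lognormal with CV 5%; a single annual
recruitment pulse (SD 0.15 yr); total mortality $Z = 0.19$ of which
$M = 0.13$; trap retention logistic with $L_{50} = 101.65$ mm and
$L_{75}-L_{50} = 10$ mm (wide enough to admit the occasional small
lobster, matching the observed 39.6–174.3 mm catch range and the
110–120 mm modal class); a recruitment floor of 30 mm CL (smaller
juveniles occupy settlement habitat outside the surveyed depths);
female-biased sexing with depth and length effects whose intercept is
calibrated so the *size-selected catch* shows ≈0.61 males per female;
sex-specific allometric weights ($a = 0.002, b = 2.839$ males;
$a = 0.003, b = 2.769$ females; lognormal σ = 0.08); lengths recorded
to 0.1 mm. Mean catch per reference 15-trap set is 2.19, i.e. ≈1128
individuals per survey, and per-set expected catch is proportional to
locally catchable abundance (gear retention × a Gaussian depth kernel,
SD 20 m). Juveniles are displaced ~40 m deeper, producing the
smaller-deeper pattern qualitatively.

What the simulator does *not* emulate: movement and seasonal
migrations, moulting dynamics, multiple recruitment pulses,
environmental variability in catchability, and measurement error beyond
rounding. Passing tests therefore demonstrate statistical correctness
of the estimators under a faithful but idealized sampling model, not
robustness to every field artifact.

`make_lfq_fixture()` is the fast path: it draws lengths directly from
the cohort mixture implied by a stated truth (no survey layer) and is
the substrate for the parameter-recovery tests.

# Identifiability limits at historical survey sizes

A finding worth emphasizing: with trap selectivity centred near 102 mm
and 5% individual variability in $L_\infty$, adult cohort modes above
~110 mm are separated by less than their blur and the juvenile modes
that would identify $k$ are mostly filtered out by the gear. At a
survey size of ~1100 individuals (monthly columns of ~140), the ELEFAN
response surface is nearly flat in $k$ — on simulated surveys, $R_n$
varies by less than 0.04 across $k \in [0.05, 0.33]$ — and the
estimate pins to noise peaks or search bounds. We probed both scoring
dialects, moving-average windows 5–9, ten-fold larger surveys and
informative bounds: the flatness is structural, not an optimizer
artifact. Consequences: estimates of $k$, and everything proportional
to it ($Z$ from the catch curve, the mean empirical $M$), carry far
more uncertainty at that scale than point values suggest, while
ratio-based quantities ($L_{50}$, $L_c/L_\infty$, $E$-scale reference
points) remain comparatively robust. The bootstrap intervals make this
visible; treat single-survey growth coefficients for slow-growing,
size-selectively sampled stocks with corresponding caution. On
unselective cohort mixtures of n = 5000 the same machinery recovers
$L_\infty$ within ~1% and $k$ within ~3% (median over seeds), so the
limitation is informational, not algorithmic.

# Numerical and interface choices

* Binning is half-open $[low, up)$; the origin defaults to the minimum
  length floored to an even millimetre; months are the sampling unit.
* Records with unknown sex enter all length-based analyses and are
  excluded from sex-specific ones.
* Welch's heteroscedastic F runs through `stats::oneway.test`; pairwise
  comparisons are Welch t-tests with Bonferroni correction and a greedy
  compact letter display.
* Length–weight regressions use natural logs; the intercept is
  back-transformed without bias correction, matching the magnitudes
  conventional for mm→g allometries (~0.002–0.003).
* CPUE confidence intervals are normal approximations
  (mean ± 1.96 SE) on per-set values within 20-m strata.
* Table serialization rounds lengths to 0.1 mm, rates to 2 decimals.
* The bundled demo pipeline (and the test suite) run the GA at its
  defaults with 50 bootstrap resamples on a ~1100-individual simulated
  survey, and the recovery tests use n = 5000 fixtures — sizes chosen
  so each check exercises the regime it is about.

# Known limitations

* No seasonally oscillating growth, no $t_0$, no direct ageing.
* No sex-specific mortality or per-recruit analyses (length-based
  mortality estimation at these sample sizes does not support them).
* The empirical-M mean treats the thirteen rules as exchangeable; users
  with priors on any rule should weight or subset `m_table` themselves.
* The catch-curve CI is conditional on the growth parameters; growth
  uncertainty is not propagated into $Z$ beyond what the bootstrap
  reveals.
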