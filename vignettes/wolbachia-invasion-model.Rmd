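---
title: "Modeling Wolbachia invasion in stage-structured mosquito populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling Wolbachia invasion in stage-structured mosquito populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(wolbinvade)
```

## The model

`wolbinvade` implements an eight-compartment, two-sex, stage-structured
ODE model of *Wolbachia* (wAlbB strain) spread in an *Anopheles* mosquito
population. The compartments are adult males $M_u, M_w$, adult females
$F_u, F_w$, eggs $E_u, E_w$, and combined larvae/pupae $L_u, L_w$, with
subscripts $u$/$w$ for the uninfected and infected cohorts. Two biological
mechanisms drive the dynamics:

* **Maternal transmission.** A fraction $v_w$ of an infected female's
  eggs inherit the infection, independent of the father; the remainder
  $v_u = 1 - v_w$ are uninfected. The wAlbB strain transmits essentially
  perfectly, so the default is $v_w = 1$.
* **Cytoplasmic incompatibility (CI).** An uninfected female mated to an
  infected male lays nonviable eggs with probability $c_i$ (default 1,
  complete CI). Males mix randomly, so the infected-male mating
  probability is $\mathcal{M}_w = M_w / (M_u + M_w)$, and the viable
  uninfected-egg birth rate is
  $\phi_u\,(\mathcal{M}_u + (1 - c_i)\,\mathcal{M}_w)\,F_u + v_u \phi_w F_w$.

Egg-to-larva inflow is throttled by the logistic factor
$K = 1 - (L_u + L_w)/K_l$, a carrying capacity on the aquatic habitat.
Adults emerge from larvae at rate $\psi$ (a fraction $b_f$ female), and
each stage has its own mortality. Defaults are lab-derived life-history
estimates for *Anopheles* carrying wAlbB: infected females live slightly
longer ($1/\mu_{fw} = 15$ d vs $1/\mu_{fu} = 13$ d) but lay the same ~50
lifetime eggs at a lower daily rate ($\phi_w = 3.3$ vs $\phi_u = 3.8$)
with poorer egg survival ($\delta/(\delta + \mu_{ew}) = 0.5$ vs $0.73$).
`wolb_params()` documents every parameter with units.

The only nonstandard conventions, chosen for degenerate states, are
$\mathcal{M}_w := 0$ when no males exist (all birth terms vanish there
anyway) and infection fractions reported as 0 for empty populations. $K$
is deliberately *not* clamped at zero: initial states are required to
satisfy $L_u + L_w \le K_l$, under which $K$ stays in $[0, 1]$ along any
trajectory, so the literal equations apply unmodified.

## Analytic layer

The cohort next-generation numbers are the expected adult females
produced per female through one life cycle,

$$G_{0u} = \frac{b_f \psi}{\psi + \mu_l}\frac{\delta}{\delta + \mu_{eu}}
\frac{\phi_u}{\mu_{fu}}, \qquad
G_{0w} = v_w\,\frac{b_f \psi}{\psi + \mu_l}\frac{\delta}{\delta + \mu_{ew}}
\frac{\phi_w}{\mu_{fw}},$$

and the basic reproductive number of the infection is their ratio,
$R_0 = G_{0w}/G_{0u}$, equivalently the spectral radius of the
next-generation matrix of the infected subsystem at the disease-free
equilibrium. Because infection carries a fitness cost, $R_0 < 1$ at
baseline (0.68): a small introduction dies out, and the system is
bistable between the disease-free equilibrium (DFE) and, under perfect
maternal transmission, the complete-infection equilibrium (CIE). The
unstable coexistence equilibrium between them is parameterized by the
larval ratio $r = L_w^*/L_u^*$, which solves a quadratic whose
perfect-transmission limit is $r = (1 - R_0)/R_0$; the female infected
fraction there,

$$p^* = \frac{c\,r}{1 + c\,r}, \qquad c = \mu_{fu}/\mu_{fw},$$

is the invasion threshold: about 0.347 at baseline (the published figure
quotes the integer percentage 34%).

```{r}
p <- wolb_params()
glance(equilibrium_report(p))
```

When two positive roots of the ratio quadratic exist (leaky
transmission), the branch continuous with the $v_w \to 1$ limit is the
smaller root; the other diverges in that limit and is reported with its
eigenvalues but without asserting a stability claim. Stability of every
equilibrium is classified from the Jacobian spectrum with a $10^{-9}$
tolerance band; eigenvalues inside the band yield an explicit
`"marginal"` verdict rather than a silent `"stable"`, because scans cross
bifurcation points where the leading eigenvalue is legitimately zero.

`basin_threshold_fraction()` cross-checks the closed-form threshold
purely dynamically. It bisects the mixing level of
$(1-p)\,\mathrm{DFE} + p\,\mathrm{CIE}$ initial states until the long-run
outcome flips. One subtlety: that mixing ray does not pass through the
unstable equilibrium, so the female fraction *at the crossing point*
(0.353 at baseline) differs from the threshold by about half a
percentage point. The separatrix is the stable manifold of the unstable
equilibrium, however, so the boundary trajectory itself stalls at that
equilibrium; the oracle therefore reports the female fraction at the
trajectory's point of minimal motion away from both stable states, which
reproduces the closed form to $10^{-8}$ without touching the equilibrium
algebra. For the same geometric reason, basin tests perturb the mixing
level $\pm 2\%$ around the threshold, not $\pm 1\%$.

## Sensitivity analysis

`sensitivity_index()` computes normalized elasticities
$S = (p/q)\,\partial q/\partial p$ by central differences with a relative
step of $10^{-3}$; $R_0$ additionally has exact closed forms
(`r0_sensitivities_analytic()`), which the numeric scheme matches to
$10^{-6}$ once the step is small enough that the $O(h^2)$ truncation bias
(exactly $10^{-6}$ at $h = 10^{-3}$ for the power-law parameters) is
negligible. Two boundary cases matter: $v_w = 1$ can only be perturbed
downward (a one-sided difference, which at $h = 10^{-3}$ reproduces the
published $-3.5$ for the threshold; the implicit-function limit is
$-3.47$), and the composite `"mu_adults"` parameter perturbs all four
adult death rates by the same relative amount — its $R_0$ and threshold
elasticities vanish because the $\mu_{fu}$ and $\mu_{fw}$ contributions
are equal and opposite.

```{r}
sensitivity_table(p, qois = c("R0", "threshold")) |>
  tidyr::pivot_wider(names_from = parameter, values_from = S)
```

The third quantity of interest, the time to 90% female infection, is
simulation-based and uses a reference scenario of practical interest:
60%/60% pre-release mitigation, total release size 2 in five batches over
60 days. A perturbed scenario in which establishment fails yields a
flagged `NA` index rather than silently dropping the parameter.

## Interventions

Releases add `release_factor` $\times F_u^0$ infected females **and** the
same number of infected males per unit factor ($F_u^0$ being the wild
females at the unmitigated DFE) — the per-sex convention, which
reproduces the published no-mitigation establishment threshold of 1.13
and was confirmed against a brute-force factor scan before being frozen.
Batches are equal and evenly spaced, batch $i$ at
$\mathrm{start} + (i-1)\,\mathrm{window}/n$, so five batches over the
60-day window leave 12-day gaps. Pre-release mitigation rescales the wild
DFE compartments: larviciding removes a fraction of $L_u$, thermal
fogging a fraction of $F_u$ and $M_u$; eggs are untouched.

Establishment is classified at a 3000-day horizon by final female
infected fraction above 0.5 — bistability separates trajectories cleanly,
so the cutoff value is immaterial at that horizon; an unresolved fraction
in $[0.4, 0.6]$ doubles the horizon once and then errors rather than
guessing. `time_to_fraction()` reports the first *upward* crossing of the
target: a very large release starts above 90% infected, dips as the wild
egg-and-larva pipeline rebounds, and recovers — the recovery crossing is
what a two-month establishment deadline can miss, which is why the
60-day-limited release factor (≈10) is larger than the naive
"start above 90%" factor of 9. For releases below that instant-exceedance
regime (factor < 3.6 after 60% adult mitigation) the metric is the plain
first crossing and the distinction is moot; the published batching
comparisons all live in that regime, and the batch-grid conclusions are
reported there (without mitigation, large releases are fastest in 4–5
batches, with an almost flat optimum beyond; after strong mitigation a
single immediate release wins).

```{r, eval = FALSE}
threshold_release_factor(p)                                   # 1.13
threshold_release_factor(p, mitigation_spec(larvae = 0.2))    # 1.03
batch_grid(p, sizes = 5, batch_counts = 1:5)                  # optimum at 4-5
```

## Seasonal forcing

Monthly rainfall drives a time-varying carrying capacity
$K_l(t) = K_l\,s(t)$. `fit_seasonal_curve()` least-squares fits a mean
plus two annual harmonics (the minimal form for a bimodal year, period
fixed at 365 d) to the twelve month-midpoint values, then rescales
affinely so that $s$ has unit annual mean and a prescribed max/min
amplitude ratio — by default the raw rainfall max/min. The affine form
guarantees $s > 0$ for any amplitude.

No site rainfall table ships with the package; `synthetic_rainfall()` is
a synthetic stand-in emulating the bimodal wet season of Grand Anse,
Haiti: main peak in May, secondary peak in September, dry minimum in
January, with a 1% log-normal per-seed jitter. Its base values were
calibrated once so that the fitted curve's extremes land within a week of
day 21 (driest) and day 134 (wettest) and so that the canonical
release-timing experiment discriminates: a factor-1 release in five
batches establishes when started at the dry-season trough and fails at
the wet-season peak, where the abundant wild population dilutes the same
absolute release below threshold. Those are emergent outcomes of the
calibrated forcing, not assertions about any specific year of real
rainfall — passing tests show the mechanism, not a site prediction.

Seasonal releases start from the seasonally periodic wild attractor,
reached by a two-year burn-in from the constant-capacity DFE (a fresh
equilibrium would conflate day-of-year effects with transients), and the
release factor is referenced to the wild female population on day 1 of
the release year.

```{r, eval = FALSE}
f <- fit_seasonal_curve(synthetic_rainfall())
seasonal_release_experiment(p, f,
  release_plan(1, n_batches = 5, window = 60, start_day = 21))$established
```

## Numerical choices

* Integration: `deSolve::lsoda` (stiff-capable), `rtol` $10^{-8}$ /
  `atol` $10^{-6}$ on the count scale, overridable everywhere. Output
  grids are 0.5 d for trajectories whose crossing times are interpolated
  (locating 90% crossings to ~0.1 d) and coarser for
  establishment-classification runs.
* Release impulses use deSolve's event mechanism (exact stop–add–restart,
  no stiff delta approximations); impulses scheduled at the start time
  are folded into the initial state so the first output row is already
  post-release.
* Bisections: release factors to resolution 0.005 (0.05 under a time
  limit, matching the coarser structure of that column); basin mixing to
  $10^{-9}$ with tightened integrator tolerances so the boundary
  trajectory tracks the separatrix long enough to stall at the unstable
  equilibrium.
* Problem sizes used by the test-suite simulations: 3000-day
  establishment horizons, 800-day batching grids, a four-year seasonal
  run for attractor convergence, and 20–100 random parameter draws for
  the residual/eigenvalue property suites.

## Limitations

The model is deterministic and spatially homogeneous: no demographic
noise at small release sizes, no spatial spread or wave-blocking, and no
coupling to human malaria transmission. Temperature and humidity do not
modulate life-history rates (defensible where annual temperature
variation is mild); seasonality acts through carrying capacity alone. The
coexistence quadratic assumes equal male death rates, as in the default
parameterization. All conclusions inherit the lab origin of the
life-history parameters.
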