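---
title: "Modelling transcutaneous alcohol diffusion and fitting blood-side input profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling transcutaneous alcohol diffusion and fitting blood-side input profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracsim)
```

## The problem

Wrist-worn alcohol sensors read the ethanol vapour that escapes through the
skin, yet the quantity of clinical interest is the concentration on the
blood side of the epidermis. Between the two sits a strongly asymmetric
transport path: three thin, permeable viable layers (stratum basale,
stratum spinosum, combined stratum granulosum and lucidum), the nearly
impermeable stratum corneum, and a 0.1 cm air headspace between skin and
sensor. `tracsim` implements the forward transport model for this stack,
three parametric families for the unknown blood-side boundary
concentration, a derivative-free hybrid optimizer that fits those families
to averaged sensor data, and a synthetic cohort generator that emulates the
structure of wrist %BAC recordings from a small drinking study (eight
volunteers, six 50 mL shots of 35% alcohol at 10-minute intervals).

## Transport model

Within each layer the ethanol concentration $C_i(x,t)$ (mol/m$^3$) obeys

$$\frac{\partial C_i}{\partial t}
  = \frac{\partial}{\partial x}\!\left(D_i \frac{\partial C_i}{\partial x}\right)
  - u\,\frac{\partial C_i}{\partial x},$$

with no source or sink term anywhere in the domain. The convective velocity
$u$ is zero in the skin and $25\times10^{-6}$ m/s (outward) in the air gap.
Boundary and interface conditions:

* blood side ($x = 0$): imposed concentration $C(0,t)$ — the *input
  profile*, the model's driving term, clamped at zero;
* outer wall: zero total (diffusive plus advective) flux — the headspace
  under the sensor is closed, so ethanol accumulates there;
* interior interfaces: concentration and flux continuity (no partition
  coefficients — the model assumes uniform dissolved-phase transport);
* initial condition: no ethanol anywhere.

The model is linear, so scaling the input profile scales the whole solution
— a property the test suite checks and the peak-delay analysis relies on.

### Layer parameters

The default stack uses the tabulated epidermis values (thicknesses 0.001,
0.002, 0.0026, 0.0015 cm, summing to 0.0071 cm — about one twentieth of the
0.15 cm average skin thickness measured by ultrasound on eight subjects —
and diffusivities $6.25\times10^{-6}$, $5.0\times10^{-6}$,
$3.75\times10^{-6}$, $5.0\times10^{-10}$ cm$^2$/s). The stratum corneum is
the rate-limiting element: its diffusion time $L^2/D \approx 75$ min sets
the scale of every delay the model produces, and it transmits only about
1.5% of the input amplitude to the headspace.

**The air-gap diffusivity is a deliberate design decision.** The source
parameter table assigns the headspace the same diffusivity as the stratum
corneum, $5\times10^{-10}$ cm$^2$/s — nine orders of magnitude below the
molecular diffusivity of ethanol vapour in air. Under the one-dimensional
reduction with a closed outer wall that value turns the gap into a one-way
accumulator (the cell Péclet number of the advection is $\sim 10^5$, so
whatever enters is swept to the wall and can never diffuse back): the
sensor signal then never peaks, the corneum gradient never reverses, and
thinning the skin cannot shift a peak that is pinned to the end of the
simulation. None of the phenomena the model is meant to reproduce — a
finite output peak, an absorptive/post-absorptive transition, the
thickness and peak-delay behaviours — survive. `default_layer_stack()`
therefore uses the gas-phase value 0.12 cm$^2$/s for the headspace, which
makes the thin gap diffusively well mixed (equilibration in well under a
second) while keeping every skin parameter at its tabulated value. The
tabulated gap value remains reachable through the
`air_gap_diffusivity_cm2_s` argument for anyone who wants to study that
variant deliberately.

### Discretization

Vertex-centred finite volumes on a grid whose nodes are uniform within each
layer, with every interface a shared node, so each face lies inside exactly
one layer and interface flux continuity is automatic. Diffusion uses
central differences with the face conductance $D/h$; advection is
first-order upwind (required for stability at the air gap's large cell
Péclet number when the condensed-phase gap variant is used; with the
gas-phase default the advective term is negligible, Pe $\sim 10^{-3}$).
Time integration is the theta method with $\theta = 1$ (backward Euler) by
default — unconditionally stable under the four-orders-of-magnitude
diffusivity contrast between the viable epidermis and the stratum corneum —
with $\theta = 0.5$ (Crank–Nicolson) available. Because the operator is
constant in time, the tridiagonal system is factorized once (Thomas
algorithm, compiled) and every step costs $O(N)$.

Default resolution is 15 nodes per skin layer, 30 in the gap, and a 1 s
step over a 230 min horizon. At this resolution halving both the spacing
and the step changes the sensor series by less than 1% in max-norm (tested)
and the pre-breakthrough front of a homogeneous slab matches the analytic
$\mathrm{erfc}$ solution within 1%.

The sensor is read at the outermost node of the gap by default
(`sensor_series(..., node = "wall")`); with a well-mixed headspace the
wall, the headspace mean and the skin-surface node differ only through the
corneum's surface resistance, and the alternatives remain available.

## Input profiles

Three families parameterize how blood alcohol builds up and decays at the
stratum basale boundary (time in minutes, concentration in mol/m$^3$):

* **piecewise linear**: $mt$ up to the peak $m\,T_{top}$ at $T_{top}$, then
  a straight decline to zero at $T_{max}$;
* **exponential linear**: $a_e + b_e e^{rt} + d_e t$ — a saturating
  exponential (typically $b_e < 0 < a_e$, $r < 0$) plus a linear drift,
  four parameters;
* **Hoerl**: $a_h\, b_h^{\,t}\, t^{d_h}$ — combined geometric and power
  growth/decay, three parameters.

Negative evaluations are clamped to zero *at evaluation time*, not in the
parameter space, so optimizers can roam freely over their boxes. The
exponential linear family is not pinned to zero at $t=0$ (the optimizer is
free to discover $a_e + b_e \approx 0$ on its own). The input-side peak is
called $BAC_{max}$ and the time to reach it the absorption time $T_{Ab}$;
the output-side peak is $C_{max}$, and the lag between them the peak delay
time $T_{PD}$.

## Fitting

The objective is the cumulative absolute difference
$\sum_k |{\rm model}(t_k) - {\rm data}(t_k)|$ evaluated at the data's own
time stamps. This convention matters: the number depends on the sampling
density of the data, so cumulative errors are comparable only between fits
to the same series. It is also why the reported errors of the original
study cannot be reproduced numerically without the raw subject data (shown
there only as figures); only their ordering across families is checked
here, on synthetic data.

The optimizer is a two-stage derivative-free hybrid:

1. **Monte Carlo**: up to 10,000 uniform draws (seeded, reproducible) in a
   finite parameter box locate the neighbourhood of the optimum.
2. **Trust-region BOBYQA**: bounded quadratic-approximation minimization
   confined to a region whose side is 10% of the box side, centred at the
   Monte Carlo argmin and clipped to the box, after rescaling all
   parameters to the unit cube so a single trust radius fits them all. The
   region is re-centred at the incumbent for up to 8 rounds (stopping once
   the relative improvement drops below $10^{-7}$), letting the refinement
   track a minimum that the sampling stage localized only to within the
   region size.
3. **Simplex continuation**: the L1 objective is piecewise linear in the
   model output, and near its minimum the surface is creased; quadratic
   interpolation models can stall on those creases far above the optimum.
   A Nelder–Mead polish (clamped to the box) is therefore run from the
   BOBYQA incumbent. It leaves a smooth quadratic minimum untouched but
   walks down creased valleys reliably; on noiseless self-generated data it
   routinely drives the objective from $\sim10^{-1}$ to $\sim10^{-12}$.

Because the stratum corneum attenuates the input by almost two orders of
magnitude, default parameter boxes are sized not from the raw data peak but
from the *input scale* — the data peak divided by a numerically measured
input-to-output gain (one reference solve; `input_scale()`). Boxes for the
piecewise linear family keep the $T_{top}$ and $T_{max}$ ranges disjoint so
every sampled point encodes a valid profile; invalid vectors elsewhere
receive a large finite penalty rather than an error. The exponential
linear box leaves the sign of the rate free ($r \in [-0.2, 0.15]$ per
minute): negative rates give the saturating build-up
$a_e(1 - e^{rt})$ plus drift, while positive rates with $b_e < 0$ encode a
build-up that collapses sharply once $|b_e|e^{rt}$ overtakes the other
terms — the shape that fits a plateau-then-decay series best. Restricting
the rate to one sign truncates the family and demonstrably worsens its
fits.

Parameter recovery on noiseless forward data (2,000 Monte Carlo samples,
the coarse fitting resolution below) recovers all three piecewise-linear
parameters and the exponential-linear peak time and value to well within
5%, across seeds — this is the package's main correctness check for the
whole fit path.

## Synthetic cohort

No subject-level recordings are published, so the generator emulates the
reported structure: a delayed onset (uniform 5–15 min), a smoothstep rise
(uniform 30–90 min), a plateau whose duration is drawn from a Beta
distribution rescaled to [20, 120] min with mean 60, a 3% downward plateau
drift, and a smoothstep decay with duration Beta-rescaled to [10, 30] min
with mean 20. Peak %BAC is uniform on [0.05, 0.15] g/dL, sampling is 1 min,
and additive Gaussian noise (default 0.002 g/dL) is clamped at zero. The
plateau/decay supports and means are the study's reported statistics;
onset, rise, peak level, sampling and noise are this package's assumptions,
all configurable in `cohort_spec()`. Per-subject sub-seeds derive from the
master seed and the subject index only, so subject $k$ is stable as the
cohort grows.

What the generator does *not* emulate: physiological pharmacokinetics
(no Widmark or Michaelis–Menten elimination), inter-subject correlation,
sensor drift or calibration error, and any covariate structure (weight,
sex, metabolism). Passing tests on this cohort therefore demonstrate that
the pipeline behaves correctly on data with the reported shape, not that
the model is validated on real skin.

Averaging aligns each subject at the first time its signal exceeds 5% of
its own peak (the alignment rule is unstated in the source; this marker is
the package's choice), converts g/dL to mol/m$^3$ via the ethanol molar
mass 46.068 g/mol, interpolates onto the union grid, averages over the
subjects contributing at each time, and truncates at 130 min.

## Model-application studies

**Thickness sensitivity.** All four skin-layer thicknesses are scaled by
±20% with the input profile held fixed; the air gap is apparatus, not skin,
and is never scaled. Thinner skin produces an earlier, higher output peak
(less diffusive resistance), thicker skin a later, lower one.

**Stratum corneum transients.** Early in a run the corneum profile
decreases outward — the blood side feeds it. Once the closed headspace has
accumulated past the skin-side supply the gradient reverses and the profile
increases outward. The reversal time essentially coincides with the output
peak; both mark the absorptive to post-absorptive transition.

**Peak delay.** For absorption times 0.05 h and 0.6 h and a sweep of
$BAC_{max}$ values, the study builds piecewise linear inputs with
$T_{top} = T_{Ab}$, $m = BAC_{max}/T_{Ab}$ and a 100 min decline (the
decline duration is unstated in the source and configurable), solves, and
records $T_{PD}$. One consequence of the model's linearity is worth
stating plainly: at fixed $T_{Ab}$, scaling $BAC_{max}$ rescales the whole
solution, so $T_{PD}$ is *exactly constant* in $BAC_{max}$ — "non-
decreasing", as the regression test phrases it, but never strictly
increasing. A genuine increase of delay with consumption, as observed in
the original study, requires some nonlinearity (concentration-dependent
diffusivity, saturable partitioning) that this model intentionally omits.
The logarithmic trend $T_{PD} = a\ln(BAC_{max}) + b$ is still fitted and
reported, with $R^2$ set to `NA` when the response is numerically flat.
The second effect is real and reproduced: at equal $BAC_{max}$, spreading
absorption over 0.6 h instead of 0.05 h shortens the delay.

## Numerical choices and degenerate inputs

* Theta in $[0.5, 1]$; backward Euler default. Divergence (non-finite
  values) aborts with the offending step size named.
* Profile evaluation overflow (e.g. $e^{rt}$ with large positive $r$)
  signals invalid parameters; the Hoerl form with $d_h < 0$ is singular at
  $t = 0$ and says so.
* `profile_peak()` is analytic for the piecewise family and a 10,001-point
  scan plus local refinement otherwise; an identically zero profile peaks
  at $(0, 0)$.
* Output-peak ties are broken toward the earliest time.
* A peak found at the simulation horizon is flagged (`at_horizon`) rather
  than silently reported.

## Problem sizes

The documented studies use the default resolution (15/30 nodes, 1 s step).
The fitting experiments and the test suite use a coarser, matched
resolution — 6 nodes per viable layer, 10 in the corneum, 12 in the gap,
5 s steps — at which one solve costs about a millisecond and a full hybrid
fit (2,000 Monte Carlo samples plus refinement) runs in about a minute;
recovery experiments generate their data at the same resolution they fit,
so the comparison isolates the optimizer rather than discretization error.
Grid-convergence and analytic-oracle checks run at finer resolutions as
stated in the tests.

## Known limitations

* One spatial dimension: lateral ventilation of the headspace, which in
  reality removes ethanol sideways and lets the sensed signal decay, is not
  represented; after its peak the modelled wall concentration declines only
  through slow back-diffusion into the skin.
* The linear model cannot reproduce a $BAC_{max}$-dependent peak delay.
* No temperature/humidity dependence of diffusivities; no partition
  coefficients at interfaces.
* The cumulative-error scale depends on data sampling density, so absolute
  objective values are not comparable across datasets.
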