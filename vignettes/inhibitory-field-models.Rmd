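---
title: "Inhibitory-field models of phyllotaxis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inhibitory-field models of phyllotaxis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyllofield)
```

## The models

Phyllotaxis — the regular placement of leaves around a stem — is modelled
here in the inhibitory-field tradition of Douady and Couder: every existing
leaf primordium emits an inhibitory power against the initiation of new
primordia, the inhibition decays with distance, and a new primordium forms
where (and, in the continuous model, when) the summed field on the
periphery of the shoot apical meristem (SAM) is weakest. All lengths are
measured in units of the radius $R_0$ of the primordium-formation circle
$M$, and times are standardized by $V_0/R_0$, where $V_0$ is the initial
radial velocity of a primordium; a primordium born at standardized time
$t_m$ sits at radius $r_m = R_0\,e^{t - t_m}$ because the apex grows
exponentially.

**DC1** (discrete, planar apex). Primordia appear one per plastochron $T$.
At step $n$ the field at azimuth $\theta$ on $M$ is
$$I(\theta) = k \sum_{m=1}^{n-1} d_m(\theta)^{-\eta}, \qquad
d_m^2 = R_0^2 + r_m^2 - 2 R_0 r_m \cos(\theta - \theta_m),$$
with $r_m = R_0 e^{G(n-m)}$ and $G \equiv V_0 T / R_0 =
\ln(r_m/r_{m+1})$, the natural log of Richards' plastochron ratio. The new
primordium takes the global minimum of $I$. Only $\eta$ and $G$ matter;
$k$ rescales the field.

**DC2** (continuous time, conical apex). The apex is a cone of flatness
$N = \sin(\psi/2)$ ($N = 1$ is a disc). The field is a sum of threshold
kernels
$$I(\theta) = \sum_m E\!\left(\frac{d_m(\theta)}{d_0}\right), \qquad
E(x) = E_s\,\frac{\coth(\alpha x) - 1}{\coth(\alpha) - 1},$$
with $E(1) = E_s$ exactly, divergence as $x \to 0^+$, and a controllable
steepness $\alpha$. When $I < E_s$ somewhere on $M$ a primordium forms
*immediately* there, so plastochrons are emergent and whorls (simultaneous
insertions) are possible. The inhibition range enters as
$\Gamma = d_0/(R_0 N)$; $E_s = 1$ throughout.

**EDC1 / EDC2** (age-dependent expansions). Each primordium's contribution
is multiplied by a logistic function of its age,
$F(\Delta) = 1/(1 + e^{-a(\Delta - b)})$, with the age in plastochron
units ($a$, $b$) for the discrete model and in standardized time ($A$,
$B$) for the continuous one. $F$ rises with age for positive rate,
falls for negative rate, and is the constant $1/2$ at rate zero — which is
why the expanded engines with zero rate reproduce the plain engines
exactly (the field is uniformly halved, the argmin unchanged). This
age-dependence is what unlocks *orixate* phyllotaxis, the tetrastichous
alternate pattern with divergence cycle $(180^\circ, 90^\circ, -180^\circ,
-90^\circ)$ named after *Orixa japonica*.

## The conical distance: a deliberate design decision

The distance between two points $(r^{(1)}, \theta^{(1)})$ and
$(r^{(2)}, \theta^{(2)})$ on the cone is implemented as the true
three-dimensional Euclidean chord,
$$d^2 = (r^{(1)} - r^{(2)})^2 + 2 N^2 r^{(1)} r^{(2)}
\left\{1 - \cos(\theta^{(1)} - \theta^{(2)})\right\},$$
selected from four candidate readings that circulate for this model family
(`radial_term` in `dc2_params()` switches between them). Two observations
drove the choice:

* Scaling the whole metric by $N$ (the `"times_n"` reading) makes $N$
  redundant — it is algebraically $\sqrt{N}$ times the planar chord, so
  $N$ only rescales $\Gamma$ and the pattern maps for different $N$ would
  be horizontal shifts of one another, which they are not.
* Under the Euclidean chord the continuous engine reproduces the
  benchmark behaviours of this model family at $N = 1/3$: stable
  distichy ($180.0^\circ$) at $\Gamma = 2.6$, $\alpha = 8$; a
  tetrastichous four-cycle at $N = 1$, $\Gamma \approx 1.8$; and at the
  orixate parameter point ($A = 4.8$, $B = 0.72$, $\Gamma = 2.8$,
  $N = 1/3$, $\alpha = 1$) a four-cycle of $(\pm 176.2^\circ, \pm
  89.3^\circ)$ whose standardized plastochrons oscillate between $0.101$
  and $0.325$ — including the characteristic linkage of the *longer*
  plastochron to the $\pm 90^\circ$ pairs.

On the formation circle ($r^{(1)} = r^{(2)} = R_0$) the chord is
$2 N R_0 \sin(\Delta\theta/2)$, so $x = d/d_0 = 2\sin(\Delta\theta/2)/\Gamma$:
$\Gamma$ is directly the angular range of inhibition, independent of $N$,
while $N$ controls how quickly receding primordia lose influence radially.

One known discrepancy is documented rather than hidden: classical cone
simulations in the literature report the divergence angle drifting from
$180^\circ$ down to the golden angle $137.5^\circ$ as $\Gamma$ falls from
2.6 to 1.9 (at $\alpha = 8$, $N = 1/3$). This implementation crosses
$137.5^\circ$ near $\Gamma \approx 2.1$ and sits at a two-cycle with mean
$|{\rm divergence}| = 134.5^\circ$ at $\Gamma = 1.9$ — under a cold
single-primordium start *and* under an adiabatic $\Gamma$ ramp from 2.6
to 1.9. Given the plastochron-level agreement at the orixate point we
regard the $\Gamma$-interval endpoints quoted in the older literature as
specific to those implementations' distance conventions.

## Simulation engines

Both engines are deterministic.

* **Grid and step.** The field is evaluated on a fixed angular grid
  (default $0.1^\circ$; must divide $360^\circ$). The continuous engine
  advances time in fixed steps $\Delta t = 0.001$; birth times are exact
  multiples of $\Delta t$, so primordia inserted in the same step compare
  equal and form a node (whorl).
* **Same-step insertion.** After each step, while the field minimum is
  below $E_s$, a primordium is inserted at the first minimising grid
  angle and its own contribution — with the kernel's pole at zero
  distance — is added before re-checking. The pole blocks the newborn's
  angular neighbourhood, so simultaneous insertions land at distinct,
  well-separated angles; more insertions than grid points in one step
  raises a "runaway" error. A newborn contributes immediately with
  $F(0)$.
* **Tie-break and chirality.** On exact ties the grid is scanned in a
  fixed direction (`tie_break`); the direction is physically arbitrary
  (chirality of spirals), and flipping it yields the exact mirror trace —
  a property the test-suite asserts.
* **Numerical form of the kernel.** $E(x)$ is evaluated as
  $E_s\,\mathrm{expm1}(2\alpha)/\mathrm{expm1}(2\alpha x)$, which is
  algebraically identical, underflows cleanly to zero at large $\alpha x$
  instead of dividing by an underflowed $\coth$, and yields $+\infty$ at
  $x = 0$.
* **Far-primordium pruning.** Primordia whose maximum possible
  contribution is below $10^{-12} E_s$ (bounding the age factor by 1 and
  the distance from below by the radial gap) are skipped; the bound only
  tightens as they recede, so the active window shrinks monotonically.
  Pruning is switchable off, and the suite checks traces agree with it on
  and off; it is disabled automatically if a rising range ramp could
  re-expand $d_0$.
* **Range ramp.** $\Gamma(t) = \tfrac{\Gamma_i + \Gamma_f}{2} -
  \tfrac{\Gamma_i - \Gamma_f}{2}\tanh\!\big(\tfrac{t - t_i}{\tau}\big)$
  is available for both continuous models (`gamma_ramp()`), the standard
  device for easing a run into a stable pattern from a strongly inhibited
  start.
* **Initial conditions.** `"single"` (one primordium at $0^\circ$) or
  `"two_at_120"`; the discrete engine always seeds one primordium at
  $0^\circ$, the minimal choice given its one-per-step rule.

## Pattern classification

Runs are judged on their tail: the last nine primordia (eight divergence
angles) for alternate patterns, the last two nodes for whorled ones.

* Nodes with more than one member put the trace in the whorled branch:
  2/2 nodes with an inter-node rotation of $90^\circ \pm 10^\circ$ are
  decussate, 3/3 with $60^\circ \pm 10^\circ$ tricussate; stable equal
  counts otherwise are "other whorled", unstable counts "other". The
  rotation check keeps rotated-but-not-decussate pair patterns out of the
  decussate class.
* Alternate traces are searched for the smallest cycle $c \in \{1, \dots,
  4\}$ under which the angle sequence repeats within a tolerance of
  $2^\circ$, requiring at least two full repeats. Angles are compared *on
  the circle*, so a distichous wobble across the $\pm 180^\circ$ seam is
  still period 1. $c = 1$ is a regular alternate pattern, $c = 2$ a
  two-cycle, and $c = 4$ with sign pattern $(p, q, -p, -q)$ a
  tetrastichous four-cycle with angle ratio $|q|/|p|$.
* Cycles whose motif is one $\approx 180^\circ$ step followed by
  $\approx 0^\circ$ steps (within $10^\circ$) are *x-cycle* patterns; for
  $c \ge 5$ the search widens to the last 30 angles, because eight angles
  cannot contain two repeats of a long cycle. The $10^\circ$ motif
  threshold separates x-cycles from the small-angle spirals that mediate
  the transitions between consecutive cycle lengths.
* The $2^\circ$ tolerance is our choice (simulated stable patterns
  fluctuate well below $1^\circ$; the grid contributes $0.1^\circ$) and
  is exposed as a parameter.

The colour legend for sweep maps encodes alternate patterns in HSL: hue
linear from cyan ($0^\circ$ mean absolute divergence) to red
($180^\circ$); saturation equal to the small/large ratio of successive
divergence angles (1 = fully saturated); lightness $1 - \rho/2$ for
plastochron ratio $\rho$ (equal plastochrons give the pure colour, ratio
0 bleaches to white). x-cycle patterns are black; decussate, tricussate,
other-whorled and residual classes take fixed reserved colours. HSL
rather than HSV is our choice; the published endpoint conventions pin
only the hue axis.

## Orixate stability analyses

`make_normal_orixate()` builds the idealized arrangement (divergence cycle
exactly $180, 90, -180, -90$; plastochrons oscillating $0.1/0.325$ for the
continuous models, unit plastochrons for the discrete ones) in the two
geometrical situations that differ by the last divergence ($\pm 90^\circ$
or $180^\circ$ to the incipient site).

For the expanded discrete model, persistence of the pattern requires
$\mathrm{d}I/\mathrm{d}\theta = 0$ at the incipient position. With the
arrangement on orthogonal axes the $0/180^\circ$ primordia drop out of
the derivative and the condition balances the age-weighted contributions
of the $\pm 90^\circ$ ranks — implemented analytically (the test suite
cross-checks it against central differences of the field). For each rate
$a$, `solve_edc1_condition()` collects *all* roots in the timing $b$ (the
residual oscillates in $b$ with decaying amplitude as the logistic
midpoint sweeps the age classes); `find_intersections()` locates
parameter sets satisfying both situations by scanning sign changes of
both residual surfaces on an $(a, b)$ raster and refining each candidate
cell with a damped two-variable Newton iteration (numeric Jacobian,
accepted below $10^{-8}$; raster cells whose residual amplitude is below
$10^{-12}$ are discarded as underflow noise). Sums are truncated at 100
preceding primordia; the weights decay like $e^{-(\eta+1) G j}$, and
doubling the truncation moves residuals by less than $10^{-9}$.

`dc1_orixate_scan()` evaluates, for the plain discrete model, both
situations' residuals together with the analytic field curvature at the
incipient site over an $(\eta, G)$ grid: no grid point shows both
residuals near zero with positive curvature, the numerical counterpart of
the claim that constant inhibitory power admits no normal orixate fixed
point. (Indeed the situation-1 residual has a fixed sign: the $\pm
90^\circ$ weights cannot balance without an age factor.)

## What the simulations do and do not emulate

The engines generate the study conditions themselves — there is no
external data. They emulate: deterministic lateral inhibition on the rim
of an exponentially growing apex, emergent plastochrons and whorls, and
age-modulated inhibitory power. They do not emulate: stochasticity of
real primordium placement, three-dimensional meristem geometry or true
geodesics on it, tissue-level mechanics or auxin transport (for which
these models are an abstraction), or secondary post-initiation
displacement of organs. Agreement of a classification here with a
botanical pattern therefore supports the abstraction, not any particular
molecular mechanism.

## Problem sizes used by the tests

The published protocol ($0.1^\circ$, $\Delta t = 0.001$, 100 primordia)
is the package default and is used for all headline reproductions in the
acceptance tests and in `scripts/acceptance.R`. Supporting property
checks use deliberately smaller runs chosen for test economy: 20–50
primordia on $0.5^\circ$–$1^\circ$ grids for engine properties, a
20-point random-parameter comparison (each point one plain and one
expanded run of 40 primordia, skipping points whose plain classification
is tolerance-sensitive, i.e. bifurcation boundaries) for the step-limit
equivalence of the expanded and plain continuous models, 60-primordium
runs for the
resolution/time-step robustness checks, and coarse (about one tenth the
published density) sweep grids. Robustness of every headline
classification to halving both the grid and the time step is asserted
directly.

## Known limitations

* The $\Gamma = 1.9$ golden-angle endpoint discussed above.
* The orixate four-cycle at the standard parameter point is "almost
  orthogonal" ($\pm 176.2^\circ$, $\pm 89.3^\circ$), not exactly
  orthogonal; rounding its larger angle to the nearest $5^\circ$ yields
  $175^\circ$, not the idealized $180^\circ$.
* Sub-grid interpolation of the insertion angle is not attempted; the
  insertion takes the exact grid minimum.
* Sweeps at the published $101 \times 101$ density are supported but
  slow on a single desk-class core; the provided defaults are coarser
  and record their scale in the result's provenance.
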