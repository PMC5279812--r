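---
title: "Modelling DNA looping with bound proteins: methods and design notes"
author: "loopsis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling DNA looping with bound proteins: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopsis)
```

## The model

`loopsis` models double-stranded DNA as a discrete semi-flexible chain of
`N` links of length `l`.  Each joint carries a hard sphere of diameter `w`
(the effective cross-section of the double helix, 4.6 nm by default), and
each link a local orthonormal frame `(u, v, t)` with `t` along the link.
The elastic energy of a configuration is the sum of per-joint bending
terms

$$\beta E_{bend}(\theta_i) = a\,(1 - \cos\theta_i),$$

where $\theta_i$ is the zenith angle of link $i$ in the frame of link
$i-1$ and $a$ is a dimensionless bending constant; the azimuth is free
(azimuthal symmetry) and the twist degree of freedom carries no energy.
The bending constant is tied to the Kuhn length $b$ (106 nm for dsDNA,
twice the persistence length) through

$$\frac{b}{l} = \frac{a - 1 + a\coth a}{a + 1 - a\coth a},$$

inverted numerically by `bending_constant_from_kuhn()`.  Hard-wall
self-avoidance forbids any two joint spheres from overlapping, except
pairs so close along the contour that their spheres overlap by
construction (the exclusion window $\Delta i \ge w/l$).

Bound proteins are hard spheres of radius $R_o$ attached to a chain link:
the centre sits at distance $w/2 + R_o$ from the joint, in the direction
obtained by rotating the link's transverse vector $u$ about the link axis
by a phase $\gamma$ (`protrusion_center()`).  $\gamma = 0$ places the
protrusion on the same side as the looping volume ("in phase"),
$\gamma = 180°$ on the opposite side.  A protrusion may instead be static
(a fixed laboratory position), and a confining sphere centred at the
first joint models the crowded nuclear environment.

A chain of length $L$ counts as looped when its distal terminus falls in
the looping volume $\delta r$: a radial shell $d_{min} \le |r_N - r_0|
\le d_{min} + \varepsilon$ intersected with a spherical cap of solid
angle $|\delta\omega'|$ about an orientation axis ($u^0$, the lab $x$
axis by our frame convention; negative $\delta\omega'$ flips the cap).
Defaults are the dsDNA study conditions: $d_{min} = w$, $\varepsilon =
2w$, $\delta\omega' = 2\pi \times 0.1$.  The central observable is the
looping-probability ratio

$$F(L) = \frac{P_{looped}^{object}(L)}{P_{looped}^{baseline}(L)},$$

whose long-chain plateau $F_\infty$ quantifies length-independent
repression by a bound object ("eclipse" effect).

## Sampling scheme and weights

Ensembles are grown link by link (`generate_ensemble()`, a compiled
kernel).  Bend angles are drawn from the exact elastic Boltzmann density
via the closed-form inverse CDF
$\cos\theta = 1 + \ln(u + (1-u)e^{-2a})/a$ — no rejection step and no
tuning parameter — so the elastic factor contributes nothing to the
importance weight.  The hard walls are handled by single-trial survival:
a chain that overlaps anything is discarded (weight 0), a surviving chain
has Rosenbluth weight 1, and the partition sum $Z$ is the number of
survivors.  This is the simplest unbiased scheme in the
sequential-importance-sampling family; a multi-trial (Rosenbluth) or
pruned-enriched variant could be slotted behind the same interface, and
the rejection-sampler equivalence test (`rejection_reference()`, run by
`run_validate()` and the test suite) would verify it unchanged.

Looping is recorded on a per-length grid (every stage-2 link boundary): a
chain contributes at length $L$ if and only if it is still alive at $L$
(plus any trailing-flank links).  Under pure survival weighting the
chains alive at $L$ are exactly the self-avoiding ensemble of length $L$,
so prefix recording is unbiased; this is pinned by a test comparing
prefix statistics with an independently grown shorter ensemble.

**Two-stage resolution.**  Chains are grown in consecutive segments: the
region hosting bound objects at base-pair resolution ($l_1$ = 0.34 nm,
exclusion window $\Delta i = \lceil (4/3)\,w/l_1\rceil = 19$, a
configurable default), the remainder with links of one chain width
($l_2 = w$, $\Delta i = 1$).  At the segment boundary a per-joint window
would misfire (a stage-2 joint is only 4.94 nm along the contour from a
stage-1 joint, closer than $w + l_1$), so the kernel implements the
exclusion as a contour-distance rule: a pair is tested only when its
contour separation is at least $\max(\Delta i_{seg}\cdot l_{seg})$ of the
two joints.  Within a uniform segment this reduces to the ordinary
window.  Exactly tangent spheres (adjacent stage-2 joints) never count as
overlapping: the overlap inequality is strict with a $10^{-9}$ relative
slack against floating-point ties.

**Random numbers.**  Each chain derives an independent counter-based
stream from the root seed and its global chain index (a splitmix64
generator keyed through a murmur-style finaliser).  Ensembles are
therefore deterministic given (seed, configuration), and sub-ensembles
generated with disjoint index ranges merge bit-identically
(`merge_ensembles()`), which is also how parallel execution would be
organised.

**Virtual conditions.**  Because hard-wall conditions consume no
randomness, the ensemble with an extra condition (a protrusion or a
confining sphere) is exactly the subset of baseline chains that never
violate it.  The kernel exploits this: conditions flagged
`enforce = FALSE` are tracked (first violating growth step) rather than
enforced, and any subset of them defines a paired sub-ensemble of one
baseline run.  This is a strong variance-reduction device — noise common
to the object and baseline ensembles cancels exactly, and an object that
affects nothing gives $F \equiv 1$ with zero variance — and it lets one
run serve many object geometries (a radius sweep, both phases, several
repressor sizes).  A test pins the subset identity: an enforced run with
the same seed reproduces the virtual subset bit for bit.  The
paper-style estimator with independent seeds
(`run_floop(paired = FALSE)`, `f_ratio()`) remains the default for the
command-line workflow; the paired estimator (`paired_f_curve()`,
`window_f()`) is used where desk-scale statistics demand it.

**Errors.**  Per-length standard errors use the effective-sample-size
binomial form $\sqrt{p(1-p)/n_{eff}}$ with $n_{eff} = (\sum w)^2/\sum
w^2$ (= $Z$ under unit weights).  Pooled window statistics accumulate
per-chain window sums and their full cross moments, so delta-method
errors on pooled ratios account exactly for the correlation between
lengths of the same chain and between paired sub-ensembles; adjacent
grid points decorrelate only over about one Kuhn length of contour, so
this bookkeeping matters.  Plateau values reported from curves
(`estimate_f_infinity()`) follow the convention of averaging a trailing
window (480 points when available, otherwise the tail beyond $5b$) with
$\pm 1.96$ SE half-widths and a flatness diagnostic (trailing slope
within 2 SE of zero; failure warns rather than errors).

## Geometry variants

*Leading and outside segments* are grown backward from joint 0 before the
main chain, starting opposite to the first forward link; the bend at
joint 0 is Boltzmann-sampled like any other joint, so the extended chain
is a single consistent polymer.  A protrusion at negative link index
$-k$ sits on this backward segment at distance $K = k\,l_1$ outside the
looping segment; the backward segment extends to $Q \ge 10|K|$ (default
$10b$) so the outside geometry is not truncated.  *Trailing flanks* are
extra links beyond a recorded length: a chain counts at $L$ only while
alive `trailing_links` further on, which models a loop embedded in a
longer chain.  *Confinement* adds a per-step hard wall
$|r_i| + w/2 \le R_{sphere}$ about the first joint; the placement of the
sphere centre at $r_0$ is a package convention (the chain start is the
only distinguished point available before growth).

## The eclipse approximation

For chain lengths far beyond the Kuhn length, looping is entropic and
termini approach the looping volume isotropically.  A bound object then
reduces $P_{looped}$ by the fraction of the sky it blocks:

$$F_\infty \approx 1 -
\frac{\mathcal I_{object}}{4\pi\,\delta r - \mathcal I_{chain}} +
\frac{\mathcal I_{chain \cap object}}{4\pi\,\delta r - \mathcal I_{chain}},$$

with $\mathcal I_X = \int_{\delta r}\Omega_X(r)\,d^3r$ the solid angle
of $X$ integrated over the looping region.  The object's solid angle has
the closed form $\Omega = 2\pi(1 - \sqrt{1 - (R_{eff}/d)^2})$ with
$R_{eff} = R_o + w/2$ (the approaching terminus is itself a sphere of
radius $w/2$).  `f_inf_static()` evaluates the one-term ("rod model")
version by uniform Monte-Carlo over the region; `f_inf_eclipse()`
evaluates all three integrals by ray casting over (region point) ×
(direction), which is exact per sample for unions of spheres — chain
joints block with effective radius $w$.  The occluding chain
configuration entering $\Omega_{chain}$ is a diagnostic choice (default:
a frozen straight run of joints); the quadratic fit below absorbs any
constant into its offset.

The rod model treats terminating segments as straight rays.
`terminating_segments_correction()` quantifies polymer flexibility: pairs
of (uniform point in $\delta r$, uniform direction) seed short phantom
chains of length $T$ whose first link lies along the chosen direction;
the correction is the chain survival fraction divided by the survival
fraction of straight rods of the same length over the same pairs, and it
multiplies the rod estimate.  With one link the chain *is* the rod and
the correction is exactly 1 (link overlap is tested as a continuous
segment for this reason); removing the object also gives exactly 1.  The
default $T = |r'| + R_o$ spans the object as seen from the region; a
warning fires when $T > b/2$ and the rod-like reading of the terminal
segment becomes loose.

For an on-chain object at fixed $K$ the model predicts the plateau to be
quadratic in the contact radius,

$$F_\infty(R_o) \approx 1 - A_K\,(R_o + w/2)^2 + B_K,$$

fitted by weighted least squares in `fit_quadratic_eclipse()` with
$R^2$ reported against the weighted mean.

## Enhancer front end

`enhancer_layout()` describes an enhancer-promoter chain by its total
length in bp and a site table (position, protein, role, occupancy).
Radii for the documented proteins are built in (dStat 3.04 nm, Zld
3.75 nm, Knirps 2.38 nm, Knirps+CtBP 3.59 nm, 450 kDa full complex
5.83 nm); other masses use $R = c\,M^{1/3}$ anchored to those five pairs
(`mass_to_radius()`), the globular-protein scaling.  Although twist
carries no elastic energy, the native twist of $2\pi/10.5$ per bp is
retained geometrically: a site at position $n$ bp binds its protein at
phase $\gamma = n \cdot 2\pi/10.5 \bmod 2\pi$ about the chain axis
(`phase_from_position()`; fractional positions round to the nearest
link, the only addressable sites).  `layout_to_schedule()` emits the
two-stage growth schedule, rejecting layouts whose occupied protrusions
already overlap on the straight chain, and returns activator-anchored
looping criteria: a chain loops with respect to an activator when its
terminus falls within $[d_{min}, d_{min} + 3\,\mathrm{nm}]$ of the
activator sphere's centre, $d_{min} = w/2 + R_{activator}$, inside the
cap $\delta\omega'$ about the axis from the chain to the activator
centre (recomputed per configuration).  The total looping probability of
a state is the *sum* over activators; overlapping acceptance shells are
not deduplicated, and `eve_looping_probability()` reports the
double-counted weight fraction as a diagnostic (it is tiny for
well-separated activators).  Binding-site coordinates are user input:
the package ships only a clearly labelled synthetic example layout
(`inst/extdata/eve37_synthetic_layout.tsv`) with a 3900 bp chain, three
activators and two repressor sites.

## What the simulations in the tests emulate — and what they do not

The test suite and the acceptance script run the study conditions at
desk scale: ensembles of $10^5$–$10^7$ chains instead of $\sim 10^9$, and
chains up to a few Kuhn lengths instead of tens.  Problem sizes were set
by standard-error arithmetic — each qualitative claim is asserted with
its Monte-Carlo error, and sizes are the smallest that make the expected
effect a multiple of that error.  Two reduced-scale conventions follow
from the same arithmetic:

* the narrow default cone $\delta\omega' = 2\pi \times 0.1$ yields of
  order one looping event per $10^5$ chains at plateau lengths, so
  checks that only need an isotropic or hemispheric acceptance use
  $\delta\omega' = 4\pi$ or $2\pi$, which multiplies the event count by
  10–20 while leaving the tested physics (eclipse magnitude, confinement
  response, inside/outside symmetry) intact.  The in-phase versus
  out-of-phase contrast is genuinely a narrow-cone effect and is tested
  with the narrow cone at the cost of a larger ensemble.
* plateau windows start at $2b$–$5b$ rather than the far asymptote, with
  pooled-window errors that respect the correlation between grid points.
* the enhancer comparison's plateau is evaluated on a 2000 bp chain over
  its trailing 300 bp: the plateau is length independent (the model's
  central claim), and the shorter distal arm multiplies the looping event
  count by the entropic factor $(3900/2000)^{3/2} \approx 2.7$.  Each
  bound protrusion independently removes 40–60 percent of chains (its
  sphere collides with local chain fluctuations), so fully bound states
  keep only a few percent of the ensemble — the binding constraint that
  sets the enhancer run's size.

One observation deserves a note: with a hemispheric acceptance cap, the
*outside* ($-K$) protrusion suppresses short-loop formation more than
the inside one, because the wide cap admits approach directions from the
origin's far side, which is exactly the sky the outside object occults.
With the narrow study-condition cone, the elastic-regime asymmetry runs
the other way (an inside in-phase protrusion constrains the teardrop
loop shape directly).  The long-chain symmetry — inside and outside
placements giving the same plateau — is cap-independent, and that is the
claim the tests and acceptance script assert.

The synthetic-data side deliberately omits: sequence-dependent
stiffness, electrostatics and twist elasticity (excluded from the
model), polymerase and cofactor volumes at the promoter-side terminus,
and chromatinisation of the looping segment.  Passing tests therefore
show the sampler and the eclipse analysis are correct for the stated
polymer model — not that the model captures every feature of nuclear
DNA.

## Numerical choices

* Overlap inequalities are strict with a $10^{-9}$ relative slack
  (tangency allowed), making the measure-zero boundary deterministic.
* `bending_constant_from_kuhn()` brackets its root in
  $[10^{-12}, (b/l+1)/2 + 2]$ and solves to near machine precision; the
  freely jointed point $b = l$ returns $a = 0$ exactly.
* Frames are renormalised every step; orthonormality drifts by less than
  $10^{-10}$ over $10^5$ links (tested).
* The spatial hash uses cell edge $\max(w, l)$ and a fixed bucket table;
  its contract is exactness of the overlap test, never speed.
* Ray casting samples $10^4$–$10^5$ region points with 40–60 directions
  each by default; all counts are arguments.
* Ensemble checkpoints are single-file RDS containers of the named
  accumulator arrays; XYZ export is available for visual debugging.

## Known limitations

* Single-trial survival wastes work at high density (no enrichment);
  inside very small confining spheres or for very long chains an
  enriched grower would be the next step behind the same interface.
* The multi-activator total can in principle double-count a terminus
  satisfying two activator criteria at once; the reported diagnostic
  quantifies this rather than resolving it.
* The eclipse evaluator treats the occluding chain as a frozen
  configuration; it is an explanatory model, not a second simulator, and
  only the simulated $F_\infty$ carries error bars suitable for
  inference.
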