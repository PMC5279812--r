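# loopsis

Monte-Carlo modelling of DNA looping in the presence of bound proteins.

Enhancers regulate genes over distances of kilobases by looping to their
promoter; short-range repressors ("quenchers") bound tens to ~150 bp from an
activator can shut this down without touching either the promoter or the
activator.  `loopsis` implements a biophysical model of this effect: dsDNA is
a discrete semi-flexible self-avoiding chain of hard spheres (width *w* =
4.6 nm, Kuhn length *b* = 106 nm, bend energy *a*(1 − cos θ) per joint),
bound proteins are hard spherical protrusions of radius *R*ₒ attached at a
helically phased offset from a chain link, and a chain of length *L* counts
as looped when its far terminus lands in a looping volume δ**r** (a radial
shell [*d*min, *d*min + ε] within a cone of solid angle δω′).  Ensembles are
grown by off-lattice sequential importance sampling with Rosenbluth-style
survival weights; the central observable is the looping-probability ratio

> *F*(*L*) = *P*ₗₒₒₚ(object) / *P*ₗₒₒₚ(bare),

whose long-chain plateau *F*∞ measures length-independent repression.  The
package also implements the analytic "eclipse" explanation of that plateau —
the protrusion occults part of the solid angle through which the distal
terminus can reach δ**r** — including the static (rod) solid-angle model, a
terminating-segments flexibility correction, the quadratic plateau-vs-size
fit *F*∞ ≈ 1 − *A*·(*R*ₒ + *w*/2)² + *B*, and an enhancer front end that
turns binding-site tables (positions in bp, protein radii, occupancy) into
simulation schedules.

Intended users: quantitative biologists and biophysicists studying
enhancer–promoter communication, quenching repression, or polymer looping
with excluded volume.

## Worked example

Grow one self-avoiding ensemble with two *virtual* protrusions (*R*ₒ =
18.4 nm, 95 bp from the chain origin, in phase and out of phase with the
looping volume) and read off the plateau of *F* for each.  Virtual
conditions are evaluated as exact paired subsets of the baseline chains, so
the comparison is variance-reduced:

```r
library(loopsis)
p <- simulation_params()        # w = 4.6 nm, b = 106 nm, dsDNA defaults
segs <- data.frame(n_links    = c(110, 84),
                   link_length = c(p$l1, p$l2),     # 0.34 nm then 4.6 nm
                   delta_i     = c(p$delta_i_stage1, 1))
prots <- list(
  protrusion("on_chain", link = 95, radius = 18.4, phase = 0,  enforce = FALSE),
  protrusion("on_chain", link = 95, radius = 18.4, phase = pi, enforce = FALSE))
sch  <- growth_schedule(segs, prots, params = p)
crit <- list(loop_criteria(p$d_min, p$epsilon, 2 * pi * 0.1))
ng   <- length(sch$record_joints)
win  <- list(list(list(ensemble = 2, group = 1, lo = 38, hi = ng),   # L > 2b
                  list(ensemble = 3, group = 1, lo = 38, hi = ng),
                  list(ensemble = 1, group = 1, lo = 38, hi = ng)))
ens <- generate_ensemble(sch, p, n_chains = 1e6, seed = 11, criteria = crit,
                         ensembles = list(integer(0), 1L, 2L), windows = win)
f_in  <- window_f(ens, 1, num = 1, den = 3)
f_out <- window_f(ens, 1, num = 2, den = 3)
cat(sprintf("F_inf in phase:  %.3f +- %.3f\nF_inf out phase: %.3f +- %.3f\n",
            f_in$value, f_in$se, f_out$value, f_out$se))
```

```
F_inf in phase:  0.748 +- 0.092
F_inf out phase: 1.062 +- 0.110
```

An in-phase protrusion depresses the plateau well below 1 (it eclipses the
looping volume); the out-of-phase protrusion, on the opposite side of the
helix, barely matters.  The analytic eclipse chain for a static object at
*d* = 41.45 nm with *R*ₒ = 23 nm:

```r
crit <- loop_criteria(p$d_min, p$epsilon, domega = 4 * pi)
set.seed(1)
rod <- f_inf_static(c(41.45, 0, 0), 23, crit, p$w, n_points = 2e5)
ts  <- suppressWarnings(      # T > b/2: the rod-like reading is loose here
  terminating_segments_correction(64.45, crit, c(41.45, 0, 0), 23, p,
                                  n_pairs = 2e5))
cat(sprintf("rod model: %.4f   terminating segments: %.4f\n",
            rod$f_inf, ts$f_inf))
```

```
rod model: 0.8910   terminating segments: 0.8635
```

The rod (pure solid-angle) model says the object blocks ~11% of the sky
seen from the looping volume; letting the terminal segments flex lowers the
plateau further, toward the simulated value.

A command-line front end wraps the experiment drivers
(`run_floop`, `run_eclipse`, `run_eve`, `run_fit`, `run_validate`):

```sh
Rscript inst/cli/loopsim.R validate --out results/
Rscript inst/cli/loopsim.R floop --config my_floop.yaml --seed 7 --out results/
```

`run_validate()` executes the built-in oracle suite (phantom-chain closed
forms, naive-rejection-sampler equivalence, brute-force solid angles,
determinism/merge checks) and writes a machine-readable report.

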