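---
title: "The myocyte-fibroblast bilayer model: equations, conventions, numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The myocyte-fibroblast bilayer model: equations, conventions, numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Cardiac fibroblasts are inexcitable cells that, when electrically coupled to
myocytes through gap junctions, load the myocyte membrane: depending on
their resting potential they act as current sources or sinks, reshaping the
action potential (AP), slowing or speeding conduction, and altering
spiral-wave reentry. `mfwave` implements this physics at two levels.

**Single myocyte-fibroblast (MF) composite.**  The myocyte is the
ten Tusscher-Noble-Noble-Panfilov (2004) human ventricular epicardial
ionic model: twelve membrane currents, eleven voltage gates, two
calcium-dependent gates, and intracellular Na+, K+, Ca2+ and SR-Ca2+
balances.  Its constants are the published ones (`tnnp_params()`); every
one can be overridden.  A passive fibroblast is an RC element,

\[ C_f \dot V_f = -G_f (V_f - E_f) + I_{gap}, \qquad
   I_{gap} = g_j (V_m - V_f) \ \mathrm{[pA]}, \]

with capacitance \(C_f\) (pF), membrane conductance \(G_f\) (nS) and
resting potential \(E_f\) (mV).  \(N_f\) identical fibroblasts attach
through per-junction conductances \(g_j\); the aggregate coupling is
\(G_{gap} = N_f g_j\), and the myocyte receives
\(-\sum_k g_j (V_m - V_{f,k}) / C_m\) as a current density, with
\(C_m = 185\) pF the model's total cellular capacitance.  \(N_f\)
identical fibroblasts are exactly equivalent to a single *cluster*
fibroblast with capacitance \(N_f C_f\), membrane conductance
\(N_f G_f\), and coupling \(G_{gap}\) -- note that all three scale
together; replacing them by one fibroblast with unscaled \((C_f, G_f)\)
at \(G_{gap}\) changes the fibroblast-side relaxation and is *not*
equivalent.  The integrator keeps all junctions explicit so the reduction
is verified, not assumed (`tests/testthat/test-composite.R`).

Depending on \((C_f, G_f, E_f, G_{gap}, N_f)\) the composite is
*excitable*, *autorhythmic* (spontaneous repetitive firing) or
*oscillatory* (sustained sub-threshold oscillation about a depolarized
level).  Spontaneous upstrokes in the autorhythmic regime are carried by
the L-type calcium current -- the sodium channels are inactivated at the
elevated diastolic potential -- and rise at well under 1 mV/ms, which is
why `detect_regime()` uses a 0.5 mV/ms slope criterion while propagated
sodium-driven upstrokes are detected at 5 mV/ms (`beat_statistics()`).

**2D bilayer tissue.**  A myocyte monolayer (monodomain diffusion,
\(D = 0.00154\) cm\(^2\)/ms, lattice spacing \(dx = 0.225\) mm, no-flux
boundaries) carries a fibroblast layer.  Per node the layers exchange
\(G_{gap}(V_m - V_f)\); laterally the wiring is *zero-sided* (no
fibroblast-fibroblast links), *one-sided* (fibroblast layer internally
connected through \(G_{ff}\)) or *two-sided* (additional cross-layer
neighbour junctions).  The cross-coupling algebra was a genuinely open
design point: it is realized as pairwise junctions between a node and its
four cross-layer neighbours -- myocyte-side junctions carry \(G_{mf}\),
fibroblast-side junctions \(G_{fm}\) -- so each myocyte/fibroblast
neighbour pair exchanges the exactly antisymmetric current
\((G_{mf}+G_{fm})(V_f - V_m)\), and summing every exchange term over the
grid gives zero at each step.  This reading is isolated in one place in
the stepper (`src/tnnp.cpp`, fibroblast-layer loop) for easy revision.

## Numerics

* Forward Euler at \(\Delta t = 0.02\) ms for the membrane potentials and
  ionic concentrations; fixed row-major traversal, no randomness -- runs
  are reproducible bit for bit, and chunked runs resume bitwise.
* Gating variables use the exponential (Rush-Larsen) update,
  \(y \leftarrow y_\infty - (y_\infty - y)e^{-\Delta t/\tau_y}\).  This is
  a necessity, not a preference: the sodium activation gate has
  \(\tau_m \approx 9\times10^{-4}\) ms near rest, so a plain Euler gate
  update at \(\Delta t = 0.02\) ms is unconditionally unstable
  (\(\Delta t/\tau \approx 22\)).  Plain Euler gates remain available
  behind `rush_larsen = FALSE` for small-step experimentation.
* Calcium buffering uses the model's instantaneous-buffer algebra (the
  quadratic update of the published code).
* The tissue stepper evaluates all voltage-dependent rate and current
  factors by linear interpolation in tables built once per run (0.05 mV
  spacing in \(V\), and auxiliary tables for the reversal-potential
  logarithms and the calcium-dependent gate targets).  The interpolation
  error (\(\sim 10^{-8}\) relative) is far below the discretisation error
  of the scheme.  The single-cell integrator evaluates everything
  analytically.
* Stability is checked before stepping: \(\Delta t \le dx^2/4D\) for the
  diffusion term and the analogous bound for the fibroblast layer.
* The ICaL GHK-type driving term has a removable singularity at
  \(V = 0\); the series limit is substituted within \(10^{-9}\) mV of it.

## Protocols and measurement conventions

**Single-cell beat.**  One beat from rest: a −52 pA/pF, 3 ms stimulus at
t = 50 ms (stimulus amplitudes enter the membrane equation as
\(-(I_{ion}+I_{stim})\), so depolarizing single-cell stimuli are negative;
tissue-protocol strengths are quoted as positive depolarizing magnitudes).
The isolated myocyte's state after a 5 s unstimulated pre-run is cached
and used as the initial condition everywhere.

**Coupled-vs-uncoupled morphology changes** (`delta_vs_uncoupled()`)
follow three conventions, chosen once because the reference values this
package reproduces identify them unambiguously (no alternative reading
comes close on all columns simultaneously):

1. *First-beat measurement*: the fibroblasts are attached ~100 ms before
   the stimulus.  The slow Na-inactivation gates (\(\tau_h \sim\) tens of
   ms to seconds at diastolic potentials) have not yet adapted to the
   elevated diastolic potential, and the change in maximal upstroke
   velocity is specific to this condition: for \(E_f = -9\) mV,
   \(N_f = 1\) the fully adapted value would be −139 mV/ms instead of the
   reproduced −92.6 mV/ms.
2. *0.1 ms measurement grid* for morphology (the integration step stays
   0.02 ms).
3. *Common repolarization reference*: APD levels of both runs are
   measured from the uncoupled myocyte's resting potential, the baseline
   against which the change is defined.  A composite whose diastolic
   potential stays above a level reports that APD as undefined (`NA`),
   which reproduces the undefined entries for strongly loaded composites
   (e.g. seven fibroblasts at \(E_f = -49\) mV).

`measure_ap_morphology()` itself stays self-contained by default (its own
pre-stimulus \(V_{rest}\), native grid); the APD reference start is the
time of maximal dV/dt, switchable to threshold crossing.

**Plane-wave CV.**  A 150 pA/pF, 3 ms pulse on a 3-node-wide left-boundary
column; CV from the −40 mV upward-crossing times (linear sub-step
interpolation) of two midline probes at 25% and 75% of the domain length;
a time budget of \(2L/\mathrm{CV}_{control}\) defines conduction failure.
On the 600 x 7 reference strip the control value is 68.6 cm/s.

**Spiral initiation (S1-S2 parallel field).**  At full scale (600 x 600):
D is reduced to a quarter from t = 0, S1 (150 pA/pF) launches a plane
wave, S2 (450 pA/pF, 3 ms) fires at 560 ms over the lower half-height of
the domain up to 2 nodes behind the −40 mV wave-back isoline (located at
run time on the lower-half midline -- the published coordinates of the S2
rectangle are not available, so the placement is defined operationally
relative to the wave back), D is restored at 882 ms, and the spiral is
developed by ~1.5 s.

**Scaled spiral domain.**  Desk-scale spiral work runs on 200 x 200
nodes with \(D/9\) (`scaled_spiral_grid()`).  Because the monodomain
equation is self-similar in space (\(x \to x/s\), \(D \to D/s^2\)), this
grid evolves exactly like the full 135 mm domain sampled at 3x coarser
effective spacing; rotation periods and single-composite dynamics carry
over unchanged.  Two consequences of the coarser effective lattice are
handled explicitly:

* the transient D-reduction of the full-scale protocol is skipped
  (`spiral_protocol_scaled()`, S2 at 460 ms): the rescaled domain already
  traps the proto-spiral hook, and quarter-D propagation on the coarse
  effective lattice is slowed disproportionately by discretisation, which
  distorts the protocol's timing geometry;
* the instantaneous sodium-current line of a front is narrower than one
  lattice cell, so `I_Na` snapshots store the peak |I_Na| per node over
  the 2 ms preceding each frame, which paints the front as a contiguous
  line for the tip tracker.

On this grid the control spiral rotates with a period of ~274 ms,
stable over many rotations.

**Tip tracking.**  The tracker thresholds |I_Na| at half the reference
value (the peak |I_Na| of the weakest stimulus-threshold AP, computed by
bisection and cached), labels 8-connected components after one binary
dilation, takes each component's geodesically most distant pixel pair as
the line's endpoints, keeps interior endpoints (a plane wave's front ends
on the boundary: no tip), refines the position as the centroid of
pre-dilation pixels near the endpoint, and follows the candidate closest
to the previous frame.  An independent cross-check tracker intersects the
V = −35 mV isoline with the dV/dt = 0 locus on lattice cells, using
closely spaced frame pairs (over long frame intervals the
finite-difference dV/dt locates the rotation centre rather than the
instantaneous tip).  On the rescaled spiral domain the two trackers agree
to ~0.7 mm RMS -- about one cell of the effective (0.675 mm) lattice --
and the ibi-based and tip-revolution period estimators agree to ~1.5%.

**Mesh control.**  A 30 pA/pF, 400 ms pulse on grid lines dividing the
domain into 4 x 4 square cells (33.75 mm at full scale, proportional on
the scaled grid).  Driven lines stay refractory and absorb incoming
waves; termination is declared when no node exceeds −40 mV and no
re-excitation occurs for 200 ms.  On the scaled domain the pulse
extinguishes the spiral while a null pulse leaves it rotating.

## Parameter choices where the record is incomplete

* 2D representative fibroblast set: \(C_f = 6.3\) pF, \(G_f = 4\) nS,
  \(E_f = -49\) mV, \(G_{gap} = 8\) nS.  This is the "high \(G_f\), high
  \(G_{gap}\)" single-cell set whose AP-shortening regime
  (\(E_f \le -39\) mV) is the one the 2D rotation-period trend relies on.
* CV-trend sampling grid: \(G_{gap} \in \{1, 2, 4, 8\}\) nS.  At
  \(E_f = -49\) mV a minute supernormal speed-up (<0.1%) exists between
  \(G_{gap} = 0\) and 1 nS -- the slight diastolic depolarization brings
  the tissue marginally closer to threshold before the load effect wins.
* Tissue stimulus geometry: boundary stimuli are 3 nodes wide; mesh lines
  are 1 node wide.

## Known limitations

* **Two-sided conduction failure.**  Under this package's cross-coupling
  algebra, no passive-fibroblast parameter set we consider physiologically
  arguable blocks a plane wave: single fibroblasts saturate within ~1 ms
  and carry too little charge to defeat the sodium upstroke (CV changes by
  a few percent at most), hyperpolarizing cluster-scale loads slow CV
  smoothly while preserving sodium availability, and depolarizing loads
  pass from slowed conduction directly into hyperexcitability and
  automaticity without a quiescent blocked window.  Conduction failure as
  reported for strongly coupled two-sided tissue would require a
  different cross-coupling algebra (for example fibroblasts inserted in
  series into the myocyte-myocyte path), which this model's bilayer
  geometry does not contain.  The corresponding acceptance expectation is
  deliberately left failing rather than redefined.
* The isolated myocyte rests at −86.4 mV (the model's canonical value);
  reported reference values near −84.6 mV are not reachable from the
  published constants.
* APD changes measured at levels close to a composite's elevated
  diastolic potential (e.g. \(\Delta\)APD90 at \(E_f = -9\) mV) sit on a
  nearly flat AP tail and are hypersensitive to sub-millivolt tail
  differences; this package reproduces the sign and order of magnitude
  but not the printed value for that single entry, while the companion
  quantities of the same parameter set match to better than 1%.
* Fibroblasts are strictly passive; active (time- and voltage-dependent)
  fibroblast formulations, mechanosensitive currents, electro-mechanical
  feedback, tissue anisotropy, diffuse fibrosis and bidomain electrics
  are out of scope.
* The synthetic rotor fixture localizes its constructed core to about the
  arm half-width (~3 nodes); it validates tracker logic, not sub-node
  accuracy.

## Problem sizes used by the shipped tests

Single-cell runs integrate 1.5 s at 0.02 ms steps after a 5 s cached
pre-run.  Conduction-velocity checks use 600 x 7 (reference value) and
300 x 5 (trends, scaling) strips.  Spiral experiments use the rescaled
200 x 200 domain: one shared initiation (1.5 s), rotation-period runs of
1.15 s per coupling value, and paired 0.7-0.9 s control runs.  Full-scale
600 x 600 runs are supported through the same entry points.
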