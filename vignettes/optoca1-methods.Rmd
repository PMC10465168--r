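---
title: "Models and methods behind optoca1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind optoca1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optoca1)
```

optoca1 asks a concrete question: from which optical-fiber positions, at
which irradiances, and under which opsin-expression strategies does a
CA1-like neuron expressing ChR2(H134R) fire? This vignette documents the
models, the numerical choices, and the boundaries of what the package's
simulations can and cannot say about real cells.

## The photocurrent model

The opsin kinetics follow a double two-state scheme: two independent
first-order gates, the opening gate $O$ and the dark-light adaptation gate
$R$, each relaxing toward an irradiance-dependent steady state
$X_\infty(\mathrm{Irr})$ with a time constant combined harmonically from an
irradiance- and a voltage-dependent component,
$\tau_X = \left[\tau_X(\mathrm{Irr})^{-1} + \tau_X(V)^{-1}\right]^{-1}$.
The current density in mA/cm² is

$$i_{\mathrm{ChR2}} = g_{\mathrm{ChR2}}\, G(V)\,(O R)\,(V - E_{\mathrm{ChR2}}),
\qquad
G(V) = \frac{1 - 1.25\, e^{-(V - E_{\mathrm{ChR2}})/44.52}}{V - E_{\mathrm{ChR2}}}.$$

The rectification numerator $D(V) = G(V)(V - E_{\mathrm{ChR2}})$ is finite
everywhere and is what the solver evaluates, so the removable singularity of
$G$ at $V = E_{\mathrm{ChR2}}$ never arises. Two consequences worth keeping
in mind:

* the actual zero-current potential is not $E_{\mathrm{ChR2}} = 0$ but
  $44.52 \ln 1.25 \approx 9.93$ mV;
* near rest the rectification is strong: $G(-68.83\,\mathrm{mV}) \approx
  0.07$, i.e. a formulation normalized to $G = 1$ at that potential needs a
  $\sim 14$-fold smaller conductance for the same current. `opsin_params()`
  therefore absorbs all proportionality into $g_{\mathrm{ChR2}}$.

Every numeric constant of the $\tau/\infty$ expressions — all sigmoids in
irradiance share the pattern $a/(1 + e^{b}\,\mathrm{Irr}^{c})$ — is a named
entry of `opsin_params()`, so a recalibrated constant set is a configuration
change, not a code change. With the default constants, $O_\infty$ rises from
0 to 1 with irradiance while $R_\infty$ falls from 1 to 0.23, which produces
the characteristic biphasic (peak-then-plateau) photocurrent at high
irradiance and long pulses; adaptation only becomes substantial above a few
tens of mW/mm².

Gates are advanced by exponential Euler,
$X \leftarrow X_\infty + (X - X_\infty)e^{-\Delta t/\tau_X}$, which is exact
for piecewise-constant inputs and unconditionally stable — important because
$\tau_O$ drops to microseconds at high irradiance. The default step is
$\Delta t = 0.025$ ms. The initial state is dark-adapted, $(O, R) = (0, 1)$,
the $\mathrm{Irr} \to 0$ steady state: the cells are at rest before
stimulation.

## Light transport

The fiber (100 µm radius, NA 0.39) illuminates a homogeneous gray-matter
medium (`optical_properties()`: $\mu_a = 0.42$ mm⁻¹, $\mu_s = 11.33$ mm⁻¹,
$g = 0.88$, $n = 1.36$ at 470 nm). Photon packets are launched uniformly
over the fiber disk — the launch profile across the face is not constrained
by the data the defaults derive from, and a uniform disk is the simplest
defensible choice — with directions uniform in the acceptance cone of
half-angle $\arcsin(\mathrm{NA}/n)$.

Transport is the classic weighted-packet random walk: step lengths
$-\ln u/\mu_t$, Henyey–Greenstein polar angles, absorbed weight
$w\,\mu_a/\mu_t$ deposited at each interaction site. Fluence rate per voxel
is deposited energy divided by $\mu_a$ times voxel volume, recorded on a
cylindrical $(r, z)$ grid and normalized by the fiber-face irradiance, so
the stored field is a unitless gain. Three choices matter for
interpretation:

* the grid boundary absorbs; escaping weight is tallied, and together with
  the Russian-roulette kill/compensation tallies the energy balance closes
  to machine precision on every run (`energy_balance()`), which is the
  suite's conservation check;
* Russian roulette triggers below weight $10^{-4}$ with survival 0.1 — the
  standard unbiased termination;
* refractive-index mismatch at the fiber face is ignored beyond the NA-cone
  restriction.

The desk-scale default is $10^6$ photons on a 10 µm grid; the full
configuration ($10^7$, 5 µm) is a parameter change. Interpolation
(`irradiance_at()`) is bilinear on voxel centers and returns 0 outside the
grid.

Fiber placement uses the cell frame (soma at origin, somato-dendritic axis
on $z$). Pitch 0 points the beam along $+z$, pitch $\pi$ along $-z$, pitch
$\pi/2$ along $-x$ so light travels toward the cell from the fiber's $x$
position; `roll` rotates the cell about $z$ before the transform. For
pitches 0 and $\pi$ the position grid covers the half-plane $x \ge 0$ and
surface results are doubled by symmetry.

## Synthetic morphologies

`generate_pyramidal()` and `generate_interneuron()` build CA1-like cells
from stochastic binary trees with tapering diameters: a cylindrical soma at
the origin, an axon, a basal tree into the $-z$ hemisphere, and an apical
trunk along $+z$ with obliques and a tuft (pyramidal), or undifferentiated
dendrites plus a large axonal arbor (interneuron; the `bistratified` preset
has an axon area near $10^5$ µm², the `basket` preset near $2.5\times10^4$
µm², slightly above its dendrites, matching the relation seen in
reconstructed cells). Default parameters were calibrated once so the
per-region membrane areas fall inside the bands spanned by reconstructed
CA1 cells (soma ≈ 400–1,400 µm², pyramidal dendrites ≈ 1.5–2.5 × 10⁴ µm²);
this is calibration of totals, not replication of geometry.

What the generator does **not** emulate: realistic branching statistics,
path-length distributions, spine area, or the fitted multi-conductance
channel distributions of reconstructed models. Passing tests therefore
demonstrate that the pipeline's machinery (titration, SoFPAN, regression,
screening) behaves correctly and reproduces the qualitative orderings —
not that its absolute thresholds equal those of any real CA1 cell.

Sections are discretized into segments of at most `max_seg_len` (default
20 µm) equal arc length — a fixed-length rule rather than the d-lambda
rule, chosen for testability; membrane area is the summed lateral area of
conical frusta, and a branch attaches to the spatially nearest segment of
its parent section so mid-trunk obliques couple at the right place.
`distribute_opsin()` spreads a preset total conductance $G_{\max}$
uniformly over one region, $g_{\mathrm{ChR2}} = G_{\max}/A_k$; the
area-weighted sum recovers $G_{\max}$ exactly, and a smaller region gets a
proportionally higher local density — the mechanism behind the excitability
advantage of confined expression.

SWC import/export uses the standard 7-column format (type codes 1/2/3/4 →
soma/axon/basal/apic; interneurons collapse 3/4 to `dend`). A one-point
soma expands to a cylinder of length equal to its diameter. Round trips of
package-generated cells are exact except for branches attached mid-section,
where the format's parent-sample semantics add one short connection edge.

## Membrane model and solver

The membrane stand-in is deliberately simple: leak plus transient Na and
delayed-rectifier K with Hodgkin–Huxley-style kinetics, with per-region
density scaling (axon > soma > dendrites) and global `na_scale`/`k_scale`
multipliers as the knob for depolarizing/hyperpolarizing channel-ratio
experiments. Defaults ($g_L = 10^{-4}$ S/cm², soma Na 0.08, axon 0.4,
dendrites 0.012 S/cm²) give a stable rest near −71 mV, no spontaneous
firing, and a clean threshold; they are a design choice of this package,
not fitted values. Voltage is initialized at −70 mV with a 100 ms settling
period before the protocol clock starts, matching the impedance protocol.

The cable equation on the branched tree is integrated by backward Euler
with Hines ordering (parent index < child index: one elimination sweep from
the leaves and one back-substitution per step), $\Delta t = 0.025$ ms.
Gates advance by exponential Euler staggered with the voltage solve; HH
rates come from a fine lookup table in $V$ (0.05 mV, linear interpolation).
The opsin current enters explicitly (previous-step voltage), which is
accurate at this step size — the suite checks threshold shifts under 4×
step refinement stay below 2%, passive attenuation against the analytic
infinite-cable form within 2%, and a single-compartment spike against a
fine-step run.

A spike is a strict somatic crossing of −10 mV anywhere in the window.
Simulations run to $T_{\mathrm{end}} = \max(500, t_0 + \mathrm{pd} + 100)$
ms so post-pulse channel closure is always integrated. Input impedance at
0 Hz is the steady deflection per small hyperpolarizing current step after
settling; for a passive isolated compartment it equals $1/(g_L A)$.

## Threshold, TAC and SoFPAN

Titration brackets the threshold with a decade scan over
$[10^{-3}, 10^{3}]$ mW/mm² (the data behind the defaults fix only the
bracket ratio $b_0/a_0 = 10$ and the seven bisection iterations; the scan
is this package's bracket-search choice), shifts the bracket down
geometrically if even the lowest decade spikes, and reports the seventh
midpoint. No spike at the cap yields the sentinel `NA` ("not excitable").
During titration probes the solver stops at the first threshold crossing;
the TAC run always integrates the full window.

The TAC is the area-weighted, time-averaged photocurrent
$\frac{1}{\mathrm{pd}}\sum_j A_j \int_{t_0}^{T_{\mathrm{end}}} i_j\,dt$
(trapezoidal rule; nA), evaluated at the titrated threshold.

The SoFPAN is the surface of fiber positions from which the cell fires at a
given fiber intensity, on the 11 × 11 position grid ($z \in [-400, 700]$
µm; $x \in [-1000, 4000]$ µm at pitch $\pi/2$, $[0, 2500]$ µm otherwise).
Three numbers are reported per intensity:

* **lower bound** — grid cells whose four corner nodes are all true;
* **upper bound** — the same count after dilating the node field with a
  3 × 3 mask;
* **point estimate** — true nodes weighted by the fraction of their grid
  cell inside the domain (interior 1, edges ½, corners ¼).

The boundary weighting makes an all-true map integrate to exactly the
domain area (5.5 mm² at every pitch, after doubling for the half-plane
pitches) and preserves lower ≤ estimate ≤ upper: each enclosed cell's four
corners contribute at least a quarter-cell each to the estimate, and
dilation can only add true nodes. "Enclosed by four true points" is read as
a cell whose four corner *nodes* are true, with dilation applied to the
node field — the reading that keeps both bounds monotone in intensity.

The uniform-field approximation treats the cell as the single point at its
soma: the position-dependent threshold is the uniform-field threshold
divided by the light-field gain at the soma's fiber-frame location, and the
relative error against the Monte Carlo SoFPAN is
$(S_{\mathrm{uniform}} - S_{\mathrm{MC}})/S_{\mathrm{MC}}$, with $\infty$
when only the uniform estimate is nonzero and −100% in the opposite case.
For soma-confined opsin the two coincide by construction, which the
acceptance suite uses as a method check.

Optimal and worst fiber depths maximize/minimize the depth of activation
(true positions along $x$ per $z$ row); ties break on the mean TAC along
$x$ (lower wins the optimal side), and a fully constant map resolves to the
first grid row — determinism documented rather than left to chance.

## Statistics

**Strength-duration regression.** The Lapicque form
$\widehat{\mathrm{TAC}} = \mathrm{TAC}_0/(1 - e^{-\mathrm{pd}/\tau})$ is
fit by nonlinear least squares *on the log scale*: strength-duration data
span decades and their noise is multiplicative, so log-residuals make the
estimator consistent (linear-scale least squares lets the shortest pulses
dominate and biases $\mathrm{TAC}_0$). Flat data identify only the
asymptote and are returned as such. The second step is ordinary least
squares of $\log_{10} I_{\mathrm{th}}$ on $\log_{10} G_{\max}$ and
$\log_{10} \widehat{\mathrm{TAC}}$, with the adjusted $R^2$ on the
$n - 3$ denominator. Sentinel thresholds are excluded from both steps.

**Wilcoxon scoring.** Classes (cell × opsin-location, optionally × pitch)
are compared pairwise with one-sided paired signed-rank tests on a shared
condition grid; a class earns 1, 0.1 or 0.01 points per beaten class at
p < 0.001, 0.01, 0.05, so the maximum score is the number of classes minus
one. Zero differences are discarded; the exact null distribution is used up
to 25 untied pairs, otherwise the normal approximation with tie and
continuity correction. The suite cross-checks the p-values against a full
$2^n$ sign-enumeration oracle at small $n$.

**Elementary effects.** The six uncertain factors ($\mu_a$, $\mu_s'$,
$G_{\max}$ — normal with CV 0.15, truncated at ±4 SD to keep the optics
physical; roll — uniform on $[-\pi, \pi)$; cell and location — discrete
uniform) live in a unit hypercube and are mapped through their inverse
distributions. The radial design takes base and step coordinates from a
Sobol sequence (own compact direction-number generator, 16 dimensions; its
first dimension is the van der Corput sequence, used as an exact oracle)
with a seeded digital shift, $r = 16$ repetitions by default.
Elementary-effect denominators are unit-hypercube steps so heterogeneous
factor types stay comparable; a discrete step that lands in its own class
advances cyclically to the next class so every effect reflects a real
perturbation. $\mu^*$ is the mean absolute effect, $\sigma$ the standard
deviation (nonlinearity/interaction).

## Problem sizes in the test suite

The suite runs everything at desk scale, as this package's own choice of
test conditions: light fields at $10^4$–$4\times10^5$ photons on coarsened
grids, reduced synthetic cells (tens of segments at 40–60 µm
discretization), position sweeps at 3 × 3 to 5 × 5 on the same coordinate
ranges as the full 11 × 11 layout, and $r = 2$–32 elementary effects. The
full-scale settings are reachable from every function signature; nothing in
the code branches on the problem size.

## Known limitations

* Homogeneous tissue only: no gray/white heterogeneity, no fibrous
  encapsulation of the fiber, no heating.
* Single-pulse excitation of isolated cells at rest; no pulse trains,
  bursting/depolarization-block characterization, synaptic input or
  networks.
* The simplified Na/K/leak membrane reproduces threshold behavior, not the
  firing phenotypes of fitted multi-conductance models; absolute thresholds
  on synthetic cells are not predictions for specific reconstructed cells.
* The 2D position grid yields a surface, not a volume, of activation.
* One opsin (ChR2(H134R)); no proton-permeability or temperature effects.
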