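---
title: "IP3 diffusion at the nanoscale: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IP3 diffusion at the nanoscale: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(papm)
```

## The physical picture

Astrocyte processes contact synapses through thin peri-synaptic projections
(PAPs). Metabotropic signalling there is supposed to run as: glutamate
activates PLC at the membrane facing the synapse, PLC cleaves PIP2 into IP3,
IP3 diffuses down the projection to IP3 receptors on Ca2+ stores, and Ca2+ is
released. Whether this chain is physically plausible at PAP dimensions is a
quantitative question: at these volumes, micromolar concentrations mean
*single-digit molecule numbers*, and the transit distance is about a
micrometre.

`papm` implements an order-of-magnitude analysis of that chain. The
projection is idealized as a cylinder of length $L = 1000$ nm (the measured
distance from the post-synaptic-density contact, the $\alpha$ face, to the
Ca2+ stores, the $\beta$ face) and diameter $D = 100$ nm. Its volume,

$$V = \pi D^2 L / 4 = 7.8539\times10^{-21}\,\mathrm{m}^3
    = 7.8539\times10^{-18}\,\mathrm{L},$$

is the unit in which concentration and molecule number are interconverted:

```{r}
conversion_table()
molecules_to_concentration(1, cylinder_volume()$litres) * 1e6 # uM per molecule
```

One molecule is already $\approx 0.21\,\mu$M; below that concentration the
compartment simply holds no molecule. This is the regime the whole package is
about.

## The diffusion model

IP3 diffusion along the cylinder axis is one-dimensional Fickian transport,

$$\frac{\partial C}{\partial t} = D_{ab}\frac{\partial^2 C}{\partial z^2},$$

nondimensionalized with $\phi = (C - C_0)/(C_1 - C_0)$, $\tau = t D_{ab}/L^2$
and $\eta = z/L$. The boundary value problem is: no IP3 initially
($\phi = 0$ at $\tau = 0$ for $\eta > 0$), a constant-concentration source at
the synaptic face ($\phi = 1$ at $\eta = 0$), and an impermeable far wall
($\partial\phi/\partial\eta = 0$ at $\eta = 1$). The separated solution is
the odd-harmonic sine series

$$\phi(\tau,\eta) = 1 - \frac{4}{\pi}\sum_{n\ge 0}
  \frac{1}{2n+1}\,e^{-(2n+1)^2\pi^2\tau/4}\,
  \sin\!\Big(\frac{(2n+1)\pi\eta}{2}\Big),$$

with eigenvalues $(2n+1)\pi/2$. A frequently reprinted variant of this
closed form with cosine eigenfunctions and $(-1)^n/(2n+2)$ coefficients does
*not* satisfy these boundary conditions (it pins $\phi = 1$ at the no-flux
wall); `phi_series()` implements the sine expansion, and the package's
finite-difference and stochastic oracles confirm it is the solution of the
stated problem.

Model assumptions worth keeping in mind: $D_{ab}$ is concentration
independent, the source concentration never varies, there is no radial or
angular dependence, and **no IP3 removal** — degradation is simply absent,
which is defensible only because every time point of interest (microseconds
to milliseconds) sits far below the earliest degradation estimate of 0.8 s.
The package carries that horizon in `papm_constants()` and warns when a
synthesis time exceeds it.

### Numerical evaluation

* **Truncation.** The series is summed adaptively until the term envelope
  $(4/\pi)e^{-(2n+1)^2\pi^2\tau/4}/(2n+1)$ falls below `tol` (default
  $10^{-12}$), with a hard cap of 1000 terms.
* **Small times.** Convergence degrades as $\tau \to 0$, but there the front
  has not felt the far wall and the similarity solution applies:
  `phi_smalltau()` evaluates $\mathrm{erfc}(\eta/2\sqrt{\tau})$ plus one
  even image about $\eta = 1$. The dispatcher `phi()` switches at
  $\tau_{\mathrm{switch}} = 0.01$, where the two forms agree to better than
  $10^{-6}$ everywhere.
* **Clamping.** Results are clamped to $[0,1]$ to absorb truncation noise at
  the $10^{-12}$ level.
* $\tau = 0$ is never summed; `dimensionless_profile(0)` returns the initial
  condition directly.

Physical time follows from $t = \tau L^2/D_{ab}$. The canonical display set
$\tau \in \{0.005, 0.1, 0.3, 0.8, 1.5\}$ maps, at the default
$D_{ab} = 300\,\mu\mathrm{m}^2/\mathrm{s}$, to 16.7 µs, 333 µs, 1 ms,
2.667 ms and 5 ms:

```{r}
signif(tau_to_time(c(0.005, 0.1, 0.3, 0.8, 1.5)), 3)
```

By $\tau \approx 1.3$ the far-wall deficit $1 - \phi(\tau, 1)$ drops below
5% (`steady_state_tau(0.05)`), which is why $\tau = 1.5$ profiles look flat.
With the disputed slow diffusivity $D_{ab} = 10\,\mu\mathrm{m}^2/\mathrm{s}$
all times stretch 30-fold ($\tau = 1.5 \to 150$ ms) while the dimensionless
profiles — and hence all molecule counts — are unchanged; `run_sweep()`
makes this explicit.

## Synthesis budget and integer molecules

IP3 production at $\alpha$ is zero-order: `n_plc` enzymes $\times$
`kcat_per_s` turnovers, capped by the local PIP2 pool of 3000 molecules
(three ~1000-molecule clusters). The spanned grid is 1–100 PLC at
1000–5000 /s. Substrate depletion kinetics, PLC regulation and PIP3 as an
alternative substrate are all deliberately out of scope.

`allocate_molecules()` turns a profile plus a synthesized total into integer
counts: the expectation at grid point $i$ is
$N_i = N_{\mathrm{tot}}\,\phi_i/\sum_j \phi_j$, rounded to the nearest
integer. Three choices here are deliberate and were fixed by internal
consistency of the reference molecule tables rather than left free:

* **Grid.** 11 equally spaced points (100 nm spacing). This point-value
  normalization — not trapezoidal integration — is the unique simple scheme
  consistent with every reference count we checked (41/2 at 333 µs, 29 at
  1 ms, 112 at 2.667 ms, 225 at 5 ms, 6/2 at 16.7 µs); trapezoid weighting
  gives e.g. ≈247 instead of 225 at 5 ms. The grid size is configurable,
  11 is the compatibility default.
* **Rounding.** Nearest integer with exact halves rounded *down*
  (`round_count()`). Ties are essentially measure-zero in the allocation
  itself, but the synthesis totals hit one exactly: 50,000 /s × 2.67 ms =
  133.5, and only the downward tie matches the reference total of 133 while
  224.52 → 225 and 40.65 → 41 fix "nearest" for everything else.
* **The 2.67 ms working time.** The exact $\tau = 0.8$ time is
  $2.6\overline{6}$ ms, but the synthesis totals of the reference table
  (1335, 267, 133, 27, 13) are consistent only with the 3-significant-figure
  working value 2.67 ms — e.g. 500,000 /s × 2.6667 ms = 1333.3, not 1335.
  Conversely the 333 µs row requires the exact value 1/3000 s (166.7 → 167;
  literal 333 µs would give the tie 166.5). `table3_scenarios()` therefore
  stores an explicit per-row working time: exact for $\tau = 0.1, 0.3, 1.5$
  and 2.67 ms for $\tau = 0.8$. The profile itself is always evaluated at
  the row's $\tau$.

The full pipeline, with face counts at both ends:

```{r}
run_table3()
```

### The low-copy caveat

When the expectation is below one molecule at *every* grid point — e.g.
1 PLC at 1000 /s after 5 ms, five molecules spread over a profile whose
grid sum is ≈10.8 — rounding would fabricate an all-zero "distribution".
The allocation flags this case `degenerate` instead: continuum transport
says nothing about where those few molecules actually sit.
`visible_profile()` applies the related display rule that only positions
with expectation ≥ 1 molecule are physically readable.

## Receptor-side estimates

The Ca2+ store membrane facing the projection is approximated by the
cylinder cross-section $\pi D^2/4 \approx 7854\,\mathrm{nm}^2$ (computed
from the geometry; a commonly quoted figure of 7583 nm² looks like a digit
slip and floors to the same capacity). With a ~380 nm² receptor footprint at
most 20 IP3Rs fit; assuming half the face is taken by other machinery
(notably RyR) leaves ~10, and at four IP3 per tetrameric receptor the full
pool needs ~40 IP3 nearby. `receptor_thresholds()` annotates the molecule
table with which conditions cross the single-receptor (≥ 4) and full-pool
(≥ 40) lines. The half-share is a modelling choice, not a measurement; it is
exposed as `sharing_fraction`.

```{r}
subset(receptor_thresholds(run_table3()), near_beta_ge_pool)
```

## Validation architecture

Because the headline numbers all flow through one analytical formula, the
package ships two independent numerical routes to the same solution:

* **Finite differences** (`solve_fd()`): backward-Euler (unconditionally
  stable, default `n_space = 200`, `d_tau = 1e-4`) and forward-Euler
  (stability-checked $r \le 1/2$) marches with a Dirichlet source node and a
  second-order ghost-point no-flux closure. The implicit scheme also tracks
  a per-step discrete flux balance — stored-mass change against boundary
  influx — which is zero to rounding by construction and is surfaced as a
  `flux_residual` attribute so a discretization defect cannot hide. The test
  suite requires three-way agreement (series, implicit, explicit) to
  $L_\infty < 10^{-3}$ at all five canonical $\tau$; for $\tau = 0.005$ the
  implicit runs use `d_tau = 1e-6`, since at the steep early transient the
  first-order time error at `1e-4` is measurably above that bar.
* **Stochastic particles** (`particle_walk()`): a lazy lattice walk
  (hop ±1 site with probability 1/4 each) whose hop variance matches unit
  diffusivity. The reflecting wall is realized by the method of images —
  the walk runs on the doubled domain $[0,2]$ with reservoirs at both ends,
  whose restriction to $[0,1]$ is exactly the no-flux solution. A naive
  "bounce in place" wall was tried first and rejected: it puts the
  effective wall half a cell beyond the last site and biased the wall
  occupancy by several percent, an error first order in the lattice
  spacing. The images formulation leaves only $O(\Delta\eta^2)$ bias, well
  inside three Monte-Carlo standard errors at the tested settings (21
  sites, 2×10⁴ source particles, 6 replicates). Rerunning it at ~8 source
  particles shows replicate-to-replicate dispersion of order one molecule —
  a direct illustration of why the continuum profile is an expectation, not
  a per-synapse prediction, at the earliest time point.

Problem sizes throughout (120–200 spatial points, $10^{-6}$–$10^{-4}$ time
steps, ≤ 2×10⁴ particles) were chosen so that the entire validation runs in
seconds on one core; the quantities being checked are fully converged at
these sizes.

## What this does and does not show

The oracles validate the *mathematics*: that the series, the PDE marches
and the particle expectation agree. They share every physical idealization
— no degradation, constant source, one dimension, constant $D_{ab}$, no
IP3-receptor binding or buffering — so agreement says nothing about those
assumptions holding in a real, leaf-shaped, crowded PAP. The model's own
authors flag the constant source and missing radial structure as the first
extensions to make. Within the stated assumptions, the quantitative story
is robust: IP3 reaches the stores in microseconds to milliseconds, and
whether receptor-activating quantities (tens of molecules) accumulate there
within the degradation window is controlled almost entirely by PLC copy
number and activity.
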