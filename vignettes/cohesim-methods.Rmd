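---
title: "Cohesive, aligning active particles: model, observables and state classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohesive, aligning active particles: model, observables and state classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohesim)
```

## The model

`cohesim` simulates a two-dimensional suspension of overdamped active
Brownian particles (ABPs) of diameter $\sigma$ whose positions
$\mathbf r_i$ and orientation angles $\phi_i$ obey

$$\dot{\mathbf r}_i = v_0\,\mathbf u_i + \mu \sum_{j\ne i}\mathbf F_{ij}
  + \sqrt{2D}\,\boldsymbol\xi_i, \qquad
  \dot\phi_i = \mu_R \sum_{j\ne i}\mathcal T_{ij} + \sqrt{2D_R}\,\eta_i,$$

with $\mathbf u_i = (\cos\phi_i, \sin\phi_i)$ and unit-variance white
noises $\boldsymbol\xi_i$, $\eta_i$. Steric repulsion is the purely
repulsive Weeks–Chandler–Andersen force, the Lennard-Jones potential
truncated and shifted at its minimum $r_c = 2^{1/6}\sigma$, with energy
scale $\epsilon$ (default $100\,k_BT$).

Two torques act in one shared interaction range $R$:

* an **alignment torque** $\mathcal T_A\,\Theta(R - r_{ij})
  \sin(\phi_j - \phi_i)$, which turns $i$ parallel to $j$ and obeys
  Newton's third law, and
* a **cohesive torque** $-\mathcal T_C\,\Theta(R - r_{ij})
  \sin\theta_{\mathbf u_i,\hat{\mathbf r}_{ij}}$, which turns
  $\mathbf u_i$ toward neighbor $j$ ($\theta$ is the signed angle from
  $\mathbf u_i$ to $\hat{\mathbf r}_{ij}$, $\mathbf r_{ij} = \mathbf r_i -
  \mathbf r_j$). This torque is **non-reciprocal**: what $j$ feels from $i$
  is generally not the negative of what $i$ feels from $j$.

The total interaction torque is
$\mathcal T_{ij} = \mathcal T_0\,\Theta(R - r_{ij})
 \left(\sin(\phi_j-\phi_i) - \tfrac{1}{\mathrm{ratio}}\sin\theta\right)$
with $\mathcal T_0 = \mathcal T_A = \mathrm{ratio}\cdot\mathcal T_C$ and a
default ratio of 2; ratios below 1 favor cohesion so strongly that groups
coalesce without ever agreeing on a direction, which is why the aligned
regime studied here keeps the ratio at 2. Competition between the two
torques in the same range is the essential ingredient: it produces six
collective states — disperse, multiple worm, line, persistent worm, rotary
worm and aster — with pronounced multistability in the $(R, \mathcal T_0)$
plane.

## Units and parameters

All quantities use $\sigma = k_BT = \tau_R = 1$, where
$\tau_R = 1/D_R$ is the reorientation time. The mobilities are related by
$\mu/\mu_R = \sigma^2/3$, so with $\mu_R = 1$: $\mu = D = 1/3$, $D_R = 1$,
and the self-propulsion speed is $v_0 = \mathrm{Pe}\cdot D/\sigma =
\mathrm{Pe}/3$. The reference conditions are $\mathrm{Pe} = 80$, packing
fraction $\Phi = 0.025$, $N = 1000$ particles (box side
$L = \sqrt{N\pi\sigma^2/4\Phi}$), $\epsilon = 100$, with $1000\,\tau_R$ of
equilibration followed by $1000\,\tau_R$ of data collection.
`sim_params()` stores these as defaults and derives everything else;
$R$ is specified in units of $r_c$, as is conventional for this model.

Tunable parameters that matter most:

| parameter | meaning | default | notes |
|---|---|---|---|
| `T0` | torque strength ($k_BT$) | 0 | swept over ~1–100 |
| `R` | interaction radius ($r_c$) | 1 | swept over ~1–3 |
| `ratio` | $\mathcal T_A/\mathcal T_C$ | 2 | also drives the stability analyses |
| `Pe` | Péclet number | 80 | $v_0 = \mathrm{Pe}/3$ |
| `Phi` | packing fraction | 0.025 | sets $L$ |
| `dt` | time step ($\tau_R$) | $5\times10^{-5}$ | see below |

## Numerical scheme

The integrator is explicit Euler–Maruyama. No published scheme or time
step accompanies the model, so the default $dt = 5\times10^{-5}\,\tau_R$
was chosen so that the displacement at the steepest sampled WCA separation,
$\mu\,24\epsilon\,dt$, stays below $0.05\sigma$; `sim_params()` warns when
that product exceeds $0.1\sigma$, and runs dominated by moderate torques
($\mathcal T_0 \lesssim 30$) are run here at $10^{-4}$ after checking that
pair distances stay near or above $\sigma$. Two guards abort cleanly
rather than produce silent nonsense: a minimum pair distance (default
$0.5\sigma$, an overlap that only a too-large step can produce) and a
non-finite-update check. Observables sensitive to absolute time scales
(e.g. the exact torque at which states change) can shift slightly with
$dt$; forces and torques are never capped.

Conventions fixed for reproducibility:

* Heaviside support is strictly inside ($\Theta(0) = 0$) — measure-zero,
  but fixed; at $R = 1\,r_c$ exactly, hexagonal contact neighbors are
  therefore *outside* the range, so radius grids start at $1.05\,r_c$.
* The signed angle is counterclockwise-positive in $(-\pi, \pi]$.
* Positions are stored wrapped into $[0, L)$ with integer image counters;
  mean squared displacements use the unwrapped coordinates (they must be
  able to exceed $L$).
* One seeded RNG stream drives initialization and thermal noise in order;
  identical configuration and seed reproduce trajectories bit for bit.
* Pair search uses a periodic cell list, verified exactly against an
  $O(N^2)$ scan; interaction cutoffs above $L/2$ are rejected (minimum
  image would be ambiguous).

## Initial conditions

Multistability makes initialization part of the experiment. Four families
are provided: random orientations on a box-spanning triangular lattice;
a hexagonally close-packed disk (spacing $r_c$, contact at the potential
minimum, so no initial force spikes) with inward ("aster") or random
orientations; and a worm — a hex-packed strip, default 5 rows wide, with
orientations along the axis plus Gaussian jitter of 0.1 rad. Strip width
and jitter are free parameters of the construction (the published
snapshots constrain them only visually); at small $N$ a width-2 strip
spans the periodic box and realizes the line state's geometry directly.

## Observables

* **Polar order** $\Psi = |\sum_i \mathbf u_i|/N$.
* **Clusters**: density-based clustering with cutoff $1.5\sigma$ and
  minimum sample count 1 — which is exactly connected components of the
  minimum-image distance graph, and is implemented (and independently
  verified) as such.
* **Periodic center of mass**: each coordinate is embedded on a circle to
  get a reference angle, then the arithmetic mean of minimum-image
  displacements about that reference is taken — exact for any cluster of
  extent below $L/2$, even straddling the boundary.
* **Cluster size** $\langle S_c\rangle_t$: mean over clusters of the
  maximum member distance to the cluster center of mass.
* **System size** $\langle S\rangle_t$: the same extent averaged *per
  particle* (each particle contributes the extent of its own cluster).
  The cluster-weighted average is diluted by background singletons,
  whereas the particle-weighted version jumps toward $L/2$ whenever most
  particles merge into one box-spanning line — which is precisely what
  detects the transient multiple-worm/line state. (Treating all $N$
  particles as literally one cluster about the global center of mass was
  also considered and rejected: any spread-out configuration, including
  the disperse state, then measures $\sim L/2$.)
* **MSD / OCF** with standard errors across particles, all time origins at
  the sampling spacing; analytic free-ABP baselines
  $4Dt + (2v_0^2/D_R^2)(D_Rt - 1 + e^{-D_Rt})$ and $e^{-D_Rt}$ are
  provided for comparison.
* **Asymmetry** $A = |I_1 - I_2|/(I_1 + I_2)$ from the eigenvalues of the
  2×2 second-moment (gyration) tensor about the periodic center of mass:
  0 for round clusters, 1 for collinear ones. Any planar inertia-tensor
  variant gives the same $A$ because the in-plane eigen-gap normalizes
  identically. Degenerate (all-coincident) clusters yield `NA` and are
  excluded from averages.
* **Radial order**: mean of $\mathbf u_i\cdot\hat{\mathbf r}_i$ with
  $\hat{\mathbf r}_i$ pointing outward from the cluster center, so a
  perfect aster scores $-1$.
* **Neighbor turnover and leadership rank** for the dynamics of
  individuals inside worms.

## State classification

The static groupings in the $(\langle\Psi\rangle_t, \langle S_c\rangle_t)$
plane are visual in origin; the numeric boundaries used here
(`classify_thresholds()`: $\Psi_{lo} = 0.3$, $\Psi_{hi} = 0.6$,
$S_{lo} = 5\sigma$, radial order $< -0.5$ for asters) separate those
groupings cleanly and are exposed for sensitivity analysis — labels of
runs near state boundaries can legitimately differ under small threshold
changes. A box-spanning cluster is recognized at extent $> 0.45L$ rather
than $L/2$: minimum-image distances are capped at $L/2$, so a spanning
line's extent approaches $L/2$ strictly from below.

The worm family is split by dynamics. The ballistic-to-diffusive
crossover is the first lag at which the local log–log MSD slope drops
below 1.5 and stays below it for the following decade; the matching
free-ABP crossover is computed from the analytic curve *with the same
estimator*, so the comparison is self-consistent. A slope check over the
last decade of lag separates a genuine crossover to diffusion (tail slope
$\approx 1$) from arrest at a plateau (tail slope $\approx 0$).
Oscillations are declared when the OCF dips below $-0.1$ and its spectrum
(interpolated onto a uniform grid) has a dominant nonzero-frequency peak
at least 3× the median background *with at least two full cycles in the
window* — a single slow swing of a persistent worm's heading is not an
oscillation — or when the MSD shows two or more local maxima beyond its
plateau onset. Then:

* **rotary worm** — oscillations with no diffusive crossover (the MSD
  turns oscillatory around a plateau instead of diffusive; the center of
  mass of a small rotating worm still drifts, so no slope condition is
  imposed on the tail beyond the absence of a diffusive crossover);
* **persistent worm** — no oscillations and either a crossover later than
  the ABP's or no crossover at all within a non-arrested window (an MSD
  that stays ballistic throughout is the extreme of persistence, not
  unclassifiable; an arrested, non-oscillating run is *not* persistent and
  falls through to `"unclassified"`);
* **persistent/rotary transition** — a diffusive crossover at or before
  the ABP's, or oscillations coexisting with a crossover.

Records that fit no branch are labeled `"unclassified"` — never silently
assigned. `sweep_state_diagram()` runs the full pipeline over an
$(R, \mathcal T_0)$ grid for several initializations and seeds and
tabulates label multisets per cell; failed runs are recorded as
`"failed"`.

## Idealized-geometry stability analyses

Why do worm edges tilt inward, and why is the worm's tip stable? The
package answers with torque-balance calculations on idealized sheets, all
particles oriented along the sheet axis, evaluating the same pairwise
torque law on a probe particle:

* **Uniform half-plane sheet** (probe on the straight edge): 2D
  Gauss–Legendre quadrature in polar coordinates. The equilibrium tilt has
  a closed form, $\alpha^* = -\arctan\!\left(\frac{2}{\pi\,\mathrm{ratio}}\right)$
  (≈ 17.6° inward at ratio 2), independent of $\mathcal T_0$, density and
  $R$ — the tests verify the quadrature against it.
* **Hexagonally packed half-plane** (probe in the top lattice row):
  explicit lattice sum. Here the tilt *does* depend on $R$: it is
  shell-wise constant, increasing overall from ≈ 0.213 rad just above
  contact toward the continuum value, with one small dip when the
  pure-alignment in-row shell at $2a$ enters. On the coarse radius grid
  $\{1.05, 1.5, 2, 3\}\,r_c$ it is monotone non-decreasing — the
  discreteness, not a failure of the trend, explains a larger inward tilt
  (hence rounder, less elongated worms) at larger interaction radii.
* **Uniform triangular wedge** (probe at the apex — the worm's tip): by
  symmetry the parallel orientation is an equilibrium, and it is stable
  for every apex angle at ratio ≥ 1: after a noise kick the tip returns,
  which produces the small curvatures of leader trajectories and the
  neighbor/leadership turnover seen in worm runs.

Root finding uses bracketed `uniroot` on $(-\pi/2, \pi/2)$ to $10^{-8}$
rad with a negative-derivative stability check; quadratures are
re-evaluated at doubled resolution and warn above $10^{-6}$ relative
change (measured against the overall torque scale — near a root the
pointwise value is ~0 and a naive relative test would always fail).

## What the synthetic data can and cannot show

Every test input is synthetic: hand-built few-particle configurations
with known answers, and simulator-generated trajectories at reduced scale
($N = 100$ at the reference packing fraction, durations of tens of
$\tau_R$ instead of $1000\,\tau_R$; the free-ABP checks use $N = 500$ for
$10\,\tau_R$, and the worm-persistence check uses $N = 200$ out to
$110\,\tau_R$).
These sizes were chosen so the full suite exercises every state at
desktop scale. Consequences to keep in mind: at $N = 100$ the state
diagram's cell boundaries shift relative to $N = 1000$ (the aster, for
instance, is only stable at sufficiently high torque with $R = 2r_c$, or
$\mathcal T_0 = 100$ with $R = 3r_c$); the line state is a finite-size
effect realized deliberately via a box-spanning initialization; and
occurrence statistics per cell are anecdotal (a handful of seeds), not
converged multistability frequencies. Passing tests demonstrate the
correctness of the mechanics, observables and classification logic, and
qualitative agreement of the emergent states — not quantitative
$N = 1000$ phase boundaries.

## Known limitations

* No hydrodynamic interactions, vision cones, 3D, or underdamped inertia;
  alignment and cohesion always share one range and one strength ratio
  per run.
* The classifier thresholds are constructions over visual groupings;
  transition-region labels are sensitive to them by design.
* Explicit Euler–Maruyama is first-order; quantitatively time-step-robust
  transition torques would need a higher-order or adaptive scheme.
* Trajectory persistence uses a versioned serialized container plus an
  extended-XYZ text export; the container is an R-native format rather
  than a cross-language one.
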