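---
title: "A compliant multi-compartment Darcy model of coronary microcirculation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A compliant multi-compartment Darcy model of coronary microcirculation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoperf)
```

## The model

Intramural coronary vessels are far too numerous to resolve individually, so
`myoperf` treats the ventricular wall as three superimposed porous continua —
small arteries (diameters roughly 100–500 µm), arterioles (8–100 µm) and
capillaries (4–8 µm) — each carrying its own pressure field $p_i(x,t)$ on the
same domain $\Omega$ (the left-ventricular free wall, or an idealized stand-in
for it).  For compartment $i$:

$$
-\nabla\!\cdot\!\big(K_i \nabla p_i\big)
  \;+\; (nL)_i\,C_i\,\frac{\partial (p_i - P_{\mathrm{im}})}{\partial t}
  \;+\; \sum_j \beta_{i,j}\,(p_i - p_j) \;=\; \theta_i
  \quad\text{in }\Omega,
$$

with homogeneous Neumann conditions on $\partial\Omega$.  The three terms are
spatial seepage, compliance (storage in distensible vessels) and hierarchical
mass exchange.  $\theta_1$ injects the flow delivered by the epicardial
coronary outlets; $\theta_3 = -\gamma\,(p_3 - p_{\mathrm{ra}})$ drains to the
venous system at right-atrial pressure.

Contraction enters through the intramyocardial pressure
$P_{\mathrm{im}}(x,t) = \left[0.9 - 0.6\,\lambda(x)\right] P_{\mathrm{LV}}(t)$,
where $\lambda$ is a transmural coordinate (0 at the endocardium, 1 at the
epicardium) and $P_{\mathrm{LV}}$ the chamber pressure: tissue pressure is 90%
of chamber pressure at the endocardium and 30% at the epicardium, decreasing
linearly in between.  The domain itself does not deform; contraction acts on
the microvessels purely through $P_{\mathrm{im}}$.

All constitutive quantities derive from the transluminal pressure
$\Delta p_i = p_i - P_{\mathrm{im}}$ through mean cross-sectional area laws
$A_i(\Delta p)$ fitted to hyperemic (maximally vasodilated, fully passive)
vessels:

* $A_1 = 0.07\ \mathrm{mm^2}$, rigid ($C_1 = 0$);
* $A_2$: a logarithmic fit for $\Delta p \ge 0$ and a sigmoid extension with
  asymptotic minimum $0.003\ \mathrm{mm^2}$ for $\Delta p < 0$;
* $A_3$: a single sigmoid between $1$ and $25\ \mathrm{\mu m^2}$.

From these, with length density $(nL)_i$ (vessel length per tissue volume)
and calibrated morphometry factors $\delta_i$:
porosity $\phi_i = (nL)_i A_i$, permeability $K_i = (\kappa/\mu)\,\phi_i$,
network conductance $\beta_i = \delta_i (nL)_i A_i^2$ (a Poiseuille-type
$A^2$ scaling), and exchange conductance
$\beta_{i,j} = (\beta_i + \beta_j)/2$ for hierarchically adjacent pairs.
The distensibility is the exact derivative $C_i = \mathrm{d}A_i/\mathrm{d}\Delta p$
of the implemented area law, so the storage term is consistent with the areas
by construction; the separately rounded closed forms for $C_2, C_3$ are kept
as a cross-check (they agree within 2%, the coefficient-rounding bound).

```{r constitutive, fig.width = 6, fig.height = 3}
curves <- tabulate_constitutive()
library(ggplot2)
ggplot(curves, aes(dp_pa, area_mm2)) +
  geom_line() +
  facet_wrap(~compartment, scales = "free_y",
             labeller = labeller(compartment = c("2" = "arterioles",
                                                 "3" = "capillaries"))) +
  labs(x = "transluminal pressure [Pa]", y = "cross-section [mm²]")
```

## Units

Internally everything is SI (Pa, m, s) except the constitutive laws, which
are evaluated in mm² against $\Delta p$ in Pa exactly as their printed
coefficients require, and mesh coordinates, which are mm (converted at the
assembly boundary).  Three unit labels in the source material are corrected
on dimensional grounds, keeping the printed numeric values: $\kappa$ carries
m² (so that $K_i$ has m² Pa⁻¹ s⁻¹), $\delta_i$ carries mm⁻² s⁻¹ Pa⁻¹ (so that
$\beta_i$ has Pa⁻¹ s⁻¹), and $\gamma$ carries Pa⁻¹ s⁻¹.  $C_i$ carries
mm² Pa⁻¹.  One printed inconsistency is kept as printed and flagged: the
rigid small-artery area $0.07\ \mathrm{mm^2}$ corresponds to a diameter of
298.5 µm, not the stated 150 µm nominal mean.

## Epicardial coupling and perfusion territories

A full 3D description of the epicardial arteries is out of scope; each outlet
$k$ (position, radius $r^k$, optional lumped resistance $R_k$) is reduced to
the flux contract the tissue model actually consumes:

$$
q_k = \frac{P_{\mathrm{in}}(t) - \overline{p_1}^{\,\Omega^k}}{R_k + 1/\alpha},
\qquad
\theta_1(x) = \sum_k \chi^k(x)\, \frac{q_k}{|\Omega^k|},
$$

where $\overline{p_1}^{\,\Omega^k}$ is the volume-averaged first-compartment
pressure over outlet $k$'s perfusion territory and $\alpha$ the coupling
conductance.  $R_k$ defaults to 0 (the pressure drop along healthy epicardial
vessels is a few mmHg) and is available as an extension knob for stenoses.
Retrograde ($q_k < 0$) flow is admissible.

Territories are assigned by a radius-weighted eikonal distance
$|\nabla d^k| = 1/r^k$ with $d^k = 0$ at the outlet's projection onto the
wall, solved as Dijkstra shortest paths on the mesh edge graph with edge
weight (length)/$r^k$ — exact on the graph metric and deterministic; the
graph-versus-continuum gap is a mesh-refinement property.  Each node joins
the outlet of minimal modified distance (ties to the lowest outlet id), so
larger feeding arteries claim larger territories.  The indicator-function
membership is implemented in the obvious way.

## Driving pressures

The chamber and aortic waveforms are C¹ parametric families whose only
personalization knobs are the peak pressure and the systolic interval
(matching how the model is personalized to a patient): a smoothstep
rise–plateau–fall bump for $P_{\mathrm{LV}}$ over a diastolic baseline
(default 8 mmHg), and an arterial-like curve with systolic peak, end-systolic
shoulder (default 0.75 peak) and diastolic decay to a floor (default
0.55 peak).  The $P_{\mathrm{LV}}$ fall ramp is deliberately centered on the
end of the systolic interval: the aortic valve closes while the chamber is
still relaxing, so relaxation completes in early diastole.  This timing is
what produces the early-diastolic coronary refill surge; confining the bump
strictly to the systolic interval would, by construction, move that surge
into "systole" and erase the diastolic-dominant inflow morphology the model
exists to reproduce.  Phase boundaries for all flow ratios are the
personalized systolic interval $[0, \mathrm{sf}\cdot T]$.  Tabulated
waveforms (e.g. digitized traces) can be imported from CSV and bypass the
parametric family.

## Discretization and coupling

Space: piecewise-linear tetrahedral finite elements; all volume integrals are
lumped at the nodes (row-sum mass), which keeps the step matrix symmetric
positive definite and makes every conservation statement an exact sum.
Time: first-order semi-implicit steps at $\Delta t = 2$ ms — the nonlinear
coefficients $K_i, C_i, \beta_{i,j}$ are frozen at $t^n$, pressures
(including exchange and the venous sink) are implicit; no inner Newton loop.
Each step is one sparse Cholesky factorization (CHOLMOD, with symbolic reuse
across steps) plus triangular solves.

The outlet model and the Darcy solve are coupled per step by a fixed-point
iteration with under-relaxation of the outlet flows — the stiffest interface
quantity — stopping when the normalized flow (Euclidean) and pressure
(volume-weighted $L^2$) differences both fall below $\varepsilon = 10^{-10}$.
For an affine interface map with slope $-g$ the relaxed iteration contracts
with factor $|1 - \eta(1+g)|$, where $g \approx \alpha / (|\Omega^k|\,
\beta_{1,2})$; $\eta$ must therefore satisfy $\eta < 2/(1+g)$.  With the
default $\eta = 0.1$ and patient-scale territories
($|\Omega^k| \sim 2\ \mathrm{ml}$) this contracts comfortably; on desk-scale
walls with millilitre territories $g$ reaches ~30 at the systolic
$\beta_{1,2}$ minimum, so the test configurations set $\eta = 0.04$, chosen
from this bound before any coupled run.  `run_heartbeats()` defaults to
Aitken dynamic relaxation (initialized at the configured $\eta$), the
standard accelerator for loosely coupled multiphysics interfaces: it reaches
the same fixed point under the same stopping rule in roughly 20 instead of
roughly 150 Darcy solves per step; `accelerate = FALSE` restores the plain
fixed-$\eta$ iteration.

The initial state is the steady rigid problem at the diastolic baseline
(starting near the attractor); because that steady problem is affine in the
outlet flows, it is solved exactly with one probe solve per outlet.  Beats
repeat until the cycle-to-cycle $L^2$ pressure difference drops below a
tolerance (default 1%; the conservation checks use $5\times10^{-4}$, since
the inflow/outflow cycle-integral match tracks residual periodicity error).
All reported results come from the last, periodic beat.

## Outputs

Arteriolar and capillary flows are $\beta_{1,2}(p_1-p_2)$ and
$\beta_{2,3}(p_2-p_3)$ (1/s), with $\beta$ evaluated at the same lagged time
level as the solver's frozen coefficients.  Myocardial blood flow is the
time-averaged capillary flow converted to ml·min⁻¹ per 100 g with tissue
density 1.05 g·ml⁻¹ (configurable; the normalization density is otherwise
unstated).  Diameters are $2\sqrt{A_i/\pi}$.  Sample waveforms are taken at
nodes nearest requested transmural depths along a wall-crossing ray.

## What the idealized substrate does and does not show

The built-in generator produces a slab or truncated half-ellipsoidal shell
with tagged endocardium/epicardium/base and a harmonic (Laplace) transmural
coordinate — exact on the slab, sensible on curved walls.  The test substrate
is a 20×20×10 mm slab (h = 2.5 mm, four outlets of heterogeneous radii;
sweeps use h ≈ 3.3 mm), sized so the full suite runs on one CPU in minutes.
Two deliberate exceptions: the permeability sweep uses a 40×40×10 mm wall,
because the regional-smoothing effect of $\kappa$ only registers while the
pressure-diffusion length $\sqrt{K/\beta}$ is below the domain size; and the
conservation checks integrate at $\Delta t = 1$ ms, because the first-order
scheme closes the cyclic inflow/outflow balance only to $O(\Delta t)$
(measured 1.15% of mean inflow at 2 ms and 0.58% at 1 ms on this substrate
— the same halving the step-refinement test demonstrates against the 0D
reference).
This reproduces the *mechanisms* — systolic impediment, phasic
inflow/outflow offset, transmural gradients, parameter sensitivities — but
not patient magnitudes: absolute MBF, compartment pressures and flow-ratio
values depend on the real ventricular geometry, outlet tree and personalized
waveforms, and single-patient reported values are not desk-reproducible.
Passing tests therefore certify model structure and qualitative physiology,
not patient-level calibration.

## Numerical choices and edge cases

* Arteriolar branch convention: $\Delta p = 0$ evaluates the logarithmic
  branch.  The printed sigmoid coefficients leave a 3.11% value jump there;
  it is kept by default (no silent smoothing), and `refit = TRUE` recomputes
  the three sigmoid coefficients for value/slope/curvature continuity while
  preserving the 0.003 mm² asymptote.
* Non-adjacent exchange $\beta_{1,3} = 0$ (no direct artery–capillary
  anastomoses); the general mean formula is available behind
  `allow_nonadjacent`.
* Sigmoids are evaluated via `plogis` to avoid overflow at extreme
  transluminal pressures.
* Outlet projection ties break to the lowest node index; colliding outlets
  fall back to the next-nearest free node with a warning; territory ties
  break to the lowest outlet id.
* A model with no venous sink and no compliance has a pure-Neumann null
  space; the solver reports this instead of returning an arbitrary level.
* Rigid mode freezes $A_i$ at $\Delta p = 0$ and zeroes $C_i$, making
  instantaneous inflow equal venous outflow exactly.

## Known limitations

No vascular tone or autoregulation (hyperemia only); no poromechanical
deformation of the wall; no 3D epicardial fluid dynamics (the outlet
surrogate keeps only the flux contract); constant material parameters across
the wall (no transmural heterogeneity in $(nL)_i$, $\delta_i$, $\kappa$);
right-ventricular branches and patient-image geometry are out of scope.
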