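# myoperf

Simulation of hyperemic coronary microcirculation and 3D myocardial
perfusion in the left-ventricular wall, for computational physiologists and
cardiovascular modellers who need phasic coronary flow and myocardial blood
flow (MBF) maps without resolving millions of individual microvessels.

## The model

The intramural circulation is homogenized into three superimposed porous
compartments — small arteries, arterioles, capillaries — each with its own
pressure field `p_i(x, t)` on the wall domain Ω:

```
-∇·(K_i ∇p_i) + (nL)_i C_i ∂(p_i − P_im)/∂t + Σ_j β_ij (p_i − p_j) = θ_i
```

with zero-flux boundaries.  Cardiac contraction enters through the
intramyocardial pressure `P_im = [0.9 − 0.6 λ(x)] P_LV(t)` (λ = transmural
coordinate, 0 at endocardium, 1 at epicardium).  All coefficients derive from
nonlinear pressure–area laws `A_i(p_i − P_im)` for maximally vasodilated
vessels: porosity `φ_i = (nL)_i A_i`, permeability `K_i = (κ/μ) φ_i`,
Poiseuille-type network conductance `β_i = δ_i (nL)_i A_i²`, exchange
conductance `β_ij = (β_i + β_j)/2` between adjacent compartments, and
distensibility `C_i = dA_i/d(p−P_im)`.  Blood enters compartment 1 from
epicardial coronary outlets reduced to a conductance coupling
`q_k = α (P_aortic − mean p_1 over territory k)`, distributed over perfusion
territories assigned by a radius-weighted eikonal distance (larger feeding
arteries claim larger territories), and leaves compartment 3 through a venous
sink `θ_3 = −γ (p_3 − p_ra)`.

The solver uses piecewise-linear tetrahedral finite elements with lumped
storage, first-order semi-implicit time stepping (nonlinear coefficients
lagged, pressures implicit, one sparse Cholesky solve per step), and a
relaxed fixed-point iteration (optionally Aitken-accelerated) coupling the
outlet model to the tissue model within each step.

Reproduced physiology: systolic impediment (arterial inflow peaks in
diastole, venous outflow in systole — the intramyocardial pump), transmural
gradients (stronger flow oscillation and systolic arteriolar squeeze at the
subendocardium), and 3D MBF maps in ml/min/100 g.

## Worked example

```r
library(myoperf)

mesh    <- generate_idealized_wall("slab", c(20, 20, 10), h = 2.5)
outlets <- read_outlets(system.file("extdata", "example_outlets.csv",
                                    package = "myoperf"))
params  <- load_parameters(system.file("extdata", "example_config.yaml",
                                       package = "myoperf"))

sim <- run_heartbeats(mesh, outlets, params, n_beats = 10, cycle_tol = 5e-4)
sim
glance(sim)
flow_ratios(sim)[, 1:2]
mbf_map(sim)
```

```
<perf_sim> compliant microcirculation, 4 beats (cycle diff 0.000229)
  mesh: 405 nodes, 4 outlets; mean fixed-point iterations 19.4
  mean inflow 16.06 ml/min, mean venous outflow 15.88 ml/min
# A tibble: 1 × 9
  beats cycle_diff mean_fp_iterations mean_inflow_ml_min mean_venous_ml_min
  <int>      <dbl>              <dbl>              <dbl>              <dbl>
1     4   0.000229               19.4               16.1               15.9
  mean_p1_mmHg mean_p2_mmHg mean_p3_mmHg mean_mbf
         <dbl>        <dbl>        <dbl>    <dbl>
1         98.4         77.7         64.0     381.
# A tibble: 1 × 2
  sys_dia_peak_ratio sys_dia_mean_ratio
               <dbl>              <dbl>
1              0.465             0.0761
<mbf_map> global mean 381.3 ml/min/100g over 4 territories
# A tibble: 4 × 3
     id volume_mm3   mbf
  <int>      <dbl> <dbl>
1     1      1651.  376.
2     2      1188.  381.
3     3       702.  388.
4     4       460.  391.
```

Reading the output: the wall is perfused at ~16 ml/min; the mean
compartment pressures fall hierarchically from small arteries (98 mmHg)
through arterioles (78 mmHg) to capillaries (64 mmHg); the
systolic/diastolic mean inflow ratio far below 1 is the systolic impediment
(in a rigid-microvessel run, `run_heartbeats(..., rigid = TRUE)`, the same
ratio exceeds 1 and inflow equals venous outflow instantaneously); the
hyperemic mean MBF of ~380 ml/min/100 g sits well above the ~150 ischemia
threshold.  `autoplot(sim)` draws the phasic inflow/outflow waveforms,
`sample_waveforms(sim)` extracts subendocardial / mid-wall / subepicardial
flow and diameter traces, `compare_rigid()` and `sensitivity_sweep()` run
the rigid-versus-compliant and parameter-sensitivity studies, and
`write_run(sim, dir)` exports CSV/VTU/JSON artifacts with a checksummed
manifest.

A thin command-line front end for shell pipelines is installed at
`system.file("cli", "myoperf", package = "myoperf")` with subcommands
`mesh`, `partition`, `simulate`, `compare-rigid`, `sweep`, `post`.

See the methods vignette (`vignettes/compliant-darcy-perfusion.Rmd`) for the
model, units, numerical choices and limitations.

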