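# fanflow

Wing-fanning induced flow and olfactory sampling volumes for flightless
insects.

The flightless silkworm moth *Bombyx mori* localises pheromone sources
without flying: the male fans its wings on the spot, which drives an airflow
past its antennae and entrains odour-laden air from in front of its head.
`fanflow` is an analysis pipeline for quantifying that mechanism:

1. **Kinematics** — reconstruct flapping-wing kinematics from 3D landmark
   time series (head/abdomen tips, antenna base/tip, wing root/tip and wing
   contour points): the stroke-plane angle β by total-least-squares fit of
   the wingtip path in the x–z plane, the positional angle φ and elevation
   angle θ of the wingtip relative to the stroke plane, the spanwise
   feathering (twist) angle α fitted from reprojected wing contours, cycle
   segmentation and phase averaging over all wingbeats and both wings, and
   the blade-element angle of attack

   v_h = r(−φ̇ cos α cos θ + θ̇ sin α),  v_v = r(−θ̇ cos α + φ̇ cos θ sin α),
   AoA = arccos( v_h / √(v_h² + v_v²) ),

   plus the study's dimensionless numbers: mean wingtip speed 2ΦfR,
   Re = 2ΦfR·c_m/ν and Sc = ν/D.
2. **Flow field** — hold one converged, time-periodic wingbeat cycle of
   gridded velocity snapshots and evaluate velocity anywhere by trilinear
   interpolation in space and third-order (4-node) Lagrangian interpolation
   in time, with virtual-antenna probing (21 stations from base to tip).
3. **Sampling volume** — trace massless pheromone particles backward in
   time from the antenna stations (21 release phases per cycle, 500 explicit
   Euler steps per wingbeat, 40 cycles of the periodic flow; RK4 available
   for convergence checks), and collect the per-cycle origin positions.
4. **Statistics** — head-relative distance, horizontal and vertical angle
   distributions by arrival time, violin-style summaries (type-7 quantiles,
   Tukey 1.5·IQR whiskers), the smallest angular interval holding 90% of
   particles, and a Kuiper test of angular uniformity that quantifies the
   anisotropy of the sampling volume.

Because neither the high-speed video nor the CFD fields of such studies are
generally available, the package includes a first-class synthetic-data
module: a parametric harmonic kinematics model that emits landmark tracks
(with optional camera projection and tracking noise), and analytic
incompressible flow fields (uniform, point sink, Rankine vortex, pulsed jet,
flapping dipole) plus a simplified flapping-induced intake flow with the
right scales and symmetries. Every downstream stage is tested against these
generators with closed-form oracles.

## Worked example

```r
library(fanflow)

spec  <- kinematics_spec()            # mean fanning parameters of B. mori
track <- generate_landmarks(spec)     # synthetic 3D landmark tracks
kin   <- reconstruct_kinematics(track)
kin
#> <wing_kinematics>
#>   f = 48.89 Hz, Phi = 98.0 deg, beta = 99.5 deg
#>   chi = -0.60 deg, mean theta = -23.8 deg, R = 17.3 mm
#>   averaged over 4 cycles on a 200-point cycle grid

schmidt_number()                                  #> 6
round(reynolds_number(98, 48.9, 0.0173, 0.0086))  #> 1659
glance(kin)$tip_speed_m_s                         #> 2.89  (2 Phi f R)
```

The reconstruction closes the loop on the generator: the wingbeat frequency
(48.9 Hz), amplitude (98.0°), stroke-plane angle (99.5°, i.e. nearly
vertical and tilted slightly posterior), body angle (−0.6°) and mean
elevation (−23.8°, the wing always flaps posterior of the stroke plane) are
recovered from the noise-free tracks to better than 0.5% / 0.1°.

```r
grid  <- analytic_flow_spec("uniform", frequency_hz = kin$frequency_hz,
                            box_min_m = c(-0.05, -0.06, -0.04),
                            box_max_m = c(0.12, 0.06, 0.10),
                            spacing_m = 0.006, snapshots_per_cycle = 50)
field <- generate_induced_flow(kin, grid)  # simplified intake stream tube
ant   <- virtual_antenna()                 # 21 stations, base -> tip
probe_antenna(field, ant)
#> <antenna_probe>
#>   21 stations, 200 samples per cycle
#>   tip station: mean 0.48 m/s, amplitude 0.343 m/s (dominant: 2f)

tr  <- backtrace(field, ant, trace_config(n_cycles = 10))
vol <- mirror_volume(assemble_sampling_volume(tr, head_m = c(0.015, 0, 0.012)))
glance(vol)
#> # A tibble: 1 x 6
#>   n_origins n_truncated mirrored median_distance_mm extent90_deg anisotropy_p
#> 1      8820           0 TRUE                   35.6         48.8            0
```

Flow speed along the antenna grows from base to tip and oscillates at twice
the wingbeat frequency (two stroke reversals per cycle). The mirrored
two-wing sampling volume is strongly anisotropic (Kuiper p ≈ 0): 90% of the
particles that reach the antenna within 10 wingbeats started inside a ~49°
horizontal cone in front of the head, a median of ~36 mm away — exactly the
property that lets a fanning moth read the direction of its own heading
from a pheromone hit. `autoplot()` methods draw the angle series, probe
series and violin summaries; `run_pipeline()` chains every stage from one
config and writes a markdown report with all figures:

```r
res <- run_pipeline(list(seed = 1), out_dir = "fanflow_run")
```

A thin command-line wrapper over the same functions ships in
`inst/cli/fanflow.R` (`run-all`, `synth-kin`, `reconstruct`, `validate`).

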