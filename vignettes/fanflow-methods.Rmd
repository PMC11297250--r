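---
title: "Models and methods behind fanflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fanflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fanflow)
```

`fanflow` quantifies how a wing-fanning insect, the flightless silkworm moth
being the motivating case, manipulates the air around its antennae and which
volume of space it thereby samples for odour molecules. This vignette
documents the models, the numerical choices and the open design decisions,
in the order the pipeline runs them.

## Coordinate conventions and angle definitions

The lab frame is right-handed with x anterior (the direction the head points
at rest), y to the animal's left, z up and the floor at z = 0. Angles are
radians internally and degrees at every I/O boundary, because that is how
the quantities are reported in the field.

The **stroke plane** passes through the wing pivot and is inclined from
horizontal by the stroke-plane angle β, fitted by total least squares (first
principal direction) of the wingtip path projected onto the x–z plane.
Ordinary regression of z on x would be singular at β = 90°, and measured
fanning stroke planes are nearly vertical (around 100°), so the total
least-squares form is a requirement, not a refinement. The fit is invariant
under rigid translation and under uniform resampling of the path.

Within the stroke-plane frame, the **positional angle** φ is the angle of
the pivot-to-tip projection from the horizontal measured inside the stroke
plane, and the **elevation angle** θ is the signed deviation of the
pivot-to-tip vector out of the plane, negative posterior of it (fanning
wings flap posterior of the stroke plane throughout the cycle, so θ stays
negative). A pivot-to-tip vector normal to the stroke plane makes φ
undefined; such samples are flagged degenerate and excluded from averaging.

The **feathering angle** α(r) is the rotation of the wing cross-section at
spanwise station r about the spanwise axis, measured from the stroke plane.
The **body angle** χ is the elevation of the head-to-abdomen axis, positive
head-up; the sign convention is an assumption documented here because the
figure geometry implies it without stating it.

## Sectional velocities and angle of attack

With spanwise location r and angular rates φ̇ and θ̇, the sectional velocity
components parallel and perpendicular to the cross-section are

$$v_h = r(-\dot\phi \cos\alpha\cos\theta + \dot\theta \sin\alpha), \qquad
  v_v = r(-\dot\theta \cos\alpha + \dot\phi \cos\theta \sin\alpha),$$

and the angle of attack is $\mathrm{AoA} = \arccos(v_h/\sqrt{v_h^2+v_v^2})
\in [0, \pi]$. Two remarks:

* The component pair is implemented exactly as printed in the source
  literature for this analysis. As printed it is not an orthogonal rotation
  of the section-frame velocity: the speed identity
  $\sqrt{v_h^2+v_v^2} = r\,\lVert(\dot\phi\cos\theta, \dot\theta)\rVert$
  holds when one rate vanishes or when α ∈ {0°, 90°}, but a mixed-rate,
  oblique-twist state picks up a $-2\dot\phi\dot\theta\cos\theta\sin 2\alpha$
  cross term. A true rotation would need one sign flipped. We keep the
  printed form because it is the defining formula of the quantity being
  reproduced; the property tests assert the identity only in the regimes
  where the printed pair satisfies it.
* AoA values above 90° occur whenever the flow meets the anatomically
  other face of the section. Published plots stay below ~90°, but the
  convention is not stated, so both series are emitted: the raw [0°, 180°]
  values and a folded variant mapping AoA → 180° − AoA into [0°, 90°].
  Plots default to the folded series.

Angular rates of the phase-averaged cycle are obtained by spectral (FFT)
differentiation, which is exact for band-limited periodic series; centered
second-order finite differences are the documented fallback for raw,
non-averaged series.

## Cycle segmentation and averaging

Wingbeat cycles are delimited at maxima of φ — the start of the downstroke,
so the downstroke occupies normalized time t̂ ∈ [0, 0.5). Maxima are
detected on a low-pass-filtered copy of the series (FFT filter, cutoff at
three times a preliminary spectral estimate of f) and refined to sub-frame
accuracy by quadratic interpolation; without the refinement the frequency
estimate would be quantized at the frame rate. Each cycle is resampled onto
a common 200-point t̂ grid by cubic spline (linear interpolation would bias
the peaks of a ~49° amplitude sinusoid by more than the 0.1° recovery
budget), then averaged across cycles and across the left and right wings.
The per-side angle conventions already mirror the right wing through the
sagittal plane, so the series average directly. The wingbeat amplitude Φ is
the peak-to-peak excursion of the averaged φ with quadratically refined
extrema, and f comes from the mean refined cycle duration.

## Sagittal deconfliction

Averaged kinematics can leave the wing slightly penetrating the sagittal
symmetry plane (typically from an animal tilting during recording). The fix
mirrors the established practice: rotate the whole wing motion about the
horizontal axis through the wing root directed toward the back of the body
by the smallest angle that restores clearance at every phase, typically a
few degrees and rejected above 15° as mis-registration. The rotation is
found by a 0.01° brute scan of the posed wing cloud (tip plus section
leading/trailing edges on a 50-phase grid); being a time-constant rigid
rotation it leaves wing speed untouched. Rotations compose additively on
the stored total, so repeated calls are consistent. Only dorsal
interference (the clap region) is fixable this way — a ventral point
penetrating the plane below the root cannot be rotated clear, which is
geometrically faithful.

## Synthetic landmark generator

The generator is the package's stand-in for two-camera high-speed
photogrammetry and defines the study conditions for every test:

* wing length 17.3 mm, wingbeat frequency 48.9 Hz (reported in the source
  table under a degree unit by an evident typo; it is a frequency),
  amplitude 98.0°, stroke-plane angle 99.5°, body angle −0.6°, mean
  elevation −23.8°;
* positional angle: a single sinusoid with mean 0° (the mean position is
  not reported; symmetric about horizontal is the neutral choice);
* elevation: amplitude 5° at f, a realistic magnitude for a fanning stroke,
  phased in quadrature with φ. The quadrature phasing makes the
  total-least-squares stroke-plane fit exactly unbiased for noise-free
  input (the covariance integrand is antisymmetric under u → π − u over a
  full cycle), so the generation→reconstruction identity is clean;
* feathering: 90° plus two harmonics with amplitudes growing linearly along
  the span (25°·r/R at f, 10°·r/R at 2f), the simplest family that
  reproduces a passively twisting wing whose twist is larger near the tip
  and during the upstroke;
* tracking noise: isotropic 3D Gaussian, because manual-click error has no
  preferred axis; seeded and bit-reproducible.

Camera models are plain pinhole rigs; the real camera geometry is not
published, so fixtures use plausible wide-baseline placements — only
round-trip properties (projection/DLT-triangulation inverses, calibration
error propagation) are asserted, and those are geometry-independent.
Feathering recovery from 2D contours poses the model wing with the known
φ, θ and a candidate spanwise-linear twist, reprojects, and minimises the
summed squared pixel distance with a quadratic penalty on second spanwise
differences; the penalty vanishes on linear twists, so a noise-free linear
profile is recovered without bias (the supplementary details of the original
procedure are not public, so the smoothing is our design).

## Flow fields and interpolation

A `flow_field` is one converged wingbeat cycle of velocity snapshots on a
structured Cartesian grid, treated as exactly periodic — the protocol of
repeating a converged cycle rather than simulating tens of seconds of flow.
Velocity at an arbitrary point and time is trilinear in space on each of
the four temporally nearest snapshots (indices wrapped periodically, two
back and two forward of the query) followed by third-order Lagrangian
interpolation in time. The scheme is exact for fields trilinear in space
and cubic in time, linear in the field, and periodic to machine precision;
with 50 snapshots per cycle the temporal error for a sinusoidal component
is below (2π/50)⁴.

Out-of-domain queries follow a configurable policy: `error` for tracing
(the trajectory is then truncated and flagged) and `freeze` (clamp to the
boundary) for probing. The published simulation domain was effectively
unbounded for this purpose; desk-scale grids are not, so the policy is a
first-class parameter.

The on-disk dialect is a long CSV of node velocities with a JSON sidecar
(dims, origin, spacing, period); this is the plain-text array-archive
dialect of the format family, chosen because no NetCDF bindings are
assumed at run time.

The **synthetic induced flow** is an axisymmetric intake stream tube along
the stroke-plane normal — the anterior axis for a near-vertical stroke
plane — with instantaneous centreline speed equal to a fixed entrainment
fraction (default 0.25) of the instantaneous wingtip speed, a Gaussian
radial profile peaking under the wingtip ring (radius 0.8 R, width 0.75 R)
and algebraic axial decay with scale 2 R. Flow on the anterior side moves
toward the moth: that sign is what makes backward-traced particles
originate in front of the head, and the wingtip-ring peak is what makes
probe speed grow from antenna base to tip, both properties the analysis
must reproduce. Because |φ̇| has two maxima per cycle the probe oscillates
at 2f, and the cycle mean of the wingtip speed of a sinusoidal stroke is
exactly 2ΦfR, so the field scales linearly with amplitude and frequency.
This is a demonstration flow with the right scales and symmetries; it is
not a Navier–Stokes solution, and quantities that depend on the detailed
CFD near field (force budgets, the absolute size of the sampling cone) are
outside what it can reproduce.

## Backward particle tracing

Pheromone particles are massless tracers advected by the local flow with
molecular diffusion neglected — at the Schmidt number of bombykol in air
(Sc = ν/D = 6.0) advection dominates, though diffusion would widen the
volume somewhat. The reference protocol releases particles at the 21
antenna stations, 21 times per cycle at equal phase intervals, and
integrates dx/dt = −u(x, t) in reversed time with step T/500 for 40 cycles
of the periodic field, recording positions at whole-cycle offsets. The
default integrator is explicit Euler — displacement equals velocity times
time step, the quoted advection rule — with classical RK4 available;
measured convergence orders on a solid-body rotation field (trilinear-exact,
so the grid contributes no error) are 1.02 and 4.00 against the analytic
rotation. "Streak line backwards" is realised as backward path lines of
particles arriving at fixed phases; in a periodic field the union over the
21 phases is the meaningful reading of a backward streak surface.
Trajectories that exit the grid are truncated, flagged and excluded from
statistics by default; trajectories that would cross the floor are treated
the same way (near-floor speeds are small under no-slip, so this is rare),
and body surfaces are not modelled.

A time-reversal check re-advects recorded origins forward with the same
scheme: exact in constant fields, and below 10⁻³ of the path length with
RK4 on smooth vortex fields at the reference step size.

## Sampling-volume statistics

Origins are expressed head-relative: distance; horizontal angle, the signed
azimuth from the resting heading measured in the horizontal plane, positive
toward the simulated (left) wing so a single-wing volume occupies one side;
and vertical angle. Whether the reference heading should be the
instantaneous or the resting body axis is not specified in the source; the
resting heading is used. Origins straight above or below the head have an
undefined azimuth and are excluded from horizontal-angle summaries only.

Violin-style summaries per 5-cycle arrival bin use linear interpolation of
order statistics (quantile type 7) and whiskers at the extrema after
removing Tukey outliers (1.5 · IQR beyond the quartiles) — the "without
outliers" rule is not defined in the source, and Tukey fences are the
standard whisker convention. The angular extent is the width of the
smallest (circularly wrapped) interval containing a coverage fraction,
default 90%; for mirrored two-wing volumes the interval is symmetrized
about dead ahead and reported two-sided, which makes the two-wing extent
exactly twice the single-wing extent of a one-sided distribution — the
30° → 60° doubling logic. Anisotropy is tested with Kuiper's statistic
(the rotation-invariant Kolmogorov–Smirnov variant appropriate for angles)
against uniformity on the angular domain; an isotropic-sink fixture with
10⁴ particles calibrates the null (p > 0.01) and an anterior-intake fixture
the alternative (p < 10⁻⁶).

## Problem sizes and determinism

The test suite and the acceptance script run the reference release protocol
(21 × 21 × 500 steps) with cycle counts chosen per purpose: 5 cycles for
round-trip and radius-law oracles, 40 cycles — the full protocol — for the
end-to-end run, whose grid (6 mm spacing over roughly a 0.22 × 0.18 ×
0.18 m box, 50 snapshots) is sized so that no trajectory of the packaged
configuration is truncated. Everything downstream of the single config seed
is deterministic: tracing has no randomness at all, and seeded generation
is bit-reproducible, so identical runs produce byte-identical reports and
matching provenance hashes.

## Known limitations

* The induced-flow generator is a parametric stand-in; absolute magnitudes
  of distances and cone angles from the end-to-end synthetic run
  characterise the generator, not a simulated moth. Passing tests show the
  pipeline's operations are correct, not that real fanning flow looks like
  the stream tube.
* Antenna aerodynamics (boundary layers, sensilla leakiness), environmental
  wind and turbulence, molecular diffusion and body surfaces are out of
  scope throughout.
* The feathering fit assumes known 2D–3D correspondence of contour points,
  which synthetic data provides; real clicked contours would need a
  correspondence step first.
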