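---
title: "Methods: semi-static microswarm steering in a bifurcating network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-static microswarm steering in a bifurcating network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microsteer)
```

This vignette documents the physical model, the numerical choices, and the
design decisions behind `microsteer`, in the spirit of a methods section: what
is modelled, what is deliberately not, and what the packaged tests do and do
not demonstrate.

## Physical model

### Semi-static force balance

The governing dynamics of a magnetically steered nanoparticle is a Newtonian
force balance between the magnetic pulling force, Stokes drag, and wall
friction. At the scales simulated here (75 nm particles, micrometre-scale
chains, water), the viscous relaxation time `m/(3πηd)` is orders of magnitude
shorter than the 0.002 s integration step, so the inertial term is never
evaluated: within every step the drag force balances the applied force and the
particle velocity is

`v_p = v_f + F_mag / (3 π η d)`.

This *semi-static* assumption is what makes a real-time-capable simulator
possible: each step costs one flow-field lookup and one vector sum per
particle. Gravity and buoyancy are excluded — the simulated plane is the
horizontal top-down view through the vessel centrelines — and particle–particle
interactions are not modelled: the swarm is a cloud of independent particles
sharing one chain model and one global actuation field.

The drag diameter is the *individual particle* diameter `d`, following the
drag law literally (the chain model enters only the magnetic force). This
makes the magnetic drift at the full 1000 mT/m command about 1.8 mm/s against
carrier flows of 5–60 mm/s, which is what gives the steering problem its
character: the gradient cannot fight the flow head-on and must instead place
the swarm on favourable streamlines. A configuration switch
(`drag_diameter_mode = "equivalent_Deq"`) applies the chain-equivalent
diameter instead, for sensitivity studies.

### Chain model and magnetization

A chain of `n` particles of diameter `d` is treated as a cylinder of diameter
`d` and height `n d`, represented in the force law by its volume-equivalent
sphere:

`D_eq = d (3 n)^(1/3)`, `V_eq = (4/3) π (D_eq / 2)^3 = (π/2) n d^3`.

With the defaults (`d` = 75 nm, `n` = 12000) this gives `D_eq` = 2.48 µm and
`V_eq` = 7.95e-18 m³. The algebraic identity `V_eq = (π/2) n d³` is asserted
as a unit test.

Magnetization per unit mass in the unsaturated low-field regime follows the
empirical power law `M_m = 1 + 19 (10 B)^0.16` with `B` in mT, which yields
33.74 emu/g at the 3 mT operating field. emu/g is numerically A·m²/kg;
multiplying by the material density (4800 kg/m³) gives volumetric
magnetization, so the force is

`F = V_eq M_m ρ ∇B`,

with the commanded gradient converted from mT/m to T/m. The commanded
"gradient" is treated as a flux-density gradient throughout, so the vacuum
permeability never appears numerically; this is the only reading that is
dimensionally consistent with the parameter table and the emu/g→SI
conversion. The field (and hence the gradient) is spatially uniform across
the workspace.

Chain length grows with the field. Only one anchor is recorded (12000
particles at 3 mT), so the package default is the linear rule
`n(B) = round(4000 B)` clamped to `[1, 40000]`, exposed as a pluggable hook
(`chain_length_for_field(rule = ...)`); it is a convention, not a measured
law, and studies that vary `B` should treat it as such.

### Vessel network and flow

The testbed geometry is a comb: a straight main channel of five 5 mm
segments with a downward 5 mm branch at each of the four junctions — one
inlet, five outlets, all vessels 1 mm wide. Published descriptions of such
testbeds give the topology and vessel dimensions but not vertex coordinates,
so the comb layout here is an explicit reconstruction: straight main channel
along +x, branches at a configurable angle (default 90°, pointing down),
origin at the inlet-gate centre, SI metres. The goal outlet defaults to the
far end of the main channel — the hardest target, requiring the swarm to
survive every branch junction, and the configuration consistent with
flow-loss behaviour at the first bifurcation dominating failure.

The carrier flow is an analytic Hagen–Poiseuille network solution standing in
for a finite-element CFD model. Each vessel is a 2D slit with conductance per
unit depth `G = w³/(12 η L)` (the slit `w³` law rather than the circular-pipe
`w⁴` law, because the simulated plane lies on the vessel centrelines of a 2D
model); nodal pressures solve the linear conservation system with all outlets
at a common reference pressure and inlet inflow `Q_in = (2/3) v_c w`.
Profiles across each vessel are parabolic with no-slip walls. With equal
vessel dimensions this gives a strongly biased split: the first branch takes
21/34 ≈ 62 % of the inlet flow, the second 8/34, and only 1/34 reaches the
far outlet — the physical reason low-gradient steering fails at the first
junction.

Velocities are served from a regular-grid lookup table (default spacing
75 µm, ≈ 7600 in-lumen points for the default network, mirroring the
several-thousand-point tables used by real-time platforms). Sampling is exact
nearest-neighbour: because the table points are grid nodes, the snapped node
is the true nearest neighbour whenever it is in-lumen, and an expanding ring
search recovers exactness otherwise; a brute-force linear scan oracle checks
this in the tests. Points at junction interiors take the velocity of the
nearest vessel centreline — a deliberate simplification (no recirculation
detail): the fidelity target is the lookup-table mechanism, not CFD. An
externally computed field can be substituted via the documented CSV format
(`x_m, y_m, u_m_per_s, v_m_per_s`).

### Two-rate loop, collisions, friction

Integration runs on two nested loops. The *major loop* (period 0.05 s, the
20 Hz cadence of an interactive input device) reads the steering input once,
caps it to the gradient limit, and logs time, input, command and positions.
The *minor loop* runs 25 physics steps of 0.05/25 = 0.002 s per major step
with all forces held constant. The package runs the loop free-running (batch)
rather than wall-clock paced; trajectories are timer-independent by
construction, so this changes nothing but the ability to run faster than real
time.

A proposed step is first tested against the outlet gates (a crossing retires
the particle and records its outlet and exit time — gates lie on the polygon
hull, so this test must precede the wall test); otherwise, if the step leaves
the lumen (boundary-inclusive even-odd point-in-polygon test), the crossing
point is located by bisection to 1e-9 m, and the residual displacement and
velocity are mirrored about the tangent of the boundary edge nearest the
outside point. Bisection plus nearest-edge selection was chosen over exact
edge intersection for robustness at junction corners, where a step can cross
the extension of several edges; the nearest-edge rule is the corner
tie-break. Up to 4 chained reflections are attempted, after which the
particle is parked on the boundary and marked `stuck` — a corner-trap
safeguard that essentially never fires in the comb geometry. Wall contact
applies friction by attenuating the tangential velocity component by
`(1 − mu)`; `mu = 0` (the default, matching elastic collision behaviour)
preserves speed exactly, and `mu = 1` is fully dissipative in the tangent.
The same attenuation applies to the reflected residual displacement so
position and velocity stay consistent within the step. No static-friction
threshold is modelled: the below-threshold "swarm stays stationary" regime
observed experimentally at very low gradients is out of scope.

Boundary points count as *inside* the lumen. This convention is load-bearing:
a swarm pressed against a wall by the gradient rests exactly on the boundary
for thousands of consecutive steps, and an exclusive convention would
misclassify it as escaping.

## Steering layer

Policies are pure functions of `(state, graph, goal, t)` returning a raw
input of magnitude ≤ 1. Three are packaged: a constant input, a log replay
(which reproduces a recorded run bit-identically under the same seed), and a
waypoint autopilot standing in for an experienced human operator.

The autopilot is deliberately simple and fully deterministic:

1. **Climb** — while any active particle is below a clearance band
   (0.1 `w`) above the main centreline, push straight up. The junctions'
   suction wedges occupy the lower half of the main channel, so the one
   robust strategy (for a human or a script) is to pin the swarm against the
   goal-side wall before the first junction arrives.
2. **Cruise** — steer the active-swarm centroid toward corridor waypoints
   (0.3 `w` above the centreline, one above each junction on the path),
   always targeting the first waypoint at least half a width ahead. The
   small downward component of the resulting direction regulates the swarm
   around the corridor height.
3. **Final approach** — past the last junction, steer toward a point beyond
   the goal gate until every particle has exited.

One design deviation is worth recording: a pure centroid-based controller is
not sufficient for the climb phase. The centroid saturates near the wall
while trailing particles are still below the centreline, and handing over to
cruise at that moment loses the stragglers to the first branch. The climb
criterion therefore uses the swarm *minimum* height — still a single global
observation feeding a single global actuation, but one that bounds the whole
swarm rather than its mean. With it, the autopilot reaches 100 % success at
the full-gradient condition; without it, roughly half the swarm is lost.

The haptic mapping (`haptic_workspace_mapping`) is a pure function from a
device handle displacement in a ±5 cm planar workspace to the unit-clamped
raw input, with the device's recentring spring (4 N at full deflection)
returned as an advisory value. Device drivers and force rendering are out of
scope; recorded-input replay covers the teleoperation use case.

## Study harness and conditions

The success metric is the percentage of the released particles whose exit
gate is the goal outlet. Sweeps run 10 independently seeded repeats per
parameter value (seeds are the only randomness: seeding draws positions, and
nothing after seeding consumes random numbers) and report mean and *sample*
standard deviation, as spread — error bars larger than the 0–100 range are
reported as-is.

Fixed study conditions, chosen once:

* **Seeding.** The clump square (side 0.8 mm, inside the 1 mm channel) is
  centred 1 mm downstream of the inlet on the centreline, upstream of the
  first junction. The second square for split mode is centred 6.5 mm
  downstream, between the first and second junctions; split mode places
  ⌈N/2⌉ particles in the clump square and the rest in the second square.
* **Runs** are capped at 30 s of simulated time; particles still in transit
  count as failures. At the gentlest flow (0.005 m/s) full transit takes
  ≈ 24 s, so the cap is not binding for steerable conditions but prevents
  unbounded runs when particles park in near-stagnant corners.
* **N = 500** particles, field 3 mT, water viscosity 1e-3 Pa·s.

The packaged acceptance checks run the two headline conditions at full size
(500 particles × 10 seeds each): 0.02 m/s flow at 1000 mT/m (expected 100 %)
and 0.005 m/s at 500 mT/m (expected ≥ 99.7 %). The monotone-trend checks —
success non-increasing in flow velocity `{0.005, 0.03, 0.06}` m/s at
500 mT/m, non-decreasing in gradient limit `{100, 500, 1000}` mT/m at
0.02 m/s, 10 seeds each — use 200 particles per run, a size at which the
success percentages are stable to a few points while keeping the whole suite
fast on one CPU.

## Digital-shadow validation utilities

The validation workflow for a physical counterpart experiment (particles on
a flat substrate under a uniform gradient, no flow) is implemented as
computations: `time_to_travel` gives the time for the swarm to cover a fixed
distance — closed-form `distance / |v_p|` under the semi-static model, with a
stepping variant that agrees to < 0.1 % as a cross-check; a zero-force input
returns the *stationary* flag rather than a number, mirroring the
below-threshold experimental case. `binarize_and_centroid` reproduces the
frame-processing chain (threshold, default Otsu via `EBImage::otsu`; dark
foreground; centre of mass; optional px→mm scale), and
`percentage_difference` is the deviation measure `mean(100 |sim − exp| /
exp)` for comparing simulated and measured travel times. Measured travel
times are user-supplied (they are not shipped with the package), so the
simulation–experiment deviation is a workflow this package enables, not a
number it asserts.

## What the tests do and do not show

The synthetic testbed emulates: the comb topology and its dimensions, the
flow magnitudes and their strongly biased junction splits, the two-rate
timing, the chain force model at the recorded operating point, and seeded
stochastic release. It does **not** emulate: real vascular geometry
(curvature, taper, elasticity), pulsatile or non-Newtonian flow,
recirculation at junctions, chain formation/breakup dynamics, Brownian
motion, particle–particle coupling, or human input. Passing tests therefore
demonstrate correctness of the implemented model and reproducibility of its
study harness — not clinical realism, and not human-operator performance
(the autopilot is a scripted stand-in whose absolute success rates are its
own, even where its trends mirror operator studies).

## Numerical choices (summary)

| Quantity | Value | Note |
|---|---|---|
| Minor timestep | 0.002 s | 0.05 s major period / 25 |
| Bisection tolerance | 1e-9 m | collision crossing point |
| Boundary inclusion band | 1e-12 m | point-on-edge tolerance |
| Lookup spacing | 7.5e-5 m | ≈ 7600 points on the default network |
| Reflection attempts | 4 | then `stuck` |
| Flow conservation check | 1e-12 · Q_in | junction balance in tests |
| Simulated-time cap | 30 s | in-transit particles count as failures |

Known limitations worth restating: nearest-neighbour flow sampling is
piecewise constant (bilinear interpolation was considered and left out — the
reference platforms load point tables, and the grid is fine relative to every
length scale that matters here); junction velocities ignore recirculation;
the autopilot is tuned for comb-like geometries with a goal on the main
channel or a branch, not for arbitrary networks loaded from JSON.
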