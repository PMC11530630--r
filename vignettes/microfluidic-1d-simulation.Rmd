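---
title: "1D lumped-element simulation of microfluidic networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{1D lumped-element simulation of microfluidic networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microflow)
```

## The abstraction

`microflow` simulates pressure-driven microfluidic chip networks at the
lumped-element ("1D") level. The abstraction applies when the flow is
laminar, fully developed, viscous and incompressible — the usual regime at
micron scales — so that each straight channel obeys a linear
pressure-flow relation, ΔP = Q·R, the hydraulic analog of Ohm's law. A
channel network then maps onto a resistor circuit: junctions become nodes,
channels become resistances, flow-rate pumps become constant current
sources and pressure pumps become voltage sources, with mass conservation
playing the role of Kirchhoff's current law.

For a rectangular cross-section of width $w$, height $h$ ($h/w < 1$),
length $l$ and carrier viscosity $\mu$,

$$R = 12\left[1 - \frac{192\,h}{\pi^5 w}\tanh\!\frac{\pi w}{2h}\right]^{-1}
      \frac{\mu\,l}{w h^3},$$

which reduces to $12\mu l/(w h^3)$ as $h/w \to 0$ (verified to 1% for
$h/w \le 0.01$ in the tests). The single-term truncation loses accuracy as
the section approaches a square, so the constructor warns above
$h/w = 0.9$ and rejects $h/w \ge 1$; inputs given in the tall orientation
are normalized by swapping $w$ and $h$, which preserves the physical
cross-section. Non-rectangular sections, channel compliance, inertia and
gravity are out of scope.

All internal quantities are SI (m, s, Pa, m³/s, Pa·s, m²/s, mol/m³); the
JSON reader converts unit-annotated inputs on load, because the resistance
and transport formulas are dimensionally consistent only in one system.

## Flow solve

Node pressures are computed by Modified Nodal Analysis: unknowns are the
pressures of all non-ground nodes plus one auxiliary flow per pressure
pump; equations are per-node mass conservation plus one pressure
constraint per pressure pump. Exactly one node is the pressure reference
(ground, 0 Pa); if the user marks none, the first sink is used with a
warning — sinks are open outlets at atmospheric pressure, which resolves
the otherwise ambiguous boundary condition in favour of the physically
natural one. The solve is dense and direct: these networks are far below
10³ nodes, so robustness beats sparse machinery. Channel resistances are
floored at $10^{-30}$ Pa·s/m³ (physically R > 0 always) so a
zero-resistance input cannot make the system singular; genuinely floating
subnetworks are reported as structured errors and flagged by
`validate_network()`.

Sign conventions are fixed once: channel flow is positive from `node_a` to
`node_b`, pumps drive from `node_from` to `node_to`. Mass-conservation
residuals (normalized by the largest flow in the network, so quiescent
dead ends do not report noise-over-noise) are exposed by
`check_conservation()` and sit at rounding level.

## Event-driven transport

Between flow solves the state advances to the next *event*, the earliest
of:

* a configured fixed step (`sim_config(fixed_step=)`),
* a slug interface reaching a channel end — for a uniformly filled
  channel this is the full residence time $t = V/Q$; a virtual interface
  is scheduled whenever the inlet mixture differs from the slug adjacent
  to the inlet,
* a droplet's leading edge reaching a channel end,
* a scheduled injection change (mixture windows, droplet injections),
* the simulation horizon.

During the step every interface in channel $c$ moves downstream by the
fraction $|Q_c|\,\Delta t/V_c$; because no interface can overshoot a
channel end, plug-flow advection is *exact* — halving the fixed step does
not move arrival times (asserted in the tests). Channels with
$|Q| \le q_\varepsilon = 10^{-18}$ m³/s are treated as quiescent, far
below any physical flow but safely above pressure-solve rounding noise.

Positions are stored as fractions of channel length in $[0,1]$ with 0 at
`node_a`; transport code always operates in flow coordinates and flips the
profile for negative flows. Interface positions are re-chained after every
step so the slugs partition $[0,1]$ exactly (no drift), and adjacent slugs
whose concentrations agree within $10^{-12}$ relative per species are
merged, bounding the slug count over long runs.

Simultaneous events (within $10^{-12}$ s) are merged and processed
deterministically: injections first, then droplet boundaries in droplet-id
order, then transits. The flow field is re-solved after every
resistance-changing action inside a merged batch, so later branch choices
see the updated field. Between events the solver result is reused while
the effective resistance vector is unchanged — numerically identical to
re-solving after every event, which is the semantics the engine presents.

A run terminates at the horizon, or earlier when the state provably cannot
change any more: all droplets have exited, no injection boundary is
pending, no membrane is attached, and every channel is uniformly filled
with its own inlet mixture. Pure-advection studies therefore stop
themselves right at steady state.

## Mixing

All streams entering a node mix instantaneously and completely; per
species the outflow concentration is the flow-weighted mean
$C_0 = \sum_i C_i Q_i / \sum_i Q_i$, and every channel leaving the node
receives that same $C_0$ (perfect mixing, then splitting — the only
reading consistent with a single outlet concentration). The model assumes
non-reactive, fully miscible fluids; lateral and axial diffusion along the
channel are neglected in the convection-dominated regime, so a slug's
composition changes only through membrane exchange. Mixtures are passive
scalars: they do not alter the carrier viscosity or the channel
resistance. A node cannot be both an injection boundary and an interior
junction; validation rejects that case because the mixing rule is
undefined there.

Steady outlet concentrations of any loop-free network equal the
closed-form cascade of the node-mixing rule applied in flow order
(`cascade_concentrations()`), which is pure algebra on the solved flow
field; the event-driven transient must relax to it exactly, and the
acceptance suite verifies agreement to $10^{-9}$ over randomized
splitter trees with 2–8 outlets.

## Droplets

A droplet of length $l_d$ adds
$R_{Droplet} = b\,a\,\mu\,l_d/(w h^3)$ to its channel, where $a$ is taken
to be the geometric prefactor of the rectangular-channel resistance. That
choice makes the expression dimensionally consistent with the channel
formula and gives $b$ a clean meaning: a droplet with $b = 1$ resists
exactly like an equal-length plug of carrier, and the experimental range
$b \approx 2\!-\!5$ expresses the excess of the dispersed phase. The
default is $b = 3$, the midpoint of that range, overridable per droplet.
A channel holding $n$ droplets has $R^* = R + \sum_i R_{Droplet,i}$.

Droplets move with the channel flow (speed $Q/(wh)$; the resistance
coupling and the kinematics are one model). At a junction the droplet
enters the outflow channel with the highest instantaneous flow rate — the
path of least resistance — with ties broken by channel id. Transfers are
atomic: a droplet is booked to exactly one channel at a time and never
contributes resistance to two channels while straddling a junction;
droplets longer than a channel are rejected. Formation, breakup,
coalescence, interfacial tension and decoupled droplet-speed models are
out of scope. Injection schedules may be given directly as times or as
spacing distances $d_i$, converted through the injection channel as
$t_i = t_{i-1} + d_i w h / Q_{in}$.

The whole event pipeline is validated against a brute-force enumerator
(an independent implementation that re-solves the full network after
every candidate event) on randomized ring networks: event sequences,
times and payload paths must match exactly.

## Membranes and tanks

A membrane patch couples a channel to a well-stirred-like tank. Its
geometry is lumped into a resistance by the pore-discovery model:
$R_d = 1/(4 r D)$ per pore, $N_p = (A_m/A_p)\,\phi$ pores with
$A_p = \pi r^2$, plus the effective-thickness term
$R_{th} = th/(A_m D)$, giving $R_M = R_d/N_p + R_{th}$ per species
(diffusivity $D$). The transmembrane molar flow is then simply
$J = \Delta C / R_M$. Zero porosity yields an explicit impermeable result
(`Inf`), under which tank concentrations provably never change. Note a
perhaps counter-intuitive property of the model: at fixed area and
porosity the pore term scales as $\pi r/(4 A_m \phi D)$, so many small
pores transmit better than few large ones — the transparent limit is
fine pores, high porosity, vanishing thickness. The model enum is
deliberately a single kind (`pore_discovery`); alternative resistance
models remain out of scope with the interface reserved.

The tank mirrors the channel's slug structure: each channel slug has an
aligned tank slug, and each aligned pair exchanges through a membrane-area
share proportional to its length fraction. Because the area share and the
compartment volumes both scale with that fraction, every pair relaxes with
the same rate constant $\lambda = (1/V_c + 1/V_t)/R_M$, and a uniform
channel reproduces the single-tank balance
$V_t \, dC_t/dt = \Delta C / R_M$ exactly. The pair ODE is integrated
with classic fourth-order Runge-Kutta; the engine step is internally
subdivided so that $\lambda h \le 0.05$, which keeps the local error near
rounding level, rules out overshoot of the linear flux law, and preserves
the linear invariant (total moles per pair) to $10^{-12}$ per step.
Integrating the coupled pair with full RK4 — flux re-evaluated at the RK4
stages — subsumes the simpler "flux from the previous concentration
difference" rule and is strictly more accurate.

When the channel advects, the tank has no advective outflow of its own:
its profile is rotated by the same fraction and material that would leave
at the downstream end re-enters at the front in order
(`mirror_and_recycle()`), so tank moles are conserved exactly. This
mirroring prevents species from short-circuiting through an ideally mixed
tank and effectively jumping ahead of the channel flow. After rotation
both profiles are re-partitioned on the union of their interfaces and
merged jointly (a pair of cells merges only if both the channel and the
tank sides agree), keeping the two profiles aligned one-to-one at all
times. Fick's first law is not discretized spatially; it is embodied in
the resistance model, which is the same reduction the lumped abstraction
applies everywhere else.

## Fixtures and what they do (and do not) show

The package generates its study systems in code:

* `make_y_junction()` — the elementary equal-flow merge; steady outlet
  composition is exactly 50/50.
* `make_gradient_tree(n)` — a triangular splitter lattice with two inlets
  (tracer/buffer) and $n$ outlets; returns the closed-form cascade
  prediction alongside. Randomized stage lengths (uniform in 0.5–2 mm at
  100 µm x 50 µm cross-section) skew the splits. This is a desk-scale
  analog of tree-type gradient generators, not a replica of any published
  device geometry.
* `make_ring_network(n)` — an injection channel feeding `n`
  bypass/module stages; default lengths satisfy
  $R_{byp} < R_{mod} < R_{byp} + R_{Droplet}$, so a header droplet
  parked in the bypass flips the next droplet's branch choice — the
  routing mechanism of time-sensitive ring designs, again as an analog.
* `make_membrane_channel()` — one channel with constant-concentration
  inflow and a full-length membrane patch to a tank. Defaults: 200 µm x
  100 µm x 10 mm channel at 1 nL/s, pore radius 0.5 µm, porosity 0.01,
  thickness 100 µm, tank volume 1 µL (10⁻⁹ m³), tracer diffusivity
  10⁻⁹ m²/s — giving $R_M \approx 7\times10^{10}$ s/m³ and a tank time
  constant $\tau = V_t R_M \approx 70$ s, a realistic hour-scale organ
  chamber loading compressed to minutes so the three-time-constant run
  stays cheap. The fixed step defaults to half the channel residence time
  and divides it exactly, so rotated tank interfaces land on a fixed grid
  and slug counts stay bounded.

Passing on these fixtures shows that the *numerics* implement the model
faithfully — it does not validate the abstraction against a physical
device. Fabrication tolerances, entrance effects, diffusive axial mixing,
viscosity contrasts between mixed fluids, droplet film dynamics and
tissue uptake in organ chambers are all outside what these tests can
exercise.

## Numerical choices, in one place

* position tolerance $10^{-12}$ (fractions), event merge window
  $10^{-12}$ s, slug merge tolerance $10^{-12}$ relative;
* quiescence threshold $q_\varepsilon = 10^{-18}$ m³/s;
* minimum channel resistance $10^{-30}$ Pa·s/m³;
* RK4 substep control $\lambda h \le 0.05$;
* droplet boundary detection within $10^{-9}$ of a channel end;
* ties in branch selection broken by sorted channel id; merged
  simultaneous events processed injections → droplet boundaries (by id)
  → transits, with a flow re-solve after every resistance change;
* runaway protection via a configurable event cap (default $10^6$).

The tank-side channel volume used in exchange is the slug's liquid volume
$w h l \times$ fraction; this two-sided bookkeeping is what makes the
conservation statements exact rather than one-sided.

## Problem sizes used by the test suite

The suite validates the solver on 200 random networks of up to 12 nodes
against an independently formulated dense solve ($10^{-9}$ agreement);
the mixing transport on 140 randomized gradient trees (2–8 outlets, 20
seeds) against the closed-form cascade ($10^{-9}$); droplet routing on 50
randomized ring scenarios (up to 6 channels, 3 droplets) against the
brute-force enumerator (exact path and event match); and the membrane
module against the analytic exponential (relative error $\le 10^{-5}$ in
the constant-channel limit; the full-network fixture carries an
additional, physical channel-depletion feedback of order 0.3% at its
default conditions and is checked at 2%), an RK4 convergence-order fit
($\ge 3.8$ over four step halvings), and mole conservation over $10^4$
exchange steps ($10^{-9}$) and 100 random mirror/recycle patterns
($10^{-12}$). These sizes keep the full suite at a few minutes on a
single core while leaving no module untested.

## Known limitations

* Steady-state detection requires exact slug merging; pathological inputs
  with concentrations differing by just above the merge tolerance will
  run to the horizon instead of stopping early (correct, merely slower).
* A droplet's resistance jumps atomically at transfer; devices whose
  behavior hinges on a droplet straddling a junction are outside the
  model.
* The mixing module treats concentration as a passive scalar; strongly
  viscous samples violating this coupling need a different resistance
  model.
* The cascade reference (`cascade_concentrations()`) requires an acyclic
  flow graph; recirculating layouts are simulated by the engine but have
  no closed-form steady state to compare against.
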