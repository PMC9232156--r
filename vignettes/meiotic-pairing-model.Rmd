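---
title: "A coarse-grained model of meiotic homolog pairing and interlock resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained model of meiotic homolog pairing and interlock resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

During meiotic prophase, homologous chromosomes must find each other and
align end to end inside a crowded nucleus.  `meiosim` models this process at
the scale where its physics lives: each chromosome is a bead--spring polymer
of `N = 100` nodes, one node per Kuhn segment of uncondensed chromatin
(100 nm), with four chromosomes (two homolog pairs) confined to a sphere of
radius 12 node diameters (a 1.2 µm budding-yeast meiotic nucleus, chromatin
volume fraction about 5%).

Each node obeys Langevin dynamics: a thermal random force, a frictional drag
`-(m/ζ)v` with damping time `ζ = 0.1` (5 ms), harmonic backbone springs with
energy `k_s (r - r0)^2` (`k_s = 100`, i.e. 0.0417 pN/nm; rest length one node
diameter), and Weeks--Chandler--Andersen excluded volume (the repulsive part
of a Lennard-Jones potential, cut at `2^(1/6) σ`) so that chains cannot pass
through one another.  Excluded volume is the point of the model: without it
there are no topological interlocks to study.  A spherical indenter pushes
any node at distance `s > R` back with force `k_nuc (s - R)^2`.

Chromosome ends (telomeres) attach to the nuclear envelope.  Tethered
telomere nodes are constrained to the sphere surface by a projection applied
every timestep: the position is rescaled onto the sphere and the radial
velocity component removed, so the net motion of a tethered end is always
tangential -- the same contract as a manifold RATTLE constraint, enforced
algebraically rather than iteratively.

Three telomere behaviours reproduce well-studied yeast strains
(`strain_preset()`):

* **WT** -- tethered ends plus *rapid telomere movements* (RTM): in every
  2000-step chunk each telomere has a 25% chance of a persistent pull of
  fixed magnitude in a uniformly random 3D direction, held for the whole
  chunk.  The sphere constraint converts the pull into surface dragging.
* **csm4** -- tethered but motionless ends (no RTM).
* **ndj1** -- untethered ends, no RTM; chromosome ends diffuse freely.

An optional *bouquet* adds a weak constant force `m·a` on every tethered
telomere directed at a fixed focus point on the envelope, clustering the
ends into a sub-region of the surface.

Homolog pairing is reversible bond kinetics: when node *i* of a chromosome
comes within the capture distance (one node diameter -- the beads must
touch) of node *i* on its homolog, a harmonic bond forms with probability
`p_pair = 0.85` per timestep; every existing bond dissolves with probability
`p_unpair = 1.25e-5` per timestep.  Pairing bonds reuse the backbone spring
constant and rest length, which avoids a new free parameter and keeps the
bond stiff enough that strand passage through a bonded pair is impossible.
Eligible sites are either every node (`"all"`) or twenty uniformly spaced
sites including both ends (`"spread"`).

## Units

One model length is 100 nm.  The damping time 0.1 corresponds to 5 ms, so
one model time is 50 ms.  The energy unit is `k_B T` at the simulation
temperature, taken as 4.17 pN·nm so that the spring constant conversion
(100 model units = 0.0417 pN/nm) is exact; at 300 K the
conventional value is 4.14 pN·nm, a 0.7% difference absorbed into the
temperature definition.  Derived units: velocity 2 µm/s, diffusivity
2×10^5 nm²/s, force 0.0417 pN.  `to_physical()` / `to_model()` convert.

The timestep is `dt = 0.01` model time units (0.5 ms): with the damping-set
time unit this is the only choice under which ten million timesteps span the
stated ~1.4 hours of prophase.  `dt/ζ = 0.1` resolves the momentum
relaxation, and the Brownian time `σ² m/(ζ k_B T) = 10` model units is a
hundred timesteps, comfortably inside the high-friction regime the model
assumes.

## Integrator

The equations of motion are integrated with the BAOAB Langevin splitting:
deterministic half-kick and half-drift around an exact Ornstein--Uhlenbeck
velocity update with friction rate `m/ζ`.  A naive scheme that adds friction
and noise as ordinary forces inside velocity Verlet carries a kinetic-energy
bias of order `dt/ζ` -- several percent at this model's `dt/ζ = 0.1` --
whereas the OU step is exact for a free particle at any timestep.  Measured
kinetic energy equilibrates to `3/2 k_B T` per node within a fraction of a
percent, and the free-particle diffusivity matches the closed form
`D = k_B T ζ/m` (2×10^4 nm²/s) to better than 1%.

The noise in the OU step is drawn from a variance-matched uniform
distribution rather than a Gaussian -- the long-standing convention of
molecular-dynamics Langevin thermostats -- because every quantity the
package measures (temperature, diffusivities, mean squared displacements,
drift velocities) depends only on second moments, and uniform draws keep the
inner loop fast enough for 10^7-step production runs.

Excluded-volume pairs come from a Verlet list built on a cell grid with a
0.8 σ skin, rebuilt whenever any node has moved half a skin since the last
build.  Directly bonded pairs (backbone neighbours and currently bonded
pairing partners) are excluded from the WCA sum, since their rest length
sits inside the WCA core.  Under periodic boundaries (used only by the
diffusion protocol, below) the cell grid tiles the box exactly, and bonded
interactions use unwrapped coordinates.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `nodes_per_chain` | 100 | nodes | 10 µm uncondensed chromosome at 100 nm/node |
| `nuclear_radius` | 12 | length | 1.2 µm meiotic nucleus |
| `k_spring` | 100 | energy/length² | 0.0417 pN/nm; stiff enough to forbid strand passage |
| `eps_lj`, `sigma_lj` | 1, 1 | energy, length | WCA at `k_B T`, bead-sized core |
| `temperature` | 1 | `k_B T` | ~300 K |
| `damping` | 0.1 | time | 5 ms; sets friction `m/ζ` and `D = k_B T ζ/m` |
| `dt` | 0.01 | time | see above |
| `capture_distance` | 1 | length | homologous beads must touch |
| `p_pair`, `p_unpair` | 0.85, 1.25e-5 | /step | reversible pairing kinetics |
| `rtm$p_pull`, `rtm$chunk_steps` | 0.25, 2000 | -, steps | one pull decision per telomere per second |
| `rtm$force_mag` | 3 | force | calibrated: peak windowed telomere speed 0.6 µm/s (below) |
| `bouquet$accel_mag` | 3 | accel | calibrated: ≥90% of telomeres within 60° of the focus at steady state |
| `k_nuc` | 5000 | force/length² | smallest stiffness keeping boundary overshoot < 0.2 σ (below) |

`k_nuc` deserves a note.  The confinement stiffness is not a physical
parameter of the nucleus; its only job is to make the wall effectively
impenetrable.  With a soft wall of the same order as the backbone spring,
thermal velocity tails let nodes penetrate over half a node diameter in long
runs; `k_nuc = 5000` is the smallest round value for which the maximum
excursion beyond the sphere stays under 0.2 σ across multi-million-step runs
while remaining stable at `dt = 0.01`.  Interior dynamics are unaffected --
the wall force is identically zero inside the sphere.

## Initialization and equilibration

All 400 nodes start on a single σ-spaced cubic grid, the chains laid head to
tail along one space-filling serpentine path (the random seed permutes the
chain order along the path and the grid orientation).  This guarantees no
initial overlaps while interleaving the chains the way a dense nucleus
would; the interleaved start matters, because the equilibrium degree of
inter-chain entanglement -- measured below by primitive path analysis -- is
what seeds topological interlocks.  Tethered terminal nodes are projected
radially onto the nuclear sphere before the first step.

Equilibration has two phases.  Phase 1 (5×10^4 steps) caps every node's
per-step displacement at σ/10 so the packed lattice can relax without force
spikes; the cap is enforced inside the integrator and the recorded maximum
displacement never exceeds it.  Phase 2 (5×10^5 steps, about 4 Rouse times
of a free chain) runs uncapped and randomizes conformations; its end marks
t = 0.  Phase lengths were chosen so that chain statistics decorrelate from
the lattice: equilibrated *unconfined* control chains with excluded volume
switched off reproduce the ideal random-chain radius of gyration
`sqrt(b²(N²-1)/6N)` (a z-test across 30 runs cannot tell them apart).  The
ideal-chain reference applies only without excluded volume: a real-chain
control with WCA on is measurably swollen (self-avoiding statistics), so the
package tests the random-chain prediction on the EV-off control and only
stationarity on the EV-on system.

## Telomere speed calibration

Windowed telomere speeds are measured as the great-circle displacement per
2000-step (1 s) window, the same interval as one RTM chunk.  The window is a
named parameter because it materially affects the numbers: diffusive motion
is subdiffusive at these scales, so a mean speed quoted without its window
is meaningless.  `calibrate_rtm_force()` bisects the pull magnitude until
the peak windowed speed matches a target; the shipped default (3 model
force units) is the calibration output for the 0.6 µm/s peak measured in
wild-type cells, and agrees with the analytic terminal-velocity estimate
`F = v m / ζ`.

A known limitation: with every parameter at its stated physical value, the
tethered-but-motionless (csm4) telomere moves on the envelope at the speed
set by chain-end subdiffusion, and at a 1 s window that is roughly three
times the 0.05 µm/s reported for the mutant *in vivo* and in the reference
simulations.  Matching both the wild-type peak at a 1 s window and the
mutant mean would require either a longer averaging window for the mean (the
subdiffusive scaling `speed ∝ window^(-3/4)` reaches 0.05 µm/s near a 5 s
window) or extra envelope friction on tethered ends, neither of which the
model specifies.  The package reports the 1 s-window value and leaves the
discrepancy visible rather than absorbing it into an unstated parameter.

## The diffusion protocol

The chromatin diffusion coefficient is measured with a density-matched
periodic-box protocol:
the four chains are simulated *without* confinement or tethering in a
periodic cubic box of volume equal to the nuclear sphere (density matched),
positions recorded unwrapped, and the time-averaged MSD of the ten
centermost nodes of each chain fitted in its linear region, slope divided
by six.  A confined measurement would bend the MSD over at the nuclear size;
the periodic box removes the wall while keeping the crowding.

Monomer motion in a polymer is subdiffusive (`MSD ~ t^{1/2}`) between the
bond-relaxation time and the Rouse time (about 170 s here), then crosses
over to centre-of-mass diffusion.  On a linear plot the curve looks linear
once the early bend has flattened; `diffusion_coefficient()` therefore fits
lag times of 10--50 s by default -- past the local-relaxation bend, well
below the Rouse crossover -- flags any fit with R² below 0.99, and
`msd_curve()` exposes the full curve so other windows can be chosen
deliberately.

## Pairing kinetics and the two layouts

With every node eligible to pair, cooperative zippering dominates: once a
few homologous contacts form, adjacent sites are held within the capture
distance and re-bind essentially instantly (the per-step two-state
occupancy at `p_pair/(p_pair + p_unpair)` is indistinguishable from 1), so
dense-site pairing runs to near completion and differences between telomere
behaviours wash out.  With twenty spread sites, zippering is weak, pairing
is search-limited, and full-length runs plateau near 55% of sites paired --
the regime in which the pairing/unpairing probabilities were calibrated and
in which strain differences are visible.  Spread-site kinetics are also
strongly heterogeneous across replicate nuclei, so small ensembles estimate
the plateau coarsely.  The package's plateau acceptance check measures the
spread-site configuration on a reduced ensemble (three runs of 5x10^6
steps); the full protocol is a single
`run_experiment("fig3b", n_steps = 1e7, n_runs = ...)` call away.

## Interlock machinery

Detection is operational, not knot-theoretic: `force_pair_completion()`
clamps `p_pair = 1`, `p_unpair = 0`, makes every node eligible, and runs the
dynamics.  A homolog pair that cannot reach pairing fraction 1 -- with no
progress over the final quarter of the assay -- is blocked by a topological
obstruction.  One blocked pair is an *open* interlock, both blocked is
*closed*, none is clean.  Planted-fixture validation: open templates,
closed templates and well-separated negative controls are typed correctly
in every test replicate.

Planted configurations are analytic curves.  Each homolog pair is a ribbon
(two chains at the bond rest distance); an unpaired mid-chain "eye" widens
the ribbon into a loop with a hole.  An open interlock threads a fully
paired straight ribbon through one eyed ribbon's hole; a closed interlock
Hopf-links two eyed ribbons through each other's holes.  Chain slack (every
chain must carry 99 bonds at rest length) is stored in rounded-square-wave
serpentines whose amplitude is solved by root finding so the arc length is
exact, whose arms stay 1.4 σ apart, and whose planes are chosen so the two
pairs never approach closer than about one node diameter.  Ends land on the
nuclear sphere.  `randomize_preserving_topology()` then decorrelates the
geometry with the bond set frozen, so the planted topology survives to
t = 0.

`interlock_position()` localizes an interlock as the contiguous run of
unpaired sites on a blocked pair whose midline is threaded by another chain
(within 1.5 σ, the smallest radius that found every planted fixture); its
position is the gap's midpoint label.  `resolution_timeline()` extracts the
three resolution steps: *migration* -- the first time the interlock comes
within 10 nodes of a chain end; *telomeric unpairing* -- the subsequent
first time the terminal 10 labels of the involved chains hold no bond; and
*diffusive unwinding* -- the subsequent first time the forced-pairing assay,
run on a copy of the frame, reports no interlock.  The first two are direct operational rules; the third replaces a visual "looks disentangled"
call with the assay, which is a re-definition and is flagged as such here:
it is the same operational criterion used for detection, applied
prospectively.

## Primitive path analysis

`primitive_path()` contracts chains to their primitive paths: endpoints of
every chain fixed, intra-chain excluded volume off, inter-chain excluded
volume on, springs retained with the rest length set to zero, and the system
quenched by FIRE minimization until the maximum force drops below 10^-3.
The zero rest length is what makes the springs contractile -- with the
thermal rest length retained a slack chain would stay slack -- and is the
standard primitive-path construction; an isolated chain contracts onto the
straight endpoint-to-endpoint segment with the interior nodes evenly
spaced.  `count_kinks()` automates the visual entanglement count: the
contracted path is Douglas--Peucker simplified (tolerance 0.3 σ), and a
retained interior vertex counts as one entanglement when its turning angle
exceeds 45° *and* it touches another chain within 1.5 σ; nearby kink
vertices merge.  The rule was validated on constructed fixtures with known
counts and is insensitive to the angle threshold between 30° and 60°.
Equilibrated nuclei carry 0--4 entanglements per chain at R = 12, with the
mean rising as the nucleus shrinks to R = 10 and 8 -- confinement entangles.

## Statistics

Pairing time courses are summarized as pointwise means with normal-theory
95% confidence intervals (`mean ± 1.96 SE`); interlock percentages use the
Wald binomial proportion interval (chosen as the plain reading of
"binomial proportion confidence interval"; the degenerate 0/n and n/n cases
are flagged rather than widened), and condition comparisons use the pooled
two-proportion z-test.  `half_max_time()` defines the plateau as the mean of
the final 10% of timepoints and interpolates the first crossing of half of
it.

## What the simulations do and do not show

Everything here is a toy model in the authors' sense: order-of-magnitude
geometry, one bead per Kuhn length, phenomenological constant forces for
motor pulls, and homology recognition reduced to equal-label bond formation.
Passing tests demonstrate that the *mechanisms* -- excluded-volume
topology, tethering constraints, active end-dragging, reversible
cooperative bonding -- behave as specified, not that any particular yeast
locus pairs at the simulated rate.  No mis-pairing, condensation dynamics,
synaptonemal-complex polymerization, or topoisomerase activity is modelled.

The test suite and the acceptance script run at reduced problem sizes
chosen to exercise the same physics: equilibration-scale ensembles for
statistical properties, 10^5--10^6-step runs for speeds and containment,
scaled-down ensembles (a few runs of 10^6--10^7 steps) for pairing plateaus
and strain ordering, and a handful of planted-interlock trajectories for
resolution timing.  The methods above are independent of these sizes; only
the statistical power changes.
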