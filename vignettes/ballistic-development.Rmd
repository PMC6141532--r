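---
title: "Ballistic development, differential canalization, and the voxdevo model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ballistic development, differential canalization, and the voxdevo model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxdevo)
```

## The model

`voxdevo` is an in-silico evo-devo laboratory.  The organism is a soft
robot: a 4 x 4 x 3 grid of 1 cm voxels, simulated as one point mass per
voxel connected to its (at most six) axis-neighbors by spring-like beams.
Two numbers per voxel define the phenotype at any moment of life:

* the **resting length** $\ell_k \in [0.25, 1.75]$ cm (morphology), and
* the **actuation phase offset** $\phi_k \in [-\pi/2, \pi/2]$ rad
  (controller).

Morphology is bilaterally symmetric: only the 24 lefthand resting lengths
are free parameters; the righthand side is their mirror image.  All 48
phase offsets are independent.

**Ballistic development.**  Every parameter may change linearly over the
robot's life from a genetically fixed start value $a$ to a final value
$b$:
$$\mathcal{B}(t) = a + \frac{t\,(b-a)}{\tau}, \qquad t \in [0, \tau],$$
with lifetime $\tau = 10$ s (40 actuation cycles at $f = 4$ Hz).
Development is open-loop — predetermined, monotone and irreversible; it
cannot respond to the environment.  Under the **Evo** treatment $a = b$
for every parameter (a static phenotype, 24 + 48 free parameters); under
**Evo-Devo** start and final values evolve independently (48 + 96 free
parameters).

**Actuation.**  A global sinusoidal signal of amplitude $A = 0.14$ cm
drives every voxel through its phase offset.  Small voxels are actuated
less, through the damping factor $\xi(x) = \min\{1, (4x-1)/3\}$, which is
1 at or above 1 cm and falls to 0 at the lower bound 0.25 cm.  The
instantaneous ("current") length of voxel $k$ is
$$\mathcal{L}_k(t) = \mathcal{B}(\ell_k, \ell^*_k; t)
  + A \sin\!\big(2\pi f t + \mathcal{B}(\phi_k, \phi^*_k; t)\big)\,
    \xi\!\big(\mathcal{B}(\ell_k, \ell^*_k; t)\big).$$
Per-beam resting lengths are the average of the two incident voxels'
current lengths, refreshed every timestep.

**Developmental windows.**  The amount of lifetime change is summarized
per robot by two statistics in $[0,1]$,
$$W_L = \frac{1}{48 \cdot 1.5}\sum_k |\ell^*_k - \ell_k|, \qquad
  W_\Phi = \frac{1}{48\,\pi}\sum_k |\phi^*_k - \phi_k|,$$
zero for non-developing robots and 1 for maximal development.  These are
the canalization measurements: a lineage whose $W_L$ rises and then
collapses to near zero while $W_\Phi$ drifts freely exhibits
*differential canalization* — the morphology is genetically assimilated,
the controller stays plastic.

**Evolution.**  Age-Fitness-Pareto optimization: a population of 30
robots; each generation the population is doubled by mutated copies,
every individual's age is incremented, one random age-0 individual is
injected (pool of 61), and Pareto-dominance selection on maximized
fitness / minimized age reduces the pool back to 30.  Fitness is the net
horizontal displacement of the center of mass over the lifetime, in
undeformed body lengths (4 voxels = 4 cm).  Mutation rates are per-voxel
and self-adaptive.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `nx, ny, nz` | 4, 4, 3 | voxels | grid (left-right, travel, vertical) |
| `amplitude` | 0.14 | cm | global actuation amplitude |
| `freq` | 4 | Hz | actuation frequency |
| `n_cycles` | 40 | – | cycles per lifetime; `tau = n_cycles/freq` |
| `sigma_ell` | 0.75 | cm | mutation s.d., resting lengths |
| `sigma_phi` | $\pi/2$ | rad | mutation s.d., phase offsets |
| `pop_size` | 30 | – | robots per trial |
| `spring_k` | 1e5 | dyn/cm | beam stiffness |
| `bend_k` | 2.5e4 | dyn/cm | straightness-spring stiffness |
| `damping_c` | 30 | g/s | global viscous damping |
| `ground_k`, `ground_c` | 4e5, 800 | – | contact penalty and normal damping |
| `mu` | 1.0 | – | Coulomb friction coefficient |
| `dt` | 1e-4 | s | integrator timestep |

The phenotypic bounds (0.25–1.75 cm, $\pm\pi/2$ rad) are constants of the
model, not knobs; configuration files stating different bounds are
rejected.

## Design choices

Several aspects of the system are genuinely open; the package resolves
them as follows and treats the choices as fixed study conditions.

**Initialization.**  Genome parameters are drawn uniformly over their
legal intervals — the maximally uninformative choice within hard bounds.
Per-voxel mutation rates start at $1/48$, so a single voxel is mutated on
average, and self-adapt by log-normal multiplicative steps
($\lambda_k \leftarrow \lambda_k e^{0.1 z}$, clipped to
$[1/480, 1]$) every time a genotype is copied — the standard
evolution-strategy scheme, which keeps rates positive and drifts them
slowly.  A `fixed_rate` option disables self-adaptation for
fixed-mutation-rate experiments.

**Mutation.**  Two stages: each applicable parameter type
($\phi, \phi^*, \ell, \ell^*$) is selected independently with probability
0.5 (redrawn if none), then each site of a selected type mutates with its
voxel's rate.  Perturbations are Gaussian ($\sigma_\ell$, $\sigma_\phi$)
and **clipped** to the bounds — the simplest scheme consistent with hard
limits, and the one the tests assert.  Draws that change nothing are
resampled (bounded retries, then one forced site), so every child differs
from its parent.  `expected_mutation_impact()` gives the closed-form
expected fraction of parameters modified under this scheme, conditioned
on at least one change; it is validated against Monte Carlo in the test
suite.

**Selection.**  The pool is reduced by repeated random dominance
tournaments: two distinct members are drawn; a dominated one is deleted.
After `pop_size^2` dominance-free draws the pool is scanned exhaustively;
if a dominated member exists it is deleted (random draws can simply have
missed it), otherwise the pool is mutually non-dominated and a random
member of the oldest cohort is deleted — never the current best-fitness
individual.  This exemption makes the elitism property ("the globally
fittest candidate always survives") unconditional, which the test suite
checks against brute-force Pareto enumeration.  Children inherit their
parent's age (age tracks the lineage, not the individual), and the age
increment is applied to the doubled population before the age-0
injection.  Unstable simulations score fitness 0 rather than aborting, so
evolution can traverse degenerate genomes.

**Physics.**  The integrator is semi-implicit (symplectic) Euler, the
standard stable choice for stiff mass-spring systems.  Beam rotational
stiffness is approximated by straightness springs spanning each collinear
beam pair — an angle-restoring force at a fraction of the complexity of
full beam elements.  Ground contact is a one-sided penalty spring with
viscous normal damping; friction is Coulomb, capped at the force that
would bring a particle's tangential velocity to rest within one timestep,
so slow contacts stick instead of chattering (an unregularized viscous
friction model is numerically stiff at these timesteps and destabilizes
the integration).  Coordinates: z up, ground at z = 0, travel along y,
mirror plane across x.

**Material constants.**  No published values exist for the reference
simulator's materials, so defaults are the package's own.  They were
chosen, once, to satisfy three requirements: the lattice's fundamental
period is far below the 0.25 s actuation period (quasi-static actuation);
the stability bound $dt \le 0.1\sqrt{m/k}$ holds with margin; and the
dynamics sits in a strongly damped regime where trajectories converge
under timestep refinement (the shuffler fixture's fitness changes about
0.5% when `dt` is halved).  Lightly damped settings make the frictional
contact dynamics chaotic — a 1e-9 cm perturbation grows to centimeters
within two seconds — which is physically admissible but makes behavior
metrics irreproducible across discretizations.  Absolute speeds therefore
do not transfer quantitatively to other simulators; treatment
*comparisons* are the meaningful output.

**Exact mirror symmetry.**  In a chaotic or near-chaotic system, even
rounding-level asymmetries in force summation order grow into macroscopic
lateral drift, which would mask the model's bilateral symmetry.  The
integrator therefore accumulates forces per particle over its neighbor
slots in a fixed direction order (x-, x+, y-, y+, z-, z+), computes every
pairwise term from the particle's own side, and combines per-axis pair
sums only after each two-term pair is summed.  A reflection then changes
each particle's accumulation only by swapping the two terms of one
commutative two-term addition, and the initial lattice is placed
center-outward so mirrored coordinates are exact negations.  The result:
a mirror-symmetric robot's net lateral displacement is zero to the last
bit, not merely small.

**Fitness.**  "Distance traveled" is implemented as net center-of-mass
displacement, not path length: rolling far is rewarded, while falling
over without advancing is penalized.  Path length is available behind
`fitness_from_trajectory(..., path_length = TRUE)`.

**Rollover.**  A robot "rolls over" at the first recorded sample where
any initially-top-layer particle is within `contact_eps` (5% of a voxel,
configurable) of the ground — the onset of rolling, not a complete roll.

**Robustness walks.**  Walks reuse the standard mutation operator but
mask the untouched subsystem (control walks mutate $\phi, \phi^*$ only;
morphology walks $\ell, \ell^*$ only) and freeze the per-voxel rates, so
the walk probes subsystem sensitivity rather than rate evolution.

## What the generated data does and does not show

All inputs are generated: seeded random genomes, deterministic fixture
robots (`static`, `oscillator`, `shuffler`, `devo-max`), and the
evolution logs they produce.  The generator's defaults are the reference
conditions (grid, lifetime, amplitude, frequency, population size,
mutation scale); tests that pass under these conditions demonstrate the
*mechanisms* — development reduces exactly to the static phenotype when
endpoints coincide, windows measure what they claim, selection is
Pareto-correct, removal preserves the birth phenotype bit-for-bit.  They
do not demonstrate full-scale evolutionary outcomes: the reference
experiment (30 trials x 10,000 generations x 30 robots) is far beyond a
test suite, and with reimplemented material constants absolute
locomotion speeds are not comparable.  The test suite's evolution runs
use a reduced 3 x 3 x 2 grid, populations of 10, and 200 generations
(5 seeds per treatment) — enough to detect selection pressure by a sign
test, not to estimate effect sizes.  The same applies to the acceptance
script's experiment (3 seeds x 150 generations per treatment, 50-step
robustness walks).

## Numerical details worth knowing

* Development is evaluated lazily at each physics timestep from the
  genome (no precomputed schedule), so any `dt` sees the exact
  interpolant; times beyond $\tau$ clamp to $\tau$.
* Trajectory samples are taken before the integration step at exact
  multiples of `record_interval` (snapped to a multiple of `dt`),
  including $t = 0$ and $t = \tau$.
* Divergence (non-finite or kilometer-scale coordinates) raises an error
  naming the offending `dt`/stiffness; evolution converts this to
  fitness 0 and flags the individual in the history log.
* The evaluation cache keys on the phenotype-determining genome values
  (mutation rates excluded), so AFPO re-evaluates only new children.
* Genome JSON stores numbers with 17 significant digits; round-trips are
  bit-exact.
* Ties in `mann_whitney_u()` use midranks; the exact p-value (both
  samples of size at most 8) enumerates group assignments of the pooled
  values, which handles ties without a separate correction; larger
  samples use the tie-corrected normal approximation with continuity
  correction.

## Known limitations

* One particle per voxel: no self-collision between non-adjacent voxels,
  no heterogeneous materials, flat terrain only.
* Straightness springs resist bending but not torsion about a beam's own
  axis; gaits that exploit torsional stiffness are outside the model.
* The strongly damped default regime trades locomotion speed for
  reproducibility; undamped gait dynamics (galloping with flight phases)
  is not represented.
* Development is strictly linear and open-loop by design; environmental
  feedback, costs of plasticity, and nonlinear schedules are out of
  scope.

## A quick tour

```{r tour, eval = FALSE}
library(voxdevo)

# evolve a small developing population
cfg <- evo_config(grid = grid_spec(3, 3, 2), treatment = "evodevo",
                  pop_size = 10, generations = 100,
                  phys_cfg = toy_physics_config())
trial <- run_trial(cfg, seed = 1)
trial$champion$fitness

# canalization along the champion's lineage
lineage <- trace_lineage(trial)
canalization_summary(list(lineage))

# is the evolved body robust to control mutations?
walk <- robustness_walk(trial$champion$genome, "control", n_steps = 100,
                        n_walks = 5, phys_cfg = toy_physics_config())
median(walk$fitness[, ncol(walk$fitness)]) / median(walk$fitness[, 1])

# strip development and compare birth phenotypes
reduced <- remove_development(trial$champion$genome)
c(window_morph(reduced), window_ctrl(reduced))
```
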