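---
title: "Simulating the adsorption of silicon-containing dendrimers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating the adsorption of silicon-containing dendrimers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrisorb)
```

## The system

Dendrimers are perfectly branched tree-like macromolecules: a core atom of
functionality $f_c$ carries $f_c$ dendrons; each dendron is a spacer leading
to a branching point, which carries two further spacers, and so on to depth
$G$ (the generation). How such a molecule adsorbs onto an attractive flat
surface depends on the interplay of its branching topology, spacer chemistry
and generation: low generations can flatten into pancakes, while dense high
generations touch the surface only with a thin shell of peripheral atoms.

`dendrisorb` models four homologous series of silicon-containing dendrimers
at united-atom resolution (CH~2~ and CH~3~ groups are single interaction
sites):

| series | spacer | ends | core $f_c$ |
|---|---|---|---|
| C4 | –(CH~2~)~3~– | butyl –(CH~2~)~3~–CH~3~ | 4 |
| C3 | –(CH~2~)~3~– | butyl | 3 |
| S  | –O– | methyl | 3 (configurable) |
| L  | –O–Si(CH~3~)~2~–O– | methyl | 3 (configurable) |

All series share three-functional ≡Si(CH~3~) branching points. The two
carbosilane series differ only in core functionality; the two siloxane series
differ in spacer length. The S-series, with a single oxygen as spacer, is by
far the most compact.

Two structural choices are not fixed by the chemistry alone and are resolved
here as follows:

* the siloxane core functionality is not uniquely determined; we default to
  $f_c = 3$, matching the three-functional branching chemistry, and expose it
  as a parameter of `dendrimer_spec()`;
* the core is modelled as a bare Si atom carrying its $f_c$ spacers (no core
  methyl); terminal branching points of the siloxane series carry two methyl
  caps, i.e. Si(CH~3~)~3~ ends, and carbosilane ones carry two butyl tails.

### Structural layers

For the layer-resolved contact analysis, the molecule is partitioned into
*structural layers*: layer $k \ge 1$ holds the branching Si atoms at
topological depth $k$, their methyls and their outgoing spacers; layer 0 is
the core plus its spacers, and layer $G$ additionally holds the terminal
segments. Interior layer populations double exactly from one layer to the
next ($2 \le k \le G-1$); the terminal layer deviates from the factor 2
because its chemistry differs (butyl or methyl caps instead of spacers):
the ratio is 2.5 for the carbosilanes, 2 for S and 2/3 for L. The
layer-resolved conclusions do not depend on where one starts counting;
`assign_layers()` documents the convention used.

## Energetics

The force field uses the functional forms conventional for united-atom
models of this family:

* bonds: $U_{12} = \sum k_b (b - b_0)^2$,
* angles: $U_{13} = \sum k_\theta (\theta - \theta_0)^2$,
* torsions (carbosilane series only): $U_{14} = \sum A (1 + \cos(n\varphi - \delta))$
  with a single generic 3-fold term,
* van der Waals: truncated-and-shifted Lennard-Jones with Lorentz–Berthelot
  mixing and a 10.5 Å cutoff,
* electrostatics: a screened Coulomb term
  $U_{qq} = C\, q_i q_j / (\kappa r \cdot r)$, i.e. Coulomb with a
  distance-dependent dielectric $\varepsilon_r = \kappa r$, also shifted to
  zero at the cutoff. Only the siloxane series carry partial charges:
  each oxygen gets $-0.2\,e$ and donates $+0.1\,e$ to each bonded silicon,
  so every molecule is exactly neutral.

1–2 and 1–3 pairs are excluded from the non-bonded terms; 1–4 pairs are kept
at half strength (configurable). No long-range corrections are applied — a
single molecule in vacuum has no periodic images. The numeric parameter
values shipped by `default_forcefield()` are nominal literature-style values
(e.g. $b_0$ = 1.53/1.89/1.64 Å for C–C/Si–C/Si–O, tetrahedral angles, a wide
soft Si–O–Si hinge at 150° with $k_\theta = 15$ kcal/mol/rad² that encodes
the flexibility of the siloxane backbone). They are deliberately exposed as
configuration — `write_forcefield()`/`read_forcefield()` round-trip them
through YAML exactly — because the package's conclusions are trend-level
properties, not parameter-faithful energies of any specific published force
field.

### The adsorbing wall

The surface at $z = 0$ attracts every united atom through the 9-3 potential

$$U_\mathrm{ads}(z) = \tfrac12\,\varepsilon\left[\left(\frac{R_\mathrm{min}}{z}\right)^{9} - 3\left(\frac{R_\mathrm{min}}{z}\right)^{3}\right],$$

the lateral integral of an atom–halfspace Lennard-Jones interaction. Its
minimum is $-\varepsilon$ at $z = R_\mathrm{min}$ (3 Å by default), its root
sits at $R_\mathrm{min}\,3^{-1/6}$, and it is cut off — exactly zero — beyond
130 Å, far enough that an entire dendrimer feels the wall. The same
parameters apply to every atom regardless of chemistry, so any difference in
adsorption behaviour between the series is purely structural. The $z^{-9}$
branch makes the plane impenetrable; the integrator aborts if an atom ever
reaches $z \le 0$ (only possible numerically, with $\varepsilon = 0$ the
plane is simply absent).

```{r wall}
w <- wall_params(epsilon = 1)
curve(wall_energy(x, w), 2, 12, xlab = "z (A)", ylab = "U_ads (kcal/mol)")
abline(h = -1, v = 3, lty = 3)
```

## Dynamics

Velocity-Verlet integration with a 1 fs timestep (the bonds are stiff and
unconstrained; the stiffest mode has a ~32 fs period, comfortably resolved).
Temperature is held at 350 K by a collisional thermostat: at every step each
atom has probability $\lambda\,\mathrm{d}t$ of an elastic collision with a
virtual particle of mass $m_0$ whose velocity is Maxwell-distributed at the
target temperature,

$$v' = v + \frac{2 m_0}{m + m_0}\,(u - v),$$

which conserves the momentum of the colliding pair and has the Maxwell
distribution at $T$ as its exact stationary state (the variance fixed point
of the affine update is $k_BT/m$). Defaults $m_0 = 1$ Da and
$\lambda = 55$ ps⁻¹ give strong but local temperature control; both are
configuration, and none of the package's conclusions depend on them.

The protocol mirrors the two-stage design of adsorption studies: a free
thermostatted relaxation (`relax()`), then `adsorb()` rotates the
equilibrated molecule by a uniformly random orientation (random unit
quaternion), places its lowest atom a configurable 5 Å above the plane and
integrates with the wall term on.

Numerical safeguards worth knowing about:

* the non-bonded terms are *shifted* to zero at the cutoff; without the
  shift, pairs crossing the cutoff inject energy and NVE conservation
  degrades by an order of magnitude;
* the neighbour list is a Verlet list over a precomputed master list of
  non-excluded pairs (skin 1.5 Å, rebuilt on the half-skin displacement
  criterion);
* with the thermostat off and no wall, total energy over 10⁴ steps drifts by
  well under 0.1 % of the kinetic energy — the symplectic-integrator
  contract that the test suite enforces;
* steepest-descent relaxation (used by `embed_3d()`) moves along the force
  direction with an adaptive trust-radius step, which is robust against the
  huge initial LJ forces of freshly placed conformations.

### Initial conformations

`embed_3d()` places atoms recursively at equilibrium bond lengths and
angles with randomized torsions (siblings offset by 120° around the parent
bond), then relaxes by steepest descent until every bonded distance is
within 10 % of its equilibrium value and no non-bonded pair sits closer than
0.8 of its LJ contact distance. The construction retries with fresh torsions
(up to 8 attempts) before failing; for generations up to 4 the first attempt
essentially always succeeds. Everything is deterministic in the seed.

## Observables

* `count_adsorbed()` / `contact_series()`: an atom is adsorbed when
  $z \le 5$ Å (boundary inclusive); `M` is the adsorbed count, `M/N` the
  fraction, partitioned by structural layer.
* `layer_contact_fractions()`: time-averaged per-layer contact fractions —
  the fingerprint that separates "brimmed-hat" adsorption (periphery only,
  carbosilanes) from interior-exposing spreading (L-series below G7).
* `density_perp()`: mass-weighted linear density vs height,
  $\rho_\perp(H) = \sum_i n_i(H)\, m_i / \mathrm{d}H$ with
  $\mathrm{d}H = 0.2$ Å; integrates exactly to the molecular mass.
* `density_parallel()`: areal density vs lateral distance from the centre of
  mass, $\rho_\parallel(R) = \sum_i n_i(R)\, m_i / S_i$ over annuli of width
  1 Å. The centre of mass is recomputed per frame so lateral diffusion does
  not smear the profile.
* `energy_audit()`: per-atom averages of every potential term across wall
  strengths, with percent changes relative to a reference ε (default: the
  smallest present — effectively an unadsorbed baseline). This is the tool
  that bounds the physically sensible ε range: bond/angle strain must stay
  small for the harmonic description to remain valid.
* `shape_metrics()`: mass-weighted gyration tensor eigenvalues, height,
  lateral radius, and relative asphericity (0 for a sphere, 1/4 for a flat
  disk, 1 for a rod).
* `aggregate_replicas()`: replica means with $n-1$ standard errors.

## Study design and problem sizes

The full-scale protocol of record for systems like these — generations 4–7,
20 ns trajectories, averages over the last 5 ns and eight independent
realizations — needs cluster-scale resources (a G7 carbosilane has ~4600
united atoms). `run_study()` supports that protocol through its
configuration, but the package's own analysis scripts and tests run a
desk-scale design chosen to exercise every qualitative trend in minutes on
one CPU:

* generations 2 and 3, all four series;
* ε = 0.4, 1.5, 3.0 kcal/mol at G2 (the weak-to-strong range) and ε = 3.0 at
  G3 — every trend assertion (monotonicity in ε, generation ordering at
  fixed ε, layer-resolved periphery dominance, S-vs-L contrast) is evaluated
  at the conditions where it is defined;
* 3 replicas per condition, 0.25 ns adsorption runs, the trailing 0.2 ns as
  production window, after a 20 ps free relaxation shared across ε within a
  replica (the equilibrated conformation is reused, as in the two-stage
  protocol).

At these sizes the trends are strong relative to replica scatter. One
comparison needs more time, not more atoms: the *relative* contact deficit
of the S-series against the L-series only appears after the larger, more
flexible L molecule has finished spreading, which takes ~0.4 ns at G3.
Block-averaged contact fractions over a 1 ns probe show L passing S at
0.3--0.4 ns and plateauing well above it, so the S-vs-L comparison uses a
dedicated 1 ns protocol with the trailing 0.4 ns as production. What
desk-scale runs do **not** show: saturation effects of very high generations
(the ~7 % contact fraction of a G7 S-dendrimer), the G7 convergence of all
series, or quantitatively transferable energy-audit percentages — those
depend on the (unpublished) force-field parameters and on full-scale
sampling, and are reported by the analysis scripts only as qualitative
orderings.

Percent changes in the energy audit use the smallest ε present as reference
(the audit's baseline is genuinely ambiguous at full scale; an unadsorbed
run is the cleanest definition and is what the scripts use). Sampling
windows for the audit are the trailing half of each trajectory.

## Known limitations

* The force field is nominal: trends are meaningful, absolute energies are
  not comparable to any specific published parameterization.
* The screened-Coulomb form (distance-dependent dielectric) is the simplest
  standard choice; siloxane charges are a minimal Si/O dipole model.
* No solvent; adsorption is driven purely by the wall potential, as intended
  for a vacuum model of van der Waals adsorption.
* Single molecule only — no surface crowding, no melt.
* The 2D projections are point sets; no rendered molecular graphics.
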