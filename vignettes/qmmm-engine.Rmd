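---
title: "Methods: the miniqmmm QM/MM engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the miniqmmm QM/MM engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own science: the energy model,
the QM/MM coupling rules, the numerical choices, what the synthetic fixtures
do and do not emulate, and the limitations a user should know about. All
quantitative statements here are computed by the test suite or by
`scripts/acceptance.R`; nothing is quoted from elsewhere.

## The energy model

The classical force field uses harmonic bonds
$V = \tfrac{1}{2} k_b (r - b_0)^2$, harmonic angles
$V = \tfrac{1}{2} k_\theta (\theta - \theta_0)^2$, cosine proper dihedrals
$V = k_\phi (1 + \cos(m\phi - \delta))$, harmonic improper dihedrals on the
signed dihedral wrapped to $(-180^\circ, 180^\circ]$, Lennard-Jones
interactions in $C_{12}/r^{12} - C_6/r^6$ form, and Coulomb electrostatics
with a generalized reaction field,

$$V(r) = k\,q_i q_j \left( \frac{1}{r} + \frac{C_{RF}\, r^2}{2 R_C^3}
  - \frac{1 + C_{RF}/2}{R_C} \right), \qquad
  C_{RF} = \frac{2\varepsilon_{RF} - 2}{2\varepsilon_{RF} + 1},$$

the zero-ionic-strength form, which vanishes exactly at the cutoff $R_C$.
Internally everything is in nm, ps, u, e, K, and kJ/mol;
$k = 1/(4\pi\varepsilon_0) = 138.9354$ kJ mol$^{-1}$ nm e$^{-2}$.

Three choices deserve comment.

**Excluded-pair reaction-field terms.** The constant and $r^2$-dependent
reaction-field terms are applied to excluded (intramolecular) pairs as well
as to pair-list pairs. The dielectric continuum responds to *all* charges,
including those whose direct Coulomb interaction is excluded; dropping these
terms would make the energy discontinuous in $\varepsilon_{RF}$. For rigid
water the contribution is a constant offset (the constrained distances never
change), visible as a positive shift of the reported Coulomb energy; it has
no effect on intermolecular interaction energies, and therefore none on the
vaporization-enthalpy estimator.

**Single-range group cutoff.** The pair list is charge-group based — a group
pair enters when the minimum-image distance between geometric centers is
within the cutoff — and is rebuilt every `pairlist_update_interval` steps
(default 5). A twin-range scheme is a performance device, not different
physics, so a single range is used at desk scale. The price is small,
well-understood noise: interactions switch on and off at list rebuilds, which
pumps a little heat. In NVT/NPT water runs the box temperature therefore sits
a few kelvin above its target (the suite asserts within 12 K); the same
behavior is characteristic of group-based reaction-field cutoffs with rigid
water generally.

**Virial and pressure.** The instantaneous pressure uses the pair virial
from the nonbonded kernels, the translation-invariant term virial of the
bonded interactions (valid because molecules are kept whole), the SHAKE
constraint virial accumulated from the Lagrange multipliers, and, in QM/MM
runs, $\sum f \cdot r$ over the gathered QM cluster (QM atoms, caps, point
charges), which is well defined because the cluster's total force vanishes.
The cap's share of that sum is taken at the cap position rather than
re-expressed at the link atoms; the difference is a bounded intramolecular
term, irrelevant at the accuracy a weak-coupling barostat needs.

## Dynamics

Leapfrog integration:
$v(t{+}\tfrac{dt}{2}) = v(t{-}\tfrac{dt}{2}) + f(t)\,dt/m$, then
$r(t{+}dt) = r(t) + v(t{+}\tfrac{dt}{2})\,dt$, with SHAKE applied to the
trial positions and the velocities recomputed from the constrained step.
Energy records pair the potential at $r(t)$ with the kinetic energy centered
at $t$ (mean of the two adjacent half-step kinetic energies); pairing
quantities half a step apart produces an apparent first-order-in-$dt$ wander
of the conserved quantity that is easy to mistake for integrator drift.

The weak-coupling thermostat scales velocities by
$\lambda = \sqrt{1 + (dt/\tau_T)(T_0/T - 1)}$. $T$ is measured on the *last
constrained* half-step velocities: the unconstrained trial velocities carry
spurious kinetic energy along the constraint directions that SHAKE removes
again, and a thermostat fed that inflated temperature systematically
under-heats. The barostat scales coordinates and box by
$\mu = (1 - (dt/\tau_P)\,\kappa\,(P_0 - P))^{1/3}$ (isotropic, atomic
scaling; SHAKE restores the constraints at the next step). Defaults:
$dt = 0.5$ fs, $\tau_T = 0.1$ ps, $\tau_P = 0.5$ ps,
$\kappa = 4.575\times10^{-4}$ (kJ mol$^{-1}$ nm$^{-3}$)$^{-1}$,
center-of-mass motion reset every 1000 steps (plus rigid-body rotation in
vacuum). Initial velocities are Maxwell-Boltzmann at $T_0$ from the
configured seed when the supplied state carries none, so a checkpointed
state continues deterministically — the suite checks bit-for-bit restart.

A deliberately simple choice: the canonical sampling here is Berendsen-type
weak coupling for both baths, not a chain thermostat. The validation
observables are means of structural quantities, which are insensitive to the
thermostat's ensemble subtleties at these run lengths; a correct-ensemble
thermostat is the natural first extension.

## Embedding schemes

`NTQMMM` codes map as $-1 \to$ MECC, $1 \to$ MEDC, $2 \to$ EE.

* **MECC** — the backend receives only the QM zone (no point charges); all
  QM-MM interactions are classical with the topology charges. With a backend
  that mirrors the pruned intramolecular terms, a MECC evaluation is
  *algebraically identical* to the pure-MM engine on the unpartitioned
  system — the suite asserts agreement to $10^{-10}$ relative in energy and
  forces, which pins down the bookkeeping (pruning, no double counting,
  force scatter) exactly.
* **MEDC** — as MECC, but the QM charges are replaced every step by charges
  the backend returns. No charge-derivative forces are computed: the forces
  are evaluated as if the charges were constants, although they are
  functions of the geometry. This is a real, documented inconsistency of
  dynamic-charge schemes, reproduced here deliberately; every run warns, and
  long simulations are discouraged.
* **EE** — MM atoms within `qmmm_cutoff` of any QM atom (atomic mode), or
  whole charge groups whose geometric center is within the cutoff (group
  mode), enter the QM calculation as point charges at their single
  consistent minimum image. The *entire* classical QM-MM electrostatic pair
  interaction — including its reaction-field terms — moves to the QM side;
  QM-MM Lennard-Jones stays classical; intra-QM excluded-pair reaction-field
  terms stay classical too (the continuum responds to the QM charges
  regardless of who computes their direct interactions). Intra-QM
  Lennard-Jones is off unless `lj_within_qm`; pruned QM-QM bonds (and any
  removed QM-zone distance constraints) can be re-imposed as constraints
  with `constrain_qm_bonds` — note that a rigid-water QM zone *needs* this
  (or a backend with intramolecular structure), because pruning removes the
  constraints that held the molecule together.

Charge scaling $q' = q\,(2/\pi)\arctan(s\,d)$ uses each MM atom's distance
to the closest *real* QM atom (capping atoms are bookkeeping, not charge
centers), with the scaled charge used consistently in the request and in
field-mode force recovery. With $s \le 0$ scaling is off, and an MM group
crossing the gathering cutoff produces an energy step equal to its Coulomb
interaction with the zone; with small $s > 0$ that step is damped — the
documented trade-off of the scheme. Gathering is recomputed every step.

The three MM-response representations (direct forces, electric field,
partial charges) are mutually consistent by construction in the mock and are
cross-checked through full assemblies to $10^{-8}$. In the charges
representation the backend's QM forces exclude the external coupling, which
the engine recovers pairwise on both sides; energies still include it.

## The link-atom scheme

The cap position is a function of the two link atoms only, so its force is
redistributed by the chain rule through
$J_{MM} = (d/d_{MM\text{-}QM})(I - \hat r \hat r^T)$:
$f^L_{MM} = J_{MM}^T f_L$, $f^L_{QM} = f_L - f^L_{MM}$. The partition is
exact (the two Jacobians sum to the identity), annihilates the component of
$f_L$ parallel to the bond on the MM side, and adds no net force or torque.
Each piece is verified against finite differences of a potential evaluated
at $r_L(r_{QM}, r_{MM})$. One subtlety found the hard way: published torsion
and link-atom gradient formulas differ in bond-vector sign conventions, so
every gradient in this package is accepted only after matching a
finite-difference oracle of the same scalar it claims to differentiate.

The cap is hydrogen at a user-set length (`CAPLEN`, default 0.109 nm, a
typical C-H bond). The boundary MM atom (M1) is completely hidden from the
QM calculation — its point charge is never gathered — while more distant MM
atoms are visible; the classical M1-Q1 bond term remains active, which is
why boundary bonds must exist in the force field. Charge redistribution
around the boundary is out of scope; the fixtures put zero charge on M1 so
the hidden-charge question stays academic there.

Periodic visibility is enforced every step with a sufficient pair of rules:
(a) the physical diameter of the QM zone (molecules whole) must stay below
half the smallest box edge — beyond that, some QM atom is closer to the
periodic copy of another QM atom than to the real one; and (b) under EE,
diameter + gathering cutoff must stay below half the smallest box edge, so
every MM atom presents one consistent image to all QM atoms. Violations
terminate the run, naming the rule, atoms, and step.

## The mock backend and the file protocol

The mock "QM program" is an analytic stand-in: an intramolecular MM-style
potential over the request atoms (QM + caps) plus fixed internal point
charges interacting with the external point charges by plain Coulomb. Its
forces are exact gradients, its total force vanishes (isolated-system
momentum conservation to $10^{-9}$ relative, asserted), and an optional
geometry-dependent charge rule $q_a = q_a^0 + \alpha \sum (b - b_0)$ feeds
the MEDC tests. It makes three kinds of statements testable that a real QM
program would blur: exact MM equivalence in MECC, exact mode consistency of
the three MM responses, and exact energy conservation of the full coupled
dynamics (the 10 ps, 0.5 fs NVE run with EE + link in the acceptance suite
conserves energy to a relative drift below $10^{-3}$).

The file protocol writes a deterministic plain-text request (header template
with an `@GUESS@` first-step token, coordinates with `*`-flagged caps, point
charges) in the QM program's units — conversion factors multiply data coming
from the QM side and divide data going to it; round trips are identities —
and parses a result file with size validation and line-level error
reporting. A generated fake executable wraps the same mock behind this
protocol; the subprocess path reproduces the in-process path to $10^{-10}$,
which bounds the text round-trip error far below anything physical.

## Fixtures: what they emulate, and what they don't

`build_water_box()` places rigid three-site SPC molecules (charges
$-0.82/+0.41$ e, O-O Lennard-Jones $\sigma = 0.3166$ nm,
$\varepsilon = 0.650$ kJ/mol, O-H 0.1 nm, H-H 0.163299 nm) on a perturbed
cubic lattice with random orientations; the edge follows from the target
density, $L = (n\,m_w/(\rho N_A))^{1/3}$, 1.862 nm for 216 molecules at
997 kg m$^{-3}$. A flexible variant (harmonic bonds/angle at the SPC/Fw
reparameterization: $b_0 = 0.1012$ nm, $k_b = 443153$ kJ mol$^{-1}$
nm$^{-2}$, $\theta_0 = 113.24^\circ$, $k_\theta = 317.57$ kJ mol$^{-1}$
rad$^{-2}$) supports QM-water tests that need intramolecular structure.

The liquid-water reference run used by the tests and the acceptance script
is deliberately scaled down: 216 molecules, 10 ps NPT equilibration from the
lattice, 30 ps NPT sampling, $dt = 2$ fs with SHAKE. In this box the half
edge is 0.93 nm, so the reaction-field cutoff is set to 0.9 nm — the largest
value the minimum-image convention permits; a 1.4 nm cutoff, the natural
choice in larger boxes, is geometrically impossible here. With that setup
the tagged-molecule estimator $\Delta H_{vap} = -\langle E_{uv}\rangle/2 +
RT$ and the O-O RDF maxima land on the accepted SPC values within their
tolerances (the suite asserts $43.7 \pm 2$ kJ/mol, $0.275 \pm 0.01$ nm,
$0.45 \pm 0.03$ nm). What 40 ps of a 216-molecule box does *not* give:
converged tails of the RDF, hydrogen-bond lifetime distributions with
quantitative error bars, or any statement about real (non-SPC) water.

`build_toy_tripeptide()` is a 19-atom alanine-X-alanine-like chain with an
aliphatic sidechain, full bonded terms across the boundary, one link
(C$_\beta$ to C$_\alpha$), zero charge on the boundary MM atom, and a
ground-truth manifest of exactly which terms pruning must remove. It is a
*boundary-bookkeeping* fixture: its parameters are plausible (harmonic
constants of a few $10^5$ kJ mol$^{-1}$ nm$^{-2}$, amide-like charges), not
a fitted force field, so its scan profile validates the machinery — torsion
pinned to target, smooth profile, zero minimum — not any real residue's
torsional landscape.

## Numerical choices

* SHAKE: relative tolerance $10^{-4}$ on squared constraint lengths, 500
  iterations maximum, failure names the first constrained atoms.
* Degenerate geometry (zero-length bond vectors, collinear angles, collapsed
  dihedral planes) raises an error naming the term rather than producing
  NaN forces; pair distances below 0.05 nm abort as overlaps.
* The dihedral-scan driver pre-rotates the subtree behind the scanned bond
  rigidly to each target angle, then relaxes by adaptive-step steepest
  descent under a harmonic restraint (default $5\times10^4$ kJ mol$^{-1}$
  rad$^{-2}$), doubling the restraint constant until the relaxed torsion is
  within $0.01^\circ$ of target (at most 10 doublings). Pre-rotation is
  what makes steepest descent viable: without it the stiff restraint must
  drag the torsion across up to $180^\circ$ through an ill-conditioned
  landscape. The reported profile is the energy *without* the restraint,
  shifted so its minimum is zero; each grid point warm-starts from the
  previous one. Grid angles are wrapped to $(-180^\circ, 180^\circ]$, so a
  grid "from $-180$" scans its equivalent representative $180$.
* RDF peak location smooths the 0.002 nm-binned curve with an 11-bin running
  mean, then takes windowed extrema (first peak, following minimum within
  0.2 nm, second peak within 0.2 nm of the minimum) — plain local-maximum
  walking is not robust to counting noise at this bin width.
* Power spectra: unbiased autocorrelation of the mean-subtracted series via
  FFT, Hann taper, zero-padded transform; the abscissa converts through the
  sampling interval and the speed of light ($2.998\times10^{-2}$ cm/ps).
  Peak positions are the contract; intensities are arbitrary.
* Hydrogen bonds: H···A $\le 0.25$ nm and D-H···A $\ge 135^\circ$,
  continuous (uninterrupted) lifetime definition; both cutoffs are
  parameters, since conventions differ and nothing in the validation depends
  on the specific pair chosen.
* Topology indices are 1-based everywhere, matching both the file formats
  and R's native indexing; a 0-based internal layer would buy nothing here.

## Known limitations

No Ewald/PME (reaction field only); no twin-range cutoff; no chain
thermostats; no polarizable or buffered embedding; no charge-redistribution
schemes at the link; at most one link per QM atom, on single covalent bonds
only; MEDC omits charge-derivative forces by design; adapters for real QM
programs are limited to the generic file protocol with the package's own
dialect; united-atom topologies must be expanded to all-atom before use.
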