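# miniqmmm

A miniature, self-contained hybrid quantum-mechanics/molecular-mechanics
(QM/MM) molecular dynamics engine in R, for people developing, teaching, or
stress-testing QM/MM coupling schemes: the boundary treatment — embedding
schemes, point-charge gathering and scaling, link atoms, periodicity rules —
is the product, not an interface detail hidden inside a large MD code. Every
ingredient is small enough to read, every force is finite-difference
verified, and an analytic mock backend stands in for the external quantum
chemistry program, so the whole package builds and validates with zero
external data or binaries.

## What it implements

**Classical force field.** Harmonic bonds and angles, cosine proper
dihedrals, harmonic improper dihedrals, Lennard-Jones interactions, and
Coulomb electrostatics with a generalized reaction field at zero ionic
strength:

    V(r) = k q_i q_j [ 1/r + C_RF r^2 / (2 R_C^3) - (1 + C_RF/2) / R_C ]
    C_RF = (2 eps_RF - 2) / (2 eps_RF + 1)

evaluated over a charge-group pair list under the minimum-image convention,
with SHAKE for holonomic distance constraints. Leapfrog integration with
weak-coupling (Berendsen) thermostat and barostat drives NVE/NVT/NPT
dynamics.

**Embedding schemes.** Mechanical embedding with constant (MECC) or
dynamically updated (MEDC) QM charges, and electrostatic embedding (EE), in
which every MM atom (or whole charge group) within a cutoff of the QM zone
enters the QM Hamiltonian as a point charge. MM charges can be damped near
the boundary by `q' = q (2/pi) arctan(s d)` with `d` the distance to the
closest QM atom. The backend may return the QM-MM coupling forces directly,
as an electric field at the point charges (`f_i = q_i E_i`), or as partial
charges from which the engine recovers all M x N pairwise Coulomb forces —
the three representations are algebraically equivalent and tested against
each other.

**Link atoms.** A covalent QM/MM boundary bond is capped by a hydrogen
placed at fixed distance `d` along the bond,

    r_L = r_QM + d (r_MM - r_QM) / |r_MM - r_QM|

and the force the cap accumulates is redistributed to the two real atoms by
the chain rule, `f_MM = J^T f_L` with
`J = (d / d_MM-QM)(I - r_hat r_hat^T)`, `f_QM = f_L - f_MM` — an exact
partition that conserves energy, force, and torque. Bonded terms fully
described by the QM calculation are pruned from the classical topology by
the standard rules (bonds with two QM atoms; angles with a QM central atom;
proper dihedrals with two QM central atoms; impropers with a QM central
atom).

**Periodic safety.** Every step, the engine verifies that no QM atom can see
a periodic copy of another QM atom and that all gathered MM atoms present a
single consistent image; a violation terminates the run with the offending
atoms and step.

**Observables.** Radial distribution functions, vibrational power spectra
from autocorrelation functions, geometric hydrogen bonds with
continuous-run lifetimes, signed improper-dihedral series of hydrogen-bond
acceptors, and a vaporization-enthalpy estimator
`dH_vap = -<E_uv>/2 + RT`.

**Fixtures.** Deterministic SPC water boxes, a 19-atom toy tripeptide whose
sidechain (from C-beta) forms a linked QM zone, a QM-specification file
parser (QMZONE/QMUNIT/CAPLEN blocks, cnf-style fixed columns), and a
generated fake QM executable that exercises the full subprocess/file
protocol.

## Worked example

```r
library(miniqmmm)

fix <- build_toy_tripeptide(seed = 1)
report <- validate_system(fix$topology, fix$qmzone)
head(report$removed, 3)
#>   class atoms
#> 1  bond   8-9
#> 2  bond  8-10
#> 3  bond  8-11
# ... 20 terms delegated to the QM calculation

out <- assemble_qmmm(fix$topology, fix$state, fix$qmzone,
                     embedding_config("EE", qmmm_cutoff = 2.0),
                     mock_qm_backend(tripeptide_mock_params(fix)),
                     mm_params(rf_cutoff = 2.5, rf_epsilon = 1,
                               pairlist_cutoff = 2.5))
out$report
#>           bond       3.8330 kJ/mol
#>          angle       0.8156 kJ/mol
#>         proper       2.0989 kJ/mol
#>       improper       0.0001 kJ/mol
#>          lj_mm      40.5173 kJ/mol
#>  coulomb_rf_mm     -31.3014 kJ/mol
#>    qm_internal       2.9716 kJ/mol
#>        qmmm_lj       6.1939 kJ/mol
#>   qmmm_coulomb      25.4363 kJ/mol
#>          total      50.5652 kJ/mol

colSums(out$forces)        # net force ~ 1e-13: nothing leaks at the boundary
```

The decomposition shows the division of labor: the sidechain's internal
terms live in `qm_internal` (the mock backend), its electrostatic coupling
to the backbone has moved into the QM calculation (EE), while the QM-MM
Lennard-Jones term and all backbone terms remain classical.

The improper dihedral used to characterize hydrogen-bond acceptor geometry
takes its textbook value on an ideal tetrahedron:

```r
dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1)) / sqrt(3)
dihedral_angle(c(0, 0, 0), dirs[1, ], dirs[2, ], dirs[3, ])
#> [1] -35.26439
```

A command-line front end wrapping the same functions ships in
`inst/scripts/miniqmmm` (`run`, `scan`, `analyze
rdf|spectrum|hbonds|improper|dhvap`, `make-fixture`).

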