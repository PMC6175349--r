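# chirasieve

Screening toolkit for membrane-based chiral separation by molecular
sieving.

Single-atom-thick membranes — nanoporous graphene or graphdiyne — can in
principle separate the enantiomers of a chiral molecule: a chiral
"gatekeeper" molecule attached to a pore rim forms a temporary bimolecular
complex with the passing target, and the complex formed by one enantiomer
is spatially larger than the complex formed by its mirror image. Because a
propagation event through a single-layer pore is a single barrier crossing,
the size difference translates directly into a difference in barrier
heights, and hence into enantioselective transport. `chirasieve` implements
the desk-scale machinery for screening this mechanism:

* **Pore models** — finite, hydrogen-passivated graphene flakes with rings
  removed, a triangular graphdiyne unit, nitrogen rim substitution, a rigid
  gatekeeper attachment, rim detection, and pore-diameter metrics.
* **Complex screening** — for a pair of chiral monomers, the lowest-energy
  rigid bimolecular complex is located for the opposite-chirality (RS) and
  same-chirality (SS) pairings, and the screen reports

  &Delta;E = E_RS − E_SS,&ensp;&Delta;R = R_RS − R_SS,

  where R, the *complex size*, is the distance between the two most
  distant atoms of the complex. Large |&Delta;R| marks a combination
  promising for size-based chiral sieving.
* **Propagation profiles** — rigid constrained scans: the target molecule is
  pushed along the membrane normal through the pore center in 0.25 Å steps
  with fixed orientation, energies referenced to infinite separation,
  interpolated by cubic splines, and the extrema classified onto the
  pathway schema (left minimum, 1st transition state, intermediate, 2nd
  transition state, right minimum).
* **Pathways** — a nudged elastic band optimizer (improved tangent,
  optional climbing image) over rigid-molecule poses, plus Boltzmann
  selectivity (`exp(-ΔΔE/k_B T)`) and permeance indicators.
* **Energy model** — an internal Lennard-Jones 12-6 + Coulomb engine
  (UFF-derived per-element parameters, Lorentz–Berthelot mixing, 12 Å
  cutoff, k_e = 332.0636 kcal·Å/(mol·e²)), behind an engine contract that
  external backends (e.g. tight-binding codes) can implement through an
  XYZ-in/energy-out adapter.

Everything is generated programmatically: probe molecules (CO2-like,
CH4-like, ethane-like, a chiral tetrahedral probe, 1-aminoethanol) and a
five-template chiral library (acid, aldehyde, alcohol, olefinic alcohol,
ether; both enantiomers each) ship as deterministic fixture generators, so
no external data are needed.

## Worked example

```r
library(chirasieve)

# the three shipped pore models and their openings
for (p in c("graphene4", "graphene3", "graphdiyne")) {
  pore <- build_pore(p)
  cat(sprintf("%-10s %2d rim atoms, diameter %.3f A\n",
              p, length(pore$rim_indices), pore$diameter))
}
#> graphene4  24 rim atoms, diameter 6.037 A
#> graphene3  18 rim atoms, diameter 5.500 A
#> graphdiyne 12 rim atoms, diameter 5.616 A

# chirality screen of one template combination
lib <- generate_template_library()
pairing_deltas(lib$acid$R, lib$acid$S, lib$alcohol$S,
               lj_engine(), search_config(n_starts = 64, seed = 7),
               combo_label = "acid-alcohol")
#>    combo_label      E_RS      E_SS    R_RS     R_SS     delta_E   delta_R
#> 1 acid-alcohol -4.810765 -4.743743 7.71014 7.096122 -0.06702119 0.6140176

# rigid propagation scan: methane-like probe through the 4-ring pore
prof <- rigid_scan(build_pore("graphene4"), generate_fixture("ch4_like"))
prof$extrema
#>            z    energy    kind
#> 1 -1.0579058 -4.539532 minimum
#> 2  0.3627522 -1.735790 maximum
#> 3  1.5905620 -3.869440 minimum
```

The scan output shows the asymmetric profile of a tetrahedral probe
entering tip-first (global minimum on the negative-z side), with the
rate-determining maximum near the pore plane; energies are kcal/mol
relative to the separated pair.

A thin command-line wrapper is installed with the package
(`exec/chirasieve`): `build-pore`, `fixtures`, `screen`, `scan`, `neb` and
`report` subcommands over the same functions.

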