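# siechit

Endpoint binding free-energy estimation and trajectory contact analysis
for protein–carbohydrate complexes, built around the solvated
interaction energy (SIE) function and the GH18 chitinase catalytic
motif.

## What it does, and for whom

Given snapshots of a receptor–ligand complex (PDB / multi-model PDB),
`siechit` estimates the binding free energy with the SIE endpoint
function

ΔG_bind(ρ, D_in, α, γ, C) = α·[ E_C(D_in) + ΔG_RF(ρ, D_in) + E_vdW + γ·ΔMSA(ρ) ] + C

where E_C and E_vdW are the intermolecular screened-Coulomb and
Lennard-Jones energies, ΔG_RF is the reaction-field (Poisson)
solvation change upon binding, ΔMSA the change in molecular surface
area, and the calibrated constants default to α = 0.1048, D_in = 2.25,
ρ = 1.1, γ = 0.0129 kcal/(mol·Å²), C = −2.89 kcal/mol. Per-frame terms
are aggregated as mean ± SEM over trajectory frames.

Companion analyses target the question *which contact anchors the
sugar*: radial distribution functions between atom selections
(`radial_distribution()`, `rdf_peak()`), distance-criterion
hydrogen-bond occupancy (`hbond_occupancy()`, default 3.0 Å), and
location of the GH18 catalytic `DXXDXDXE` motif in protein sequences
(`find_motif()`, `catalytic_residues()` — the last Asp of the motif
hydrogen-bonds the substrate acetamido nitrogen; the Glu is the
catalytic acid). A seeded synthetic generator
(`build_toy_complex()`, `generate_trajectory()`) builds toy
pocket/chito-oligosaccharide complexes with a designed
carboxylate–amide-nitrogen contact, so every stage runs and is testable
with no external data. Intended users: structural
bioinformaticians triaging modeled glycosidase–oligosaccharide
complexes, and method developers who need a transparent, fully
validated reference implementation of the SIE terms.

## Worked example

```r
library(siechit)

## 1. recombine a published per-term SIE table into binding free energies
sie_from_components(chitinase1198_sie_components())
#>          complex   dg_bind
#> 1 glcnac12_unit2 -12.46453
#> 2 glcnac12_unit3 -11.76656
#> 3  glcnac3_unit2  -9.99544

## 2. synthetic trimer complex with a designed Asp440-N2 contact at 2.75 A
spec <- toy_complex_spec(n_sugar_units = 3, contact_unit = 2,
                         contact_distance_mean = 2.75,
                         contact_distance_sd = 0.1, seed = 7)
cx   <- build_toy_complex(spec)
traj <- generate_trajectory(cx, spec, n_frames = 2000)

od <- select_atoms(cx, "resname ASP and name OD1 OD2")
n2 <- select_atoms(cx, "resname NAG and resid 2 and name N2")
rdf_peak(radial_distribution(traj, od, n2))
#> [1] 2.775
hbond_occupancy(traj, od, n2, cutoff = 3.0)$occupancy
#> [1] 0.996

## 3. score one snapshot (screened Coulomb + LJ + Poisson + cavity)
score_snapshot(cx, select_atoms(cx, chain = "A"),
               select_atoms(cx, chain = "B"),
               grid = grid_spec(spacing = 0.6, padding = 2.4))
#> Inter vdW           1.41 kcal/mol
#> Inter Coulomb      26.23 kcal/mol
#> Reaction Field    -17.49 kcal/mol
#> Cavity             -5.14 kcal/mol
#> Constant           -2.89 kcal/mol
#> dG_Binding         -2.36 kcal/mol
```

The first block reproduces the three published binding free energies
(−12.46, −11.77, −10.00 kcal/mol) from their printed per-term
components. The second shows the analysis stack recovering the designed
contact-distance mode (2.775 Å, within one 0.05 Å bin of the 2.75 Å
design) and its hydrogen-bond occupancy at the 3.0 Å criterion. The
third scores a toy snapshot end to end; on this deliberately charged
toy geometry the screened Coulomb term is repulsive and the reaction
field compensates — the printed rows always satisfy the SIE combination
identity exactly.

A thin command-line wrapper covering the same operations ships in
`inst/scripts/siechit` (subcommands `score`, `rdf`, `motif`,
`simulate`, `born-check`; `--config` takes a YAML file, flags win).

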