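# popstate

Conformational-state calling, solution-scattering analysis and enzyme
kinetics for two-domain prolyloligopeptidase (POP) family serine peptidases.

## The scientific problem

POP-family enzymes — prolylendopeptidases (PEP), acylaminoacylpeptidases and
oligopeptidases B (OpB) such as PSP from *Serratia proteomaculans* — consist
of a catalytic α/β-hydrolase domain carrying a Ser–His–Asp triad and a
seven-bladed β-propeller domain, linked by two short hinge strands. The
enzyme cycles between a **closed** state (domains packed together, triad
assembled, catalysis possible), an **open** state (domains apart, triad
disrupted, substrate can enter) and a rarer **intermediate** state that
combines closed-like domain packing with an open-like, disrupted triad.
Which state a structure or a solution ensemble occupies is diagnostic for
the activation mechanism and matters for inhibitor design.

`popstate` implements the quantitative framework for making that call, and
the companion solution-state analysis:

- **Structure side.** Atomic structures (PDB/mmCIF, via bio3d) are
  partitioned into the POP domain scheme (N-terminal loop 1–70, hinge 71–76,
  β-propeller 77–404, hinge 405–410, hydrolase fold 411–676 in PSP
  numbering). The triad is scored by the Ser OG–His NE2 and His ND1–Asp OD
  distances; domain closeness by the interdomain centre-of-mass separation
  and the Shrake–Rupley buried-surface fraction. The two-axis rule is:

  | triad intact (both gaps ≤ 4 Å) | domains close (COM ≤ 34.5 Å) | state |
  |---|---|---|
  | yes | yes | closed |
  | no | yes | intermediate |
  | no | no | open |

  Aperture (channel/opening) distances, interdomain salt bridges, hydrogen
  bonds, polar contacts, ligand proximities, B-factor profiles and Kabsch
  superposition complete the structural toolbox.

- **Solution (SAXS) side.** Forward scattering from coordinates by the
  Debye formula `I(q) = Σᵢⱼ fᵢfⱼ sin(q rᵢⱼ)/(q rᵢⱼ)`; Guinier analysis
  (`I(q) ≈ I₀ e^{−q²Rg²/3}`); the pair-distance distribution `P(r)` by a
  regularized, non-negative indirect Fourier transform with Dmax scanning;
  the volume of correlation `Vc = I(0)/∫ q I(q) dq`; dimensionless Kratky
  plots; χ² scaling of model curves onto experimental ones; and two-state
  mixture deconvolution `I ≈ c·(f·I_A + (1−f)·I_B)` for open/intermediate
  equilibria. A simplified dummy-atom annealer reconstructs low-resolution
  shapes from a scattering curve.

- **Kinetics.** Michaelis–Menten fits (`v/E = kcat·S/(Km+S)`) with
  catalytic efficiencies on the conventional ×10⁷ M⁻¹min⁻¹ scale and
  mutant-panel comparisons relative to a reference enzyme.

- **Synthetic ground truth.** Generators for two-domain toy structures with
  a tunable hinge angle and planted triad geometry, globular scatterers
  with exact Rg, noisy scattering curves, mixtures at planted fractions and
  rate data — every validation input is produced in code with known truth.

## Worked example

```r
library(popstate)

# two synthetic two-domain enzymes: fully closed, and opened by 35 degrees
closed <- make_toy_two_domain(toy_spec(hinge_angle = 0,  triad_gap = 3.3, seed = 1))
open   <- make_toy_two_domain(toy_spec(hinge_angle = 35, triad_gap = 15,  seed = 1))
run_state_profile(list(closed$structure, open$structure))[,
  c("id", "d_og_ne2", "com_distance", "buried_catalytic", "conformation")]
#>            id d_og_ne2 com_distance buried_catalytic conformation
#> 1 toy_angle00      3.3         31.8              3.8       closed
#> 2 toy_angle35     15.0         39.3              0.3         open
```

Opening the hinge moved the centres of mass 7.5 Å apart and emptied the
interface; the planted 15 Å nucleophile gap disrupts the triad, so the call
flips from closed to open.

Applying the same classifier to the published domain-positioning metrics of
nine POP-family crystal structures reproduces every reported assignment:

```r
state_call_table(pop_reference_metrics())[,
  c("pdb_id", "protein", "com_distance", "d_og_ne2", "reported_conformation", "label")]
#>   pdb_id protein com_distance d_og_ne2 reported_conformation        label
#> 1   7OB1     PSP         32.3     13.9          intermediate intermediate
#> 2   4BP8   TbOpB         36.7     18.3                  open         open
#> 3   4BP9   TbOpB         30.4      3.5                closed       closed
#> 4   3IUL   ApPEP         38.7       NA                  open         open
#> 5   3IVM   ApPEP         30.7      3.3                closed       closed
#> 6   5N4F   GmPEP         39.4       NA                  open         open
#> 7   5N4C   GmPEP         32.0       NA          intermediate intermediate
#> 8   5T88   PfPEP         30.9     17.4          intermediate intermediate
```

A solution-scattering run on a synthetic globule of planted Rg 27.4 Å (the
size of the ~76 kDa PSP monomer) with 1% noise:

```r
g    <- make_toy_globule(rg = 27.4, n_atoms = 1500, seed = 8)
prof <- simulate_saxs(g, noise_model(level = 0.01, seed = 3))
run_saxs_analysis(list(globule = prof))[, c("name", "rg", "dmax", "vc")]
#>      name       rg     dmax       vc
#> 1 globule 27.67272 70.01775 553.6527
```

The Guinier Rg lands ~1% above the planted value (the known window bias for
solid globules; the real-space Rg from `pddf()` recovers 27.4 to ~0.1%),
and Dmax matches the globule's true diameter 2·27.4·√(5/3) ≈ 70.8 Å.

Kinetic panel arithmetic, e.g. reproducing published efficiencies:

```r
recompute_efficiency_panel()[c(1, 10),
  c("enzyme", "substrate", "kcat", "km_uM", "printed_eff", "computed_rounded", "match")]
#>    enzyme substrate  kcat km_uM printed_eff computed_rounded match
#> 1  PSPmod     BAPNA  91.7 188.8       0.049            0.049  TRUE
#> 10    PSP     BAPNA 791.2  78.1        1.01            1.010  TRUE
```

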