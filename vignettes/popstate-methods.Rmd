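---
title: "Methods: state calling, scattering analysis and kinetics in popstate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: state calling, scattering analysis and kinetics in popstate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `popstate`, the defaults
and why they were chosen, the numerical machinery, and what the synthetic
validation does and does not establish.

## The conformational-state model

POP-family peptidases are scored on two independent axes.

**Triad integrity.** The catalytic triad (Ser532/His652/Asp617 in PSP
numbering) is *intact* when both side-chain contacts are at hydrogen-bond
distance: Ser OG–His NE2 ≤ `t_triad` and His ND1–Asp OD ≤ `t_triad`, with
the Asp gap taken as the minimum over OD1/OD2 (which carboxylate oxygen
engages the histidine is structure-dependent, so we report the minimum and
note it). Default `t_triad = 4.0` Å: intact triads in closed POP structures
sit at 2.9–3.5 Å while disrupted ones exceed 7 Å, leaving a wide margin on
both sides. When His-loop side-chain atoms are absent from a model —
typical for open-state structures, whose His-loops are disordered — the
triad counts as disrupted, with the reason recorded, rather than erroring
or silently reporting zero. The same rule covers a mutated catalytic serine.

**Domain closeness.** The primary metric is the separation of the domain
centres of mass (catalytic = N-terminal loop + hydrolase fold; hinge
strands belong to neither domain). Open-state separations run 6–8 Å larger
than closed/intermediate ones, and the two clusters in the POP structural
corpus sit near 30–32 Å and 36–39 Å; the default threshold `t_com = 34.5` Å
is the midpoint. Because centre-of-mass distances within ~1 Å of the
threshold would make the call fragile, a secondary vote applies inside that
band: the buried-surface fraction of the catalytic domain (`t_buried = 10%`;
open structures bury ≤ 8.4%, closed/intermediate ≥ 11.3%). Mass-weighted
and unit-weighted centres of mass differ by well under the decision margin
for globular domains; the state profile reports both.

The label follows directly: intact + close = closed; disrupted + close =
intermediate; disrupted + apart = open. Intact + apart is geometrically odd
(a formed triad across separated domains) and is returned as
`indeterminate` rather than forced into a category. All thresholds live in
`state_thresholds()` and are carried inside every call object, never
hard-coded downstream.

## Interface quantification

Solvent-accessible surface areas use the Shrake–Rupley construction: 960
quasi-uniform (golden-spiral, hence deterministic) test points per atom on
the probe-expanded van der Waals sphere (C 1.70, N 1.55, O 1.52, S 1.80 Å;
probe 1.4 Å). The buried fraction of a domain is
`100 × (SASA(alone) − SASA(in context)) / SASA(alone)`, with hinge strands
excluded from both domains — they are covalent connectors, not interface —
and waters/ligands excluded from the context. A residue is interfacial when
its area drops by more than `dsasa_min = 0.1` Å² between the two states.
These conventions differ in detail from PISA's (no solvation-energy model,
no angular hydrogen-bond term since deposited models carry no hydrogens),
so buried percentages are comparable across structures analysed the same
way but not expected to reproduce PISA to better than ~1–2 percentage
points. Salt bridges pair formally charged side-chain nitrogens (Arg
NE/NH1/NH2, Lys NZ; His only on request) with Asp/Glu carboxylate oxygens
at ≤ 4.0 Å, one bridge per residue pair at the minimum distance.

## Solution scattering

**Debye forward model.** Point scatterers with unit weights by default
(shape-only) or atomic-number weights; no excluded-volume or hydration
terms. Consequently absolute χ² values against experimental curves from
hydration-aware programs are not comparable — only orderings, recovered
sizes and mixture fractions are meaningful, and those are what the package
asserts. Above 1000 scatterers the O(N²) sum switches to a pair-distance
histogram (0.25 Å bins), which is exact to well under 1% over the
instrument q-range.

**Guinier.** Weighted linear fit of ln I on q² over the widest low-q window
with q·Rg ≤ 1.3 (globular convention), iterated until the window implied by
the fitted Rg is stable. A non-negative low-q slope (aggregation,
non-globular input) is a hard error, not a number. One bias is worth
knowing: for solid globular particles the qRg ≤ 1.3 window overestimates Rg
by ~2% (the Guinier parabola lies above the true sphere form factor's
curvature). Size recovery claims therefore rest on the real-space Rg from
the indirect transform, which recovers planted radii to ~0.1%; the Guinier
value is reported alongside as the conventional quantity.

**Indirect transform.** P(r) is represented on a 101-point grid anchored to
zero at r = 0 and r = Dmax, and obtained by minimizing the weighted data
misfit plus `alpha` times a second-difference roughness penalty subject to
P ≥ 0 (clipped coordinate descent from the clipped ridge solution). `alpha`
defaults to the L-curve corner over a 13-point log-spaced scan. Dmax is
estimated by scanning candidates over (1.4–4.5)·Rg, scoring misfit plus a
penalty on P(r) mass stranded at the endpoint, and taking the smallest
candidate within 5% of the best score — the classical corner where misfit
stops improving — followed by a finer local scan. A flat score profile
raises an `ambiguous-dmax` warning.

**Vc and Kratky.** The volume of correlation integrates q·I(q) by
trapezoid with a Guinier extrapolation closing [0, q_min] and an upper
limit of 0.3 Å⁻¹ (common practice; a convergence check in the tests shows
< 2% movement when extending to 0.5 Å⁻¹). The dimensionless Kratky default
is the Rg-based scaling ((qRg)²I/I₀ against qRg), under which an ideal
globule peaks at (√3, 3/e); the Vc-based scaling (q²·Vc·I/I₀) is provided
as an option since conventions differ between analysis suites — the default
is ours, documented rather than asserted as anyone else's.

**Mixture deconvolution.** For a two-state equilibrium the experimental
curve is modelled as a global scale times f·I_A + (1−f)·I_B; f is scanned
at 0.01 resolution with the scale solved analytically, then refined
locally. The +1-χ² interval around the optimum is reported; when the two
components are (near-)indistinguishable the interval spans essentially
[0, 1] and a degenerate-components warning fires instead of a false
confident fraction.

## Bead-model reconstruction

The annealer is a deliberately simplified dummy-atom method: single-bead
occupancy flips on a simple-cubic lattice (bead radius 3 Å by default,
spacing one diameter) under Metropolis acceptance on

E = χ²(model, target) + w_conn · (fraction of occupied beads with no
occupied neighbour) + w_comp · max(0, Rg/Rg_target − 1),

with χ² evaluated on a ≤100-point q grid from an incrementally maintained
pair-distance histogram. The schedule calibrates T₀ so that about half of
the initial proposals are accepted (median uphill step / ln 2), cools by
0.9 per stage, runs 5·N_sites moves per stage and stops after three stages
with < 0.1% best-energy improvement. Published slow-annealing schedules for
dummy-atom refinement are not fully specified in the literature we model;
this schedule is an independent choice and is documented as such. No
hydration shell, no bead form factor, no multi-run averaging, no symmetry
constraints: the product is a low-resolution envelope whose Rg and overall
dimension are testable, not a density map.

## Kinetics

Michaelis–Menten parameters come from unweighted nonlinear least squares
(`nlsLM`), initialized from the Lineweaver–Burk linearization; optional
1/v² weighting is available behind a flag. Efficiencies are reported on the
conventional ×10⁷ M⁻¹min⁻¹ scale (kcat in min⁻¹, Km in µM). The curated
reference panel for the PSP series keeps the published efficiency column as
a string so comparisons can honour each cell's printed precision; the
recomputation utility flags, rather than reconciles, cells whose printed
efficiency disagrees with their own kcat and Km (one such cell exists in
the panel, printed 8.15 where kcat/Km gives 7.16, and the published
activity-restoration percentages 35/21/6% likewise recompute to
36.0/5.5/23.0%). Relative-activity claims are therefore evaluated on the
published efficiency column itself.

## Synthetic ground truth, and what the tests do and do not show

The toy generator builds two pseudo-globular domains (random dense packings
in spheres of radius 17 and 21 Å, one C-alpha pseudo-atom per residue)
numbered exactly like the real domain scheme, joined by two 6-residue
linkers. The hinge angle rotates the propeller about a spine 15 Å below the
interface midpoint, so the centre-of-mass separation grows monotonically
(~0.25 Å/degree, reaching the 6–8 Å open/closed gap by ~30–35°) while the
buried surface shrinks — the geometry of book-like domain opening. Triad
marker atoms realize requested gaps exactly, ligand plants sit at exact
offsets, and per-residue B-factors are drawn once and recorded, so every
downstream quantity has a known expected value. Noise defaults to 1%
multiplicative Gaussian, the scale of high-flux synchrotron data; a
Poisson-like counting model is available. Everything is a pure function of
its specification plus seed, byte-reproducibly.

These toys are not folded proteins: no secondary structure, no side chains,
no hydration, no interparticle effects, no beam smearing. Passing tests
demonstrate that the estimators recover known geometry and planted
parameters under controlled noise — they do not certify accuracy on real
detector data, where buffer subtraction and hydration contrast dominate the
error budget. Likewise, buried-surface percentages on CA-only toys are
smaller than on all-atom structures; the toy assertions target
monotonicity and zero limits, not absolute values.

## Problem sizes and determinism

Defaults were chosen so the whole validation suite runs on a laptop-scale
budget: 1200–3000 scatterers for Debye curves (histogram path beyond 1000),
101-point P(r) grids with 25 + 9 Dmax candidates, ~900 lattice sites and 25
temperature stages for the annealer, 50-seed replicate sets for noise
studies. Every stochastic step (toy generation, noise, annealing, random
fills) flows through an explicit seed and restores the caller's RNG state,
so identical inputs give byte-identical outputs.

## Interfaces

The package is an R-level toolkit: the exported functions plus the two
workflow drivers `run_state_profile()` and `run_saxs_analysis()` (which
write plain TSV reports) are the intended entry points, and
`scripts/acceptance.R` is the reproducibility driver. File formats are the
field's plain-text standards: PDB/mmCIF in, PDB out for toys and bead
models, whitespace-delimited (q, I, σ) with `#` comments for scattering
curves, TSV for tables.

## Known limitations

- Real deposited structures are required for absolute interface
  percentages and the crystallographic regression values; they are not
  redistributed with the package.
- The Debye model's lack of solvent terms makes absolute χ² against
  hydration-aware theoretical curves non-comparable by design.
- The indirect transform's Dmax scoring assumes a single monodisperse
  particle; polydispersity will bias it high.
- The annealer reconstructs envelopes at bead resolution; it does not
  attempt uniqueness (no multi-run averaging) and its connectivity and
  compactness penalties are heuristics, not physical priors.
- Custom domain ranges must be supplied for POP homologs whose boundaries
  differ from the PSP scheme; the shipped comparator metrics table is
  curated from published per-structure measurements.
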