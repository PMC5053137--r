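---
title: "Detecting, correcting and validating tetrahedral zinc sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting, correcting and validating tetrahedral zinc sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(znsite)
```

## The problem

Structural zinc sites in proteins are typically Zn²⁺ ions coordinated
tetrahedrally by four cysteine thiolates and/or histidine imidazole
nitrogens — ZnCys<sub>x</sub>His<sub>y</sub> with x + y = 4.  Deposited
crystallographic models frequently get these sites wrong: Zn–ligand
bonds are unrestrained by default in refinement, automatic
disulfide-bond detection can pull two zinc-binding cysteines into a
spurious cysteine bridge, and LINK/SSBOND header annotation is often
missing or wrong, which in turn makes refinement programs generate the
wrong restraints.

`znsite` implements the remediation workflow around these sites:

1. **Detection** of putative tetrahedral ZnCys<sub>x</sub>His<sub>y</sub>
   complexes around every Zn ion.
2. **Cys-cleaning**: correction of SSBOND/LINK annotation at detected
   sites.
3. **Restraint generation** in the REFMAC external-restraint keyword
   dialect.
4. **Geometric validation** with composition-specific Z-scores combined
   into a root-mean-square Z (r.m.s.Z) quality metric.
5. A **synthetic-site generator** so the entire pipeline is testable
   without any deposited data.

Actual crystallographic re-refinement (running REFMAC), electron-density
metrics and bond-valence ion identification are out of scope; the
package prepares inputs for and judges the output of such refinements.

## Detection model

Around each Zn atom (highest-occupancy conformer, hydrogens ignored)
the detector searches for Cys S^γ^ atoms within **4.8 Å** and His
N^δ1^/N^ε2^ atoms within **3.8 Å**; at most one nitrogen per imidazole
is a candidate (the nearer one, ties towards N^δ1^, since an imidazole
donates one coordination bond).  When five or more candidates are
found, Dixon's Q-test (one-sided r10 variant) is applied iteratively to
the sorted Zn–ligand distances: the largest distance is tested with

Q = (d_n − d_{n−1}) / (d_n − d_1)

and removed while Q exceeds the critical value and more than four
candidates remain.  The critical table for n = 3..10 at 90/95/99 %
confidence is embedded; 95 % is the default (the source method does not
state its level, so it is configurable).  A degenerate sample in which
the gap equals the range gives Q = 1 and is always rejected; a
zero-range sample cannot reject.

Exactly four survivors are required.  Two discard conditions are then
evaluated:

* **(i)** a *foreign* donor atom (N, O, S, P or a halogen — not carbon,
  not hydrogen, and not a side-chain atom of the candidate residues
  themselves) lies at **2.9 Å** or closer to the Zn;
* **(ii)** any surviving ligand lies at **3.25 Å** or further.

By default a site is discarded when *both* hold.  ZnHis₄ sites are
additionally discarded when (i) alone holds — this is what keeps
octahedral ZnHis₆-like sites (which present four nitrogens plus other
donors) out of the result.  Sites with at least three His ligands must
have all four ligands within **3.0 Å**.  A configuration switch
(`discard_combination = "or"`) treats (i) and (ii) as independent
discard rules instead, because the published phrasing is ambiguous;
the conjunction is the default since the source explicitly says ZnHis₄
is *also* discarded "if only requirement (i) is satisfied".  One
consequence of the conjunction, exercised by the tests: a ZnCys₄ site
with one bond stretched to 3.3 Å but no foreign atom nearby is still
accepted (and will simply validate badly).

Accepted sites sharing an S^γ^ atom are joined into cluster groups
(bridging cysteines such as the Cys₃–Zn–Cys–Zn–Cys₂His₁ arrangement),
and each site is flagged when a ligand residue sits next to a chain
break — a sequence neighbour missing from the chain interior, or a
peptide C–N distance above 2.5 Å (a generous bound over the ~1.33 Å
peptide bond; the source gives no number).  Chain termini do not count
as breaks.

## Annotation cleaning

`plan_changes()` removes every SSBOND in which either cysteine
coordinates a detected Zn, removes LINKs from a site's Zn to anything
that is not one of its four ligands (and spurious LINKs joining atoms
of two detected sites), and adds one LINK per missing Zn–ligand bond,
with the measured distance in the LINK distance field.  A bridging
S^γ^ receives one LINK per coordinated Zn.  Records referencing atoms
absent from the model are preserved verbatim and logged.  Applying a
plan and re-planning yields an empty changeset (idempotence), and
coordinates are never touched.

## Restraints

Distance restraints use the refinement-dictionary targets
Zn–S^γ^ = 2.340 ± 0.020 Å, Zn–N^δ^ = 2.057 ± 0.064 Å,
Zn–N^ε^ = 2.058 ± 0.073 Å.  External angle restraints are generated for
every S^γ^–Zn–S^γ^ pair at the ideal tetrahedral 109.5 ± 3.0°; angles
involving histidine are never restrained (imidazole positions are
already well defined by the ring's rigidity).  So a ZnCys₄ site yields
4 distance + 6 angle lines and ZnHis₄ yields 4 + 0.  Dictionary-style
angles (Zn–S^γ^–C^β^ 109.000 ± 3.000°; Zn–N–C ring angles
125.350 ± 3.000°, two per coordinated nitrogen) are emitted only on
request, because in the source workflow they travel through the
refinement dictionary via LINK records rather than the external
restraint file.

The exact keyword layout is not published; the dialect here follows the
documented REFMAC external-restraint grammar:

```
exte dist first chain A resi 101 atom ZN second chain A resi 10 atom SG value 2.340 sigma 0.020
exte angle first chain A resi 10 atom SG next chain A resi 101 atom ZN next chain A resi 20 atom SG value 109.500 sigma 3.000
```

with an `ins <code>` selector for insertion codes and `symm y` appended
to selectors of atoms reached through a symmetry operation.
`parse_refmac_external()` round-trips this text for testing.

## Validation model

For each accepted site, `measure_site()` records the four Zn–ligand
distances, all six ligand-pair angles at the Zn vertex, S^γ^–S^γ^
distances, Zn–C^β^ distances per Cys, the deviation of the Zn from the
centroid of its four ligand atoms, occupancy/B-factor summaries, the
apparent cysteine-bridge multiplicity (ligand S^γ^ pairs closer than
2.5 Å), and a per-His flip flag (a ring carbon C^δ2^/C^ε1^ nearer to
the Zn than both ring nitrogens indicates a 180° mislabelled
imidazole; flips are flagged, never rebuilt).

Z-scores are computed against composition-specific targets for
structures solved at 1.6 Å or better (`builtin_targets("res16")`):

```{r targets}
tg <- builtin_targets("res16")
subset(as.data.frame(tg), kind %in% c("zn_sg_distance", "sg_zn_sg_angle",
                                      "zn_n_distance", "n_zn_n_angle"))
```

Entries published as n/a or with insufficient data (all His₄ rows, the
Cys₁His₃ angle) are simply absent; features without a target are
excluded from r.m.s.Z and listed under `insufficient_targets`.  The
N^δ^/N^ε^ split is pooled for validation (there are not yet enough data
to separate them), while restraint *generation* uses the split
dictionary values.  Mixed S–Zn–N angles have no published target
anywhere and are reported raw only.  A `res25` class (2.5 Å or better)
exists in the interface, but its source table is not distributed with
this package, so requesting it is an error rather than a silent
substitution.

Three derived target kinds are filled by first-order error propagation
from the primary ones:

* **S^γ^–S^γ^ distance**: mean 2·μ_d·sin(μ_θ/2) from the Zn–S^γ^ and
  S^γ^–Zn–S^γ^ targets.
* **Zn–C^β^ distance**: law of cosines over the Zn–S^γ^ target, a fixed
  1.81 Å S^γ^–C^β^ bond and the 109.000° Zn–S^γ^–C^β^ angle target.
* **Zn-centroid deviation**: this package *derives* its expected value
  from the published means instead of assuming zero.  The published
  Cys and His bond lengths differ (2.306 vs 2.040 Å in Cys₂His₂, for
  example), so even a site built exactly at the published means has its
  ligand centroid displaced from the Zn by
  |x·d_S·g(x, θ_S) − y·d_N·g(y, θ_N)|/4, where g is the axial sum of a
  symmetric cone of ligand directions at the published within-class
  pair angle (g = 0 for the regular tetrahedron).  That offset is
  0.021–0.030 Å for the mixed compositions and exactly 0 for Cys₄ and
  His₄.  With an assumed expectation of 0 a perfect mixed site would
  be penalised ~0.2–0.3 Z and could never validate to r.m.s.Z ≈ 0.
  The spread σ_pos = 0.10 Å is an assumption (no published value
  exists) and is configurable via `builtin_targets(sigma_pos =)`.

r.m.s.Z is the root of the mean squared Z over the included components;
it is 0 exactly when every included component sits at its target, and
well-refined sites are expected near 1.  Aggregate per-structure
statistics exclude chain-break-flagged sites.

```{r validate}
s <- build_composition_suite()
vs <- validate_structure(s)
vs$summary[, c("zn", "composition", "rmsz", "chain_break")]
```

## The synthetic world

`build_site()` places the Zn at the origin and the four ligand atoms on
exact tetrahedral vertices (pair angle arccos(−1/3) ≈ 109.47°) at the
composition's published mean bond lengths; His₄, which has no published
validation distance, uses the 2.057/2.058 Å dictionary targets.  Each
Cys is completed with C^β^ (1.81 Å, Zn–S^γ^–C^β^ 109°) and backbone;
each His with a planar imidazole (regular pentagon, 1.35 Å sides)
oriented so the chosen ring nitrogen's lone pair points at the Zn.
Ligand residues sit at well-separated numbers (10, 20, 30, 40) in one
chain, each flanked by glycine stub residues at r ± 1 with proper
peptide C–N distances so chain-break flags are false by construction;
fixture variants that delete a stub exercise the flag.  Backbone
geometry beyond bond lengths is legal-but-arbitrary: only side-chain
geometry matters to the method.

`site_spec(pair_angles = "table")` instead places the Cys and His
groups on two opposing symmetric cones whose within-class pair angles
equal the published composition means — the "built exactly at the
published means" fixture, and the same construction that defines the
derived centroid target.  With it, all five compositions validate at
r.m.s.Z < 0.05 (the acceptance property); with the default tetrahedral
directions, mixed compositions legitimately score 0.3–0.8 because their
angles are *not* at the published means.

`distort()` reproduces the error classes seen in deposited models:
coordinate noise, one bond stretched, a cysteine rotated away about its
C^β^, a displaced Zn, a planted water oxygen, a spurious disulfide
SSBOND, dropped LINKs, and a flipped His ring.  `decoy_suite()` bundles
the adversarial cases: an octahedral ZnHis₆ site (must not be detected),
a ZnCys₃+water site (rejected — with only three candidate ligands it is
undercoordinated before the foreign-ligand rule can even apply), an
ideal ZnCys₄ plus a fifth S^γ^ at 4.5 Å (Q = 1.0 > 0.71, the outlier is
rejected and the site accepted), and a bridged two-Zn cluster (two
sites, one cluster group).  In the bridged cluster the Zn–S^γ^–Zn
bridge angle is set to 120° so that neither Zn's candidate shell
contains stray atoms of the other site — the iterative one-sided
Q-test, like the original, can be masked by two clustered outliers,
and the fixture is built not to probe that known limitation.

What a green synthetic suite does **not** establish: behaviour on real
electron density, on catalytic Zn sites with water/Asp/Glu ligands, on
non-P1 crystallographic symmetry (only P1 lattice translations are
expanded; other space groups fall back to the identity with a warning),
or on the full variety of deposited-model pathologies.

## Numerical and degenerate-input choices

* Alternate locations: the highest-occupancy conformer per atom is used
  for all geometry (ties: first in file).
* Hydrogens are ignored everywhere.
* Author residue numbering plus insertion codes is the site identity;
  nothing is renumbered.
* Zero-range Dixon samples never reject; sample sizes above 10 clamp to
  the n = 10 critical value (unreachable with the published radii).
* A missing Cys C^β^ drops that Zn–C^β^ component with a warning; an
  incomplete imidazole ring makes the flip flag FALSE with a warning.
* Coordinates are written with three decimals; rendered restraint
  values and sigmas with three decimals.
* The 3.25 Å ligand rule is applied to the four Q-test survivors (the
  source does not state the order).
* mmCIF is read-only; corrected output is always PDB, where
  LINK/SSBOND semantics are defined.

## Known limitations

* Only P1 symmetry expansion; general space-group operators would need
  a symmetry library this package deliberately does not reimplement.
* The `res25` target table is not distributed.
* The Q-test confidence level of the original implementation is
  unknown; 95 % is an assumption.
* The centroid-deviation spread σ_pos = 0.10 Å is an assumption.
* Detection requires all four ligands to be modelled; incompletely
  built sites stay undetected, as in the original method.
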