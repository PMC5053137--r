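# znsite

Detection, annotation correction, restraint generation and geometric
validation of tetrahedral zinc sites in macromolecular structure
models.

## The problem

Zn²⁺ is the most common transition-metal ion in protein crystal
structures. Structural zinc sites are usually ZnCys<sub>x</sub>His<sub>y</sub>
complexes (x + y = 4): a Zn²⁺ ion tetrahedrally coordinated by x
cysteine S^γ^ thiolates and y histidine imidazole nitrogens
(N^δ1^ or N^ε2^). Deposited models often distort these sites —
Zn–ligand bonds are typically unrestrained, automatic disulfide
detection can draw two zinc-binding cysteines into a spurious cysteine
bridge, and missing or wrong LINK/SSBOND header records make
refinement programs build the wrong restraints.

`znsite` is for crystallographers and model-validation pipelines. It:

* **detects** putative tetrahedral sites around each Zn (S^γ^ within
  4.8 Å, ring N within 3.8 Å, Dixon Q-test outlier rejection on the
  Zn–ligand distances, empirically tuned discard rules against
  octahedral and foreign-ligand sites, bridging-S^γ^ cluster
  detection);
* **Cys-cleans** the annotation (removes SSBONDs between
  zinc-coordinating cysteines and spurious LINKs, adds the four
  canonical Zn–ligand LINKs);
* **generates restraints** in the REFMAC external-restraint dialect
  (Zn–S^γ^ 2.340 ± 0.020 Å, Zn–N^δ^ 2.057 ± 0.064 Å, Zn–N^ε^
  2.058 ± 0.073 Å, S^γ^–Zn–S^γ^ 109.5 ± 3.0°; angles involving His are
  never restrained);
* **validates** site geometry with composition-specific Z-scores,
  Z = (observed − μ)/σ against targets derived from structures solved
  at 1.6 Å or better, combined into the root-mean-square Z-score

  r.m.s.Z = sqrt(mean(Z²))

  over Zn–ligand distances, S^γ^–Zn–S^γ^ and N–Zn–N angles, S^γ^–S^γ^
  and Zn–C^β^ distances and the Zn-centroid deviation. Well-refined
  sites score near 1; ideal geometry scores near 0.

A synthetic-site generator (`build_site()`, `distort()`,
`decoy_suite()`) builds ideal, distorted and adversarial fixtures so
the whole pipeline is testable without any deposited data.

## Worked example

```r
library(znsite)

s <- build_site(site_spec("Cys3His1"))   # ideal ZnCys3His1 fixture
ss <- detect_sites(s)
ss
#> <zn_site_set: 1 accepted, 0 rejected, 0 cluster group(s)>
#> <zn_site A ZN101: ZnCys3His1; d = 2.07, 2.32, 2.32, 2.32 A>

cat(render_refmac_external(restraint_set(ss$sites[[1]])))
#> # Zn site A/ZN101 (Cys3His1)
#> exte dist first chain A resi 101 atom ZN second chain A resi 40 atom ND1 value 2.057 sigma 0.064
#> exte dist first chain A resi 101 atom ZN second chain A resi 10 atom SG value 2.340 sigma 0.020
#> exte dist first chain A resi 101 atom ZN second chain A resi 20 atom SG value 2.340 sigma 0.020
#> exte dist first chain A resi 101 atom ZN second chain A resi 30 atom SG value 2.340 sigma 0.020
#> exte angle first chain A resi 10 atom SG next chain A resi 101 atom ZN next chain A resi 20 atom SG value 109.500 sigma 3.000
#> exte angle first chain A resi 10 atom SG next chain A resi 101 atom ZN next chain A resi 30 atom SG value 109.500 sigma 3.000
#> exte angle first chain A resi 20 atom SG next chain A resi 101 atom ZN next chain A resi 30 atom SG value 109.500 sigma 3.000

validate_site(ss$sites[[1]], s)
#> <validation A/ZN101 Cys3His1: rmsz = 0.437 over 14 component(s)>

noisy <- distort(s, "gaussian_noise", 0.2, seed = 7)
validate_site(detect_sites(noisy)$sites[[1]], noisy)
#> <validation A/ZN101 Cys3His1: rmsz = 5.072 over 14 component(s)>
```

The one distance line per ligand carries the class-specific dictionary
target; the three angle lines are the C(3,2) S^γ^ pairs at the ideal
tetrahedral value. The ideal fixture (built on exact tetrahedral
vertices) scores r.m.s.Z 0.44 — its angles are tetrahedral rather than
at the composition-specific 112.15° mean — while
`build_site(site_spec("Cys3His1", pair_angles = "table"))`, built
exactly at the published means, scores < 0.05. Adding 0.2 Å coordinate
noise pushes the same site above 5.

## Command line

```sh
Rscript inst/scripts/znsite-cli.R detect   --input model.pdb --outdir out
Rscript inst/scripts/znsite-cli.R clean    --input model.pdb --outdir out
Rscript inst/scripts/znsite-cli.R restrain --input model.pdb --outdir out
Rscript inst/scripts/znsite-cli.R validate --input model.pdb --outdir out --format tsv,json
Rscript inst/scripts/znsite-cli.R fixture  --outdir fixtures --seed 1
```

Reports go to the output directory (TSV/JSON/text), logs to standard
error; exit status is nonzero only on I/O or parse failure.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline from scratch against the installed
package: it generates the synthetic fixture suite (one ideal site per
composition plus the decoys), runs detection, Cys-cleaning, restraint
generation and validation over it, cleans a corrupted-annotation
fixture and validates a noise-distorted replicate, then writes the
JSON report to `--out`.

## Scope

Crystallographic re-refinement itself, electron-density metrics
(RSCC/RSZD), bond-valence ion identification and His-flip *rebuilding*
are out of scope: flips are flagged, not fixed, and the package
prepares inputs for — and judges the output of — refinement rather
than running it. See `vignettes/zinc-site-validation.Rmd` for the
model, parameter and design details.
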