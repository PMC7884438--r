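# pigmentnet

Structural analysis of pigment–protein supercomplexes — photosystem I
with its light-harvesting antenna (PSI–LHCI) and relatives — for
structural biologists and photosynthesis researchers working from
deposited mmCIF/PDB coordinate models.

Given a coordinate model, the package

* classifies hetero residues into chlorophyll / carotenoid / lipid
  classes by chemical component id and builds per-subunit pigment
  inventories;
* computes **edge-to-edge distances**
  \(d_{\mathrm{edge}}(a,b)=\min_{i\in C_a,\,j\in C_b}\lVert x_i-x_j\rVert\)
  over the conjugated atom sets \(C_a, C_b\) of pigment pairs — the
  standard geometric proxy for excitation energy-transfer (EET)
  plausibility;
* detects the axial ligand of each chlorophyll's central Mg (nearest
  protein side-chain N/O within 3 Å) and identifies 603/609 red-form
  dimer candidates, whose His-vs-Asn ligation tracks the red shift of
  the long-wavelength fluorescence;
* builds the distance-thresholded pigment adjacency graph
  (\(d_{\mathrm{edge}} \le D_{\max}\), default 15 Å) and enumerates
  antenna→core pathways under a bottleneck-first objective (minimise
  the largest hop, then total length, then hop count);
* superposes homologous structures on their PsaA/PsaB cores (Kabsch,
  det +1), matches pigments geometrically across structures, and ranks
  antenna sites by mean pigment displacement;
* generates deterministic synthetic structures with all distances,
  ligands and transforms known by construction, which drive the whole
  validation suite.

The methods vignette (`vignettes/pigment-networks.Rmd`) documents the
model, every tunable parameter, and the design decisions.

## Worked example

```r
library(pigmentnet)

# two chlorophylls built to an exact 7.4 A edge-to-edge distance
fx <- make_pair(7.4, seed = 1)
pg <- extract_pigments(fx$model)
edge_to_edge(pg[[1]], pg[[2]])
#> [1] 7.4
mg_mg(pg[[1]], pg[[2]])
#> [1] 14.26117

# a 10-chlorophyll grid through the full file-based pipeline
dir <- tempfile(); grid <- make_grid(10, 12, seed = 1)
path <- write_fixture(grid, dir, "mmcif")
inv <- run_inventory(path, map = read_subunit_map(file.path(dir, "syngrid.map")))
inv$inventory
#> pigment_inventory: 10 Chl (10 a, 0 b), 0 Car, 0 lipid
```

The first number is the minimum distance between the two conjugated
macrocycles — equal to the generator's brute-force ledger value to
1e-6 Å; the Mg–Mg distance is larger because the macrocycle edges
approach far closer than their centres. The inventory confirms all ten
residues classified as chlorophyll *a* after a round trip through an
mmCIF file.

A planted comparison (`analysis/05_comparative_shift.R`) shows the
shift analysis end-to-end; with a 3 Å shift planted at the second
antenna site it prints:

```
core superposition: 50 atoms, rmsd 4.94e-15 A
site shift ranking (mean pigment displacement, A):
   site subunit n_pigments mean_disp median_disp max_disp
1 Lhca5   Lhca5          3  3.00e+00           3 3.00e+00
2 Lhca2   Lhca2          3  2.25e-07           0 6.74e-07
...
lost pigments: Lhca3:CLA:603 (planted deletion: Lhca3:CLA:603)
```

## Analysis workflow

The `analysis/` scripts run the study as a numbered pipeline, writing
tables under `results/`:

1. `01_synthetic_fixtures.R` — generate the validation structures.
2. `02_inventory_census.R` — cofactor census (and for the real moss
   entry when `structures/6L35.cif` is supplied).
3. `03_distance_network.R` — distance tables, the 15 Å graph, pathways.
4. `04_ligands_redforms.R` — axial ligands and 603/609 dimers.
5. `05_comparative_shift.R` — core superposition, pigment matching,
   belt-shift ranking (with `structures/4XK8` for the real comparison).
6. `06_repro_report.R` — the consolidated claim table
   (pass/fail/skipped) via `run_repro()`.

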