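# stressmap

Comparative stress analysis of multidomain protein MD trajectories in R.

Antibody Fab fragments — four immunoglobulin domains (VL and CL on the
light chain, VH and CH1 on the heavy chain) joined by two inter-chain
interfaces — destabilise along different routes under different stresses:
acidification tends to deform specific domains and break glutamate salt
bridges, while thermal stress loosens the inter-chain interfaces before
any single domain unfolds.  `stressmap` quantifies these routes from
molecular-dynamics trajectories by comparing each stress condition against
a reference condition, replicate by replicate:

* **deformation** — per-domain all-heavy-atom RMSD after fitting on the
  domain itself (Kabsch superposition), windowed per-residue RMSF, radius
  of gyration;
* **native contacts** — the soft-cutoff fraction
  Q = (1/N) Σ 1/(1 + exp[β(r<sub>ij</sub> − λ·r⁰<sub>ij</sub>)])
  (β = 5 Å⁻¹, λ = 1.8, reference radius 4.5 Å) at domain, interface and
  residue level, plus total-contact counts;
* **salt bridges** — residue-level detection at a 3.2 Å O–N cutoff,
  per-replicate occurrence percentages, 10%-threshold tables and
  per-region counts;
* **β structure** — a minimal Kabsch–Sander assignment (reconstructed
  amide hydrogens, E = 27.888·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN), bond
  iff E < −0.5 kcal/mol) with per-strand occupancy change between
  conditions;
* **surface** — Shrake–Rupley SASA, aggregation-prone-region (APR)
  exposure change, and occluded-surface packing (OSP) density;
* **sequence statistics** — single-mutant enumeration (19 × L mutations),
  stabilising-consensus intersection of external ΔΔG scans, alignment
  column entropy in nats over the 21-symbol alphabet, and 3-of-4 APR
  predictor consensus.

A synthetic mini-Fab generator produces idealised four-domain structures
and stress trajectories with exactly known ground truth (designed
salt-bridge occupancy schedules, loop-displacement and interface-
separation ramps), so the entire pipeline is verifiable at desk scale.
Running MD itself, computing ΔΔG, and running APR sequence predictors are
out of scope: trajectories, ΔΔG tables and predictor masks are inputs.

## Worked example

```r
library(stressmap)
fab <- build_toy_fab()
fab$structure
#> fab_structure: 556 atoms, 96 residues, chains L,H

ref <- simulate_stress_trajectory(fab, stress_profile("reference", seed = 1),
                                  n_frames = 61, n_replicates = 3)
low <- simulate_stress_trajectory(fab, stress_profile("low_ph_like", seed = 1),
                                  n_frames = 61, n_replicates = 3)

# per-domain RMSD at the final frame, stress minus reference (Angstrom)
final_rmsd <- function(trajs, region) mean(sapply(trajs, function(tr)
  tail(domain_rmsd_series(tr, fab$structure, region, fab$map)$value, 1)))
round(sapply(names(fab$map$domains), function(rg)
  final_rmsd(low, rg) - final_rmsd(ref, rg)), 3)
#>    VL    CL    VH   CH1
#> 0.000 0.988 0.000 0.000

# the constant-domain interface is untouched by the low-pH-like stress
cs <- build_reference_contacts(fab$structure, "CL-CH1", fab$map)
round(mean(sapply(low, function(tr) tail(contact_series(tr, cs)$q, 1))), 3)
#> [1] 0.998

# salt bridges retained above 10% mean occurrence: only aspartate bridges
# survive the glutamate-eliminating schedule
aggregate_occurrence(lapply(low, bridge_occurrence))[, c(1, 2, 5, 6)]
#>   acid_resno base_resno     mean sem
#> 1         31         42 60.65574   0
#> 2          4         21 44.26230   0
#> 3         80         89 34.42623   0

# APR solvent exposure: the targeted domain's buried loop roughly doubles
# its accessible area, the other APRs stay flat
apr_sasa_change(low, ref, fab$aprs, stride = 10)[, c("apr", "change", "sem")]
#>       apr   change      sem
#> 1  APR_VL  0.00000 0.000000
#> 2  APR_CL 98.39954 2.434816
#> 3  APR_VH  0.00000 0.000000
#> 4 APR_CH1  0.00000 0.000000
```

The low-pH-like profile deforms only the CL-analogue domain (ΔRMSD
+0.99 Å, the other three at 0), leaves the interfaces intact (Q ≈ 1),
drops the glutamate salt bridges from the occurrence table, and roughly
doubles the targeted APR's solvent exposure — the localized-deformation
signature.  The high-temperature-like profile instead deforms all domains
mildly while both interfaces lose most of their native contacts.

For file-based work, `write_toy_fixture()` emits multi-model PDB
trajectories, a ground-truth JSON and a ready-made YAML config, and
`run_comparison(config, out_dir)` writes the full CSV report set (RMSD,
Q, RMSF, salt-bridge tables and counts, strand-occupancy change, APR
exposure change, per-residue Δ maps projected onto PDB B-factors, and a
manifest).  A thin command-line front end lives in
`inst/scripts/stressmap` (`fixture`, `analyze`, `entropy`, `ddg`,
`mutants`).

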