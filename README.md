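# aquasol

Aqueous solubility QSPR modelling in R: molecular descriptors versus
Morgan fingerprints, with interpretable models and end-to-end
reproducibility.

`aquasol` predicts logS (base-10 logarithm of molar aqueous solubility)
for low molecular weight organic compounds and compares two chemical
representations of the same molecules:

* a **2D molecular-descriptor matrix** (~165 constitutional, topological,
  autocorrelation and estimated-property descriptors) pruned through a
  fixed cascade — non-numeric columns, low variance, pairwise
  correlation, and named leakage exclusions;
* **2048-bit Morgan (ECFP4) circular fingerprints** with LASSO bit
  selection and a bit-to-substructure atlas that maps every important bit
  back to fragment SMILES.

On either representation it fits a random forest and a multiple linear
regression, reports R²/RMSE/MAE per train/test partition, explains the
forest with exact path-dependent TreeSHAP (implemented in C++, with the
local-accuracy identity holding to machine precision), ranks standardized
MLR coefficients, screens training molecules with a from-scratch Local
Outlier Factor (plus per-feature Welch t-tests and rare-bit ratios), and
scores the fragments behind influential bits with a hydration
Gibbs-energy group model (ΔG₂₉₈ = −0.5 − 1.37·α + 3.84·ΣCa − 2.97·ΣCd).

## Quick start

```r
library(aquasol)

# synthetic dataset with a planted structure-logS relationship
sim <- simulate_solubility_table(500, max_carbons = 12,
                                 n_exact = 15, n_conflict = 10, seed = 1)

cfg <- run_config(output_dir = "solubility_run")
run <- run_pipeline(sim$table, cfg)

run$metrics                             # Tables of R2 / RMSE / MAE
head(run$importance$shap_descriptors$importance)
run$fragment_thermo                     # Gibbs energies of top fragments

# blind evaluation on molecules disjoint from the study
blind <- data.frame(name = "caffeine-like", smiles = "CCc1ccccc1O",
                    logS = -1.8)
evaluate_blind(run, blind)
```

Every stochastic stage takes an explicit seed from the configuration;
re-running the same configuration reproduces all output tables byte for
byte, and each table carries the configuration hash.

For real data, `read_molecule_table()` reads a CSV of SMILES + logS
(column names configurable) and `curate()` applies the merging rules:
canonical-SMILES deduplication, mean-collapse of agreeing repeats,
dropping of conflicting measurements, and a provenance report satisfying
the conservation identity `inputs = kept + collapsed + conflict rows +
parse failures + mixtures`.

## Package layout

| Area | Entry points |
| --- | --- |
| Data curation | `read_molecule_table()`, `curate()`, `profile_dataset()` |
| Synthetic data | `simulate_solubility_table()`, `planted_model()`, `generate_molecules()` |
| Descriptors | `compute_descriptors()`, `descriptor_cascade()` |
| Fingerprints | `morgan_fingerprints()`, `bit_atlas()`, `bit_to_substructure()`, `lasso_select()` |
| Models | `fit_solubility()`, `evaluate_metrics()`, `split_train_test()` |
| Interpretation | `shap_importance()`, `coefficient_report()` |
| Outliers | `lof_flags()`, `group_ttests()`, `refit_without_outliers()` |
| Thermodynamics | `gibbs_energy()`, `fragment_thermo_table()` |
| Orchestration | `run_config()`, `run_pipeline()`, `evaluate_blind()` |

See the vignette (`vignettes/solubility-pipeline.Rmd`) for a worked
end-to-end study on synthetic data.

## Testing

```r
testthat::test_dir("tests/testthat", package = "aquasol",
                   load_package = "installed")
```

The suite includes property-based acceptance tests: loop-based metric
oracles, a brute-force Shapley oracle for TreeSHAP, exhaustive
pair-checking for the correlation prune, fingerprint round-trip and
atom-renumbering invariance, planted-parameter recovery across 100 noise
seeds, and curation fixtures with counts known by construction. One
acceptance test requires an externally distributed curated dataset that
is not bundled; it fails with a clear message until that file is
supplied.

`scripts/acceptance.R --seed 1 --out report.json` writes a JSON report of
the main computed quantities against the installed package.
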