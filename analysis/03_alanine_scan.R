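#!/usr/bin/env Rscript
# Computational alanine/glycine scan of the 15-residue hairpin on a rigid
# snapshot set, at the production PB settings (0.5 A grid).  Positions
# whose wild type is alanine receive the glycine mutation (hotspot
# convention).  The per-position ddG profile is compared with the
# generator's analytic side-chain interaction energies.

suppressMessages(library(bindfe))

cfg <- run_config(seed = 1)
dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)

fx <- build_complex(fixture_spec(seed = cfg$seed, ligand_net_charge = 1,
                                 fluctuation_sigma = 0, n_frames = 2,
                                 intermittent_bonds = list()))
ens <- sample_ensemble(fx)
sc <- residue_scan(ens, settings = do.call(pb_settings, cfg$pb),
                   gamma = cfg$sasa_gamma_kcal_A2, offset = cfg$sasa_offset_kcal,
                   ch_length = cfg$ch_cap_length_A)
truth <- fx$truth$per_residue
sc$truth_gas_ddG <- truth$ddG_gas[match(sc$position, truth$position)]
sc$deviation <- sc$ddG - sc$truth_gas_ddG
utils::write.csv(sc, file.path(cfg$output_dir, "alanine_scan.csv"),
                 row.names = FALSE)
write_report(list(scan = sc), file.path(cfg$output_dir, "scan_report.json"), cfg)

hot <- fx$spec$hotspot_positions
cat("Per-position ddG (kcal/mol):\n")
print(sc[, c("label", "wild_type", "mutation", "ddG", "truth_gas_ddG")],
      row.names = FALSE, digits = 3)
cat(sprintf("\nHotspot module (positions %s) carries %.0f%% of the summed |ddG|;\n",
            paste(hot, collapse = ","),
            100 * sum(abs(sc$ddG[sc$position %in% hot])) / sum(abs(sc$ddG))))
cat(sprintf("largest PB/SA perturbation of a hotspot ddG vs the gas-phase truth: %.2f kcal/mol.\n",
            max(abs(sc$deviation[sc$position %in% hot]))))
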