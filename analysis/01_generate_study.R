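#!/usr/bin/env Rscript
# Step 1 — simulate the study: 27 Agiorgitiko + 19 Xinomavro wines over two
# vintages, 5 pooled QCs, a solvent blank every 10 injections, ethyl
# vanillin IS at 2 mg/L, plus 7-point solvent and matrix-matched
# calibration series.  Writes the peak tables, metadata and truth record.
library(oenoscreen)

seed <- 1
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

gen <- generate_study(seed = seed)
cal <- generate_calibration_series(seed = seed + 1)

write_peak_table(gen$features, "results/data/peak_table.tsv")
write_report(gen$metadata, "results/data/sample_metadata.tsv",
             header = c(seed = seed))
write_report(gen$truth$concentrations, "results/data/truth_concentrations.tsv",
             header = c(seed = seed))
write_report(cal$solvent, "results/data/calibration_solvent.tsv",
             header = c(seed = seed + 1))
write_report(cal$matrix, "results/data/calibration_matrix.tsv",
             header = c(seed = seed + 1))
write_compound_db(default_panel(), "results/data/compound_panel.tsv")

cat(sprintf("generated %d features over %d injections (%d samples, %d QCs, %d blanks)\n",
            nrow(gen$features), nrow(gen$metadata),
            sum(gen$metadata$type == "sample"), sum(gen$metadata$type == "qc"),
            sum(gen$metadata$type == "blank")))
cat(sprintf("calibration: %d analytes x %d levels, solvent + matrix-matched\n",
            length(unique(cal$solvent$analyte)),
            length(unique(cal$solvent$concentration))))
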