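#!/usr/bin/env Rscript
# Forward-model the dilution experiments: vary the primary-antibody
# concentration (Langmuir occupancy) and the secondary-antibody dilution
# (proportional, limiting-reagent regime) and tabulate the expected
# specific signal. Writes results/dilution_series.csv.

suppressPackageStartupMessages(library(tagquant))

ab <- antibody_model("anti_tag", rho = 1, K_p = 76.9)

primary <- simulate_dilution_series(ab, primary_concs = c(5000, 500, 50, 5),
                                    secondary_scales = 1)
secondary <- simulate_dilution_series(ab, primary_concs = 5000,
                                      secondary_scales = c(1, 0.25, 0.1, 0.01))
series <- rbind(cbind(varied = "primary", primary),
                cbind(varied = "secondary", secondary))
dir.create("results", showWarnings = FALSE)
write.csv(series, "results/dilution_series.csv", row.names = FALSE)
print(series, digits = 3)

drop <- 100 * (1 - primary$signal[primary$primary_conc == 50] /
                 primary$signal[primary$primary_conc == 5000])
message(sprintf(paste0(
  "found: a 100-fold primary dilution (5000 -> 50 ng/mL) loses only %.0f%% ",
  "of the specific signal (K_p = 76.9 ng/mL), while diluting the secondary ",
  "scales the signal proportionally - the secondary is limiting."), drop))
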