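#!/usr/bin/env Rscript
# Incubation kinetics: killed-control correction of the simulated light
# incubation, light-phase regression rate under the 12 h light / 12 h dark
# schedule, and scaling to daily rates. Run after 01_simulate.R.

suppressPackageStartupMessages(library(ironcline))

live <- read_incubation("results/incubation.csv", illuminated_hours = 12)
ctrl <- read_incubation("results/incubation_killed.csv", killed = TRUE)

corrected <- killed_control_correct(live, ctrl)
hourly <- light_phase_rate(corrected)
cat(sprintf("light-phase Fe(II) oxidation (killed-control corrected): %.2f umol l-1 h-1\n",
            hourly$value))

win <- window_rate(corrected, 0, 120)
cat(sprintf("whole-run window rate 0-120 h: %.2f umol l-1 h-1 (light and dark averaged)\n",
            win$value))

daily24 <- daily_rate(hourly, 24)
daily12 <- daily_rate(hourly, 12)
cat(sprintf("daily potential rate: %.1f umol l-1 d-1 at 24 h, %.1f at 12 h of illumination\n",
            daily24, daily12))

utils::write.table(
  data.frame(quantity = c("light_phase_rate_umol_l_h",
                          "window_rate_umol_l_h",
                          "daily_rate_24h_umol_l_d",
                          "daily_rate_12h_umol_l_d"),
             value = c(hourly$value, win$value, daily24, daily12)),
  "results/incubation_rates.tsv", sep = "\t", row.names = FALSE, quote = FALSE)
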