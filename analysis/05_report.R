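#!/usr/bin/env Rscript
# Final comparison report: runs the full pipeline on the simulated profile
# plus the study's measured incubation and tracer parameters, printing one
# record per estimator (flux-based, tracer-based, incubation-based) next
# to the deposition-flux benchmark and the population estimate. Run after
# 01_simulate.R.

suppressPackageStartupMessages(library(ironcline))

hourly <- utils::read.table("results/incubation_rates.tsv", header = TRUE,
                            sep = "\t")
hourly <- hourly$value[hourly$quantity == "light_phase_rate_umol_l_h"]

cfg <- analysis_config(profile_file = "results/profiles.csv",
                       exsitu_hourly_rate = hourly)
report <- run_pipeline(cfg)
print(report)
write_report(report, "results/rate_comparison.tsv")
cat("\nwrote results/rate_comparison.tsv\n")
cat("the three estimators span ~0.2 to ~60 umol l-1 d-1: the flux-based rate\n")
cat("is the in-situ supply limit, the tracer rate the in-situ photoferrotrophic\n")
cat("activity, and the incubation rate the light- and Fe(II)-replete potential,\n")
cat("which approaches the deposition benchmark's order of magnitude.\n")
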