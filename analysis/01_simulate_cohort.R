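#!/usr/bin/env Rscript
# Generate the synthetic study cohort all downstream analyses run on:
# n = 4480 adults with correlated nutrient intakes, three FTO SNPs in HWE,
# baseline/follow-up anthropometry, and a built-in quartile-by-genotype
# interaction on the change-in-WC outcome (wild-type stratum ORs
# 1, 1.43, 1.33, 1.37; carrier stratum near-null) so the modelling scripts
# have a known signal to find.

suppressPackageStartupMessages(library(diigrs))

dir.create("results/cohort", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(
  n = 4480, seed = 20260930 %% 1e6,
  stratifier = "rs1421085",
  cell_logor = list(
    wc = cell_logor_from_or(c(1, 1.43, 1.33, 1.37), c(1, 0.94, 0.94, 0.97)))
)
tabs <- simulate_cohort(cfg)
paths <- write_cohort_tables(tabs, "results/cohort/sim")

message("Simulated cohort of ", cfg$n, " participants (seed ", cfg$seed, ")")
message("Outcome prevalences (generative truth):")
print(colMeans(tabs$truth$flags))
message("Tables written:")
print(unname(paths))
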