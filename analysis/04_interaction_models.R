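#!/usr/bin/env Rscript
# The main event: adjusted 8-group logistic models for every change outcome
# (BMI, WC, WHR, VAI) stratified by each FTO SNP (dominant model) and by the
# GRS median split, with per-stratum trend tests and the quartile-by-stratum
# interaction test. The simulated truth carries a WC effect through
# rs1421085 (wild-type quartile ORs 1.43/1.33/1.37, carriers near-null),
# which should surface as elevated wild-type cells in the WC x rs1421085
# table; note the ordinal interaction test has modest power against this
# hump-shaped (non-monotone) alternative, so its p-value varies widely
# across simulated cohorts.

suppressPackageStartupMessages(library(diigrs))

tabs <- read_cohort_tables("results/cohort/sim")
res <- run_pipeline(tabs)

dir.create("results/or_tables", recursive = TRUE, showWarnings = FALSE)
for (o in names(res$or_tables)) {
  for (s in names(res$or_tables[[o]])) {
    tab <- res$or_tables[[o]][[s]]
    cells <- tab$cells
    cells$p_trend <- tab$p_trend[cells$stratum + 1]
    cells$p_interaction <- tab$p_interaction
    readr::write_tsv(cells,
                     sprintf("results/or_tables/%s_by_%s.tsv", o, s))
  }
}

message("Change in WC stratified by rs1421085 (injected interaction):")
print(res$or_tables$wc$rs1421085)
message("Change in BMI stratified by rs1421085 (simulated null):")
print(res$or_tables$bmi$rs1421085)

pint <- sapply(res$or_tables, function(by_strat)
  sapply(by_strat, function(t) t$p_interaction))
message("P-interaction grid (rows: stratifiers, cols: outcomes):")
print(round(pint, 3))

estimates_json(res, "results/estimates.json")
message("All estimates written to results/estimates.json")
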