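#!/usr/bin/env Rscript
# Stage 1: generate the synthetic case-control cohort.
#
# Emulates the margins of the motivating study: 587 children with ASD and
# 356 typically developing controls, ~12%/11% reported prenatal exposure,
# education/race/parity/pet/sex/age/region covariates, correlated exposure
# windows, and non-differential reporting error (Se 0.85, FPP 0.05) from a
# true prevalence near 8%.

suppressPackageStartupMessages(library(bayesmisclass))
seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 20140123L
started <- proc.time()
dir.create("results", showWarnings = FALSE)

config <- charge_like_config(seed = seed)
cohort <- generate_cohort(config)
write_cohort(cohort, "results/cohort.csv")

cat(sprintf("cohort: %d cases / %d controls\n",
            sum(cohort$outcome == 1), sum(cohort$outcome == 0)))
cat(sprintf("reported prenatal exposure: %.1f%% cases, %.1f%% controls\n",
            100 * mean(cohort$reported_prenatal[cohort$outcome == 1]),
            100 * mean(cohort$reported_prenatal[cohort$outcome == 0])))
cat(sprintf("consistent use among exposed: %.0f%%\n",
            100 * mean(cohort$consistency[cohort$reported_prenatal == 1] ==
                         "consistent")))

run_manifest("results/01_simulate.manifest.json",
             seeds = list(cohort = seed),
             config = list(n_cases = config$n_cases,
                           n_controls = config$n_controls,
                           scenario = config$scenario$label,
                           window_agreement = config$window_agreement),
             outputs = c("results/cohort.csv", "results/cohort.csv.dict.json"),
             started = started)
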