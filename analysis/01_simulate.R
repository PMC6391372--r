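#!/usr/bin/env Rscript
# Stage 1: generate the synthetic 27-state x 10-year soybean study.
#
# Produces every input the downstream stages read - daily weather for the
# 135 trial locations, the long-format trial-yield table (three maturity
# groups per trial), weekly crop-progress reports, state economics and
# CPI tables, and 46-year frost climatologies - together with the
# recorded ground truth (per-state optimal sowing shifts, gains, and the
# planted window-effect coefficients). Large intermediates are cached
# under scratch/ (not tracked); small summaries land in results/.

suppressPackageStartupMessages(library(sowshift))

seed <- 1L
dir.create("scratch/cache", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

cfg <- sim_config()
message("Generating study (", nrow(cfg$states), " states, ",
        length(cfg$years), " years, seed ", seed, ") ...")
dat <- simulate_dataset(seed = seed, config = cfg)
saveRDS(list(cfg = cfg, dat = dat), "scratch/cache/study.rds")

tr <- dat$truth
message(sprintf("Planted national conditions: mean optimal shift %.1f days, ",
                tr$national$mean_shift_days),
        sprintf("weighted yield gain %.1f%%", tr$national$total_yield_change_pct))
message(sprintf("%d trials at %d locations; state-year yields %.0f-%.0f kg/ha expected",
                nrow(dat$trials), nrow(dat$locations),
                min(tr$states$yield_at_typical), max(tr$states$yield_at_typical)))

write_outputs(list(
  truth_states = tr$states,
  truth_national = tr$national
), "results")
message("Wrote results/truth_states.csv and results/truth_national.json")
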