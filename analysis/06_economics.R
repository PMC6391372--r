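#!/usr/bin/env Rscript
# Stage 6: monetary effect of optimal sowing. The state's fractional
# yield gain at its optimum is applied to each year's inflation-adjusted
# (2016 US$) income and accumulated over the decade; per-hectare effects
# divide by hectare-years.

suppressPackageStartupMessages(library(sowshift))

st <- readRDS("scratch/cache/study.rds")
opt <- readRDS("scratch/cache/optima.rds")

econ <- compute_economics(opt$curves, st$dat$econ, st$dat$cpi)
by_state <- econ$by_state[order(-econ$by_state$cum_gain_usd2016), ]
message(sprintf("National cumulative gain: %.2f billion 2016 US$",
                econ$national$cum_gain_usd2016 / 1e9))
message("Largest state gains (billion 2016 US$): ",
        paste(sprintf("%s %.2f", by_state$state[1:3],
                      by_state$cum_gain_usd2016[1:3] / 1e9), collapse = ", "))
message(sprintf("Per-hectare effects span %.0f-%.0f 2016 US$/ha",
                min(by_state$per_ha_usd2016), max(by_state$per_ha_usd2016)))

write_outputs(list(
  economics_by_state = by_state,
  economics_national = econ$national
), "results")
message("Wrote results/economics_by_state.csv")
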