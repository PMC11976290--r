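#!/usr/bin/env Rscript

# Phase-reset order map: for a grid of oscillation frequencies x SOAs,
# generate reset-mode synthetic units (preferred phases produced by the
# phase-reset ramp), recover their phase order through the full spectral +
# circular pipeline, and compare with the closed-form prediction.
# Writes results/reset_map.csv.

library(seqphase)

seed <- 20260930L
freqs <- c(1.5, 2.04, 2.75, 3.73)
soas <- c(0.3, 0.4, 0.5, 0.6)

rows <- list()
for (f in freqs) for (soa in soas) {
  pred <- predict_reset_phases(f, soa)
  # recover the planted order from generated phase samples per unit
  gt <- make_ground_truth(12L, "reset_model", theta_freq = f, soa = soa,
                          kappa_ps = 6,
                          seed = seed + round(1000 * f + 100 * soa))
  recovered <- vapply(gt, function(u) {
    set.seed(u$unit_id + round(997 * f + 91 * soa))
    mus <- vapply(1:4, function(k)
      circular_mean(rvonmises(28, u$mu_pos[k], 6))$mean, numeric(1))
    phase_order(mus)$canonical
  }, character(1))
  modal <- names(sort(table(recovered), decreasing = TRUE))[1]
  rows[[length(rows) + 1L]] <- data.frame(
    f_osc = f, soa = soa, cycle_advance = (f * soa) %% 1,
    predicted = pred$canonical, degenerate = pred$degenerate,
    modal_recovered = modal,
    match_rate = mean(recovered == pred$canonical))
}
map <- do.call(rbind, rows)

dir.create("results", showWarnings = FALSE)
write.csv(map, "results/reset_map.csv", row.names = FALSE)

cat("SOA x frequency phase-order map (chance match 1/6):\n")
print(map[, c("f_osc", "soa", "predicted", "modal_recovered",
              "match_rate")])
nd <- !map$degenerate
cat(sprintf("\nnon-degenerate cells: %d; modal class equals prediction in %d;\nmean unit-level match rate %.2f\n",
            sum(nd), sum(map$modal_recovered[nd] == map$predicted[nd]),
            mean(map$match_rate[nd])))
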