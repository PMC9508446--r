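#!/usr/bin/env Rscript
# Monte Carlo validation of the two end-member transport formulas: isotropic
# fixed-step walks must give RMS displacement sqrt(n) * L, prevailing-wind
# walks exactly n * L. Run at a reduced hop count (n = 100) so 1e4 walkers
# finish in seconds; the closed forms are n-independent.

library(marsalt)

n <- 100; L <- 29; walkers <- 1e4
iso <- simulate_walk(n, L, mode = "isotropic", n_walkers = walkers, seed = 1)
pre <- simulate_walk(n, L, mode = "prevailing_wind", n_walkers = walkers,
                     seed = 1)

cat(sprintf("isotropic:  RMS = %.1f m (theory %.1f), mean = %.1f m (theory %.1f)\n",
            iso$rms, sqrt(n) * L, iso$mean, sqrt(pi) / 2 * sqrt(n) * L))
cat(sprintf("prevailing: every walker at %.0f m (n * L = %.0f)\n",
            pre$mean, n * L))

out <- data.frame(
  mode = c("isotropic", "prevailing_wind"),
  n_hops = n, hop_length_m = L, n_walkers = walkers,
  mean_m = c(iso$mean, pre$mean),
  rms_m = c(iso$rms, pre$rms),
  rms_theory_m = c(sqrt(n) * L, n * L),
  max_m = c(iso$max, pre$max)
)
dir.create("results", showWarnings = FALSE)
write.csv(out, "results/walk_validation.csv", row.names = FALSE)
cat("Wrote results/walk_validation.csv\n")
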