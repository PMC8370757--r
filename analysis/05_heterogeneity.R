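#!/usr/bin/env Rscript
# Replicate-heterogeneity profiling: does the coefficient-of-variation
# profile of G' discriminate a two-regime kinetic mixture (IAPP alone, six
# replicates drawn fast/slow) from a homogeneous intermediate ensemble
# (crowded system, three replicates)? The raw condition data are not
# deposited, so the contrast is covered qualitatively over 20 seed pairs.

suppressPackageStartupMessages(library(gelkin))
dir.create("results", showWarnings = FALSE)

inter <- list(lag = 0.94, rate_gp = 1.12, plateau_gp = 3.15, rate_gpp = 0.39)
covmax <- function(traces) {
  lst <- lapply(traces, function(tr)
    data.frame(time = tr$time_h, value = tr$g_prime_pa))
  cov_profile(align_replicates(lst, lst[[1]]$time))$max_cov
}

rows <- NULL
for (seed in 1:20) {
  mix <- simulate_regime_ensemble(6, prob_fast = 0.5, seed = seed)
  hom <- simulate_regime_ensemble(3, prob_fast = 1, fast = inter,
                                  slow = inter, seed = seed + 1000)
  rows <- rbind(rows, data.frame(
    seed = seed,
    n_fast = sum(mix$regimes == "fast"),
    max_cov_mixture = covmax(mix$traces),
    max_cov_homogeneous = covmax(hom$traces)))
}
rows$mixture_wins <- rows$max_cov_mixture > rows$max_cov_homogeneous
write.csv(rows, "results/05_cov_summary.csv", row.names = FALSE)

cat(sprintf("mixture max CoV exceeds homogeneous in %d / 20 seed pairs\n",
            sum(rows$mixture_wins)))
cat(sprintf("median max CoV: mixture %.2f, homogeneous %.2f\n",
            median(rows$max_cov_mixture), median(rows$max_cov_homogeneous)))
cat("Per-seed table in results/05_cov_summary.csv\n")
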