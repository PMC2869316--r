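#!/usr/bin/env Rscript
# Generate one example of every synthetic input the pipeline consumes:
# a paired mock/Fpg Southern lane, a Q-FISH metaphase image with ground
# truth, and a CO-FISH per-chromosome signal table.

suppressMessages(library(telodamage))
seed <- 20260927L
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

pair <- sim_lane_pair(n = 10000, rate = 0.05, seed = seed)
write_lane_profile(pair$mock, file.path(out, "lane_mock.tsv"))
write_lane_profile(pair$fpg, file.path(out, "lane_fpg.tsv"))
cat(sprintf("lane pair: %d fragments, mass-weighted mean %.1f kb (mock)\n",
            10000, population_mean_length(pair$pop_mock)))

m <- sim_metaphase(n_chrom = 40, sfe_fraction = 0.05, snr = 10,
                   seed = child_seed(seed, 1))
write_metaphase(m, out, "metaphase")
cat(sprintf("metaphase: 40 chromosomes, %d true spots, %d true SFEs\n",
            nrow(m$truth), 160 - nrow(m$truth)))

cf <- sim_cofish(2000, seed = child_seed(seed, 2))
write_cofish_table(cf$records, file.path(out, "cofish.tsv"))
cat(sprintf("cofish: 2000 chromosomes, %d non-normal events\n",
            sum(cf$truth$label != "normal")))
cat("inputs written to", out, "\n")
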