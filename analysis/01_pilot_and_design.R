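#!/usr/bin/env Rscript
# Stage 1 - pilot MAF and the pooled-screen design curve.
#
# A 50-animal pilot genotyped one-by-one found a single heterozygote, so the
# working minor-allele frequency is 0.01. With 2350 animals to genotype, the
# expected-reaction-count curve over pool sizes 3..20 picks the pool size
# that minimizes total PCR reactions.

library(sheeppool)
dir.create("results", showWarnings = FALSE)

pilot <- estimate_pilot_maf(c(n_II = 49, n_ID = 1, n_DD = 0))
cat(sprintf("Pilot: %d animals, %d heterozygote(s) -> MAF estimate %.3g\n",
            pilot$n_pilot, pilot$counts[["n_ID"]], pilot$maf_hat))

curve <- design_curve(N = 2350, p = pilot$maf_hat, a_min = 3, a_max = 20)
print(curve)

rep <- savings_report(curve)
cat(sprintf(
  "Pooling %d per group needs %.1f expected reactions vs %d one-by-one (%.1f%% of the cost)\n",
  rep$a_optimum, rep$n_expected, rep$n_one_by_one, 100 * rep$ratio))

out <- as.data.frame(curve)
out$n_expected <- round(out$n_expected, 1)
write_tsv(out, "results/curve.tsv")
cat("written: results/curve.tsv\n")
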