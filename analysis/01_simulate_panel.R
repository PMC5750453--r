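#!/usr/bin/env Rscript
# Build a seeded block-LD haplotype panel, confirm its realized r2
# structure, and show that greedy P-ordered clumping at r2 > 0.05 recovers
# exactly the planted blocks. Writes the panel (phased VCF) and the clump
# report under results/.

suppressPackageStartupMessages(library(postgwas))
dir.create("results", showWarnings = FALSE)

g <- generate_panel(n_haplotypes = 1000, n_blocks = 5, snps_per_block = 4,
                    within_block_r2 = 0.9, seed = 1)
panel <- g$panel
print(panel)

fc <- sapply(1:5, function(b) {
  mean(sapply(2:4, function(s) {
    pairwise_r2(panel, sprintf("b%d_s1", b), sprintf("b%d_s%d", b, s))
  }))
})
cat(sprintf("mean founder-copy r2 per block: %s (target 0.9)\n",
            paste(round(fc, 3), collapse = " ")))

set.seed(2)
variants <- data.frame(snp = panel$snps$snp, p = 10^(-runif(20, 6, 20)))
clumps <- greedy_clump(variants, panel, r2_threshold = 0.05)
cat(sprintf("clumping 20 variants at r2 > 0.05: %d clumps (5 planted blocks)\n",
            nrow(clumps)))
stopifnot(nrow(clumps) == 5)

write_panel_vcf(panel, "results/synthetic_panel.vcf")
write_clump_report(clumps, "results/clump_report.tsv")
cat("wrote results/synthetic_panel.vcf and results/clump_report.tsv\n")
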