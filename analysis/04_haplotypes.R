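#!/usr/bin/env Rscript
# Stage 4: two-locus EM haplotype estimation (DPA1~DPB1 and DQA1~DQB1) with
# chi-squared haplotype association tests, plus the EM-free direct-counting
# sensitivity recoding.

suppressPackageStartupMessages(library(hlapocket))
tab <- read_cohort("results/cohort.csv")

for (pair in list(c("DPA1", "DPB1"), c("DQA1", "DQB1"))) {
  em <- em_fit(tab, pair[1], pair[2])
  ht <- haplotype_test(em, tab)
  stem <- tolower(substr(pair[1], 1, 2))
  write.table(em$haplotypes, sprintf("results/%s_haplotype_freqs.tsv", stem),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ht, sprintf("results/%s_haplotype_tests.tsv", stem),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s~%s: %d haplotypes, loglik %.1f after %d iterations\n",
              pair[1], pair[2], nrow(em$haplotypes), em$loglik, em$n_iter))
  top <- ht[order(ht$p), ][1:3, ]
  for (i in 1:3)
    cat(sprintf("  %-28s OR %.2f (%.2f, %.2f)  p = %.3g\n",
                top$haplotype[i], top$or.[i], top$ci_lo[i], top$ci_hi[i],
                top$p[i]))
}

# sensitivity: direct counting over phase-unambiguous subjects
em <- em_fit(tab)
direct <- direct_count_frequencies(tab)
m <- merge(em$haplotypes, direct, by = c("a", "b"),
           suffixes = c("_em", "_direct"))
cat(sprintf("EM vs direct counting (DP): max |diff| = %.4f over %d shared haplotypes\n",
            max(abs(m$freq_em - m$freq_direct)), nrow(m)))
cat("wrote results/dp_*.tsv, results/dq_*.tsv\n")
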