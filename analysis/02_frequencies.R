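#!/usr/bin/env Rscript
# Stage 2: chromosome-based allele frequencies with Wald intervals, and the
# disjunctive >= 0.05 retention filter (full cohort or either stratum).

suppressPackageStartupMessages(library(hlapocket))
tab <- read_cohort("results/cohort.csv")

freqs <- do.call(rbind, lapply(cohort_genes(tab), function(g)
  allele_frequencies(tab, g)))
retained <- frequency_filter(freqs, 0.05)

write.table(freqs, "results/allele_frequencies.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(retained, "results/retained_alleles.txt")

for (g in cohort_genes(tab)) {
  r <- grep(paste0("^", g), retained, value = TRUE)
  cat(sprintf("%s: %d alleles at >= 0.05 in some scope: %s\n", g,
              length(r), paste(sub(".*\\*", "", r), collapse = " ")))
}
cat("wrote results/allele_frequencies.tsv, retained_alleles.txt\n")
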