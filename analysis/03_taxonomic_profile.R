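#!/usr/bin/env Rscript
# Stage 3: SSU rRNA taxonomic profiles. Filters SSU hits (>= 100 bp
# alignment, e-value < 1e-5, longest gene per scaffold, contaminant
# scaffolds removed), converts per-scaffold coverage to RPKM-normalized
# relative abundances, and aggregates to phylum level with Proteobacteria
# reported at class level.

suppressPackageStartupMessages(library(dwmeta))

study <- read_study("results/study")
cls <- read.delim("results/decontam/classification.tsv")

hits <- filter_ssu_hits(study$ssu_hits, classification = cls)
hits <- dedupe_per_scaffold(hits)
cat(sprintf("SSU hits: %d of %d retained after filters\n",
            nrow(hits), nrow(study$ssu_hits)))

profiles <- do.call(rbind, lapply(study$samples$sample_id, function(sid) {
  prof <- ssu_relative_abundance(hits, study$scaffolds, study$sample_coverage,
                                 sid)
  phy <- aggregate_by_rank(prof, "phylum", split_proteobacteria = TRUE)
  data.frame(sample_id = sid, taxon = phy$taxon, abundance = phy$abundance)
}))

dir.create("results/taxonomy", showWarnings = FALSE, recursive = TRUE)
write.table(profiles, "results/taxonomy/phylum_profiles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

groups <- sample_groups(study)
top <- aggregate(abundance ~ taxon + groups[sample_id], data = profiles, mean)
names(top) <- c("taxon", "group", "mean_abundance")
top <- top[order(-top$mean_abundance), ]
cat("Mean phylum/class abundance by group (top 8):\n")
print(head(top, 8), row.names = FALSE)
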