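#!/usr/bin/env Rscript
# Stage 4: KO and module profiles. Retains KOs on scaffolds with > 1x
# coverage seen in at least two samples of a system, estimates per-KO read
# counts from coverage, and summarizes KEGG modules by the median abundance
# of their detected member KOs, keeping modules at most one block short and
# at least 50% complete.

suppressPackageStartupMessages(library(dwmeta))

study <- read_study("results/study")
cls <- read.delim("results/decontam/classification.tsv")
sc_true <- true_scaffolds(study$scaffolds, cls)
cov_true <- study$sample_coverage[
  study$sample_coverage$scaffold_id %in% sc_true$scaffold_id, ]
ann <- study$ko_annotations[
  study$ko_annotations$scaffold_id %in% sc_true$scaffold_id, ]

retained <- filter_kos(ann, cov_true, study$samples)
cat(sprintf("Retained %d (sample, KO) pairs; %d distinct KOs\n",
            nrow(retained), length(unique(retained$ko_id))))

ko_abund <- ko_abundance(ann, sc_true, cov_true, retained = retained)
profiles <- filter_modules(module_profiles(study$module_catalog, ko_abund))

dir.create("results/function", showWarnings = FALSE, recursive = TRUE)
write.table(ko_abund, "results/function/ko_abundance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(profiles, "results/function/module_profiles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

groups <- sample_groups(study)
agg <- aggregate(abundance ~ module_id + groups[sample_id], data = profiles,
                 mean)
names(agg) <- c("module_id", "group", "mean_reads")
wide <- reshape(agg, idvar = "module_id", timevar = "group",
                direction = "wide")
wide$log2_d_over_nd <- log2((wide$mean_reads.D + 1) / (wide$mean_reads.ND + 1))
wide <- wide[order(-abs(wide$log2_d_over_nd)), ]
cat("Modules ranked by group contrast (median KO read count):\n")
print(head(wide, 6), row.names = FALSE)
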