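#!/usr/bin/env Rscript
# Stage 5: community comparison. Bray-Curtis dissimilarities on KO RPKM,
# MinHash sketch distances on per-sample read fragments, exhaustive BioEnv
# fitting of the water chemistry, the disinfection-contrast permutation
# test, and the read-level vs system-level distance correlation.

suppressPackageStartupMessages(library(dwmeta))

study <- read_study("results/study")
ko_abund <- read.delim("results/function/ko_abundance.tsv")
dir.create("results/distance", showWarnings = FALSE, recursive = TRUE)
groups <- sample_groups(study)

bc <- bray_curtis_matrix(ko_matrix(ko_abund, "rpkm"))
write.table(unclass(bc), "results/distance/bray_curtis.tsv", sep = "\t",
            quote = FALSE)

be <- bioenv(bc, study$env_table)
print(be)
write.table(be$subsets, "results/distance/bioenv_subsets.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

gt <- group_distance_test(bc, groups[rownames(bc)], n_perm = 999, seed = 101)
print(gt)

# read sketches from the per-sample FASTA written at stage 1
fasta <- list.files("results/study", pattern = "^reads_.*\\.fasta$",
                    full.names = TRUE)
frag_sets <- lapply(fasta, function(f) {
  as.character(Biostrings::readDNAStringSet(f))
})
names(frag_sets) <- sub("^reads_(.*)\\.fasta$", "\\1", basename(fasta))
mash <- sketch_distance_matrix(frag_sets, k = 15, size = 5000, seed = 101)
write.table(unclass(mash), "results/distance/mash_samples.tsv", sep = "\t",
            quote = FALSE)

gt_mash <- group_distance_test(mash, groups[rownames(mash)], n_perm = 999,
                               seed = 102)
cat("Sketch-distance group test:\n")
print(gt_mash)

sys_sets <- lapply(split(frag_sets, sample_systems(study)[names(frag_sets)]),
                   unlist)
mash_sys <- sketch_distance_matrix(sys_sets, k = 15, size = 5000, seed = 101)
r <- matrix_correlation(mash, mash_sys, map = sample_systems(study))
cat(sprintf("Read-level vs system-level sketch distance correlation: R = %.3f\n",
            r))
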