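#' Run the full comparison workflow on a study
#'
#' Chains the pipeline stages end to end: length-filter and decontaminate
#' scaffolds, filter KOs and build the KO RPKM table from true scaffolds
#' only, compute Bray-Curtis dissimilarities between samples, fit
#' environmental variable subsets by exhaustive BioEnv search, test the
#' disinfected / non-disinfected contrast with a label-permutation test, and
#' detect and categorize MAGs.
#'
#' @param study A `synthetic_study` (or any object holding the same tables).
#' @param min_scaffold_len Scaffold length cutoff in bp (default 500).
#' @param breadth_threshold MAG detection breadth (default 0.25).
#' @param freq_threshold MAG category detection frequency (default 0.2).
#' @param n_perm Permutations for the group test (default 999).
#' @param seed Seed for the permutation stream.
#' @return List: `classification`, `scaffolds_true`, `ko_retained`,
#'   `ko_abundance`, `ko_rpkm` (matrix), `module_profiles` (completeness
#'   filtered), `bray_curtis` (dist_matrix), `bioenv`, `group_test`,
#'   `mag_detection`, `mag_categories`.
#' @export
run_study_analysis <- function(study, min_scaffold_len = 500,
                               breadth_threshold = 0.25, freq_threshold = 0.2,
                               n_perm = 999, seed = 1) {
  scaffolds <- length_filter(study$scaffolds, min_scaffold_len)
  classification <- classify_all(scaffolds, study$sample_coverage,
                                 study$control_coverage)
  sc_true <- true_scaffolds(scaffolds, classification)
  cov_true <- study$sample_coverage[
    study$sample_coverage$scaffold_id %in% sc_true$scaffold_id, , drop = FALSE]

  ann <- study$ko_annotations[
    study$ko_annotations$scaffold_id %in% sc_true$scaffold_id, , drop = FALSE]
  retained <- filter_kos(ann, cov_true, study$samples)
  ko_abund <- ko_abundance(ann, sc_true, cov_true, retained = retained,
                           read_len = study$config$read_length %||% 250)
  ko_rpkm <- ko_matrix(ko_abund, "rpkm")

  profiles <- filter_modules(module_profiles(study$module_catalog, ko_abund))

  bc <- bray_curtis_matrix(ko_rpkm)
  groups <- stats::setNames(study$samples$group, study$samples$sample_id)
  groups <- groups[rownames(bc)]
  be <- bioenv(bc, study$env_table)
  gt <- group_distance_test(bc, groups, n_perm = n_perm, seed = seed)

  mag_detection <- NULL; mag_categories <- NULL
  if (!is.null(study$mags) && nrow(study$mags) > 0) {
    qc <- quality_filter(study$mags)
    mag_detection <- detect_mags(
      study$mag_breadth[qc$mag_id, , drop = FALSE], breadth_threshold)
    mag_categories <- categorize_mags(mag_detection, sample_groups(study),
                                      freq_threshold)
  }

  list(classification = classification, scaffolds_true = sc_true,
       ko_retained = retained, ko_abundance = ko_abund, ko_rpkm = ko_rpkm,
       module_profiles = profiles, bray_curtis = bc, bioenv = be,
       group_test = gt, mag_detection = mag_detection,
       mag_categories = mag_categories)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
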