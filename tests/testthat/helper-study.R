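# Shared study fixtures, built in code. Small configurations keep the suite
# fast; the strong/no-noise configuration is used wherever exact planted-
# structure recovery is asserted.

small_config <- function(seed = 42, ...) {
  defaults <- list(
    n_systems_d = 2, n_systems_nd = 2, samples_per_system = 2,
    n_taxa = 12, n_contaminant_taxa = 3, scaffolds_per_taxon = 4,
    n_kos = 60, n_modules = 8, kos_per_taxon = 15,
    n_mags = 4, seed = seed
  )
  do.call(study_config, utils::modifyList(defaults, list(...)))
}

# strong planted group effects, noise-free coverage, tight dispersion
strong_config <- function(seed = 42, ...) {
  defaults <- list(
    n_systems_d = 3, n_systems_nd = 3, samples_per_system = 3,
    n_taxa = 20, n_contaminant_taxa = 3, scaffolds_per_taxon = 4,
    coverage_noise_sd = 0, abundance_dispersion = c(D = 0.3, ND = 0.4),
    group_effect = 2, n_kos = 80, n_modules = 10, kos_per_taxon = 20,
    n_mags = 8, seed = seed
  )
  do.call(study_config, utils::modifyList(defaults, list(...)))
}

.study_cache <- new.env(parent = emptyenv())

cached_study <- function(name, cfg_fun) {
  if (is.null(.study_cache[[name]])) {
    assign(name, generate_study(cfg_fun()), envir = .study_cache)
  }
  .study_cache[[name]]
}

small_study <- function() cached_study("small", small_config)
strong_study <- function() cached_study("strong", strong_config)
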