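test_that("invalid configurations are rejected", {
  expect_error(study_config(n_taxa = 0), "positive count")
  expect_error(study_config(samples_per_system = -1), "positive count")
  expect_error(study_config(contaminant_leak_rate = 2), "leak_rate")
  expect_error(
    study_config(env_vars = list(
      chlorine = list(mean = c(D = 0.37, ND = 0.1), sd = c(D = 0.1, ND = 0)))),
    "exactly 0")
})

test_that("the same configuration yields byte-identical studies", {
  a <- generate_study(small_config(seed = 9))
  b <- generate_study(small_config(seed = 9))
  expect_identical(a, b)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study(a, d1)
  write_study(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # and a different seed changes the draw
  expect_false(identical(a$sample_coverage,
                         generate_study(small_config(seed = 10))$sample_coverage))
})

test_that("chlorine is exactly zero in ND samples and averages 0.37 in D", {
  st <- generate_study(study_config(seed = 2))
  chl <- st$env_table$chlorine
  nd <- st$samples$group == "ND"
  expect_true(all(chl[nd] == 0))
  d_vals <- chl[!nd]
  se <- sd(d_vals) / sqrt(length(d_vals))
  expect_lt(abs(mean(d_vals) - 0.37), 3 * se)
})

test_that("without contaminant taxa nothing is flagged", {
  st <- generate_study(small_config(seed = 3, n_contaminant_taxa = 0))
  expect_false(any(st$truth$scaffolds$contaminant))
  expect_equal(nrow(st$control_coverage), 0)
})

test_that("pure-contaminant mode keeps contaminants out of true samples", {
  st <- small_study()
  contam <- st$truth$scaffolds$scaffold_id[st$truth$scaffolds$contaminant]
  expect_false(any(st$sample_coverage$scaffold_id %in% contam))
  # every contaminant scaffold covered in at least one negative control
  expect_true(all(contam %in% st$control_coverage$scaffold_id))
  # a leak rate lets some cross over
  leaky <- generate_study(small_config(seed = 8, contaminant_leak_rate = 0.5))
  leaked <- leaky$truth$scaffolds$scaffold_id[leaky$truth$scaffolds$contaminant]
  expect_true(any(leaky$sample_coverage$scaffold_id %in% leaked))
})

test_that("referenced scaffolds all exist and truth covers everything", {
  st <- small_study()
  ids <- st$scaffolds$scaffold_id
  expect_true(all(st$ssu_hits$scaffold_id %in% ids))
  expect_true(all(st$ko_annotations$scaffold_id %in% ids))
  expect_true(all(st$mag_members$scaffold_id %in% ids))
  expect_setequal(st$truth$scaffolds$scaffold_id, ids)
  expect_setequal(st$truth$mags$mag_id, st$mags$mag_id)
})

test_that("MAG breadth is monotone in the backing taxon's coverage", {
  st <- small_study()
  for (i in seq_len(nrow(st$mags))) {
    cov <- st$taxon_abundance[st$mags$taxon[i], ]
    br <- st$mag_breadth[st$mags$mag_id[i], ]
    ord <- order(cov)
    expect_true(all(diff(br[ord]) >= 0))
  }
})

test_that("noise-free group structure separates every within-group pair", {
  # zero dispersion, zero coverage noise, constant chlorine within D: samples
  # inside a group are replicates, so all within-group dissimilarity vanishes
  env <- study_config()$env_vars
  env$chlorine$sd[["D"]] <- 0
  st <- generate_study(strong_config(
    abundance_dispersion = c(D = 0, ND = 0), n_mags = 0, env_vars = env
  ))
  res <- run_study_analysis(st, n_perm = 99, seed = 1)
  d <- unclass(res$bray_curtis)
  g <- sample_groups(st)[rownames(d)]
  same <- outer(g, g, "==")
  within <- d[same & upper.tri(d)]
  between <- d[!same & upper.tri(d)]
  expect_lt(max(within), min(between))
})

test_that("strong group effects separate groups on average", {
  st <- strong_study()
  res <- run_study_analysis(st, n_perm = 99, seed = 1)
  d <- unclass(res$bray_curtis)
  g <- sample_groups(st)[rownames(d)]
  same <- outer(g, g, "==")
  expect_lt(mean(d[same & upper.tri(d)]), mean(d[!same & upper.tri(d)]))
})

test_that("studies round-trip through the writers and readers", {
  st <- small_study()
  dir <- withr::local_tempdir()
  manifest <- write_study(st, dir, write_fasta = TRUE, n_fragments = 50)
  rt <- read_study(dir)
  for (tab in c("samples", "controls", "scaffolds", "sample_coverage",
                "control_coverage", "ssu_hits", "ko_annotations",
                "mags", "mag_members")) {
    expect_equal(rt[[tab]], st[[tab]], label = tab, tolerance = 1e-12)
  }
  expect_equal(rt$env_table, st$env_table, tolerance = 1e-12)
  expect_equal(rt$mag_breadth, st$mag_breadth, tolerance = 1e-12)
  expect_equal(rt$mag_reads, st$mag_reads, tolerance = 1e-12)
  expect_identical(rt$module_definitions, st$module_definitions)
  expect_identical(rt$taxon_refs, st$taxon_refs)
  expect_equal(rt$truth, st$truth)

  # manifest row counts match the emitted tables
  expect_equal(unname(manifest[["scaffolds.tsv"]]), nrow(st$scaffolds))
  lines <- readLines(file.path(dir, "manifest.txt"))
  expect_setequal(sub("=.*", "", lines), names(manifest))
  for (f in setdiff(names(manifest), "manifest.txt")) {
    expect_true(file.exists(file.path(dir, f)), label = f)
  }
})

test_that("an empty study writes valid tables with headers", {
  st <- generate_study(small_config(seed = 4, n_contaminant_taxa = 0, n_mags = 0))
  st$scaffolds <- st$scaffolds[0, ]
  st$sample_coverage <- st$sample_coverage[0, ]
  st$ssu_hits <- st$ssu_hits[0, ]
  st$ko_annotations <- st$ko_annotations[0, ]
  st$truth$scaffolds <- st$truth$scaffolds[0, ]
  dir <- withr::local_tempdir()
  write_study(st, dir)
  rt <- read_study(dir)
  expect_equal(nrow(rt$scaffolds), 0)
  expect_equal(names(rt$scaffolds), names(st$scaffolds))
})

test_that("fragments come from the sample's taxa in abundance proportion", {
  st <- generate_study(study_config(
    n_systems_d = 1, n_systems_nd = 1, samples_per_system = 1,
    n_taxa = 1, n_contaminant_taxa = 0, scaffolds_per_taxon = 2, n_mags = 0,
    seed = 6
  ))
  sid <- st$samples$sample_id[1]
  frags <- generate_sample_sequences(st, sid, n_fragments = 30, seed = 2)
  expect_length(frags, 30)
  ref <- st$taxon_refs[[1]]
  expect_true(all(vapply(frags, grepl, logical(1), x = ref, fixed = TRUE)))
  # same seed, same abundances: identical multisets
  expect_identical(frags, generate_sample_sequences(st, sid, 30, seed = 2))
  expect_error(generate_sample_sequences(st, "nope", 10), "unknown sample")
})
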