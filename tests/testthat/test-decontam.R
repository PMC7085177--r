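test_that("length filter keeps scaffolds at the cutoff and preserves order", {
  sc <- data.frame(scaffold_id = c("a", "b", "c"), length = c(499, 500, 501))
  expect_equal(length_filter(sc, 500)$length, c(500, 501))
  expect_equal(length_filter(sc, 1), sc)
  empty <- sc[0, ]
  expect_equal(nrow(length_filter(empty, 500)), 0)
  expect_error(length_filter(sc, 0), "min_len")
})

test_that("relative abundance follows the read-set normalization", {
  expect_equal(relative_abundance(c(2, 2)), c(0.5, 0.5))
  expect_equal(relative_abundance(c(0, 0)), c(0, 0))
  # contaminant coverage over total negative-control coverage
  expect_equal(relative_abundance(c(1, 3), denom_cov = c(5, 3)), c(0.125, 0.375))
  expect_error(relative_abundance(c(1, 0), denom_cov = c(0, 0)), "undefined")
  expect_error(relative_abundance(c(-1, 0)), ">= 0")
})

test_that("normalized coverage deviation handles uniform and zero coverage", {
  expect_equal(ncd(2, 0), 0)
  expect_equal(ncd(2, 1), 0.5)
  expect_equal(ncd(0, 0), Inf)
  expect_equal(ncd(c(2, 0), c(1, 5)), c(0.5, Inf))
  expect_error(ncd(-1, 0), ">= 0")
})

test_that("classification branches fire as printed", {
  r <- classify_scaffold(0.005, 0, 1.2, 0.4)
  expect_equal(as.character(r$label), "true")
  expect_equal(r$branch, "RA_C=0")

  r <- classify_scaffold(0, 0.01, 0.5, 0.5)
  expect_equal(as.character(r$label), "contaminant")
  expect_equal(r$branch, "RA_S=0")

  # higher RA in sample but also higher NCD: no branch covers it
  r <- classify_scaffold(0.02, 0.01, 0.9, 0.8)
  expect_equal(as.character(r$label), "ambiguous")
  expect_equal(r$branch, "none")

  # covered by neither read set: uninformative, excluded
  r <- classify_scaffold(0, 0, Inf, Inf)
  expect_equal(as.character(r$label), "contaminant")
})

test_that("classifier agrees with the brute-force rule on random tuples", {
  set.seed(11)
  n <- 2000
  ra_s <- ifelse(runif(n) < 0.15, 0, runif(n, 0, 0.1))
  ra_c <- ifelse(runif(n) < 0.15, 0, runif(n, 0, 0.1))
  ncd_s <- ifelse(runif(n) < 0.05, Inf, runif(n, 0, 2))
  ncd_c <- ifelse(runif(n) < 0.05, Inf, runif(n, 0, 2))
  got <- as.character(classify_scaffold(ra_s, ra_c, ncd_s, ncd_c)$label)
  want <- mapply(oracle_classify, ra_s, ra_c, ncd_s, ncd_c)
  expect_identical(got, unname(want))
})

test_that("labels partition the scaffolds and are coverage-scale invariant", {
  st <- small_study()
  cls <- classify_all(st$scaffolds, st$sample_coverage, st$control_coverage)
  expect_equal(nrow(cls), nrow(st$scaffolds))
  expect_false(anyNA(cls$label))

  scale10 <- function(df, cols) { df[cols] <- df[cols] * 10; df }
  cls10 <- classify_all(
    st$scaffolds,
    scale10(st$sample_coverage, c("depth", "depth_sd")),
    scale10(st$control_coverage,
            c("contam_depth", "contam_sd", "total_depth", "total_sd"))
  )
  expect_identical(as.character(cls$label), as.character(cls10$label))
  expect_identical(cls$branch, cls10$branch)
})

test_that("sample relative abundances sum to 1 per system", {
  st <- small_study()
  cls <- classify_all(st$scaffolds, st$sample_coverage, st$control_coverage)
  for (sys in unique(cls$system_id)) {
    expect_equal(sum(cls$ra_s[cls$system_id == sys]), 1, tolerance = 1e-9)
  }
})

test_that("pure-contaminant study labels recover planted truth exactly", {
  st <- generate_study(study_config(
    n_systems_d = 2, n_systems_nd = 2, samples_per_system = 2,
    n_taxa = 15, n_contaminant_taxa = 5, scaffolds_per_taxon = 4,
    n_mags = 0, seed = 5
  ))
  # contaminant purity by construction
  contam_ids <- st$truth$scaffolds$scaffold_id[st$truth$scaffolds$contaminant]
  expect_false(any(st$sample_coverage$scaffold_id %in% contam_ids))
  expect_true(all(contam_ids %in% st$control_coverage$scaffold_id))

  cls <- classify_all(st$scaffolds, st$sample_coverage, st$control_coverage)
  m <- merge(cls, st$truth$scaffolds, by = "scaffold_id")
  expect_identical(as.character(m$label),
                   ifelse(m$contaminant, "contaminant", "true"))
})

test_that("N50 matches exhaustive search and handles degenerate tables", {
  sc <- function(lens) data.frame(scaffold_id = seq_along(lens), length = lens,
                                  gc = 0.5)
  expect_equal(assembly_stats(sc(c(5, 4, 3, 2, 1)))$n50, 4)
  expect_equal(assembly_stats(sc(7))$n50, 7)
  expect_equal(assembly_stats(sc(rep(120, 9)))$n50, 120)
  empty <- data.frame(scaffold_id = character(0), length = numeric(0),
                      gc = numeric(0))
  expect_error(assembly_stats(empty), "empty")

  set.seed(21)
  for (i in 1:25) {
    lens <- sample(100:20000, sample(1:100, 1), replace = TRUE)
    expect_equal(assembly_stats(sc(lens))$n50, oracle_n50(lens))
  }
})

test_that("assembly stats report size, GC and percent mapped", {
  sc <- data.frame(scaffold_id = 1:3, length = c(1000, 2000, 3000),
                   gc = c(0.4, 0.5, 0.6))
  st <- assembly_stats(sc, mapped_reads = 8e5, total_reads = 1e6)
  expect_equal(st$n_scaffolds, 3)
  expect_equal(st$total_size, 6000)
  expect_equal(st$gc_mean, 50)
  expect_equal(st$pct_mapped, 80)
})
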