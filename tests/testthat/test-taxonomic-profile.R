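make_hits <- function(...) {
  data.frame(..., stringsAsFactors = FALSE)
}

base_hits <- make_hits(
  hit_id = c("h1", "h2", "h3", "h4"),
  scaffold_id = c("s1", "s2", "s3", "s4"),
  domain = "bacteria",
  lineage = paste0("Bacteria;Phylum", 1:4, ";Class", 1:4),
  align_len = c(100, 99, 400, 1200),
  evalue = c(1e-6, 1e-10, 1e-5, 1e-20),
  gene_len = c(1500, 1400, 1500, 1500)
)

test_that("SSU filters are inclusive on length and strict on e-value", {
  kept <- filter_ssu_hits(base_hits)
  # h1: exactly 100 bp kept; h2: 99 bp dropped; h3: e-value exactly 1e-5 dropped
  expect_setequal(kept$hit_id, c("h1", "h4"))
  expect_equal(nrow(filter_ssu_hits(base_hits[0, ])), 0)
  # filtering is idempotent
  expect_equal(filter_ssu_hits(kept), kept)
})

test_that("hits on contaminant scaffolds are removed", {
  cls <- data.frame(scaffold_id = c("s1", "s4"),
                    label = factor(c("true", "contaminant"),
                                   levels = c("true", "contaminant", "ambiguous")))
  kept <- filter_ssu_hits(base_hits, classification = cls)
  expect_equal(kept$hit_id, "h1")
})

test_that("dedupe keeps the longest SSU gene per scaffold, ties lexicographic", {
  hits <- make_hits(
    hit_id = c("hB", "hA", "hC", "hD"),
    scaffold_id = c("s1", "s1", "s2", "s2"),
    gene_len = c(1200, 800, 900, 900)
  )
  out <- dedupe_per_scaffold(hits)
  expect_setequal(out$hit_id, c("hB", "hC"))
  expect_equal(dedupe_per_scaffold(out), out)
  one_per <- make_hits(hit_id = c("x", "y"), scaffold_id = c("a", "b"),
                       gene_len = c(5, 6))
  expect_equal(dedupe_per_scaffold(one_per), one_per)
})

ssu_fixture <- function(lengths, depths) {
  n <- length(lengths)
  list(
    hits = make_hits(
      hit_id = paste0("h", 1:n), scaffold_id = paste0("s", 1:n),
      domain = "bacteria",
      lineage = paste0("Bacteria;P", 1:n, ";C", 1:n, ";O;F;G", 1:n),
      align_len = 500, evalue = 1e-10, gene_len = 1500
    ),
    scaffolds = data.frame(scaffold_id = paste0("s", 1:n), length = lengths),
    coverage = data.frame(scaffold_id = paste0("s", 1:n), sample_id = "A",
                          depth = depths)
  )
}

test_that("SSU relative abundance is RPKM-normalized across SSU scaffolds", {
  fx <- ssu_fixture(2000, 10)
  prof <- ssu_relative_abundance(fx$hits, fx$scaffolds, fx$coverage, "A")
  expect_equal(prof$abundance, 1)

  # equal coverage gives equal RPKM regardless of scaffold length
  fx <- ssu_fixture(c(2000, 1000), c(10, 10))
  prof <- ssu_relative_abundance(fx$hits, fx$scaffolds, fx$coverage, "A")
  expect_equal(prof$abundance, c(0.5, 0.5))

  # doubling one scaffold's coverage doubles its share
  fx <- ssu_fixture(c(2000, 1000), c(20, 10))
  prof <- ssu_relative_abundance(fx$hits, fx$scaffolds, fx$coverage, "A")
  expect_equal(prof$abundance, c(2 / 3, 1 / 3))

  fx <- ssu_fixture(c(2000, 1000), c(0, 0))
  expect_error(
    ssu_relative_abundance(fx$hits, fx$scaffolds, fx$coverage, "A"),
    "zero coverage")
})

test_that("abundance is monotone in a scaffold's coverage", {
  shares <- vapply(c(5, 10, 20, 40), function(d) {
    fx <- ssu_fixture(c(1500, 3000, 800), c(d, 8, 8))
    prof <- ssu_relative_abundance(fx$hits, fx$scaffolds, fx$coverage, "A")
    prof$abundance[prof$scaffold_id == "s1"]
  }, numeric(1))
  expect_true(all(diff(shares) > 0))
})

test_that("rank aggregation is additive and preserves the total", {
  prof <- structure(
    data.frame(
      lineage = c("Bacteria;Proteobacteria;Alphaproteobacteria;O;F;G1",
                  "Bacteria;Proteobacteria;Gammaproteobacteria;O;F;G2",
                  "Bacteria;Nitrospirota;Nitrospiria;O;F;G3",
                  "Eukaryota;Ochrophyta"),
      domain = c("bacteria", "bacteria", "bacteria", "eukaryota"),
      scaffold_id = paste0("s", 1:4),
      abundance = c(0.2, 0.1, 0.5, 0.2),
      stringsAsFactors = FALSE),
    class = c("taxon_profile", "data.frame"), sample_id = "A", rank = "lineage")

  phy <- aggregate_by_rank(prof, "phylum")
  expect_equal(sum(phy$abundance), 1)
  expect_equal(phy$abundance[phy$taxon == "Proteobacteria"], 0.3)

  split <- aggregate_by_rank(prof, "phylum", split_proteobacteria = TRUE)
  expect_equal(sum(split$abundance), 1)
  expect_false("Proteobacteria" %in% split$taxon)
  expect_equal(split$abundance[split$taxon == "Alphaproteobacteria"], 0.2)
  expect_equal(split$abundance[split$taxon == "Gammaproteobacteria"], 0.1)

  dom <- aggregate_by_rank(prof, "domain")
  expect_equal(sum(dom$abundance), 1)
  # truncated lineage pools into unclassified below its depth
  cls <- aggregate_by_rank(prof, "class")
  expect_equal(cls$abundance[cls$taxon == "unclassified"], 0.2)
  expect_error(aggregate_by_rank(prof, "strain"), "unknown rank")
})

test_that("profiles from a generated study are normalized per sample", {
  st <- small_study()
  hits <- dedupe_per_scaffold(filter_ssu_hits(st$ssu_hits))
  sid <- st$samples$sample_id[1]
  prof <- ssu_relative_abundance(hits, st$scaffolds, st$sample_coverage, sid)
  expect_gt(nrow(prof), 0)
  expect_equal(sum(prof$abundance), 1, tolerance = 1e-9)
  phy <- aggregate_by_rank(prof, "phylum")
  expect_equal(sum(phy$abundance), 1, tolerance = 1e-9)
})
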