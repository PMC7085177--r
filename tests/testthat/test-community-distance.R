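revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

test_that("sketching is deterministic, strand-canonical, and length-aware", {
  set.seed(51)
  s <- random_dna_string(400)
  a <- minhash_sketch(s, k = 15, size = 100, seed = 3)
  b <- minhash_sketch(s, k = 15, size = 100, seed = 3)
  expect_identical(a$hashes, b$hashes)
  expect_false(is.unsorted(a$hashes, strictly = TRUE))

  rc <- minhash_sketch(revcomp(s), k = 15, size = 100, seed = 3)
  expect_identical(a$hashes, rc$hashes)

  short <- minhash_sketch("ACGT", k = 15, size = 100, seed = 3)
  expect_length(short$hashes, 0)
  # non-ACGT symbols break k-mers instead of hashing
  with_n <- minhash_sketch(paste0(s, "N", s), k = 15, size = 1e6, seed = 3)
  expect_identical(with_n$hashes, minhash_sketch(s, 15, 1e6, 3)$hashes)
})

test_that("minimum-multiplicity mode drops singleton k-mers", {
  set.seed(52)
  s <- random_dna_string(200)
  once <- minhash_sketch(s, k = 15, size = 1e6, seed = 1, min_mult = 2)
  expect_length(once$hashes, 0)
  twice <- minhash_sketch(c(s, s), k = 15, size = 1e6, seed = 1, min_mult = 2)
  expect_identical(twice$hashes, minhash_sketch(s, 15, 1e6, 1)$hashes)
})

test_that("sketch distance equals the closed form at the exact Jaccard index", {
  set.seed(53)
  k <- 15
  for (i in 1:10) {
    a <- random_dna_string(sample(100:600, 1))
    # mutate a into b to get a range of overlaps
    b <- strsplit(a, "")[[1]]
    swap <- sample(length(b), round(length(b) * runif(1, 0, 0.2)))
    b[swap] <- sample(c("A", "C", "G", "T"), length(swap), replace = TRUE)
    b <- paste(b, collapse = "")

    sa <- minhash_sketch(a, k, size = 1e6, seed = 9)
    sb <- minhash_sketch(b, k, size = 1e6, seed = 9)
    j <- oracle_jaccard(a, b, k)
    want <- if (j == 0) 1 else min(1, -log(2 * j / (1 + j)) / k)
    expect_equal(sketch_distance(sa, sb), want, tolerance = 1e-12)
  }
  sa <- minhash_sketch("ACGTACGTACGTACGTACGT", 5, 100, 1)
  expect_equal(sketch_distance(sa, sa), 0)
  expect_error(sketch_distance(sa, minhash_sketch("ACGT", 3, 100, 1)), "mismatched")
})

test_that("disjoint sketches are at the distance cap", {
  a <- minhash_sketch("AAAAAAAAAA", k = 5, size = 10, seed = 1)
  b <- minhash_sketch("CCCCCCCCCC", k = 5, size = 10, seed = 1)
  expect_equal(sketch_distance(a, b), 1)
})

test_that("Bray-Curtis matches the formula and vegan on random data", {
  expect_equal(bray_curtis(c(3, 1), c(3, 1)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 2)), 1)
  expect_equal(bray_curtis(c(2, 1), c(1, 1)), 0.2)
  expect_equal(bray_curtis(c(0, 0), c(0, 0)), 0)
  expect_error(bray_curtis(c(-1, 0), c(0, 0)), ">= 0")

  # joint coordinate permutation leaves the dissimilarity unchanged
  set.seed(61)
  x <- runif(20); y <- runif(20); p <- sample(20)
  expect_equal(bray_curtis(x[p], y[p]), bray_curtis(x, y))

  m <- matrix(rexp(60), 6, 10, dimnames = list(paste0("s", 1:6), NULL))
  ours <- bray_curtis_matrix(m)
  ref <- as.matrix(vegan::vegdist(m, method = "bray"))
  expect_equal(unclass(ours), ref[rownames(ours), colnames(ours)],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("bioenv enumerates every subset and recovers a rank-identical driver", {
  set.seed(71)
  n <- 10
  env <- as.data.frame(matrix(rnorm(n * 4), n,
                              dimnames = list(paste0("s", 1:n),
                                              c("v1", "v2", "v3", "v4"))))
  # community distance built from one scaled variable: that singleton wins
  d <- as.matrix(dist(scale(env$v2)))
  dimnames(d) <- list(rownames(env), rownames(env))
  res <- bioenv(dist_matrix(d), env)
  expect_equal(res$n_subsets, 15)
  expect_equal(nrow(res$subsets), 15)
  expect_equal(anyDuplicated(res$subsets$subset), 0)
  expect_equal(res$best_subset, "v2")
  expect_equal(res$best_rho, 1)
  # best rho dominates every singleton
  singles <- res$subsets$rho[res$subsets$size == 1]
  expect_true(all(res$best_rho >= singles))

  env$flat <- 1
  expect_warning(bioenv(dist_matrix(d), env), "constant")
})

test_that("bioenv agrees with an independent implementation on the best rho", {
  set.seed(72)
  n <- 12
  env <- as.data.frame(matrix(rnorm(n * 3), n,
                              dimnames = list(paste0("s", 1:n),
                                              c("a", "b", "c"))))
  comm <- matrix(rexp(n * 8), n, dimnames = list(rownames(env), NULL))
  d <- as.matrix(vegan::vegdist(comm))
  res <- bioenv(dist_matrix(d), env)
  ref <- summary(vegan::bioenv(as.dist(d), env, index = "euclidean", upto = 3))
  expect_equal(res$best_rho, max(ref$correlation), tolerance = 1e-10)
  expect_setequal(res$best_subset,
                  strsplit(ref$variables[which.max(ref$correlation)], " ")[[1]])
})

test_that("perfect cluster separation attains the minimal p-value", {
  # n large enough that no permutation plausibly recreates the split
  n <- 20
  labels <- paste0("s", 1:n)
  grp <- setNames(rep(c("D", "ND"), each = n / 2), labels)
  d <- matrix(1, n, n, dimnames = list(labels, labels))
  same <- outer(grp[labels], grp[labels], "==")
  d[same] <- 0.05
  diag(d) <- 0
  res <- group_distance_test(dist_matrix(d), grp, n_perm = 999, seed = 4)
  expect_equal(res$p_value, 1 / 1000)
  # identical seed reproduces the identical test
  res2 <- group_distance_test(dist_matrix(d), grp, n_perm = 999, seed = 4)
  expect_identical(res, res2)
  expect_error(group_distance_test(dist_matrix(d), setNames(rep("D", n), labels)),
               "two groups")
})

test_that("matrix correlation matches the direct Pearson formula", {
  labels <- paste0("s", 1:4)
  a <- matrix(0, 4, 4, dimnames = list(labels, labels))
  a[upper.tri(a)] <- c(0.1, 0.4, 0.2, 0.3, 0.6, 0.5)
  a <- a + t(a)
  b <- matrix(0, 4, 4, dimnames = list(labels, labels))
  b[upper.tri(b)] <- c(0.15, 0.35, 0.1, 0.4, 0.55, 0.45)
  b <- b + t(b)
  da <- dist_matrix(a); db <- dist_matrix(b)

  expect_equal(matrix_correlation(da, da), 1)
  expect_equal(matrix_correlation(da, dist_matrix(2 * a + 0.1 * (1 - diag(4)))), 1)

  x <- a[upper.tri(a)]; y <- b[upper.tri(b)]
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(matrix_correlation(da, db), r_direct)
  expect_error(matrix_correlation(dist_matrix(a[1:2, 1:2]),
                                  dist_matrix(b[1:2, 1:2])), "3 distance pairs")
})

test_that("sample distances aggregate to system level for cross-scale correlation", {
  labels <- c("a1", "a2", "b1", "b2")
  d <- matrix(0, 4, 4, dimnames = list(labels, labels))
  d[upper.tri(d)] <- c(0.1, 0.5, 0.6, 0.7, 0.8, 0.2)
  d <- d + t(d)
  map <- setNames(c("A", "A", "B", "B"), labels)
  agg <- aggregate_distance(dist_matrix(d), map)
  expect_equal(unclass(agg)["A", "B"], mean(c(0.5, 0.6, 0.7, 0.8)))
})

test_that("fragment sketch distances track planted abundance divergence", {
  divs <- numeric(0); dists <- numeric(0)
  for (seed in 1:10) {
    # sparse fragment sampling: k-mer containment tracks taxon abundance
    st <- generate_study(study_config(
      n_systems_d = 2, n_systems_nd = 2, samples_per_system = 1,
      n_taxa = 8, n_contaminant_taxa = 0, scaffolds_per_taxon = 2,
      n_mags = 0, group_effect = 2.5, coverage_noise_sd = 0, ref_len = 5000,
      seed = seed
    ))
    ids <- st$samples$sample_id
    frags <- lapply(seq_along(ids), function(i) {
      generate_sample_sequences(st, ids[i], n_fragments = 150, frag_len = 100,
                                seed = seed * 100 + i)
    })
    sk <- lapply(frags, minhash_sketch, k = 15, size = 5000, seed = 7)
    ab <- st$taxon_abundance
    for (i in 1:(length(ids) - 1)) {
      for (j in (i + 1):length(ids)) {
        divs <- c(divs, bray_curtis(ab[, i], ab[, j]))
        dists <- c(dists, sketch_distance(sk[[i]], sk[[j]]))
      }
    }
  }
  expect_gt(cor(divs, dists, method = "spearman"), 0.3)
})
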