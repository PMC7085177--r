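#' Labeled symmetric dissimilarity matrix
#'
#' Light container shared by the sketch-based and Bray-Curtis workflows and
#' consumed by [bioenv()], [group_distance_test()] and
#' [matrix_correlation()].
#'
#' @param values Square numeric matrix with row/column names, symmetric,
#'   zero diagonal, finite nonnegative entries.
#' @return Object of class `dist_matrix` (the validated matrix).
#' @export
dist_matrix <- function(values) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(rownames(values))) stop("dist_matrix requires labels")
  if (!isTRUE(all.equal(values, t(values)))) stop("matrix must be symmetric")
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("entries must be finite and >= 0")
  }
  if (any(diag(values) != 0)) stop("diagonal must be zero")
  colnames(values) <- rownames(values)
  structure(values, class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("Distance matrix over %d labels\n", nrow(x)))
  print(unclass(x), ...)
  invisible(x)
}

# condensed upper-triangle vector, column-major pair order
condense <- function(m) m[upper.tri(m)]

# row/col index pairs matching condense() order
pair_index <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  list(i = idx[, 1], j = idx[, 2])
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `sum(|x - y|) / sum(x + y)`; 0 when both vectors are all-zero. Bounded in
#' `[0, 1]` for nonnegative input and invariant under any joint permutation
#' of the coordinates.
#'
#' @param x,y Nonnegative numeric vectors of equal length (e.g., per-sample
#'   KO RPKM profiles).
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) stop("abundances must be >= 0")
  tot <- sum(x + y)
  if (tot == 0) return(0)
  sum(abs(x - y)) / tot
}

#' Pairwise Bray-Curtis distance matrix
#'
#' @param abundance Numeric matrix, samples in rows (row names required),
#'   features in columns.
#' @return A labeled [dist_matrix()].
#' @export
bray_curtis_matrix <- function(abundance) {
  stopifnot(is.matrix(abundance), !is.null(rownames(abundance)))
  n <- nrow(abundance)
  m <- matrix(0, n, n, dimnames = list(rownames(abundance), rownames(abundance)))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        m[i, j] <- m[j, i] <- bray_curtis(abundance[i, ], abundance[j, ])
      }
    }
  }
  dist_matrix(m)
}

# Spearman rho with average ranks (ties expected in permuted distances)
spearman_rho <- function(x, y) stats::cor(rank(x), rank(y), method = "pearson")

#' Exhaustive BioEnv search over environmental-variable subsets
#'
#' For every nonempty subset of the candidate variables: z-scores each
#' variable across samples, computes Euclidean distances between samples on
#' the scaled subset, and computes the Spearman rank correlation between that
#' distance vector and the community dissimilarities. With n candidate
#' variables exactly 2^n - 1 subsets are evaluated; the subset with maximal
#' rho is the combination of water-chemistry parameters best matching
#' community structure.
#'
#' @param community A [dist_matrix()] of community dissimilarities.
#' @param env Data frame of numeric environmental variables, row names =
#'   sample ids matching `community` labels.
#' @param variables Candidate variable names (default: all columns of `env`).
#' @return List of class `bioenv_result`: `subsets` (data frame of all
#'   subsets with size and rho, ranked by rho descending), `best_subset`
#'   (character vector), `best_rho`, `n_subsets`.
#' @export
bioenv <- function(community, env, variables = colnames(env)) {
  stopifnot(inherits(community, "dist_matrix"), length(variables) >= 1)
  labels <- rownames(community)
  if (!all(labels %in% rownames(env))) {
    stop("every community sample needs a complete env row")
  }
  env <- env[labels, variables, drop = FALSE]
  if (anyNA(env)) stop("env table has missing values for analysed samples")

  sds <- vapply(env, stats::sd, numeric(1))
  if (any(sds == 0)) {
    warning("excluding constant environmental variable(s): ",
            paste(variables[sds == 0], collapse = ", "))
    variables <- variables[sds > 0]
    env <- env[, variables, drop = FALSE]
  }
  if (length(variables) == 0) stop("no non-constant variables left")

  scaled <- scale(as.matrix(env))
  comm_v <- condense(unclass(community))

  n <- length(variables)
  subset_list <- vector("list", 2^n - 1)
  rho <- numeric(2^n - 1)
  for (code in seq_len(2^n - 1)) {
    sel <- which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
    env_d <- condense(as.matrix(stats::dist(scaled[, sel, drop = FALSE])))
    subset_list[[code]] <- variables[sel]
    rho[code] <- spearman_rho(comm_v, env_d)
  }
  ord <- order(rho, decreasing = TRUE)
  subsets <- data.frame(
    subset = vapply(subset_list, paste, character(1), collapse = "+"),
    size = vapply(subset_list, length, integer(1)),
    rho = rho,
    stringsAsFactors = FALSE
  )[ord, , drop = FALSE]
  rownames(subsets) <- NULL
  structure(
    list(subsets = subsets, best_subset = subset_list[[ord[1]]],
         best_rho = rho[ord[1]], n_subsets = 2^n - 1),
    class = "bioenv_result"
  )
}

#' @export
print.bioenv_result <- function(x, ...) {
  cat(sprintf("BioEnv: %d subsets evaluated; best rho = %.3f for {%s}\n",
              x$n_subsets, x$best_rho, paste(x$best_subset, collapse = ", ")))
  print(utils::head(x$subsets, 5))
  invisible(x)
}

# One-way F-like ratio over pairwise distances grouped into pair classes
# (within-D, within-ND, between). cls is an integer vector in 0:2.
pair_class_f <- function(d, cls) {
  k_tab <- tabulate(cls + 1L, 3L)
  used <- k_tab > 0
  k <- sum(used)
  n <- length(d)
  if (k < 2 || n <= k) return(NA_real_)
  means <- rowsum(d, cls) / k_tab[used]
  grand <- mean(d)
  ss_between <- sum(k_tab[used] * (means - grand)^2)
  ss_within <- sum((d - means[match(cls, sort(unique(cls)))])^2)
  (ss_between / (k - 1)) / (ss_within / (n - k))
}

#' Permutation test for group differences in pairwise distances
#'
#' Tests whether dissimilarities differ between the three pair classes
#' induced by a two-group design (within-D, within-ND, between-group pairs)
#' using an F-like among/within ratio on the pooled pairwise distances. The
#' null distribution is built by reshuffling the sample group labels; the
#' p-value is `(exceedances + 1) / (n_perm + 1)` and is exact under
#' exchangeability of the samples.
#'
#' @param dist A [dist_matrix()].
#' @param groups Named character/factor vector mapping each sample label to
#'   one of two groups (e.g., `"D"`/`"ND"`).
#' @param n_perm Number of label permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return List of class `perm_test_result`: `statistic`, `n_perm`,
#'   `p_value`, `seed`, `statistic_name`.
#' @export
group_distance_test <- function(dist, groups, n_perm = 999, seed = 1) {
  stopifnot(inherits(dist, "dist_matrix"))
  labels <- rownames(dist)
  if (!all(labels %in% names(groups))) stop("groups must cover all samples")
  g <- factor(groups[labels])
  if (nlevels(g) != 2) stop("exactly two groups required")
  if (any(table(g) < 2)) stop("need >= 2 samples per group")

  n <- length(labels)
  pi <- pair_index(n)
  d <- condense(unclass(dist))
  is1 <- as.integer(g == levels(g)[1])

  cls_obs <- is1[pi$i] + is1[pi$j]
  obs <- pair_class_f(d, cls_obs)

  set.seed(seed)
  # permuted labels as a matrix so the null is computed with vector ops
  perm_is1 <- vapply(seq_len(n_perm), function(p) sample(is1), integer(n))
  cls_perm <- perm_is1[pi$i, , drop = FALSE] + perm_is1[pi$j, , drop = FALSE]
  null <- vapply(seq_len(n_perm), function(p) pair_class_f(d, cls_perm[, p]),
                 numeric(1))
  p <- (sum(null >= obs) + 1) / (n_perm + 1)
  structure(
    list(statistic = obs, n_perm = n_perm, p_value = p, seed = seed,
         statistic_name = "pair-class F ratio (within-D / within-ND / between)"),
    class = "perm_test_result"
  )
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat(sprintf("Permutation test: F = %.3f, p = %.4f (%d permutations, seed %d)\n",
              x$statistic, x$p_value, x$n_perm, x$seed))
  invisible(x)
}

#' Pearson correlation between two distance matrices
#'
#' Correlates the condensed upper triangles of two distance matrices over the
#' same labels. When the first matrix is finer-grained (e.g., read-based
#' distances between samples) than the second (scaffold-based distances
#' between systems), supply `map` to average the first matrix's distances
#' within each pair of higher-level units first.
#'
#' @param a,b [dist_matrix()] objects.
#' @param map Optional named vector mapping `a`'s labels to `b`'s labels
#'   (e.g., sample -> system).
#' @return Pearson r.
#' @export
matrix_correlation <- function(a, b, map = NULL) {
  stopifnot(inherits(a, "dist_matrix"), inherits(b, "dist_matrix"))
  if (!is.null(map)) a <- aggregate_distance(a, map)
  if (!setequal(rownames(a), rownames(b))) stop("labels must match")
  bm <- unclass(b)[rownames(a), rownames(a)]
  va <- condense(unclass(a))
  vb <- condense(bm)
  if (length(va) < 3) stop("need at least 3 distance pairs")
  stats::cor(va, vb, method = "pearson")
}

#' Average a distance matrix within groups of labels
#'
#' Off-diagonal block means give between-group distances; within-group
#' off-diagonal means are not needed downstream and the diagonal is set to 0.
#'
#' @param dist A [dist_matrix()].
#' @param map Named vector: label -> group.
#' @return A [dist_matrix()] over the groups.
#' @export
aggregate_distance <- function(dist, map) {
  labels <- rownames(dist)
  if (!all(labels %in% names(map))) stop("map must cover all labels")
  grp <- as.character(map[labels])
  ug <- unique(grp)
  n <- length(ug)
  out <- matrix(0, n, n, dimnames = list(ug, ug))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      out[i, j] <- mean(unclass(dist)[grp == ug[i], grp == ug[j], drop = FALSE])
    }
  }
  out <- (out + t(out)) / 2
  dist_matrix(out)
}
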