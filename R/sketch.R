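#' MinHash sketch of a sequence set
#'
#' Hashes every canonical (strand-minimal) k-mer of the input with a seeded
#' 64-bit mixing function and keeps the `size` smallest distinct hash values.
#' Two sketches built with the same `k`, `size` and `seed` estimate the
#' Jaccard index of the underlying k-mer sets, from which [sketch_distance()]
#' derives a Mash-style evolutionary distance. K-mers containing non-ACGT
#' symbols are skipped; a sequence and its reverse complement sketch
#' identically.
#'
#' @param sequences Character vector of DNA sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param k K-mer size, 1-31 (default 21, the usual genomic choice).
#' @param size Sketch cardinality (number of minimum hashes retained).
#' @param seed Integer hash seed; sketches are only comparable at equal seeds.
#' @param min_mult Minimum k-mer multiplicity. Leave at 1 for assembled
#'   scaffolds; 2 is the conventional read-mode setting that suppresses
#'   singleton error k-mers.
#' @return Object of class `minhash_sketch`: list with `k`, `size`, `seed`,
#'   `min_mult` and the sorted numeric vector `hashes`.
#' @export
minhash_sketch <- function(sequences, k = 21, size = 1000, seed = 42,
                           min_mult = 1) {
  sequences <- as.character(sequences)
  hashes <- .minhash_hashes(sequences, as.integer(k), as.integer(size),
                            as.numeric(seed), as.integer(min_mult))
  structure(
    list(k = as.integer(k), size = as.integer(size), seed = as.numeric(seed),
         min_mult = as.integer(min_mult), hashes = hashes),
    class = "minhash_sketch"
  )
}

#' @export
print.minhash_sketch <- function(x, ...) {
  cat(sprintf("MinHash sketch: k=%d, size=%d (%d hashes), seed=%g\n",
              x$k, x$size, length(x$hashes), x$seed))
  invisible(x)
}

#' Mash distance between two MinHash sketches
#'
#' Estimates the Jaccard index j from the merged-sketch construction (the
#' fraction of the smallest `size` union hashes shared by both sketches) and
#' converts it to a mutation-rate distance
#' \deqn{D = -\frac{1}{k}\ln\frac{2j}{1+j},}
#' capped at 1; disjoint sketches (j = 0) give distance 1. When both sketches
#' hold every distinct k-mer (cardinality below `size`), j is the exact
#' Jaccard index and D its exact transform.
#'
#' @param a,b `minhash_sketch` objects with identical `k`, `size` and `seed`.
#' @return Dissimilarity in `[0, 1]`.
#' @export
sketch_distance <- function(a, b) {
  stopifnot(inherits(a, "minhash_sketch"), inherits(b, "minhash_sketch"))
  if (a$k != b$k || a$size != b$size || a$seed != b$seed) {
    stop("sketches have mismatched parameters (k/size/seed)")
  }
  j <- sketch_jaccard(a, b)
  if (j <= 0) return(1)
  min(1, -log(2 * j / (1 + j)) / a$k)
}

#' Jaccard index estimated from two sketches
#'
#' @inheritParams sketch_distance
#' @return Estimated Jaccard index in `[0, 1]`; 0 if either sketch is empty.
#' @export
sketch_jaccard <- function(a, b) {
  if (length(a$hashes) == 0 || length(b$hashes) == 0) return(0)
  merged <- sort(unique(c(a$hashes, b$hashes)))
  m <- min(a$size, length(merged))
  merged <- merged[seq_len(m)]
  shared <- sum(merged %in% a$hashes & merged %in% b$hashes)
  shared / m
}

#' Pairwise Mash distance matrix over sequence sets
#'
#' @param seq_sets Named list of character vectors (one sequence set per
#'   sample or system).
#' @param ... Passed to [minhash_sketch()].
#' @return A labeled symmetric [dist_matrix()].
#' @export
sketch_distance_matrix <- function(seq_sets, ...) {
  stopifnot(is.list(seq_sets), !is.null(names(seq_sets)))
  sketches <- lapply(seq_sets, minhash_sketch, ...)
  n <- length(sketches)
  m <- matrix(0, n, n, dimnames = list(names(seq_sets), names(seq_sets)))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        m[i, j] <- m[j, i] <- sketch_distance(sketches[[i]], sketches[[j]])
      }
    }
  }
  dist_matrix(m)
}
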