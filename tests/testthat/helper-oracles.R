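# Independent brute-force oracles. These re-derive expected values from first
# principles and share no code with the implementation paths they check.

# The piecewise true/contaminant rule, written as literal branch checks.
# A scaffold covered by neither read set is excluded (labeled contaminant).
oracle_classify <- function(ra_s, ra_c, ncd_s, ncd_c) {
  if (ra_s == 0 && ra_c == 0) return("contaminant")
  if (ra_c == 0) return("true")
  if (ra_s > ra_c && ncd_s < ncd_c) return("true")
  if (ra_s == 0) return("contaminant")
  if (ra_c > ra_s && ncd_c < ncd_s) return("contaminant")
  "ambiguous"
}

# N50 by exhaustive search over all candidate lengths.
oracle_n50 <- function(lengths) {
  total <- sum(lengths)
  cands <- sort(unique(lengths))
  # largest candidate length still covering half the bases
  ok <- vapply(cands, function(L) sum(lengths[lengths >= L]) >= total / 2,
               logical(1))
  max(cands[ok])
}

# Median by explicit sort-and-middle.
oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

# Module completeness by direct block-by-block evaluation on the parsed
# structure (blocks = list of alternative KO vectors).
oracle_completeness <- function(blocks, present) {
  done <- 0
  for (b in blocks) {
    alt_ok <- FALSE
    for (alt in b) {
      if (all(alt %in% present)) alt_ok <- TRUE
    }
    if (alt_ok) done <- done + 1
  }
  c(completeness = done / length(blocks), missing = length(blocks) - done)
}

# Distinct canonical k-mers of a DNA string, enumerated in plain R.
oracle_kmers <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < k) return(character(0))
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  rc <- function(x) {
    chartr("ACGT", "TGCA",
           vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                  character(1)))
  }
  unique(unname(pmin(kmers, rc(kmers))))
}

# Exact Jaccard of two sequences' canonical k-mer sets.
oracle_jaccard <- function(a, b, k) {
  ka <- oracle_kmers(a, k)
  kb <- oracle_kmers(b, k)
  if (length(ka) == 0 && length(kb) == 0) return(0)
  length(intersect(ka, kb)) / length(union(ka, kb))
}

# MAG category by independent explicit counting over a detection row.
oracle_category <- function(det_row, is_d, t = 0.2) {
  nd_hits <- sum(det_row[!is_d])
  d_hits <- sum(det_row[is_d])
  fd <- d_hits / sum(is_d)
  fnd <- nd_hits / sum(!is_d)
  if (fd >= t && nd_hits == 0) return("D-only")
  if (fnd >= t && d_hits == 0) return("ND-only")
  if (fd >= t && fnd >= t) return("both")
  "other"
}

random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
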