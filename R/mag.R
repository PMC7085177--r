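#' Quality-filter MAGs by completeness and redundancy
#'
#' Retains metagenome-assembled genomes with completeness strictly greater
#' than `min_completeness` and redundancy strictly less than
#' `max_redundancy`; a MAG at exactly 50% completeness or exactly 10%
#' redundancy is removed.
#'
#' @param mags MAG table: `mag_id`, `length` (bp), `completeness` (%),
#'   `redundancy` (%).
#' @param min_completeness Percent, exclusive lower bound (default 50).
#' @param max_redundancy Percent, exclusive upper bound (default 10).
#' @return Filtered MAG table.
#' @export
quality_filter <- function(mags, min_completeness = 50, max_redundancy = 10) {
  stopifnot(all(c("completeness", "redundancy") %in% names(mags)))
  mags[mags$completeness > min_completeness &
         mags$redundancy < max_redundancy, , drop = FALSE]
}

#' MAG detection from breadth of coverage
#'
#' A MAG is detected in a sample if at least `threshold` of its bases are
#' covered by one or more reads from that sample (inclusive: breadth exactly
#' at the threshold counts as detected).
#'
#' @param breadth Numeric matrix, MAGs in rows, samples in columns, entries
#'   in `[0, 1]` (fraction of MAG bases with >= 1x coverage).
#' @param threshold Detection breadth (default 0.25).
#' @return Logical matrix of the same shape (the detection matrix).
#' @export
detect_mags <- function(breadth, threshold = 0.25) {
  stopifnot(is.matrix(breadth))
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (any(breadth < 0) || any(breadth > 1)) stop("breadth must be in [0, 1]")
  breadth >= threshold
}

#' Categorize MAGs by detection frequency in the two system groups
#'
#' Detection frequencies pool all samples of each group:
#' `freq_X = detections among group-X samples / group-X samples`. With
#' frequency threshold t (default 0.20, inclusive):
#' * `D-only`: `freq_D >= t` and zero ND detections;
#' * `ND-only`: `freq_ND >= t` and zero D detections;
#' * `both`: `freq_D >= t` and `freq_ND >= t`;
#' * `other`: everything else.
#'
#' @param detection Logical MAG x sample matrix from [detect_mags()].
#' @param groups Named vector mapping sample ids to `"D"` / `"ND"`.
#' @param freq_threshold Detection-frequency threshold (default 0.2).
#' @return Data frame: `mag_id`, `category` (factor D-only/ND-only/both/
#'   other), `freq_d`, `freq_nd`.
#' @export
categorize_mags <- function(detection, groups, freq_threshold = 0.2) {
  stopifnot(is.matrix(detection), is.logical(detection))
  samples <- colnames(detection)
  if (!all(samples %in% names(groups))) stop("groups must cover all samples")
  g <- as.character(groups[samples])
  if (!all(g %in% c("D", "ND"))) stop("groups must be 'D' or 'ND'")
  if (!all(c("D", "ND") %in% g)) stop("both groups must be present")

  freq_d <- rowMeans(detection[, g == "D", drop = FALSE])
  freq_nd <- rowMeans(detection[, g == "ND", drop = FALSE])
  t <- freq_threshold
  category <- ifelse(freq_d >= t & freq_nd == 0, "D-only",
              ifelse(freq_nd >= t & freq_d == 0, "ND-only",
              ifelse(freq_d >= t & freq_nd >= t, "both", "other")))
  data.frame(
    mag_id = rownames(detection),
    category = factor(category, levels = c("D-only", "ND-only", "both", "other")),
    freq_d = freq_d, freq_nd = freq_nd,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Per-sample MAG RPKM, masked by detection
#'
#' \deqn{RPKM = \frac{reads\ mapped\ to\ MAG}
#'                  {(total\ reads/10^6) \times (MAG\ length/10^3)}}
#' Values are only reported for (MAG, sample) cells where the MAG is
#' detected; undetected cells are `NA` regardless of mapped-read count, so
#' spurious cross-mapping to absent genomes never enters abundance summaries.
#'
#' @param read_count Reads mapped to the MAG (vectorized).
#' @param total_reads Total reads in the sample.
#' @param mag_len MAG length in bp.
#' @param detected Logical detection flag(s).
#' @return RPKM values with `NA` where not detected.
#' @export
mag_rpkm <- function(read_count, total_reads, mag_len, detected = TRUE) {
  if (any(total_reads <= 0)) stop("total reads must be positive")
  if (any(mag_len <= 0)) stop("MAG length must be positive")
  if (any(read_count < 0)) stop("read counts must be >= 0")
  rpkm <- read_count / ((total_reads / 1e6) * (mag_len / 1e3))
  ifelse(detected, rpkm, NA_real_)
}

#' Completeness-corrected genome size
#'
#' Estimated genome size = MAG length x 100 / completeness(%): the assembled
#' fraction scaled up by the inverse of the single-copy-gene completeness
#' estimate.
#'
#' @param mag_len MAG length in bp (vectorized).
#' @param completeness Completeness percent in (0, 100].
#' @return Estimated genome size in bp.
#' @export
estimate_genome_size <- function(mag_len, completeness) {
  if (any(completeness <= 0) || any(completeness > 100)) {
    stop("completeness must be in (0, 100]")
  }
  if (any(mag_len <= 0)) stop("MAG length must be positive")
  mag_len * 100 / completeness
}
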