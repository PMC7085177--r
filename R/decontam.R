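#' Discard scaffolds below a minimum length
#'
#' Assembled scaffolds shorter than `min_len` are dropped before any
#' downstream profiling; the conventional cutoff for short-read co-assemblies
#' is 500 bp. A scaffold exactly at the cutoff survives.
#'
#' @param scaffolds Scaffold table (data frame with at least a `length`
#'   column in bp).
#' @param min_len Minimum scaffold length in bp to retain (default 500).
#' @return The scaffold table restricted to rows with `length >= min_len`,
#'   original order preserved.
#' @export
length_filter <- function(scaffolds, min_len = 500) {
  stopifnot(is.data.frame(scaffolds), "length" %in% names(scaffolds))
  if (min_len < 1) stop("min_len must be >= 1")
  scaffolds[scaffolds$length >= min_len, , drop = FALSE]
}

#' Per-scaffold relative abundance of a read set
#'
#' RA_i = cov_i / sum_j(denom_cov_j). For sample reads the denominator is the
#' sample coverage itself (so abundances sum to 1); for contaminant reads the
#' denominator is the total negative-control coverage, so contaminant
#' abundances need not sum to 1.
#'
#' @param cov Numeric vector of mean depths (fold coverage), one per scaffold.
#' @param denom_cov Numeric vector defining the denominator read set; defaults
#'   to `cov`.
#' @return Numeric vector of relative abundances.
#' @export
relative_abundance <- function(cov, denom_cov = cov) {
  stopifnot(is.numeric(cov), is.numeric(denom_cov))
  if (any(cov < 0) || any(denom_cov < 0)) stop("coverages must be >= 0")
  total <- sum(denom_cov)
  if (total == 0) {
    if (any(cov > 0)) {
      stop("relative abundance undefined: zero denominator with nonzero coverage")
    }
    return(rep(0, length(cov)))
  }
  cov / total
}

#' Normalized coverage deviation
#'
#' NCD = per-base depth SD / mean depth, a coverage-evenness statistic.
#' Contaminant-derived scaffolds tend to show patchier (higher-NCD) coverage
#' under sample reads than genuine community members. Zero mean depth returns
#' `Inf`: a scaffold with no coverage carries no evenness evidence and must
#' never win a "lower NCD" comparison.
#'
#' @param depth_mean Mean fold coverage (vectorized).
#' @param depth_sd Per-base depth standard deviation (vectorized).
#' @return NCD values; `Inf` where `depth_mean` is 0.
#' @export
ncd <- function(depth_mean, depth_sd) {
  if (any(depth_mean < 0) || any(depth_sd < 0)) {
    stop("depth mean and sd must be >= 0")
  }
  out <- ifelse(depth_mean == 0, Inf, depth_sd / depth_mean)
  as.numeric(out)
}

#' Classify scaffolds as true, contaminant, or ambiguous
#'
#' Applies the piecewise decontamination rule comparing relative abundance and
#' normalized coverage deviation under sample reads (S) versus contaminant
#' reads in negative controls (C):
#' * true if `RA_C == 0`, or if `RA_S > RA_C` and `NCD_S < NCD_C`;
#' * contaminant if `RA_S == 0`, or if `RA_C > RA_S` and `NCD_C < NCD_S`;
#' * ambiguous otherwise (no branch fires; excluded downstream).
#'
#' A scaffold covered by neither read set (`RA_S == 0` and `RA_C == 0`)
#' satisfies both zero branches; it is resolved to contaminant (excluded)
#' because an uncovered scaffold is uninformative and must not enter profiles.
#'
#' @param ra_s,ra_c Relative abundances under sample / contaminant reads.
#' @param ncd_s,ncd_c Normalized coverage deviations (Inf sentinel allowed).
#' @return Data frame with columns `label` (factor true/contaminant/ambiguous)
#'   and `branch` (which printed condition fired: `RA_C=0`,
#'   `RA_S>RA_C&NCD_S<NCD_C`, `RA_S=0`, `RA_C>RA_S&NCD_C<NCD_S`, or `none`).
#' @export
classify_scaffold <- function(ra_s, ra_c, ncd_s, ncd_c) {
  n <- length(ra_s)
  stopifnot(length(ra_c) == n, length(ncd_s) == n, length(ncd_c) == n)
  if (any(ra_s < 0) || any(ra_c < 0) || any(ncd_s < 0) || any(ncd_c < 0)) {
    stop("classification inputs must be >= 0")
  }
  label <- rep("ambiguous", n)
  branch <- rep("none", n)

  both_zero <- ra_s == 0 & ra_c == 0
  true1 <- !both_zero & ra_c == 0
  contam1 <- both_zero | (ra_s == 0 & !true1)
  true2 <- !true1 & !contam1 & ra_s > ra_c & ncd_s < ncd_c
  contam2 <- !true1 & !contam1 & !true2 & ra_c > ra_s & ncd_c < ncd_s

  label[true1 | true2] <- "true"
  label[contam1 | contam2] <- "contaminant"
  branch[true1] <- "RA_C=0"
  branch[true2] <- "RA_S>RA_C&NCD_S<NCD_C"
  branch[contam1] <- "RA_S=0"
  branch[contam2] <- "RA_C>RA_S&NCD_C<NCD_S"

  data.frame(
    label = factor(label, levels = c("true", "contaminant", "ambiguous")),
    branch = branch,
    ra_s = ra_s, ra_c = ra_c, ncd_s = ncd_s, ncd_c = ncd_c,
    stringsAsFactors = FALSE
  )
}

# Pool per-read-set coverage over samples/controls for one scaffold set.
# Depths add when read sets are pooled; per-base variances are treated as
# additive across independent read sets, so pooled SD = sqrt(sum(sd^2)).
pool_coverage <- function(cov_long, id_col, depth_col, sd_col, scaffold_ids) {
  depth <- rowsum(cov_long[[depth_col]], cov_long$scaffold_id)
  var <- rowsum(cov_long[[sd_col]]^2, cov_long$scaffold_id)
  idx <- match(scaffold_ids, rownames(depth))
  d <- ifelse(is.na(idx), 0, depth[idx, 1])
  s <- sqrt(ifelse(is.na(idx), 0, var[idx, 1]))
  list(depth = as.numeric(d), sd = as.numeric(s))
}

#' Classify every scaffold of a study against its negative controls
#'
#' Computes per-scaffold RA and NCD under sample reads and under contaminant
#' reads, then applies [classify_scaffold()]. Each co-assembly (system) is
#' classified independently: relative-abundance denominators are sums over
#' that system's scaffolds only.
#'
#' @param scaffolds Scaffold table: `scaffold_id`, `system_id`, `length`, `gc`.
#' @param sample_coverage Long table of per-true-sample coverage:
#'   `scaffold_id`, `sample_id`, `depth`, `depth_sd`.
#' @param control_coverage Long table of per-negative-control coverage:
#'   `scaffold_id`, `control_id`, `contam_depth`, `contam_sd` (depth from
#'   contaminant reads) and `total_depth`, `total_sd` (depth from all
#'   negative-control reads; the RA_C denominator read set).
#' @return Data frame: `scaffold_id`, `system_id`, `label`, `branch`, `ra_s`,
#'   `ra_c`, `ncd_s`, `ncd_c`, one row per scaffold, input order preserved.
#' @export
classify_all <- function(scaffolds, sample_coverage, control_coverage) {
  stopifnot(all(c("scaffold_id", "system_id") %in% names(scaffolds)))
  res <- lapply(split(seq_len(nrow(scaffolds)), scaffolds$system_id), function(rows) {
    ids <- scaffolds$scaffold_id[rows]
    sc <- sample_coverage[sample_coverage$scaffold_id %in% ids, , drop = FALSE]
    cc <- control_coverage[control_coverage$scaffold_id %in% ids, , drop = FALSE]
    s <- pool_coverage(sc, "sample_id", "depth", "depth_sd", ids)
    contam <- pool_coverage(cc, "control_id", "contam_depth", "contam_sd", ids)
    nc <- pool_coverage(cc, "control_id", "total_depth", "total_sd", ids)
    ra_s <- relative_abundance(s$depth)
    ra_c <- if (sum(nc$depth) == 0) rep(0, length(ids)) else contam$depth / sum(nc$depth)
    cls <- classify_scaffold(ra_s, ra_c, ncd(s$depth, s$sd), ncd(contam$depth, contam$sd))
    cbind(
      data.frame(scaffold_id = ids, system_id = scaffolds$system_id[rows],
                 stringsAsFactors = FALSE),
      cls
    )
  })
  out <- do.call(rbind, res)
  out <- out[match(scaffolds$scaffold_id, out$scaffold_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep only scaffolds classified as true
#'
#' Contaminant and ambiguous scaffolds are excluded from all downstream
#' analyses.
#'
#' @param scaffolds Scaffold table.
#' @param classification Output of [classify_all()].
#' @return Scaffold table restricted to `label == "true"`.
#' @export
true_scaffolds <- function(scaffolds, classification) {
  keep <- classification$scaffold_id[classification$label == "true"]
  scaffolds[scaffolds$scaffold_id %in% keep, , drop = FALSE]
}

#' Assembly summary statistics
#'
#' N50 is the smallest scaffold length L such that scaffolds of length >= L
#' hold at least half of all assembled bases; it is always the length of some
#' scaffold. Percent mapped is computed from properly-paired mapped read
#' counts against per-sample read totals.
#'
#' @param scaffolds Scaffold table with `length` and `gc` columns.
#' @param mapped_reads Total properly-paired reads mapped (scalar), optional.
#' @param total_reads Total reads sequenced (scalar), optional.
#' @return List: `n_scaffolds`, `total_size` (bp), `n50` (bp), `gc_mean` (%),
#'   `pct_mapped` (%, `NA` if read totals not given).
#' @export
assembly_stats <- function(scaffolds, mapped_reads = NA, total_reads = NA) {
  n <- nrow(scaffolds)
  if (n == 0) stop("assembly statistics undefined for an empty scaffold table")
  len <- sort(scaffolds$length, decreasing = TRUE)
  cum <- cumsum(len)
  n50 <- len[which(cum >= sum(len) / 2)[1]]
  pct <- if (is.na(mapped_reads) || is.na(total_reads)) NA_real_ else 100 * mapped_reads / total_reads
  list(
    n_scaffolds = n,
    total_size = sum(scaffolds$length),
    n50 = n50,
    gc_mean = 100 * mean(scaffolds$gc),
    pct_mapped = pct
  )
}
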