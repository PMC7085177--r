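#' Filter SSU rRNA hits by alignment length and e-value
#'
#' Keeps hits with alignment length at or above `min_align` (inclusive) and
#' e-value strictly below `max_evalue`. Hits on scaffolds classified as
#' contaminant are removed when a classification is supplied.
#'
#' @param hits SSU hit table: `hit_id`, `scaffold_id`, `domain`, `lineage`,
#'   `align_len`, `evalue`, `gene_len`.
#' @param min_align Minimum alignment length in bp (default 100, inclusive).
#' @param max_evalue E-value cutoff (default 1e-5, strict).
#' @param classification Optional [classify_all()] output; hits on
#'   non-`true` scaffolds are dropped.
#' @return Filtered hit table, input order preserved.
#' @export
filter_ssu_hits <- function(hits, min_align = 100, max_evalue = 1e-5,
                            classification = NULL) {
  if (min_align <= 0 || max_evalue <= 0) stop("thresholds must be positive")
  keep <- hits$align_len >= min_align & hits$evalue < max_evalue
  if (!is.null(classification)) {
    ok <- classification$scaffold_id[classification$label == "true"]
    keep <- keep & hits$scaffold_id %in% ok
  }
  hits[keep, , drop = FALSE]
}

#' Keep the longest SSU gene per scaffold
#'
#' When a scaffold carries more than one SSU hit, only the hit with maximal
#' `gene_len` is retained; exact length ties resolve to the lexicographically
#' first `hit_id` for determinism.
#'
#' @param hits SSU hit table (see [filter_ssu_hits()]).
#' @return Hit table with at most one row per scaffold, ordered as the
#'   retained rows appeared in the input.
#' @export
dedupe_per_scaffold <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  ord <- order(hits$scaffold_id, -hits$gene_len, hits$hit_id)
  sorted <- hits[ord, , drop = FALSE]
  best <- sorted[!duplicated(sorted$scaffold_id), , drop = FALSE]
  out <- hits[sort(match(rownames(best), rownames(hits))), , drop = FALSE]
  out
}

#' SSU-based taxon relative abundances for one sample
#'
#' Per SSU-bearing scaffold i with per-sample mean depth cov_i and length
#' L_i, the mapped read count is reconstructed as `cov_i * L_i / read_len`,
#' normalized to RPKM (reads per kb of scaffold per million mapped reads of
#' the sample), then to relative abundance across the sample's SSU-bearing
#' scaffolds:
#' \deqn{RPKM_i = reads_i / (L_i/10^3 \times N/10^6), \quad
#'       p_i = RPKM_i / \sum_j RPKM_j.}
#' Each abundance is assigned to the hit's lineage.
#'
#' @param hits Filtered, deduplicated SSU hit table.
#' @param scaffolds Scaffold table with `scaffold_id`, `length`.
#' @param sample_coverage Long coverage table (`scaffold_id`, `sample_id`,
#'   `depth`).
#' @param sample_id Sample to profile.
#' @param total_reads Total mapped reads in the sample; reconstructed from
#'   coverage over all scaffolds when `NULL`.
#' @param read_len Nominal read length in bp (default 250).
#' @return Object of class `taxon_profile`: data frame `lineage`, `domain`,
#'   `scaffold_id`, `abundance`, with attributes `sample_id` and `rank`
#'   (`"lineage"` until aggregated).
#' @export
ssu_relative_abundance <- function(hits, scaffolds, sample_coverage, sample_id,
                                   total_reads = NULL, read_len = 250) {
  sc <- sample_coverage[sample_coverage$sample_id == sample_id, , drop = FALSE]
  if (is.null(total_reads)) {
    len_all <- scaffolds$length[match(sc$scaffold_id, scaffolds$scaffold_id)]
    total_reads <- sum(ko_read_count(sc$depth, len_all, read_len))
  }
  h <- hits[hits$scaffold_id %in% sc$scaffold_id, , drop = FALSE]
  len <- scaffolds$length[match(h$scaffold_id, scaffolds$scaffold_id)]
  depth <- sc$depth[match(h$scaffold_id, sc$scaffold_id)]
  reads <- ko_read_count(depth, len, read_len)
  if (nrow(h) > 0 && (total_reads == 0 || sum(reads) == 0)) {
    stop("all SSU-bearing scaffolds have zero coverage in sample ", sample_id)
  }
  rpkm <- reads / ((len / 1e3) * (total_reads / 1e6))
  prof <- data.frame(
    lineage = h$lineage, domain = h$domain, scaffold_id = h$scaffold_id,
    abundance = if (nrow(h) == 0) numeric(0) else rpkm / sum(rpkm),
    stringsAsFactors = FALSE
  )
  structure(prof, class = c("taxon_profile", "data.frame"),
            sample_id = sample_id, rank = "lineage")
}

#' Taxonomic ranks recognized by [aggregate_by_rank()]
#' @format Character vector, highest to lowest rank.
#' @export
taxon_ranks <- c("domain", "phylum", "class", "order", "family", "genus")

# taxon name at a rank from a semicolon-separated lineage path
lineage_at_rank <- function(lineage, rank) {
  depth <- match(rank, taxon_ranks)
  if (is.na(depth)) stop("unknown rank: ", rank)
  parts <- strsplit(lineage, ";", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) >= depth) trimws(p[depth]) else "unclassified"
  }, character(1))
}

#' Aggregate a taxon profile to a taxonomic rank
#'
#' Sums relative abundances within each taxon at the requested rank; lineages
#' not reaching the rank pool into `"unclassified"`. With
#' `split_proteobacteria = TRUE` and `rank = "phylum"`, Proteobacteria are
#' reported at class level instead (the usual convention for community
#' barplots), leaving all other phyla intact; the total is preserved exactly.
#'
#' @param profile A `taxon_profile` from [ssu_relative_abundance()].
#' @param rank One of [taxon_ranks] (domain ... genus).
#' @param split_proteobacteria Report Proteobacteria classes at phylum rank.
#' @return A `taxon_profile` data frame: `taxon`, `abundance`, attributes
#'   `sample_id` and `rank`.
#' @export
aggregate_by_rank <- function(profile, rank, split_proteobacteria = FALSE) {
  if (!rank %in% taxon_ranks) stop("unknown rank: ", rank)
  taxon <- lineage_at_rank(profile$lineage, rank)
  if (split_proteobacteria && rank == "phylum") {
    is_proteo <- taxon == "Proteobacteria"
    taxon[is_proteo] <- lineage_at_rank(profile$lineage[is_proteo], "class")
  }
  agg <- tapply(profile$abundance, taxon, sum)
  out <- data.frame(taxon = names(agg), abundance = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$abundance, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("taxon_profile", "data.frame"),
            sample_id = attr(profile, "sample_id"), rank = rank)
}
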