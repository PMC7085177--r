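#' Estimate reads mapped to a region from mean depth
#'
#' `reads = depth * length / read_length`: the depth-length product is total
#' sequenced bases over the region, divided by bases per read. Used both to
#' reconstruct per-KO read counts from host-scaffold coverage and to rebuild
#' per-scaffold read counts for RPKM normalization.
#'
#' @param cov Mean fold coverage (vectorized).
#' @param scaffold_len Host scaffold length in bp.
#' @param read_len Nominal read length in bp (default 250).
#' @return Estimated read count(s).
#' @export
ko_read_count <- function(cov, scaffold_len, read_len = 250) {
  if (any(read_len <= 0)) stop("read length must be positive")
  if (any(scaffold_len <= 0)) stop("scaffold length must be positive")
  if (any(cov < 0)) stop("coverage must be >= 0")
  cov * scaffold_len / read_len
}

#' Retain KOs by per-sample coverage and within-system recurrence
#'
#' A (sample, KO) pair is retained iff the KO lies on at least one scaffold
#' with strictly greater than `min_cov` fold coverage in that sample, and the
#' KO passes that criterion in at least `min_samples` samples of the same
#' drinking water system. Exactly 1.0x coverage does not qualify, and a KO
#' seen in a single sample of a system is dropped everywhere in that system.
#'
#' @param annotations Data frame: `orf_id`, `scaffold_id`, `ko_id`.
#' @param sample_coverage Long coverage table: `scaffold_id`, `sample_id`,
#'   `depth`.
#' @param samples Sample metadata: `sample_id`, `system_id`.
#' @param min_cov Coverage threshold, strict (default 1).
#' @param min_samples Minimum samples per system in which the KO must be
#'   detected (default 2, i.e., "more than once").
#' @return Data frame of retained pairs: `sample_id`, `ko_id`.
#' @export
filter_kos <- function(annotations, sample_coverage, samples,
                       min_cov = 1, min_samples = 2) {
  stopifnot(all(c("scaffold_id", "ko_id") %in% names(annotations)))
  cov_ok <- sample_coverage[sample_coverage$depth > min_cov,
                            c("scaffold_id", "sample_id")]
  hits <- merge(unique(annotations[, c("scaffold_id", "ko_id")]), cov_ok,
                by = "scaffold_id")
  det <- unique(hits[, c("sample_id", "ko_id")])
  if (nrow(det) == 0) {
    return(data.frame(sample_id = character(), ko_id = character(),
                      stringsAsFactors = FALSE))
  }
  det$system_id <- samples$system_id[match(det$sample_id, samples$sample_id)]
  key <- paste(det$system_id, det$ko_id)
  counts <- table(key)
  det <- det[counts[key] >= min_samples, c("sample_id", "ko_id")]
  det <- det[order(det$sample_id, det$ko_id), , drop = FALSE]
  rownames(det) <- NULL
  det
}

#' Per-sample KO abundance table
#'
#' Sums [ko_read_count()] over every scaffold carrying each retained KO in
#' each sample, and reports an RPKM-normalized abundance alongside
#' (`reads / (scaffold kb * total mapped reads in millions)`, summed over
#' host scaffolds).
#'
#' @param annotations Data frame: `orf_id`, `scaffold_id`, `ko_id`.
#' @param scaffolds Scaffold table with `scaffold_id`, `length`.
#' @param sample_coverage Long coverage table: `scaffold_id`, `sample_id`,
#'   `depth`.
#' @param retained Retained (sample, ko) pairs from [filter_kos()]; `NULL`
#'   keeps everything.
#' @param total_reads Named vector of total mapped reads per sample (for
#'   RPKM); reconstructed from coverage when `NULL`.
#' @param read_len Nominal read length in bp.
#' @return Data frame: `sample_id`, `ko_id`, `reads`, `rpkm`.
#' @export
ko_abundance <- function(annotations, scaffolds, sample_coverage,
                         retained = NULL, total_reads = NULL, read_len = 250) {
  ann <- unique(annotations[, c("scaffold_id", "ko_id")])
  cov <- sample_coverage[sample_coverage$depth > 0, , drop = FALSE]
  m <- merge(ann, cov[, c("scaffold_id", "sample_id", "depth")], by = "scaffold_id")
  if (nrow(m) == 0) {
    return(data.frame(sample_id = character(), ko_id = character(),
                      reads = numeric(), rpkm = numeric(), stringsAsFactors = FALSE))
  }
  m$length <- scaffolds$length[match(m$scaffold_id, scaffolds$scaffold_id)]
  m$reads <- ko_read_count(m$depth, m$length, read_len)

  if (is.null(total_reads)) {
    sc_all <- merge(sample_coverage, scaffolds[, c("scaffold_id", "length")],
                    by = "scaffold_id")
    tot <- tapply(ko_read_count(sc_all$depth, sc_all$length, read_len),
                  sc_all$sample_id, sum)
    total_reads <- as.numeric(tot)
    names(total_reads) <- names(tot)
  }
  m$rpkm_part <- m$reads / ((m$length / 1e3) *
                              (total_reads[m$sample_id] / 1e6))

  agg <- stats::aggregate(cbind(reads, rpkm_part) ~ sample_id + ko_id,
                          data = m, FUN = sum)
  names(agg)[names(agg) == "rpkm_part"] <- "rpkm"
  if (!is.null(retained)) {
    keep <- paste(agg$sample_id, agg$ko_id) %in%
      paste(retained$sample_id, retained$ko_id)
    agg <- agg[keep, , drop = FALSE]
  }
  agg <- agg[order(agg$sample_id, agg$ko_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Samples x KO abundance matrix
#'
#' @param ko_abund Output of [ko_abundance()].
#' @param value `"rpkm"` (default) or `"reads"`.
#' @return Numeric matrix, samples in rows, KOs in columns, zeros for
#'   non-retained pairs.
#' @export
ko_matrix <- function(ko_abund, value = c("rpkm", "reads")) {
  value <- match.arg(value)
  samples <- sort(unique(ko_abund$sample_id))
  kos <- sort(unique(ko_abund$ko_id))
  m <- matrix(0, length(samples), length(kos), dimnames = list(samples, kos))
  m[cbind(match(ko_abund$sample_id, samples), match(ko_abund$ko_id, kos))] <-
    ko_abund[[value]]
  m
}

#' Parse a KEGG-module definition catalog
#'
#' One module per line, `module_id TAB definition`. Definitions use the
#' standard KEGG DEFINITION grammar restricted to one level of nesting:
#' space-separated blocks (reaction steps, AND across blocks), comma-separated
#' alternatives within a block (OR), and `+`-joined KOs forming a complex
#' (AND within an alternative). Example: `K00001 (K00002,K00003+K00004)`.
#'
#' @param path File path, or `text` lines via the `text` argument.
#' @param text Optional character vector of lines instead of a file.
#' @return Named list (`module_catalog`): per module a list of blocks, each
#'   block a list of character vectors (each vector one alternative, its
#'   elements the complex subunits).
#' @export
read_module_catalog <- function(path = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(path) else text
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  bad <- lengths(parts) != 2
  if (any(bad)) stop("malformed catalog line(s): ", paste(which(bad), collapse = ", "))
  ids <- vapply(parts, `[[`, character(1), 1)
  defs <- vapply(parts, `[[`, character(1), 2)
  catalog <- lapply(defs, parse_module_definition)
  names(catalog) <- ids
  structure(catalog, class = "module_catalog")
}

# split a definition string on `sep` at paren depth 0
split_top_level <- function(x, sep) {
  chars <- strsplit(x, "")[[1]]
  depth <- 0
  cuts <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1
    else if (chars[i] == ")") depth <- depth - 1
    else if (chars[i] == sep && depth == 0) cuts <- c(cuts, i)
    if (depth < 0) stop("unbalanced parentheses in module definition: ", x)
  }
  if (depth != 0) stop("unbalanced parentheses in module definition: ", x)
  starts <- c(1, cuts + 1)
  ends <- c(cuts - 1, length(chars))
  pieces <- substring(x, starts, ends)
  pieces[nzchar(trimws(pieces))]
}

#' Parse one KEGG-module definition string
#'
#' @param def Definition string (see [read_module_catalog()]).
#' @return List of blocks; each block a list of character vectors
#'   (alternatives; vector elements are complex subunits, AND semantics).
#' @export
parse_module_definition <- function(def) {
  def <- trimws(def)
  if (!nzchar(def)) stop("empty module definition")
  blocks <- split_top_level(def, " ")
  out <- lapply(blocks, function(b) {
    b <- trimws(b)
    if (startsWith(b, "(") && endsWith(b, ")")) b <- substr(b, 2, nchar(b) - 1)
    alts <- split_top_level(b, ",")
    if (length(alts) == 0) stop("empty block in module definition")
    lapply(alts, function(a) {
      kos <- trimws(strsplit(trimws(a), "+", fixed = TRUE)[[1]])
      kos <- kos[nzchar(kos)]
      if (length(kos) == 0) stop("empty alternative in module definition")
      kos
    })
  })
  if (length(out) == 0) stop("module definition has no blocks")
  out
}

#' KEGG-module completeness for a set of present KOs
#'
#' A block is complete iff at least one of its alternatives is fully present
#' (a complex alternative requires all its subunits). Completeness is the
#' fraction of complete blocks.
#'
#' @param module One entry of a `module_catalog` (list of blocks), or a
#'   definition string.
#' @param present_kos Character vector of KO ids present (detected).
#' @return List: `completeness` in `[0, 1]`, `missing_blocks`,
#'   `total_blocks`.
#' @export
module_completeness <- function(module, present_kos) {
  if (is.character(module) && length(module) == 1) {
    module <- parse_module_definition(module)
  }
  ok <- vapply(module, function(block) {
    any(vapply(block, function(alt) all(alt %in% present_kos), logical(1)))
  }, logical(1))
  list(
    completeness = mean(ok),
    missing_blocks = sum(!ok),
    total_blocks = length(ok)
  )
}

# all KOs referenced anywhere in a module definition
module_kos <- function(module) unique(unlist(module))

#' Median-based module abundance in one sample
#'
#' The abundance of a module is the median abundance of its detected member
#' KOs (those present in the retained KO set for the sample). Even counts
#' take the mean of the two central values. A module with no detected member
#' KOs has abundance 0 and `detected = FALSE`.
#'
#' @param module One `module_catalog` entry (or definition string).
#' @param ko_abund Named numeric vector: KO id -> abundance in this sample
#'   (only retained/detected KOs should be present).
#' @return List: `abundance`, `n_detected`, `detected`.
#' @export
module_abundance <- function(module, ko_abund) {
  if (is.character(module) && length(module) == 1) {
    module <- parse_module_definition(module)
  }
  kos <- intersect(module_kos(module), names(ko_abund))
  if (length(kos) == 0) {
    return(list(abundance = 0, n_detected = 0L, detected = FALSE))
  }
  list(abundance = stats::median(ko_abund[kos]), n_detected = length(kos),
       detected = TRUE)
}

#' Per-sample module profiles over a catalog
#'
#' @param catalog A `module_catalog`.
#' @param ko_abund Output of [ko_abundance()] (already filtered).
#' @param value Abundance column to aggregate (`"reads"` default, the median
#'   scaffold-length normalized read count fed to differential testing, or
#'   `"rpkm"`).
#' @return Data frame: `sample_id`, `module_id`, `abundance`, `n_detected`,
#'   `detected`, `completeness`, `missing_blocks`, `total_blocks`.
#'   Completeness is evaluated against the KOs detected in that sample.
#' @export
module_profiles <- function(catalog, ko_abund, value = c("reads", "rpkm")) {
  value <- match.arg(value)
  stopifnot(inherits(catalog, "module_catalog"))
  samples <- sort(unique(ko_abund$sample_id))
  rows <- lapply(samples, function(s) {
    sub <- ko_abund[ko_abund$sample_id == s, , drop = FALSE]
    abund <- stats::setNames(sub[[value]], sub$ko_id)
    per_mod <- lapply(names(catalog), function(mid) {
      comp <- module_completeness(catalog[[mid]], names(abund))
      ab <- module_abundance(catalog[[mid]], abund)
      data.frame(sample_id = s, module_id = mid, abundance = ab$abundance,
                 n_detected = ab$n_detected, detected = ab$detected,
                 completeness = comp$completeness,
                 missing_blocks = comp$missing_blocks,
                 total_blocks = comp$total_blocks, stringsAsFactors = FALSE)
    })
    do.call(rbind, per_mod)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter module profiles by completeness
#'
#' Retains modules with at most `max_missing` blocks missing AND completeness
#' greater than or equal to `min_completeness` — both bounds inclusive, so a
#' two-block module with one block missing (completeness exactly 0.5)
#' survives. The filter is applied module-wide: a module is kept if any
#' sample's profile passes.
#'
#' @param profiles Output of [module_profiles()].
#' @param max_missing Maximum missing blocks (default 1).
#' @param min_completeness Minimum completeness fraction (default 0.5).
#' @return Filtered profiles (all samples of every passing module).
#' @export
filter_modules <- function(profiles, max_missing = 1, min_completeness = 0.5) {
  pass <- profiles$missing_blocks <= max_missing &
    profiles$completeness >= min_completeness
  keep_modules <- unique(profiles$module_id[pass])
  out <- profiles[profiles$module_id %in% keep_modules, , drop = FALSE]
  rownames(out) <- NULL
  out
}
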