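# TSV/FASTA serialization of synthetic studies. All tables are plain
# tab-separated text with named header columns; the manifest is a flat
# key=value file listing every emitted file and its row (or sequence) count.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  nrow(df)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

matrix_to_long <- function(m, value_name) {
  if (nrow(m) == 0) {
    return(stats::setNames(
      data.frame(character(), character(), numeric(), stringsAsFactors = FALSE),
      c("mag_id", "sample_id", value_name)))
  }
  out <- data.frame(
    mag_id = rep(rownames(m), ncol(m)),
    sample_id = rep(colnames(m), each = nrow(m)),
    value = as.vector(m),
    stringsAsFactors = FALSE
  )
  names(out)[3] <- value_name
  out
}

long_to_matrix <- function(df, value_name, sample_ids) {
  mags <- unique(df$mag_id)
  m <- matrix(0, length(mags), length(sample_ids),
              dimnames = list(mags, sample_ids))
  if (nrow(df) > 0) {
    m[cbind(match(df$mag_id, mags), match(df$sample_id, sample_ids))] <-
      df[[value_name]]
  }
  m
}

#' Write a synthetic study to a directory
#'
#' Emits one TSV per table, the module catalog as `id TAB definition` lines,
#' taxon reference sequences and (optionally) per-sample fragment sets as
#' FASTA, ground truth as a separate `truth.tsv`, and a `manifest.txt` of
#' `file=row_count` entries. The written tables round-trip through
#' [read_study()].
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if missing).
#' @param write_fasta Also write per-sample fragment FASTA files (default
#'   `FALSE`; reference sequences are always written).
#' @param n_fragments,frag_len Passed to [generate_sample_sequences()] when
#'   `write_fasta = TRUE`.
#' @return Invisibly, the manifest as a named integer vector.
#' @export
write_study <- function(study, dir, write_fasta = FALSE,
                        n_fragments = 200, frag_len = 150) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- c(
    samples.tsv = write_tsv(study$samples, file.path(dir, "samples.tsv")),
    controls.tsv = write_tsv(study$controls, file.path(dir, "controls.tsv")),
    scaffolds.tsv = write_tsv(study$scaffolds, file.path(dir, "scaffolds.tsv")),
    sample_coverage.tsv = write_tsv(study$sample_coverage,
                                    file.path(dir, "sample_coverage.tsv")),
    control_coverage.tsv = write_tsv(study$control_coverage,
                                     file.path(dir, "control_coverage.tsv")),
    ssu_hits.tsv = write_tsv(study$ssu_hits, file.path(dir, "ssu_hits.tsv")),
    ko_annotations.tsv = write_tsv(study$ko_annotations,
                                   file.path(dir, "ko_annotations.tsv"))
  )

  writeLines(study$module_definitions, file.path(dir, "modules.tsv"))
  manifest["modules.tsv"] <- length(study$module_definitions)

  env <- cbind(sample_id = rownames(study$env_table), study$env_table)
  manifest["env.tsv"] <- write_tsv(env, file.path(dir, "env.tsv"))

  if (!is.null(study$mags)) {
    manifest["mags.tsv"] <- write_tsv(study$mags, file.path(dir, "mags.tsv"))
    manifest["mag_members.tsv"] <-
      write_tsv(study$mag_members, file.path(dir, "mag_members.tsv"))
    manifest["mag_breadth.tsv"] <- write_tsv(
      matrix_to_long(study$mag_breadth, "breadth"),
      file.path(dir, "mag_breadth.tsv"))
    manifest["mag_reads.tsv"] <- write_tsv(
      matrix_to_long(study$mag_reads, "reads"),
      file.path(dir, "mag_reads.tsv"))
  }

  truth_part <- function(entity, id, value, detail = rep("", length(id))) {
    data.frame(entity = rep(entity, length(id)), id = id,
               value = as.character(value), detail = as.character(detail),
               stringsAsFactors = FALSE)
  }
  truth <- rbind(
    truth_part("scaffold", study$truth$scaffolds$scaffold_id,
               study$truth$scaffolds$contaminant),
    truth_part("taxon", study$truth$taxa$taxon, study$truth$taxa$response,
               study$truth$taxa$is_mag),
    truth_part("mag", study$truth$mags$mag_id, study$truth$mags$category,
               study$truth$mags$taxon),
    truth_part("module", study$truth$modules$module_id,
               study$truth$modules$group)
  )
  manifest["truth.tsv"] <- write_tsv(truth, file.path(dir, "truth.tsv"))

  refs <- Biostrings::DNAStringSet(study$taxon_refs)
  Biostrings::writeXStringSet(refs, file.path(dir, "taxon_refs.fasta"))
  manifest["taxon_refs.fasta"] <- length(refs)

  if (write_fasta) {
    for (i in seq_len(nrow(study$samples))) {
      sid <- study$samples$sample_id[i]
      frags <- generate_sample_sequences(study, sid, n_fragments, frag_len,
                                         seed = study$config$seed + i)
      fn <- paste0("reads_", sid, ".fasta")
      if (length(frags) > 0) {
        names(frags) <- sprintf("%s_frag%05d", sid, seq_along(frags))
        Biostrings::writeXStringSet(Biostrings::DNAStringSet(frags),
                                    file.path(dir, fn))
      } else {
        file.create(file.path(dir, fn))
      }
      manifest[fn] <- length(frags)
    }
  }

  writeLines(paste0(names(manifest), "=", manifest),
             file.path(dir, "manifest.txt"))
  invisible(manifest)
}

#' Read a study back from a directory
#'
#' Reconstructs the tables written by [write_study()]. The generator
#' configuration is not serialized; the returned object carries the tables,
#' matrices, module catalog, reference sequences, and (if `truth.tsv` is
#' present) the ground-truth labels.
#'
#' @param dir Directory written by [write_study()].
#' @return A `synthetic_study` (with `config = NULL`).
#' @export
read_study <- function(dir) {
  samples <- read_tsv(file.path(dir, "samples.tsv"))
  env <- read_tsv(file.path(dir, "env.tsv"))
  env_table <- env[, setdiff(names(env), "sample_id"), drop = FALSE]
  rownames(env_table) <- env$sample_id

  module_definitions <- readLines(file.path(dir, "modules.tsv"))
  catalog <- if (length(module_definitions) > 0) {
    read_module_catalog(text = module_definitions)
  } else structure(list(), class = "module_catalog")

  mags <- mag_members <- NULL
  mag_breadth <- matrix(numeric(0), 0, nrow(samples),
                        dimnames = list(NULL, samples$sample_id))
  mag_reads <- mag_breadth
  if (file.exists(file.path(dir, "mags.tsv"))) {
    mags <- read_tsv(file.path(dir, "mags.tsv"))
    mag_members <- read_tsv(file.path(dir, "mag_members.tsv"))
    mag_breadth <- long_to_matrix(read_tsv(file.path(dir, "mag_breadth.tsv")),
                                  "breadth", samples$sample_id)
    mag_reads <- long_to_matrix(read_tsv(file.path(dir, "mag_reads.tsv")),
                                "reads", samples$sample_id)
  }

  truth <- NULL
  if (file.exists(file.path(dir, "truth.tsv"))) {
    tr <- read_tsv(file.path(dir, "truth.tsv"))
    tr$id <- as.character(tr$id)
    truth <- list(
      scaffolds = with(tr[tr$entity == "scaffold", ],
        data.frame(scaffold_id = id, contaminant = as.logical(value),
                   stringsAsFactors = FALSE)),
      taxa = with(tr[tr$entity == "taxon", ],
        data.frame(taxon = id, response = value, is_mag = as.logical(detail),
                   stringsAsFactors = FALSE)),
      mags = with(tr[tr$entity == "mag", ],
        data.frame(mag_id = id, taxon = detail, category = value,
                   stringsAsFactors = FALSE)),
      modules = with(tr[tr$entity == "module", ],
        data.frame(module_id = id, group = value, stringsAsFactors = FALSE))
    )
  }

  refs_path <- file.path(dir, "taxon_refs.fasta")
  taxon_refs <- character(0)
  if (file.exists(refs_path)) {
    refs <- Biostrings::readDNAStringSet(refs_path)
    taxon_refs <- stats::setNames(as.character(refs), names(refs))
  }

  structure(
    list(config = NULL, samples = samples,
         controls = read_tsv(file.path(dir, "controls.tsv")),
         scaffolds = read_tsv(file.path(dir, "scaffolds.tsv")),
         sample_coverage = read_tsv(file.path(dir, "sample_coverage.tsv")),
         control_coverage = read_tsv(file.path(dir, "control_coverage.tsv")),
         ssu_hits = read_tsv(file.path(dir, "ssu_hits.tsv")),
         ko_annotations = read_tsv(file.path(dir, "ko_annotations.tsv")),
         module_catalog = catalog, module_definitions = module_definitions,
         mags = mags, mag_members = mag_members,
         mag_breadth = mag_breadth, mag_reads = mag_reads,
         env_table = env_table, taxon_abundance = NULL,
         taxon_refs = taxon_refs, truth = truth),
    class = "synthetic_study"
  )
}
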