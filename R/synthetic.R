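# Synthetic drinking-water study generator.
#
# Emulates the tables an assembly-and-mapping workflow would produce for a
# two-country survey of chlorinated (D) and non-chlorinated (ND) distribution
# systems: per-system co-assembled scaffolds with per-sample coverage,
# negative-control coverage carrying kit/handling contaminants, SSU rRNA
# hits, ORF -> KO annotations with a KEGG-style module catalog, MAGs with
# per-sample breadth, water chemistry, and per-taxon reference sequences for
# sketching. Ground truth (which scaffolds are contaminants, which taxa and
# modules respond to chlorine, each MAG's intended detection category) is
# carried alongside so every downstream stage can be scored.

child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483647)
}

default_env_vars <- function() {
  list(
    temperature = list(mean = c(D = 17, ND = 12), sd = c(D = 2, ND = 2)),
    ph = list(mean = c(D = 7.8, ND = 7.9), sd = c(D = 0.2, ND = 0.2)),
    conductivity = list(mean = c(D = 450, ND = 400), sd = c(D = 80, ND = 80)),
    do_mgl = list(mean = c(D = 8, ND = 8), sd = c(D = 1, ND = 1)),
    chlorine = list(mean = c(D = 0.37, ND = 0), sd = c(D = 0.12, ND = 0)),
    phosphate = list(mean = c(D = 2.3, ND = 0), sd = c(D = 0.8, ND = 0)),
    toc = list(mean = c(D = 2, ND = 2), sd = c(D = 0.5, ND = 0.5)),
    ammonium = list(mean = c(D = 0.05, ND = 0.05), sd = c(D = 0.02, ND = 0.02)),
    nitrate = list(mean = c(D = 1.5, ND = 1.5), sd = c(D = 0.5, ND = 0.5))
  )
}

#' Configuration for a synthetic drinking-water study
#'
#' Defaults reproduce the surveyed design: 7 disinfected and 5 non-disinfected
#' systems sampled at 3 locations each, 2 x 250 bp sequencing, chlorine
#' averaging 0.37 mg/l in disinfected systems and exactly 0 where no residual
#' is maintained, phosphate dosed only in disinfected systems, and a larger
#' taxon-abundance dispersion in non-disinfected systems (the more variable
#' communities seen without a residual). Community structure is driven
#' mechanistically by the chlorine dose: chlorine-favoured taxa rise and
#' chlorine-sensitive taxa fall log-linearly with a sample's measured
#' chlorine.
#'
#' @param n_systems_d,n_systems_nd Number of disinfected / non-disinfected
#'   systems (each a separate co-assembly).
#' @param samples_per_system Sampling locations per system.
#' @param n_taxa Community taxa (includes the MAG-backed taxa).
#' @param n_contaminant_taxa Contaminant taxa present in negative controls.
#' @param scaffolds_per_taxon Scaffolds each taxon contributes per
#'   co-assembly.
#' @param scaffold_len_range Scaffold length range in bp.
#' @param mean_depth Average fold coverage of a typical taxon.
#' @param abundance_dispersion Log-scale SD of per-system taxon abundances,
#'   named `D` and `ND` (larger in ND).
#' @param coverage_noise_sd Log-scale SD of per-scaffold multiplicative
#'   coverage noise; 0 gives noise-free coverage.
#' @param group_effect Log-scale abundance shift per unit chlorine dose for
#'   chlorine-responsive taxa; 0 removes planted group structure.
#' @param frac_group_taxa Fraction of (non-MAG) community taxa that respond
#'   to chlorine, split evenly between favoured and sensitive.
#' @param n_kos,n_modules,kos_per_taxon KEGG orthology pool size, module
#'   count, and KOs per taxon genome.
#' @param read_length Nominal read length in bp.
#' @param reads_per_sample Total read count per sample (for percent-mapped
#'   accounting).
#' @param n_controls Negative controls (reagent/filter blanks).
#' @param contaminant_leak_rate Probability a contaminant taxon leaks
#'   coverage into a true sample; 0 is pure-contaminant mode.
#' @param n_mags MAG-backed taxa; intended detection categories cycle
#'   through D-only, ND-only, both, other.
#' @param ref_len Per-taxon reference sequence length in bp (for sketching).
#' @param ref_gc Reference GC fraction.
#' @param env_vars Named list of environmental variables, each
#'   `list(mean = c(D=, ND=), sd = c(D=, ND=))`. Chlorine must be exactly 0
#'   in ND (no measurable residual).
#' @param seed Root seed; per-table child streams are derived by fixed
#'   offsets so adding one table never perturbs another.
#' @return Object of class `study_config`.
#' @export
study_config <- function(n_systems_d = 7, n_systems_nd = 5,
                         samples_per_system = 3,
                         n_taxa = 30, n_contaminant_taxa = 4,
                         scaffolds_per_taxon = 8,
                         scaffold_len_range = c(1000, 20000),
                         mean_depth = 10,
                         abundance_dispersion = c(D = 0.7, ND = 1.2),
                         coverage_noise_sd = 0.3,
                         group_effect = 1.5,
                         frac_group_taxa = 0.4,
                         n_kos = 120, n_modules = 12, kos_per_taxon = 25,
                         read_length = 250, reads_per_sample = 2e6,
                         n_controls = 2,
                         contaminant_leak_rate = 0,
                         n_mags = 8,
                         ref_len = 1500, ref_gc = 0.5,
                         env_vars = default_env_vars(),
                         seed = 1) {
  cfg <- list(
    n_systems_d = n_systems_d, n_systems_nd = n_systems_nd,
    samples_per_system = samples_per_system,
    n_taxa = n_taxa, n_contaminant_taxa = n_contaminant_taxa,
    scaffolds_per_taxon = scaffolds_per_taxon,
    scaffold_len_range = scaffold_len_range,
    mean_depth = mean_depth,
    abundance_dispersion = abundance_dispersion,
    coverage_noise_sd = coverage_noise_sd,
    group_effect = group_effect,
    frac_group_taxa = frac_group_taxa,
    n_kos = n_kos, n_modules = n_modules, kos_per_taxon = kos_per_taxon,
    read_length = read_length, reads_per_sample = reads_per_sample,
    n_controls = n_controls,
    contaminant_leak_rate = contaminant_leak_rate,
    n_mags = n_mags,
    ref_len = ref_len, ref_gc = ref_gc,
    env_vars = env_vars,
    seed = seed
  )
  counts <- c("n_systems_d", "n_systems_nd", "samples_per_system", "n_taxa",
              "scaffolds_per_taxon", "n_kos", "n_modules", "kos_per_taxon",
              "read_length", "reads_per_sample", "n_controls", "ref_len")
  for (f in counts) {
    if (length(cfg[[f]]) != 1 || cfg[[f]] <= 0) stop(f, " must be a positive count")
  }
  if (cfg$n_contaminant_taxa < 0 || cfg$n_mags < 0) {
    stop("n_contaminant_taxa and n_mags must be >= 0")
  }
  if (cfg$n_mags > cfg$n_taxa) stop("n_mags cannot exceed n_taxa")
  if (cfg$contaminant_leak_rate < 0 || cfg$contaminant_leak_rate > 1) {
    stop("contaminant_leak_rate must be in [0, 1]")
  }
  if (!all(c("D", "ND") %in% names(cfg$abundance_dispersion))) {
    stop("abundance_dispersion needs named D and ND entries")
  }
  if ("chlorine" %in% names(cfg$env_vars)) {
    chl <- cfg$env_vars$chlorine
    if (chl$mean[["ND"]] != 0 || chl$sd[["ND"]] != 0) {
      stop("chlorine must be exactly 0 in non-disinfected systems")
    }
  }
  structure(cfg, class = "study_config")
}

# small bacterial/eukaryotic taxonomy pool for synthetic lineages
phylum_pool <- function() {
  list(
    list(domain = "bacteria", phylum = "Proteobacteria",
         classes = c("Alphaproteobacteria", "Betaproteobacteria",
                     "Gammaproteobacteria")),
    list(domain = "bacteria", phylum = "Actinobacteriota", classes = "Actinomycetia"),
    list(domain = "bacteria", phylum = "Bacteroidota", classes = "Bacteroidia"),
    list(domain = "bacteria", phylum = "Planctomycetota", classes = "Planctomycetia"),
    list(domain = "bacteria", phylum = "Nitrospirota", classes = "Nitrospiria"),
    list(domain = "bacteria", phylum = "Patescibacteria", classes = "Paceibacteria"),
    list(domain = "bacteria", phylum = "Acidobacteriota", classes = "Blastocatellia"),
    list(domain = "bacteria", phylum = "Verrucomicrobiota", classes = "Verrucomicrobiae"),
    list(domain = "archaea", phylum = "Thermoproteota", classes = "Nitrososphaeria"),
    list(domain = "eukaryota", phylum = "Ochrophyta", classes = "Chrysophyceae")
  )
}

make_lineage <- function(entry, cls, taxon) {
  dom <- c(bacteria = "Bacteria", archaea = "Archaea", eukaryota = "Eukaryota")
  paste(dom[[entry$domain]], entry$phylum, cls,
        paste0("Order_", taxon), paste0("Family_", taxon), paste0("Genus_", taxon),
        sep = ";")
}

random_dna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a complete synthetic study
#'
#' Draws taxon abundances log-normally with per-system dispersion and a
#' log-linear chlorine dose response, converts them to per-scaffold coverage
#' with multiplicative noise, plants contaminant taxa whose coverage appears
#' in negative controls (and, in pure-contaminant mode, never in true
#' samples), assigns KOs and modules so that some modules are exclusive to
#' chlorine-favoured or chlorine-sensitive taxa, and gives each MAG-backed
#' taxon a presence mask matching its intended detection category. Identical
#' configs (including seed) produce identical studies.
#'
#' @param config A [study_config()].
#' @return Object of class `synthetic_study`: list with `config`, `samples`,
#'   `controls`, `scaffolds`, `sample_coverage`, `control_coverage`,
#'   `ssu_hits`, `ko_annotations`, `module_catalog`, `module_definitions`,
#'   `mags`, `mag_members`, `mag_breadth`, `mag_reads`, `env_table`,
#'   `taxon_abundance`, `taxon_refs`, and `truth` (per-scaffold contaminant
#'   flags, per-taxon chlorine response, per-MAG intended category,
#'   per-module group association).
#' @export
generate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  cfg <- config
  seed <- cfg$seed

  systems <- data.frame(
    system_id = c(paste0("D", seq_len(cfg$n_systems_d)),
                  paste0("ND", seq_len(cfg$n_systems_nd))),
    group = rep(c("D", "ND"), c(cfg$n_systems_d, cfg$n_systems_nd)),
    stringsAsFactors = FALSE
  )
  samples <- do.call(rbind, lapply(seq_len(nrow(systems)), function(i) {
    data.frame(
      sample_id = sprintf("%s_s%d", systems$system_id[i],
                          seq_len(cfg$samples_per_system)),
      system_id = systems$system_id[i],
      group = systems$group[i],
      total_reads = cfg$reads_per_sample,
      stringsAsFactors = FALSE
    )
  }))
  controls <- data.frame(control_id = paste0("NC", seq_len(cfg$n_controls)),
                         stringsAsFactors = FALSE)

  ## environmental table (drawn before abundances: chlorine drives structure)
  set.seed(child_seed(seed, 11))
  env_table <- as.data.frame(lapply(cfg$env_vars, function(v) {
    vals <- numeric(nrow(samples))
    for (g in c("D", "ND")) {
      idx <- samples$group == g
      if (v$sd[[g]] == 0) {
        vals[idx] <- v$mean[[g]]
      } else {
        vals[idx] <- pmax(0, stats::rnorm(sum(idx), v$mean[[g]], v$sd[[g]]))
      }
    }
    vals
  }))
  rownames(env_table) <- samples$sample_id

  ## taxa: identities, lineages, chlorine response, MAG roles
  set.seed(child_seed(seed, 23))
  comm_taxa <- sprintf("T%02d", seq_len(cfg$n_taxa))
  contam_taxa <- if (cfg$n_contaminant_taxa > 0) {
    sprintf("C%02d", seq_len(cfg$n_contaminant_taxa))
  } else character(0)
  taxa <- c(comm_taxa, contam_taxa)
  pool <- phylum_pool()
  pool_idx <- sample(length(pool), length(taxa), replace = TRUE)
  cls_pick <- vapply(pool_idx, function(i) sample(pool[[i]]$classes, 1), character(1))
  lineage <- vapply(seq_along(taxa), function(i) {
    make_lineage(pool[[pool_idx[i]]], cls_pick[i], taxa[i])
  }, character(1))
  domain <- vapply(pool_idx, function(i) pool[[i]]$domain, character(1))
  taxon_gc <- stats::runif(length(taxa), 0.35, 0.65)

  is_mag <- seq_along(taxa) <= cfg$n_mags
  mag_cats <- if (cfg$n_mags > 0) {
    rep(c("D-only", "ND-only", "both", "other"), length.out = cfg$n_mags)
  } else character(0)

  response <- rep("neutral", length(taxa))
  free <- which(!is_mag & seq_along(taxa) <= cfg$n_taxa)
  n_resp <- round(cfg$frac_group_taxa * length(free))
  n_up <- ceiling(n_resp / 2)
  resp_idx <- if (n_resp > 0) sample(free, n_resp) else integer(0)
  response[resp_idx[seq_len(n_up)]] <- "D"
  if (n_resp > n_up) response[resp_idx[(n_up + 1):n_resp]] <- "ND"
  response[seq_along(taxa) > cfg$n_taxa] <- "contaminant"

  mu <- stats::rnorm(length(taxa), 0, 1)
  mu[is_mag] <- mu[is_mag] / 2 + 0.5  # MAG taxa never vanishingly rare
  beta <- ifelse(response == "D", cfg$group_effect,
                 ifelse(response == "ND", -cfg$group_effect, 0))

  ## chlorine dose per sample, scaled to ~1 at the disinfected average
  chl_ref <- if ("chlorine" %in% names(cfg$env_vars) &&
                 cfg$env_vars$chlorine$mean[["D"]] > 0) {
    cfg$env_vars$chlorine$mean[["D"]]
  } else 1
  dose <- if ("chlorine" %in% colnames(env_table)) {
    env_table$chlorine / chl_ref
  } else as.numeric(samples$group == "D")

  ## MAG presence masks by intended category
  set.seed(child_seed(seed, 29))
  mask <- matrix(1, length(taxa), nrow(samples),
                 dimnames = list(taxa, samples$sample_id))
  d_samples <- samples$sample_id[samples$group == "D"]
  nd_samples <- samples$sample_id[samples$group == "ND"]
  pick <- function(ids, frac) {
    k <- max(ceiling(0.2 * length(ids)), round(frac * length(ids)))
    sample(ids, min(k, length(ids)))
  }
  below_thresh <- function(ids) {
    k <- ceiling(0.2 * length(ids)) - 1  # largest count with frequency < 20%
    if (k < 1) character(0) else sample(ids, k)
  }
  for (m in which(is_mag)) {
    present <- switch(mag_cats[m],
      "D-only" = pick(d_samples, 0.6),
      "ND-only" = pick(nd_samples, 0.6),
      "both" = c(pick(d_samples, 0.6), pick(nd_samples, 0.6)),
      "other" = below_thresh(d_samples)
    )
    mask[m, ] <- as.numeric(samples$sample_id %in% present)
  }

  ## abundances and base coverage per taxon per sample
  set.seed(child_seed(seed, 37))
  disp <- cfg$abundance_dispersion[systems$group]
  eta <- matrix(stats::rnorm(length(taxa) * nrow(systems), 0,
                             rep(disp, each = length(taxa))),
                length(taxa), nrow(systems),
                dimnames = list(taxa, systems$system_id))
  logA <- outer(mu, rep(1, nrow(samples))) +
    outer(beta, dose) + eta[, samples$system_id]
  A <- exp(logA) * mask
  A[response == "contaminant", ] <- 0  # contaminants live in blanks only
  p <- sweep(A, 2, pmax(colSums(A), .Machine$double.xmin), "/")
  cov_base <- p * cfg$n_taxa * cfg$mean_depth
  dimnames(cov_base) <- list(taxa, samples$sample_id)

  ## scaffolds per system co-assembly
  set.seed(child_seed(seed, 41))
  scaffolds <- do.call(rbind, lapply(systems$system_id, function(sy) {
    data.frame(
      scaffold_id = sprintf("%s_%s_c%02d", sy, rep(taxa, each = cfg$scaffolds_per_taxon),
                            seq_len(cfg$scaffolds_per_taxon)),
      system_id = sy,
      taxon = rep(taxa, each = cfg$scaffolds_per_taxon),
      length = round(stats::runif(length(taxa) * cfg$scaffolds_per_taxon,
                                  cfg$scaffold_len_range[1], cfg$scaffold_len_range[2])),
      stringsAsFactors = FALSE
    )
  }))
  scaffolds$gc <- pmin(0.8, pmax(0.2,
    taxon_gc[match(scaffolds$taxon, taxa)] +
      stats::rnorm(nrow(scaffolds), 0, 0.02)))

  ## per-sample coverage of the sample's own co-assembly
  set.seed(child_seed(seed, 53))
  cov_rows <- lapply(seq_len(nrow(samples)), function(si) {
    sy <- samples$system_id[si]
    sc <- scaffolds[scaffolds$system_id == sy, , drop = FALSE]
    base <- cov_base[sc$taxon, si]
    leak <- cfg$contaminant_leak_rate > 0 &
      sc$taxon %in% contam_taxa &
      stats::runif(nrow(sc)) < cfg$contaminant_leak_rate
    base[leak] <- cfg$mean_depth * exp(stats::rnorm(sum(leak), -1, 0.5))
    noise <- if (cfg$coverage_noise_sd > 0) {
      exp(stats::rnorm(nrow(sc), 0, cfg$coverage_noise_sd))
    } else 1
    depth <- base * noise
    keep <- depth > 0
    data.frame(
      scaffold_id = sc$scaffold_id[keep],
      sample_id = samples$sample_id[si],
      depth = depth[keep],
      depth_sd = depth[keep] * stats::runif(sum(keep), 0.2, 0.6),
      mapped_reads = round(depth[keep] * sc$length[keep] / cfg$read_length),
      stringsAsFactors = FALSE
    )
  })
  sample_coverage <- do.call(rbind, cov_rows)

  ## negative-control coverage on contaminant scaffolds
  set.seed(child_seed(seed, 59))
  ctrl_rows <- list()
  if (cfg$n_contaminant_taxa > 0) {
    contam_sc <- scaffolds[scaffolds$taxon %in% contam_taxa, , drop = FALSE]
    contam_level <- matrix(
      exp(stats::rnorm(length(contam_taxa) * cfg$n_controls,
                       log(cfg$mean_depth), 0.5)),
      length(contam_taxa), cfg$n_controls, dimnames = list(contam_taxa, NULL))
    ctrl_rows <- lapply(seq_len(cfg$n_controls), function(ci) {
      noise <- if (cfg$coverage_noise_sd > 0) {
        exp(stats::rnorm(nrow(contam_sc), 0, cfg$coverage_noise_sd))
      } else 1
      depth <- contam_level[contam_sc$taxon, ci] * noise
      data.frame(
        scaffold_id = contam_sc$scaffold_id,
        control_id = controls$control_id[ci],
        contam_depth = depth,
        contam_sd = depth * stats::runif(nrow(contam_sc), 0.2, 0.6),
        total_depth = depth,
        total_sd = depth * stats::runif(nrow(contam_sc), 0.2, 0.6),
        stringsAsFactors = FALSE
      )
    })
  }
  control_coverage <- if (length(ctrl_rows) > 0) {
    do.call(rbind, ctrl_rows)
  } else {
    data.frame(scaffold_id = character(), control_id = character(),
               contam_depth = numeric(), contam_sd = numeric(),
               total_depth = numeric(), total_sd = numeric(),
               stringsAsFactors = FALSE)
  }

  ## SSU rRNA hits: one marker-bearing scaffold per taxon per co-assembly
  set.seed(child_seed(seed, 67))
  ssu_sc <- scaffolds[!duplicated(paste(scaffolds$system_id, scaffolds$taxon)), ,
                      drop = FALSE]
  ssu_hits <- data.frame(
    hit_id = sprintf("ssu%04d", seq_len(nrow(ssu_sc))),
    scaffold_id = ssu_sc$scaffold_id,
    domain = domain[match(ssu_sc$taxon, taxa)],
    lineage = lineage[match(ssu_sc$taxon, taxa)],
    align_len = round(stats::runif(nrow(ssu_sc), 200, 1400)),
    evalue = 10^stats::runif(nrow(ssu_sc), -30, -6),
    gene_len = round(stats::rnorm(nrow(ssu_sc), 1500, 60)),
    stringsAsFactors = FALSE
  )

  ## KO pools and per-taxon genomes
  set.seed(child_seed(seed, 71))
  all_kos <- sprintf("K%05d", seq_len(cfg$n_kos))
  n_grp <- max(1, round(0.2 * cfg$n_kos))
  d_pool <- all_kos[seq_len(n_grp)]
  nd_pool <- all_kos[n_grp + seq_len(n_grp)]
  shared_pool <- all_kos[(2 * n_grp + 1):cfg$n_kos]
  taxon_kos <- lapply(seq_along(taxa), function(i) {
    k <- min(cfg$kos_per_taxon, cfg$n_kos)
    if (response[i] == "D") {
      k_grp <- min(length(d_pool), ceiling(0.4 * k))
      c(sample(d_pool, k_grp), sample(shared_pool, min(k - k_grp, length(shared_pool))))
    } else if (response[i] == "ND") {
      k_grp <- min(length(nd_pool), ceiling(0.4 * k))
      c(sample(nd_pool, k_grp), sample(shared_pool, min(k - k_grp, length(shared_pool))))
    } else {
      sample(shared_pool, min(k, length(shared_pool)))
    }
  })
  names(taxon_kos) <- taxa

  ko_rows <- lapply(systems$system_id, function(sy) {
    sc <- scaffolds[scaffolds$system_id == sy, , drop = FALSE]
    per_taxon <- lapply(taxa, function(t) {
      kos <- taxon_kos[[t]]
      host <- sample(sc$scaffold_id[sc$taxon == t], length(kos), replace = TRUE)
      data.frame(scaffold_id = host, ko_id = kos, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, per_taxon)
    out$orf_id <- sprintf("%s_orf%05d", sy, seq_len(nrow(out)))
    out[, c("orf_id", "scaffold_id", "ko_id")]
  })
  ko_annotations <- do.call(rbind, ko_rows)

  ## module catalog: some modules exclusive to chlorine-responsive taxa
  set.seed(child_seed(seed, 79))
  n_dm <- max(1, round(0.25 * cfg$n_modules))
  mod_group <- rep("shared", cfg$n_modules)
  mod_group[seq_len(min(n_dm, cfg$n_modules))] <- "D"
  if (cfg$n_modules > n_dm) {
    mod_group[n_dm + seq_len(min(n_dm, cfg$n_modules - n_dm))] <- "ND"
  }
  build_module <- function(pool) {
    nb <- sample(2:4, 1)
    used <- character(0)
    blocks <- vapply(seq_len(nb), function(b) {
      na <- sample(c(1, 1, 2, 3), 1)
      alts <- vapply(seq_len(na), function(a) {
        avail <- setdiff(pool, used)
        if (length(avail) < 2) avail <- pool
        if (stats::runif(1) < 0.2 && length(avail) >= 2) {
          kos <- sample(avail, 2)
        } else {
          kos <- sample(avail, 1)
        }
        used <<- c(used, kos)
        paste(kos, collapse = "+")
      }, character(1))
      if (length(alts) > 1) paste0("(", paste(alts, collapse = ","), ")") else alts
    }, character(1))
    paste(blocks, collapse = " ")
  }
  module_ids <- sprintf("M%05d", seq_len(cfg$n_modules))
  defs <- vapply(seq_len(cfg$n_modules), function(m) {
    pool <- switch(mod_group[m], D = d_pool, ND = nd_pool, shared = shared_pool)
    build_module(pool)
  }, character(1))
  module_definitions <- paste(module_ids, defs, sep = "\t")
  module_catalog <- read_module_catalog(text = module_definitions)

  ## MAGs: one per MAG-backed taxon, members from the first co-assembly
  set.seed(child_seed(seed, 83))
  mags <- NULL; mag_members <- NULL
  mag_breadth <- matrix(numeric(0), 0, nrow(samples),
                        dimnames = list(NULL, samples$sample_id))
  mag_reads <- mag_breadth
  if (cfg$n_mags > 0) {
    rep_sys <- systems$system_id[1]
    mag_taxa <- taxa[is_mag]
    members <- lapply(mag_taxa, function(t) {
      scaffolds$scaffold_id[scaffolds$system_id == rep_sys & scaffolds$taxon == t]
    })
    mag_len <- vapply(members, function(m) {
      sum(scaffolds$length[match(m, scaffolds$scaffold_id)])
    }, numeric(1))
    mags <- data.frame(
      mag_id = sprintf("MAG%03d", seq_len(cfg$n_mags)),
      taxon = mag_taxa,
      length = mag_len,
      completeness = stats::runif(cfg$n_mags, 55, 99),
      redundancy = stats::runif(cfg$n_mags, 0, 9),
      stringsAsFactors = FALSE
    )
    mag_members <- data.frame(
      mag_id = rep(mags$mag_id, lengths(members)),
      scaffold_id = unlist(members),
      stringsAsFactors = FALSE
    )
    cov_mag <- cov_base[mag_taxa, , drop = FALSE]
    mag_breadth <- 1 - exp(-cov_mag)  # Poisson coverage: breadth rises with depth
    mag_reads <- round(cov_mag * mag_len / cfg$read_length)
    dimnames(mag_breadth) <- dimnames(mag_reads) <-
      list(mags$mag_id, samples$sample_id)
  }

  ## per-taxon reference sequences for sketching
  set.seed(child_seed(seed, 89))
  taxon_refs <- vapply(seq_along(taxa), function(i) {
    random_dna(cfg$ref_len, cfg$ref_gc)
  }, character(1))
  names(taxon_refs) <- taxa

  truth <- list(
    scaffolds = data.frame(
      scaffold_id = scaffolds$scaffold_id,
      contaminant = scaffolds$taxon %in% contam_taxa,
      stringsAsFactors = FALSE
    ),
    taxa = data.frame(taxon = taxa, response = response, is_mag = is_mag,
                      stringsAsFactors = FALSE),
    mags = if (cfg$n_mags > 0) {
      data.frame(mag_id = mags$mag_id, taxon = mags$taxon,
                 category = mag_cats, stringsAsFactors = FALSE)
    } else data.frame(mag_id = character(), taxon = character(),
                      category = character(), stringsAsFactors = FALSE),
    modules = data.frame(module_id = module_ids, group = mod_group,
                         stringsAsFactors = FALSE)
  )

  rownames(samples) <- rownames(scaffolds) <- NULL
  if (!is.null(sample_coverage)) rownames(sample_coverage) <- NULL
  structure(
    list(config = cfg, samples = samples, controls = controls,
         scaffolds = scaffolds, sample_coverage = sample_coverage,
         control_coverage = control_coverage, ssu_hits = ssu_hits,
         ko_annotations = ko_annotations, module_catalog = module_catalog,
         module_definitions = module_definitions,
         mags = mags, mag_members = mag_members,
         mag_breadth = mag_breadth, mag_reads = mag_reads,
         env_table = env_table, taxon_abundance = cov_base,
         taxon_refs = taxon_refs, truth = truth),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic study: %d systems (%d D / %d ND), %d samples, %d scaffolds, %d MAGs\n",
    x$config$n_systems_d + x$config$n_systems_nd,
    x$config$n_systems_d, x$config$n_systems_nd,
    nrow(x$samples), nrow(x$scaffolds),
    if (is.null(x$mags)) 0L else nrow(x$mags)))
  invisible(x)
}

#' Sample-to-group and sample-to-system maps
#'
#' @param study A `synthetic_study`.
#' @return Named character vector: sample id -> `"D"`/`"ND"` (or system id).
#' @export
sample_groups <- function(study) {
  stats::setNames(study$samples$group, study$samples$sample_id)
}

#' @rdname sample_groups
#' @export
sample_systems <- function(study) {
  stats::setNames(study$samples$system_id, study$samples$sample_id)
}

#' Draw sequence fragments for one sample
#'
#' Fragments are substrings of the per-taxon reference sequences, drawn in
#' proportion to the sample's taxon abundances; the draw depends only on the
#' abundance vector and the seed, so samples with identical abundances yield
#' identical fragment multisets.
#'
#' @param study A `synthetic_study`.
#' @param sample_id Sample to draw for.
#' @param n_fragments Number of fragments (default 300).
#' @param frag_len Fragment length in bp (default 150; capped at reference
#'   length).
#' @param seed Seed for the draw.
#' @return Character vector of fragment sequences.
#' @export
generate_sample_sequences <- function(study, sample_id, n_fragments = 300,
                                      frag_len = 150, seed = 1) {
  stopifnot(inherits(study, "synthetic_study"))
  if (!sample_id %in% colnames(study$taxon_abundance)) {
    stop("unknown sample id: ", sample_id)
  }
  ab <- stats::setNames(as.numeric(study$taxon_abundance[, sample_id]),
                        rownames(study$taxon_abundance))
  ab <- ab[ab > 0]
  if (length(ab) == 0) return(character(0))
  frag_len <- min(frag_len, study$config$ref_len)
  set.seed(seed)
  counts <- as.vector(stats::rmultinom(1, n_fragments, ab / sum(ab)))
  names(counts) <- names(ab)
  frags <- unlist(lapply(names(counts)[counts > 0], function(t) {
    ref <- study$taxon_refs[[t]]
    starts <- sample.int(nchar(ref) - frag_len + 1, counts[[t]], replace = TRUE)
    substring(ref, starts, starts + frag_len - 1)
  }))
  unname(frags)
}
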