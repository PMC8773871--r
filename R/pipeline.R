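# End-to-end orchestration: simulate (or load) paired-component data, build
# per-component consensus callsets, filter, compare the components, profile
# signatures, derive gene copy-number states and differential promoter
# methylation, and emit one machine-readable report. Reruns with the same
# config produce byte-identical reports.

#' Pipeline configuration
#'
#' @param seed Master seed; reference simulation, mutation simulation and
#'   every stochastic stage derive from it.
#' @param tumour_id Label used in reports.
#' @param sim A [simulation_config()] describing the paired-tumour data to
#'   generate (its own seed is overridden by `seed`).
#' @param n_contigs,contig_length Synthetic reference dimensions.
#' @param filters A [filter_thresholds()].
#' @param relatedness Named cut-points on the SNV overlap coefficient:
#'   at or above `related` the pair is called clonally related, below
#'   `independent` it is called independent, in between indeterminate.
#'   These are heuristics anchored on the observed range of related pairs
#'   (median overlap ~0.6, with related outliers down to ~0.3); they are
#'   reported, not hidden.
#' @param k_max Components considered by the subclone mixture fit.
#' @param write_vcfs When TRUE (default) caller VCFs are written and read
#'   back through the VCF parser, exercising the full IO path; when FALSE
#'   the in-memory callsets feed consensus directly.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            tumour_id = "SIM1",
                            sim = simulation_config(),
                            n_contigs = 5L,
                            contig_length = 200000L,
                            filters = filter_thresholds(),
                            relatedness = c(related = 0.3, independent = 0.1),
                            k_max = 3L,
                            write_vcfs = TRUE) {
  sim$seed <- as.integer(seed)
  stopifnot(relatedness[["independent"]] <= relatedness[["related"]])
  structure(list(
    seed = as.integer(seed), tumour_id = tumour_id, sim = sim,
    n_contigs = as.integer(n_contigs),
    contig_length = as.integer(contig_length),
    filters = filters, relatedness = relatedness,
    k_max = as.integer(k_max), write_vcfs = isTRUE(write_vcfs)
  ), class = "pipeline_config")
}

#' Classify the relatedness of a component pair
#'
#' Rule-based call on the SNV overlap coefficient: `clonally_related` at or
#' above the `related` cut-point, `independent` below the `independent`
#' cut-point, `indeterminate` in between.
#'
#' @param overlap_snv SNV overlap coefficient in `[0, 1]`.
#' @param thresholds Named vector `c(related=, independent=)`.
#' @return One of `"clonally_related"`, `"indeterminate"`, `"independent"`.
#' @export
#' @examples
#' classify_relatedness(0.61) # clonally_related
#' classify_relatedness(0.0)  # independent
classify_relatedness <- function(overlap_snv,
                                 thresholds = c(related = 0.3,
                                                independent = 0.1)) {
  if (overlap_snv >= thresholds[["related"]]) {
    "clonally_related"
  } else if (overlap_snv < thresholds[["independent"]]) {
    "independent"
  } else {
    "indeterminate"
  }
}

#' Run the full paired-component pipeline on simulated data
#'
#' Stages, in dependency order: simulate reference + paired callsets + copy
#' number + methylation; write artifacts; per-component consensus; post hoc
#' filters; shared/private partition and overlap; substitution spectra; SBS
#' profiles, catalogue similarity and clustering; subclone mixture fits;
#' per-gene copy-number states and differential table; probe filtering and
#' differential promoter methylation; relatedness call. Per-stage counts go
#' to the structured log (`message()`), the machine-readable report to
#' `report.json` in `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created). Intermediate TSV/VCF
#'   artifacts and `report.json` are written here; the serialized config
#'   goes alongside as `config.yaml`.
#' @param quiet Suppress per-stage log messages.
#' @return The report, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- function(...) if (!quiet) message("[hetpair] ", ...)
  .write_config_yaml(config, file.path(out_dir, "config.yaml"))
  comp <- c("Neg", "Abr")

  log("simulate: reference (", config$n_contigs, " x ",
      config$contig_length, " bp)")
  reference <- simulate_reference(seed = config$seed,
                                  n_contigs = config$n_contigs,
                                  contig_length = config$contig_length)
  sim <- simulate_mutation_set(config$sim, reference)
  log("simulate: ", nrow(sim$truth), " distinct variants")
  cna <- simulate_cna_segments(config$sim, reference, sim$genes)
  meth <- simulate_methylation(config$sim, sim$genes)
  paths <- write_simulation(sim, out_dir)
  for (cc in comp) {
    utils::write.table(cna[[cc]], file.path(out_dir, paste0(cc, ".segments.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(meth$probes, file.path(out_dir, "probes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  callsets <- if (config$write_vcfs) {
    lapply(stats::setNames(comp, comp), function(cc) {
      lapply(stats::setNames(names(sim$callsets[[cc]]),
                             names(sim$callsets[[cc]])), function(caller) {
        read_caller_vcf(paths[[paste0(cc, "_", caller)]], caller,
                        reference = reference)
      })
    })
  } else {
    sim$callsets
  }
  consensus <- lapply(callsets, build_consensus, reference = reference)
  for (cc in comp) {
    log("consensus ", cc, ": ", nrow(consensus[[cc]]), " variants (",
        sum(consensus[[cc]]$class == "SNV"), " SNV, ",
        sum(consensus[[cc]]$class == "indel"), " indel)")
    utils::write.table(consensus[[cc]],
                       file.path(out_dir, paste0(cc, ".consensus.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  filtered <- lapply(consensus, apply_post_hoc_filters,
                     thresholds = config$filters)
  for (cc in comp) {
    log("filter ", cc, ": ", filtered[[cc]]$report$n_pass, "/",
        filtered[[cc]]$report$n_input, " pass")
    utils::write.table(filtered[[cc]]$variants,
                       file.path(out_dir, paste0(cc, ".filtered.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  pair <- component_pair(filtered$Neg$variants, filtered$Abr$variants,
                         tumour_id = config$tumour_id)
  log("pair: SNV overlap ", round(pair$overlap_snv, 3),
      ", indel overlap ", round(pair$overlap_indel, 3))

  spectra <- lapply(filtered, function(f) {
    substitution_spectrum(f$variants[f$variants$class == "SNV", , drop = FALSE])
  })

  profiles <- lapply(comp, function(cc) {
    v <- filtered[[cc]]$variants
    build_sbs_profile(v[v$class == "SNV", , drop = FALSE], reference,
                      sample_id = paste0(config$tumour_id, "_", cc))
  })
  catalog <- config$sim$signature_catalog
  similarity <- profile_catalog_similarity(profiles, catalog)
  clust <- cluster_similarity(similarity)
  sim_tab <- data.frame(sample = rownames(similarity), unclass(similarity),
                        check.names = FALSE)
  utils::write.table(sim_tab, file.path(out_dir, "signature_similarity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  subclones <- lapply(comp, function(cc) {
    v <- filtered[[cc]]$variants
    v <- v[v$class == "SNV", , drop = FALSE]
    if (nrow(v) < 20L) return(NULL)
    fit <- fit_vaf_mixture(v$tumour_alt, v$tumour_depth,
                           k_max = config$k_max)
    list(k = fit$k, means = fit$means, weights = fit$weights)
  })
  names(subclones) <- comp

  gene_states <- lapply(comp, function(cc) {
    assign_segments_to_genes(cna[[cc]], sim$genes,
                             ploidy = config$sim$ploidy[[cc]])
  })
  names(gene_states) <- comp
  diff_cna <- differential_gene_states(gene_states$Neg, gene_states$Abr)
  log("cna: ", nrow(diff_cna), " genes with discordant state")
  utils::write.table(diff_cna, file.path(out_dir, "differential_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  probes_f <- filter_probes(meth$probes)
  diff_probes <- differential_probes(probes_f$probes)
  log("methylation: ", probes_f$report$n_pass, " probes pass, ",
      nrow(diff_probes), " differential")
  utils::write.table(diff_probes,
                     file.path(out_dir, "differential_probes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  prom_summary <- promoter_methylation_summary(probes_f$probes)
  utils::write.table(prom_summary, file.path(out_dir, "promoter_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  prom_hits <- prom_summary[!is.na(prom_summary$promoter_methylated) &
                              prom_summary$promoter_methylated, ]

  call <- classify_relatedness(pair$overlap_snv, config$relatedness)
  log("relatedness: ", call)

  report <- list(
    tumour_id = config$tumour_id,
    seed = config$seed,
    relatedness = call,
    overlap = list(snv = pair$overlap_snv, indel = pair$overlap_indel),
    set_sizes = list(
      neg = as.list(pair$n_neg), abr = as.list(pair$n_abr),
      shared_snv = length(pair$shared$SNV),
      shared_indel = length(pair$shared$indel)
    ),
    consensus = lapply(consensus, nrow),
    filters = lapply(filtered, function(f) {
      c(stats::setNames(as.list(f$report$per_filter$removed),
                        f$report$per_filter$filter),
        list(pass = f$report$n_pass, input = f$report$n_input))
    }),
    spectra = lapply(spectra, function(s) as.list(round(s, 6))),
    signatures = list(
      similarity = apply(round(unclass(similarity), 6), 1L, as.list),
      best_match = as.list(attr(similarity, "best_match")),
      row_order = clust$row_order, col_order = clust$col_order,
      catalog_checksum = attr(catalog, "checksum")
    ),
    subclones = subclones,
    cna = list(
      n_differential = nrow(diff_cna),
      differential = diff_cna[, c("gene", "state_neg", "state_abr",
                                  "loh_neg", "loh_abr")]
    ),
    methylation = list(
      probes_pass = probes_f$report$n_pass,
      removed = stats::setNames(
        as.list(probes_f$report$per_criterion$removed),
        probes_f$report$per_criterion$criterion),
      n_differential = nrow(diff_probes),
      differential_genes = sort(unique(diff_probes$gene)),
      promoter_methylated = if (nrow(prom_hits)) {
        paste(prom_hits$gene, prom_hits$sample, sep = "_")
      } else {
        character(0)
      }
    )
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}

#' Bundled demonstration configuration
#'
#' A small but complete study: two components sharing 60% of ~400 mutations,
#' clock-like (SBS1/5) plus APOBEC (SBS2/13) signature activity, one
#' low-cellularity subclone in the Neg component, a planted CDH1 loss with
#' LOH in Neg only, a hypermethylated CTNNA1 promoter in Neg, and 3000
#' methylation probes. Completes in a few seconds per stage on one CPU.
#'
#' @param seed Master seed.
#' @return A [pipeline_config()].
#' @export
demo_pipeline_config <- function(seed = 7L) {
  pipeline_config(
    seed = seed,
    tumour_id = "DEMO1",
    sim = simulation_config(
      n_mutations = 400L, trunk_fraction = 0.6,
      signature_mixture = list(
        Neg = c(SBS1 = 0.25, SBS5 = 0.25, SBS2 = 0.35, SBS13 = 0.15),
        Abr = c(SBS1 = 0.45, SBS5 = 0.45, SBS2 = 0.07, SBS13 = 0.03)),
      purity = 0.7,
      subclones = list(Neg = data.frame(ccf = 0.3, n = 120L), Abr = NULL),
      cna_events = data.frame(gene = "CDH1", component = "Neg",
                              total_cn = 1L, minor_cn = 0L),
      methyl_events = data.frame(gene = "CTNNA1", component = "Neg"),
      n_probes = 3000L, n_genes = 120L),
    n_contigs = 4L, contig_length = 120000L
  )
}

# serialize the config (minus the catalogue matrix) for provenance; the
# serialized file is sufficient to rerun the pipeline byte-identically via
# load_pipeline_config (with the bundled catalogue)
.write_config_yaml <- function(config, path) {
  df_cols <- function(d) if (is.null(d)) NULL else as.list(d)
  sim <- config$sim
  sim_list <- unclass(sim)
  sim_list$signature_catalog <- list(
    signatures = colnames(sim$signature_catalog),
    checksum = attr(sim$signature_catalog, "checksum") %||% "bundled-synthetic"
  )
  sim_list$caller_profiles <- df_cols(sim$caller_profiles)
  sim_list$cna_events <- df_cols(sim$cna_events)
  sim_list$methyl_events <- df_cols(sim$methyl_events)
  sim_list$subclones <- lapply(sim$subclones, df_cols)
  sim_list$signature_mixture <- lapply(sim$signature_mixture, as.list)
  sim_list$purity <- as.list(sim$purity)
  sim_list$ploidy <- as.list(sim$ploidy)
  out <- unclass(config)
  out$sim <- sim_list
  out$filters <- unclass(config$filters)
  out$relatedness <- as.list(config$relatedness)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Rebuild a pipeline configuration from its serialized YAML
#'
#' Reads the `config.yaml` written into every run directory and
#' reconstructs the [pipeline_config()], so a run can be reproduced from
#' its own provenance file. The signature catalogue is restored from the
#' bundled synthetic catalogue (the YAML records its identity by checksum).
#'
#' @param path Path to a serialized `config.yaml`.
#' @return A [pipeline_config()].
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  as_df <- function(x) {
    if (is.null(x) || !length(x)) NULL
    else as.data.frame(x, stringsAsFactors = FALSE)
  }
  s <- y$sim
  sub <- lapply(c(Neg = "Neg", Abr = "Abr"), function(cc) {
    as_df(s$subclones[[cc]])
  })
  sim <- simulation_config(
    seed = s$seed, n_mutations = s$n_mutations,
    trunk_fraction = s$trunk_fraction,
    signature_mixture = lapply(s$signature_mixture, unlist),
    purity = unlist(s$purity),
    mean_depth_tumour = s$mean_depth_tumour,
    mean_depth_normal = s$mean_depth_normal,
    subclones = sub,
    caller_profiles = as_df(s$caller_profiles),
    indel_fraction = s$indel_fraction,
    n_multiallelic = s$n_multiallelic, n_common = s$n_common,
    n_shared_artifacts = s$n_shared_artifacts,
    rare_af_fraction = s$rare_af_fraction, n_lowqual = s$n_lowqual,
    n_genes = s$n_genes, ploidy = unlist(s$ploidy),
    cna_events = as_df(s$cna_events),
    n_probes = s$n_probes,
    discordant_probe_fraction = s$discordant_probe_fraction,
    probe_fail_fraction = s$probe_fail_fraction,
    beta_noise_sd = s$beta_noise_sd,
    methyl_events = as_df(s$methyl_events)
  )
  pipeline_config(
    seed = y$seed, tumour_id = y$tumour_id, sim = sim,
    n_contigs = y$n_contigs, contig_length = y$contig_length,
    filters = do.call(filter_thresholds, y$filters),
    relatedness = unlist(y$relatedness),
    k_max = y$k_max, write_vcfs = y$write_vcfs
  )
}
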