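# Simulation configuration. The defaults define the study conditions the
# simulator emulates: two macrodissected components of one tumour that share
# a truncal mutation set (common-ancestor regime), clock-like plus APOBEC
# signature activity, ~80x tumour / ~40x normal whole-genome depth, and
# three somatic callers (two of which call indels) with high but imperfect
# sensitivity and a modest false-positive load.

#' Default per-caller behaviour profiles
#'
#' Three callers mirror the common tumour/normal trio: two SNV+indel
#' callers (`mutect2`, `strelka2`) and one SNV-only caller (`muse`) that
#' does not report an allele-fraction FORMAT field, which exercises the
#' VAF-precedence fallback in consensus building.
#'
#' @return data.frame with columns `caller`, `calls_indels`, `reports_vaf`,
#'   `sensitivity`, `fp_count`, `vaf_noise_sd`.
#' @export
default_caller_profiles <- function() {
  data.frame(
    caller       = c("mutect2", "strelka2", "muse"),
    calls_indels = c(TRUE, TRUE, FALSE),
    reports_vaf  = c(TRUE, TRUE, FALSE),
    sensitivity  = c(0.98, 0.97, 0.95),
    fp_count     = c(25L, 25L, 25L),
    vaf_noise_sd = c(0.01, 0.01, 0),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the paired-tumour simulator
#'
#' @param seed Integer seed; one global RNG stream is seeded once per
#'   simulation, so identical config implies byte-identical outputs.
#' @param n_mutations Somatic mutations per component (truncal + private).
#' @param trunk_fraction Fraction in `[0,1]` of each component's mutations
#'   that are truncal (shared with the other component). `trunk_fraction *
#'   n_mutations` is the expected shared count; 0 gives the
#'   collision-of-independent-tumours regime, values near 1 the
#'   common-ancestor regime.
#' @param signature_mixture Named weights over catalogue signatures, either
#'   one vector used for both components or `list(Neg = ..., Abr = ...)`.
#'   Weights must be non-negative and sum to 1 (tolerance 1e-9). Truncal
#'   mutations are drawn from the mean of the two component mixtures.
#' @param purity Tumour cell fraction in `(0,1]`, scalar or named
#'   `c(Neg=, Abr=)`. A clonal diploid-heterozygous mutation has expected
#'   VAF `purity/2`.
#' @param mean_depth_tumour,mean_depth_normal Mean sequencing depth; per-site
#'   depth is Poisson around the mean.
#' @param subclones Per component (`list(Neg=, Abr=)`), `NULL` or a
#'   data.frame with columns `ccf` (cellular fraction in `(0,1]`) and `n`
#'   (mutation count); subclonal mutations are added on top of
#'   `n_mutations` with expected VAF `purity * ccf / 2`.
#' @param caller_profiles data.frame as in [default_caller_profiles()].
#' @param indel_fraction Fraction of mutations simulated as 1-5 bp
#'   insertions/deletions (left-aligned truth representation).
#' @param n_multiallelic Sites emitted with two ALT alleles (consensus-level
#'   false positives removed by the multiallelic filter).
#' @param n_common Germline-leak sites with population allele frequency
#'   above 1% present in both components and all callers.
#' @param n_shared_artifacts Consensus-level artifact sites (present in all
#'   callers) violating, in turn, the low-VAF, low-depth, tumour-alt and
#'   normal-alt filters, so every post hoc filter sees failing records.
#' @param rare_af_fraction Fraction of true mutations given a small nonzero
#'   population AF (< 1%, must survive the common-variant filter).
#' @param n_lowqual Per caller, records written with `FILTER=LowQual`
#'   (dropped at parse time).
#' @param n_genes Genes placed on the reference for annotation, recurrence
#'   and CNA/methylation simulation.
#' @param ploidy Tumour ploidy, scalar or named `c(Neg=, Abr=)`.
#' @param cna_events `NULL` or data.frame with columns `gene`, `component`,
#'   `total_cn`, `minor_cn`: copy-number events planted on a gene locus.
#' @param n_probes Methylation probe count.
#' @param discordant_probe_fraction Fraction of probes planted as truly
#'   differentially methylated between components (opposite status, planted
#'   delta >= 0.2).
#' @param probe_fail_fraction Fraction of probes given each of the four
#'   removal reasons (failed detection p, Y chromosome, SNP at CpG,
#'   cross-reactive).
#' @param beta_noise_sd Gaussian noise added to planted beta values.
#' @param methyl_events `NULL` or data.frame with columns `gene`,
#'   `component`: promoters planted as hypermethylated (betas ~ 0.7) in one
#'   component.
#' @param signature_catalog 96 x S matrix of channel probabilities used to
#'   draw mutation contexts; defaults to the bundled synthetic catalogue.
#' @return Validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_mutations = 2000L,
                              trunk_fraction = 0.6,
                              signature_mixture = c(SBS1 = 0.35, SBS5 = 0.35,
                                                    SBS2 = 0.2, SBS13 = 0.1),
                              purity = 0.7,
                              mean_depth_tumour = 80,
                              mean_depth_normal = 40,
                              subclones = list(Neg = NULL, Abr = NULL),
                              caller_profiles = default_caller_profiles(),
                              indel_fraction = 0.1,
                              n_multiallelic = 2L,
                              n_common = 5L,
                              n_shared_artifacts = 4L,
                              rare_af_fraction = 0.02,
                              n_lowqual = 3L,
                              n_genes = 200L,
                              ploidy = 2,
                              cna_events = NULL,
                              n_probes = 10000L,
                              discordant_probe_fraction = 0.01,
                              probe_fail_fraction = 0.01,
                              beta_noise_sd = 0.02,
                              methyl_events = NULL,
                              signature_catalog = synthetic_signature_catalog()) {
  comp <- c("Neg", "Abr")
  if (!is.list(signature_mixture)) {
    signature_mixture <- list(Neg = signature_mixture, Abr = signature_mixture)
  }
  stopifnot(setequal(names(signature_mixture), comp))
  for (cc in comp) {
    w <- signature_mixture[[cc]]
    if (is.null(names(w)) || any(w < 0)) {
      stop("signature_mixture must be a named vector of non-negative weights")
    }
    if (abs(sum(w) - 1) > 1e-9) {
      stop("signature weights for component ", cc, " sum to ", sum(w),
           ", not 1")
    }
    missing_sig <- setdiff(names(w), colnames(signature_catalog))
    if (length(missing_sig)) {
      stop("signatures not in catalogue: ", paste(missing_sig, collapse = ", "))
    }
  }
  if (!is.numeric(trunk_fraction) || trunk_fraction < 0 || trunk_fraction > 1) {
    stop("trunk_fraction must be in [0, 1]")
  }
  if (length(purity) == 1L) purity <- stats::setNames(rep(purity, 2), comp)
  if (length(ploidy) == 1L) ploidy <- stats::setNames(rep(ploidy, 2), comp)
  stopifnot(
    setequal(names(purity), comp), all(purity > 0), all(purity <= 1),
    setequal(names(ploidy), comp), all(ploidy > 0),
    indel_fraction >= 0, indel_fraction <= 1,
    discordant_probe_fraction >= 0, discordant_probe_fraction <= 1,
    n_mutations >= 0, n_probes >= 1, mean_depth_tumour > 0,
    all(c("caller", "calls_indels", "reports_vaf", "sensitivity",
          "fp_count", "vaf_noise_sd") %in% names(caller_profiles)),
    all(caller_profiles$sensitivity >= 0 & caller_profiles$sensitivity <= 1)
  )
  for (cc in comp) {
    sc <- subclones[[cc]]
    if (!is.null(sc)) {
      stopifnot(all(c("ccf", "n") %in% names(sc)),
                all(sc$ccf > 0), all(sc$ccf <= 1), all(sc$n >= 0))
    }
  }
  structure(list(
    seed = as.integer(seed), n_mutations = as.integer(n_mutations),
    trunk_fraction = trunk_fraction, signature_mixture = signature_mixture,
    purity = purity, mean_depth_tumour = mean_depth_tumour,
    mean_depth_normal = mean_depth_normal, subclones = subclones,
    caller_profiles = caller_profiles, indel_fraction = indel_fraction,
    n_multiallelic = as.integer(n_multiallelic),
    n_common = as.integer(n_common),
    n_shared_artifacts = as.integer(n_shared_artifacts),
    rare_af_fraction = rare_af_fraction, n_lowqual = as.integer(n_lowqual),
    n_genes = as.integer(n_genes), ploidy = ploidy, cna_events = cna_events,
    n_probes = as.integer(n_probes),
    discordant_probe_fraction = discordant_probe_fraction,
    probe_fail_fraction = probe_fail_fraction,
    beta_noise_sd = beta_noise_sd, methyl_events = methyl_events,
    signature_catalog = signature_catalog
  ), class = "simulation_config")
}
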