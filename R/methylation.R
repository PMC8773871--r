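# Differential promoter methylation between two tumour components, on
# methylation-array beta values. Probes are filtered (failed detection
# p-value in any sample, Y chromosome, SNP at the CpG, cross-reactive),
# status is called by a hard beta threshold (methylated iff beta > 0.3),
# and a probe is differential when the two components have opposite status
# and the absolute beta difference (delta) is at least 0.1.

#' Call methylation status from beta values
#'
#' Methylated iff `beta > threshold` (strict: a beta exactly at the
#' threshold is unmethylated). Values outside `[0, 1]` are an error.
#'
#' @param beta Numeric vector of beta values.
#' @param threshold Status cut-point (default 0.3).
#' @return Character vector `"methylated"` / `"unmethylated"`.
#' @export
#' @examples
#' call_status(c(0.30, 0.31)) # boundary: unmethylated, methylated
call_status <- function(beta, threshold = 0.3) {
  if (any(is.na(beta)) || any(beta < 0 | beta > 1)) {
    stop("beta values must lie in [0, 1]")
  }
  ifelse(beta > threshold, "methylated", "unmethylated")
}

.sample_cols <- function(probes, prefix, samples) {
  cols <- paste0(prefix, samples)
  miss <- setdiff(cols, names(probes))
  if (length(miss)) {
    stop("unknown sample column(s): ", paste(miss, collapse = ", "))
  }
  cols
}

#' Filter methylation probes before analysis
#'
#' Removes probes with a detection p-value above `p_threshold` in one or
#' more samples, probes on the Y chromosome, probes carrying a common SNP
#' at the CpG site, and cross-reactive probes. A probe is attributed to the
#' first criterion it trips, so the report counts sum to the removed total.
#'
#' @param probes Wide probe table: `probe_id`, `chrom`, plus
#'   `detp_<sample>` columns and logical `snp_at_cpg`, `cross_reactive`.
#' @param samples Sample names whose detection p-values are checked
#'   (default: every `detp_*` column present).
#' @param p_threshold Detection p-value cut-off (strict `>` removes).
#' @return List with `probes` (survivors) and `report` (data.frame of
#'   criterion and removed count, plus `n_input`, `n_pass`).
#' @export
filter_probes <- function(probes, samples = NULL, p_threshold = 0.05) {
  if (is.null(samples)) {
    samples <- sub("^detp_", "", grep("^detp_", names(probes), value = TRUE))
  }
  cols <- .sample_cols(probes, "detp_", samples)
  pmat <- as.matrix(probes[, cols, drop = FALSE])
  if (anyNA(pmat)) {
    stop("missing detection p-value for probe ",
         probes$probe_id[which(rowSums(is.na(pmat)) > 0)[1L]])
  }
  reasons <- list(
    failed_detection = rowSums(pmat > p_threshold) > 0L,
    y_chromosome = probes$chrom %in% c("Y", "chrY"),
    snp_at_cpg = as.logical(probes$snp_at_cpg),
    cross_reactive = as.logical(probes$cross_reactive)
  )
  failed <- rep(NA_character_, nrow(probes))
  for (r in names(reasons)) {
    failed[reasons[[r]] & is.na(failed)] <- r
  }
  report <- data.frame(
    criterion = names(reasons),
    removed = vapply(names(reasons),
                     function(r) sum(failed == r, na.rm = TRUE), integer(1)),
    row.names = NULL
  )
  survivors <- probes[is.na(failed), , drop = FALSE]
  rownames(survivors) <- NULL
  list(probes = survivors,
       report = list(per_criterion = report, n_input = nrow(probes),
                     n_pass = nrow(survivors)))
}

#' Probes differentially methylated between the two components
#'
#' A probe qualifies when it maps to a promoter (and, when `gene_filter`
#' is given, to one of those genes), the two components have opposite
#' methylation status, and the absolute beta difference is at least
#' `min_delta`. Run on filtered probes.
#'
#' @param probes Wide probe table with `beta_<sample>` columns and logical
#'   `promoter`.
#' @param neg,abr Sample names of the two components.
#' @param gene_filter Optional character vector restricting to genes.
#' @param min_delta Minimum absolute beta difference (default 0.1).
#' @param threshold Status threshold passed to [call_status()].
#' @return data.frame: `probe_id`, `gene`, `beta_neg`, `beta_abr`, `delta`,
#'   `status_neg`, `status_abr`.
#' @export
differential_probes <- function(probes, neg = "Neg", abr = "Abr",
                                gene_filter = NULL, min_delta = 0.1,
                                threshold = 0.3) {
  cols <- .sample_cols(probes, "beta_", c(neg, abr))
  keep <- as.logical(probes$promoter)
  if (!is.null(gene_filter)) keep <- keep & probes$gene %in% gene_filter
  probes <- probes[keep, , drop = FALSE]
  beta_neg <- probes[[cols[1L]]]
  beta_abr <- probes[[cols[2L]]]
  status_neg <- call_status(beta_neg, threshold)
  status_abr <- call_status(beta_abr, threshold)
  delta <- abs(beta_neg - beta_abr)
  hit <- status_neg != status_abr & delta >= min_delta
  out <- data.frame(
    probe_id = probes$probe_id[hit], gene = probes$gene[hit],
    beta_neg = beta_neg[hit], beta_abr = beta_abr[hit], delta = delta[hit],
    status_neg = status_neg[hit], status_abr = status_abr[hit],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Per-gene promoter methylation summary
#'
#' For each gene and component: promoter probe count, methylated count and
#' fraction, plus a gene-level `promoter_methylated` flag when the fraction
#' of methylated promoter probes exceeds `gene_threshold`. Genes without
#' promoter probes are reported as `no_data` rather than unmethylated.
#'
#' @param probes Wide probe table (filtered).
#' @param samples Sample names to summarise.
#' @param genes Optional gene universe; defaults to genes present in the
#'   probe map, but listing absent genes yields `no_data` rows.
#' @param gene_threshold Fraction of methylated promoter probes above which
#'   a promoter is called methylated (default 0.5).
#' @param threshold Probe-status threshold passed to [call_status()].
#' @return data.frame: `gene`, `sample`, `n_probes`, `n_methylated`,
#'   `fraction`, `promoter_methylated` (logical, NA for no-data rows).
#' @export
promoter_methylation_summary <- function(probes, samples = c("Neg", "Abr"),
                                         genes = NULL, gene_threshold = 0.5,
                                         threshold = 0.3) {
  cols <- .sample_cols(probes, "beta_", samples)
  prom <- probes[as.logical(probes$promoter) & !is.na(probes$gene), ,
                 drop = FALSE]
  if (is.null(genes)) genes <- sort(unique(prom$gene))
  rows <- list()
  for (g in genes) {
    pg <- prom[prom$gene == g, , drop = FALSE]
    for (i in seq_along(samples)) {
      if (nrow(pg) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, sample = samples[i], n_probes = 0L, n_methylated = NA_integer_,
          fraction = NA_real_, promoter_methylated = NA,
          stringsAsFactors = FALSE)
      } else {
        st <- call_status(pg[[cols[i]]], threshold)
        nm <- sum(st == "methylated")
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, sample = samples[i], n_probes = nrow(pg),
          n_methylated = nm, fraction = nm / nrow(pg),
          promoter_methylated = nm / nrow(pg) > gene_threshold,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a paired-component methylation probe table
#'
#' Probes are laid over gene promoters (TSS1500/TSS200/5'UTR regions) plus
#' a gene-body fraction. Concordant probes draw both components' betas
#' around a common base value kept away from the 0.3 status threshold;
#' planted differential probes put the two components on opposite sides
#' with a beta difference of at least ~0.25 before noise. A configurable
#' fraction of (non-differential) probes receives each removal reason:
#' failed detection p-value in one sample, Y-chromosome location, SNP at
#' the CpG, cross-reactivity. Genes listed in `config$methyl_events` have
#' their whole promoter hypermethylated (betas ~0.7) in one component.
#'
#' @param config A [simulation_config()]; uses `n_probes`,
#'   `discordant_probe_fraction`, `probe_fail_fraction`, `beta_noise_sd`,
#'   `methyl_events`. Consumes the current RNG stream.
#' @param genes Gene table (see [simulate_genes()]).
#' @return List with `probes` (wide table) and `truth` (probe ids planted
#'   as differential, plus the planted promoter events).
#' @export
simulate_methylation <- function(config, genes) {
  n <- config$n_probes
  regions <- c("TSS1500", "TSS200", "5UTR", "Body")
  region <- sample_from(regions, n, prob = c(0.3, 0.25, 0.15, 0.3))
  promoter <- region != "Body"
  gi <- sample.int(nrow(genes), n, replace = TRUE)
  probe <- data.frame(
    probe_id = sprintf("cg%08d", seq_len(n)),
    chrom = genes$chrom[gi],
    pos = pmax(1L, genes$tss[gi] - sample.int(1500L, n, replace = TRUE)),
    gene = genes$gene[gi], region = region, promoter = promoter,
    snp_at_cpg = FALSE, cross_reactive = FALSE, stringsAsFactors = FALSE
  )
  # concordant baseline: both components share a base value away from the
  # 0.3 threshold by at least 0.1
  lowish <- stats::runif(n) < 0.6
  base <- ifelse(lowish, stats::runif(n, 0.02, 0.20),
                 stats::runif(n, 0.42, 0.90))
  beta_neg <- base
  beta_abr <- base
  # planted promoter hypermethylation events (gene-level truth)
  ev <- config$methyl_events
  if (!is.null(ev) && nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      sel <- probe$gene == ev$gene[i] & probe$promoter
      hyper <- stats::runif(sum(sel), 0.6, 0.85)
      hypo <- stats::runif(sum(sel), 0.03, 0.15)
      if (ev$component[i] == "Neg") {
        beta_neg[sel] <- hyper; beta_abr[sel] <- hypo
      } else {
        beta_abr[sel] <- hyper; beta_neg[sel] <- hypo
      }
    }
  }
  # planted differential probes, restricted to promoter probes of genes
  # untouched by gene-level events
  event_genes <- if (is.null(ev)) character(0) else ev$gene
  n_diff <- round(n * config$discordant_probe_fraction)
  eligible <- which(probe$promoter & !(probe$gene %in% event_genes))
  diff_idx <- sort(sample(eligible, min(n_diff, length(eligible))))
  n_d <- length(diff_idx)
  if (n_d) {
    hi <- stats::runif(n_d, 0.45, 0.80)
    lo <- stats::runif(n_d, 0.05, 0.20)
    neg_high <- stats::runif(n_d) < 0.5
    beta_neg[diff_idx] <- ifelse(neg_high, hi, lo)
    beta_abr[diff_idx] <- ifelse(neg_high, lo, hi)
  }
  noise <- function(x) clip01(x + stats::rnorm(n, 0, config$beta_noise_sd))
  probe$beta_Neg <- noise(beta_neg)
  probe$beta_Abr <- noise(beta_abr)
  probe$detp_Neg <- stats::runif(n, 0, 0.01)
  probe$detp_Abr <- stats::runif(n, 0, 0.01)
  # removal-reason planting on probes that are neither differential nor in
  # a gene-level event, so filtering never eats planted truth
  clean <- setdiff(seq_len(n), c(diff_idx, which(probe$gene %in% event_genes)))
  n_fail <- round(n * config$probe_fail_fraction)
  pick <- function(k) {
    got <- sample(clean, min(k, length(clean)))
    clean <<- setdiff(clean, got)
    got
  }
  idx <- pick(n_fail)
  probe$detp_Neg[idx] <- stats::runif(length(idx), 0.051, 0.2)
  idx <- pick(n_fail)
  probe$chrom[idx] <- "chrY"
  idx <- pick(n_fail)
  probe$snp_at_cpg[idx] <- TRUE
  idx <- pick(n_fail)
  probe$cross_reactive[idx] <- TRUE
  list(
    probes = probe,
    truth = list(
      differential_probes = probe$probe_id[diff_idx],
      promoter_events = ev
    )
  )
}
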