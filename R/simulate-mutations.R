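# Paired-tumour mutation simulator. Generates, with known ground truth, the
# somatic callsets three tumour/normal callers would emit for the two
# macrodissected components of one tumour: a truncal mutation set shared by
# both components, private sets per component, optional subclones at lower
# cellular fraction, trinucleotide contexts drawn from mutational-signature
# mixtures, Poisson depth / binomial allele sampling under purity, and
# caller-specific sensitivity, false positives and VAF noise.

GENE_NAMES_KNOWN <- c("CDH1", "CTNNA1", "CTNNB1", "CTNND1", "CDH3",
                      "PIK3CA", "APC", "CTCF", "MAP2K4", "GATA3")

#' Place a synthetic gene annotation on a reference
#'
#' Genes are laid out in non-overlapping windows proportional to contig
#' length; the first few carry the names of loci recurrently discussed in
#' lobular breast cancer (CDH1, the catenins, PIK3CA, ...) so planted events
#' can target them by name. Consumes the current RNG stream.
#'
#' @param reference A `hp_reference`.
#' @param n_genes Number of genes.
#' @return data.frame with columns `gene`, `chrom`, `start`, `end`, `tss`.
#' @export
simulate_genes <- function(reference, n_genes = 200L) {
  lens <- ref_lengths(reference)
  alloc <- floor(n_genes * lens / sum(lens))
  rem <- n_genes - sum(alloc)
  if (rem > 0L) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1L
  rows <- lapply(names(lens), function(chrom) {
    k <- alloc[[chrom]]
    if (k == 0L) return(NULL)
    slot <- floor(lens[[chrom]] / k)
    glen <- pmax(pmin(round(stats::runif(k, 1500, 6000)), slot - 200L), 100L)
    offset <- floor(stats::runif(k, 100, pmax(slot - glen - 100, 101)))
    start <- (seq_len(k) - 1L) * slot + offset
    data.frame(chrom = chrom, start = as.integer(start),
               end = as.integer(start + glen - 1L), stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, rows)
  n_known <- min(n_genes, length(GENE_NAMES_KNOWN))
  nm <- c(GENE_NAMES_KNOWN[seq_len(n_known)],
          sprintf("GENE%03d", seq_len(max(0L, n_genes - n_known))))
  genes$gene <- nm
  genes$tss <- genes$start
  genes[, c("gene", "chrom", "start", "end", "tss")]
}

# annotate positions with gene and a functional class consistent with their
# location; consumes RNG
.annotate_positions <- function(chrom, pos, is_indel, genes) {
  n <- length(pos)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  ggr <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$start, genes$end))
  hit <- GenomicRanges::findOverlaps(gr, ggr, select = "first")
  gene <- ifelse(is.na(hit), NA_character_, genes$gene[hit])
  in_gene <- !is.na(hit)
  func <- character(n)
  n_in <- sum(in_gene & !is_indel)
  if (n_in) {
    func[in_gene & !is_indel] <- sample_from(
      c("nonsynonymous", "synonymous", "stopgain", "intronic", "UTR5", "UTR3"),
      n_in, prob = c(0.40, 0.15, 0.04, 0.30, 0.05, 0.06))
  }
  n_ini <- sum(in_gene & is_indel)
  if (n_ini) {
    func[in_gene & is_indel] <- sample_from(
      c("frameshift", "nonframeshift", "intronic"), n_ini,
      prob = c(0.5, 0.2, 0.3))
  }
  n_out <- sum(!in_gene)
  if (n_out) {
    func[!in_gene] <- sample_from(
      c("intergenic", "upstream", "downstream"), n_out,
      prob = c(0.6, 0.2, 0.2))
  }
  list(gene = gene, func_class = func)
}

# draw unique random SNV-able positions away from contig edges; consumes RNG
.random_sites <- function(reference, n, margin = 10L, taken = character(0)) {
  if (n == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0)))
  }
  lens <- ref_lengths(reference)
  out <- NULL
  for (tries in 1:50) {
    need <- n - if (is.null(out)) 0L else nrow(out)
    if (need <= 0L) break
    chrom <- sample_from(names(lens), need, prob = lens)
    pos <- vapply(chrom, function(cc) {
      sample.int(lens[[cc]] - 2L * margin, 1L) + margin
    }, integer(1))
    cand <- data.frame(chrom = chrom, pos = as.integer(pos),
                       stringsAsFactors = FALSE, row.names = NULL)
    cand <- cand[!paste(cand$chrom, cand$pos) %in% taken, , drop = FALSE]
    out <- rbind(out, cand)
    out <- out[!duplicated(paste(out$chrom, out$pos)), , drop = FALSE]
  }
  if (nrow(out) < n) stop("could not place ", n, " unique sites")
  out <- out[seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# channel string helpers: "A[C>T]G" -> parts
.channel_parts <- function(channel) {
  data.frame(
    p5 = substr(channel, 1L, 1L),
    ref = substr(channel, 3L, 3L),
    alt = substr(channel, 5L, 5L),
    p3 = substr(channel, 7L, 7L),
    context = paste0(substr(channel, 1L, 1L), substr(channel, 3L, 3L),
                     substr(channel, 7L, 7L)),
    stringsAsFactors = FALSE
  )
}

# place SNVs whose folded trinucleotide context matches their drawn channel;
# consumes RNG. Returns data.frame(chrom, pos, ref, alt) aligned to channels.
.place_snvs <- function(reference, channels) {
  n <- length(channels)
  parts <- .channel_parts(channels)
  idx <- context_index(reference)
  chrom <- character(n); pos <- integer(n)
  for (ctx in unique(parts$context)) {
    rows <- which(parts$context == ctx)
    avail <- idx[[ctx]]
    if (is.null(avail) || nrow(avail) < length(rows)) {
      stop("reference too short: need ", length(rows),
           " sites with folded context ", ctx, " but only ",
           if (is.null(avail)) 0L else nrow(avail), " available")
    }
    pick <- avail[sample.int(nrow(avail), length(rows)), ]
    chrom[rows] <- pick$chrom
    pos[rows] <- pick$pos
  }
  base <- character(n)
  for (cc in unique(chrom)) {
    i <- chrom == cc
    base[i] <- ref_seq(reference, cc, pos[i])
  }
  flip <- base %in% c("A", "G") # channel describes the pyrimidine strand
  data.frame(
    chrom = chrom, pos = pos, ref = base,
    alt = ifelse(flip, dna_complement(parts$alt), parts$alt),
    stringsAsFactors = FALSE
  )
}

# random 1-5 bp insertions/deletions, left-aligned; consumes RNG
.place_indels <- function(reference, n, taken) {
  if (n == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0)))
  }
  sites <- .random_sites(reference, n, margin = 60L, taken = taken)
  L <- sample(1:5, n, replace = TRUE)
  is_del <- stats::runif(n) < 0.5
  ref <- character(n); alt <- character(n)
  for (i in seq_len(n)) {
    anchor <- ref_seq(reference, sites$chrom[i], sites$pos[i])
    if (is_del[i]) {
      ref[i] <- ref_seq(reference, sites$chrom[i], sites$pos[i],
                        sites$pos[i] + L[i])
      alt[i] <- anchor
    } else {
      ref[i] <- anchor
      alt[i] <- paste0(anchor, paste(sample(DNA_BASES, L[i], replace = TRUE),
                                     collapse = ""))
    }
  }
  out <- data.frame(chrom = sites$chrom, pos = sites$pos, ref = ref, alt = alt,
                    stringsAsFactors = FALSE)
  normalize_variants(out, reference)[, c("chrom", "pos", "ref", "alt")]
}

#' Simulate paired-component caller callsets with ground truth
#'
#' The central generative step: draws the truncal/private/subclonal mutation
#' structure of two tumour components, places SNVs at reference positions
#' whose trinucleotide context matches channels drawn from the configured
#' signature mixtures, samples read counts (Poisson depth, binomial alt
#' reads at `purity * ccf / 2` for diploid-heterozygous mutations), and
#' derives one callset per caller per component by applying caller
#' sensitivity, injected false positives and VAF noise. Consensus-level
#' contaminants (multiallelic sites, common germline-frequency variants,
#' low-quality artifact sites) are injected so every downstream filter sees
#' failing records; every emitted record carries exactly one truth label.
#'
#' @param config A [simulation_config()].
#' @param reference A `hp_reference` long enough to place all mutations.
#' @param genes Optional gene table; simulated via [simulate_genes()] when
#'   `NULL`.
#' @return An `hp_simulation` list: `callsets` (per component, per caller
#'   data.frames of variant calls), `truth` (one row per distinct variant
#'   with label `truncal`, `private_Neg`, `private_Abr`, `subclone_<comp>_<i>`
#'   or `false_positive`, plus true per-component VAFs), `genes`, `config`,
#'   `reference`.
#' @export
simulate_mutation_set <- function(config, reference, genes = NULL) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(reference, "hp_reference"))
  set.seed(config$seed)
  if (is.null(genes)) genes <- simulate_genes(reference, config$n_genes)
  comp <- c("Neg", "Abr")
  catalog <- config$signature_catalog
  mix <- config$signature_mixture
  mix_trunk <- (
    .full_mixture(mix$Neg, catalog) + .full_mixture(mix$Abr, catalog)) / 2

  n <- config$n_mutations
  n_trunk <- stats::rbinom(1L, n, config$trunk_fraction)
  blocks <- list(
    list(label = "truncal", n = n_trunk, in_Neg = TRUE, in_Abr = TRUE,
         ccf = 1, mix = mix_trunk),
    list(label = "private_Neg", n = n - n_trunk, in_Neg = TRUE,
         in_Abr = FALSE, ccf = 1, mix = .full_mixture(mix$Neg, catalog)),
    list(label = "private_Abr", n = n - n_trunk, in_Neg = FALSE,
         in_Abr = TRUE, ccf = 1, mix = .full_mixture(mix$Abr, catalog))
  )
  for (cc in comp) {
    sc <- config$subclones[[cc]]
    if (!is.null(sc)) {
      for (j in seq_len(nrow(sc))) {
        blocks <- c(blocks, list(list(
          label = sprintf("subclone_%s_%d", cc, j), n = sc$n[j],
          in_Neg = cc == "Neg", in_Abr = cc == "Abr", ccf = sc$ccf[j],
          mix = .full_mixture(mix[[cc]], catalog))))
      }
    }
  }
  blocks <- Filter(function(b) b$n > 0L, blocks)

  truth <- data.table::rbindlist(lapply(blocks, function(b) {
    data.table::data.table(
      label = b$label, in_Neg = b$in_Neg, in_Abr = b$in_Abr, ccf = b$ccf,
      is_indel = stats::runif(b$n) < config$indel_fraction
    )
  }))
  # mutation channels for SNVs (drawn block-wise from the block's mixture)
  truth$channel <- NA_character_
  offset <- 0L
  chans <- sbs_channels()
  for (b in blocks) {
    rows <- offset + seq_len(b$n)
    snv_rows <- rows[!truth$is_indel[rows]]
    if (length(snv_rows)) {
      probs <- as.numeric(catalog %*% b$mix)
      truth$channel[snv_rows] <- sample_from(chans, length(snv_rows), probs)
    }
    offset <- offset + b$n
  }
  # placement
  truth$chrom <- NA_character_; truth$pos <- NA_integer_
  truth$ref <- NA_character_; truth$alt <- NA_character_
  snv_i <- which(!truth$is_indel)
  if (length(snv_i)) {
    placed <- .place_snvs(reference, truth$channel[snv_i])
    truth$chrom[snv_i] <- placed$chrom; truth$pos[snv_i] <- placed$pos
    truth$ref[snv_i] <- placed$ref; truth$alt[snv_i] <- placed$alt
  }
  ind_i <- which(truth$is_indel)
  if (length(ind_i)) {
    placed <- .place_indels(reference, length(ind_i),
                            taken = paste(truth$chrom, truth$pos))
    truth$chrom[ind_i] <- placed$chrom; truth$pos[ind_i] <- placed$pos
    truth$ref[ind_i] <- placed$ref; truth$alt[ind_i] <- placed$alt
  }
  truth$multiallelic <- FALSE
  truth$is_common <- FALSE
  truth$pop_af <- ifelse(stats::runif(nrow(truth)) < config$rare_af_fraction,
                         stats::runif(nrow(truth), 0, 0.009), 0)
  truth$true_vaf_Neg <- ifelse(truth$in_Neg,
                               config$purity[["Neg"]] * truth$ccf / 2, 0)
  truth$true_vaf_Abr <- ifelse(truth$in_Abr,
                               config$purity[["Abr"]] * truth$ccf / 2, 0)
  truth$override <- NA_character_

  taken <- paste(truth$chrom, truth$pos)
  contam <- .contaminant_truth(config, reference, taken)
  if (!is.null(contam) && nrow(contam)) {
    truth <- rbind(truth, contam, use.names = TRUE)
  }
  truth <- as.data.frame(truth)
  truth$class <- variant_class(truth$ref, truth$alt)
  ann <- .annotate_positions(truth$chrom, truth$pos, truth$is_indel, genes)
  truth$gene <- ann$gene
  truth$func_class <- ann$func_class
  # both ALT rows of a multiallelic site share one VCF record, hence one
  # set of site-level values
  ma <- which(truth$multiallelic)
  if (length(ma)) {
    site <- paste(truth$chrom[ma], truth$pos[ma])
    map <- match(site, unique(site))
    firsts <- ma[!duplicated(site)]
    truth$func_class[ma] <- truth$func_class[firsts][map]
    truth$gene[ma] <- truth$gene[firsts][map]
    truth$pop_af[ma] <- truth$pop_af[firsts][map]
  }
  truth$key <- variant_key(truth$chrom, truth$pos, truth$ref, truth$alt)
  if (anyDuplicated(truth$key)) {
    truth <- truth[!duplicated(truth$key), , drop = FALSE]
  }

  # sequencing reads per component (identical read pool seen by all callers)
  reads <- lapply(comp, function(cc) .draw_reads(truth, cc, config))
  names(reads) <- comp

  callsets <- lapply(comp, function(cc) {
    .caller_callsets(truth, reads[[cc]], cc, config, reference)
  })
  names(callsets) <- comp

  # caller-private false positives and low-quality records enter the truth
  # table too (labelled false_positive); gather them from the callsets
  fp_rows <- .collect_fp_truth(callsets, truth, genes)
  truth_out <- rbind(
    truth[, .truth_cols()],
    fp_rows
  )
  rownames(truth_out) <- NULL

  structure(list(
    callsets = callsets, reads = reads, truth = truth_out, genes = genes,
    config = config, reference = reference
  ), class = "hp_simulation")
}

.truth_cols <- function() {
  c("key", "chrom", "pos", "ref", "alt", "class", "label", "channel",
    "in_Neg", "in_Abr", "true_vaf_Neg", "true_vaf_Abr", "gene", "func_class",
    "pop_af", "multiallelic")
}

# expand a named mixture to the full signature space of the catalogue
.full_mixture <- function(w, catalog) {
  full <- stats::setNames(numeric(ncol(catalog)), colnames(catalog))
  full[names(w)] <- w
  full
}

# consensus-level contaminants: multiallelic sites, common germline leaks,
# and artifact sites engineered to fail one post hoc filter each
.contaminant_truth <- function(config, reference, taken) {
  out <- list()
  other_base <- function(b, k = 1L) {
    vapply(b, function(x) paste(sample(setdiff(DNA_BASES, x), k), collapse = ","),
           character(1))
  }
  if (config$n_common > 0L) {
    s <- .random_sites(reference, config$n_common, taken = taken)
    base <- mapply(function(cc, pp) ref_seq(reference, cc, pp),
                   s$chrom, s$pos)
    out$common <- data.table::data.table(
      label = "false_positive", in_Neg = TRUE, in_Abr = TRUE, ccf = 1,
      is_indel = FALSE, channel = NA_character_, chrom = s$chrom, pos = s$pos,
      ref = unname(base), alt = unname(other_base(base)),
      multiallelic = FALSE, is_common = TRUE,
      pop_af = stats::runif(config$n_common, 0.02, 0.3),
      true_vaf_Neg = 0.5, true_vaf_Abr = 0.5, override = NA_character_)
    taken <- c(taken, paste(s$chrom, s$pos))
  }
  if (config$n_multiallelic > 0L) {
    s <- .random_sites(reference, config$n_multiallelic, taken = taken)
    base <- unname(mapply(function(cc, pp) ref_seq(reference, cc, pp),
                          s$chrom, s$pos))
    alts <- lapply(base, function(b) sample(setdiff(DNA_BASES, b), 2L))
    out$multi <- data.table::data.table(
      label = "false_positive", in_Neg = TRUE, in_Abr = TRUE, ccf = 1,
      is_indel = FALSE, channel = NA_character_,
      chrom = rep(s$chrom, each = 2L), pos = rep(s$pos, each = 2L),
      ref = rep(base, each = 2L), alt = unlist(alts),
      multiallelic = TRUE, is_common = FALSE, pop_af = 0,
      true_vaf_Neg = 0.25, true_vaf_Abr = 0.25, override = NA_character_)
    taken <- c(taken, paste(s$chrom, s$pos))
  }
  if (config$n_shared_artifacts > 0L) {
    kinds <- rep_len(c("low_vaf", "low_depth", "low_alt", "high_normal_alt"),
                     config$n_shared_artifacts)
    s <- .random_sites(reference, config$n_shared_artifacts, taken = taken)
    base <- unname(mapply(function(cc, pp) ref_seq(reference, cc, pp),
                          s$chrom, s$pos))
    out$artifact <- data.table::data.table(
      label = "false_positive", in_Neg = TRUE, in_Abr = TRUE, ccf = 1,
      is_indel = FALSE, channel = NA_character_, chrom = s$chrom, pos = s$pos,
      ref = base, alt = unname(other_base(base)),
      multiallelic = FALSE, is_common = FALSE, pop_af = 0,
      true_vaf_Neg = 0, true_vaf_Abr = 0, override = kinds)
  }
  data.table::rbindlist(out)
}

# per-site sequencing draws for one component; artifact sites override the
# generic sampling so that each engineered filter violation materialises
.draw_reads <- function(truth, component, config) {
  n <- nrow(truth)
  vaf <- truth[[paste0("true_vaf_", component)]]
  depth <- stats::rpois(n, config$mean_depth_tumour)
  ndepth <- stats::rpois(n, config$mean_depth_normal)
  alt <- stats::rbinom(n, depth, vaf)
  nalt <- ifelse(truth$is_common, stats::rbinom(n, ndepth, 0.5), 0L)
  ov <- truth$override
  low_depth <- !is.na(ov) & ov == "low_depth"
  depth[low_depth] <- sample(3:8, sum(low_depth), replace = TRUE)
  ndepth[low_depth] <- sample(3:8, sum(low_depth), replace = TRUE)
  alt[low_depth] <- pmin(depth[low_depth], 2L)
  low_alt <- !is.na(ov) & ov == "low_alt"
  alt[low_alt] <- sample(1:4, sum(low_alt), replace = TRUE)
  high_nalt <- !is.na(ov) & ov == "high_normal_alt"
  alt[high_nalt] <- pmax(5L, stats::rbinom(sum(high_nalt),
                                           depth[high_nalt], 0.3))
  nalt[high_nalt] <- sample(3:6, sum(high_nalt), replace = TRUE)
  low_vaf <- !is.na(ov) & ov == "low_vaf"
  alt[low_vaf] <- 1L
  ma <- which(truth$multiallelic) # one record per site => one DP per site
  if (length(ma)) {
    site <- paste(truth$chrom[ma], truth$pos[ma])
    map <- match(site, unique(site))
    firsts <- ma[!duplicated(site)]
    depth[ma] <- depth[firsts][map]
    ndepth[ma] <- ndepth[firsts][map]
  }
  data.frame(
    key = truth$key, tumour_depth = depth, tumour_alt = alt,
    normal_depth = ndepth, normal_alt = as.integer(nalt),
    vaf_override = ifelse(low_vaf, stats::runif(n, 0.002, 0.008), NA_real_),
    stringsAsFactors = FALSE
  )
}

# one callset per caller for one component
.caller_callsets <- function(truth, reads, component, config, reference) {
  present <- truth[[paste0("in_", component)]]
  cp <- config$caller_profiles
  site <- paste(truth$chrom, truth$pos, truth$ref) # multiallelic pairs share
  out <- list()
  for (i in seq_len(nrow(cp))) {
    caller <- cp$caller[i]
    eligible <- present & (cp$calls_indels[i] | !truth$is_indel)
    u_site <- unique(site[eligible])
    det_site <- u_site[stats::runif(length(u_site)) < cp$sensitivity[i]]
    idx <- which(eligible & site %in% det_site & reads$tumour_alt >= 1L)
    df <- data.frame(
      chrom = truth$chrom[idx], pos = truth$pos[idx], ref = truth$ref[idx],
      alt = truth$alt[idx], caller = caller, filter = "PASS",
      tumour_depth = reads$tumour_depth[idx],
      tumour_alt = reads$tumour_alt[idx],
      normal_depth = reads$normal_depth[idx],
      normal_alt = reads$normal_alt[idx],
      vaf = NA_real_, pop_af = truth$pop_af[idx],
      func_class = truth$func_class[idx], gene = truth$gene[idx],
      multiallelic = truth$multiallelic[idx], stringsAsFactors = FALSE
    )
    if (cp$reports_vaf[i] && nrow(df)) {
      raw <- df$tumour_alt / pmax(df$tumour_depth, 1L)
      df$vaf <- clip01(raw + stats::rnorm(nrow(df), 0, cp$vaf_noise_sd[i]))
      ovr <- reads$vaf_override[idx]
      df$vaf[!is.na(ovr)] <- ovr[!is.na(ovr)]
    }
    # caller-private false positives: tumour-only alt support, truth VAF 0
    fp <- .caller_fp(reference, cp$fp_count[i], caller, config,
                     reports_vaf = cp$reports_vaf[i], filter = "PASS",
                     taken = paste(truth$chrom, truth$pos))
    lq <- .caller_fp(reference, config$n_lowqual, caller, config,
                     reports_vaf = cp$reports_vaf[i], filter = "LowQual",
                     taken = paste(truth$chrom, truth$pos))
    df <- rbind(df, fp, lq)
    # strelka2-like caller emits right-shifted indel representations;
    # consensus must reconcile them through normalization
    if (caller == "strelka2") df <- shift_right_variants(df, reference)
    df <- df[order(df$chrom, df$pos, df$alt), , drop = FALSE]
    rownames(df) <- NULL
    out[[caller]] <- df
  }
  out
}

.caller_fp <- function(reference, n, caller, config, reports_vaf, filter,
                       taken) {
  if (n == 0L) {
    return(NULL)
  }
  s <- .random_sites(reference, n, taken = taken)
  base <- unname(mapply(function(cc, pp) ref_seq(reference, cc, pp),
                        s$chrom, s$pos))
  alt <- vapply(base, function(b) sample(setdiff(DNA_BASES, b), 1L),
                character(1))
  depth <- stats::rpois(n, config$mean_depth_tumour)
  talt <- sample(1:6, n, replace = TRUE)
  data.frame(
    chrom = s$chrom, pos = s$pos, ref = base, alt = unname(alt),
    caller = caller, filter = filter,
    tumour_depth = pmax(depth, talt), tumour_alt = talt,
    normal_depth = stats::rpois(n, config$mean_depth_normal),
    normal_alt = 0L,
    vaf = if (reports_vaf) talt / pmax(depth, talt) else NA_real_,
    pop_af = 0, func_class = "intergenic", gene = NA_character_,
    multiallelic = FALSE, stringsAsFactors = FALSE
  )
}

# truth rows for caller-private FP/LowQual records (normalized keys so the
# truth table matches what consensus building sees)
.collect_fp_truth <- function(callsets, truth, genes) {
  seen <- truth$key
  rows <- list()
  for (cc in names(callsets)) {
    for (caller in names(callsets[[cc]])) {
      df <- callsets[[cc]][[caller]]
      key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
      new <- !(key %in% seen) & !duplicated(key)
      if (!any(new)) next
      nd <- df[new, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        key = key[new], chrom = nd$chrom, pos = nd$pos, ref = nd$ref,
        alt = nd$alt, class = variant_class(nd$ref, nd$alt),
        label = "false_positive", channel = NA_character_,
        in_Neg = FALSE, in_Abr = FALSE, true_vaf_Neg = 0, true_vaf_Abr = 0,
        gene = nd$gene, func_class = nd$func_class, pop_af = nd$pop_af,
        multiallelic = nd$multiallelic, stringsAsFactors = FALSE
      )
      seen <- c(seen, key[new])
    }
  }
  if (!length(rows)) {
    return(truth[0L, .truth_cols()])
  }
  do.call(rbind, rows)
}

#' @export
print.hp_simulation <- function(x, ...) {
  tr <- table(x$truth$label)
  cat("hp_simulation:", nrow(x$truth), "distinct variants\n")
  print(tr)
  invisible(x)
}

#' True consensus keys for one component
#'
#' Keys of variants genuinely present in a component (truncal, private or
#' subclonal; excludes every false-positive class), the oracle against which
#' recovered callsets are scored.
#'
#' @param sim An `hp_simulation`.
#' @param component `"Neg"` or `"Abr"`.
#' @param class Optional `"SNV"` or `"indel"` restriction.
#' @return Character vector of variant keys.
#' @export
true_component_keys <- function(sim, component, class = NULL) {
  tr <- sim$truth
  keep <- tr[[paste0("in_", component)]] & tr$label != "false_positive"
  if (!is.null(class)) keep <- keep & tr$class == class
  tr$key[keep]
}
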