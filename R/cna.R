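# Allele-specific copy number at the gene level. Segments (from an
# ASCAT-like caller, purity-corrected upstream) are mapped to genes; a gene
# crossing several segments takes the one covering the largest number of
# its bases (ties to the lower-coordinate segment). Copy-number states are
# interpreted relative to tumour ploidy, so total CN 4 at ploidy 4 is
# neutral -- with LOH if the minor allele count is zero.

#' Ploidy-adjusted effective copy-number state
#'
#' Classifies a total copy number by its ratio `r = total_cn / ploidy`:
#' `r < loss` is a loss, `r < gain` neutral, `r < amplification` a gain,
#' and anything above an amplification. At ploidy 2 the defaults reduce to
#' conventional diploid calls (0-1 loss, 2 neutral, 3 gain, >= 4
#' amplification).
#'
#' @param total_cn Non-negative integer vector.
#' @param ploidy Positive tumour ploidy (scalar or vector).
#' @param thresholds Named ratio cut-points `c(loss=, gain=, amplification=)`;
#'   each class is `[lower, upper)`.
#' @return Character vector: `"loss"`, `"neutral"`, `"gain"` or
#'   `"amplification"`.
#' @export
#' @examples
#' effective_copy_state(4, ploidy = 4) # neutral
#' effective_copy_state(1, ploidy = 2) # loss
effective_copy_state <- function(total_cn, ploidy,
                                 thresholds = c(loss = 0.75, gain = 1.25,
                                                amplification = 2)) {
  if (any(total_cn < 0)) stop("total_cn must be non-negative")
  stopifnot(all(ploidy > 0),
            all(c("loss", "gain", "amplification") %in% names(thresholds)))
  r <- total_cn / ploidy
  ifelse(r < thresholds[["loss"]], "loss",
         ifelse(r < thresholds[["gain"]], "neutral",
                ifelse(r < thresholds[["amplification"]], "gain",
                       "amplification")))
}

#' Assign copy-number segments to genes and derive per-gene states
#'
#' Every gene overlapping at least one segment is assigned exactly one: the
#' segment with the largest overlapped base count (`overlap_unit = "bases"`)
#' or largest overlapped fraction of the gene (`"fraction"`); exact ties go
#' to the segment with the lower start coordinate. Genes with no overlap
#' are reported with `covered = FALSE`. Overlapping segments within the
#' input are an error.
#'
#' @param segments data.frame: `chrom`, `start`, `end` (1-based inclusive),
#'   `total_cn`, `minor_cn`; optionally `ploidy` (else supply via `ploidy`).
#' @param genes data.frame: `gene`, `chrom`, `start`, `end`.
#' @param ploidy Tumour ploidy used for the effective state; defaults to a
#'   `ploidy` column in `segments`, else 2.
#' @param thresholds Passed to [effective_copy_state()].
#' @param overlap_unit `"bases"` (default) or `"fraction"`.
#' @return data.frame per gene: assigned segment coordinates, `total_cn`,
#'   `minor_cn`, `effective_state`, `loh` (`minor_cn == 0` and
#'   `total_cn > 0`), `covered`.
#' @export
assign_segments_to_genes <- function(segments, genes, ploidy = NULL,
                                     thresholds = c(loss = 0.75, gain = 1.25,
                                                    amplification = 2),
                                     overlap_unit = c("bases", "fraction")) {
  overlap_unit <- match.arg(overlap_unit)
  stopifnot(all(segments$start <= segments$end),
            all(segments$minor_cn <= segments$total_cn),
            all(segments$minor_cn >= 0))
  if (is.null(ploidy)) {
    ploidy <- if ("ploidy" %in% names(segments)) segments$ploidy[1L] else 2
  }
  sgr <- GenomicRanges::GRanges(segments$chrom,
                                IRanges::IRanges(segments$start,
                                                 segments$end))
  self <- GenomicRanges::findOverlaps(sgr, sgr)
  if (length(self) > length(sgr)) {
    stop("segments overlap within one sample")
  }
  ggr <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$start, genes$end))
  hits <- GenomicRanges::findOverlaps(ggr, sgr)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- BiocGenerics::width(IRanges::pintersect(
    IRanges::ranges(ggr)[qh], IRanges::ranges(sgr)[sh]))
  score <- if (overlap_unit == "bases") {
    ov
  } else {
    ov / (genes$end - genes$start + 1)[qh]
  }
  assigned <- rep(NA_integer_, nrow(genes))
  if (length(qh)) {
    ord <- order(qh, -score, segments$start[sh], method = "radix")
    first <- !duplicated(qh[ord])
    assigned[qh[ord][first]] <- sh[ord][first]
  }
  covered <- !is.na(assigned)
  out <- data.frame(
    gene = genes$gene, chrom = genes$chrom, gene_start = genes$start,
    gene_end = genes$end, covered = covered,
    seg_start = ifelse(covered, segments$start[assigned], NA_integer_),
    seg_end = ifelse(covered, segments$end[assigned], NA_integer_),
    total_cn = ifelse(covered, segments$total_cn[assigned], NA_integer_),
    minor_cn = ifelse(covered, segments$minor_cn[assigned], NA_integer_),
    stringsAsFactors = FALSE
  )
  out$effective_state <- NA_character_
  out$effective_state[covered] <- effective_copy_state(
    out$total_cn[covered], ploidy, thresholds)
  out$loh <- out$minor_cn == 0L & out$total_cn > 0L
  out
}

#' Genes with discordant copy-number state between components
#'
#' Joins the two per-gene state tables and returns the genes whose
#' effective state or LOH status differs. Genes uncovered in either
#' component are excluded from the comparison and listed in the
#' `uncovered` attribute.
#'
#' @param neg,abr Outputs of [assign_segments_to_genes()] for the two
#'   components (same gene universe).
#' @return data.frame with per-component state and LOH columns, one row per
#'   discordant gene; attribute `uncovered` names genes skipped for missing
#'   coverage.
#' @export
differential_gene_states <- function(neg, abr) {
  stopifnot(setequal(neg$gene, abr$gene))
  abr <- abr[match(neg$gene, abr$gene), , drop = FALSE]
  both <- neg$covered & abr$covered
  discord <- both & (neg$effective_state != abr$effective_state |
                       neg$loh != abr$loh)
  out <- data.frame(
    gene = neg$gene[discord], chrom = neg$chrom[discord],
    state_neg = neg$effective_state[discord],
    state_abr = abr$effective_state[discord],
    loh_neg = neg$loh[discord], loh_abr = abr$loh[discord],
    total_cn_neg = neg$total_cn[discord], total_cn_abr = abr$total_cn[discord],
    minor_cn_neg = neg$minor_cn[discord], minor_cn_abr = abr$minor_cn[discord],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "uncovered") <- neg$gene[!both]
  out
}

#' Read a copy-number segment table from TSV or BED
#'
#' TSV input is 1-based inclusive (`chrom`, `start`, `end`, `total_cn`,
#' `minor_cn`, optionally `purity`, `ploidy`). BED input is 0-based
#' half-open and is converted to 1-based inclusive at this boundary
#' (`start + 1`, `end` unchanged); columns 4-5 are taken as
#' `total_cn`/`minor_cn`.
#'
#' @param path File path.
#' @param format `"tsv"` (headered) or `"bed"` (headerless).
#' @return data.frame in the package's 1-based inclusive convention.
#' @export
read_segment_table <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    seg <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "total_cn", "minor_cn")
    miss <- setdiff(need, names(seg))
    if (length(miss)) {
      stop("segment TSV lacks column(s): ", paste(miss, collapse = ", "))
    }
  } else {
    seg <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(seg) < 5L) stop("segment BED needs 5 columns")
    names(seg)[1:5] <- c("chrom", "start", "end", "total_cn", "minor_cn")
    seg$start <- seg$start + 1L # 0-based half-open -> 1-based inclusive
  }
  seg$start <- as.integer(seg$start); seg$end <- as.integer(seg$end)
  stopifnot(all(seg$start <= seg$end))
  seg
}

#' Write a segment table as BED (converting back to 0-based half-open)
#' @param segments data.frame in 1-based inclusive coordinates.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segment_bed <- function(segments, path) {
  out <- data.frame(segments$chrom, segments$start - 1L, segments$end,
                    segments$total_cn, segments$minor_cn)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Simulate allele-specific copy-number segment tables for both components
#'
#' Tiles every contig with non-overlapping segments at the component's
#' baseline copy number (total = round(ploidy), minor = floor(ploidy / 2))
#' and carves out dedicated segments for planted events (`config$cna_events`:
#' gene, component, total_cn, minor_cn), so a loss or copy-neutral LOH can
#' be placed on a named locus in one component only.
#'
#' @param config A [simulation_config()]; uses `ploidy`, `purity` and
#'   `cna_events`. Consumes the current RNG stream (call after `set.seed`
#'   or within a pipeline run).
#' @param reference A `hp_reference`.
#' @param genes Gene table (see [simulate_genes()]).
#' @return List with per-component segment data.frames (`chrom`, `start`,
#'   `end`, `total_cn`, `minor_cn`, `purity`, `ploidy`) and `truth` (the
#'   planted events).
#' @export
simulate_cna_segments <- function(config, reference, genes) {
  lens <- ref_lengths(reference)
  out <- list()
  for (comp in c("Neg", "Abr")) {
    pl <- config$ploidy[[comp]]
    base_total <- max(1L, round(pl))
    base_minor <- max(0L, floor(pl / 2))
    ev <- config$cna_events
    ev <- if (is.null(ev)) NULL else ev[ev$component == comp, , drop = FALSE]
    segs <- lapply(names(lens), function(chrom) {
      # random interior breakpoints so genes span segment boundaries
      n_break <- max(1L, round(lens[[chrom]] / 80000))
      brk <- sort(sample.int(lens[[chrom]] - 2L, n_break) + 1L)
      bounds <- unique(c(1L, brk, lens[[chrom]] + 1L))
      df <- data.frame(
        chrom = chrom, start = bounds[-length(bounds)],
        end = bounds[-1L] - 1L, total_cn = base_total,
        minor_cn = base_minor, stringsAsFactors = FALSE
      )
      if (!is.null(ev) && nrow(ev)) {
        here <- merge(ev, genes, by = "gene")
        here <- here[here$chrom == chrom, , drop = FALSE]
        for (i in seq_len(nrow(here))) {
          df <- .carve_segment(df, here$start[i], here$end[i],
                               here$total_cn[i], here$minor_cn[i])
        }
      }
      df
    })
    df <- do.call(rbind, segs)
    df$purity <- config$purity[[comp]]
    df$ploidy <- pl
    rownames(df) <- NULL
    out[[comp]] <- df
  }
  out$truth <- config$cna_events
  out
}

# replace the part of a segment tiling covered by [start, end] with a
# dedicated segment carrying the planted copy numbers
.carve_segment <- function(df, start, end, total_cn, minor_cn) {
  keep <- df[df$end < start | df$start > end, , drop = FALSE]
  cut <- df[!(df$end < start | df$start > end), , drop = FALSE]
  pieces <- list()
  for (i in seq_len(nrow(cut))) {
    if (cut$start[i] < start) {
      left <- cut[i, , drop = FALSE]; left$end <- start - 1L
      pieces[[length(pieces) + 1L]] <- left
    }
    if (cut$end[i] > end) {
      right <- cut[i, , drop = FALSE]; right$start <- end + 1L
      pieces[[length(pieces) + 1L]] <- right
    }
  }
  planted <- cut[1L, , drop = FALSE]
  planted$start <- start; planted$end <- end
  planted$total_cn <- total_cn; planted$minor_cn <- minor_cn
  out <- rbind(keep, do.call(rbind, pieces), planted)
  out[order(out$start), , drop = FALSE]
}
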