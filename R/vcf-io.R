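# VCF round trip. The simulator writes one VCFv4.2 per caller per component
# (tumour + normal sample columns, AD/DP/AF FORMAT fields, population AF and
# functional class as INFO); parsing goes through VariantAnnotation so real
# caller output is handled the same way as simulated files.

#' Write a caller callset as VCFv4.2
#'
#' Multiallelic rows (same chrom/pos/ref, several ALTs) are merged into one
#' record with comma-separated ALT alleles and per-allele AD/AF entries.
#'
#' @param calls data.frame as produced by the simulator (columns `chrom`,
#'   `pos`, `ref`, `alt`, `filter`, read counts, `vaf`, `pop_af`,
#'   `func_class`, `gene`, `multiallelic`).
#' @param path Output path (`.vcf`).
#' @param reference `hp_reference` supplying contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_caller_vcf <- function(calls, path, reference) {
  lens <- ref_lengths(reference)
  has_af <- any(!is.na(calls$vaf))
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", names(lens), ",length=", unname(lens), ">"),
    "##FILTER=<ID=LowQual,Description=\"Low quality call\">",
    "##INFO=<ID=POPAF,Number=1,Type=Float,Description=\"Population allele frequency\">",
    "##INFO=<ID=FCLASS,Number=1,Type=String,Description=\"Functional annotation class\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    if (has_af) "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR\tNORMAL"
  )
  fmt <- if (has_af) "AD:DP:AF" else "AD:DP"
  calls <- calls[order(calls$chrom, calls$pos, calls$alt), , drop = FALSE]
  site <- paste(calls$chrom, calls$pos, calls$ref, sep = "\r")
  body <- vapply(unique(site), function(s) {
    rows <- calls[site == s, , drop = FALSE]
    alt <- paste(rows$alt, collapse = ",")
    dp <- rows$tumour_depth[1L]
    t_ad <- paste(c(max(dp - sum(rows$tumour_alt), 0L), rows$tumour_alt),
                  collapse = ",")
    ndp <- rows$normal_depth[1L]
    n_ad <- paste(c(max(ndp - sum(rows$normal_alt), 0L), rows$normal_alt),
                  collapse = ",")
    info <- paste0(
      "POPAF=", format(rows$pop_af[1L], scientific = FALSE, digits = 6),
      ";FCLASS=", rows$func_class[1L],
      ";GENE=", ifelse(is.na(rows$gene[1L]), ".", rows$gene[1L])
    )
    t_field <- paste0(t_ad, ":", dp)
    n_field <- paste0(n_ad, ":", ndp)
    if (has_af) {
      af <- paste(format(round(ifelse(is.na(rows$vaf), 0, rows$vaf), 5),
                         scientific = FALSE, trim = TRUE), collapse = ",")
      n_af <- paste(rep("0", nrow(rows)), collapse = ",")
      t_field <- paste0(t_field, ":", af)
      n_field <- paste0(n_field, ":", n_af)
    }
    paste(rows$chrom[1L], rows$pos[1L], ".", rows$ref[1L], alt, ".",
          rows$filter[1L], info, fmt, t_field, n_field, sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write all simulated artifacts of a mutation simulation to disk
#'
#' Emits the reference FASTA (+ .fai), one VCF per caller per component
#' (named `<component>.<caller>.vcf`), the gene table and the truth table.
#'
#' @param sim An `hp_simulation`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(reference = file.path(dir, "reference.fa"))
  write_reference(sim$reference, paths$reference)
  for (comp in names(sim$callsets)) {
    for (caller in names(sim$callsets[[comp]])) {
      p <- file.path(dir, paste0(comp, ".", caller, ".vcf"))
      write_caller_vcf(sim$callsets[[comp]][[caller]], p, sim$reference)
      paths[[paste0(comp, "_", caller)]] <- p
    }
  }
  paths$genes <- file.path(dir, "genes.tsv")
  utils::write.table(sim$genes, paths$genes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$truth <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Read one caller's somatic VCF into the unified call model
#'
#' Parses a VCFv4.2 file (plain or bgzipped) with identifiable tumour and
#' normal sample columns, keeps `FILTER == PASS` records only, and emits one
#' row per ALT allele; records with several ALT alleles are expanded and
#' flagged `multiallelic`. AD and DP FORMAT fields are required (a missing
#' field is an error naming it); AF is used when present, otherwise the VAF
#' is left `NA` for downstream fallback.
#'
#' @param path VCF file.
#' @param caller Caller label recorded in the output.
#' @param tumour_sample,normal_sample Sample column names.
#' @param reference Optional `hp_reference`; when supplied, record contigs
#'   are checked against it (unknown contig is an error).
#' @return data.frame of variant calls (same shape as simulator callsets).
#' @export
read_caller_vcf <- function(path, caller,
                            tumour_sample = "TUMOR",
                            normal_sample = "NORMAL",
                            reference = NULL) {
  vcf <- VariantAnnotation::readVcf(path)
  smp <- colnames(vcf)
  for (s in c(tumour_sample, normal_sample)) {
    if (!s %in% smp) stop("sample column '", s, "' not present in ", path)
  }
  gfields <- rownames(VariantAnnotation::geno(VariantAnnotation::header(vcf)))
  for (f in c("AD", "DP")) {
    if (!f %in% gfields) {
      stop("required FORMAT field '", f, "' missing from ", path)
    }
  }
  nalt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))
  multi <- rep(nalt > 1L, nalt)
  evcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(evcf)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  if (!is.null(reference)) {
    unknown <- setdiff(unique(chrom), names(ref_lengths(reference)))
    if (length(unknown)) {
      stop("unknown contig in ", path, ": ", paste(unknown, collapse = ", "))
    }
  }
  filt <- VariantAnnotation::filt(evcf)
  keep <- filt == "PASS"
  g <- VariantAnnotation::geno(evcf)
  ad_mat <- g$AD
  get_ad <- function(sample, slot) {
    if (is.array(ad_mat) && length(dim(ad_mat)) == 3L) {
      as.integer(ad_mat[, sample, slot])
    } else {
      vapply(ad_mat[, sample], function(x) as.integer(x[slot]), integer(1))
    }
  }
  # expand() trims Number=R fields to (ref, this alt)
  tumour_alt <- get_ad(tumour_sample, 2L)
  normal_alt <- get_ad(normal_sample, 2L)
  dp <- g$DP
  af <- if ("AF" %in% names(g)) {
    a <- g$AF[, tumour_sample]
    if (is.list(a)) vapply(a, function(x) as.numeric(x[1L]), numeric(1))
    else as.numeric(a)
  } else {
    rep(NA_real_, length(chrom))
  }
  inf <- VariantAnnotation::info(evcf)
  grab_info <- function(name, default) {
    if (name %in% names(inf)) {
      v <- inf[[name]]
      if (inherits(v, "List") || is.list(v)) {
        v <- vapply(v, function(x) if (length(x)) x[1L] else default,
                    default)
      }
      v
    } else {
      rep(default, length(chrom))
    }
  }
  func_class <- as.character(grab_info("FCLASS", NA_character_))
  gene <- as.character(grab_info("GENE", NA_character_))
  gene[gene == "."] <- NA_character_
  out <- data.frame(
    chrom = chrom,
    pos = BiocGenerics::start(rr),
    ref = as.character(VariantAnnotation::ref(evcf)),
    alt = as.character(VariantAnnotation::alt(evcf)),
    caller = caller, filter = as.character(filt),
    tumour_depth = as.integer(dp[, tumour_sample]),
    tumour_alt = tumour_alt,
    normal_depth = as.integer(dp[, normal_sample]),
    normal_alt = normal_alt,
    vaf = af,
    pop_af = as.numeric(grab_info("POPAF", NA_real_)),
    func_class = func_class, gene = gene,
    multiallelic = multi, stringsAsFactors = FALSE
  )
  bad <- out$tumour_alt > out$tumour_depth | out$normal_alt > out$normal_depth
  if (any(bad, na.rm = TRUE)) {
    stop("alt count exceeds depth at ",
         paste(out$chrom[bad], out$pos[bad], sep = ":", collapse = ", "))
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
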