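# Reference signature catalogue: a 96 x S matrix of channel probabilities
# with one column per mutational process. A synthetic stand-in for the
# breast-cancer SBS set is bundled (see `synthetic_signature_catalog`);
# any real COSMIC TSV can be loaded with `load_signature_catalog`.

# build one signature column from peaked channels + per-class mass + flat
# background; masses must sum to <= 1, the background takes the remainder
.sig_column <- function(channels, peaks = NULL, classes = NULL) {
  w <- stats::setNames(numeric(length(channels)), channels)
  used <- 0
  if (!is.null(peaks)) {
    stopifnot(all(names(peaks) %in% channels))
    w[names(peaks)] <- w[names(peaks)] + peaks
    used <- used + sum(peaks)
  }
  if (!is.null(classes)) {
    for (cl in names(classes)) {
      idx <- grepl(paste0("[", cl, "]"), channels, fixed = TRUE)
      w[idx] <- w[idx] + classes[[cl]] / sum(idx)
      used <- used + classes[[cl]]
    }
  }
  stopifnot(used <= 1 + 1e-12)
  w + (1 - used) / length(channels)
}

#' Synthetic 12-signature breast-cancer-like SBS catalogue
#'
#' A deterministically constructed, synthetic stand-in for the twelve
#' single-base-substitution signatures commonly reported in breast cancer.
#' Each column reproduces the qualitative channel concentration of the
#' process it is named after -- SBS1 is dominated by `C>T` at NpCpG sites
#' (5-methylcytosine deamination), SBS2 and SBS13 by `C>T` and `C>G` at
#' TpCpN sites (APOBEC cytidine-deaminase activity), SBS5 is a flat
#' clock-like mix of `C>T` and `T>C`, SBS3 is near-featureless, and so on --
#' but the numeric values are NOT the COSMIC estimates. The catalogue exists
#' so signature construction, cosine-similarity comparison and mixture
#' recovery can be exercised end to end without external downloads; swap in
#' a real catalogue via [load_signature_catalog()] for production use.
#'
#' @return A 96 x 12 numeric matrix; rownames are the channels of
#'   [sbs_channels()], colnames `SBS1 ... SBS30`. Every column sums to 1.
#' @export
#' @examples
#' cat <- synthetic_signature_catalog()
#' colSums(cat)
synthetic_signature_catalog <- function() {
  ch <- sbs_channels()
  tcn_t <- paste0("T[C>T]", DNA_BASES) # APOBEC C>T peaks, 3' base order A,C,G,T
  tcn_g <- paste0("T[C>G]", DNA_BASES)
  sigs <- list(
    SBS1 = .sig_column(ch,
      peaks = stats::setNames(rep(0.19, 4), paste0(DNA_BASES, "[C>T]G")),
      classes = c("C>T" = 0.12)),
    SBS2 = .sig_column(ch,
      peaks = stats::setNames(c(0.36, 0.12, 0.08, 0.30), tcn_t)),
    SBS3 = .sig_column(ch, classes = c("C>A" = 0.10, "C>T" = 0.10, "T>C" = 0.10)),
    SBS5 = .sig_column(ch, classes = c("C>T" = 0.30, "T>C" = 0.35)),
    SBS6 = .sig_column(ch,
      peaks = stats::setNames(rep(0.09, 4), paste0("G[C>T]", DNA_BASES)),
      classes = c("C>T" = 0.28)),
    SBS8 = .sig_column(ch, classes = c("C>A" = 0.55, "C>T" = 0.15)),
    SBS13 = .sig_column(ch,
      peaks = stats::setNames(c(0.30, 0.12, 0.08, 0.34), tcn_g)),
    SBS17 = .sig_column(ch,
      peaks = c("C[T>G]T" = 0.25, "A[T>G]T" = 0.20, "T[T>G]T" = 0.15,
                "G[T>G]T" = 0.10)),
    SBS18 = .sig_column(ch,
      peaks = c("C[C>A]A" = 0.15, "C[C>A]T" = 0.12, "G[C>A]A" = 0.10),
      classes = c("C>A" = 0.33)),
    SBS20 = .sig_column(ch, classes = c("C>A" = 0.30, "C>T" = 0.30)),
    SBS26 = .sig_column(ch, classes = c("T>C" = 0.60)),
    SBS30 = .sig_column(ch, classes = c("C>T" = 0.60))
  )
  mat <- do.call(cbind, sigs)
  rownames(mat) <- ch
  mat
}

#' Path to the bundled synthetic signature catalogue TSV
#' @return File path inside the installed package.
#' @export
synthetic_catalog_path <- function() {
  system.file("extdata", "signatures_synthetic_breast12.tsv",
              package = "hetpair", mustWork = TRUE)
}

#' Load a 96 x S signature catalogue from TSV
#'
#' Accepts either a simple layout (first column the channel label
#' `"A[C>T]G"`, remaining columns one signature each) or the COSMIC v2
#' layout (columns `Substitution Type`, `Trinucleotide`,
#' `Somatic Mutation Type`, then signatures). Rows are reordered to the
#' canonical channel order and every column is checked to sum to 1.
#'
#' @param path TSV file; defaults to the bundled synthetic catalogue.
#' @param tol Tolerance on each column sum.
#' @return Numeric 96 x S matrix with channel rownames; the file's MD5
#'   checksum is attached as attribute `"checksum"` so downstream reports
#'   can pin the catalogue version.
#' @export
load_signature_catalog <- function(path = synthetic_catalog_path(),
                                   tol = 1e-6) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if ("Somatic Mutation Type" %in% names(tab)) {
    channels <- tab[["Somatic Mutation Type"]]
    drop <- names(tab) %in% c("Substitution Type", "Trinucleotide",
                              "Somatic Mutation Type")
    tab <- tab[, !drop, drop = FALSE]
  } else {
    channels <- tab[[1L]]
    tab <- tab[, -1L, drop = FALSE]
  }
  # some COSMIC exports carry trailing empty columns
  tab <- tab[, vapply(tab, function(x) !all(is.na(x)), logical(1)), drop = FALSE]
  if (length(channels) != 96L || anyDuplicated(channels) ||
      !setequal(channels, sbs_channels())) {
    stop("catalogue must contain exactly the 96 canonical channels; got ",
         length(channels), " rows")
  }
  mat <- as.matrix(tab)
  storage.mode(mat) <- "double"
  rownames(mat) <- channels
  mat <- mat[sbs_channels(), , drop = FALSE]
  sums <- colSums(mat)
  off <- abs(sums - 1) > tol
  if (any(off)) {
    stop("catalogue columns do not sum to 1: ",
         paste(colnames(mat)[off], collapse = ", "))
  }
  attr(mat, "checksum") <- unname(tools::md5sum(path))
  mat
}
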