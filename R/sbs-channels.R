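# 96-channel single-base-substitution machinery: channel ordering, strand
# folding, trinucleotide handling. Channel order follows the COSMIC
# convention: substitution class major (C>A, C>G, C>T, T>A, T>C, T>G), then
# 5' base, then 3' base, both alphabetical, so real COSMIC catalogue TSVs
# can be loaded unmodified.

SBS_SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
DNA_BASES <- c("A", "C", "G", "T")

#' The 96 single-base-substitution channels in canonical order
#'
#' Channels are pyrimidine-centred trinucleotide contexts written as
#' `"A[C>T]G"`: the flanking 5' and 3' bases around one of the six
#' substitution classes `C>A, C>G, C>T, T>A, T>C, T>G`. Ordering is
#' substitution class major, then 5' base, then 3' base (alphabetical),
#' matching the layout of COSMIC signature tables.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(sbs_channels())
sbs_channels <- function() {
  unlist(lapply(SBS_SUBSTITUTIONS, function(sub) {
    unlist(lapply(DNA_BASES, function(p5) {
      paste0(p5, "[", sub, "]", DNA_BASES)
    }))
  }))
}

# complement of a vector of single bases (or strings via chartr)
dna_complement <- function(x) chartr("ACGT", "TGCA", x)

# reverse complement of trinucleotide strings, vectorised
revcomp_trinuc <- function(tri) {
  paste0(
    dna_complement(substr(tri, 3L, 3L)),
    dna_complement(substr(tri, 2L, 2L)),
    dna_complement(substr(tri, 1L, 1L))
  )
}

#' Fold substitutions onto the pyrimidine strand
#'
#' Substitutions whose reference base is a purine (A or G) are replaced by
#' their reverse complement so every substitution is expressed with a C or T
#' reference, the convention used for substitution spectra and SBS profiles.
#' Folding is an involution restricted to its image: applying it twice
#' equals applying it once.
#'
#' @param ref,alt Character vectors of single reference/alternate bases.
#' @param context Optional character vector of trinucleotides centred on the
#'   substituted base; folded alongside `ref`/`alt` when supplied.
#' @return A data.frame with columns `ref`, `alt` and (when `context` was
#'   given) `context`, plus `channel` (`"A[C>T]G"` style) when context is
#'   available.
#' @export
fold_pyrimidine <- function(ref, alt, context = NULL) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  bad <- !(ref %in% DNA_BASES)
  if (any(bad)) {
    stop("reference allele is not A/C/G/T at entries: ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  flip <- ref %in% c("A", "G")
  out <- data.frame(
    ref = ifelse(flip, dna_complement(ref), ref),
    alt = ifelse(flip, dna_complement(alt), alt),
    stringsAsFactors = FALSE
  )
  if (!is.null(context)) {
    context <- toupper(context)
    out$context <- ifelse(flip, revcomp_trinuc(context), context)
    out$channel <- paste0(
      substr(out$context, 1L, 1L), "[", out$ref, ">", out$alt, "]",
      substr(out$context, 3L, 3L)
    )
  }
  out
}

# map folded trinucleotide context (pyrimidine-centred) to its 32 context id;
# every genomic position belongs to exactly one folded context
fold_context_only <- function(tri) {
  centre <- substr(tri, 2L, 2L)
  flip <- centre %in% c("A", "G")
  ifelse(flip, revcomp_trinuc(tri), tri)
}
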