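# Synthetic reference sequence used to place simulated mutations. A handful
# of megabase-scale contigs is plenty: trinucleotide contexts are what
# matter, not genome content. The folded-context position index is built
# lazily and cached on the object, since signature-conditioned placement
# needs fast lookup of "all positions whose context is T[C]A" etc.

#' Simulate a small reference genome
#'
#' Draws i.i.d. bases at roughly human GC content and wraps them as a
#' `hp_reference`. Intended as the placement substrate for
#' [simulate_mutation_set()]; real analyses pass an on-disk FASTA through
#' [load_reference()] instead.
#'
#' @param seed Integer seed for the reference draw (independent of the
#'   mutation-simulation seed so one reference can serve many simulations).
#' @param n_contigs Number of contigs.
#' @param contig_length Length of each contig in bp.
#' @param gc GC content of the drawn sequence.
#' @return An object of class `hp_reference`.
#' @export
#' @examples
#' ref <- simulate_reference(seed = 1, n_contigs = 2, contig_length = 1e4)
#' ref_lengths(ref)
simulate_reference <- function(seed = 1L, n_contigs = 5L,
                               contig_length = 200000L, gc = 0.41) {
  stopifnot(n_contigs >= 1L, contig_length >= 100L, gc > 0, gc < 1)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- withr::with_seed(seed, {
    lapply(seq_len(n_contigs), function(i) {
      paste(sample(DNA_BASES, contig_length, replace = TRUE, prob = probs),
            collapse = "")
    })
  })
  names(seqs) <- paste0("chr", seq_len(n_contigs))
  new_hp_reference(Biostrings::DNAStringSet(unlist(seqs)))
}

new_hp_reference <- function(dss) {
  structure(
    list(seq = dss, cache = new.env(parent = emptyenv())),
    class = "hp_reference"
  )
}

#' @export
print.hp_reference <- function(x, ...) {
  cat("hp_reference:", length(x$seq), "contigs,",
      sum(Biostrings::width(x$seq)), "bp total\n")
  invisible(x)
}

#' Contig lengths of a reference
#' @param ref A `hp_reference`.
#' @return Named integer vector.
#' @export
ref_lengths <- function(ref) {
  if (is.null(ref$cache$lengths)) {
    ref$cache$lengths <- stats::setNames(Biostrings::width(ref$seq),
                                         names(ref$seq))
  }
  ref$cache$lengths
}

# contig sequence as a plain character string, cached
ref_chars <- function(ref, chrom) {
  key <- paste0("chars_", chrom)
  if (is.null(ref$cache[[key]])) {
    if (!chrom %in% names(ref$seq)) stop("unknown contig: ", chrom)
    ref$cache[[key]] <- as.character(ref$seq[[chrom]])
  }
  ref$cache[[key]]
}

#' Fetch reference bases
#'
#' @param ref A `hp_reference`.
#' @param chrom Contig name (scalar).
#' @param start,end Positive 1-based inclusive positions, vectorised.
#' @return Character vector of sequences.
#' @export
ref_seq <- function(ref, chrom, start, end = start) {
  s <- ref_chars(ref, chrom)
  n <- ref_lengths(ref)[[chrom]]
  if (any(start < 1L) || any(end > n)) {
    stop("coordinates outside contig ", chrom, " (length ", n, ")")
  }
  substring(s, start, end)
}

# trinucleotide context centred on pos (pos must be >= 2 and <= len-1)
ref_context <- function(ref, chrom, pos) ref_seq(ref, chrom, pos - 1L, pos + 1L)

#' Write a reference to FASTA with a samtools-style .fai index
#' @param ref A `hp_reference`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  Biostrings::writeXStringSet(ref$seq, path, width = 70L)
  Rsamtools::indexFa(path)
  invisible(path)
}

#' Load a reference from an on-disk FASTA
#' @param path FASTA file.
#' @return A `hp_reference`.
#' @export
load_reference <- function(path) {
  new_hp_reference(Biostrings::readDNAStringSet(path))
}

# Index of genomic positions by folded trinucleotide context (32 pyrimidine
# centred contexts such as "ACA", "TCG"). Built once per reference and
# cached. Returns list context -> data.frame(chrom, pos).
context_index <- function(ref) {
  if (!is.null(ref$cache$context_index)) return(ref$cache$context_index)
  per_contig <- lapply(names(ref$seq), function(chrom) {
    s <- ref_chars(ref, chrom)
    n <- nchar(s)
    pos <- 2:(n - 1L)
    tri <- substring(s, pos - 1L, pos + 1L)
    folded <- fold_context_only(tri)
    data.table::data.table(chrom = chrom, pos = pos, context = folded)
  })
  dt <- data.table::rbindlist(per_contig)
  idx <- split(dt[, c("chrom", "pos")], dt$context)
  ref$cache$context_index <- idx
  idx
}
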