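#' @useDynLib strainseq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif setNames
#' @importFrom utils read.delim write.table modifyList
NULL

NUC_ALPHABET <- c("A", "C", "G", "T", "N")

#' Normalize a nucleotide sequence
#'
#' Upper-cases, converts RNA `U` to `T` and checks the alphabet. All sequence
#' input into the package passes through this function, so downstream code can
#' assume upper-case `A/C/G/T/N`.
#'
#' @param seq A single character string.
#' @param what Label used in error messages.
#' @return The normalized sequence string.
#' @export
normalize_seq <- function(seq, what = "sequence") {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- chartr("u", "t", seq)
  s <- toupper(s)
  s <- chartr("U", "T", s)
  bad <- gsub("[ACGTN]", "", s)
  if (nzchar(bad)) {
    stop(sprintf("%s contains non-nucleotide characters: '%s'", what,
                 substr(bad, 1, 10)), call. = FALSE)
  }
  s
}

#' Reference gene record
#'
#' Bundles a gene's genomic placement with its forward-genomic-strand
#' sequence. Coordinates are 1-based inclusive, as reported by genome
#' browsers and variant tables. For genes annotated on the complement strand
#' the stored sequence is still the forward strand; strand is resolved only
#' when an imputed sequence is finalized (see [flatten()]).
#'
#' @param symbol Gene symbol.
#' @param chromosome Chromosome name.
#' @param genomic_start,genomic_end 1-based inclusive genomic coordinates.
#' @param strand `"+"` (forward) or `"-"` (complement).
#' @param sequence Forward-strand nucleotide sequence covering
#'   `[genomic_start, genomic_end]`.
#' @return An object of class `reference_gene`.
#' @examples
#' g <- reference_gene("Demo", "chr1", 1001, 1010, "+", "ACGTACGTAA")
#' genomic_to_local(g, 1001)
#' @export
reference_gene <- function(symbol, chromosome, genomic_start, genomic_end,
                           strand = c("+", "-"), sequence) {
  strand <- match.arg(strand)
  genomic_start <- as.integer(genomic_start)
  genomic_end <- as.integer(genomic_end)
  sequence <- normalize_seq(sequence, sprintf("gene %s sequence", symbol))
  if (genomic_end < genomic_start) {
    stop("genomic_end must be >= genomic_start", call. = FALSE)
  }
  if (nchar(sequence) != genomic_end - genomic_start + 1L) {
    stop(sprintf(
      "gene %s: sequence length (%d) does not match coordinates [%d, %d]",
      symbol, nchar(sequence), genomic_start, genomic_end), call. = FALSE)
  }
  structure(
    list(symbol = symbol, chromosome = chromosome,
         genomic_start = genomic_start, genomic_end = genomic_end,
         strand = strand, sequence = sequence),
    class = "reference_gene")
}

#' @export
print.reference_gene <- function(x, ...) {
  cat(sprintf("<reference_gene> %s %s:%d-%d (%s), %d bp\n",
              x$symbol, x$chromosome, x$genomic_start, x$genomic_end,
              x$strand, nchar(x$sequence)))
  invisible(x)
}

#' Transcript (mRNA) record
#'
#' The sense-strand (5'->3') sequence of an mRNA.
#'
#' @param id Transcript identifier.
#' @param sequence Nucleotide sequence.
#' @return An object of class `transcript`.
#' @export
transcript <- function(id, sequence) {
  sequence <- normalize_seq(sequence, sprintf("transcript %s", id))
  if (!nzchar(sequence)) stop("transcript sequence must be non-empty", call. = FALSE)
  structure(list(id = id, sequence = sequence), class = "transcript")
}

#' Reverse complement of a nucleotide string
#'
#' `N` maps to `N`; applying the function twice returns the input.
#'
#' @param seq Nucleotide string over `A/C/G/T/N` (case-insensitive; `U`
#'   accepted and treated as `T`).
#' @return The reverse complement, upper case.
#' @examples
#' reverse_complement("AAGT")  # "ACTT"
#' @export
reverse_complement <- function(seq) {
  s <- normalize_seq(seq)
  if (!nzchar(s)) return(s)
  comp <- chartr("ACGT", "TGCA", s)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Map a genomic coordinate to a local forward-strand index
#'
#' Converts a 1-based genomic position into the 0-based index into the gene's
#' forward-strand sequence. Strand-independent: variant tables report
#' forward-strand positions, and all edits are applied on the forward strand.
#'
#' @param gene A [reference_gene()].
#' @param pos 1-based genomic position(s).
#' @return Integer vector of 0-based indices.
#' @export
genomic_to_local <- function(gene, pos) {
  pos <- as.integer(pos)
  bad <- pos < gene$genomic_start | pos > gene$genomic_end
  if (any(bad)) {
    stop(sprintf(
      "position %d outside gene %s bounds [%d, %d]",
      pos[which(bad)[1]], gene$symbol, gene$genomic_start, gene$genomic_end),
      call. = FALSE)
  }
  pos - gene$genomic_start
}

#' Read sequences from a FASTA file
#'
#' Sequences are upper-cased but not alphabet-checked, so both nucleotide
#' and protein FASTA can be read; nucleotide consumers ([reference_gene()],
#' [transcript()]) normalize and validate on construction.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of upper-case sequences (names are the
#'   full header lines minus `>`).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- names(ss)
  out
}

#' Write sequences to a FASTA file
#'
#' Records are wrapped at 60 columns; headers are `><name>`.
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  ss <- Biostrings::BStringSet(unlist(seqs))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}
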