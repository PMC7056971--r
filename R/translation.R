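# ORF identification and translation. Only ATG starts an ORF; stop codons
# are the standard TAA/TAG/TGA; translation uses NCBI table 1.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Locate the open reading frame of an mRNA
#'
#' Two policies mirror the two ways a predicted transcript is usually read:
#' `"minimize_5utr"` takes the ORF beginning at the very first ATG;
#' `"maximize_orf"` scores the ORF starting at every ATG and returns the
#' longest (ties to the leftmost start). ORF length is measured in
#' nucleotides from the start codon through the stop codon inclusive; an ORF
#' reaching the mRNA end without a stop counts its full remaining length.
#'
#' @param mrna Nucleotide string (non-empty).
#' @param policy `"minimize_5utr"` or `"maximize_orf"`.
#' @return List of class `orf_region`: `start` (0-based index of the A of
#'   ATG), `end` (0-based exclusive; one past the stop codon, or the mRNA
#'   end), `has_stop`.
#' @examples
#' find_orf("CCATGAAATAA", "minimize_5utr")
#' @export
find_orf <- function(mrna, policy = c("minimize_5utr", "maximize_orf")) {
  policy <- match.arg(policy)
  mrna <- normalize_seq(mrna, "mRNA")
  if (!nzchar(mrna)) stop("mRNA is empty", call. = FALSE)
  n <- nchar(mrna)
  starts <- gregexpr("ATG", mrna, fixed = TRUE)[[1]]
  if (starts[1] == -1L) {
    stop("no start codon (ATG) found in mRNA", call. = FALSE)
  }
  starts <- as.integer(starts) - 1L            # 0-based
  ncod <- n - 2L
  cods <- if (ncod >= 1L) substring(mrna, seq_len(ncod), seq_len(ncod) + 2L)
          else character()
  stop_pos <- which(cods %in% STOP_CODONS) - 1L   # 0-based codon start
  orf_of <- function(s) {
    inframe <- stop_pos[stop_pos >= s + 3L & (stop_pos - s) %% 3L == 0L]
    if (length(inframe)) list(start = s, end = inframe[1] + 3L, has_stop = TRUE)
    else list(start = s, end = n, has_stop = FALSE)
  }
  orf <- if (policy == "minimize_5utr") {
    orf_of(starts[1])
  } else {
    cands <- lapply(starts, orf_of)
    lens <- vapply(cands, function(o) o$end - o$start, integer(1))
    cands[[which.max(lens)]]        # which.max returns the leftmost maximum
  }
  structure(orf, class = "orf_region")
}

#' Translate a coding sequence
#'
#' Standard-genetic-code translation of a sequence beginning at its ATG.
#' Stops at the first in-frame stop codon (not emitted); a trailing partial
#' codon is dropped; any codon containing `N` emits `X`.
#'
#' @param orf_seq Nucleotide string starting with `ATG`.
#' @return Amino-acid string.
#' @examples
#' translate_cds("ATGGCC")   # "MA"
#' @export
translate_cds <- function(orf_seq) {
  s <- normalize_seq(orf_seq, "ORF")
  if (substr(s, 1, 3) != "ATG") {
    stop("ORF sequence must start with ATG", call. = FALSE)
  }
  n <- nchar(s) %/% 3L
  if (n == 0L) return("")
  cods <- substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  first_stop <- which(cods %in% STOP_CODONS)
  if (length(first_stop)) cods <- cods[seq_len(first_stop[1] - 1L)]
  if (!length(cods)) return("")
  aa <- Biostrings::GENETIC_CODE[cods]
  aa[is.na(aa)] <- "X"            # ambiguous (N-containing) codons
  paste(aa, collapse = "")
}

#' Predict the protein encoded by an mRNA
#'
#' [find_orf()] followed by [translate_cds()]. When the mRNA contains no ATG
#' an empty protein is returned with a warning.
#'
#' @inheritParams find_orf
#' @return Amino-acid string (possibly empty).
#' @export
predict_protein <- function(mrna, policy = c("minimize_5utr", "maximize_orf")) {
  orf <- tryCatch(find_orf(mrna, policy), error = function(e) NULL)
  if (is.null(orf)) {
    warning("no open reading frame found; returning an empty protein",
            call. = FALSE)
    return("")
  }
  translate_cds(substr(normalize_seq(mrna), orf$start + 1L, orf$end))
}
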