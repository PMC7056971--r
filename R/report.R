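# Pairwise identity statistics and allele-table bookkeeping.

round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Pairwise percent identity from a global alignment
#'
#' Gotoh-aligns two sequences (nucleotide or protein) and reports the count
#' of identical aligned columns out of the total alignment length. Gap
#' columns count in the denominator; percent is rounded half-up to one
#' decimal.
#'
#' @param a,b Sequences.
#' @param params An [alignment_params()] (scoring only).
#' @param band Optional band half-width passed to [gotoh_global()]; required
#'   for pairs whose full DP matrix would exceed `cell_budget`.
#' @param cell_budget Maximum `nchar(a) * nchar(b)` for unbanded alignment.
#' @return Object of class `identity_stats`: `matched`, `total`, `percent`.
#' @examples
#' identity_report("ACGT", "ACTT")   # 3/4 (75.0%)
#' @export
identity_report <- function(a, b, params = alignment_params(), band = NULL,
                            cell_budget = 2.5e7) {
  cells <- as.numeric(nchar(a)) * nchar(b)
  if (is.null(band) && cells > cell_budget) {
    stop(sprintf(
      "alignment needs %.3g DP cells (budget %.3g); supply `band` for long sequences",
      cells, cell_budget), call. = FALSE)
  }
  al <- gotoh_global(a, b, params, band)
  ca <- strsplit(al$a, "", fixed = TRUE)[[1]]
  cb <- strsplit(al$b, "", fixed = TRUE)[[1]]
  total <- length(ca)
  matched <- sum(ca == cb)
  structure(list(matched = matched, total = total,
                 percent = round_half_up(100 * matched / max(1L, total), 1L)),
            class = "identity_stats")
}

#' @export
format.identity_stats <- function(x, ...) {
  sprintf("%d/%d (%s%%)", x$matched, x$total,
          formatC(x$percent, format = "f", digits = 1))
}

#' @export
print.identity_stats <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Read a strain-to-allele assignment table
#'
#' Tab-separated with columns `strain`, `allele`, `previously_reported`
#' (`yes`/`no`) and `reference` (`yes` for the reference strain). The
#' package ships the published aryl-hydrocarbon-receptor (Ahr) assignments
#' for 37 inbred mouse strains in
#' `system.file("extdata", "ahr_allele_assignments.tsv", package = "strainseq")`.
#'
#' @param path Path to the table.
#' @return Data frame.
#' @export
read_allele_assignments <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("strain", "allele", "previously_reported", "reference")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("allele table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' Tally allele frequencies across strains
#'
#' Counts how many non-reference strains carry each allele, the percentage
#' each represents (rounded half-up to one decimal), and how many strains
#' had no previously reported assignment.
#'
#' @param assignments Data frame from [read_allele_assignments()].
#' @return List: `n_strains`, `n_nonreference`, `counts` (named integer),
#'   `percent` (named numeric), `n_uncharacterized`.
#' @examples
#' tab <- read_allele_assignments(
#'   system.file("extdata", "ahr_allele_assignments.tsv", package = "strainseq"))
#' tally_alleles(tab)
#' @export
tally_alleles <- function(assignments) {
  ref <- tolower(assignments$reference) %in% c("yes", "true", "1")
  nonref <- assignments[!ref, , drop = FALSE]
  counts <- table(nonref$allele)
  pct <- round_half_up(100 * as.numeric(counts) / nrow(nonref), 1L)
  names(pct) <- names(counts)
  novel <- !(tolower(nonref$previously_reported) %in% c("yes", "true", "1"))
  list(n_strains = nrow(assignments), n_nonreference = nrow(nonref),
       counts = setNames(as.integer(counts), names(counts)),
       percent = pct, n_uncharacterized = sum(novel))
}
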