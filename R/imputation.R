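# Index-preserving imputation: each 0-based reference index maps to a
# replacement string (its own base when unedited, the alternate base at a
# SNP, base-plus-inserted-bases at an insertion anchor, the empty string at a
# deleted base). The reference index set never changes, so annotations keyed
# to reference coordinates stay addressable after editing.

#' Build an index-preserving edit map
#'
#' Applies a strain's normalized variants to a reference gene as per-index
#' replacement strings. A SNP substitutes one base; an insertion appends the
#' inserted bases to its anchor index; each deleted index maps to the empty
#' string. Variants are validated first (see [validate_variants()]).
#'
#' @param gene A [reference_gene()].
#' @param vs A [variant_set()].
#' @param het_policy `"error"` (default) to refuse heterozygous calls, or
#'   `"first_allele"` to impute their first differing allele.
#' @return An object of class `edit_map`: a character vector of length
#'   `nchar(gene$sequence)` of replacement strings, with attributes `pre`
#'   (bases inserted before index 0, normally `""`) and `ref_len`.
#' @examples
#' g <- reference_gene("Demo", "chr1", 1, 10, "+", "AAAAACAAAA")
#' vs <- variant_set("s1", data.frame(chrom = "chr1", pos = 6, kind = "SNP",
#'                                    ref_allele = "C", alt_allele = "T"))
#' flatten(build_edit_map(g, vs))
#' @export
build_edit_map <- function(gene, vs, het_policy = c("error", "first_allele")) {
  df <- apply_variant_policy(gene, vs, match.arg(het_policy))
  n <- nchar(gene$sequence)
  em <- strsplit(gene$sequence, "", fixed = TRUE)[[1]]
  pre <- ""
  edited <- logical(n)   # guards "an index carries at most one edit"
  for (i in seq_len(nrow(df))) {
    loc <- df$pos[i] - gene$genomic_start
    kind <- df$kind[i]
    if (kind == "SNP") {
      idx <- loc + 1L
      if (edited[idx]) stop("edit conflict at reference index ", loc, call. = FALSE)
      em[idx] <- df$alt_allele[i]
      edited[idx] <- TRUE
    } else if (kind == "INS") {
      if (loc == -1L) {            # insertion before the first base
        pre <- paste0(pre, df$alt_allele[i])
        next
      }
      idx <- loc + 1L
      if (edited[idx]) stop("edit conflict at reference index ", loc, call. = FALSE)
      em[idx] <- paste0(em[idx], df$alt_allele[i])
      edited[idx] <- TRUE
    } else {                       # DEL, clipped to the gene
      idxs <- loc + seq_len(nchar(df$ref_allele[i]))
      idxs <- idxs[idxs >= 1L & idxs <= n]
      if (any(edited[idxs])) stop("edit conflict inside deletion at position ",
                                  df$pos[i], call. = FALSE)
      em[idxs] <- ""
      edited[idxs] <- TRUE
    }
  }
  structure(em, pre = pre, ref_len = n, class = "edit_map")
}

#' Impute a strain-specific gene sequence
#'
#' @inheritParams build_edit_map
#' @return Object of class `imputed_sequence` with fields `gene`, `strain`,
#'   `edits` (the [build_edit_map()] result).
#' @export
impute <- function(gene, vs, het_policy = c("error", "first_allele")) {
  structure(
    list(gene = gene, strain = vs$strain,
         edits = build_edit_map(gene, vs, het_policy)),
    class = "imputed_sequence")
}

#' Flatten an edit map or imputed sequence into a nucleotide string
#'
#' Concatenates the per-index replacement strings in reference order. For an
#' [impute()] result whose gene is annotated on the complement strand, the
#' concatenation is reverse-complemented as a final step, so the returned
#' sequence always reads in the gene's sense (mRNA-like) orientation.
#'
#' @param x An `edit_map` or `imputed_sequence`.
#' @param ... Unused.
#' @return A nucleotide string.
#' @export
flatten <- function(x, ...) UseMethod("flatten")

#' @export
flatten.edit_map <- function(x, ...) {
  paste0(attr(x, "pre"), paste(unclass(x), collapse = ""))
}

#' @export
flatten.imputed_sequence <- function(x, ...) {
  s <- flatten(x$edits)
  if (x$gene$strand == "-") reverse_complement(s) else s
}

#' @export
print.imputed_sequence <- function(x, ...) {
  cat(sprintf("<imputed_sequence> %s | %s: %d bp reference -> %d bp imputed (%s strand)\n",
              x$gene$symbol, x$strain, attr(x$edits, "ref_len"),
              nchar(flatten(x$edits)) , x$gene$strand))
  invisible(x)
}

#' Project a reference index into the flattened sequence
#'
#' Returns, for each 0-based reference index, the 0-based position in
#' [flatten()]'s output (before any strand flip) where that index's
#' replacement string begins. Monotone non-decreasing. For a deleted index
#' the returned position is where the deleted base would have been; such
#' positions are flagged in the `"deleted"` attribute.
#'
#' @param edits An `edit_map`.
#' @param ref_index 0-based reference index (vectorized).
#' @return Integer vector with logical attribute `"deleted"`.
#' @export
project_index <- function(edits, ref_index) {
  n <- attr(edits, "ref_len")
  ref_index <- as.integer(ref_index)
  if (any(ref_index < 0L | ref_index >= n)) {
    stop(sprintf("reference index out of range [0, %d)", n), call. = FALSE)
  }
  lens <- nchar(unclass(edits))
  offs <- c(0L, cumsum(lens))
  out <- nchar(attr(edits, "pre")) + offs[ref_index + 1L]
  attr(out, "deleted") <- lens[ref_index + 1L] == 0L
  out
}

# Independent editing routine used for generator ground truths and as the
# oracle against build_edit_map/flatten in tests: applies normalized variants
# to the raw string right-to-left by substring surgery, so earlier positions
# are never shifted by later edits.
splice_replace <- function(sequence, df, origin = 1L) {
  ord <- order(df$pos, decreasing = TRUE)
  s <- sequence
  n <- nchar(sequence)
  for (i in ord) {
    loc <- df$pos[i] - origin + 1L   # 1-based local
    if (df$kind[i] == "SNP") {
      s <- paste0(substr(s, 1L, loc - 1L), df$alt_allele[i],
                  substr(s, loc + 1L, nchar(s)))
    } else if (df$kind[i] == "INS") {
      s <- paste0(substr(s, 1L, loc), df$alt_allele[i],
                  substr(s, loc + 1L, nchar(s)))
    } else {
      from <- max(1L, loc)
      to <- min(n, loc + nchar(df$ref_allele[i]) - 1L)
      if (to < from) next
      s <- paste0(substr(s, 1L, from - 1L), substr(s, to + 1L, nchar(s)))
    }
  }
  s
}
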