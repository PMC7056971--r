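# Variant tables: minimal VCF dialect and delimited strain-export tables,
# normalized to the per-index edit form the imputation engine consumes.
#
# Normalized representation (one row per variant):
#   kind "SNP": pos = 1-based genomic position, ref/alt single differing bases
#   kind "INS": pos = 1-based genomic position of the anchor base AFTER which
#               alt_allele is inserted; ref_allele == ""
#   kind "DEL": pos = 1-based genomic position of the first deleted base;
#               ref_allele = deleted bases, alt_allele == ""
# `anchor` keeps the VCF anchor base (NA when unknown) so records can be
# written back in left-anchored VCF form.

variant_columns <- c("chrom", "pos", "kind", "ref_allele", "alt_allele",
                     "anchor", "zygosity", "id")

empty_variant_frame <- function() {
  data.frame(chrom = character(), pos = integer(), kind = character(),
             ref_allele = character(), alt_allele = character(),
             anchor = character(), zygosity = character(), id = character(),
             stringsAsFactors = FALSE)
}

#' Construct a per-strain variant set
#'
#' @param strain Strain identifier.
#' @param variants Data frame with columns `chrom`, `pos`, `kind`,
#'   `ref_allele`, `alt_allele`, `anchor`, `zygosity`, `id` (missing optional
#'   columns are filled). Rows are sorted by `pos`.
#' @return An object of class `variant_set` with fields `strain` and
#'   `variants`.
#' @export
variant_set <- function(strain, variants = empty_variant_frame()) {
  if (is.null(variants$anchor)) variants$anchor <- NA_character_
  if (is.null(variants$zygosity)) variants$zygosity <- "homozygous"
  if (is.null(variants$id)) variants$id <- "."
  if (is.null(variants$chrom)) variants$chrom <- NA_character_
  variants$pos <- as.integer(variants$pos)
  variants <- variants[variant_columns]
  variants <- variants[order(variants$pos), , drop = FALSE]
  rownames(variants) <- NULL
  bad <- !variants$kind %in% c("SNP", "INS", "DEL")
  if (any(bad)) stop("unknown variant kind: ", variants$kind[which(bad)[1]],
                     call. = FALSE)
  structure(list(strain = strain, variants = variants), class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  k <- table(factor(x$variants$kind, levels = c("SNP", "INS", "DEL")))
  cat(sprintf("<variant_set> strain %s: %d SNP, %d INS, %d DEL\n",
              x$strain, k[["SNP"]], k[["INS"]], k[["DEL"]]))
  invisible(x)
}

n_variants <- function(vs) nrow(vs$variants)

# Strip the shared VCF anchor from an (pos, ref, alt) allele pair and classify
# it. Idempotent on already-normalized records (ref == "" for INS,
# alt == "" for DEL).
norm_alleles <- function(pos, ref, alt) {
  pos <- as.integer(pos)
  if (ref == alt) return(NULL)                     # non-variant site
  if (ref == "" || ref == "-") {                   # already-normalized INS
    return(list(kind = "INS", pos = pos, ref = "", alt = alt,
                anchor = NA_character_))
  }
  if (alt == "" || alt == "-") {                   # already-normalized DEL
    return(list(kind = "DEL", pos = pos, ref = ref, alt = "",
                anchor = NA_character_))
  }
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == 1L && na == 1L) {
    return(list(kind = "SNP", pos = pos, ref = ref, alt = alt,
                anchor = NA_character_))
  }
  if (nr < na && substr(alt, 1L, nr) == ref) {     # left-anchored insertion
    return(list(kind = "INS", pos = pos + nr - 1L,
                ref = "", alt = substr(alt, nr + 1L, na),
                anchor = substr(ref, nr, nr)))
  }
  if (na < nr && substr(ref, 1L, na) == alt) {     # left-anchored deletion
    return(list(kind = "DEL", pos = pos + na,
                ref = substr(ref, na + 1L, nr), alt = "",
                anchor = substr(alt, na, na)))
  }
  stop(sprintf("unsupported complex allele pair %s>%s at position %d",
               ref, alt, pos), call. = FALSE)
}

classify_genotype <- function(gt) {
  gt <- sub(":.*", "", gt)
  al <- strsplit(gt, "[/|]")[[1]]
  al <- al[nzchar(al)]
  if (length(al) == 0L || all(al %in% c("0", "."))) return("absent")
  if (all(al == "1")) return("homozygous")
  if (any(al == "1")) return("heterozygous")
  "absent"
}

read_lines_arg <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) readLines(x) else x
}

#' Parse a minimal VCF dialect into per-strain variant sets
#'
#' Accepts tab-separated records with at least `CHROM POS ID REF ALT` columns
#' and optional per-strain genotype columns (column 10 onward, named on the
#' `#CHROM` header line). VCF-style left-anchored indels are converted to the
#' normalized `INS`/`DEL` form. For a strain column, records with genotype
#' `0/0` or `./.` are dropped; `0/1`-style genotypes are kept with
#' `zygosity = "heterozygous"`. With no genotype columns a single strain named
#' `"sample"` is returned.
#'
#' @param x Path to a VCF file, or a character vector of its lines.
#' @return Named list of [variant_set()] objects, one per strain.
#' @export
parse_vcf_minimal <- function(x) {
  lines <- read_lines_arg(x)
  lines <- lines[nzchar(trimws(lines))]
  strains <- NULL
  header <- grep("^#CHROM", lines)
  if (length(header)) {
    cols <- strsplit(sub("^#", "", lines[header[1]]), "\t")[[1]]
    if (length(cols) >= 10L) strains <- cols[-(1:9)]
  }
  body <- lines[!startsWith(lines, "#")]
  if (is.null(strains)) strains <- "sample"
  rows <- setNames(vector("list", length(strains)), strains)
  for (ln in seq_along(body)) {
    f <- strsplit(body[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 5L) {
      stop(sprintf("malformed VCF record at data line %d: fewer than 5 fields", ln),
           call. = FALSE)
    }
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos)) {
      stop(sprintf("malformed VCF record at data line %d: bad POS '%s'", ln, f[2]),
           call. = FALSE)
    }
    if (grepl(",", f[5], fixed = TRUE)) {
      stop(sprintf(
        "multi-allelic ALT '%s' at data line %d is not supported (inbred, homozygous input expected)",
        f[5], ln), call. = FALSE)
    }
    nz <- tryCatch(norm_alleles(pos, toupper(f[4]), toupper(f[5])),
                   error = function(e) {
                     stop(sprintf("data line %d: %s", ln, conditionMessage(e)),
                          call. = FALSE)
                   })
    if (is.null(nz)) next
    rec <- function(zyg) {
      data.frame(chrom = f[1], pos = nz$pos, kind = nz$kind,
                 ref_allele = nz$ref, alt_allele = nz$alt,
                 anchor = nz$anchor, zygosity = zyg, id = f[3],
                 stringsAsFactors = FALSE)
    }
    if (length(f) >= 10L && length(strains) == length(f) - 9L) {
      gts <- f[10:length(f)]
      for (si in seq_along(strains)) {
        cls <- classify_genotype(gts[si])
        if (cls == "absent") next
        rows[[strains[si]]] <- c(rows[[strains[si]]], list(rec(cls)))
      }
    } else {
      rows[[1]] <- c(rows[[1]], list(rec("homozygous")))
    }
  }
  out <- lapply(strains, function(s) {
    df <- if (length(rows[[s]])) do.call(rbind, rows[[s]]) else empty_variant_frame()
    variant_set(s, df)
  })
  setNames(out, strains)
}

#' Write variant sets in the minimal VCF dialect
#'
#' Inverse of [parse_vcf_minimal()]: normalized `INS`/`DEL` records are
#' re-anchored in VCF style. The anchor base comes from the record's stored
#' `anchor` field, or is looked up in `gene` when supplied.
#'
#' @param vsets A [variant_set()] or (possibly named) list of them. All sets
#'   must describe the same loci when several strains share one file; records
#'   are keyed by `(pos, ref, alt)`.
#' @param path Output path, or `NULL` to return the lines.
#' @param gene Optional [reference_gene()] used to fill missing anchor bases.
#' @return The lines, invisibly when written to `path`.
#' @export
write_vcf_minimal <- function(vsets, path = NULL, gene = NULL) {
  if (inherits(vsets, "variant_set")) vsets <- setNames(list(vsets), vsets$strain)
  strains <- vapply(vsets, function(v) v$strain, character(1))
  anchored <- function(v) {
    df <- v$variants
    out <- lapply(seq_len(nrow(df)), function(i) {
      r <- df[i, ]
      anch <- r$anchor
      lookup <- function(gpos) {
        if (!is.na(anch)) return(anch)
        if (is.null(gene)) {
          stop("anchor base unknown for indel at position ", r$pos,
               "; supply `gene` to write_vcf_minimal()", call. = FALSE)
        }
        substr(gene$sequence, gpos - gene$genomic_start + 1L,
               gpos - gene$genomic_start + 1L)
      }
      switch(r$kind,
        SNP = list(pos = r$pos, ref = r$ref_allele, alt = r$alt_allele,
                   id = r$id, chrom = r$chrom, zyg = r$zygosity),
        INS = {
          a <- lookup(r$pos)
          list(pos = r$pos, ref = a, alt = paste0(a, r$alt_allele),
               id = r$id, chrom = r$chrom, zyg = r$zygosity)
        },
        DEL = {
          a <- lookup(r$pos - 1L)
          list(pos = r$pos - 1L, ref = paste0(a, r$ref_allele), alt = a,
               id = r$id, chrom = r$chrom, zyg = r$zygosity)
        })
    })
    out
  }
  recs <- list()   # keyed by chrom:pos:ref:alt -> list(rec, gts named by strain)
  for (v in vsets) {
    for (r in anchored(v)) {
      key <- paste(r$chrom, r$pos, r$ref, r$alt, sep = ":")
      if (is.null(recs[[key]])) recs[[key]] <- list(rec = r, gts = character())
      recs[[key]]$gts[[v$strain]] <-
        if (identical(r$zyg, "heterozygous")) "0/1" else "1/1"
    }
  }
  ord <- order(vapply(recs, function(e) e$rec$pos, integer(1)))
  recs <- recs[ord]
  head <- c("##fileformat=VCFv4.2",
            paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", strains), collapse = "\t"))
  body <- vapply(recs, function(e) {
    gts <- unname(e$gts[strains])
    gts[is.na(gts)] <- "0/0"
    paste(c(e$rec$chrom, e$rec$pos, e$rec$id, e$rec$ref, e$rec$alt,
            ".", "PASS", ".", "GT", gts), collapse = "\t")
  }, character(1))
  lines <- c(head, unname(body))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Column-name dialect for delimited strain variant tables
#'
#' Variant-viewer exports differ in column naming; the dialect map pins which
#' columns hold the chromosome, position and reference allele, and which
#' columns are strains.
#'
#' @param chrom,pos,ref Column names.
#' @param strains Character vector of strain column names, or `NULL` to treat
#'   every unmapped column as a strain.
#' @param sep Field separator.
#' @return A dialect list for [parse_strain_csv()].
#' @export
csv_dialect <- function(chrom = "chromosome", pos = "position", ref = "ref",
                        strains = NULL, sep = ",") {
  list(chrom = chrom, pos = pos, ref = ref, strains = strains, sep = sep)
}

#' Parse a delimited per-strain variant table
#'
#' One row per site; one column per strain holding that strain's allele.
#' An allele equal to the reference, empty, or `"-"` yields no variant.
#' Heterozygous notation (`"A/G"`) records the first allele that differs from
#' the reference with `zygosity = "heterozygous"`. Indels use the same
#' left-anchored convention as VCF (e.g. ref `AT`, allele `A` deletes one
#' base).
#'
#' @param x Path to the table, or a character vector of its lines.
#' @param dialect A [csv_dialect()].
#' @return Named list of [variant_set()] objects, one per strain column.
#' @export
parse_strain_csv <- function(x, dialect = csv_dialect()) {
  lines <- read_lines_arg(x)
  df <- read.delim(text = paste(lines, collapse = "\n"), sep = dialect$sep,
                   header = TRUE, check.names = FALSE, colClasses = "character",
                   strip.white = TRUE)
  need <- c(dialect$chrom, dialect$pos, dialect$ref)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("dialect maps column(s) not present in table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  strains <- dialect$strains
  if (is.null(strains)) strains <- setdiff(names(df), need)
  miss <- setdiff(strains, names(df))
  if (length(miss)) {
    stop("strain column(s) not present in table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  pos <- suppressWarnings(as.integer(df[[dialect$pos]]))
  if (anyNA(pos)) {
    stop(sprintf("unparseable position '%s' at table row %d",
                 df[[dialect$pos]][which(is.na(pos))[1]], which(is.na(pos))[1]),
         call. = FALSE)
  }
  out <- lapply(strains, function(s) {
    recs <- list()
    for (i in seq_len(nrow(df))) {
      ref <- toupper(trimws(df[[dialect$ref]][i]))
      allele <- toupper(trimws(df[[s]][i]))
      if (allele %in% c("", "-", ref)) next
      zyg <- "homozygous"
      if (grepl("/", allele, fixed = TRUE)) {
        parts <- strsplit(allele, "/", fixed = TRUE)[[1]]
        zyg <- "heterozygous"
        diffp <- parts[parts != ref]
        if (length(diffp) == 0L) next
        allele <- diffp[1]
      }
      nz <- norm_alleles(pos[i], ref, allele)
      if (is.null(nz)) next
      recs <- c(recs, list(data.frame(
        chrom = df[[dialect$chrom]][i], pos = nz$pos, kind = nz$kind,
        ref_allele = nz$ref, alt_allele = nz$alt, anchor = nz$anchor,
        zygosity = zyg, id = ".", stringsAsFactors = FALSE)))
    }
    vdf <- if (length(recs)) do.call(rbind, recs) else empty_variant_frame()
    variant_set(s, vdf)
  })
  setNames(out, strains)
}

# 0-based local reference indices claimed by a normalized variant; an INS
# claims its anchor index (the edit lives there), a DEL claims every deleted
# index, clipped to the gene.
claimed_indices <- function(gene, kind, pos, ref_allele) {
  loc <- pos - gene$genomic_start   # may be out of range; caller clips
  n <- nchar(gene$sequence)
  idx <- switch(kind,
    SNP = loc,
    INS = loc,
    DEL = loc + seq_len(nchar(ref_allele)) - 1L)
  idx[idx >= 0L & idx < n]
}

#' Validate a variant set against a reference gene
#'
#' Flags variants outside the gene, reference-allele mismatches, overlapping
#' normalized edits and heterozygous calls. The imputation pipeline's default
#' policy silently skips out-of-gene variants, stops on mismatch/overlap, and
#' stops on heterozygous calls unless the first-allele override is chosen.
#'
#' @param gene A [reference_gene()].
#' @param vs A [variant_set()].
#' @return Data frame with one row per variant: `pos`, `kind`, `status`
#'   (`"clean"`, `"out_of_gene"`, `"ref_mismatch"`, `"overlap"`,
#'   `"heterozygous"`, `"clipped"`) and `message`.
#' @export
validate_variants <- function(gene, vs) {
  df <- vs$variants
  n <- nrow(df)
  status <- rep("clean", n)
  msg <- rep("", n)
  glen <- nchar(gene$sequence)
  for (i in seq_len(n)) {
    kind <- df$kind[i]; pos <- df$pos[i]
    loc <- pos - gene$genomic_start
    if (!is.na(df$chrom[i]) && !is.na(gene$chromosome) &&
        df$chrom[i] != gene$chromosome) {
      status[i] <- "out_of_gene"; msg[i] <- "different chromosome"; next
    }
    if (kind == "SNP") {
      if (loc < 0L || loc >= glen) {
        status[i] <- "out_of_gene"; msg[i] <- "position outside gene"; next
      }
      base <- substr(gene$sequence, loc + 1L, loc + 1L)
      if (base != df$ref_allele[i]) {
        status[i] <- "ref_mismatch"
        msg[i] <- sprintf("gene has %s, variant claims %s", base, df$ref_allele[i])
        next
      }
    } else if (kind == "INS") {
      if (loc < 0L || loc >= glen) {
        status[i] <- "out_of_gene"; msg[i] <- "anchor outside gene"; next
      }
      if (!is.na(df$anchor[i])) {
        base <- substr(gene$sequence, loc + 1L, loc + 1L)
        if (base != df$anchor[i]) {
          status[i] <- "ref_mismatch"
          msg[i] <- sprintf("anchor base is %s, variant claims %s", base, df$anchor[i])
          next
        }
      }
    } else {  # DEL
      dlen <- nchar(df$ref_allele[i])
      if (loc + dlen <= 0L || loc >= glen) {
        status[i] <- "out_of_gene"; msg[i] <- "deleted range outside gene"; next
      }
      clip_lo <- max(0L, -loc)
      clip_hi <- max(0L, loc + dlen - glen)
      inner <- substr(df$ref_allele[i], clip_lo + 1L, dlen - clip_hi)
      found <- substr(gene$sequence, loc + clip_lo + 1L, loc + dlen - clip_hi)
      if (inner != found) {
        status[i] <- "ref_mismatch"
        msg[i] <- sprintf("gene has %s, variant claims %s", found, inner)
        next
      }
      if (clip_lo > 0L || clip_hi > 0L) {
        status[i] <- "clipped"
        msg[i] <- "deletion clipped to gene bounds"
      }
    }
    if (df$zygosity[i] == "heterozygous" && status[i] %in% c("clean", "clipped")) {
      status[i] <- "heterozygous"
      msg[i] <- "heterozygous call in homozygous-consensus pipeline"
    }
  }
  # overlap: any 0-based index claimed by more than one in-gene variant
  keep <- which(!status %in% "out_of_gene")
  claims <- lapply(keep, function(i) {
    claimed_indices(gene, df$kind[i], df$pos[i], df$ref_allele[i])
  })
  all_idx <- unlist(claims)
  dup <- unique(all_idx[duplicated(all_idx)])
  if (length(dup)) {
    for (k in seq_along(keep)) {
      if (any(claims[[k]] %in% dup)) {
        i <- keep[k]
        status[i] <- "overlap"
        msg[i] <- "normalized edit shares a reference index with another variant"
      }
    }
  }
  data.frame(pos = df$pos, kind = df$kind, status = status, message = msg,
             stringsAsFactors = FALSE)
}

# Apply the default validation policy, returning the variant rows to impute.
# het_policy "error" stops on heterozygous calls; "first_allele" keeps them
# (the stored alt is already the first differing allele).
apply_variant_policy <- function(gene, vs,
                                 het_policy = c("error", "first_allele")) {
  het_policy <- match.arg(het_policy)
  rep <- validate_variants(gene, vs)
  if (any(rep$status == "ref_mismatch")) {
    i <- which(rep$status == "ref_mismatch")[1]
    stop(sprintf("strain %s: reference-allele mismatch at position %d (%s)",
                 vs$strain, rep$pos[i], rep$message[i]), call. = FALSE)
  }
  if (any(rep$status == "overlap")) {
    i <- which(rep$status == "overlap")[1]
    stop(sprintf("strain %s: overlapping variants at position %d",
                 vs$strain, rep$pos[i]), call. = FALSE)
  }
  if (het_policy == "error" && any(rep$status == "heterozygous")) {
    i <- which(rep$status == "heterozygous")[1]
    stop(sprintf(
      "strain %s: heterozygous variant at position %d; this pipeline targets homozygous (inbred) genomes. Set het_policy = 'first_allele' to take the first allele.",
      vs$strain, rep$pos[i]), call. = FALSE)
  }
  if (any(rep$status == "clipped")) {
    warning(sprintf("strain %s: %d deletion(s) clipped to gene bounds",
                    vs$strain, sum(rep$status == "clipped")), call. = FALSE)
  }
  keep <- rep$status %in% c("clean", "clipped", "heterozygous")
  df <- vs$variants[keep, , drop = FALSE]
  rownames(df) <- NULL
  df
}
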