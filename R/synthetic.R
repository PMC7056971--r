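# Synthetic genes, strains and ground truths. The generator emulates the
# input structure the pipeline assumes — a multi-exon gene whose introns
# carry the GT/AG consensus, a transcript with a clean ATG..stop CDS, and
# per-strain SNP/indel sets — with every truth computed by direct coordinate
# bookkeeping so the pipeline under test never feeds its own answers back.

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rand_nuc <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rint <- function(rng) {
  if (rng[1] >= rng[2]) rng[1] else sample(seq.int(rng[1], rng[2]), 1L)
}

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# Minimal stand-alone translation used only for ground truths: first ATG,
# codons to the first stop.
truth_translate <- function(mrna) {
  s <- regexpr("ATG", mrna, fixed = TRUE)[1]
  if (s == -1L) return("")
  aa <- character()
  i <- s
  while (i + 2L <= nchar(mrna)) {
    cod <- substr(mrna, i, i + 2L)
    if (cod %in% STOP_CODONS) break
    a <- Biostrings::GENETIC_CODE[[cod]]
    aa <- c(aa, if (is.null(a)) "X" else a)
    i <- i + 3L
  }
  paste(aa, collapse = "")
}

#' Generate a synthetic gene with known exon structure
#'
#' Builds a transcript (5'UTR free of ATG, an ATG..stop CDS of sense codons,
#' 3'UTR), splits it into exons, inserts GT..AG introns and flanking
#' sequence, and enforces by rejection sampling that every exon k-mer occurs
#' exactly once in the gene — the premise of single-perfect-match seeding.
#' Deterministic for a given seed.
#'
#' @param n_exons Number of exons (>= 1).
#' @param exon_len,intron_len,flank_len,utr5_len,utr3_len Length ranges
#'   (inclusive), in bases.
#' @param seed Integer seed; the caller's RNG state is preserved.
#' @param seed_k k-mer length whose uniqueness is enforced.
#' @param strand `"+"` or `"-"`; for `"-"` the stored gene sequence is the
#'   reverse complement of the constructed sense sequence, exercising the
#'   strand-resolution path.
#' @param symbol,chromosome,genomic_start Gene annotation fields.
#' @param max_tries Rejection-sampling retry cap.
#' @return Object of class `synthetic_gene`: fields `gene`
#'   ([reference_gene()]), `sense_seq`, `truth_exons` (0-based half-open
#'   intervals in sense coordinates), `truth_mrna`, `truth_protein`,
#'   `cds_start`, `cds_end` (0-based, in the mRNA), `seed`, `seed_k`.
#' @export
generate_gene <- function(n_exons, exon_len = c(160L, 320L),
                          intron_len = c(80L, 300L),
                          flank_len = c(120L, 260L), seed = 1L,
                          seed_k = 16L, utr5_len = c(20L, 60L),
                          utr3_len = c(20L, 60L), strand = "+",
                          symbol = "SYNG", chromosome = "chrS",
                          genomic_start = 3000001L, max_tries = 100L) {
  stopifnot(n_exons >= 1L, intron_len[1] >= 24L,
            exon_len[1] >= utr5_len[2] + utr3_len[2] + 36L ||
              n_exons * exon_len[1] >= utr5_len[2] + utr3_len[2] + 36L)
  with_preserved_seed(seed, {
    for (try in seq_len(max_tries)) {
      exlens <- vapply(seq_len(n_exons), function(i) rint(exon_len), integer(1))
      total <- sum(exlens)
      u5 <- rint(utr5_len)
      u3 <- rint(utr3_len)
      cds <- total - u5 - u3
      cds <- cds - cds %% 3L
      u3 <- total - u5 - cds
      n_aa <- cds %/% 3L - 2L
      u5s <- rand_nuc(u5)
      while (grepl("ATG", u5s, fixed = TRUE)) {
        u5s <- gsub("ATG", "ATC", u5s, fixed = TRUE)
      }
      cod <- sample(sense_codons(), n_aa, replace = TRUE)
      stopc <- sample(STOP_CODONS, 1L)
      mrna <- paste0(u5s, "ATG", paste(cod, collapse = ""), stopc, rand_nuc(u3))
      cuts <- c(0L, cumsum(exlens))
      exon_seqs <- substring(mrna, cuts[-length(cuts)] + 1L, cuts[-1])
      introns <- if (n_exons > 1L) {
        vapply(seq_len(n_exons - 1L), function(i) {
          paste0("GT", rand_nuc(rint(intron_len) - 4L), "AG")
        }, character(1))
      } else character()
      f5 <- rand_nuc(rint(flank_len)); f3 <- rand_nuc(rint(flank_len))
      pieces <- character(2L * n_exons - 1L)
      pieces[seq(1L, by = 2L, length.out = n_exons)] <- exon_seqs
      if (n_exons > 1L) pieces[seq(2L, by = 2L, length.out = n_exons - 1L)] <- introns
      body <- paste(pieces, collapse = "")
      sense <- paste0(f5, body, f3)
      # sense-space exon intervals (0-based half-open)
      starts <- integer(n_exons); pos <- nchar(f5)
      for (i in seq_len(n_exons)) {
        starts[i] <- pos
        pos <- pos + exlens[i] + if (i < n_exons) nchar(introns[i]) else 0L
      }
      ex <- data.frame(start = starts, end = starts + exlens)
      # uniqueness of every exon k-mer in the whole gene
      k <- seed_k
      ng <- nchar(sense) - k + 1L
      gk <- substring(sense, seq_len(ng), seq_len(ng) + k - 1L)
      dup <- duplicated(gk) | duplicated(gk, fromLast = TRUE)
      exon_kpos <- unlist(lapply(seq_len(n_exons), function(i) {
        if (ex$end[i] - ex$start[i] >= k) seq.int(ex$start[i], ex$end[i] - k)
        else integer()
      }))
      if (any(dup[exon_kpos + 1L])) next
      n <- nchar(sense)
      fwd <- if (strand == "-") reverse_complement(sense) else sense
      g <- reference_gene(symbol, chromosome, genomic_start,
                          genomic_start + n - 1L, strand, fwd)
      return(structure(
        list(gene = g, sense_seq = sense, truth_exons = ex,
             truth_mrna = mrna,
             truth_protein = paste0("M", paste(Biostrings::GENETIC_CODE[cod],
                                               collapse = "")),
             cds_start = u5, cds_end = u5 + cds, seed = seed, seed_k = k),
        class = "synthetic_gene"))
    }
    stop(sprintf(
      "could not generate a gene with unique exon %d-mers in %d tries; relax the constraints",
      seed_k, max_tries), call. = FALSE)
  })
}

#' @export
print.synthetic_gene <- function(x, ...) {
  cat(sprintf("<synthetic_gene> %s: %d bp, %d exon(s), mRNA %d bp, protein %d aa (%s strand)\n",
              x$gene$symbol, nchar(x$sense_seq), nrow(x$truth_exons),
              nchar(x$truth_mrna), nchar(x$truth_protein), x$gene$strand))
  invisible(x)
}

# map a 0-based mRNA index to its 0-based sense-gene position
mrna_to_sense <- function(g, m) {
  lens <- g$truth_exons$end - g$truth_exons$start
  cum <- c(0L, cumsum(lens))
  j <- findInterval(m, cum, rightmost.closed = FALSE)
  g$truth_exons$start[j] + (m - cum[j])
}

#' Generate a synthetic strain: variants plus ground truths
#'
#' Places non-overlapping SNPs, insertions and deletions uniformly over the
#' gene. With `protect_splice` (default), splice dinucleotides (plus a 3 bp
#' margin around every junction) and the start/stop codons are excluded, and
#' variants keep a minimum spacing of `seed_k + 4` bases so no exon loses
#' all its seeds. With `in_frame_cds`, insertions landing in the CDS are
#' placed at codon boundaries with lengths a multiple of 3 and stop-free
#' (sense-codon) content, so the encoded protein simply gains
#' `length / 3` residues.
#'
#' Ground truths (imputed gene, mRNA, protein) are computed by direct
#' right-to-left editing of the sense sequence and of each exon interval —
#' never by the alignment pipeline.
#'
#' @param g A [generate_gene()] result.
#' @param n_snp,n_ins,n_del Variant counts.
#' @param seed Integer seed.
#' @param strain Strain name.
#' @param protect_splice Keep splice signals and start/stop codons intact.
#' @param in_frame_cds Restrict CDS insertions to in-frame, stop-free ones.
#' @param ins_len,del_len Length ranges.
#' @param min_spacing Minimum distance between the claimed index ranges of
#'   two variants.
#' @param max_tries Placement retry cap.
#' @return Object of class `synthetic_strain`: `base`, `strain`, `variants`
#'   (a forward-strand [variant_set()]), `truth_imputed_gene` (sense
#'   orientation), `truth_mrna`, `truth_protein`, `sense_edits`.
#' @export
generate_variants <- function(g, n_snp, n_ins, n_del, seed = 1L,
                              strain = sprintf("sim_s%d", seed),
                              protect_splice = TRUE, in_frame_cds = FALSE,
                              ins_len = c(2L, 8L), del_len = c(1L, 6L),
                              min_spacing = g$seed_k + 4L, max_tries = 100L) {
  sense <- g$sense_seq
  n <- nchar(sense)
  schars <- strsplit(sense, "", fixed = TRUE)[[1]]
  prot <- logical(n)
  if (protect_splice) {
    ne <- nrow(g$truth_exons)
    if (ne > 1L) for (i in seq_len(ne - 1L)) {
      e <- g$truth_exons$end[i]        # intron starts at e (0-based)
      s2 <- g$truth_exons$start[i + 1L] # intron ends at s2 - 1
      idx <- c((e - 3L):(e + 4L), (s2 - 5L):(s2 + 2L)) + 1L
      prot[idx[idx >= 1L & idx <= n]] <- TRUE
    }
    for (m in c(g$cds_start:(g$cds_start + 2L),
                (g$cds_end - 3L):(g$cds_end - 1L))) {
      p <- mrna_to_sense(g, m)
      prot[pmax(1L, pmin(n, (p - 1L):(p + 1L) + 1L))] <- TRUE
    }
  }
  # an exonic indel must keep a seedable exact anchor between itself and the
  # exon boundary, or the junction loses its exact placement signal
  indel_margin <- g$seed_k + 4L
  in_exon_noanchor <- function(lo, hi) {
    for (i in seq_len(nrow(g$truth_exons))) {
      s <- g$truth_exons$start[i]; e <- g$truth_exons$end[i]
      if (hi >= s && lo < e) {       # touches this exon
        if (lo < s + indel_margin || hi >= e - indel_margin) return(TRUE)
      }
    }
    FALSE
  }
  with_preserved_seed(seed, {
    claims <- list()   # claimed 0-based [lo, hi] ranges
    ok_claim <- function(lo, hi, indel = FALSE) {
      if (lo < 0L || hi >= n) return(FALSE)
      if (any(prot[(lo:hi) + 1L])) return(FALSE)
      if (indel && protect_splice && in_exon_noanchor(lo, hi)) return(FALSE)
      for (cl in claims) {
        if (!(lo > cl[2] + min_spacing || hi < cl[1] - min_spacing)) return(FALSE)
      }
      TRUE
    }
    place <- function(width_fn, build_fn, count, label) {
      out <- list()
      tries <- 0L
      while (length(out) < count) {
        tries <- tries + 1L
        if (tries > max_tries * max(1L, count) * 20L) {
          stop(sprintf("could not place %d %s variants", count, label),
               call. = FALSE)
        }
        rec <- build_fn()
        if (is.null(rec)) next
        if (!ok_claim(rec$lo, rec$hi, isTRUE(rec$indel))) next
        claims[[length(claims) + 1L]] <<- c(rec$lo, rec$hi)
        out[[length(out) + 1L]] <- rec$row
      }
      out
    }
    snps <- place(NULL, function() {
      i <- sample.int(n, 1L) - 1L
      ref <- schars[i + 1L]
      list(lo = i, hi = i, indel = FALSE,
           row = data.frame(pos = i + 1L, kind = "SNP", ref_allele = ref,
                            alt_allele = sample(setdiff(c("A", "C", "G", "T"), ref), 1L),
                            stringsAsFactors = FALSE))
    }, n_snp, "SNP")
    dels <- place(NULL, function() {
      L <- rint(del_len)
      i <- sample.int(n - L, 1L) - 1L
      list(lo = i, hi = i + L - 1L, indel = TRUE,
           row = data.frame(pos = i + 1L, kind = "DEL",
                            ref_allele = substr(sense, i + 1L, i + L),
                            alt_allele = "", stringsAsFactors = FALSE))
    }, n_del, "DEL")
    # in-frame CDS anchors: after the third base of a codon, interior to an exon
    cds_anchor_pool <- if (in_frame_cds) {
      ms <- seq.int(g$cds_start + 2L, g$cds_end - 4L, by = 3L)
      ms[vapply(ms, function(m) {
        mrna_to_sense(g, m + 1L) == mrna_to_sense(g, m) + 1L
      }, logical(1))]
    } else integer()
    inss <- place(NULL, function() {
      if (in_frame_cds && length(cds_anchor_pool)) {
        m <- sample(cds_anchor_pool, 1L)
        i <- mrna_to_sense(g, m)
        L <- rint(ins_len)
        L <- max(3L, L - L %% 3L)
        content <- paste(sample(sense_codons(), L %/% 3L, replace = TRUE),
                         collapse = "")
      } else {
        i <- sample.int(n - 1L, 1L) - 1L
        L <- rint(ins_len)
        content <- rand_nuc(L)
      }
      list(lo = i, hi = i, indel = TRUE,
           row = data.frame(pos = i + 1L, kind = "INS", ref_allele = "",
                            alt_allele = content, stringsAsFactors = FALSE))
    }, n_ins, "INS")
    sense_df <- do.call(rbind, c(snps, dels, inss,
                                 list(data.frame(pos = integer(), kind = character(),
                                                 ref_allele = character(),
                                                 alt_allele = character(),
                                                 stringsAsFactors = FALSE))))
    sense_df <- sense_df[order(sense_df$pos), , drop = FALSE]
    rownames(sense_df) <- NULL

    # ground truths by direct editing (sense space)
    truth_gene <- splice_replace(sense, sense_df, origin = 1L)
    exon_piece <- function(s, e) {
      rows <- sense_df[
        (sense_df$kind == "SNP" & sense_df$pos > s & sense_df$pos <= e) |
        (sense_df$kind == "INS" & sense_df$pos > s & sense_df$pos < e) |
        (sense_df$kind == "DEL" & sense_df$pos > s &
           sense_df$pos + nchar(sense_df$ref_allele) - 1L <= e), , drop = FALSE]
      splice_replace(substr(sense, s + 1L, e), rows, origin = s + 1L)
    }
    truth_mrna <- paste(mapply(exon_piece, g$truth_exons$start, g$truth_exons$end),
                        collapse = "")
    truth_protein <- truth_translate(truth_mrna)

    # forward-strand variant records
    fwd <- g$gene$sequence
    g0 <- g$gene$genomic_start
    rows <- lapply(seq_len(nrow(sense_df)), function(i) {
      r <- sense_df[i, ]
      if (g$gene$strand == "+") {
        pos <- g0 + r$pos - 1L
        ref <- r$ref_allele; alt <- r$alt_allele
      } else {
        si <- r$pos - 1L   # 0-based sense index
        if (r$kind == "SNP") {
          pos <- g0 + (n - 1L - si)
          ref <- chartr("ACGT", "TGCA", r$ref_allele)
          alt <- chartr("ACGT", "TGCA", r$alt_allele)
        } else if (r$kind == "DEL") {
          L <- nchar(r$ref_allele)
          pos <- g0 + (n - si - L)
          ref <- reverse_complement(r$ref_allele)
          alt <- ""
        } else {
          pos <- g0 + (n - 2L - si)
          ref <- ""
          alt <- reverse_complement(r$alt_allele)
        }
      }
      floc <- pos - g0
      anchor <- if (r$kind == "INS" && floc >= 0L) substr(fwd, floc + 1L, floc + 1L)
                else if (r$kind == "DEL" && floc >= 1L) substr(fwd, floc, floc)
                else NA_character_
      data.frame(chrom = g$gene$chromosome, pos = pos, kind = r$kind,
                 ref_allele = ref, alt_allele = alt, anchor = anchor,
                 zygosity = "homozygous", id = ".", stringsAsFactors = FALSE)
    })
    vdf <- if (length(rows)) do.call(rbind, rows) else empty_variant_frame()
    structure(
      list(base = g, strain = strain, variants = variant_set(strain, vdf),
           truth_imputed_gene = truth_gene, truth_mrna = truth_mrna,
           truth_protein = truth_protein, sense_edits = sense_df),
      class = "synthetic_strain")
  })
}

#' @export
print.synthetic_strain <- function(x, ...) {
  cat(sprintf("<synthetic_strain> %s on %s: %d variant(s); truth protein %d aa\n",
              x$strain, x$base$gene$symbol, n_variants(x$variants),
              nchar(x$truth_protein)))
  invisible(x)
}
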