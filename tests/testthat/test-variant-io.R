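vcf_lines <- function(records, strains = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", if (!is.null(strains)) c("FORMAT", strains)),
                 collapse = "\t"))
  c(hdr, records)
}

test_that("minimal VCF parsing normalizes SNPs and anchored indels", {
  vs <- parse_vcf_minimal(vcf_lines(c(
    "chr12\t1000\trs1\tA\tG\t.\tPASS\t.",
    "chr12\t1000\trs2\tAT\tA\t.\tPASS\t.",
    "chr12\t1000\trs3\tA\tAGG\t.\tPASS\t.")))
  expect_named(vs, "sample")
  df <- vs$sample$variants
  expect_identical(df$kind, c("SNP", "INS", "DEL"))
  snp <- df[df$kind == "SNP", ]
  expect_identical(snp$pos, 1000L)
  expect_identical(snp$alt_allele, "G")
  del <- df[df$kind == "DEL", ]
  expect_identical(del$pos, 1001L)       # left-anchor stripped
  expect_identical(del$ref_allele, "T")
  ins <- df[df$kind == "INS", ]
  expect_identical(ins$pos, 1000L)       # inserted after the anchor base
  expect_identical(ins$alt_allele, "GG")
})

test_that("genotype columns split records per strain and drop absent calls", {
  vs <- parse_vcf_minimal(vcf_lines(c(
    "chr1\t10\t.\tA\tG\t.\tPASS\t.\tGT\t1/1\t0/0",
    "chr1\t20\t.\tC\tT\t.\tPASS\t.\tGT\t./.\t0/1"),
    strains = c("s1", "s2")))
  expect_named(vs, c("s1", "s2"))
  expect_identical(vs$s1$variants$pos, 10L)
  expect_identical(vs$s2$variants$pos, 20L)
  expect_identical(vs$s2$variants$zygosity, "heterozygous")
})

test_that("multi-allelic and malformed records are rejected with context", {
  expect_error(parse_vcf_minimal(vcf_lines("chr1\t10\t.\tA\tG,T\t.\t.\t.")),
               "multi-allelic")
  expect_error(parse_vcf_minimal(vcf_lines("chr1\tabc\t.\tA\tG\t.\t.\t.")),
               "line 1")
  expect_error(parse_vcf_minimal(vcf_lines("chr1\t10")), "fewer than 5")
})

test_that("strain CSV parsing follows the dialect map", {
  lines <- c("chromosome,position,ref,strainX,strainY",
             "chr1,500,C,C,T",          # X matches ref -> no variant
             "chr1,600,G,-,C/G",        # X dash -> none; Y heterozygous
             "chr1,700,AT,A,AT")        # X anchored deletion
  vs <- parse_strain_csv(lines, csv_dialect())
  expect_named(vs, c("strainX", "strainY"))
  expect_identical(vs$strainX$variants$kind, "DEL")
  expect_identical(vs$strainX$variants$pos, 701L)
  y <- vs$strainY$variants
  expect_identical(y$pos, c(500L, 600L))
  expect_identical(y$zygosity, c("homozygous", "heterozygous"))
  expect_identical(y$alt_allele[2], "C")
  expect_error(parse_strain_csv(lines, csv_dialect(pos = "POS")),
               "not present")
  expect_error(parse_strain_csv(c("chromosome,position,ref,s", "chr1,xx,C,T")),
               "unparseable position")
})

test_that("normalization is idempotent", {
  nz <- strainseq:::norm_alleles
  expect_identical(nz(10L, "A", "G")$kind, "SNP")
  ins <- nz(10L, "A", "AGG")
  expect_identical(nz(ins$pos, ins$ref, ins$alt)[c("kind", "pos", "alt")],
                   ins[c("kind", "pos", "alt")])
  del <- nz(10L, "AT", "A")
  expect_identical(nz(del$pos, del$ref, del$alt)[c("kind", "pos", "ref")],
                   del[c("kind", "pos", "ref")])
  expect_null(nz(10L, "A", "A"))
  expect_error(nz(10L, "AT", "GC"), "complex")
})

test_that("VCF writing and re-parsing round-trips variant sets", {
  set.seed(21)
  g <- reference_gene("G", "chrT", 101L, 400L, "+", random_nuc_string(300))
  for (rep in 1:20) {
    df <- random_variant_frame(g$sequence, 5L)
    df$pos <- df$pos + 100L            # local -> genomic
    df$chrom <- "chrT"
    vs <- variant_set(sprintf("s%d", rep), df)
    lines <- write_vcf_minimal(vs, gene = g)
    back <- parse_vcf_minimal(lines)[[1]]
    expect_identical(back$variants[c("pos", "kind", "ref_allele", "alt_allele")],
                     vs$variants[c("pos", "kind", "ref_allele", "alt_allele")])
  }
})

test_that("validate_variants flags mismatches, overlaps and heterozygotes", {
  g <- reference_gene("G", "chr1", 1L, 10L, "+", "ACGTACGTAA")
  clean <- variant_set("s", data.frame(chrom = "chr1", pos = 3L, kind = "SNP",
                                       ref_allele = "G", alt_allele = "A"))
  expect_identical(validate_variants(g, clean)$status, "clean")
  bad <- variant_set("s", data.frame(chrom = "chr1", pos = 3L, kind = "SNP",
                                     ref_allele = "C", alt_allele = "A"))
  expect_identical(validate_variants(g, bad)$status, "ref_mismatch")
  expect_error(build_edit_map(g, bad), "mismatch")
  overl <- variant_set("s", data.frame(
    chrom = "chr1", pos = c(2L, 4L), kind = "DEL",
    ref_allele = c("CGTA", "TACG"), alt_allele = ""))
  expect_identical(validate_variants(g, overl)$status, rep("overlap", 2))
  het <- variant_set("s", data.frame(chrom = "chr1", pos = 1L, kind = "SNP",
                                     ref_allele = "A", alt_allele = "G",
                                     zygosity = "heterozygous"))
  expect_identical(validate_variants(g, het)$status, "heterozygous")
  expect_error(build_edit_map(g, het), "inbred")
  expect_identical(flatten(build_edit_map(g, het, het_policy = "first_allele")),
                   "GCGTACGTAA")
  # out-of-gene variants are skipped silently by the policy
  out <- variant_set("s", data.frame(chrom = "chr1", pos = 99L, kind = "SNP",
                                     ref_allele = "A", alt_allele = "G"))
  expect_identical(validate_variants(g, out)$status, "out_of_gene")
  expect_identical(flatten(build_edit_map(g, out)), g$sequence)
  # boundary-straddling deletion is clipped with a warning
  clip <- variant_set("s", data.frame(chrom = "chr1", pos = 9L, kind = "DEL",
                                      ref_allele = "AACC", alt_allele = ""))
  expect_warning(em <- build_edit_map(g, clip), "clipped")
  expect_identical(flatten(em), "ACGTACGT")
})
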