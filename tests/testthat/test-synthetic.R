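test_that("gene generation is deterministic and leaves the caller's RNG alone", {
  g1 <- generate_gene(3, seed = 7)
  g2 <- generate_gene(3, seed = 7)
  expect_identical(g1, g2)
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generate_gene(2, seed = 5)); after <- runif(3)
  expect_identical(before, after)
})

test_that("a single-exon gene is intron-free with the mRNA as its interior", {
  g <- generate_gene(1, seed = 7)
  expect_identical(nrow(g$truth_exons), 1L)
  expect_identical(
    substr(g$sense_seq, g$truth_exons$start + 1L, g$truth_exons$end),
    g$truth_mrna)
})

test_that("every generated gene satisfies the structural invariants", {
  for (sd in 1:50) {
    g <- generate_gene(5, seed = sd)
    ex <- g$truth_exons
    # mRNA is the concatenation of the exon substrings
    expect_identical(
      paste(substring(g$sense_seq, ex$start + 1L, ex$end), collapse = ""),
      g$truth_mrna)
    # introns carry the GT/AG consensus
    for (i in seq_len(nrow(ex) - 1L)) {
      expect_identical(substr(g$sense_seq, ex$end[i] + 1L, ex$end[i] + 2L), "GT")
      expect_identical(substr(g$sense_seq, ex$start[i + 1L] - 1L,
                              ex$start[i + 1L]), "AG")
    }
    # every exon k-mer occurs exactly once in the gene
    k <- g$seed_k
    ng <- nchar(g$sense_seq) - k + 1L
    gk <- substring(g$sense_seq, seq_len(ng), seq_len(ng) + k - 1L)
    dup <- duplicated(gk) | duplicated(gk, fromLast = TRUE)
    kpos <- unlist(lapply(seq_len(nrow(ex)), function(i) {
      seq.int(ex$start[i], ex$end[i] - k)
    }))
    expect_false(any(dup[kpos + 1L]))
    # the CDS begins at the first ATG and translates to the truth protein
    orf <- find_orf(g$truth_mrna, "minimize_5utr")
    expect_identical(orf$start, g$cds_start)
    expect_true(orf$has_stop)
    expect_identical(translate_cds(substr(g$truth_mrna, orf$start + 1L, orf$end)),
                     g$truth_protein)
  }
})

test_that("zero variants leave every truth at the base gene's values", {
  g <- generate_gene(3, seed = 12)
  st <- generate_variants(g, 0, 0, 0, seed = 1)
  expect_identical(st$truth_imputed_gene, g$sense_seq)
  expect_identical(st$truth_mrna, g$truth_mrna)
  expect_identical(st$truth_protein, g$truth_protein)
  expect_identical(n_variants <- nrow(st$variants$variants), 0L)
})

test_that("truth mRNA distance equals the number of exonic SNPs", {
  for (sd in 1:10) {
    g <- generate_gene(3, seed = sd + 40)
    st <- generate_variants(g, 5, 0, 0, seed = sd)
    n_ex <- sum(vapply(st$sense_edits$pos, function(p) {
      any(p > g$truth_exons$start & p <= g$truth_exons$end)
    }, logical(1)))
    d <- sum(strsplit(st$truth_mrna, "")[[1]] !=
               strsplit(g$truth_mrna, "")[[1]])
    expect_identical(d, n_ex)
  }
})

test_that("an in-frame 12-base CDS insertion adds exactly 4 residues", {
  g <- generate_gene(3, seed = 42)
  st <- generate_variants(g, 0, 1, 0, seed = 5, in_frame_cds = TRUE,
                          ins_len = c(12L, 12L))
  expect_identical(nchar(st$truth_protein), nchar(g$truth_protein) + 4L)
  expect_identical(nchar(st$truth_mrna), nchar(g$truth_mrna) + 12L)
})

test_that("splice protection keeps junction signals and start/stop intact", {
  for (sd in 1:10) {
    g <- generate_gene(4, seed = sd + 60)
    st <- generate_variants(g, 6, 2, 2, seed = sd)
    ex <- g$truth_exons
    prot <- unlist(lapply(seq_len(nrow(ex) - 1L), function(i) {
      c(ex$end[i] + 0:1, ex$start[i + 1L] - 2:1)
    }))
    claims <- unlist(lapply(seq_len(nrow(st$sense_edits)), function(i) {
      r <- st$sense_edits[i, ]
      if (r$kind == "DEL") (r$pos - 1L) + seq_len(nchar(r$ref_allele)) - 1L
      else r$pos - 1L
    }))
    expect_length(intersect(claims, prot), 0L)
  }
})

test_that("truth self-consistency: package translation reproduces truth proteins", {
  for (sd in 1:30) {
    g <- generate_gene(2 + (sd %% 4), seed = sd)
    st <- generate_variants(g, 4, 1, 1, seed = sd + 7)
    expect_identical(predict_protein(st$truth_mrna, "minimize_5utr"),
                     st$truth_protein)
  }
})
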