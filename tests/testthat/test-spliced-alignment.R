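p16 <- alignment_params()
p8 <- alignment_params(seed_k = 8L)

test_that("seeding finds unique perfect matches and merges diagonal runs", {
  set.seed(51)
  gene <- random_nuc_string(400)
  mrna <- substr(gene, 101, 160)
  seeds <- seed_perfect_matches(mrna, gene, p16)
  expect_identical(nrow(seeds), 1L)
  expect_identical(seeds$mrna_start, 0L)
  expect_identical(seeds$gene_start, 100L)
  expect_identical(seeds$length, 60L)
})

test_that("a spliced transcript seeds one block per exon", {
  set.seed(52)
  e1 <- random_nuc_string(60); e2 <- random_nuc_string(60)
  intron <- paste0("GT", random_nuc_string(80), "AG")
  gene <- paste0(random_nuc_string(50), e1, intron, e2, random_nuc_string(50))
  seeds <- seed_perfect_matches(paste0(e1, e2), gene, p16)
  expect_identical(nrow(seeds), 2L)
  expect_identical(seeds$gene_start, c(50L, 50L + 60L + 84L))
  expect_identical(seeds$length, c(60L, 60L))
})

test_that("repeated k-mers and k-mers containing N never seed", {
  set.seed(53)
  unit <- random_nuc_string(30)
  gene <- paste0(random_nuc_string(40), unit, random_nuc_string(35), unit,
                 random_nuc_string(40))
  expect_identical(nrow(seed_perfect_matches(unit, gene, p16)), 0L)
  gene2 <- random_nuc_string(200)
  mrna2 <- substr(gene2, 51, 90)
  substr(mrna2, 20, 20) <- "N"
  seeds <- seed_perfect_matches(mrna2, gene2, p16)
  expect_true(all(seeds$length < 40L))   # the N splits the perfect run
  expect_identical(nrow(seed_perfect_matches("ACGTACGTAC", gene2, p16)), 0L)
})

test_that("chaining covers the trivial cases with the documented costs", {
  one <- data.frame(mrna_start = 0L, gene_start = 10L, length = 50L)
  ch <- chain_seeds(one, 50L, p16)
  expect_identical(ch$cost, 0)
  expect_identical(ch$n_intron, 0L)
  two <- data.frame(mrna_start = c(0L, 30L), gene_start = c(10L, 140L),
                    length = c(30L, 30L))
  ch <- chain_seeds(two, 60L, p16)
  expect_identical(ch$cost, p16$intron_penalty)
  expect_identical(ch$n_intron, 1L)
  empty <- chain_seeds(one[0, ], 75L, p16)
  expect_identical(empty$cost, 75L)
  expect_identical(nrow(empty$blocks), 0L)
})

test_that("chain cost equals exhaustive subset enumeration", {
  set.seed(54)
  for (i in 1:60) {
    seeds <- random_seed_instance(sample(2:8, 1))
    ch <- chain_seeds(seeds, 120L, p16)
    expect_equal(ch$cost, chain_cost_oracle(seeds, 120L, p16),
                 info = paste("instance", i))
  }
})

# two-exon fixture with a planted junction ambiguity: the downstream exon
# begins with the same dinucleotide as the intron, so the chained junction
# can sit 2 bases too far right until GT/AG refinement pulls it back
make_ambig_fixture <- function(seed) {
  set.seed(seed)
  repeat {
    e1 <- random_nuc_string(60)
    e2 <- paste0("GT", random_nuc_string(58))
    mid <- random_nuc_string(90)
    intron <- paste0("GT", mid, "AG")
    if (substr(intron, 3, 3) == substr(e2, 3, 3)) next
    f5 <- random_nuc_string(60); f3 <- random_nuc_string(60)
    gene <- paste0(f5, e1, intron, e2, f3)
    k <- 16L
    ng <- nchar(gene) - k + 1L
    gk <- substring(gene, seq_len(ng), seq_len(ng) + k - 1L)
    if (anyDuplicated(gk)) next
    return(list(gene = gene, mrna = paste0(e1, e2),
                exon_starts = c(60L, 60L + 60L + nchar(intron)),
                exon_ends = c(120L, 120L + nchar(intron) + 60L),
                intron = c(120L, 120L + nchar(intron))))
  }
}

test_that("boundary refinement selects the GT/AG placement in its window", {
  hits <- 0L
  for (seed in 1:100) {
    fx <- make_ambig_fixture(seed)
    # exhaustive window scan: the truth placement must be the unique GT/AG
    # optimum before we trust the fixture
    scores <- vapply(-3:3, function(s) {
      donor <- substr(fx$gene, fx$intron[1] + s + 1L, fx$intron[1] + s + 2L)
      accep <- substr(fx$gene, fx$intron[2] + s - 1L, fx$intron[2] + s)
      2L * (donor == "GT") + 2L * (accep == "AG")
    }, integer(1))
    expect_identical(which.max(scores), 4L)   # shift 0 is the only 4-pointer
    aln <- spliced_align(fx$mrna, fx$gene, p16)
    if (identical(aln$exons$gene_start, fx$exon_starts) &&
        identical(aln$exons$gene_end, fx$exon_ends)) hits <- hits + 1L
  }
  expect_identical(hits, 100L)
})

test_that("refinement lands on the GT/AG truth junction and is idempotent", {
  for (sd in c(19, 23, 29)) {
    g <- generate_gene(3, seed = sd)
    seeds <- seed_perfect_matches(g$truth_mrna, g$sense_seq, p16)
    ch <- chain_seeds(seeds, nchar(g$truth_mrna), p16)
    ref <- refine_boundaries(ch, g$truth_mrna, g$sense_seq, p16)
    b <- ref$blocks
    # junction-adjacent block boundaries sit exactly on the truth junctions
    expect_identical(b$gene_start[1] + b$length[1], g$truth_exons$end[1])
    expect_identical(b$gene_start[nrow(b)], g$truth_exons$start[3])
    expect_identical(refine_boundaries(ref, g$truth_mrna, g$sense_seq, p16)$blocks,
                     b)
  }
})

test_that("fill is a no-op on a fully covered chain", {
  set.seed(56)
  gene <- random_nuc_string(300)
  mrna <- substr(gene, 101, 180)
  aln <- spliced_align(mrna, gene, p16)
  expect_identical(nrow(aln$exons), 1L)
  expect_identical(aln$n_mismatch, 0L)
  expect_identical(aln$exons$gene_start, 100L)
  expect_identical(aln$exons$gene_end, 180L)
})

test_that("a single exonic SNP merges to one exon with one mismatch", {
  set.seed(57)
  gene <- random_nuc_string(300)
  mrna <- substr(gene, 101, 180)
  old <- substr(gene, 140, 140)
  substr(gene, 140, 140) <- setdiff(c("A", "C", "G", "T"), old)[1]
  aln <- spliced_align(mrna, gene, p8)
  expect_identical(nrow(aln$exons), 1L)
  expect_identical(aln$n_mismatch, 1L)
  # agrees with a full Gotoh alignment of the mRNA against the exon window
  al <- gotoh_global(mrna, substr(gene, 101, 180), p8)
  expect_identical(strainseq:::count_mrna_mismatches(al$a, al$b), 1L)
})

test_that("an exactly matching uncovered 5' prefix is absorbed mismatch-free", {
  set.seed(58)
  gene <- random_nuc_string(300)
  mrna <- substr(gene, 96, 180)     # 5 bases before the seeded block
  chain <- structure(list(
    blocks = data.frame(mrna_start = 5L, gene_start = 100L, length = 80L),
    cost = 5, n_intron = 0L, mrna_len = 85L), class = "exon_chain")
  aln <- fill_unaligned(chain, mrna, gene, p16)
  expect_identical(aln$exons$gene_start, 95L)
  expect_identical(aln$exons$mrna_start, 0L)
  expect_identical(aln$n_mismatch, 0L)
})

test_that("alignment recovers generated exon structures exactly", {
  for (sd in 1:30) {
    g <- generate_gene(2 + (sd %% 5), seed = sd)
    aln <- spliced_align(g$truth_mrna, g$sense_seq, p16)
    expect_identical(aln$exons$gene_start, g$truth_exons$start)
    expect_identical(aln$exons$gene_end, g$truth_exons$end)
    expect_identical(aln$n_mismatch, 0L)
    expect_identical(aln$n_intron, nrow(g$truth_exons) - 1L)
  }
})

test_that("exonic SNPs raise the mismatch count without changing structure", {
  # three SNPs in exon interiors
  g <- generate_gene(3, seed = 77)
  sense <- g$sense_seq
  mids <- (g$truth_exons$start + g$truth_exons$end) %/% 2L
  for (m in mids) {
    old <- substr(sense, m + 1L, m + 1L)
    substr(sense, m + 1L, m + 1L) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  aln <- spliced_align(g$truth_mrna, sense, p16)
  expect_identical(aln$n_intron, 2L)
  expect_identical(aln$n_mismatch, 3L)
  expect_identical(aln$exons$gene_start, g$truth_exons$start)

  # monotonicity: one central exonic SNP adds exactly one mismatch
  for (sd in 1:20) {
    g <- generate_gene(2 + (sd %% 4), seed = sd + 300)
    base <- spliced_align(g$truth_mrna, g$sense_seq, p16)
    s2 <- g$sense_seq
    m <- (g$truth_exons$start[1] + g$truth_exons$end[1]) %/% 2L
    old <- substr(s2, m + 1L, m + 1L)
    substr(s2, m + 1L, m + 1L) <- setdiff(c("A", "C", "G", "T"), old)[1]
    mut <- spliced_align(g$truth_mrna, s2, p16)
    expect_identical(mut$n_intron, base$n_intron)
    expect_identical(mut$n_mismatch, base$n_mismatch + 1L)
  }
})

test_that("short seedless queries fall back to whole-sequence Gotoh", {
  set.seed(59)
  gene <- random_nuc_string(80)
  mrna <- substr(gene, 11, 20)
  aln <- spliced_align(mrna, gene, p16)
  expect_identical(nrow(aln$exons), 1L)
  expect_identical(aln$n_intron, 0L)
  tiny <- alignment_params(seedless_cell_budget = 10)
  expect_error(spliced_align(mrna, gene, tiny), "seedless")
})

test_that("predicted mRNA extraction concatenates gene-side exons", {
  g <- generate_gene(4, seed = 88)
  aln <- spliced_align(g$truth_mrna, g$sense_seq, p16)
  expect_identical(extract_predicted_mrna(g$sense_seq, aln), g$truth_mrna)
  # one exonic SNP -> exactly one differing position
  st <- generate_variants(g, 20, 0, 0, seed = 1)
  gseq <- flatten(impute(g$gene, st$variants))
  pm <- extract_predicted_mrna(gseq, spliced_align(g$truth_mrna, gseq, p16))
  expect_identical(nchar(pm), nchar(g$truth_mrna))
  n_ex <- sum(vapply(seq_len(nrow(st$sense_edits)), function(i) {
    any(st$sense_edits$pos[i] > g$truth_exons$start &
          st$sense_edits$pos[i] <= g$truth_exons$end)
  }, logical(1)))
  expect_identical(
    sum(strsplit(pm, "")[[1]] != strsplit(g$truth_mrna, "")[[1]]), n_ex)
  # a 12-base exonic insertion lengthens the prediction by 12
  st2 <- generate_variants(g, 0, 1, 0, seed = 2, in_frame_cds = TRUE,
                           ins_len = c(12L, 12L))
  gseq2 <- flatten(impute(g$gene, st2$variants))
  pm2 <- extract_predicted_mrna(gseq2, spliced_align(g$truth_mrna, gseq2, p16))
  expect_identical(nchar(pm2), nchar(g$truth_mrna) + 12L)
  # alignments against the wrong target are caught
  expect_error(extract_predicted_mrna(substr(gseq2, 1, 100),
                                      spliced_align(g$truth_mrna, gseq2, p16)),
               "outside")
})

test_that("the alignment report names GT/AG donor and acceptor sites", {
  g <- generate_gene(3, seed = 91)
  aln <- spliced_align(g$truth_mrna, g$sense_seq, p16)
  rep <- alignment_report(aln, g$sense_seq)
  expect_identical(rep$intron_donor, c("GT", "GT", NA))
  expect_identical(rep$intron_acceptor, c("AG", "AG", NA))
  expect_identical(rep$gene_start, g$truth_exons$start + 1L)
})
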