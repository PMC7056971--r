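# Spliced alignment of an mRNA to a (possibly imputed) gene, in four stages:
# 1. seed: unique perfect k-mer matches, merged along diagonals;
# 2. chain: shortest path through the seed DAG minimizing
#    uncovered mRNA bases + intron_penalty * introns (Dijkstra);
# 3. refine: slide ambiguous exon junctions toward the GT/AG intron consensus;
# 4. fill: Gotoh-align residual mRNA segments into flanking gene windows.
#
# All coordinates in this module are 0-based half-open.

#' Alignment parameter set
#'
#' @param seed_k Seed k-mer length (>= 8). A seed is an mRNA k-mer occurring
#'   exactly once in the gene.
#' @param intron_penalty Cost units charged per intron when chaining; must
#'   exceed the typical mismatch saving of a spurious junction.
#' @param min_intron A gene-side gap qualifies as an intron when
#'   `gene_gap - mrna_gap >= min_intron`; smaller gaps are treated as
#'   deletions and handled by the Gotoh fill.
#' @param match,mismatch,gap_open,gap_extend Gotoh scoring (a gap run of
#'   length L costs `gap_open + (L-1) * gap_extend`); requires
#'   `gap_open <= gap_extend <= 0`.
#' @param seedless_cell_budget Maximum DP cells (`mRNA length * gene length`)
#'   allowed for the whole-sequence Gotoh fallback used when no seeds exist.
#' @return A list of class `alignment_params`.
#' @export
alignment_params <- function(seed_k = 16L, intron_penalty = 8, min_intron = 20L,
                             match = 1L, mismatch = -1L,
                             gap_open = -4L, gap_extend = -1L,
                             seedless_cell_budget = 2.5e7) {
  stopifnot(seed_k >= 8L, min_intron > 0L,
            gap_open <= gap_extend, gap_extend <= 0L)
  structure(list(seed_k = as.integer(seed_k), intron_penalty = intron_penalty,
                 min_intron = as.integer(min_intron),
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 seedless_cell_budget = seedless_cell_budget),
            class = "alignment_params")
}

as_seq <- function(x) {
  if (inherits(x, "transcript")) x$sequence
  else if (inherits(x, "reference_gene")) x$sequence
  else normalize_seq(x)
}

#' Seed perfect matches between an mRNA and a gene
#'
#' Indexes every gene k-mer; an mRNA k-mer seeds only where it occurs exactly
#' once in the gene (k-mers containing `N` never seed). Overlapping or
#' adjacent hits on the same diagonal are merged into maximal perfect blocks.
#'
#' @param mrna,gene Nucleotide strings (or [transcript()] /
#'   [reference_gene()]).
#' @param params An [alignment_params()].
#' @return Data frame of seed blocks with 0-based columns `mrna_start`,
#'   `gene_start`, `length`, sorted by `mrna_start`.
#' @export
seed_perfect_matches <- function(mrna, gene, params = alignment_params()) {
  mrna <- as_seq(mrna); gene <- as_seq(gene)
  k <- params$seed_k
  empty <- data.frame(mrna_start = integer(), gene_start = integer(),
                      length = integer())
  if (nchar(mrna) < k || nchar(gene) < k) return(empty)
  ng <- nchar(gene) - k + 1L
  gk <- substring(gene, seq_len(ng), seq_len(ng) + k - 1L)
  multi <- duplicated(gk) | duplicated(gk, fromLast = TRUE)
  ok_g <- !multi & !grepl("N", gk, fixed = TRUE)
  if (!any(ok_g)) return(empty)
  nm <- nchar(mrna) - k + 1L
  mk <- substring(mrna, seq_len(nm), seq_len(nm) + k - 1L)
  ok_m <- !grepl("N", mk, fixed = TRUE)
  hit <- match(mk, gk[ok_g])
  gpos <- which(ok_g)
  sel <- which(!is.na(hit) & ok_m)
  if (!length(sel)) return(empty)
  i0 <- sel - 1L                      # 0-based mRNA positions
  j0 <- gpos[hit[sel]] - 1L           # 0-based gene positions
  dg <- j0 - i0
  ord <- order(dg, i0)
  i0 <- i0[ord]; j0 <- j0[ord]; dg <- dg[ord]
  # merge runs on the same diagonal with mRNA gaps <= k (overlap/adjacency)
  newblk <- c(TRUE, diff(dg) != 0L | diff(i0) > k)
  grp <- cumsum(newblk)
  first <- tapply(seq_along(i0), grp, min)
  last <- tapply(seq_along(i0), grp, max)
  out <- data.frame(mrna_start = i0[first], gene_start = j0[first],
                    length = i0[last] - i0[first] + k)
  out <- out[order(out$mrna_start, out$gene_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Edge from block u to block v, or NULL when v cannot follow u. Blocks may
# overlap slightly in either coordinate (a perfect-match run can extend past
# the true splice or indel junction when the following bases coincide); the
# overlap is trimmed off v's start, which must still leave v a positive
# length.
chain_edge <- function(blocks, u, v, params) {
  u_me <- blocks$mrna_start[u] + blocks$length[u]
  u_ge <- blocks$gene_start[u] + blocks$length[u]
  o <- max(0L, u_me - blocks$mrna_start[v], u_ge - blocks$gene_start[v])
  if (blocks$length[v] - o < 1L) return(NULL)
  mg <- blocks$mrna_start[v] + o - u_me
  gg <- blocks$gene_start[v] + o - u_ge
  intron <- (gg - mg) >= params$min_intron
  list(cost = mg + if (intron) params$intron_penalty else 0,
       intron = intron, trim = o)
}

#' Chain seed blocks into an exon skeleton
#'
#' Builds a DAG over the seeds (an edge joins blocks that strictly follow
#' each other in both mRNA and gene coordinates) and finds the minimum-cost
#' source-to-sink path with Dijkstra's algorithm. An edge costs the mRNA
#' bases between the two blocks (potential mismatches) plus
#' `intron_penalty` when the gene-side gap qualifies as an intron; source
#' and sink edges charge the uncovered mRNA prefix/suffix. Ties break toward
#' fewer introns, then leftmost gene coordinates.
#'
#' @param seeds Seed data frame from [seed_perfect_matches()].
#' @param mrna_len mRNA length in bases.
#' @param params An [alignment_params()].
#' @return List of class `exon_chain`: `blocks` (subset of seeds, in order),
#'   `cost`, `n_intron`, `mrna_len`.
#' @export
chain_seeds <- function(seeds, mrna_len, params = alignment_params()) {
  S <- nrow(seeds)
  if (S == 0L) {
    return(structure(list(blocks = seeds, cost = mrna_len, n_intron = 0L,
                          mrna_len = mrna_len), class = "exon_chain"))
  }
  # nodes: 1..S blocks, S+1 source, S+2 sink
  n_nodes <- S + 2L
  src <- S + 1L; snk <- S + 2L
  dist <- rep(Inf, n_nodes); nintr <- rep(0L, n_nodes)
  pathkey <- rep("", n_nodes)     # zero-padded gene starts, for tie-breaking
  prev <- rep(NA_integer_, n_nodes)
  trim_in <- rep(0L, n_nodes)     # overlap trimmed off the node's start
  settled <- rep(FALSE, n_nodes)
  dist[src] <- 0
  relax <- function(u, v, w, is_intron, gkey, trim = 0L) {
    nd <- dist[u] + w
    ni <- nintr[u] + as.integer(is_intron)
    nk <- paste0(pathkey[u], gkey)
    if (nd < dist[v] ||
        (nd == dist[v] && (ni < nintr[v] ||
                           (ni == nintr[v] && nk < pathkey[v])))) {
      dist[v] <<- nd; nintr[v] <<- ni; pathkey[v] <<- nk
      prev[v] <<- u; trim_in[v] <<- trim
    }
  }
  gkey_of <- function(v) sprintf("%012d", seeds$gene_start[v])
  repeat {
    cand <- which(!settled & is.finite(dist))
    if (!length(cand)) break
    o <- cand[order(dist[cand], nintr[cand], pathkey[cand])][1]
    settled[o] <- TRUE
    if (o == snk) break
    if (o == src) {
      for (v in seq_len(S)) relax(src, v, seeds$mrna_start[v], FALSE, gkey_of(v))
    } else {
      relax(o, snk, mrna_len - (seeds$mrna_start[o] + seeds$length[o]), FALSE, "")
      for (v in seq_len(S)) {
        if (!settled[v]) {
          e <- chain_edge(seeds, o, v, params)
          if (!is.null(e)) relax(o, v, e$cost, e$intron, gkey_of(v), e$trim)
        }
      }
    }
  }
  path <- integer(); v <- snk
  while (!is.na(prev[v])) { path <- c(prev[v], path); v <- prev[v] }
  path <- setdiff(path, src)
  blocks <- seeds[path, , drop = FALSE]
  if (length(path)) {
    tr <- trim_in[path]
    blocks$mrna_start <- blocks$mrna_start + tr
    blocks$gene_start <- blocks$gene_start + tr
    blocks$length <- blocks$length - tr
  }
  rownames(blocks) <- NULL
  structure(list(blocks = blocks, cost = dist[snk], n_intron = nintr[snk],
                 mrna_len = mrna_len), class = "exon_chain")
}

# classify the gap after chain block i (i < nrow) as intron or co-exon gap
gap_is_intron <- function(blocks, i, params) {
  mg <- blocks$mrna_start[i + 1L] - (blocks$mrna_start[i] + blocks$length[i])
  gg <- blocks$gene_start[i + 1L] - (blocks$gene_start[i] + blocks$length[i])
  (gg - mg) >= params$min_intron
}

#' Refine exon junctions toward the GT/AG intron consensus
#'
#' For each adjacent pair of chained blocks separated by an intron, slides
#' the junction across its ambiguity window (positions where the junction
#' mRNA bases match the gene on both sides) and scores each placement +2 if
#' the intron then starts `GT` and +2 if it ends `AG`. The best-scoring
#' placement wins; ties go to the leftmost junction; a window with no GT/AG
#' keeps the chained placement.
#'
#' @param chain An `exon_chain`.
#' @param mrna,gene Nucleotide strings.
#' @param params An [alignment_params()].
#' @return The refined `exon_chain`.
#' @export
refine_boundaries <- function(chain, mrna, gene, params = alignment_params()) {
  mrna <- as_seq(mrna); gene <- as_seq(gene)
  b <- chain$blocks
  if (nrow(b) < 2L) return(chain)
  ch_at <- function(s, i) substr(s, i + 1L, i + 1L)   # 0-based char
  for (i in seq_len(nrow(b) - 1L)) {
    if (!gap_is_intron(b, i, params)) next
    u_me <- b$mrna_start[i] + b$length[i]
    v_ms <- b$mrna_start[i + 1L]
    if (v_ms != u_me) next      # uncovered mRNA at the junction: leave to fill
    u_ge <- b$gene_start[i] + b$length[i]
    v_gs <- b$gene_start[i + 1L]
    # rightward ambiguity: first bases of the right exon also match after u
    r <- 0L
    while (r < b$length[i + 1L] - 1L &&
           ch_at(mrna, v_ms + r) == ch_at(gene, u_ge + r)) r <- r + 1L
    # leftward ambiguity: last bases of the left exon also match before v
    l <- 0L
    while (l < b$length[i] - 1L &&
           ch_at(mrna, u_me - 1L - l) == ch_at(gene, v_gs - 1L - l)) l <- l + 1L
    shifts <- seq.int(-l, r)
    sc <- vapply(shifts, function(s) {
      donor <- substr(gene, u_ge + s + 1L, u_ge + s + 2L)
      accep <- substr(gene, v_gs + s - 1L, v_gs + s)
      2L * (donor == "GT") + 2L * (accep == "AG")
    }, integer(1))
    if (max(sc) == 0L) next
    s <- shifts[sc == max(sc)][1]   # shifts ascending => leftmost junction
    b$length[i] <- b$length[i] + s
    b$mrna_start[i + 1L] <- b$mrna_start[i + 1L] + s
    b$gene_start[i + 1L] <- b$gene_start[i + 1L] + s
    b$length[i + 1L] <- b$length[i + 1L] - s
  }
  chain$blocks <- b
  chain
}

#' Global affine-gap (Gotoh) alignment
#'
#' Optimal global alignment under the scoring in `params`, computed by the
#' three-matrix affine-gap recurrence. Traceback ties prefer diagonal, then
#' up (gap in `b`), then left. Works for nucleotide or amino-acid strings.
#'
#' @param a,b Sequences (either may be empty).
#' @param params An [alignment_params()].
#' @param band Optional band half-width: cells with `|i - j| > band` are
#'   excluded, bounding work and memory to roughly
#'   `length(a) * (2 * band + 1)` cells.
#' @return List with `score` and gapped strings `a`, `b`.
#' @examples
#' gotoh_global("ACGT", "ACTT")$score
#' @export
gotoh_global <- function(a, b, params = alignment_params(), band = NULL) {
  if (is.null(band)) band <- -1L
  .gotoh_cpp(toupper(a), toupper(b), params$match, params$mismatch,
             params$gap_open, params$gap_extend, as.integer(band))
}

# mRNA bases not matched identically in a Gotoh alignment: mismatch columns
# plus mRNA bases sitting opposite a gap.
count_mrna_mismatches <- function(aln_mrna, aln_gene) {
  if (!nzchar(aln_mrna)) return(0L)
  am <- strsplit(aln_mrna, "", fixed = TRUE)[[1]]
  ag <- strsplit(aln_gene, "", fixed = TRUE)[[1]]
  sum(am != "-" & (ag == "-" | am != ag))
}

#' Fill residual mRNA segments and assemble the final spliced alignment
#'
#' Uncovered mRNA segments — the 5' prefix, the 3' suffix, and gaps between
#' co-exonic blocks — are Gotoh-aligned to their flanking-constrained gene
#' windows and absorbed into the adjacent exon; their mismatches and short
#' indels accumulate into `n_mismatch`. Consecutive blocks not separated by
#' an intron merge into one exon.
#'
#' @param chain A refined `exon_chain` with at least one block.
#' @param mrna,gene Nucleotide strings.
#' @param params An [alignment_params()].
#' @return A `spliced_alignment`: list with `exons` (data frame
#'   `gene_start`, `gene_end`, `mrna_start`, `mrna_end`, `mismatches`;
#'   0-based half-open), `n_mismatch`, `n_intron`, `cost`, `mrna_len`.
#' @export
fill_unaligned <- function(chain, mrna, gene, params = alignment_params()) {
  mrna <- as_seq(mrna); gene <- as_seq(gene)
  b <- chain$blocks
  if (nrow(b) == 0L) stop("cannot fill an empty chain", call. = FALSE)
  glen <- nchar(gene); mlen <- chain$mrna_len
  sub0 <- function(s, from, to) {       # 0-based half-open substring
    if (to <= from) "" else substr(s, from + 1L, to)
  }
  seg_mm <- function(seg_m, seg_g) {
    if (!nzchar(seg_m)) return(0L)
    if (!nzchar(seg_g)) return(nchar(seg_m))
    al <- gotoh_global(seg_m, seg_g, params)
    count_mrna_mismatches(al$a, al$b)
  }

  revstr <- function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }
  # best score of aligning every prefix of `seg` against a prefix of `win`
  # (window end free), plus the window length used
  prefix_best <- function(seg, win) {
    .gotoh_prefix_best(seg, win, params$match, params$mismatch,
                       params$gap_open, params$gap_extend)
  }
  # mismatches of segment vs an exon-anchored window, fitting the free end
  fit_mm <- function(seg, win_used) {
    if (!nzchar(seg)) return(0L)
    if (!nzchar(win_used)) return(nchar(seg))
    al <- gotoh_global(seg, win_used, params)
    count_mrna_mismatches(al$a, al$b)
  }
  pad <- 8L

  exons <- list()
  # current exon under construction
  cur <- list(gs = b$gene_start[1], ge = b$gene_start[1] + b$length[1],
              ms = b$mrna_start[1], me = b$mrna_start[1] + b$length[1],
              mm = 0L)
  # 5' prefix: fit into the window just upstream of the first block (window
  # start free) and extend the exon start over the gene bases actually used
  if (cur$ms > 0L) {
    seg <- sub0(mrna, 0L, cur$ms)
    w <- min(cur$ms + pad, cur$gs)
    win <- sub0(gene, cur$gs - w, cur$gs)
    pb <- prefix_best(revstr(seg), revstr(win))
    u <- pb$b_len[nchar(seg) + 1L]
    cur$mm <- cur$mm + fit_mm(seg, sub0(gene, cur$gs - u, cur$gs))
    cur$gs <- cur$gs - u
    cur$ms <- 0L
  }
  if (nrow(b) > 1L) for (i in seq_len(nrow(b) - 1L)) {
    v_gs <- b$gene_start[i + 1L]; v_ge <- v_gs + b$length[i + 1L]
    v_ms <- b$mrna_start[i + 1L]; v_me <- v_ms + b$length[i + 1L]
    if (gap_is_intron(b, i, params)) {
      mg <- v_ms - cur$me
      if (mg > 0L) {
        # Uncovered mRNA at an intron junction. A seed block can overhang
        # the true junction (its run extended into coincidentally matching
        # intron sequence), so pull a few bases back from both flanking
        # blocks and re-fit the enlarged segment: choose the split and the
        # per-side gene extents that maximize alignment score plus a
        # splice-consensus bonus on the resulting intron ends.
        sL <- min(pad, cur$me - cur$ms - 1L)
        sR <- min(pad, v_me - v_ms - 1L)
        Lg <- cur$ge - sL; Rg <- v_gs + sR
        seg <- sub0(mrna, cur$me - sL, v_ms + sR)
        m2 <- nchar(seg)
        w <- min(m2 + pad, (Rg - Lg) %/% 2L)
        winL <- sub0(gene, Lg, Lg + w)
        winR <- sub0(gene, Rg - w, Rg)
        SL <- prefix_best(seg, winL)$scores
        SR <- prefix_best(revstr(seg), revstr(winR))$scores
        # strong canonical-splice prior: a few chance matches in intronic
        # sequence can outscore the true gapped placement, so the GT/AG
        # signal must dominate small score differences here
        us <- 0L:w
        donor_b <- 6L * (substring(gene, Lg + us + 1L, Lg + us + 2L) == "GT")
        accep_b <- 6L * (substring(gene, Rg - us - 1L, Rg - us) == "AG")
        bL <- apply(sweep(SL, 2L, donor_b, "+"), 1L, max)
        aL <- apply(sweep(SL, 2L, donor_b, "+"), 1L, which.max) - 1L
        bR <- apply(sweep(SR, 2L, accep_b, "+"), 1L, max)
        aR <- apply(sweep(SR, 2L, accep_b, "+"), 1L, which.max) - 1L
        tot <- bL + rev(bR)               # split after t = 0..m2 seg bases
        t <- which.max(tot) - 1L
        uL <- aL[t + 1L]
        uR <- aR[m2 - t + 1L]
        cur$mm <- cur$mm +
          fit_mm(sub0(seg, 0L, t), sub0(gene, Lg, Lg + uL)) +
          fit_mm(sub0(seg, t, m2), sub0(gene, Rg - uR, Rg))
        cur$ge <- Lg + uL
        v_gs <- Rg - uR
        cur$me <- cur$me - sL + t
        v_ms <- cur$me
      }
      exons[[length(exons) + 1L]] <- cur
      cur <- list(gs = v_gs, ge = v_ge, ms = v_ms, me = v_me, mm = 0L)
    } else {
      # co-exonic gap: Gotoh the interior segment, merge into one exon
      cur$mm <- cur$mm + seg_mm(sub0(mrna, cur$me, v_ms),
                                sub0(gene, cur$ge, v_gs))
      cur$ge <- v_ge; cur$me <- v_me
    }
  }
  # 3' suffix: fit into the window just downstream (window end free)
  if (cur$me < mlen) {
    seg <- sub0(mrna, cur$me, mlen)
    w <- min(mlen - cur$me + pad, glen - cur$ge)
    pb <- prefix_best(seg, sub0(gene, cur$ge, cur$ge + w))
    u <- pb$b_len[nchar(seg) + 1L]
    cur$mm <- cur$mm + fit_mm(seg, sub0(gene, cur$ge, cur$ge + u))
    cur$ge <- cur$ge + u
    cur$me <- mlen
  }
  exons[[length(exons) + 1L]] <- cur

  ex <- data.frame(
    gene_start = vapply(exons, `[[`, integer(1), "gs"),
    gene_end = vapply(exons, `[[`, integer(1), "ge"),
    mrna_start = vapply(exons, `[[`, integer(1), "ms"),
    mrna_end = vapply(exons, `[[`, integer(1), "me"),
    mismatches = vapply(exons, function(e) as.integer(e$mm), integer(1)))
  n_mismatch <- sum(ex$mismatches)
  n_intron <- nrow(ex) - 1L
  structure(list(exons = ex, n_mismatch = n_mismatch, n_intron = n_intron,
                 cost = n_mismatch + params$intron_penalty * n_intron,
                 mrna_len = mlen),
            class = "spliced_alignment")
}

#' @export
print.spliced_alignment <- function(x, ...) {
  cat(sprintf("<spliced_alignment> %d exon(s), %d intron(s), %d mismatched mRNA base(s)\n",
              nrow(x$exons), x$n_intron, x$n_mismatch))
  invisible(x)
}

#' Spliced-align an mRNA to a gene sequence
#'
#' Runs the full seed, chain, refine and fill stages. When no seeds exist
#' (e.g. very short mRNA) the whole mRNA is Gotoh-aligned to the whole gene,
#' provided the DP size fits `params$seedless_cell_budget`.
#'
#' @param mrna A [transcript()] or nucleotide string.
#' @param gene_seq Gene (target) nucleotide string, usually an imputed
#'   sequence from [flatten()].
#' @param params An [alignment_params()].
#' @return A `spliced_alignment` (see [fill_unaligned()]).
#' @export
spliced_align <- function(mrna, gene_seq, params = alignment_params()) {
  m <- as_seq(mrna); g <- as_seq(gene_seq)
  seeds <- seed_perfect_matches(m, g, params)
  if (nrow(seeds) == 0L) {
    cells <- as.numeric(nchar(m)) * nchar(g)
    if (cells > params$seedless_cell_budget) {
      stop(sprintf(
        "no alignment seeds and the seedless Gotoh fallback would need %.3g DP cells (budget %.3g); raise seedless_cell_budget or shorten the target",
        cells, params$seedless_cell_budget), call. = FALSE)
    }
    al <- gotoh_global(m, g, params)
    mm <- count_mrna_mismatches(al$a, al$b)
    ex <- data.frame(gene_start = 0L, gene_end = nchar(g),
                     mrna_start = 0L, mrna_end = nchar(m), mismatches = mm)
    return(structure(list(exons = ex, n_mismatch = mm, n_intron = 0L,
                          cost = mm, mrna_len = nchar(m)),
                     class = "spliced_alignment"))
  }
  chain <- chain_seeds(seeds, nchar(m), params)
  chain <- refine_boundaries(chain, m, g, params)
  fill_unaligned(chain, m, g, params)
}

#' Extract the predicted mRNA from a spliced alignment
#'
#' Concatenates the gene-side exon substrings in order. Because the
#' alignment target is the imputed gene itself, exonic SNPs and intra-exon
#' indels flow directly into the predicted transcript.
#'
#' @param gene_seq The gene sequence the alignment was computed against.
#' @param aln A `spliced_alignment`.
#' @return Nucleotide string of the predicted mRNA.
#' @export
extract_predicted_mrna <- function(gene_seq, aln) {
  g <- as_seq(gene_seq)
  ex <- aln$exons
  if (any(ex$gene_start < 0L) || any(ex$gene_end > nchar(g))) {
    stop("exon coordinates fall outside the gene sequence; was the alignment computed against this sequence?", call. = FALSE)
  }
  paste(substring(g, ex$gene_start + 1L, ex$gene_end), collapse = "")
}

#' Tabulate a spliced alignment for reporting
#'
#' @param aln A `spliced_alignment`.
#' @param gene_seq The gene sequence, used to report each intron's donor and
#'   acceptor dinucleotides.
#' @return Data frame with 1-based inclusive exon coordinates, per-exon
#'   mismatch counts and the donor/acceptor dinucleotides of the following
#'   intron (`NA` for the last exon).
#' @export
alignment_report <- function(aln, gene_seq) {
  g <- as_seq(gene_seq)
  ex <- aln$exons
  n <- nrow(ex)
  donor <- acceptor <- rep(NA_character_, n)
  if (n > 1L) for (i in seq_len(n - 1L)) {
    donor[i] <- substr(g, ex$gene_end[i] + 1L, ex$gene_end[i] + 2L)
    acceptor[i] <- substr(g, ex$gene_start[i + 1L] - 1L, ex$gene_start[i + 1L])
  }
  data.frame(exon = seq_len(n),
             gene_start = ex$gene_start + 1L, gene_end = ex$gene_end,
             mrna_start = ex$mrna_start + 1L, mrna_end = ex$mrna_end,
             mismatches = ex$mismatches,
             intron_donor = donor, intron_acceptor = acceptor)
}
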