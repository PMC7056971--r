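# Independent oracles used across the suite. These deliberately avoid the
# package's own DP implementations: alignment scores come from exhaustive
# enumeration of alignment paths, chain costs from exhaustive subset
# enumeration, and imputation truths from direct string surgery.

default_p <- alignment_params()

# --- brute-force affine-gap alignment oracle -------------------------------
#
# Enumerate every monotone alignment path for shape (m, n) once. A path is
# its set of diagonal (substitution) cells plus the affine cost of its gap
# runs. For all 2^m * 2^n binary ({A,C}) string pairs at once, the score of
# a path is match/mismatch-weighted agreement over its diagonal cells plus
# its gap cost; the oracle score is the maximum over paths.

enum_align_paths <- function(m, n) {
  paths_cells <- list()
  paths_gap <- numeric()
  go <- default_p$gap_open; ge <- default_p$gap_extend
  rec <- function(i, j, cells, gap, last) {
    if (i == m && j == n) {
      paths_cells[[length(paths_cells) + 1L]] <<- cells
      paths_gap[[length(paths_gap) + 1L]] <<- gap
      return(invisible())
    }
    if (i < m && j < n) rec(i + 1L, j + 1L, c(cells, i * n + j + 1L), gap, "D")
    if (i < m) rec(i + 1L, j, cells, gap + if (last == "U") ge else go, "U")
    if (j < n) rec(i, j + 1L, cells, gap + if (last == "L") ge else go, "L")
  }
  rec(0L, 0L, integer(), 0, "")
  list(cells = paths_cells, gap = paths_gap)
}

binary_strings <- function(len) {
  if (len == 0L) return(list(matrix(0L, 1, 0), ""))
  g <- as.matrix(expand.grid(rep(list(0:1), len)))[, len:1, drop = FALSE]
  strs <- apply(g, 1L, function(r) paste(c("A", "C")[r + 1L], collapse = ""))
  list(g, strs)
}

# oracle scores for every {A,C} pair of shape (m, n), in row-major pair order
# (a index varies slowest); also returns the pair strings
brute_affine_scores <- function(m, n) {
  p <- default_p
  pa <- enum_align_paths(m, n)
  A <- binary_strings(m); B <- binary_strings(n)
  npair <- nrow(A[[1]]) * nrow(B[[1]])
  if (m == 0L || n == 0L) {
    sc <- if (m == 0L && n == 0L) 0
          else p$gap_open + (max(m, n) - 1L) * p$gap_extend
    return(list(scores = rep(sc, npair), a = rep(A[[2]], each = nrow(B[[1]])),
                b = rep(B[[2]], times = nrow(A[[1]]))))
  }
  # agreement matrix: pairs x diagonal cells
  G <- matrix(0, npair, m * n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    G[, (i - 1L) * n + j] <-
      as.vector(t(outer(A[[1]][, i], B[[1]][, j], "==")))
  }
  npaths <- length(pa$cells)
  slen <- vapply(pa$cells, length, integer(1))
  best <- rep(-Inf, npair)
  chunk <- 1500L
  for (s in seq(1L, npaths, by = chunk)) {
    e <- min(npaths, s + chunk - 1L)
    P <- matrix(0, e - s + 1L, m * n)
    for (k in s:e) P[k - s + 1L, pa$cells[[k]]] <- 1
    H <- G %*% t(P)                          # hits per (pair, path)
    sc <- H * (p$match - p$mismatch) +
      rep(slen[s:e] * p$mismatch + pa$gap[s:e], each = npair)
    best <- pmax(best, apply(sc, 1L, max))
  }
  list(scores = best, a = rep(A[[2]], each = nrow(B[[1]])),
       b = rep(B[[2]], times = nrow(A[[1]])))
}

# --- exhaustive chain oracle ------------------------------------------------
#
# Minimum chain cost over every ordered compatible subset of the seeds,
# mirroring the chain cost model (uncovered mRNA bases + intron penalty,
# overlaps trimmed off the downstream block).

chain_cost_oracle <- function(seeds, mrna_len, params) {
  S <- nrow(seeds)
  ord <- order(seeds$mrna_start, seeds$gene_start)
  seeds <- seeds[ord, , drop = FALSE]
  best <- mrna_len   # empty chain
  for (mask in seq_len(2^S - 1L)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(S) - 1L)) > 0L)
    sub <- seeds[sel, , drop = FALSE]
    cost <- sub$mrna_start[1]
    n_int <- 0L
    feasible <- TRUE
    me <- sub$mrna_start[1] + sub$length[1]
    ge <- sub$gene_start[1] + sub$length[1]
    if (nrow(sub) > 1L) for (k in 2:nrow(sub)) {
      o <- max(0L, me - sub$mrna_start[k], ge - sub$gene_start[k])
      if (sub$length[k] - o < 1L) { feasible <- FALSE; break }
      mg <- sub$mrna_start[k] + o - me
      gg <- sub$gene_start[k] + o - ge
      intron <- (gg - mg) >= params$min_intron
      cost <- cost + mg + if (intron) params$intron_penalty else 0
      n_int <- n_int + intron
      me <- sub$mrna_start[k] + sub$length[k]
      ge <- sub$gene_start[k] + sub$length[k]
    }
    if (!feasible) next
    cost <- cost + (mrna_len - me)
    if (cost < best) best <- cost
  }
  best
}

random_seed_instance <- function(n_seeds, mrna_len = 120L) {
  ms <- sort(sample.int(mrna_len - 12L, n_seeds))
  data.frame(
    mrna_start = ms,
    gene_start = sort(sample.int(600L, n_seeds)),
    length = pmin(sample(4:20, n_seeds, replace = TRUE), mrna_len - ms))
}

# --- misc helpers -----------------------------------------------------------

random_nuc_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random normalized variant frame over a reference string (1-based local pos)
random_variant_frame <- function(ref, n_var = 4L) {
  n <- nchar(ref)
  rows <- list()
  claimed <- rep(FALSE, n)
  tries <- 0L
  while (length(rows) < n_var && tries < 200L) {
    tries <- tries + 1L
    kind <- sample(c("SNP", "INS", "DEL"), 1L)
    if (kind == "SNP") {
      i <- sample.int(n, 1L)
      if (claimed[i]) next
      rb <- substr(ref, i, i)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = "c", pos = i, kind = "SNP", ref_allele = rb,
        alt_allele = sample(setdiff(c("A", "C", "G", "T"), rb), 1L),
        stringsAsFactors = FALSE)
      claimed[i] <- TRUE
    } else if (kind == "INS") {
      i <- sample.int(n, 1L)
      if (claimed[i]) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = "c", pos = i, kind = "INS", ref_allele = "",
        alt_allele = random_nuc_string(sample(1:5, 1L)),
        stringsAsFactors = FALSE)
      claimed[i] <- TRUE
    } else {
      L <- sample(1:4, 1L)
      i <- sample.int(n - L, 1L)
      if (any(claimed[i:(i + L - 1L)])) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = "c", pos = i, kind = "DEL",
        ref_allele = substr(ref, i, i + L - 1L), alt_allele = "",
        stringsAsFactors = FALSE)
      claimed[i:(i + L - 1L)] <- TRUE
    }
  }
  do.call(rbind, rows)
}
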