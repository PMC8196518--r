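# Independent oracles used by the test suite.  Each is a deliberately naive
# implementation (brute force, enumeration, full dynamic programming) kept
# separate from the package's algorithms.

DNA <- c("A", "C", "G", "T")

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(DNA, n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# --- brute-force maximal-exact-match enumeration (one strand) ---------------
# O(n*m) over the match matrix; runs along diagonals, maximality checked at
# both ends.  Returns 0-based ref/query starts.
oracle_mems_strand <- function(ref, query, minlen) {
  r <- strsplit(ref, "")[[1]]
  q <- strsplit(query, "")[[1]]
  n <- length(r); m <- length(q)
  res <- list()
  for (d in (-(m - 1)):(n - 1)) {
    i0 <- max(1, 1 + d); j0 <- i0 - d
    len_diag <- min(n - i0, m - j0) + 1
    if (len_diag < minlen) next
    ii <- i0:(i0 + len_diag - 1); jj <- j0:(j0 + len_diag - 1)
    eq <- r[ii] == q[jj] & r[ii] %in% DNA & q[jj] %in% DNA
    rl <- rle(eq)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1
    for (k in which(rl$values & rl$lengths >= minlen)) {
      res[[length(res) + 1L]] <- data.frame(
        ref_pos = ii[starts[k]] - 1L, query_pos = jj[starts[k]] - 1L,
        length = rl$lengths[k])
    }
  }
  if (!length(res)) {
    return(data.frame(ref_pos = integer(), query_pos = integer(), length = integer()))
  }
  do.call(rbind, res)
}

oracle_mems <- function(ref, query, minlen) {
  plus <- oracle_mems_strand(ref, query, minlen)
  if (nrow(plus)) plus$strand <- "+"
  rcq <- oracle_revcomp(query)
  minus <- oracle_mems_strand(ref, rcq, minlen)
  if (nrow(minus)) {
    minus$query_pos <- nchar(query) - (minus$query_pos + minus$length)
    minus$strand <- "-"
  }
  out <- rbind(if (nrow(plus)) plus, if (nrow(minus)) minus)
  if (is.null(out)) {
    return(data.frame(ref_pos = integer(), query_pos = integer(),
                      length = integer(), strand = character()))
  }
  out[order(out$ref_pos, out$query_pos, out$strand), , drop = FALSE]
}

# --- full Needleman-Wunsch, unit scores, documented tie-break ---------------
# match +1, mismatch -1, gap -1; traceback prefers diagonal, then up
# (reference-only column D), then left (query-only column I)
oracle_nw_ops <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -(0:n); S[1, ] <- -(0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d <- S[i, j] + if (av[i] == bv[j]) 1 else -1
      u <- S[i, j + 1] - 1
      l <- S[i + 1, j] - 1
      S[i + 1, j + 1] <- max(d, u, l)
    }
  }
  ops <- character(0)
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + (if (av[i] == bv[j]) 1 else -1)) {
      ops <- c(if (av[i] == bv[j]) "M" else "X", ops); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 1) {
      ops <- c("D", ops); i <- i - 1
    } else {
      ops <- c("I", ops); j <- j - 1
    }
  }
  ops
}

oracle_nw_score <- function(ops) sum((ops == "M") - (ops != "M"))

# --- exhaustive best chain over anchors -------------------------------------
# same scoring contract as chain_anchors: sum of lengths minus once-counted
# overlap between consecutive anchors; gap <= max_gap on both axes; strict
# monotonicity of starts; overlap < min of the pair's lengths
oracle_best_chain_score <- function(anchors, max_gap) {
  n <- nrow(anchors)
  rs <- anchors$r_s; re <- anchors$r_e; qs <- anchors$q_s; qe <- anchors$q_e
  len <- anchors$len
  best <- 0
  extend <- function(chain, score) {
    best <<- max(best, score)
    last <- chain[length(chain)]
    for (nx in seq_len(n)) {
      if (nx %in% chain) next
      gr <- rs[nx] - re[last]; gq <- qs[nx] - qe[last]
      ov <- max(0, -gr, -gq)
      if (rs[last] < rs[nx] && qs[last] < qs[nx] &&
          gr <= max_gap && gq <= max_gap && ov < min(len[last], len[nx])) {
        extend(c(chain, nx), score + len[nx] - ov)
      }
    }
  }
  for (s in seq_len(n)) extend(s, len[s])
  best
}

# --- exhaustive conflict-free block subset search ---------------------------
# conflict: overlap > slop on the reference or the query axis
oracle_best_subset_score <- function(blocks, slop = 0) {
  n <- nrow(blocks)
  conflict <- function(i, j) {
    ovr <- if (blocks$ref_chrom[i] == blocks$ref_chrom[j])
      min(blocks$ref_end[i], blocks$ref_end[j]) -
        max(blocks$ref_start[i], blocks$ref_start[j]) else 0
    ovq <- if (blocks$query_chrom[i] == blocks$query_chrom[j])
      min(blocks$query_end[i], blocks$query_end[j]) -
        max(blocks$query_start[i], blocks$query_start[j]) else 0
    ovr > slop || ovq > slop
  }
  best <- 0
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    ok <- TRUE
    if (length(sel) > 1) {
      for (ii in seq_along(sel)[-1]) {
        for (jj in seq_len(ii - 1)) {
          if (conflict(sel[ii], sel[jj])) { ok <- FALSE; break }
        }
        if (!ok) break
      }
    }
    if (ok) best <- max(best, sum(blocks$score[sel]))
  }
  best
}

# --- per-base bitmap oracles ------------------------------------------------
oracle_union_segments <- function(windows, flags, chrom_len, min_segment) {
  mask <- logical(chrom_len)
  f <- windows[flags, , drop = FALSE]
  for (i in seq_len(nrow(f))) mask[(f$start[i] + 1):f$end[i]] <- TRUE
  r <- rle(mask)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  seg <- data.frame(start = starts[r$values] - 1L, end = ends[r$values])
  seg[seg$end - seg$start > min_segment, , drop = FALSE]
}

oracle_cds_covered_fraction <- function(cds, segments, chrom_len) {
  segmask <- logical(chrom_len)
  for (i in seq_len(nrow(segments)))
    segmask[(segments$start[i] + 1):segments$end[i]] <- TRUE
  cdsmask <- logical(chrom_len)
  for (i in seq_len(nrow(cds)))
    cdsmask[(cds$start[i] + 1):cds$end[i]] <- TRUE
  sum(segmask & cdsmask) / sum(cdsmask)
}

# --- exact hypergeometric upper tail by pmf enumeration ---------------------
oracle_hyper_tail <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# --- shared small fixtures --------------------------------------------------
# a small cultivar-pair simulation used by several suites
small_sim <- function(seed = 5, chrom_length = 200000) {
  cfg <- sim_config(n_chromosomes = 2, chrom_length = chrom_length,
                    n_pav_insertions = 4, n_pav_deletions = 4, n_inversions = 2,
                    n_intra_translocations = 1, n_inter_translocations = 1,
                    seed = seed)
  a <- simulate_ancestor(cfg)
  d <- derive_cultivar(a, cfg)
  list(config = cfg, a = a, b = d$genome, truth = d$truth)
}
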