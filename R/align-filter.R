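# One-to-one and colinear block filtering, whole-genome alignment driver,
# and the pluggable PAF-like block interface.

# trim a block by the given number of bases per forward-coordinate side,
# walking the cigar (chain orientation: ref forward; query reversed for '-')
trim_block <- function(b, trim_rs = 0L, trim_re = 0L, trim_qs = 0L, trim_qe = 0L) {
  if (trim_rs + trim_re + trim_qs + trim_qe == 0L) return(b)
  runs <- cigar_to_runs(b$cigar)
  # per-column expansion (overlap trims are small; columns stay modest)
  ops <- rep(runs$op, runs$len)
  cr <- ops %in% c("M", "X", "D")
  cq <- ops %in% c("M", "X", "I")
  head_r <- trim_rs
  head_q <- if (b$strand == "+") trim_qs else trim_qe
  tail_r <- trim_re
  tail_q <- if (b$strand == "+") trim_qe else trim_qs
  n <- length(ops)
  # head: consume columns until both axes satisfied
  h <- 0L; hr <- 0L; hq <- 0L
  while (h < n && (hr < head_r || hq < head_q)) {
    h <- h + 1L; hr <- hr + cr[h]; hq <- hq + cq[h]
  }
  t <- 0L; tr <- 0L; tq <- 0L
  while (t < n - h && (tr < tail_r || tq < tail_q)) {
    t <- t + 1L
    tr <- tr + cr[n - t + 1L]; tq <- tq + cq[n - t + 1L]
  }
  keep <- if (h + t >= n) integer(0) else (h + 1L):(n - t)
  if (!length(keep)) return(NULL)
  ops <- ops[keep]
  b$ref_start <- b$ref_start + hr
  b$ref_end <- b$ref_end - tr
  if (b$strand == "+") {
    b$query_start <- b$query_start + hq
    b$query_end <- b$query_end - tq
  } else {
    b$query_end <- b$query_end - hq
    b$query_start <- b$query_start + tq
  }
  b$n_match <- sum(ops == "M")
  b$aligned_len <- length(ops)
  b$identity <- b$n_match / b$aligned_len * 100
  b$score <- (b$ref_end - b$ref_start + b$query_end - b$query_start) / 2 *
    b$identity / 100
  b$cigar <- ops_to_cigar(ops)
  b
}

# resolve residual overlaps (all <= slop by construction) among kept blocks
# by trimming the lower-scoring block; drops blocks trimmed below min length
trim_kept_overlaps <- function(b, params) {
  if (nrow(b) <= 1L) return(b)
  ord <- order(-b$score)
  kept <- list()
  for (i in ord) {
    blk <- b[i, ]
    trims <- c(rs = 0L, re = 0L, qs = 0L, qe = 0L)
    for (kb in kept) {
      if (blk$ref_chrom == kb$ref_chrom) {
        ov <- min(blk$ref_end, kb$ref_end) - max(blk$ref_start, kb$ref_start)
        if (ov > 0L) {
          if (kb$ref_start <= blk$ref_start) trims["rs"] <- max(trims["rs"], ov)
          else trims["re"] <- max(trims["re"], ov)
        }
      }
      if (blk$query_chrom == kb$query_chrom) {
        ov <- min(blk$query_end, kb$query_end) - max(blk$query_start, kb$query_start)
        if (ov > 0L) {
          if (kb$query_start <= blk$query_start) trims["qs"] <- max(trims["qs"], ov)
          else trims["qe"] <- max(trims["qe"], ov)
        }
      }
    }
    blk <- trim_block(blk, trims["rs"], trims["re"], trims["qs"], trims["qe"])
    if (!is.null(blk) &&
        min(blk$ref_end - blk$ref_start, blk$query_end - blk$query_start) >=
          params$min_block_len)
      kept[[length(kept) + 1L]] <- blk
  }
  out <- do.call(rbind, kept)
  out <- out[order(out$ref_chrom, out$ref_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# conflict edges among blocks: overlap beyond `slop` on reference or query
block_conflicts <- function(b, slop = 0L) {
  edges <- list()
  pair_overlaps <- function(chrom, start, end) {
    d <- data.table(id = seq_along(chrom), chrom = chrom, start = start, end = end)
    setkey(d, chrom, start, end)
    ov <- foverlaps(d, d, type = "any")
    ov <- ov[ov$id < ov$i.id &
               pmin(ov$end, ov$i.end) - pmax(ov$start, ov$i.start) > slop, ]
    unique(data.table(a = ov$id, b = ov$i.id))
  }
  e1 <- pair_overlaps(b$ref_chrom, b$ref_start, b$ref_end)
  e2 <- pair_overlaps(b$query_chrom, b$query_start, b$query_end)
  unique(rbind(e1, e2))
}

# exact maximum-weight independent set by branch and bound with a
# sum-of-weights upper bound; adj: list of integer neighbour vectors
mwis_exact <- function(weights, adj) {
  n <- length(weights)
  best_set <- integer(0)
  best_w <- -Inf
  rec <- function(avail, cur_set, cur_w) {
    if (!length(avail)) {
      if (cur_w > best_w) { best_w <<- cur_w; best_set <<- cur_set }
      return(invisible())
    }
    if (cur_w + sum(weights[avail]) <= best_w) return(invisible())
    v <- avail[which.max(weights[avail])]
    # include v
    rec(setdiff(avail, c(v, adj[[v]])), c(cur_set, v), cur_w + weights[v])
    # exclude v
    rec(setdiff(avail, v), cur_set, cur_w)
  }
  rec(seq_len(n), integer(0), 0)
  sort(best_set)
}

# sequential weighted interval scheduling on one axis; returns kept indices
wis_axis <- function(ids, chrom, start, end, weight) {
  keep <- integer(0)
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    o <- sel[order(end[sel])]
    n <- length(o)
    s <- start[o]; e <- end[o]; w <- weight[o]
    opt <- numeric(n); take <- logical(n); prev <- integer(n)
    for (i in seq_len(n)) {
      p <- findInterval(s[i], e)  # last j with e[j] <= s[i]
      prev[i] <- p
      with_i <- w[i] + if (p > 0) opt[p] else 0
      without <- if (i > 1) opt[i - 1] else 0
      opt[i] <- max(with_i, without)
      take[i] <- with_i >= without
    }
    i <- n
    while (i > 0) {
      if (take[i]) { keep <- c(keep, o[i]); i <- prev[i] } else i <- i - 1L
    }
  }
  ids[keep]
}

#' One-to-one block filter
#'
#' Drops blocks below `params$min_identity`, then keeps a maximum-total-score
#' subset with no overlap on either genome (rearrangements permitted) —
#' the "delta-filter -1" semantics.  Overlaps of at most
#' `params$overlap_slop` bp (seed spillover across event junctions) are not
#' conflicts; they are trimmed from the lower-scoring block afterwards, so
#' the output never contains two blocks overlapping on either genome.  The
#' optimum is computed exactly per conflict-graph component (branch and
#' bound); components larger than `max_exact` fall back to sequential
#' weighted interval scheduling on the reference and then the query axis.
#'
#' @param blocks Block data frame (from [polish_block()]/[align_genomes()]).
#' @param params [align_params()].
#' @param max_exact Largest component size solved exactly.
#' @return Filtered block data frame.
#' @export
filter_one_to_one <- function(blocks, params = align_params(), max_exact = 28L) {
  b <- blocks[blocks$identity >= params$min_identity, , drop = FALSE]
  if (nrow(b) <= 1L) return(b)
  edges <- block_conflicts(b, slop = params$overlap_slop)
  if (!nrow(edges)) return(trim_kept_overlaps(b, params))
  n <- nrow(b)
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    adj[[edges$a[i]]] <- c(adj[[edges$a[i]]], edges$b[i])
    adj[[edges$b[i]]] <- c(adj[[edges$b[i]]], edges$a[i])
  }
  # connected components
  comp <- integer(n); cid <- 0L
  for (v in seq_len(n)) {
    if (comp[v] == 0L) {
      cid <- cid + 1L
      queue <- v; comp[v] <- cid
      while (length(queue)) {
        u <- queue[[1L]]; queue <- queue[-1L]
        for (x in adj[[u]]) if (comp[x] == 0L) { comp[x] <- cid; queue <- c(queue, x) }
      }
    }
  }
  keep <- logical(n)
  for (cc in seq_len(cid)) {
    vs <- which(comp == cc)
    if (length(vs) == 1L) { keep[vs] <- TRUE; next }
    if (length(vs) <= max_exact) {
      sub_adj <- lapply(vs, function(v) match(intersect(adj[[v]], vs), vs))
      sel <- mwis_exact(b$score[vs], sub_adj)
      keep[vs[sel]] <- TRUE
    } else {
      # large component: reference-axis then query-axis interval scheduling
      k1 <- wis_axis(vs, b$ref_chrom[vs], b$ref_start[vs], b$ref_end[vs], b$score[vs])
      k2 <- wis_axis(k1, b$query_chrom[k1], b$query_start[k1], b$query_end[k1], b$score[k1])
      keep[k2] <- TRUE
    }
  }
  trim_kept_overlaps(b[keep, , drop = FALSE], params)
}

#' Colinear (global) block filter
#'
#' Applies the one-to-one filter, then keeps for each reference chromosome
#' the single maximum-score chain of `+`-strand blocks strictly increasing
#' in both genomes on one query chromosome (no rearrangements) — the
#' "delta-filter -g" semantics.  Output is by construction a subset of the
#' one-to-one output.
#'
#' @inheritParams filter_one_to_one
#' @return Filtered block data frame.
#' @export
filter_colinear <- function(blocks, params = align_params()) {
  b <- filter_one_to_one(blocks, params)
  if (!nrow(b)) return(b)
  keep <- logical(nrow(b))
  for (rc in unique(b$ref_chrom)) {
    best_chain <- integer(0); best_score <- -Inf
    for (qc in unique(b$query_chrom[b$ref_chrom == rc])) {
      sel <- which(b$ref_chrom == rc & b$query_chrom == qc & b$strand == "+")
      if (!length(sel)) next
      o <- sel[order(b$ref_start[sel])]
      n <- length(o)
      qs <- b$query_start[o]; w <- b$score[o]
      opt <- numeric(n); prev <- rep(0L, n)
      for (i in seq_len(n)) {
        opt[i] <- w[i]
        js <- which(qs[seq_len(i - 1L)] < qs[i])
        if (length(js)) {
          j <- js[which.max(opt[js])]
          if (opt[j] + w[i] > opt[i]) { opt[i] <- opt[j] + w[i]; prev[i] <- j }
        }
      }
      i <- which.max(opt)
      sc <- opt[i]
      chain <- integer(0)
      while (i > 0L) { chain <- c(o[i], chain); i <- prev[i] }
      if (sc > best_score) { best_score <- sc; best_chain <- chain }
    }
    keep[best_chain] <- TRUE
  }
  b[keep, , drop = FALSE]
}

#' Align two genomes into base-level blocks
#'
#' MEM seeding across all chromosome pairs, chaining, and banded gap closing.
#' Returns raw polished blocks; apply [filter_one_to_one()] /
#' [filter_colinear()] downstream.
#'
#' @param ref_genome,query_genome Genomes (named character vectors).
#' @param params [align_params()].
#' @param anchors Optional precomputed anchor table (from an earlier pass).
#' @return Block data frame with CIGAR-like edit runs.
#' @export
align_genomes <- function(ref_genome, query_genome, params = align_params(),
                          anchors = NULL) {
  ref_genome <- as_genome(ref_genome)
  query_genome <- as_genome(query_genome)
  if (is.null(anchors))
    anchors <- find_anchors_genome(ref_genome, query_genome, params$min_mem_len)
  if (!nrow(anchors)) return(empty_blocks())
  rc_cache <- new.env(parent = emptyenv())
  rc_of <- function(ch) {
    if (is.null(rc_cache[[ch]])) rc_cache[[ch]] <- revcomp(query_genome[[ch]])
    rc_cache[[ch]]
  }
  out <- list()
  pairs <- unique(data.frame(rc = anchors$ref_chrom, qc = anchors$query_chrom))
  for (i in seq_len(nrow(pairs))) {
    rc <- pairs$rc[i]; qc <- pairs$qc[i]
    sub <- anchors[anchors$ref_chrom == rc & anchors$query_chrom == qc, ]
    qlen <- nchar(query_genome[[qc]])
    chains <- chain_anchors(data.frame(ref_pos = sub$ref_pos, query_pos = sub$query_pos,
                                       length = sub$length, strand = sub$strand),
                            params, query_len = qlen)
    for (ch in chains) {
      if (attr(ch, "score") < params$min_block_len) next
      qseq <- if (ch$strand[1L] == "-") rc_of(qc) else query_genome[[qc]]
      bl <- polish_chain_one(ch, ref_genome[[rc]], qseq, qlen, params,
                             ref_chrom = rc, query_chrom = qc)
      if (nrow(bl)) out[[length(out) + 1L]] <- bl
    }
  }
  if (!length(out)) return(empty_blocks())
  blocks <- do.call(rbind, out)
  blocks <- blocks[order(blocks$ref_chrom, blocks$ref_start, blocks$query_chrom,
                         blocks$query_start), , drop = FALSE]
  blocks$block_id <- seq_len(nrow(blocks))
  rownames(blocks) <- NULL
  blocks
}

#' Write blocks as PAF-like TSV
#' @param blocks Block data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(blocks, path) {
  df <- data.frame(query = blocks$query_chrom, q_start = blocks$query_start,
                   q_end = blocks$query_end, strand = blocks$strand,
                   target = blocks$ref_chrom, t_start = blocks$ref_start,
                   t_end = blocks$ref_end, matches = blocks$n_match,
                   aligned_len = blocks$aligned_len,
                   identity = round(blocks$identity, 4), score = round(blocks$score, 4),
                   cigar = blocks$cigar)
  write_tsv_file(df, path)
}

#' Read externally produced blocks (PAF-like TSV)
#'
#' The pluggable alignment path: users with real data can feed blocks from an
#' external aligner.  Blocks without a `cigar` column carry no base-level
#' edit detail and cannot feed [call_variants()].
#'
#' @param path Path to a TSV written by [write_paf()] or equivalent.
#' @return Block data frame.
#' @export
read_paf <- function(path) {
  df <- read_tsv_file(path)
  data.frame(block_id = seq_len(nrow(df)), ref_chrom = df$target,
             ref_start = df$t_start, ref_end = df$t_end,
             query_chrom = df$query, query_start = df$q_start,
             query_end = df$q_end, strand = df$strand,
             identity = df$identity, score = df$score,
             aligned_len = df$aligned_len, n_match = df$matches,
             cigar = if ("cigar" %in% colnames(df)) df$cigar else NA_character_,
             stringsAsFactors = FALSE)
}
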