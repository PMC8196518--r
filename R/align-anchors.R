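# MEM seeding and anchor chaining.
#
# Anchors are maximal exact matches (MEMs) of length >= min_mem_len, found by
# joining exact k-mer (k = min_mem_len) positions of reference and query and
# collapsing runs of consecutive hits on the same diagonal; a shared substring
# of length L >= k yields exactly the run of its L - k + 1 constituent k-mers,
# so collapsed runs are maximal on both sides by construction.  N never
# matches and breaks anchors.

#' Alignment parameters
#'
#' @param min_mem_len Minimum maximal-exact-match (seed) length, bp.
#' @param max_anchor_gap Maximum inter-anchor gap inside one chain, bp.
#' @param band_width Band half-width for gap-closing global alignment, bp.
#' @param min_identity Minimum block identity kept by the filters, percent.
#' @param min_block_len Minimum polished block length, bp.
#' @param overlap_slop Block overlaps up to this many bp (seed-extension
#'   spillover at event junctions) are trimmed from the lower-scoring block
#'   instead of counting as conflicts in the one-to-one filter.
#' @return A list of class `"align_params"`.
#' @export
align_params <- function(min_mem_len = 20L, max_anchor_gap = 1000L,
                         band_width = 100L, min_identity = 90,
                         min_block_len = 200L, overlap_slop = 50L) {
  p <- list(min_mem_len = as.integer(min_mem_len),
            max_anchor_gap = as.integer(max_anchor_gap),
            band_width = as.integer(band_width),
            min_identity = min_identity,
            min_block_len = as.integer(min_block_len),
            overlap_slop = as.integer(overlap_slop))
  check_field(p$min_identity >= 0 && p$min_identity <= 100, "min_identity", "must be in [0,100]")
  check_field(p$min_mem_len >= 4L, "min_mem_len", "must be >= 4")
  check_field(p$band_width >= 1L, "band_width", "must be positive")
  class(p) <- "align_params"
  p
}

# k-mer start-position table for one sequence: data.table(val, pos) (0-based)
kmer_table <- function(seq, k) {
  codes <- seq_to_int(seq)
  v <- kmer_values(codes, k)
  keep <- !is.na(v)
  data.table(val = v[keep], pos = which(keep) - 1L)
}

# collapse k-mer hit pairs into maximal runs; hits: data.table(rpos, qpos),
# 0-based starts.  Returns data.table(ref_pos, query_pos, length).
collapse_diagonal_runs <- function(hits, k) {
  if (!nrow(hits)) {
    return(data.table(ref_pos = integer(), query_pos = integer(), length = integer()))
  }
  hits[, diag := rpos - qpos]
  setorder(hits, diag, qpos)
  new_run <- c(TRUE, diff(hits$diag) != 0 | diff(hits$qpos) != 1)
  hits[, run := cumsum(new_run)]
  out <- hits[, .(ref_pos = rpos[1L], query_pos = qpos[1L],
                  length = .N + k - 1L), by = run]
  out[, run := NULL]
  out[]
}

#' Find maximal exact matches between two sequences
#'
#' Returns every maximal exact match of length >= `min_mem_len` on both
#' strands.  `query_pos` is always on the forward query strand; for `-`
#' anchors the query interval `[query_pos, query_pos + length)` is the
#' reverse complement of the reference interval.
#'
#' @param ref,query DNA sequences (single strings over A/C/G/T/N).
#' @param min_mem_len Minimum match length.
#' @return Data frame with columns `ref_pos`, `query_pos` (0-based),
#'   `length`, `strand`.
#' @export
find_anchors <- function(ref, query, min_mem_len = 20L) {
  k <- as.integer(min_mem_len)
  if (nchar(ref) < k || nchar(query) < k) {
    return(data.frame(ref_pos = integer(), query_pos = integer(),
                      length = integer(), strand = character()))
  }
  rt <- kmer_table(ref, k)
  qt <- kmer_table(query, k)
  qn <- nchar(query)
  plus <- merge(rt, qt, by = "val", allow.cartesian = TRUE,
                suffixes = c(".r", ".q"))
  plus <- collapse_diagonal_runs(data.table(rpos = plus$pos.r, qpos = plus$pos.q), k)
  plus[, strand := "+"]
  qrc <- kmer_table(revcomp(query), k)
  minus <- merge(rt, qrc, by = "val", allow.cartesian = TRUE,
                 suffixes = c(".r", ".q"))
  minus <- collapse_diagonal_runs(data.table(rpos = minus$pos.r, qpos = minus$pos.q), k)
  if (nrow(minus)) {
    # map back to forward-strand query coordinates
    minus[, query_pos := qn - (query_pos + length)]
  }
  minus[, strand := "-"]
  out <- rbind(plus, minus)
  setorder(out, ref_pos, query_pos, strand)
  as.data.frame(out)
}

# genome-wide anchor discovery: one k-mer join across all chromosome pairs.
# Returns data.table(ref_chrom, ref_pos, query_chrom, query_pos, length, strand).
find_anchors_genome <- function(ref_genome, query_genome, min_mem_len = 20L) {
  k <- as.integer(min_mem_len)
  tab_genome <- function(g) {
    rbindlist(lapply(names(g), function(ch) {
      t <- kmer_table(g[[ch]], k)
      if (nrow(t)) t[, chrom := ch]
      t
    }), fill = TRUE)
  }
  rt <- tab_genome(ref_genome)
  empty <- data.table(ref_chrom = character(), ref_pos = integer(),
                      query_chrom = character(), query_pos = integer(),
                      length = integer(), strand = character())
  if (!nrow(rt)) return(empty)
  one_strand <- function(qg, strand) {
    qt <- tab_genome(qg)
    if (!nrow(qt)) return(NULL)
    m <- merge(rt, qt, by = "val", allow.cartesian = TRUE, suffixes = c(".r", ".q"))
    if (!nrow(m)) return(NULL)
    res <- m[, {
      r <- collapse_diagonal_runs(data.table(rpos = pos.r, qpos = pos.q), k)
      r
    }, by = .(chrom.r, chrom.q)]
    setnames(res, c("chrom.r", "chrom.q"), c("ref_chrom", "query_chrom"))
    res[, strand := strand]
    res
  }
  plus <- one_strand(query_genome, "+")
  qrc <- setNames(revcomp(query_genome), names(query_genome))
  minus <- one_strand(qrc, "-")
  if (!is.null(minus) && nrow(minus)) {
    qlen <- nchar(query_genome)
    minus[, query_pos := qlen[query_chrom] - (query_pos + length)]
  }
  out <- rbindlist(list(plus, minus), use.names = TRUE)
  if (is.null(out) || !nrow(out)) return(empty)
  setcolorder(out, c("ref_chrom", "ref_pos", "query_chrom", "query_pos", "length", "strand"))
  setorder(out, ref_chrom, ref_pos, query_chrom, query_pos)
  out[]
}

# Chain scoring: chain score = sum of anchor lengths minus, for each
# consecutive pair, max(0, -gap_ref, -gap_query) (overlap trimmed once).
# A predecessor p of anchor a must satisfy, in chain coordinates (query
# reverse-complemented for '-' chains): p.start < a.start on both axes,
# gap_ref and gap_query <= max_anchor_gap, and overlap < min(p.len, a.len).
chain_pair_ok <- function(pr_s, pr_e, pq_s, pq_e, plen, ar_s, aq_s, alen, max_gap) {
  gr <- ar_s - pr_e
  gq <- aq_s - pq_e
  ov <- pmax(0, pmax(-gr, -gq))
  pr_s < ar_s & pq_s < aq_s & gr <= max_gap & gq <= max_gap & ov < pmin(plen, alen)
}

#' Chain co-strand anchors into collinear chains
#'
#' Partitions anchors of one chromosome pair into maximal-score collinear
#' chains: coordinates strictly increasing on both axes per strand (query
#' axis reversed for `-` anchors), inter-anchor gaps at most
#' `params$max_anchor_gap` on both axes.  Chain score is the summed anchor
#' length minus once-counted overlaps between consecutive anchors.  Each
#' anchor joins at most one chain.
#'
#' @param anchors Data frame from [find_anchors()] (one chromosome pair).
#' @param params [align_params()].
#' @param query_len Forward-strand query length (needed to orient `-`
#'   anchors); defaults to the maximum query end seen.
#' @return List of chains; each chain is a data frame of its anchors (sorted
#'   by `ref_pos`) with attribute `score`.
#' @export
chain_anchors <- function(anchors, params = align_params(), query_len = NULL) {
  a <- as.data.table(anchors)
  if (!nrow(a)) return(list())
  if (is.null(query_len)) query_len <- max(a$query_pos + a$length)
  chains <- list()
  for (st in unique(a$strand)) {
    g <- a[a$strand == st, ]
    # chain coordinates: query axis flipped for '-'
    g[, `:=`(r_s = ref_pos, r_e = ref_pos + length)]
    if (st == "+") {
      g[, `:=`(q_s = query_pos, q_e = query_pos + length)]
    } else {
      g[, `:=`(q_s = query_len - (query_pos + length), q_e = query_len - query_pos)]
    }
    setorder(g, r_s, q_s)
    n <- nrow(g)
    score <- as.numeric(g$length)
    prev <- rep(NA_integer_, n)
    max_gap <- params$max_anchor_gap
    max_len <- max(g$length)
    lo <- 1L
    for (i in seq_len(n)) {
      # candidate predecessors: r_s within reach of the gap constraint
      while (g$r_s[lo] < g$r_s[i] - max_gap - max_len && lo < i) lo <- lo + 1L
      js <- lo:i
      js <- js[js < i]
      if (length(js)) {
        ok <- chain_pair_ok(g$r_s[js], g$r_e[js], g$q_s[js], g$q_e[js], g$length[js],
                            g$r_s[i], g$q_s[i], g$length[i], max_gap)
        js <- js[ok]
        if (length(js)) {
          gr <- g$r_s[i] - g$r_e[js]
          gq <- g$q_s[i] - g$q_e[js]
          cand <- score[js] + g$length[i] - pmax(0, pmax(-gr, -gq))
          b <- which.max(cand)
          if (cand[b] > score[i]) {
            score[i] <- cand[b]
            prev[i] <- js[b]
          }
        }
      }
    }
    used <- rep(FALSE, n)
    for (i in order(score, decreasing = TRUE)) {
      if (used[i]) next
      idx <- integer(0)
      j <- i
      while (!is.na(j) && !used[j]) {
        idx <- c(j, idx)
        used[j] <- TRUE
        j <- prev[j]
      }
      ch <- as.data.frame(g[idx, .(ref_pos, query_pos, length, strand)])
      # actual score of the extracted chain (backtracking may stop early at a
      # previously used anchor, so recompute from the members)
      if (length(idx) > 1L) {
        gr <- g$r_s[idx[-1L]] - g$r_e[idx[-length(idx)]]
        gq <- g$q_s[idx[-1L]] - g$q_e[idx[-length(idx)]]
        attr(ch, "score") <- sum(g$length[idx]) - sum(pmax(0, pmax(-gr, -gq)))
      } else {
        attr(ch, "score") <- as.numeric(g$length[idx])
      }
      chains[[length(chains) + 1L]] <- ch
    }
  }
  # deterministic order: by score descending, then ref position
  ord <- order(-vapply(chains, attr, numeric(1), "score"),
               vapply(chains, function(c) c$ref_pos[1L], numeric(1)))
  chains[ord]
}
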