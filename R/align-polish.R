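# Gap closing and block polishing.
#
# Inter-anchor gaps are closed by banded global alignment with unit scores
# (match +1, mismatch -1, gap -1) and a documented deterministic tie-break:
# diagonal (match/mismatch) preferred over up (deletion from the query) over
# left (insertion into the query).  A gap whose length difference exceeds the
# band even after doubling the band splits the block at that gap.
#
# Block edit operations are stored as CIGAR-like strings over
# M (match), X (mismatch), I (query-only base), D (reference-only base).

# banded global alignment of coded int vectors; returns character vector of
# per-column ops (M/X/I/D) or NULL if the band is infeasible
nw_banded_ops <- function(a, b, band) {
  la <- length(a); lb <- length(b)
  if (abs(la - lb) > band) return(NULL)
  if (la == 0L) return(rep("I", lb))
  if (lb == 0L) return(rep("D", la))
  NEG <- -1e9
  # rows i over a (0..la), cols j over b; band: |j - i| <= band
  prev <- rep(NEG, lb + 1L)
  jlo_prev <- 0L
  jhi_prev <- min(lb, band)
  prev[(jlo_prev:jhi_prev) + 1L] <- -(jlo_prev:jhi_prev)
  tb <- vector("list", la + 1L)  # traceback rows: 1=diag, 2=up, 3=left
  tb[[1L]] <- list(jlo = jlo_prev, dir = rep(3L, jhi_prev - jlo_prev + 1L))
  for (i in seq_len(la)) {
    jlo <- max(0L, i - band); jhi <- min(lb, i + band)
    cur <- rep(NEG, lb + 1L)
    js <- jlo:jhi
    # up: gap in b (consume a[i]) -> op D
    up <- prev[js + 1L] - 1
    # diag: consume a[i], b[j]
    dg <- rep(NEG, length(js))
    jd <- js[js >= 1L]
    if (length(jd)) {
      m <- ifelse(!is.na(a[i]) & !is.na(b[jd]) & a[i] == b[jd], 1, -1)
      dg[js >= 1L] <- prev[jd] + m
    }
    # left: filled in-order below
    best <- pmax(dg, up)
    dir <- ifelse(dg >= up, 1L, 2L)
    # in-band left transitions require a sequential pass
    vals <- best
    for (t in seq_along(js)) {
      if (t > 1L) {
        lf <- vals[t - 1L] - 1
        if (lf > vals[t]) { vals[t] <- lf; dir[t] <- 3L }
      }
    }
    cur[js + 1L] <- vals
    tb[[i + 1L]] <- list(jlo = jlo, dir = dir)
    prev <- cur
  }
  # traceback
  ops <- character(la + lb)
  n <- 0L
  i <- la; j <- lb
  while (i > 0L || j > 0L) {
    row <- tb[[i + 1L]]
    d <- row$dir[j - row$jlo + 1L]
    n <- n + 1L
    if (d == 1L) {
      ops[n] <- if (!is.na(a[i]) && !is.na(b[j]) && a[i] == b[j]) "M" else "X"
      i <- i - 1L; j <- j - 1L
    } else if (d == 2L) {
      ops[n] <- "D"; i <- i - 1L
    } else {
      ops[n] <- "I"; j <- j - 1L
    }
  }
  rev(ops[seq_len(n)])
}

# run-length encode op characters into a CIGAR-like string
ops_to_cigar <- function(ops) {
  if (!length(ops)) return("")
  r <- rle(ops)
  paste0(r$lengths, r$values, collapse = "")
}

cigar_to_runs <- function(cigar) {
  if (is.na(cigar) || cigar == "") {
    return(data.frame(len = integer(), op = character()))
  }
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[MXID]", cigar))[[1]]
  data.frame(len = len, op = op)
}

cigar_stats <- function(cigar) {
  r <- cigar_to_runs(cigar)
  c(match = sum(r$len[r$op == "M"]),
    mismatch = sum(r$len[r$op == "X"]),
    ins = sum(r$len[r$op == "I"]),
    del = sum(r$len[r$op == "D"]),
    cols = sum(r$len))
}

# align one inter-anchor gap; returns op character vector or NULL (split)
close_gap_ops <- function(ra, qa, band) {
  lr <- length(ra); lq <- length(qa)
  if (lr == 0L && lq == 0L) return(character(0))
  if (abs(lr - lq) > 2L * band) return(NULL)  # beyond the doubled band: split
  if (lr == 0L) return(rep("I", lq))
  if (lq == 0L) return(rep("D", lr))
  if (lr == lq) {
    same <- !is.na(ra) & !is.na(qa) & ra == qa
    h <- sum(!same)
    if (h <= 1L) return(ifelse(same, "M", "X"))  # provably NW-optimal
  }
  ops <- nw_banded_ops(ra, qa, band)
  if (is.null(ops)) ops <- nw_banded_ops(ra, qa, 2L * band)
  ops
}

empty_blocks <- function() {
  data.frame(block_id = integer(), ref_chrom = character(), ref_start = integer(),
             ref_end = integer(), query_chrom = character(), query_start = integer(),
             query_end = integer(), strand = character(), identity = numeric(),
             score = numeric(), aligned_len = integer(), n_match = integer(),
             cigar = character(), stringsAsFactors = FALSE)
}

# polish one chain into >= 0 alignment blocks.
# ref_seq: reference chromosome; query_chain_seq: query chromosome already
# reverse-complemented for '-' chains (chain coordinates).  qlen: forward
# query chromosome length, for reporting forward-strand query coordinates.
polish_chain_one <- function(chain, ref_seq, query_chain_seq, qlen, params,
                             ref_chrom = "ref", query_chrom = "query") {
  st <- chain$strand[1L]
  g <- data.table(r_s = chain$ref_pos, r_e = chain$ref_pos + chain$length,
                  len = chain$length)
  if (st == "+") {
    g[, `:=`(q_s = chain$query_pos, q_e = chain$query_pos + chain$length)]
  } else {
    g[, `:=`(q_s = qlen - (chain$query_pos + chain$length),
             q_e = qlen - chain$query_pos)]
  }
  setorder(g, r_s)
  # trim overlaps with the previous anchor
  n <- nrow(g)
  if (n > 1L) {
    for (i in 2:n) {
      ov <- max(0L, g$r_e[i - 1L] - g$r_s[i], g$q_e[i - 1L] - g$q_s[i])
      if (ov > 0L) {
        g$r_s[i] <- g$r_s[i] + ov
        g$q_s[i] <- g$q_s[i] + ov
      }
    }
  }
  segs <- list()  # finished blocks (op vectors + coord ranges)
  cur_ops <- list(); cur_r0 <- g$r_s[1L]; cur_q0 <- g$q_s[1L]
  flush <- function(r_end, q_end) {
    ops <- unlist(cur_ops)
    if (length(ops)) {
      segs[[length(segs) + 1L]] <<- list(ops = ops, r0 = cur_r0, r1 = r_end,
                                         q0 = cur_q0, q1 = q_end)
    }
  }
  cur_ops[[1L]] <- rep("M", g$r_e[1L] - g$r_s[1L])
  for (i in seq_len(n - 1L)[n > 1L]) {
    ra <- seq_to_int(substr0(ref_seq, g$r_e[i], g$r_s[i + 1L]))
    qa <- seq_to_int(substr0(query_chain_seq, g$q_e[i], g$q_s[i + 1L]))
    ops <- close_gap_ops(ra, qa, params$band_width)
    if (is.null(ops)) {
      flush(g$r_e[i], g$q_e[i])
      cur_ops <- list(); cur_r0 <- g$r_s[i + 1L]; cur_q0 <- g$q_s[i + 1L]
    } else {
      cur_ops[[length(cur_ops) + 1L]] <- ops
    }
    cur_ops[[length(cur_ops) + 1L]] <- rep("M", g$r_e[i + 1L] - g$r_s[i + 1L])
  }
  flush(g$r_e[n], g$q_e[n])

  rows <- lapply(segs, function(s) {
    cols <- length(s$ops)
    nm <- sum(s$ops == "M")
    identity <- if (cols > 0) nm / cols * 100 else 0
    if (min(s$r1 - s$r0, s$q1 - s$q0) < params$min_block_len) return(NULL)
    qf <- if (st == "+") c(s$q0, s$q1) else c(qlen - s$q1, qlen - s$q0)
    data.frame(block_id = NA_integer_, ref_chrom = ref_chrom, ref_start = s$r0,
               ref_end = s$r1, query_chrom = query_chrom, query_start = qf[1L],
               query_end = qf[2L], strand = st, identity = identity,
               score = (s$r1 - s$r0 + s$q1 - s$q0) / 2 * identity / 100,
               aligned_len = cols, n_match = nm,
               cigar = ops_to_cigar(s$ops), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_blocks())
  do.call(rbind, rows)
}

#' Polish an anchor chain into alignment blocks
#'
#' Closes inter-anchor gaps by banded global alignment (unit scores) and
#' reports base-level blocks.  A gap exceeding the band after a retry with a
#' doubled band splits the chain into separate blocks; blocks shorter than
#' `params$min_block_len` are discarded.
#'
#' @param chain One chain from [chain_anchors()].
#' @param ref,query The two full sequences the anchors index into.
#' @param params [align_params()].
#' @return Data frame of blocks with per-column edit runs in `cigar`
#'   (M/X/I/D), identity in percent and `score = aligned_length x identity`.
#' @export
polish_block <- function(chain, ref, query, params = align_params()) {
  if (!nrow(chain)) return(empty_blocks())
  qlen <- nchar(query)
  qseq <- if (chain$strand[1L] == "-") revcomp(query) else query
  out <- polish_chain_one(chain, ref, qseq, qlen, params)
  if (nrow(out)) out$block_id <- seq_len(nrow(out))
  out
}

#' Map a window sequence onto a target genome
#'
#' Finds the best-supported local placement of `window` in `target`:
#' anchors are clustered per target chromosome/strand with internal gaps up
#' to `max_gap` (500 bp, the window mapper's gap allowance), and coverage is
#' the fraction of window bases covered by the best single cluster.
#'
#' @param window Window sequence (length = the configured window size).
#' @param target Target genome (named character vector).
#' @param params [align_params()].
#' @param max_gap Maximum internal gap within one placement, bp.
#' @return List with `coverage` (fraction) and `best_hit` (data frame with
#'   `chrom`, `start`, `end`, `strand`, or `NULL` when no anchor chain is
#'   found).
#' @export
map_window <- function(window, target, params = align_params(), max_gap = 500L) {
  target <- as_genome(target)
  wlen <- nchar(window)
  hits <- rbindlist(lapply(names(target), function(ch) {
    a <- find_anchors(target[[ch]], window, params$min_mem_len)
    if (!nrow(a)) return(NULL)
    data.table(tchrom = ch, tpos = a$ref_pos, qs = a$query_pos,
               qe = a$query_pos + a$length, strand = a$strand,
               dnum = ifelse(a$strand == "+", a$ref_pos - a$query_pos,
                             a$ref_pos + a$query_pos))
  }))
  if (is.null(hits) || !nrow(hits)) return(list(coverage = 0, best_hit = NULL))
  setorder(hits, tchrom, strand, qs, qe)
  hits[, cl := cumsum(c(TRUE, diff(qs) > max_gap | abs(diff(dnum)) > max_gap)),
       by = .(tchrom, strand)]
  cov <- hits[, {
    cm <- cummax(c(-1L, head(qe, -1L)))
    list(covered = sum(pmax(0L, qe - pmax(qs, cm))),
         t0 = min(tpos), t1 = max(tpos + (qe - qs)))
  }, by = .(tchrom, strand, cl)]
  best <- cov[which.max(cov$covered), ]
  list(coverage = min(1, best$covered / wlen),
       best_hit = data.frame(chrom = best$tchrom, start = best$t0, end = best$t1,
                             strand = best$strand))
}

# Batch window coverage of every query window against a target genome, using
# one genome-wide anchor pass (identical clustering rule to map_window).
# windows: data.frame(chrom, start, end [, wid]).  Returns coverage per window
# (same order), 0 for unmapped windows.
window_coverage_batch <- function(windows, query_genome, target_genome,
                                  params = align_params(), max_gap = 500L,
                                  anchors = NULL) {
  w <- as.data.table(windows)
  w[, wid := .I]
  if (is.null(anchors))
    anchors <- find_anchors_genome(target_genome, query_genome, params$min_mem_len)
  if (!nrow(anchors)) return(rep(0, nrow(w)))
  a <- data.table(chrom = anchors$query_chrom, qs = anchors$query_pos,
                  qe = anchors$query_pos + anchors$length,
                  tchrom = anchors$ref_chrom, strand = anchors$strand,
                  dnum = ifelse(anchors$strand == "+",
                                anchors$ref_pos - anchors$query_pos,
                                anchors$ref_pos + anchors$query_pos))
  setkey(a, chrom, qs, qe)
  ov <- foverlaps(w[, .(wid, chrom, start, end)], a,
                  by.x = c("chrom", "start", "end"),
                  by.y = c("chrom", "qs", "qe"), type = "any", nomatch = NULL)
  if (!nrow(ov)) return(rep(0, nrow(w)))
  ov[, `:=`(cs = pmax(qs, start), ce = pmin(qe, end))]
  ov <- ov[ce > cs]
  setorder(ov, wid, tchrom, strand, cs, ce)
  ov[, cl := cumsum(c(TRUE, diff(cs) > max_gap | abs(diff(dnum)) > max_gap)),
     by = .(wid, tchrom, strand)]
  cov <- ov[, {
    cm <- cummax(c(-1L, head(ce, -1L)))
    list(covered = sum(pmax(0L, ce - pmax(cs, cm))))
  }, by = .(wid, tchrom, strand, cl)]
  best <- cov[, .(covered = max(covered)), by = wid]
  res <- rep(0, nrow(w))
  res[best$wid] <- pmin(1, best$covered / (w$end - w$start)[best$wid])
  res
}
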