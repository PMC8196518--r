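# Sliding-window PAV calling: window generation, coverage classification,
# segment merging, cluster calling, PAV-gene assignment and hypergeometric
# pathway enrichment.

#' PAV-calling parameters
#'
#' @param window_size Sliding-window size, bp.
#' @param step Window step, bp (`step <= window_size`).
#' @param min_coverage Windows with mapped coverage strictly below this
#'   fraction (or unmapped) are genome-specific.
#' @param min_segment Merged segments must be strictly longer than this, bp.
#' @param cluster_merge_dist Maximum gap between segments chained into one
#'   cluster, bp.
#' @param cluster_min_density Minimum covered fraction of a chained span for
#'   it to be a cluster (strict).
#' @param gene_cds_fraction A gene is a PAV gene when more than this fraction
#'   of its CDS bases is covered by PAV segments (strict).
#' @param length_summary_cutoff Length cutoff for the PAV length summary, bp.
#' @return A list of class `"pav_params"`.
#' @export
pav_params <- function(window_size = 500L, step = 100L, min_coverage = 0.20,
                       min_segment = 500L, cluster_merge_dist = 100000L,
                       cluster_min_density = 0.10, gene_cds_fraction = 0.75,
                       length_summary_cutoff = 5000L) {
  p <- list(window_size = as.integer(window_size), step = as.integer(step),
            min_coverage = min_coverage, min_segment = as.integer(min_segment),
            cluster_merge_dist = as.integer(cluster_merge_dist),
            cluster_min_density = cluster_min_density,
            gene_cds_fraction = gene_cds_fraction,
            length_summary_cutoff = as.integer(length_summary_cutoff))
  check_field(p$step <= p$window_size, "step", "must be <= window_size")
  for (f in c("min_coverage", "cluster_min_density", "gene_cds_fraction"))
    check_field(p[[f]] >= 0 && p[[f]] <= 1, f, "must be in [0,1]")
  class(p) <- "pav_params"
  p
}

#' Generate sliding windows over a genome
#'
#' Windows start at 0, step, 2*step, ...; every window is exactly
#' `window_size` bp; a final window anchored at `chrom_length - window_size`
#' is added when the regular grid does not already end there, so every base
#' is windowed.  Chromosomes shorter than the window are skipped with a
#' warning.
#'
#' @param genome Genome (named character vector).
#' @param params [pav_params()].
#' @return Data frame: `chrom`, `start`, `end` (0-based half-open).
#' @export
make_windows <- function(genome, params = pav_params()) {
  genome <- as_genome(genome)
  wsz <- params$window_size; st <- params$step
  out <- lapply(names(genome), function(ch) {
    L <- nchar(genome[[ch]])
    if (L < wsz) {
      warning(sprintf("chromosome %s (%d bp) shorter than window size %d: skipped",
                      ch, L, wsz))
      return(NULL)
    }
    starts <- seq(0L, L - wsz, by = st)
    tail_start <- L - wsz
    if (tail_start > starts[length(starts)]) starts <- c(starts, tail_start)
    data.frame(chrom = ch, start = starts, end = starts + wsz,
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(data.frame(chrom = character(), start = integer(),
                                      end = integer()))
  do.call(rbind, out)
}

#' Classify windows as genome-specific
#'
#' A window is specific when it is unmapped (`NA` coverage) or its coverage
#' is strictly below `params$min_coverage`.
#'
#' @param coverages Per-window coverage fractions; `NA` marks unmapped
#'   windows.
#' @param params [pav_params()].
#' @return Logical vector of specific-window flags.
#' @export
classify_windows <- function(coverages, params = pav_params()) {
  bad <- !is.na(coverages) & (coverages < 0 | coverages > 1)
  if (any(bad)) stop("validation error: coverage outside [0,1]")
  is.na(coverages) | coverages < params$min_coverage
}

#' Merge flagged windows into specific segments
#'
#' Takes the per-chromosome union of overlapping or adjacent flagged windows;
#' segments not strictly longer than `params$min_segment` are discarded.
#'
#' @param windows Window data frame from [make_windows()] (sorted by chrom,
#'   start).
#' @param flags Logical specific-window flags aligned with `windows`.
#' @param params [pav_params()].
#' @param genome_label Label stored with the segments (which genome they are
#'   specific to).
#' @return Data frame of segments: `genome_label`, `chrom`, `start`, `end`,
#'   `length`, `n_supporting_windows`.
#' @export
merge_specific_windows <- function(windows, flags, params = pav_params(),
                                   genome_label = "query") {
  f <- windows[flags, , drop = FALSE]
  if (!nrow(f)) {
    return(data.frame(genome_label = character(), chrom = character(),
                      start = integer(), end = integer(), length = integer(),
                      n_supporting_windows = integer()))
  }
  f <- f[order(f$chrom, f$start), ]
  new_seg <- c(TRUE, f$chrom[-1L] != f$chrom[-nrow(f)] |
                 f$start[-1L] > cummax_by(f$end, f$chrom)[-nrow(f)])
  grp <- cumsum(new_seg)
  segs <- do.call(rbind, lapply(split(f, grp), function(g) {
    data.frame(genome_label = genome_label, chrom = g$chrom[1L],
               start = min(g$start), end = max(g$end),
               n_supporting_windows = nrow(g), stringsAsFactors = FALSE)
  }))
  segs$length <- segs$end - segs$start
  segs <- segs[segs$length > params$min_segment, , drop = FALSE]
  rownames(segs) <- NULL
  segs[, c("genome_label", "chrom", "start", "end", "length", "n_supporting_windows")]
}

# running max of `x` restarted at each change of `by` (both sorted by `by`)
cummax_by <- function(x, by) {
  unlist(lapply(split(x, factor(by, levels = unique(by))), cummax), use.names = FALSE)
}

#' Chain specific segments into PAV clusters
#'
#' Single-linkage chaining of segments whose inter-segment gap is at most
#' `params$cluster_merge_dist`; a chain's span becomes a cluster iff the
#' fraction of the span covered by segments strictly exceeds
#' `params$cluster_min_density`.
#'
#' @param segments Segment data frame from [merge_specific_windows()].
#' @param params [pav_params()].
#' @return Data frame of clusters: `chrom`, `start`, `end`, `covered_bp`,
#'   `density`, `n_segments`.
#' @export
call_clusters <- function(segments, params = pav_params()) {
  if (!nrow(segments)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      covered_bp = integer(), density = numeric(),
                      n_segments = integer()))
  }
  s <- segments[order(segments$chrom, segments$start), ]
  new_chain <- c(TRUE, s$chrom[-1L] != s$chrom[-nrow(s)] |
                   s$start[-1L] - cummax_by(s$end, s$chrom)[-nrow(s)] >
                   params$cluster_merge_dist)
  grp <- cumsum(new_chain)
  cl <- do.call(rbind, lapply(split(s, grp), function(g) {
    span <- max(g$end) - min(g$start)
    cov <- sum(g$end - g$start)  # same-label segments never overlap
    data.frame(chrom = g$chrom[1L], start = min(g$start), end = max(g$end),
               covered_bp = cov, density = cov / span, n_segments = nrow(g),
               stringsAsFactors = FALSE)
  }))
  cl <- cl[cl$density > params$cluster_min_density, , drop = FALSE]
  rownames(cl) <- NULL
  cl
}

#' Call PAV genes from CDS annotation
#'
#' Per transcript, the covered fraction is the overlap of the union of its
#' CDS intervals with the union of the PAV segments; transcripts whose
#' fraction strictly exceeds `params$gene_cds_fraction` are PAV genes.
#'
#' @param segments Segment data frame (same assembly as the annotation).
#' @param annotation Data frame of CDS features: `gene_id`, `chrom`,
#'   `start`, `end` (0-based half-open).  Use [read_gff_cds()] for GFF3.
#' @param params [pav_params()].
#' @return Data frame: `gene_id`, `cds_len`, `covered`, `fraction`,
#'   `is_pav_gene`.
#' @export
call_pav_genes <- function(segments, annotation, params = pav_params()) {
  genes <- unique(annotation$gene_id)
  seg_ir <- split(IRanges::IRanges(segments$start + 1L, segments$end),
                  factor(segments$chrom))
  res <- lapply(genes, function(g) {
    cds <- annotation[annotation$gene_id == g, , drop = FALSE]
    if (!nrow(cds)) {
      warning(sprintf("transcript %s has no CDS features: skipped", g))
      return(NULL)
    }
    cds_ir <- IRanges::reduce(IRanges::IRanges(cds$start + 1L, cds$end))
    total <- sum(IRanges::width(cds_ir))
    ch <- cds$chrom[1L]
    segs <- seg_ir[[ch]]
    covered <- if (is.null(segs) || !length(segs)) 0L else
      sum(IRanges::width(IRanges::intersect(cds_ir, IRanges::reduce(segs))))
    data.frame(gene_id = g, cds_len = total, covered = covered,
               fraction = covered / total, stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(data.frame(gene_id = character(), cds_len = integer(),
                      covered = integer(), fraction = numeric(),
                      is_pav_gene = logical()))
  }
  out <- do.call(rbind, res)
  out$is_pav_gene <- out$fraction > params$gene_cds_fraction
  rownames(out) <- NULL
  out
}

#' Parse CDS features from a GFF3 file
#'
#' @param path GFF3 path.
#' @return Data frame `gene_id`, `chrom`, `start`, `end` (0-based half-open),
#'   gene_id taken from the `Parent` (or else `ID`) attribute of CDS rows.
#' @export
read_gff_cds <- function(path) {
  g <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                  quote = "", stringsAsFactors = FALSE)
  colnames(g) <- c("chrom", "source", "type", "start", "end", "score",
                   "strand", "phase", "attr")
  g <- g[g$type == "CDS", , drop = FALSE]
  parent <- sub(".*Parent=([^;]+).*", "\\1", g$attr)
  noparent <- !grepl("Parent=", g$attr)
  parent[noparent] <- sub(".*ID=([^;]+).*", "\\1", g$attr[noparent])
  data.frame(gene_id = parent, chrom = g$chrom, start = g$start - 1L,
             end = g$end, stringsAsFactors = FALSE)
}

#' Summarize PAV segment lengths
#'
#' @param segments Segment data frame (or a numeric vector of lengths).
#' @param cutoff Length cutoff, bp.
#' @return List: `n_total`, `n_above_cutoff`, `percent_below` (2 decimals;
#'   `NULL` for empty input).
#' @export
summarize_lengths <- function(segments, cutoff = 5000L) {
  lens <- if (is.numeric(segments)) segments else segments$length
  n <- length(lens)
  if (n == 0L) return(list(n_total = 0L, n_above_cutoff = 0L, percent_below = NULL))
  n_above <- sum(lens > cutoff)
  list(n_total = n, n_above_cutoff = n_above,
       percent_below = round((n - n_above) / n * 100, 2))
}

#' Hypergeometric pathway enrichment of PAV genes
#'
#' Upper-tail hypergeometric probability P(X >= k) per term with population
#' `N = |universe|`, term successes `K`, draws `n = |pav_genes|`, overlap
#' `k`; Benjamini-Hochberg adjustment across terms.  Terms with no universe
#' genes are skipped.
#'
#' @param pav_genes Character vector of PAV gene ids (subset of `universe`).
#' @param gene2term Data frame `gene_id`, `term`.
#' @param universe Character vector of all gene ids.
#' @return Data frame: `term`, `k`, `K`, `n`, `N`, `p_raw`, `p_adj`, sorted
#'   by `p_raw`.
#' @export
enrich_pathways <- function(pav_genes, gene2term, universe) {
  if (!all(pav_genes %in% universe))
    stop("pav_genes must be a subset of the universe")
  g2t <- gene2term[gene2term$gene_id %in% universe, , drop = FALSE]
  N <- length(unique(universe))
  n <- length(unique(pav_genes))
  terms <- unique(g2t$term)
  rows <- lapply(terms, function(tm) {
    tg <- unique(g2t$gene_id[g2t$term == tm])
    K <- length(tg)
    if (K == 0L) return(NULL)
    k <- length(intersect(tg, pav_genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, K = K, n = n, N = N, p_raw = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p_raw = numeric(),
                      p_adj = numeric()))
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_raw, method = "BH")
  out <- out[order(out$p_raw, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Sharpen merged-window segment breakpoints to the per-base seed-coverage
# gap they contain: the window grid localizes a specific segment to +/- step,
# the longest uncovered run inside it gives near-base-pair boundaries.
refine_segment_breakpoints <- function(segments, anchors, chrom_lens, params) {
  if (!nrow(segments)) return(segments)
  for (ch in unique(segments$chrom)) {
    a <- anchors[anchors$query_chrom == ch, ]
    L <- chrom_lens[[ch]]
    cov <- if (nrow(a)) IRanges::reduce(IRanges::IRanges(a$query_pos + 1L,
                                                         a$query_pos + a$length))
           else IRanges::IRanges()
    gaps <- IRanges::setdiff(IRanges::IRanges(1L, L), cov)
    idx <- which(segments$chrom == ch)
    for (i in idx) {
      st <- segments$start[i]; en <- segments$end[i]
      ov <- pmax(0L, pmin(IRanges::end(gaps), en) -
                   pmax(IRanges::start(gaps), st + 1L) + 1L)
      if (!length(ov) || max(ov) <= params$min_segment) next
      g <- gaps[which.max(ov)]
      new_st <- IRanges::start(g) - 1L
      new_en <- IRanges::end(g)
      # stay within one window step of the grid-called segment
      if (new_st >= st - params$step && new_en <= en + params$step) {
        segments$start[i] <- new_st
        segments$end[i] <- new_en
      }
    }
  }
  segments$length <- segments$end - segments$start
  segments <- segments[segments$length > params$min_segment, , drop = FALSE]
  rownames(segments) <- NULL
  segments
}

#' Call genome-specific (PAV) segments of one genome against another
#'
#' The full sliding-window pipeline: windows over `query_genome`, best-hit
#' coverage against `target_genome`, strict-threshold classification,
#' segment merging, and breakpoint refinement of each merged segment to the
#' longest seed-coverage gap it contains.  Segments are reported in
#' `query_genome` coordinates.
#'
#' @param query_genome Genome whose specific sequence is sought.
#' @param target_genome Genome mapped against.
#' @param params [pav_params()].
#' @param aln [align_params()] controlling the window mapper's seeds.
#' @param genome_label Label stored with the segments.
#' @param anchors Optional precomputed anchor table
#'   (`find_anchors_genome(target, query)`).
#' @return Segment data frame (see [merge_specific_windows()]).
#' @export
call_pav <- function(query_genome, target_genome, params = pav_params(),
                     aln = align_params(), genome_label = "query",
                     anchors = NULL) {
  query_genome <- as_genome(query_genome)
  target_genome <- as_genome(target_genome)
  if (is.null(anchors))
    anchors <- find_anchors_genome(target_genome, query_genome, aln$min_mem_len)
  w <- make_windows(query_genome, params)
  cov <- window_coverage_batch(w, query_genome, target_genome, aln,
                               max_gap = 500L, anchors = anchors)
  flags <- classify_windows(cov, params)
  seg <- merge_specific_windows(w, flags, params, genome_label = genome_label)
  refine_segment_breakpoints(seg, anchors, nchar(query_genome), params)
}
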