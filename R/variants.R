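# SNP/indel calling from one-to-one alignment blocks, adjacent-indel merging,
# per-window SNP density and SNP-enrichment regions.

#' SNP-density / enrichment parameters
#'
#' @param window Non-overlapping tiling window size, bp.
#' @param fold Enrichment multiplier over the genome-wide mean (> 1).
#' @param merge_dist Maximum gap between flagged windows merged into one
#'   region, bp.
#' @param report_min_span Report-layer minimum region span, bp.
#' @param threshold_override Absolute SNP-count threshold overriding
#'   `fold x mean` (e.g. a published rounded threshold), or `NULL`.
#' @return A list of class `"density_params"`.
#' @export
density_params <- function(window = 50000L, fold = 1.5, merge_dist = 100000L,
                           report_min_span = 450000L, threshold_override = NULL) {
  p <- list(window = as.integer(window), fold = fold,
            merge_dist = as.integer(merge_dist),
            report_min_span = as.integer(report_min_span),
            threshold_override = threshold_override)
  check_field(p$fold > 1, "fold", "must exceed 1")
  check_field(p$window > 0L, "window", "must be positive")
  class(p) <- "density_params"
  p
}

empty_variants <- function() {
  data.frame(kind = character(), ref_chrom = character(), ref_pos = integer(),
             query_chrom = character(), query_pos = integer(),
             ref_allele = character(), query_allele = character(),
             length = integer(), block_id = integer(), stringsAsFactors = FALSE)
}

#' Call SNPs and indels from one-to-one alignment blocks
#'
#' Reads the base-level edit runs of each block: one SNP per mismatch column,
#' one indel per gap run, positions reported in both genomes (1-based;
#' query positions on the forward strand).  Alignment columns containing N
#' are excluded.  Feed one-to-one filtered blocks so no variant has an
#' ambiguous placement.
#'
#' @param blocks One-to-one blocks carrying `cigar` edit runs.
#' @param ref_genome,query_genome The aligned genomes.
#' @return Data frame of variant records: `kind` (SNP/insertion/deletion),
#'   `ref_chrom`, `ref_pos`, `query_chrom`, `query_pos`, `ref_allele`,
#'   `query_allele`, `length`, `block_id`.  For indels the position is the
#'   first affected base of the genome carrying the extra sequence, and the
#'   anchoring position in the other genome.
#' @export
call_variants <- function(blocks, ref_genome, query_genome) {
  ref_genome <- as_genome(ref_genome)
  query_genome <- as_genome(query_genome)
  if (!nrow(blocks)) return(empty_variants())
  if (any(is.na(blocks$cigar) | blocks$cigar == ""))
    stop("contract violation: block without base-level edit detail (cigar)")
  out <- list()
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    runs <- cigar_to_runs(b$cigar)
    if (!nrow(runs)) next
    consumes_r <- runs$op %in% c("M", "X", "D")
    consumes_q <- runs$op %in% c("M", "X", "I")
    r_off <- cumsum(c(0L, (runs$len * consumes_r)[-nrow(runs)]))
    q_off <- cumsum(c(0L, (runs$len * consumes_q)[-nrow(runs)]))
    # chain-space -> genome-space: ref always forward; query flipped for '-'
    qlen_chain <- sum(runs$len[consumes_q])
    q_fwd <- function(qc_start, len) {
      # chain-space query interval [qc_start, qc_start+len) -> forward-strand
      if (b$strand == "+") b$query_start + qc_start
      else b$query_end - qc_start - len
    }
    rseq <- ref_genome[[b$ref_chrom]]
    qseq_f <- query_genome[[b$query_chrom]]
    # SNPs: expand X runs into columns
    xi <- which(runs$op == "X")
    if (length(xi)) {
      reps <- runs$len[xi]
      col <- unlist(lapply(seq_along(xi), function(j) seq_len(reps[j]) - 1L))
      base_r <- rep(r_off[xi], reps) + col
      base_qc <- rep(q_off[xi], reps) + col
      rpos <- b$ref_start + base_r
      qpos <- if (b$strand == "+") b$query_start + base_qc
              else b$query_end - 1L - base_qc
      ra <- substring(rseq, rpos + 1L, rpos + 1L)
      qa <- substring(qseq_f, qpos + 1L, qpos + 1L)
      keep <- ra %in% DNA_BASES & qa %in% DNA_BASES
      if (any(keep)) {
        out[[length(out) + 1L]] <- data.frame(
          kind = "SNP", ref_chrom = b$ref_chrom, ref_pos = rpos[keep] + 1L,
          query_chrom = b$query_chrom, query_pos = qpos[keep] + 1L,
          ref_allele = ra[keep], query_allele = qa[keep], length = 1L,
          block_id = b$block_id, stringsAsFactors = FALSE)
      }
    }
    # indels: one record per gap run
    gi <- which(runs$op %in% c("I", "D"))
    if (length(gi)) {
      for (j in gi) {
        len <- runs$len[j]
        if (runs$op[j] == "D") {          # reference-only bases: deletion in query
          rpos <- b$ref_start + r_off[j]
          allele <- substr0(rseq, rpos, rpos + len)
          qf <- q_fwd(q_off[j], 0L)
          if (grepl("N", allele, fixed = TRUE)) next
          out[[length(out) + 1L]] <- data.frame(
            kind = "deletion", ref_chrom = b$ref_chrom, ref_pos = rpos + 1L,
            query_chrom = b$query_chrom, query_pos = qf + 1L,
            ref_allele = allele, query_allele = "-", length = len,
            block_id = b$block_id, stringsAsFactors = FALSE)
        } else {                          # query-only bases: insertion in query
          qf <- q_fwd(q_off[j], len)
          allele_f <- substr0(qseq_f, qf, qf + len)
          if (grepl("N", allele_f, fixed = TRUE)) next
          rpos <- b$ref_start + r_off[j]
          out[[length(out) + 1L]] <- data.frame(
            kind = "insertion", ref_chrom = b$ref_chrom, ref_pos = rpos + 1L,
            query_chrom = b$query_chrom, query_pos = qf + 1L,
            ref_allele = "-", query_allele = allele_f, length = len,
            block_id = b$block_id, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) return(empty_variants())
  v <- do.call(rbind, out)
  v <- v[order(v$ref_chrom, v$ref_pos, v$kind), , drop = FALSE]
  rownames(v) <- NULL
  v
}

#' Merge adjacent single-base indels
#'
#' Runs of single-base indels of the same kind at consecutive positions on
#' both genomes collapse to one record whose length is the run length; SNPs
#' are unaffected.
#'
#' @param variants Variant data frame from [call_variants()].
#' @return Variant data frame with merged indel records.
#' @export
merge_adjacent_indels <- function(variants) {
  v <- variants
  if (!nrow(v)) return(v)
  is_ind <- v$kind %in% c("insertion", "deletion") & v$length == 1L
  idx <- which(is_ind)
  if (length(idx) < 2L) return(v)
  vi <- v[idx, ]
  o <- order(vi$kind, vi$ref_chrom, vi$query_chrom, vi$ref_pos, vi$query_pos)
  vi <- vi[o, ]
  # consecutive on the genome carrying the bases; anchored at the same or
  # consecutive position on the other genome
  same_run <- vi$kind[-1L] == vi$kind[-nrow(vi)] &
    vi$ref_chrom[-1L] == vi$ref_chrom[-nrow(vi)] &
    vi$query_chrom[-1L] == vi$query_chrom[-nrow(vi)] &
    ifelse(vi$kind[-1L] == "deletion",
           vi$ref_pos[-1L] == vi$ref_pos[-nrow(vi)] + 1L &
             vi$query_pos[-1L] == vi$query_pos[-nrow(vi)],
           vi$query_pos[-1L] == vi$query_pos[-nrow(vi)] + 1L &
             vi$ref_pos[-1L] == vi$ref_pos[-nrow(vi)])
  run <- cumsum(c(TRUE, !same_run))
  merged <- lapply(split(seq_len(nrow(vi)), run), function(ii) {
    m <- vi[ii[1L], ]
    m$length <- length(ii)
    if (m$kind == "deletion") {
      m$ref_allele <- paste(vi$ref_allele[ii], collapse = "")
    } else {
      m$query_allele <- paste(vi$query_allele[ii], collapse = "")
    }
    m
  })
  out <- rbind(v[-idx, , drop = FALSE], do.call(rbind, merged))
  out <- out[order(out$ref_chrom, out$ref_pos, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-window SNP counts
#'
#' Non-overlapping windows of `params$window` bp tiled from each chromosome
#' start; the last partial window keeps its true span.  Counts conserve the
#' total SNP number.
#'
#' @param snps Variant data frame (rows with `kind == "SNP"` are counted)
#'   positioned on `genome` via `ref_chrom`/`ref_pos` (1-based).
#' @param genome The genome the positions refer to.
#' @param params [density_params()].
#' @return Data frame: `chrom`, `start`, `end` (0-based half-open), `span`,
#'   `count`, `full` (whether the window has the full span).
#' @export
snp_density <- function(snps, genome, params = density_params()) {
  genome <- as_genome(genome)
  wsz <- params$window
  out <- lapply(names(genome), function(ch) {
    L <- nchar(genome[[ch]])
    starts <- seq(0L, max(0L, L - 1L), by = wsz)
    ends <- pmin(starts + wsz, L)
    s <- snps[snps$kind == "SNP" & snps$ref_chrom == ch, , drop = FALSE]
    cnt <- if (nrow(s)) tabulate(findInterval(s$ref_pos - 1L, starts), length(starts))
           else integer(length(starts))
    data.frame(chrom = ch, start = starts, end = ends, span = ends - starts,
               count = cnt, full = (ends - starts) == wsz,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' SNP-enrichment regions
#'
#' Windows whose SNP count reaches `fold x` the genome-wide mean over
#' full-length windows (or `threshold_override` when set) are flagged;
#' partial tail windows are flagged against a span-prorated threshold.
#' Flagged windows whose gaps are at most `merge_dist` merge into regions.
#'
#' @param window_counts Output of [snp_density()].
#' @param params [density_params()].
#' @param min_span Optional report-layer filter: keep only regions whose
#'   span exceeds `min_span` bp (e.g. `params$report_min_span`); `NULL`
#'   keeps all.
#' @return Data frame: `chrom`, `start`, `end`, `n_windows`, `n_snps`
#'   (plus the threshold used, as attribute `"threshold"`).
#' @export
enrichment_regions <- function(window_counts, params = density_params(),
                               min_span = NULL) {
  wc <- window_counts
  thr <- if (!is.null(params$threshold_override)) params$threshold_override
         else params$fold * mean(wc$count[wc$full])
  flag <- ifelse(wc$full, wc$count >= thr, wc$count >= thr * wc$span / params$window)
  f <- wc[flag, , drop = FALSE]
  if (!nrow(f)) {
    res <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_windows = integer(), n_snps = integer())
    attr(res, "threshold") <- thr
    return(res)
  }
  f <- f[order(f$chrom, f$start), ]
  gap_new <- c(TRUE, f$chrom[-1L] != f$chrom[-nrow(f)] |
                 f$start[-1L] - f$end[-nrow(f)] > params$merge_dist)
  grp <- cumsum(gap_new)
  res <- do.call(rbind, lapply(split(f, grp), function(g) {
    data.frame(chrom = g$chrom[1L], start = min(g$start), end = max(g$end),
               n_windows = nrow(g), n_snps = sum(g$count), stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  if (!is.null(min_span)) res <- res[res$end - res$start > min_span, , drop = FALSE]
  attr(res, "threshold") <- thr
  res
}

#' Genome-wide variant density summary
#'
#' @param snps,indels Variant data frames (SNP rows / indel rows).
#' @param denominator_bp Explicit denominator in bp (the choice of
#'   denominator — assembly length, aligned length — is the caller's).
#' @return List: `snps_per_kb`, `indels_per_kb`, `indel_bp_per_kb`, each
#'   rounded to 2 decimals.
#' @export
density_summary <- function(snps, indels, denominator_bp) {
  if (denominator_bp <= 0) stop("denominator_bp must be positive")
  n_snp <- sum(snps$kind == "SNP")
  ind <- indels[indels$kind %in% c("insertion", "deletion"), , drop = FALSE]
  list(snps_per_kb = round(n_snp / denominator_bp * 1000, 2),
       indels_per_kb = round(nrow(ind) / denominator_bp * 1000, 2),
       indel_bp_per_kb = round(sum(ind$length) / denominator_bp * 1000, 2))
}

#' Write variants as minimal VCF 4.2
#'
#' @param variants Variant data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"SNP, insertion or deletion\">",
               "##INFO=<ID=QCHROM,Number=1,Type=String,Description=\"Query chromosome\">",
               "##INFO=<ID=QPOS,Number=1,Type=Integer,Description=\"Query position (1-based)\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con, sep = "\n")
  if (nrow(variants)) {
    info <- sprintf("TYPE=%s;QCHROM=%s;QPOS=%d", variants$kind,
                    variants$query_chrom, as.integer(variants$query_pos))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s", variants$ref_chrom,
                       as.integer(variants$ref_pos),
                       ifelse(variants$ref_allele == "-", ".", variants$ref_allele),
                       ifelse(variants$query_allele == "-", ".", variants$query_allele),
                       info), con, sep = "\n")
  }
  invisible(path)
}
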