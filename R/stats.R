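# K-mer genome-size estimation and assembly Nx statistics.

#' K-mer occurrence-depth histogram of a read set
#'
#' Counts canonical k-mers (lexicographic minimum of a k-mer and its reverse
#' complement); k-mers containing N are skipped, reads shorter than k are
#' skipped.
#'
#' @param reads Character vector of reads.
#' @param k Odd k-mer size, 11-31 (default 17).
#' @return A list of class `"kmer_histogram"`: `k`, `counts` (data frame
#'   `depth`, `n_kmers`) and `total_kmers` (= sum depth x n_kmers).
#' @export
kmer_histogram <- function(reads, k = 17L) {
  k <- as.integer(k)
  if (k %% 2L == 0L || k < 11L || k > 31L) stop("k must be odd and in [11, 31]")
  reads <- reads[nchar(reads) >= k]
  if (!length(reads)) stop("no read is at least k bases long")
  # concatenate with single-N separators so no k-mer spans two reads
  joined <- paste(reads, collapse = "N")
  codes <- seq_to_int(joined)
  fwd <- kmer_values(codes, k)
  # reverse-complement values: complement codes, reverse, same rolling scheme
  rcodes <- rev(3L - codes)
  rcv <- kmer_values(rcodes, k)
  n <- length(codes)
  # forward k-mer starting at i (1-based) ~ rc k-mer starting at n-k+2-i
  rcv_aligned <- rcv[n - k + 2L - seq_along(fwd)]
  canon <- pmin(fwd, rcv_aligned)
  canon <- canon[!is.na(canon)]
  dt <- data.table(v = canon)
  depth_per_kmer <- dt[, .N, by = v]$N
  h <- as.data.frame(table(depth_per_kmer), stringsAsFactors = FALSE)
  counts <- data.frame(depth = as.integer(h$depth_per_kmer), n_kmers = h$Freq)
  counts <- counts[order(counts$depth), ]
  rownames(counts) <- NULL
  out <- list(k = k, counts = counts,
              total_kmers = sum(as.numeric(counts$depth) * counts$n_kmers))
  class(out) <- "kmer_histogram"
  out
}

#' Estimate genome size from a k-mer histogram
#'
#' `size = total_kmers(depth > cutoff) / peak_depth`, where `peak_depth` is
#' the modal depth above the error cutoff.  The default cutoff is the first
#' local minimum of the histogram (the valley between the error peak at
#' depth ~1 and the genomic peak).
#'
#' @param hist A `"kmer_histogram"`.
#' @param error_depth_cutoff Depths `<= cutoff` are excluded from both the
#'   peak search and the numerator; `NULL` uses the first local minimum.
#' @param refine_peak Refine the integer modal depth to a fractional peak as
#'   the count-weighted centroid of depths within 60-140% of the mode
#'   (damps the +/-1 jitter of the discrete mode); `FALSE` uses the raw mode.
#' @return Estimated genome size in bp (rounded), with attributes
#'   `peak_depth` and `cutoff`.
#' @export
estimate_genome_size <- function(hist, error_depth_cutoff = NULL,
                                 refine_peak = TRUE) {
  stopifnot(inherits(hist, "kmer_histogram"))
  cnt <- hist$counts
  # dense vector over 1..max depth
  dmax <- max(cnt$depth)
  dense <- numeric(dmax)
  dense[cnt$depth] <- cnt$n_kmers
  cutoff <- error_depth_cutoff
  if (is.null(cutoff)) {
    inc <- which(diff(dense) > 0)
    if (!length(inc)) stop("estimation error: histogram has no local minimum above the error peak")
    cutoff <- inc[1L]
  }
  sel <- cnt$depth > cutoff
  if (!any(sel)) stop("estimation error: no k-mer depth above the error cutoff")
  peak_depth <- cnt$depth[sel][which.max(cnt$n_kmers[sel])]
  if (peak_depth <= cutoff) stop("estimation error: no peak above the error cutoff")
  if (refine_peak) {
    wnd <- max(cutoff + 1, round(0.6 * peak_depth)):min(dmax, round(1.4 * peak_depth))
    peak_depth <- sum(wnd * dense[wnd]) / sum(dense[wnd])
  }
  total <- sum(as.numeric(cnt$depth[sel]) * cnt$n_kmers[sel])
  size <- round(total / peak_depth)
  attr(size, "peak_depth") <- peak_depth
  attr(size, "cutoff") <- cutoff
  size
}

#' Assembly Nx statistics
#'
#' Sorts lengths descending; `nX_size` is the length at which the cumulative
#' sum first reaches X% of the total, `nX_count` its 1-based rank.
#'
#' @param lengths Positive sequence lengths.
#' @param X Percent in (0, 100).
#' @return List: `nX_size`, `nX_count`.
#' @export
nX_stats <- function(lengths, X = 50) {
  if (!length(lengths)) stop("empty length list")
  if (any(lengths <= 0)) stop("lengths must be positive")
  if (X <= 0 || X >= 100) stop("X must be in (0, 100)")
  s <- sort(lengths, decreasing = TRUE)
  idx <- which(cumsum(as.numeric(s)) >= X / 100 * sum(as.numeric(s)))[1L]
  list(nX_size = s[idx], nX_count = idx)
}
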