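# Inversion / translocation classification from the difference between the
# rearrangement-permitting (one-to-one) and colinear block sets.

#' Classify rearranged blocks into inversions and translocations
#'
#' Candidates are one-to-one blocks absent from the colinear set.  A `-`
#' strand candidate is an inversion.  A `+` candidate whose query chromosome
#' differs from the consensus of its nearest flanking colinear blocks on the
#' reference is an inter-chromosomal translocation; one on the consensus
#' chromosome but breaking the flanks' query-order monotonicity is an
#' intra-chromosomal translocation.  Adjacent same-type candidates (gaps at
#' most `params$max_anchor_gap` on both genomes) merge into one event.
#'
#' @param one_to_one Blocks from [filter_one_to_one()].
#' @param colinear Blocks from [filter_colinear()] on the same input.
#' @param params [align_params()].
#' @return Data frame of events: `type`, `ref_chrom`, `ref_start`,
#'   `ref_end`, `query_chrom`, `query_start`, `query_end`, `length`
#'   (mean of the two genome spans), `source_blocks`.
#' @export
classify_rearrangements <- function(one_to_one, colinear,
                                    params = align_params()) {
  empty <- data.frame(type = character(), ref_chrom = character(),
                      ref_start = integer(), ref_end = integer(),
                      query_chrom = character(), query_start = integer(),
                      query_end = integer(), length = numeric(),
                      source_blocks = character(), stringsAsFactors = FALSE)
  if (!nrow(one_to_one)) return(empty)
  cand <- one_to_one[!(one_to_one$block_id %in% colinear$block_id), , drop = FALSE]
  if (!nrow(cand)) return(empty)
  cand$type <- NA_character_
  for (i in seq_len(nrow(cand))) {
    b <- cand[i, ]
    if (b$strand == "-") { cand$type[i] <- "inversion"; next }
    col <- colinear[colinear$ref_chrom == b$ref_chrom, , drop = FALSE]
    if (!nrow(col)) {
      # no colinear backbone on this chromosome: classify against global order
      warning(sprintf("no colinear block on %s: classifying against global order",
                      b$ref_chrom))
      other <- one_to_one[one_to_one$ref_chrom == b$ref_chrom &
                            one_to_one$block_id != b$block_id &
                            one_to_one$strand == "+", , drop = FALSE]
      col <- other
      if (!nrow(col)) { cand$type[i] <- "intra_translocation"; next }
    }
    col <- col[order(col$ref_start), ]
    left <- col[col$ref_end <= b$ref_start, , drop = FALSE]
    right <- col[col$ref_start >= b$ref_end, , drop = FALSE]
    left <- if (nrow(left)) left[nrow(left), ] else NULL
    right <- if (nrow(right)) right[1L, ] else NULL
    flank_chrom <- unique(c(if (!is.null(left)) left$query_chrom,
                            if (!is.null(right)) right$query_chrom))
    consensus <- if (length(flank_chrom) == 1L) flank_chrom else {
      # disagreeing flanks: take the nearer one
      dl <- if (!is.null(left)) b$ref_start - left$ref_end else Inf
      dr <- if (!is.null(right)) right$ref_start - b$ref_end else Inf
      if (dl <= dr) left$query_chrom else right$query_chrom
    }
    if (!length(consensus)) { cand$type[i] <- "intra_translocation"; next }
    if (b$query_chrom != consensus) {
      cand$type[i] <- "inter_translocation"
    } else {
      in_order <- (is.null(left) || left$query_chrom != b$query_chrom ||
                     left$query_end <= b$query_start) &&
                  (is.null(right) || right$query_chrom != b$query_chrom ||
                     b$query_end <= right$query_start)
      cand$type[i] <- if (in_order) NA_character_ else "intra_translocation"
    }
  }
  # '+' same-chromosome candidates still in order are not rearrangements
  cand <- cand[!is.na(cand$type), , drop = FALSE]
  if (!nrow(cand)) return(empty)
  # merge adjacent same-type candidates (gap <= max_anchor_gap on both genomes)
  cand <- cand[order(cand$type, cand$ref_chrom, cand$ref_start), ]
  n <- nrow(cand)
  new_ev <- c(TRUE, !(cand$type[-1L] == cand$type[-n] &
                        cand$ref_chrom[-1L] == cand$ref_chrom[-n] &
                        cand$query_chrom[-1L] == cand$query_chrom[-n] &
                        cand$ref_start[-1L] - cand$ref_end[-n] <= params$max_anchor_gap &
                        pmax(cand$query_start[-1L], cand$query_start[-n]) -
                          pmin(cand$query_end[-1L], cand$query_end[-n]) <=
                          params$max_anchor_gap))
  grp <- cumsum(new_ev)
  ev <- do.call(rbind, lapply(split(cand, grp), function(g) {
    data.frame(type = g$type[1L], ref_chrom = g$ref_chrom[1L],
               ref_start = min(g$ref_start), ref_end = max(g$ref_end),
               query_chrom = g$query_chrom[1L],
               query_start = min(g$query_start), query_end = max(g$query_end),
               length = (max(g$ref_end) - min(g$ref_start) +
                           max(g$query_end) - min(g$query_start)) / 2,
               source_blocks = paste(g$block_id, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  ev <- ev[order(ev$ref_chrom, ev$ref_start), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Summarize structural-variant events
#'
#' @param events Data frame from [classify_rearrangements()].
#' @return List: per-type counts and bp, plus `total_events` and `total_bp`.
#' @export
sv_summary <- function(events) {
  types <- c("inversion", "intra_translocation", "inter_translocation")
  counts <- vapply(types, function(t) sum(events$type == t), integer(1))
  bp <- vapply(types, function(t) sum(events$length[events$type == t]), numeric(1))
  list(n_inversions = counts[["inversion"]],
       n_intra_translocations = counts[["intra_translocation"]],
       n_inter_translocations = counts[["inter_translocation"]],
       bp_inversions = bp[["inversion"]],
       bp_intra_translocations = bp[["intra_translocation"]],
       bp_inter_translocations = bp[["inter_translocation"]],
       total_events = sum(counts), total_bp = sum(bp))
}

#' Write SV events as BEDPE-like TSV
#' @param events Event data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sv_events <- function(events, path) {
  write_tsv_file(events, path)
}
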