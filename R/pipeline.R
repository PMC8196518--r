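# End-to-end orchestration: simulation bundles, the full comparison pipeline,
# and truth-based evaluation of the calls.

# transpose an anchor table (MEMs are symmetric between the two genomes)
transpose_anchors <- function(anchors) {
  if (!nrow(anchors)) return(anchors)
  data.table(ref_chrom = anchors$query_chrom, ref_pos = anchors$query_pos,
             query_chrom = anchors$ref_chrom, query_pos = anchors$ref_pos,
             length = anchors$length, strand = anchors$strand)
}

#' Run the full pairwise comparison
#'
#' Aligns genome B (query) to genome A (reference), filters one-to-one and
#' colinear block sets, calls PAV in both directions, SNPs/indels, SNP
#' density and enrichment regions, and classifies rearrangements.  All
#' stage outputs are returned; per-module files and a JSON summary are
#' written when `out_dir` is given.
#'
#' @param genome_a,genome_b The two genomes (named character vectors);
#'   A is the reference side.
#' @param aln [align_params()].
#' @param pav [pav_params()].
#' @param dens [density_params()].
#' @param out_dir Output directory, or `NULL` for no files.
#' @param enrichment_min_span Report-layer span filter for enrichment
#'   regions (`NULL` keeps all regions in the summary).
#' @return List of stage outputs plus `summary` (the JSON-ready summary).
#' @export
run_compare <- function(genome_a, genome_b, aln = align_params(),
                        pav = pav_params(), dens = density_params(),
                        out_dir = NULL, enrichment_min_span = NULL) {
  genome_a <- as_genome(genome_a)
  genome_b <- as_genome(genome_b)
  anchors_ab <- find_anchors_genome(genome_a, genome_b, aln$min_mem_len)

  blocks <- align_genomes(genome_a, genome_b, aln, anchors = anchors_ab)
  one2one <- filter_one_to_one(blocks, aln)
  colin <- filter_colinear(one2one, aln)

  # PAV both directions (B windows vs A uses the same anchors; A vs B the
  # transposed table)
  pav_b <- call_pav(genome_b, genome_a, pav, aln, genome_label = "B",
                    anchors = anchors_ab)
  pav_a <- call_pav(genome_a, genome_b, pav, aln, genome_label = "A",
                    anchors = transpose_anchors(anchors_ab))
  clusters_a <- call_clusters(pav_a, pav)
  clusters_b <- call_clusters(pav_b, pav)

  variants <- merge_adjacent_indels(call_variants(one2one, genome_a, genome_b))
  snps <- variants[variants$kind == "SNP", , drop = FALSE]
  indels <- variants[variants$kind != "SNP", , drop = FALSE]
  wc <- snp_density(variants, genome_a, dens)
  enr <- enrichment_regions(wc, dens, min_span = enrichment_min_span)
  events <- classify_rearrangements(one2one, colin, aln)

  len_a <- sum(nchar(genome_a)); len_b <- sum(nchar(genome_b))
  summary <- list(
    genomes = list(a_bp = len_a, b_bp = len_b,
                   n_chrom_a = length(genome_a), n_chrom_b = length(genome_b)),
    alignment = list(
      n_blocks_raw = nrow(blocks), n_blocks_one_to_one = nrow(one2one),
      n_blocks_colinear = nrow(colin),
      one_to_one_fraction_a = round(sum(one2one$ref_end - one2one$ref_start) / len_a, 6),
      one_to_one_fraction_b = round(sum(one2one$query_end - one2one$query_start) / len_b, 6),
      mean_identity = round(mean(one2one$identity), 4)),
    pav = list(
      a_specific = c(summarize_lengths(pav_a, pav$length_summary_cutoff),
                     list(total_bp = sum(pav_a$length), n_clusters = nrow(clusters_a))),
      b_specific = c(summarize_lengths(pav_b, pav$length_summary_cutoff),
                     list(total_bp = sum(pav_b$length), n_clusters = nrow(clusters_b)))),
    variants = c(list(n_snps = nrow(snps), n_indels = nrow(indels),
                      indel_bp = sum(indels$length)),
                 density_summary(snps, indels, len_a)),
    enrichment = list(threshold = attr(enr, "threshold"), n_regions = nrow(enr),
                      region_bp = sum(enr$end - enr$start)),
    sv = sv_summary(events))

  res <- list(blocks = blocks, one_to_one = one2one, colinear = colin,
              pav_a = pav_a, pav_b = pav_b, clusters_a = clusters_a,
              clusters_b = clusters_b, variants = variants,
              window_counts = wc, enrichment = enr, events = events,
              summary = summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_paf(one2one, file.path(out_dir, "blocks.one_to_one.paf.tsv"))
    write_paf(colin, file.path(out_dir, "blocks.colinear.paf.tsv"))
    write_bed(cbind(pav_a[, c("chrom", "start", "end")], name = "A_specific"),
              file.path(out_dir, "pav.A_specific.bed"))
    write_bed(cbind(pav_b[, c("chrom", "start", "end")], name = "B_specific"),
              file.path(out_dir, "pav.B_specific.bed"))
    write_vcf(variants, file.path(out_dir, "variants.vcf"))
    write_tsv_file(wc, file.path(out_dir, "snp_density.tsv"))
    write_tsv_file(as.data.frame(enr), file.path(out_dir, "enrichment_regions.tsv"))
    write_sv_events(events, file.path(out_dir, "sv_events.tsv"))
    con <- file(file.path(out_dir, "summary.json"), open = "wb")
    writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA, null = "null"), con, sep = "\n")
    close(con)
  }
  res
}

#' Generate a simulation bundle
#'
#' Simulates the ancestor and derived genomes (plus optional reads), and
#' writes FASTA genomes, truth files and a config echo under `out_dir`.
#'
#' @param config [sim_config()].
#' @param out_dir Output directory, or `NULL` for no files.
#' @param with_reads Also simulate reads from the ancestor.
#' @return List: `genome_a`, `genome_b`, `truth`, optionally `reads`.
#' @export
run_simulate <- function(config, out_dir = NULL, with_reads = FALSE) {
  a <- simulate_ancestor(config)
  d <- derive_cultivar(a, config, seed = config$seed + 1L)
  reads <- NULL
  if (with_reads)
    reads <- simulate_reads(a, config$read_coverage, config$read_length,
                            config$read_error_rate, seed = config$seed + 2L)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_genome(a, file.path(out_dir, "genome_A.fa"))
    write_genome(d$genome, file.path(out_dir, "genome_B.fa"))
    write_truth(d$truth, file.path(out_dir, "truth"))
    if (!is.null(reads)) write_genome(reads, file.path(out_dir, "reads.fa"))
    con <- file(file.path(out_dir, "config.json"), open = "wb")
    writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, pretty = TRUE,
                                digits = NA), con, sep = "\n")
    close(con)
  }
  list(genome_a = a, genome_b = d$genome, truth = d$truth, reads = reads)
}

# interval overlap helpers ---------------------------------------------------

interval_overlap_bp <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

#' Evaluate PAV calls against the simulation truth
#'
#' A planted segment is recovered when a called segment of the same genome
#' label has both breakpoints within `tol` bp; a called segment is a true
#' positive when it matches a planted segment the same way.
#'
#' @param pav_a,pav_b Called A-specific and B-specific segments.
#' @param truth Simulation `truth_set`.
#' @param tol Breakpoint tolerance, bp.
#' @return List: `recall`, `precision`, `n_truth`, `n_called`.
#' @export
evaluate_pav <- function(pav_a, pav_b, truth, tol = 100L) {
  tr <- truth$pav_segments
  called <- rbind(
    if (nrow(pav_a)) data.frame(genome = "A", chrom = pav_a$chrom,
                                start = pav_a$start, end = pav_a$end),
    if (nrow(pav_b)) data.frame(genome = "B", chrom = pav_b$chrom,
                                start = pav_b$start, end = pav_b$end))
  if (is.null(called)) called <- data.frame(genome = character(), chrom = character(),
                                            start = numeric(), end = numeric())
  match_one <- function(g, ch, s, e, against) {
    any(against$genome == g & against$chrom == ch &
          abs(against$start - s) <= tol & abs(against$end - e) <= tol)
  }
  rec <- vapply(seq_len(nrow(tr)), function(i)
    match_one(tr$genome[i], tr$chrom[i], tr$start[i], tr$end[i], called), logical(1))
  prec <- vapply(seq_len(nrow(called)), function(i)
    match_one(called$genome[i], called$chrom[i], called$start[i], called$end[i],
              tr), logical(1))
  list(recall = if (nrow(tr)) mean(rec) else NA_real_,
       precision = if (nrow(called)) mean(prec) else NA_real_,
       n_truth = nrow(tr), n_called = nrow(called))
}

#' Evaluate SNP calls against the simulation truth
#'
#' Restricted to truth SNPs whose reference position lies inside a
#' one-to-one block.  A truth SNP is recovered when a called SNP matches
#' its reference position and both alleles (query allele on the forward
#' strand).
#'
#' @param variants Called variants.
#' @param truth Simulation `truth_set`.
#' @param one_to_one One-to-one blocks defining the evaluable space.
#' @return List: `recall`, `precision`, `n_truth_in_blocks`, `n_called`.
#' @export
evaluate_snps <- function(variants, truth, one_to_one) {
  sn <- variants[variants$kind == "SNP", , drop = FALSE]
  tr <- as.data.table(truth$snps)
  if (nrow(tr)) {
    bl <- as.data.table(one_to_one[, c("ref_chrom", "ref_start", "ref_end")])
    setkey(bl, ref_chrom, ref_start, ref_end)
    tr[, `:=`(s = posA, e = posA + 1)]
    hit <- foverlaps(tr, bl, by.x = c("chromA", "s", "e"),
                     by.y = c("ref_chrom", "ref_start", "ref_end"),
                     type = "within", nomatch = NULL)
    tr_in <- unique(hit[, .(chromA, posA, baseA, baseB)])
  } else tr_in <- tr
  key_t <- paste(tr_in$chromA, tr_in$posA + 1, tr_in$baseA, tr_in$baseB)
  key_c <- paste(sn$ref_chrom, sn$ref_pos, sn$ref_allele, sn$query_allele)
  list(recall = if (length(key_t)) mean(key_t %in% key_c) else NA_real_,
       precision = if (length(key_c)) mean(key_c %in% key_t) else NA_real_,
       n_truth_in_blocks = length(key_t), n_called = length(key_c))
}

#' Evaluate SV classification against the simulation truth
#'
#' A planted event is recovered when a reported event of the same type
#' reciprocally overlaps its reference-side interval by at least
#' `min_reciprocal`.
#'
#' @param events Called events from [classify_rearrangements()].
#' @param truth Simulation `truth_set`.
#' @param min_reciprocal Minimum reciprocal overlap fraction.
#' @return List: per-type recovered counts and totals, plus overall recall.
#' @export
evaluate_svs <- function(events, truth, min_reciprocal = 0.9) {
  tr <- truth$svs
  hit <- vapply(seq_len(nrow(tr)), function(i) {
    t <- tr[i, ]
    e <- events[events$type == t$type & events$ref_chrom == t$a_chrom, , drop = FALSE]
    if (!nrow(e)) return(FALSE)
    ov <- interval_overlap_bp(e$ref_start, e$ref_end, t$a_start, t$a_end)
    any(ov / (t$a_end - t$a_start) >= min_reciprocal &
          ov / (e$ref_end - e$ref_start) >= min_reciprocal)
  }, logical(1))
  per_type <- tapply(hit, tr$type, sum)
  list(recovered = as.list(per_type),
       n_truth = as.list(table(tr$type)),
       recall = if (nrow(tr)) mean(hit) else NA_real_)
}

#' Evaluate enrichment-region recovery against planted enriched blocks
#'
#' @param regions Reported enrichment regions.
#' @param truth Simulation `truth_set` (with `enriched_regions`).
#' @param min_cover Minimum fraction of each planted block covered by
#'   reported regions.
#' @return List: `min_fraction`, `mean_fraction`, `all_recovered`.
#' @export
evaluate_enrichment <- function(regions, truth, min_cover = 0.8) {
  tr <- truth$enriched_regions
  frac <- vapply(seq_len(nrow(tr)), function(i) {
    t <- tr[i, ]
    r <- regions[regions$chrom == t$chrom, , drop = FALSE]
    if (!nrow(r)) return(0)
    sum(interval_overlap_bp(r$start, r$end, t$start, t$end)) / (t$end - t$start)
  }, numeric(1))
  list(min_fraction = if (length(frac)) min(frac) else NA_real_,
       mean_fraction = if (length(frac)) mean(frac) else NA_real_,
       all_recovered = all(frac >= min_cover))
}
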