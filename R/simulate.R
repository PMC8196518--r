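# Cultivar-pair simulator.
#
# Generates an ancestor genome A and a derived genome B by planting, in a fixed
# order, inter-chromosomal translocations, intra-chromosomal translocations,
# inversions, PAV deletions/insertions (> 500 bp), short indels (1-100 bp) and
# SNPs (with density-enriched blocks), recording exact truth coordinates in
# both genomes.  A single RNG stream per seed is consumed in a documented fixed
# order: SV intervals, PAV intervals/anchors, indel intervals/anchors, enriched
# regions, SNP positions and alleles, novel insertion sequences, in that order.

#' Simulation configuration
#'
#' Defaults describe a pair of closely related cultivar genomes: mostly
#' syntenic, SNPs clustered in density-enriched blocks, short indels, PAV
#' segments > 500 bp with ~99% of mass below 5 kb, a few inversions and
#' translocations.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param gc_content Target GC fraction.
#' @param seed Integer seed for `simulate_ancestor`.
#' @param snp_rate_background Background substitution rate (per bp).
#' @param enriched_fraction Fraction of the genome inside SNP-enriched blocks.
#' @param enriched_fold SNP-rate multiplier inside enriched blocks (> 1.5).
#' @param enriched_block_length Length of each contiguous enriched block (bp).
#' @param indel_rate Short-indel event rate (events per bp); lengths 1-100 bp.
#' @param indel_length_p Geometric parameter for indel lengths
#'   (`1 + rgeom(p)`, truncated at 100).
#' @param n_pav_insertions,n_pav_deletions Number of PAV segments inserted
#'   into / deleted from the derived genome.
#' @param pav_fraction_below_5kb Fraction of PAV lengths below 5 kb.
#' @param pav_min_length Minimum PAV length (bp, >= 501).
#' @param pav_below_max,pav_above_max Upper length bounds of the short and
#'   long mixture components (bp).
#' @param n_inversions Number of inversions.
#' @param inversion_length_range Length range of inversions (bp).
#' @param n_intra_translocations,n_inter_translocations Translocation counts.
#' @param translocation_length_range Length range of translocated segments (bp).
#' @param read_coverage,read_length,read_error_rate Read-simulation defaults.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_chromosomes = 2L,
                       chrom_length = 1e6,
                       gc_content = 0.46,
                       seed = 1L,
                       snp_rate_background = 0.002,
                       enriched_fraction = 0.20,
                       enriched_fold = 3.0,
                       enriched_block_length = 2e5,
                       indel_rate = 4e-4,
                       indel_length_p = 0.25,
                       n_pav_insertions = 15L,
                       n_pav_deletions = 15L,
                       pav_fraction_below_5kb = 0.99,
                       pav_min_length = 501L,
                       pav_below_max = 5000L,
                       pav_above_max = 20000L,
                       n_inversions = 3L,
                       inversion_length_range = c(5000L, 50000L),
                       n_intra_translocations = 1L,
                       n_inter_translocations = 1L,
                       translocation_length_range = c(5000L, 30000L),
                       read_coverage = 30,
                       read_length = 100L,
                       read_error_rate = 0.001) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes), chrom_length = as.integer(chrom_length),
    gc_content = gc_content, seed = as.integer(seed),
    snp_rate_background = snp_rate_background, enriched_fraction = enriched_fraction,
    enriched_fold = enriched_fold, enriched_block_length = as.integer(enriched_block_length),
    indel_rate = indel_rate, indel_length_p = indel_length_p,
    n_pav_insertions = as.integer(n_pav_insertions),
    n_pav_deletions = as.integer(n_pav_deletions),
    pav_fraction_below_5kb = pav_fraction_below_5kb,
    pav_min_length = as.integer(pav_min_length),
    pav_below_max = as.integer(pav_below_max), pav_above_max = as.integer(pav_above_max),
    n_inversions = as.integer(n_inversions),
    inversion_length_range = as.integer(inversion_length_range),
    n_intra_translocations = as.integer(n_intra_translocations),
    n_inter_translocations = as.integer(n_inter_translocations),
    translocation_length_range = as.integer(translocation_length_range),
    read_coverage = read_coverage, read_length = as.integer(read_length),
    read_error_rate = read_error_rate)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  check_field(cfg$n_chromosomes >= 1L, "n_chromosomes", "must be >= 1")
  check_field(cfg$chrom_length >= 1L, "chrom_length", "must be positive")
  check_field(cfg$gc_content >= 0 && cfg$gc_content <= 1, "gc_content", "must be in [0,1]")
  for (f in c("snp_rate_background", "enriched_fraction", "indel_rate",
              "read_error_rate", "pav_fraction_below_5kb", "indel_length_p"))
    check_field(cfg[[f]] >= 0 && cfg[[f]] <= 1, f, "must be in [0,1]")
  check_field(cfg$enriched_fold > 1.5, "enriched_fold", "must exceed 1.5")
  check_field(cfg$pav_min_length >= 501L, "pav_min_length", "must be >= 501 (PAV is > 500 bp)")
  check_field(cfg$pav_below_max > cfg$pav_min_length, "pav_below_max", "must exceed pav_min_length")
  check_field(cfg$pav_above_max >= 5000L, "pav_above_max", "must be >= 5000")
  for (f in c("n_pav_insertions", "n_pav_deletions", "n_inversions",
              "n_intra_translocations", "n_inter_translocations"))
    check_field(cfg[[f]] >= 0L, f, "must be non-negative")
  check_field(all(cfg$inversion_length_range >= 1L) &&
                cfg$inversion_length_range[1] <= cfg$inversion_length_range[2],
              "inversion_length_range", "must be a positive increasing pair")
  check_field(all(cfg$translocation_length_range >= 1L) &&
                cfg$translocation_length_range[1] <= cfg$translocation_length_range[2],
              "translocation_length_range", "must be a positive increasing pair")
  check_field(cfg$read_length >= 1L, "read_length", "must be positive")
  invisible(cfg)
}

#' Simulate the ancestor genome
#'
#' @param config A [sim_config()].
#' @return Named character vector of chromosome sequences
#'   (`chr1`, `chr2`, ...), deterministic under `config$seed`.
#' @export
simulate_ancestor <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  g <- vapply(seq_len(config$n_chromosomes),
              function(i) random_seq(config$chrom_length, config$gc_content),
              character(1))
  names(g) <- paste0("chr", seq_len(config$n_chromosomes))
  g
}

# sample `lengths` non-overlapping intervals across chromosomes, respecting an
# occupied set (data.table chrom/start/end) expanded by `margin`, and keeping
# `end_margin` away from chromosome ends.  Returns data.table(chrom,start,end).
sample_event_intervals <- function(lengths, chrom_lens, occupied, margin = 2000L,
                                   end_margin = 5000L, what = "event") {
  out <- vector("list", length(lengths))
  for (i in seq_along(lengths)) {
    len <- lengths[i]
    avail <- names(chrom_lens)[chrom_lens >= len + 2L * end_margin]
    if (!length(avail))
      stop(sprintf("simulation error: %s length %d exceeds usable chromosome length", what, len))
    placed <- FALSE
    for (try in seq_len(2000L)) {
      ch_pick <- if (length(avail) == 1L) avail else
        sample(avail, 1L, prob = chrom_lens[avail] - len - 2 * end_margin + 1)
      start <- floor(runif(1, end_margin, chrom_lens[[ch_pick]] - end_margin - len + 1))
      cand <- data.table(chrom = ch_pick, start = start, end = start + len)
      occ <- occupied[which(occupied$chrom == ch_pick), ]
      if (!nrow(occ) || all(cand$end + margin <= occ$start | cand$start >= occ$end + margin)) {
        out[[i]] <- cand
        occupied <- rbind(occupied, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf("simulation error: could not place %s of length %d without overlap", what, len))
  }
  list(intervals = if (length(out)) rbindlist(out) else
    data.table(chrom = character(), start = numeric(), end = numeric()),
    occupied = occupied)
}

# sample anchor points (insertions / translocation destinations) clear of the
# occupied set by `margin`
sample_event_anchors <- function(n, chrom_lens, occupied, margin = 2000L,
                                 end_margin = 5000L, chrom_exclude = rep(NA, n)) {
  res <- data.table(chrom = character(n), pos = numeric(n))
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(2000L)) {
      avail <- names(chrom_lens)
      if (!is.na(chrom_exclude[i])) avail <- setdiff(avail, chrom_exclude[i])
      if (!length(avail)) stop("simulation error: no chromosome available for anchor")
      ch_pick <- if (length(avail) == 1L) avail else sample(avail, 1L, prob = chrom_lens[avail])
      pos <- floor(runif(1, end_margin, chrom_lens[[ch_pick]] - end_margin))
      occ <- occupied[which(occupied$chrom == ch_pick), ]
      if (!nrow(occ) || all(pos + margin <= occ$start | pos >= occ$end + margin)) {
        res$chrom[i] <- ch_pick; res$pos[i] <- pos
        occupied <- rbind(occupied, data.table(chrom = ch_pick, start = pos, end = pos))
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("simulation error: could not place anchor point")
  }
  list(anchors = res, occupied = occupied)
}

sample_pav_lengths <- function(n, cfg) {
  if (n == 0L) return(integer(0))
  below <- runif(n) < cfg$pav_fraction_below_5kb
  len <- integer(n)
  len[below] <- floor(runif(sum(below), cfg$pav_min_length, min(cfg$pav_below_max, 5000L)))
  len[!below] <- floor(runif(sum(!below), 5000L, cfg$pav_above_max + 1))
  len
}

#' Derive a cultivar genome with a full truth set
#'
#' Applies, in order, inter-chromosomal translocations, intra-chromosomal
#' translocations, inversions, PAV deletions/insertions, short indels and SNPs
#' (enriched regions drawn first) to `ancestor`, logging every edit with
#' coordinates in both genomes.  No two structural events overlap.
#'
#' @param ancestor Genome (named character vector), e.g. from
#'   [simulate_ancestor()].
#' @param config A [sim_config()].
#' @param seed Integer seed for the derivation stream.
#' @return A list with elements `genome` (the derived genome B) and `truth`
#'   (a `truth_set`: data.frames `snps`, `indels`, `pav_segments`, `svs`,
#'   `enriched_regions`, the `liftover` block map and novel sequences).
#' @export
derive_cultivar <- function(ancestor, config, seed = config$seed + 1L) {
  ancestor <- as_genome(ancestor)
  validate_sim_config(config)
  if (!length(ancestor) || any(nchar(ancestor) == 0L))
    stop("simulation error: ancestor genome is empty")
  set.seed(seed)
  chrom_lens <- nchar(ancestor)
  total_len <- sum(chrom_lens)
  occupied <- data.table(chrom = character(), start = numeric(), end = numeric())

  rint <- function(rng, n) if (n == 0L) integer(0) else floor(runif(n, rng[1], rng[2] + 1))

  # -- 1. structural events on A coordinates ---------------------------------
  ev <- list()
  # inter-chromosomal translocations
  if (config$n_inter_translocations > 0L && length(ancestor) < 2L)
    stop("simulation error: inter-chromosomal translocation needs >= 2 chromosomes")
  s <- sample_event_intervals(rint(config$translocation_length_range, config$n_inter_translocations),
                              chrom_lens, occupied, what = "inter-translocation")
  occupied <- s$occupied
  inter_src <- s$intervals
  s <- sample_event_intervals(rint(config$translocation_length_range, config$n_intra_translocations),
                              chrom_lens, occupied, what = "intra-translocation")
  occupied <- s$occupied
  intra_src <- s$intervals
  s <- sample_event_intervals(rint(config$inversion_length_range, config$n_inversions),
                              chrom_lens, occupied, what = "inversion")
  occupied <- s$occupied
  inv_iv <- s$intervals
  # PAV deletions (segments of A absent from B)
  s <- sample_event_intervals(sample_pav_lengths(config$n_pav_deletions, config),
                              chrom_lens, occupied, what = "PAV deletion")
  occupied <- s$occupied
  pav_del <- s$intervals
  # PAV insertion anchors (novel sequence in B)
  pav_ins_len <- sample_pav_lengths(config$n_pav_insertions, config)
  s <- sample_event_anchors(config$n_pav_insertions, chrom_lens, occupied)
  occupied <- s$occupied
  pav_ins <- s$anchors
  pav_ins$len <- pav_ins_len
  # translocation destination anchors (inter: forced onto a different chromosome)
  s <- sample_event_anchors(config$n_inter_translocations, chrom_lens, occupied,
                            chrom_exclude = inter_src$chrom)
  occupied <- s$occupied
  inter_dst <- s$anchors
  s <- sample_event_anchors(config$n_intra_translocations, chrom_lens, occupied,
                            chrom_exclude = rep(NA, config$n_intra_translocations))
  occupied <- s$occupied
  intra_dst <- s$anchors
  # keep intra destinations on the source chromosome
  intra_dst$chrom <- intra_src$chrom
  if (nrow(intra_dst)) {
    for (i in seq_len(nrow(intra_dst))) {
      ok <- FALSE
      for (try in seq_len(2000L)) {
        pos <- floor(runif(1, 5000L, chrom_lens[[intra_src$chrom[i]]] - 5000L))
        occ <- occupied[which(occupied$chrom == intra_src$chrom[i]), ]
        if (all(pos + 2000L <= occ$start | pos >= occ$end + 2000L)) {
          intra_dst$pos[i] <- pos; ok <- TRUE
          occupied <- rbind(occupied,
                            data.table(chrom = intra_src$chrom[i], start = pos, end = pos))
          break
        }
      }
      if (!ok) stop("simulation error: could not place intra-translocation destination")
    }
  }

  # -- 2. short indels -------------------------------------------------------
  n_indel <- rbinom(1L, total_len, config$indel_rate)
  is_del <- runif(n_indel) < 0.5
  indel_len <- pmin(1L + rgeom(n_indel, config$indel_length_p), 100L)
  s <- sample_event_intervals(indel_len[is_del], chrom_lens, occupied,
                              margin = 300L, end_margin = 1000L, what = "short deletion")
  occupied <- s$occupied
  small_del <- s$intervals
  s <- sample_event_anchors(sum(!is_del), chrom_lens, occupied,
                            margin = 300L, end_margin = 1000L)
  occupied <- s$occupied
  small_ins <- s$anchors
  small_ins$len <- indel_len[!is_del]

  # -- 3. enriched SNP regions ----------------------------------------------
  n_enr <- round(config$enriched_fraction * total_len / config$enriched_block_length)
  # enriched regions may overlap point events and SVs (SNPs landing in deleted
  # sequence are dropped later); they only avoid each other.  Starts snap to a
  # 50-kb grid: density analyses tile the genome in 50-kb windows, so blocks
  # off-grid would have sub-window edges that no tiled method can resolve.
  enr_rows <- list()
  grid <- 50000L
  for (i in seq_len(n_enr)) {
    placed <- FALSE
    for (try in seq_len(2000L)) {
      ch_pick <- sample(names(chrom_lens), 1L, prob = chrom_lens)
      cand_starts <- seq(0L, chrom_lens[[ch_pick]] - config$enriched_block_length,
                         by = grid)
      if (!length(cand_starts)) next
      st <- sample(cand_starts, 1L)
      en <- st + config$enriched_block_length
      prior <- rbindlist(enr_rows)
      clash <- length(enr_rows) &&
        any(prior$chrom == ch_pick & st < prior$end & prior$start < en)
      if (!clash) {
        enr_rows[[i]] <- data.table(chrom = ch_pick, start = st, end = en)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("simulation error: could not place enriched region without overlap")
  }
  enriched <- if (length(enr_rows)) rbindlist(enr_rows)[order(chrom, start)] else
    data.table(chrom = character(), start = numeric(), end = numeric())

  # -- 4. assemble the atomic-segment table ---------------------------------
  events <- rbindlist(list(
    if (nrow(inter_src)) cbind(inter_src, type = "inter_tx", id = seq_len(nrow(inter_src))),
    if (nrow(intra_src)) cbind(intra_src, type = "intra_tx", id = seq_len(nrow(intra_src))),
    if (nrow(inv_iv))    cbind(inv_iv,    type = "inversion", id = seq_len(nrow(inv_iv))),
    if (nrow(pav_del))   cbind(pav_del,   type = "pav_del", id = seq_len(nrow(pav_del))),
    if (nrow(small_del)) cbind(small_del, type = "small_del", id = seq_len(nrow(small_del)))
  ), use.names = TRUE)
  anchors <- rbindlist(list(
    if (nrow(pav_ins))   data.table(chrom = pav_ins$chrom, pos = pav_ins$pos,
                                    type = "pav_ins", id = seq_len(nrow(pav_ins)),
                                    len = pav_ins$len),
    if (nrow(small_ins)) data.table(chrom = small_ins$chrom, pos = small_ins$pos,
                                    type = "small_ins", id = seq_len(nrow(small_ins)),
                                    len = small_ins$len),
    if (nrow(inter_dst)) data.table(chrom = inter_dst$chrom, pos = inter_dst$pos,
                                    type = "inter_dst", id = seq_len(nrow(inter_dst)),
                                    len = NA_integer_),
    if (nrow(intra_dst)) data.table(chrom = intra_dst$chrom, pos = intra_dst$pos,
                                    type = "intra_dst", id = seq_len(nrow(intra_dst)),
                                    len = NA_integer_)
  ), use.names = TRUE)
  if (is.null(anchors) || !ncol(anchors))
    anchors <- data.table(chrom = character(), pos = numeric(),
                          type = character(), id = integer(), len = integer())
  if (is.null(events) || !ncol(events))
    events <- data.table(chrom = character(), start = numeric(),
                         end = numeric(), type = character(), id = integer())

  # novel sequences for insertions, drawn in a fixed order (PAV then short)
  novel <- character(0)
  if (nrow(anchors)) {
    ins <- anchors[anchors$type %in% c("pav_ins", "small_ins"), ]
    ins <- ins[order(match(ins$type, c("pav_ins", "small_ins")), ins$id), ]
    novel <- vapply(ins$len, function(l) random_seq(l, config$gc_content), character(1))
    names(novel) <- paste0(ins$type, "_", ins$id)
  }

  # -- 5. build the B block list --------------------------------------------
  blocks <- build_block_map(ancestor, events, anchors, novel)

  # -- 6. SNPs ---------------------------------------------------------------
  snps <- plant_snps(ancestor, blocks, enriched, config)

  # -- 7. materialize B ------------------------------------------------------
  derived <- materialize_derived(ancestor, blocks, novel, snps)

  truth <- build_truth(blocks, events, anchors, novel, snps, enriched, seed)
  list(genome = derived, truth = truth)
}

# Build the ordered block map of genome B.  Blocks are atomic A segments (kept,
# inverted, translocated) or novel insertions; b coordinates follow from the
# emission order.  Returns a data.table with columns:
# b_chrom, b_start, b_end, src ("A"/"novel"), a_chrom, a_start, a_end, strand,
# novel_id, event_type, event_id
build_block_map <- function(ancestor, events, anchors, novel) {
  chroms <- names(ancestor)
  # translocated segments indexed by type/id
  tx <- events[events$type %in% c("inter_tx", "intra_tx"), ]
  out <- list()
  for (ch in chroms) {
    L <- nchar(ancestor[[ch]])
    ev <- events[events$chrom == ch, ][order(start)]
    an <- anchors[anchors$chrom == ch, ][order(pos)]
    bps <- sort(unique(c(0, L, ev$start, ev$end, an$pos)))
    seg <- data.table(start = head(bps, -1L), end = tail(bps, -1L))
    seg <- seg[seg$end > seg$start, ]
    # fate of each segment (margins guarantee at most one covering event)
    seg$type <- "keep"; seg$event_id <- NA_integer_
    if (nrow(ev)) {
      idx <- findInterval(seg$start, ev$start)
      cov <- idx >= 1L & seg$end <= ev$end[pmax(idx, 1L)] & seg$start >= ev$start[pmax(idx, 1L)]
      seg$type[cov] <- ev$type[idx[cov]]
      seg$event_id[cov] <- ev$id[idx[cov]]
    }
    items <- list(); n <- 0L
    emit <- function(x) { n <<- n + 1L; items[[n]] <<- x }
    emit_anchor <- function(a) {
      if (a$type %in% c("pav_ins", "small_ins")) {
        emit(data.table(src = "novel", a_chrom = ch, a_start = a$pos, a_end = a$pos,
                        strand = "+", novel_id = paste0(a$type, "_", a$id),
                        event_type = a$type, event_id = a$id))
      } else {
        src_type <- if (a$type == "inter_dst") "inter_tx" else "intra_tx"
        sv <- tx[tx$type == src_type & tx$id == a$id, ]
        emit(data.table(src = "A", a_chrom = sv$chrom, a_start = sv$start, a_end = sv$end,
                        strand = "+", novel_id = NA_character_,
                        event_type = src_type, event_id = a$id))
      }
    }
    ai <- 1L
    for (si in seq_len(nrow(seg))) {
      while (ai <= nrow(an) && an$pos[ai] <= seg$start[si]) { emit_anchor(an[ai, ]); ai <- ai + 1L }
      ty <- seg$type[si]
      if (ty %in% c("keep", "inversion")) {
        emit(data.table(src = "A", a_chrom = ch, a_start = seg$start[si], a_end = seg$end[si],
                        strand = if (ty == "inversion") "-" else "+",
                        novel_id = NA_character_,
                        event_type = if (ty == "inversion") "inversion" else NA_character_,
                        event_id = seg$event_id[si]))
      }
      # deletions and translocation sources are skipped here
    }
    while (ai <= nrow(an)) { emit_anchor(an[ai, ]); ai <- ai + 1L }
    bl <- rbindlist(items)
    bl$b_chrom <- ch
    out[[ch]] <- bl
  }
  blocks <- rbindlist(out)
  blocks$len <- ifelse(blocks$src == "novel",
                       nchar(novel[blocks$novel_id]),
                       blocks$a_end - blocks$a_start)
  blocks[, `:=`(b_end = cumsum(len), b_start = cumsum(len) - len), by = "b_chrom"]
  blocks[]
}

# lift an A position (0-based) through the block map; NA if not copied
lift_pos <- function(blocks, chrom, pos) {
  cand <- blocks[blocks$src == "A" & blocks$a_chrom == chrom &
                   blocks$a_start <= pos & pos < blocks$a_end, ]
  if (!nrow(cand)) return(list(chrom = NA_character_, pos = NA_real_, strand = NA_character_))
  b <- cand[1L, ]
  p <- if (b$strand == "+") b$b_start + (pos - b$a_start) else b$b_start + (b$a_end - 1L - pos)
  list(chrom = b$b_chrom, pos = p, strand = b$strand)
}

comp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

plant_snps <- function(ancestor, blocks, enriched, config) {
  rate_bg <- config$snp_rate_background
  if (rate_bg == 0 && (config$enriched_fold == 0 || nrow(enriched) == 0L))
    return(empty_snp_table())
  pos_list <- list()
  for (ch in names(ancestor)) {
    L <- nchar(ancestor[[ch]])
    enr <- enriched[enriched$chrom == ch, ][order(start)]
    # background = complement of enriched regions
    bg_start <- c(0, enr$end); bg_end <- c(enr$start, L)
    bg <- data.table(start = bg_start, end = bg_end)[end > start]
    draw <- function(iv, rate) {
      if (!nrow(iv) || rate <= 0) return(numeric(0))
      unlist(lapply(seq_len(nrow(iv)), function(i) {
        len <- iv$end[i] - iv$start[i]
        n <- rbinom(1L, len, min(rate, 1))
        if (n == 0L) return(numeric(0))
        iv$start[i] + sample.int(len, n) - 1
      }))
    }
    p <- c(draw(bg, rate_bg), draw(enr, rate_bg * config$enriched_fold))
    if (length(p)) pos_list[[ch]] <- data.table(chromA = ch, posA = sort(unique(p)))
  }
  if (!length(pos_list)) return(empty_snp_table())
  snps <- rbindlist(pos_list)
  # keep only positions copied into B (drop deleted / uncopied bases)
  ab <- blocks[blocks$src == "A", ]
  setkey(ab, a_chrom, a_start, a_end)
  snps[, `:=`(s = posA, e = posA + 1)]
  hit <- foverlaps(snps, ab, by.x = c("chromA", "s", "e"),
                   by.y = c("a_chrom", "a_start", "a_end"), type = "within", nomatch = NULL)
  if (!nrow(hit)) return(empty_snp_table())
  hit[, posB := ifelse(strand == "+", b_start + (posA - a_start), b_start + (a_end - 1 - posA))]
  snps <- hit[, .(chromA, posA, chromB = b_chrom, posB, strandB = strand)]
  setorder(snps, chromA, posA)
  # alleles
  baseA <- substring(ancestor[snps$chromA], snps$posA + 1, snps$posA + 1)
  shift <- sample.int(3L, nrow(snps), replace = TRUE)
  idx <- (match(baseA, DNA_BASES) - 1L + shift) %% 4L
  mut <- DNA_BASES[idx + 1L]
  snps$baseA <- baseA
  snps$baseB <- ifelse(snps$strandB == "+", mut, unname(comp_base(mut)))
  snps[]
}

empty_snp_table <- function() {
  data.table(chromA = character(), posA = numeric(), chromB = character(),
             posB = numeric(), strandB = character(), baseA = character(),
             baseB = character())
}

materialize_derived <- function(ancestor, blocks, novel, snps) {
  chroms <- unique(blocks$b_chrom)
  derived <- setNames(character(length(chroms)), chroms)
  for (ch in chroms) {
    bl <- blocks[blocks$b_chrom == ch, ][order(b_start)]
    parts <- character(nrow(bl))
    for (i in seq_len(nrow(bl))) {
      if (bl$src[i] == "novel") {
        parts[i] <- novel[[bl$novel_id[i]]]
      } else {
        s <- substr0(ancestor[[bl$a_chrom[i]]], bl$a_start[i], bl$a_end[i])
        if (bl$strand[i] == "-") s <- revcomp(s)
        parts[i] <- s
      }
    }
    seq <- paste(parts, collapse = "")
    sn <- snps[snps$chromB == ch, ]
    if (nrow(sn)) {
      r <- charToRaw(seq)
      r[sn$posB + 1] <- charToRaw(paste(sn$baseB, collapse = ""))
      seq <- rawToChar(r)
    }
    derived[[ch]] <- seq
  }
  derived
}

build_truth <- function(blocks, events, anchors, novel, snps, enriched, seed) {
  bA <- blocks[blocks$src == "A", ]
  blk_of <- function(ty, id) bA[!is.na(bA$event_type) & bA$event_type == ty & bA$event_id == id, ][1L, ]
  svs <- list()
  for (ty in c("inversion", "intra_tx", "inter_tx")) {
    ids <- sort(unique(events$id[events$type == ty]))
    for (id in ids) {
      b <- blk_of(ty, id)
      svs[[length(svs) + 1L]] <- data.table(
        type = c(inversion = "inversion", intra_tx = "intra_translocation",
                 inter_tx = "inter_translocation")[[ty]],
        a_chrom = b$a_chrom, a_start = b$a_start, a_end = b$a_end,
        b_chrom = b$b_chrom, b_start = b$b_start, b_end = b$b_end,
        strand = b$strand)
    }
  }
  svs <- if (length(svs)) rbindlist(svs) else
    data.table(type = character(), a_chrom = character(), a_start = numeric(),
               a_end = numeric(), b_chrom = character(), b_start = numeric(),
               b_end = numeric(), strand = character())

  pav <- list()
  pd <- events[events$type == "pav_del", ]
  if (nrow(pd)) pav[[1L]] <- data.table(genome = "A", chrom = pd$chrom, start = pd$start,
                                        end = pd$end, origin = "deletion")
  nb <- blocks[blocks$src == "novel" & blocks$event_type == "pav_ins", ]
  if (nrow(nb)) pav[[length(pav) + 1L]] <- data.table(genome = "B", chrom = nb$b_chrom,
                                                      start = nb$b_start, end = nb$b_end,
                                                      origin = "insertion")
  pav <- if (length(pav)) rbindlist(pav) else
    data.table(genome = character(), chrom = character(), start = numeric(),
               end = numeric(), origin = character())
  setorder(pav, genome, chrom, start)

  ind <- list()
  sd <- events[events$type == "small_del", ]
  if (nrow(sd)) {
    bpos <- vapply(seq_len(nrow(sd)), function(i)
      lift_pos(blocks, sd$chrom[i], sd$end[i])$pos, numeric(1))
    bch <- vapply(seq_len(nrow(sd)), function(i)
      lift_pos(blocks, sd$chrom[i], sd$end[i])$chrom, character(1))
    ind[[1L]] <- data.table(kind = "deletion", a_chrom = sd$chrom, a_start = sd$start,
                            a_end = sd$end, b_chrom = bch, b_start = bpos, b_end = bpos,
                            length = sd$end - sd$start)
  }
  si <- blocks[blocks$src == "novel" & blocks$event_type == "small_ins", ]
  if (nrow(si)) {
    ind[[length(ind) + 1L]] <- data.table(kind = "insertion", a_chrom = si$a_chrom,
                                          a_start = si$a_start, a_end = si$a_start,
                                          b_chrom = si$b_chrom, b_start = si$b_start,
                                          b_end = si$b_end, length = si$b_end - si$b_start)
  }
  ind <- if (length(ind)) rbindlist(ind) else
    data.table(kind = character(), a_chrom = character(), a_start = numeric(),
               a_end = numeric(), b_chrom = character(), b_start = numeric(),
               b_end = numeric(), length = numeric())
  setorder(ind, a_chrom, a_start)

  truth <- list(snps = as.data.frame(snps),
                indels = as.data.frame(ind),
                pav_segments = as.data.frame(pav),
                svs = as.data.frame(svs),
                enriched_regions = as.data.frame(enriched[, .(chrom, start, end)]),
                liftover = as.data.frame(blocks[, .(b_chrom, b_start, b_end, src, a_chrom,
                                                    a_start, a_end, strand, novel_id)]),
                novel_seqs = novel,
                seed = seed)
  class(truth) <- "truth_set"
  truth
}

#' Replay a truth set on the ancestor genome
#'
#' Reconstructs the derived genome from the recorded edits (block map, novel
#' insertion sequences and SNPs).  Used as the replay invariant: the result
#' must be byte-identical to the emitted derived genome.
#'
#' @param ancestor Ancestor genome.
#' @param truth A `truth_set`.
#' @return The reconstructed derived genome.
#' @export
replay_truth <- function(ancestor, truth) {
  ancestor <- as_genome(ancestor)
  blocks <- as.data.table(truth$liftover)
  snps <- as.data.table(truth$snps)
  materialize_derived(ancestor, blocks, truth$novel_seqs, snps)
}

#' Simulate error-bearing reads from a genome
#'
#' Uniform start positions, both strands, substitution errors only (no indel
#' errors, no quality strings).
#'
#' @param genome Genome (named character vector).
#' @param coverage Target fold coverage (> 0).
#' @param read_length Read length (bp).
#' @param error_rate Per-base substitution error rate.
#' @param seed Integer seed.
#' @return Named character vector of reads.
#' @export
simulate_reads <- function(genome, coverage, read_length, error_rate = 0, seed = 1L) {
  genome <- as_genome(genome)
  if (coverage <= 0) stop("coverage must be > 0")
  lens <- nchar(genome)
  if (read_length > max(lens)) stop("read_length exceeds chromosome length")
  usable <- lens >= read_length
  set.seed(seed)
  g_len <- sum(lens)
  n_reads <- round(coverage * g_len / read_length)
  chroms <- sample(names(genome)[usable], n_reads, replace = TRUE,
                   prob = lens[usable] - read_length + 1)
  starts <- floor(runif(n_reads) * (lens[chroms] - read_length + 1))
  reads <- substring(genome[chroms], starts + 1, starts + read_length)
  minus <- runif(n_reads) < 0.5
  if (any(minus)) reads[minus] <- revcomp(reads[minus])
  if (error_rate > 0) {
    n_err <- rbinom(n_reads, read_length, error_rate)
    which_err <- which(n_err > 0L)
    for (i in which_err) {
      p <- sample.int(read_length, n_err[i])
      old <- substring(reads[i], p, p)
      shift <- sample.int(3L, n_err[i], replace = TRUE)
      new <- DNA_BASES[((match(old, DNA_BASES) - 1L + shift) %% 4L) + 1L]
      r <- charToRaw(reads[i])
      r[p] <- charToRaw(paste(new, collapse = ""))
      reads[i] <- rawToChar(r)
    }
  }
  names(reads) <- sprintf("read_%07d", seq_len(n_reads))
  reads
}
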