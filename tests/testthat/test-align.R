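test_that("trivial anchor cases behave as specified", {
  a <- find_anchors("ACGTACGTAC", "ACGTACGTAC", 10)
  # identity match plus any shorter self-overlap is excluded by min length
  expect_true(nrow(a[a$strand == "+", ]) >= 1)
  exact <- a[a$ref_pos == 0 & a$query_pos == 0 & a$strand == "+", ]
  expect_equal(exact$length, 10L)

  none <- find_anchors(strrep("A", 50), strrep("C", 50), 20)
  expect_equal(nrow(none), 0L)

  # empty sequence is an empty result, not an error
  expect_equal(nrow(find_anchors("", "ACGT", 4)), 0L)

  # N never matches
  withN <- find_anchors("ACGTNACGT", "ACGTNACGT", 9)
  expect_false(any(withN$length == 9))
})

test_that("anchors equal the brute-force maximal-substring enumeration", {
  for (seed in 1:5) {
    ref <- random_dna(200, seed = seed)
    query <- random_dna(200, seed = seed + 100)
    # embed shared material so matches exist on both strands
    substr(query, 30, 69) <- substr(ref, 80, 119)
    substr(query, 120, 149) <- oracle_revcomp(substr(ref, 10, 39))
    got <- find_anchors(ref, query, 8)
    want <- oracle_mems(ref, query, 8)
    got <- got[order(got$ref_pos, got$query_pos, got$strand), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, label = sprintf("seed %d", seed))
  }
})

test_that("chaining matches the exhaustive best-chain search", {
  params <- align_params(max_anchor_gap = 300)
  for (seed in 1:6) {
    set.seed(seed)
    n <- 15
    anc <- data.frame(ref_pos = sample.int(2000, n),
                      query_pos = sample.int(2000, n),
                      length = sample(20:80, n, replace = TRUE),
                      strand = "+")
    chains <- chain_anchors(anc, params, query_len = 3000)
    top <- max(vapply(chains, attr, numeric(1), "score"))
    oracle <- oracle_best_chain_score(
      data.frame(r_s = anc$ref_pos, r_e = anc$ref_pos + anc$length,
                 q_s = anc$query_pos, q_e = anc$query_pos + anc$length,
                 len = anc$length), params$max_anchor_gap)
    expect_equal(top, oracle, label = sprintf("seed %d", seed))
  }
  # partition property: each anchor in exactly one chain
  set.seed(99)
  anc <- data.frame(ref_pos = sample.int(3000, 40), query_pos = sample.int(3000, 40),
                    length = sample(20:60, 40, replace = TRUE), strand = "+")
  chains <- chain_anchors(anc, params, query_len = 4000)
  expect_equal(sum(vapply(chains, nrow, integer(1))), 40L)
})

test_that("two collinear anchors a short gap apart form one chain", {
  anc <- data.frame(ref_pos = c(0, 150), query_pos = c(0, 150),
                    length = c(50, 50), strand = "+")
  chains <- chain_anchors(anc, align_params(), query_len = 300)
  expect_length(chains, 1L)
  expect_equal(nrow(chains[[1]]), 2L)
  # single anchor: single chain
  expect_length(chain_anchors(anc[1, ], align_params(), query_len = 300), 1L)
})

test_that("polished blocks report exact identity arithmetic", {
  ref <- random_dna(1000, seed = 42)
  chains <- chain_anchors(find_anchors(ref, ref, 20), align_params(),
                          query_len = 1000)
  b <- polish_block(chains[[1]], ref, ref)
  expect_equal(b$identity, 100)
  expect_equal(b$aligned_len, 1000L)

  query <- ref
  substr(query, 500, 500) <- if (substr(ref, 500, 500) == "A") "C" else "A"
  chains <- chain_anchors(find_anchors(ref, query, 20), align_params(),
                          query_len = 1000)
  b <- polish_block(chains[[1]], ref, query)
  expect_equal(b$identity, 99.9)
  expect_equal(b$n_match, 999L)
})

test_that("polished edit lists match the full Needleman-Wunsch oracle", {
  set.seed(7)
  ref <- random_dna(500)
  # five well-separated substitutions with unambiguous contexts
  query <- ref
  for (p in c(60, 150, 260, 350, 430)) {
    old <- substr(query, p, p)
    substr(query, p, p) <- DNA[DNA != old][1]
  }
  chains <- chain_anchors(find_anchors(ref, query, 20), align_params(),
                          query_len = nchar(query))
  b <- polish_block(chains[[1]], ref, query)
  oracle <- paste0(rle(oracle_nw_ops(ref, query))$lengths,
                   rle(oracle_nw_ops(ref, query))$values, collapse = "")
  expect_equal(b$cigar, oracle)

  # an indel whose junction admits a single optimal path aligns identically
  ref2 <- paste0(random_dna(196, seed = 11), "ACGACGTA", random_dna(196, seed = 12))
  query2 <- paste0(substr(ref2, 1, 200), "TTTTTTTT", substr(ref2, 201, 400))
  chains2 <- chain_anchors(find_anchors(ref2, query2, 20), align_params(),
                           query_len = nchar(query2))
  b2 <- polish_block(chains2[[1]], ref2, query2)
  o2 <- rle(oracle_nw_ops(ref2, query2))
  expect_equal(b2$cigar, paste0(o2$lengths, o2$values, collapse = ""))
})

test_that("a gap exceeding the doubled band splits the block", {
  set.seed(3)
  flank1 <- random_dna(400)
  flank2 <- random_dna(400)
  insert <- random_dna(600)  # novel: |gap length difference| = 600 > 2 x 100
  ref <- paste0(flank1, flank2)
  query <- paste0(flank1, insert, flank2)
  chains <- chain_anchors(find_anchors(ref, query, 20),
                          align_params(max_anchor_gap = 2000),
                          query_len = nchar(query))
  b <- polish_block(chains[[1]], ref, query,
                    params = align_params(max_anchor_gap = 2000))
  expect_equal(nrow(b), 2L)
  expect_true(all(b$identity == 100))
})

test_that("one-to-one filtering matches the exhaustive subset search", {
  params <- align_params(overlap_slop = 50)
  for (seed in 1:6) {
    set.seed(seed)
    n <- 12
    # coordinates on a 200-bp lattice so overlaps are 0 or >= 200 (> slop)
    mk <- function() {
      s <- sample(seq(0, 4000, by = 200), n, replace = TRUE)
      cbind(s, s + sample(seq(200, 1200, by = 200), n, replace = TRUE))
    }
    r <- mk(); q <- mk()
    b <- data.frame(block_id = 1:n, ref_chrom = sample(c("c1", "c2"), n, TRUE),
                    ref_start = r[, 1], ref_end = r[, 2],
                    query_chrom = sample(c("c1", "c2"), n, TRUE),
                    query_start = q[, 1], query_end = q[, 2],
                    strand = "+", identity = 95,
                    score = round(runif(n, 100, 1000)),
                    aligned_len = r[, 2] - r[, 1], n_match = r[, 2] - r[, 1],
                    cigar = paste0(r[, 2] - r[, 1], "M"),
                    stringsAsFactors = FALSE)
    kept <- filter_one_to_one(b, params)
    expect_equal(sum(kept$score), oracle_best_subset_score(b, params$overlap_slop),
                 label = sprintf("seed %d", seed))
  }
})

test_that("identity threshold and overlap dominance behave as published", {
  b <- data.frame(block_id = 1:2, ref_chrom = "c1",
                  ref_start = c(0, 5000), ref_end = c(1000, 6000),
                  query_chrom = "c1", query_start = c(0, 200),
                  query_end = c(1000, 1200), strand = "+",
                  identity = c(95, 95), score = c(900, 500),
                  aligned_len = 1000, n_match = 950,
                  cigar = "1000M", stringsAsFactors = FALSE)
  kept <- filter_one_to_one(b, align_params())
  expect_equal(kept$block_id, 1L)  # query overlap: only the 900 survives

  b$identity <- c(89.9, 95)
  kept <- filter_one_to_one(b, align_params(min_identity = 90))
  expect_equal(kept$block_id, 2L)  # 89.9 removed by the -i 90 analog
})

test_that("one-to-one output never overlaps on either genome", {
  s <- small_sim(seed = 7)
  o <- filter_one_to_one(align_genomes(s$a, s$b))
  for (axis in list(c("ref_chrom", "ref_start", "ref_end"),
                    c("query_chrom", "query_start", "query_end"))) {
    d <- o[order(o[[axis[1]]], o[[axis[2]]]), ]
    same <- d[[axis[1]]][-1] == d[[axis[1]]][-nrow(d)]
    gap_ok <- d[[axis[2]]][-1] >= d[[axis[3]]][-nrow(d)]
    expect_true(all(!same | gap_ok), label = axis[1])
  }
})

test_that("colinear filtering drops rearranged blocks and stays a subset", {
  s <- small_sim(seed = 7)
  blocks <- align_genomes(s$a, s$b)
  o <- filter_one_to_one(blocks)
  co <- filter_colinear(blocks)
  expect_true(all(co$block_id %in% o$block_id))
  expect_true(all(co$strand == "+"))
  # inverted one-to-one blocks are absent from the colinear set
  inv <- o$block_id[o$strand == "-"]
  expect_true(length(inv) > 0)
  expect_false(any(inv %in% co$block_id))
  # already-collinear input passes through unchanged
  expect_equal(nrow(filter_colinear(co)), nrow(co))
})

test_that("near-identical genomes are almost fully covered by one-to-one blocks", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length = 200000,
                    snp_rate_background = 0.001, enriched_fraction = 0,
                    indel_rate = 0, n_pav_insertions = 0, n_pav_deletions = 0,
                    n_inversions = 0, n_intra_translocations = 0,
                    n_inter_translocations = 0, seed = 17)
  a <- simulate_ancestor(cfg)
  d <- derive_cultivar(a, cfg)
  o <- filter_one_to_one(align_genomes(a, d$genome))
  expect_gte(sum(o$ref_end - o$ref_start) / sum(nchar(a)), 0.99)
  expect_gte(sum(o$query_end - o$query_start) / sum(nchar(d$genome)), 0.99)
  expect_true(all(o$identity >= 99))
})

test_that("window mapping reports coverage against a local-alignment reading", {
  set.seed(21)
  target <- setNames(random_dna(20000), "chr1")
  w <- substr(target[[1]], 5001, 5500)
  hit <- map_window(w, target)
  expect_equal(hit$coverage, 1.0)
  expect_equal(hit$best_hit$chrom, "chr1")

  absent <- random_dna(500, seed = 5)
  miss <- map_window(absent, target)
  expect_equal(miss$coverage, 0)
  expect_null(miss$best_hit)

  # window with its first 400 bp foreign: coverage ~ 0.2 (band effects allowed)
  partial <- paste0(random_dna(400, seed = 6), substr(target[[1]], 9001, 9100))
  p <- map_window(partial, target)
  expect_lt(abs(p$coverage - 0.2), 0.05)

  # reverse-complemented placement is found via the minus strand
  m <- map_window(oracle_revcomp(w), target)
  expect_equal(m$coverage, 1.0)
  expect_equal(m$best_hit$strand, "-")
})

test_that("PAF round trip preserves block geometry", {
  s <- small_sim(seed = 7, chrom_length = 100000)
  o <- filter_one_to_one(align_genomes(s$a, s$b))
  f <- tempfile(fileext = ".paf.tsv")
  write_paf(o, f)
  back <- read_paf(f)
  expect_equal(back$ref_start, o$ref_start)
  expect_equal(back$query_end, o$query_end)
  expect_equal(back$strand, o$strand)
  expect_equal(back$cigar, o$cigar)
})
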