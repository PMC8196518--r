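align_pair_blocks <- function(ref, query) {
  chains <- chain_anchors(find_anchors(ref, query, 20), align_params(),
                          query_len = nchar(query))
  polish_block(chains[[1]], ref, query)
}

test_that("identical sequences yield no variants; one substitution yields one SNP", {
  ref <- random_dna(1000, seed = 1)
  b <- align_pair_blocks(ref, ref)
  b$ref_chrom <- b$query_chrom <- "chr"
  expect_equal(nrow(call_variants(b, c(chr = ref), c(chr = ref))), 0L)

  query <- ref
  old <- substr(query, 400, 400)
  substr(query, 400, 400) <- DNA[DNA != old][1]
  b <- align_pair_blocks(ref, query)
  b$ref_chrom <- b$query_chrom <- "chr"
  v <- call_variants(b, c(chr = ref), c(chr = query))
  expect_equal(nrow(v), 1L)
  expect_equal(v$kind, "SNP")
  expect_equal(v$ref_pos, 400)       # 1-based
  expect_equal(v$ref_allele, old)
  expect_equal(v$query_allele, substr(query, 400, 400))
})

test_that("variant read-out equals the full-DP oracle on planted edits", {
  set.seed(33)
  ref <- random_dna(1000)
  query <- ref
  subs <- c(100, 230, 380, 520, 700, 850)
  for (p in subs) {
    old <- substr(query, p, p)
    substr(query, p, p) <- DNA[DNA != old][1]
  }
  # two unambiguous indels (poly-T insert / clean deletion between anchors)
  query <- paste0(substr(query, 1, 300), "TTTT", substr(query, 301, 1000))
  b <- align_pair_blocks(ref, query)
  b$ref_chrom <- b$query_chrom <- "chr"
  v <- call_variants(b, c(chr = ref), c(chr = query))
  # oracle: column read-out of the full NW alignment
  ops <- oracle_nw_ops(ref, query)
  ri <- cumsum(ops %in% c("M", "X", "D"))
  oracle_snp_pos <- ri[ops == "X"]
  expect_equal(v$ref_pos[v$kind == "SNP"], oracle_snp_pos)
  expect_equal(sort(v$ref_pos[v$kind == "SNP"]), sort(subs))
  expect_equal(v$length[v$kind == "insertion"], 4L)
  expect_equal(sum(ops == "I"), 4L)
})

test_that("a block without edit detail is a contract violation", {
  b <- data.frame(block_id = 1L, ref_chrom = "c", ref_start = 0L, ref_end = 10L,
                  query_chrom = "c", query_start = 0L, query_end = 10L,
                  strand = "+", identity = 100, score = 10, aligned_len = 10L,
                  n_match = 10L, cigar = NA_character_)
  expect_error(call_variants(b, c(c = "ACGTACGTAC"), c(c = "ACGTACGTAC")),
               "contract violation")
})

test_that("adjacent single-base indels merge per the published rule", {
  v <- data.frame(
    kind = c("deletion", "deletion", "deletion", "SNP", "insertion", "insertion"),
    ref_chrom = "c", ref_pos = c(10, 11, 12, 30, 50, 50),
    query_chrom = "c", query_pos = c(9, 9, 9, 28, 48, 49),
    ref_allele = c("A", "C", "G", "T", "-", "-"),
    query_allele = c("-", "-", "-", "A", "G", "T"),
    length = c(1L, 1L, 1L, 1L, 1L, 1L), block_id = 1L,
    stringsAsFactors = FALSE)
  m <- merge_adjacent_indels(v)
  del <- m[m$kind == "deletion", ]
  expect_equal(nrow(del), 1L)
  expect_equal(del$length, 3L)
  expect_equal(del$ref_allele, "ACG")
  ins <- m[m$kind == "insertion", ]
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$query_allele, "GT")
  expect_equal(nrow(m[m$kind == "SNP", ]), 1L)

  # separated by a matched base: not merged
  v2 <- v[5:6, ]
  v2$ref_pos <- c(50, 51)
  v2$query_pos <- c(48, 50)
  expect_equal(nrow(merge_adjacent_indels(v2)), 2L)
})

test_that("random single-base indel patterns merge like a run-length scan", {
  for (seed in 1:5) {
    set.seed(seed)
    pos <- sort(sample(1:60, 20))
    v <- data.frame(kind = "deletion", ref_chrom = "c", ref_pos = pos,
                    query_chrom = "c", query_pos = cumsum(c(5, rep(0, 19))),
                    ref_allele = "A", query_allele = "-", length = 1L,
                    block_id = 1L, stringsAsFactors = FALSE)
    # oracle: runs of consecutive ref positions (query anchor fixed)
    runs <- rle(cumsum(c(1, diff(pos) != 1)))
    m <- merge_adjacent_indels(v)
    expect_equal(nrow(m), length(runs$lengths), label = sprintf("seed %d", seed))
    expect_equal(sort(m$length), sort(runs$lengths), label = sprintf("seed %d", seed))
  }
})

test_that("window counts tile correctly and conserve totals", {
  g <- setNames(random_dna(120000, seed = 2), "c")
  p <- density_params(window = 50000)
  none <- snp_density(empty_vars <- data.frame(kind = character(),
                                               ref_chrom = character(),
                                               ref_pos = numeric()), g, p)
  expect_true(all(none$count == 0))
  expect_equal(none$span, c(50000, 50000, 20000))

  set.seed(8)
  snps <- data.frame(kind = "SNP", ref_chrom = "c",
                     ref_pos = sample.int(120000, 777))
  wc <- snp_density(snps, g, p)
  expect_equal(sum(wc$count), 777L)
  # uniform placement in one window
  one <- data.frame(kind = "SNP", ref_chrom = "c", ref_pos = sample(1:50000, 121))
  expect_equal(snp_density(one, g, p)$count[1], 121L)
})

test_that("enrichment regions use fold x mean, prorated tails, and gap merging", {
  wc <- data.frame(chrom = "c",
                   start = seq(0, 9) * 50000, end = seq(1, 10) * 50000,
                   span = 50000, count = c(300, 310, 100, 320, 100, 100, 100, 100, 100, 100),
                   full = TRUE)
  p <- density_params(window = 50000, fold = 1.5, merge_dist = 100000)
  r <- enrichment_regions(wc, p)
  thr <- 1.5 * mean(wc$count)
  expect_equal(attr(r, "threshold"), thr)
  # flagged: windows 1,2,4 (0-50k, 50-100k, 150-200k); gaps <= 100 kb merge all
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start, r$end), c(0, 200000))
  expect_equal(r$n_snps, 300 + 310 + 320)

  # no window above threshold
  wc$count <- rep(100, 10)
  expect_equal(nrow(enrichment_regions(wc, p)), 0L)

  # threshold override reproduces a published rounded threshold
  wc$count <- c(rep(100, 9), 185)
  r <- enrichment_regions(wc, density_params(threshold_override = 180))
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, 450000)
})

test_that("density summary is plain ratio arithmetic with explicit denominator", {
  snps <- data.frame(kind = rep("SNP", 100))
  d <- density_summary(snps, data.frame(kind = character(), length = numeric()),
                       50000)
  expect_equal(d$snps_per_kb, 2.00)
  expect_equal(d$indels_per_kb, 0)
  expect_equal(d$indel_bp_per_kb, 0)
  expect_error(density_summary(snps, snps, 0), "denominator")
})

test_that("SNP and indel rates are recovered from simulated genomes", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 1e6, seed = 27,
                    snp_rate_background = 0.002, enriched_fraction = 0,
                    n_pav_insertions = 2, n_pav_deletions = 2, n_inversions = 1,
                    n_intra_translocations = 0, n_inter_translocations = 0)
  a <- simulate_ancestor(cfg)
  d <- derive_cultivar(a, cfg)
  o <- filter_one_to_one(align_genomes(a, d$genome))
  v <- merge_adjacent_indels(call_variants(o, a, d$genome))
  snps <- v[v$kind == "SNP", ]
  aligned <- sum(o$ref_end - o$ref_start)
  rate <- nrow(snps) / aligned
  expect_lt(abs(rate - 0.002) / 0.002, 0.05)

  ev <- evaluate_snps(v, d$truth, o)
  expect_gte(ev$recall, 0.99)
  expect_gte(ev$precision, 0.99)

  # per-window SNP and indel counts are positively correlated (both scale
  # with alignable sequence)
  wc <- snp_density(v, a, density_params())
  vi <- v[v$kind != "SNP", ]
  ic <- snp_density(transform(vi, kind = "SNP"), a, density_params())
  expect_gt(cor(wc$count, ic$count), 0)
})

test_that("planted enriched blocks are recovered as enrichment regions", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 1.5e6, seed = 31,
                    n_pav_insertions = 3, n_pav_deletions = 3, n_inversions = 1,
                    n_intra_translocations = 1, n_inter_translocations = 0)
  a <- simulate_ancestor(cfg)
  d <- derive_cultivar(a, cfg)
  o <- filter_one_to_one(align_genomes(a, d$genome))
  v <- call_variants(o, a, d$genome)
  wc <- snp_density(v, a, density_params())
  regions <- enrichment_regions(wc, density_params())
  ee <- evaluate_enrichment(regions, d$truth, min_cover = 0.8)
  expect_true(ee$all_recovered)
})

test_that("VCF output is well-formed", {
  v <- data.frame(kind = c("SNP", "deletion"), ref_chrom = "chr1",
                  ref_pos = c(10, 20), query_chrom = "chr1",
                  query_pos = c(10, 19), ref_allele = c("A", "CG"),
                  query_allele = c("T", "-"), length = c(1L, 2L), block_id = 1L)
  f <- tempfile(fileext = ".vcf")
  write_vcf(v, f)
  lines <- readLines(f)
  expect_true(grepl("^##fileformat=VCFv4.2", lines[1]))
  body <- lines[!grepl("^#", lines)]
  expect_length(body, 2L)
  expect_match(body[1], "TYPE=SNP")
})
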