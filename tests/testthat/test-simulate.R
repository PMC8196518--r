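test_that("ancestor simulation respects length, composition and seed", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 10000, gc_content = 0.5,
                    seed = 7)
  g <- simulate_ancestor(cfg)
  expect_length(g, 1L)
  expect_equal(nchar(g[[1]]), 10000L)
  expect_true(all(strsplit(g[[1]], "")[[1]] %in% c("A", "C", "G", "T")))

  gc_only <- simulate_ancestor(sim_config(n_chromosomes = 1, chrom_length = 500,
                                          gc_content = 1, seed = 1))
  expect_true(all(strsplit(gc_only[[1]], "")[[1]] %in% c("G", "C")))

  # determinism: identical FASTA bytes
  g2 <- simulate_ancestor(cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write_genome(g, f1); write_genome(g2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  # realized GC within 2% of target for >= 100 kb
  big <- simulate_ancestor(sim_config(n_chromosomes = 1, chrom_length = 100000,
                                      gc_content = 0.46, seed = 3))
  gc <- mean(strsplit(big[[1]], "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.46), 0.02)
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(sim_config(gc_content = 1.5), "gc_content")
  expect_error(sim_config(enriched_fold = 1.2), "enriched_fold")
  expect_error(sim_config(pav_min_length = 100), "pav_min_length")
  expect_error(sim_config(snp_rate_background = -0.1), "snp_rate_background")
})

test_that("a no-edit derivation returns the ancestor and an empty truth set", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 20000,
                    snp_rate_background = 0, indel_rate = 0,
                    n_pav_insertions = 0, n_pav_deletions = 0, n_inversions = 0,
                    n_intra_translocations = 0, n_inter_translocations = 0,
                    enriched_fraction = 0, seed = 2)
  a <- simulate_ancestor(cfg)
  d <- derive_cultivar(a, cfg)
  expect_identical(d$genome, a)
  expect_equal(nrow(d$truth$snps), 0L)
  expect_equal(nrow(d$truth$indels), 0L)
  expect_equal(nrow(d$truth$pav_segments), 0L)
  expect_equal(nrow(d$truth$svs), 0L)
})

test_that("planted PAV counts and lengths are logged exactly", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 100000,
                    snp_rate_background = 0, indel_rate = 0,
                    n_pav_insertions = 3, n_pav_deletions = 0, n_inversions = 0,
                    n_intra_translocations = 0, n_inter_translocations = 0,
                    pav_min_length = 1000, pav_below_max = 1001,
                    pav_fraction_below_5kb = 1, enriched_fraction = 0, seed = 9)
  a <- simulate_ancestor(cfg)
  d <- derive_cultivar(a, cfg)
  pv <- d$truth$pav_segments
  expect_equal(nrow(pv), 3L)
  expect_true(all(pv$genome == "B"))
  expect_true(all(pv$end - pv$start == 1000L))
  expect_equal(sum(nchar(d$genome)) - sum(nchar(a)), 3000L)
})

test_that("structural events exceeding the chromosome fail loudly", {
  cfg <- sim_config(n_chromosomes = 2, chrom_length = 20000,
                    inversion_length_range = c(50000, 50000), n_inversions = 1,
                    seed = 1)
  a <- simulate_ancestor(cfg)
  expect_error(derive_cultivar(a, cfg), "simulation error")
})

test_that("replaying the truth set reproduces the derived genome (many seeds)", {
  for (seed in 1:25) {
    cfg <- sim_config(n_chromosomes = 2, chrom_length = 60000,
                      n_pav_insertions = 2, n_pav_deletions = 2,
                      n_inversions = 1, n_intra_translocations = 1,
                      n_inter_translocations = 1,
                      inversion_length_range = c(2000, 5000),
                      translocation_length_range = c(2000, 5000),
                      pav_below_max = 2000, pav_above_max = 5000, seed = seed)
    a <- simulate_ancestor(cfg)
    d <- derive_cultivar(a, cfg, seed = seed + 1000)
    expect_identical(replay_truth(a, d$truth), d$genome,
                     label = sprintf("replay, seed %d", seed))
  }
})

test_that("truth SV intervals never overlap within the ancestor", {
  s <- small_sim(seed = 13)
  iv <- rbind(
    data.frame(chrom = s$truth$svs$a_chrom, start = s$truth$svs$a_start,
               end = s$truth$svs$a_end),
    with(subset(s$truth$pav_segments, genome == "A"),
         data.frame(chrom = chrom, start = start, end = end)))
  iv <- iv[order(iv$chrom, iv$start), ]
  same <- iv$chrom[-1] == iv$chrom[-nrow(iv)]
  expect_true(all(!same | iv$start[-1] >= iv$end[-nrow(iv)]))
})

test_that("realized SNP density in enriched regions matches the planted fold", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 1e6, seed = 21,
                    n_pav_insertions = 2, n_pav_deletions = 2, n_inversions = 1,
                    n_intra_translocations = 1, n_inter_translocations = 0)
  a <- simulate_ancestor(cfg)
  d <- derive_cultivar(a, cfg)
  enr <- d$truth$enriched_regions
  sn <- d$truth$snps
  in_enr <- rep(FALSE, nrow(sn))
  for (i in seq_len(nrow(enr)))
    in_enr <- in_enr | (sn$chromA == enr$chrom[i] & sn$posA >= enr$start[i] &
                          sn$posA < enr$end[i])
  enr_bp <- sum(enr$end - enr$start)
  bg_bp <- sum(nchar(a)) - enr_bp
  dens_enr <- sum(in_enr) / enr_bp
  dens_bg <- sum(!in_enr) / bg_bp
  expect_gte(dens_enr / dens_bg, cfg$enriched_fold * 0.8)
})

test_that("the PAV length law puts the configured mass below 5 kb", {
  cfg <- sim_config(seed = 1)
  set.seed(42)
  lens <- genopair:::sample_pav_lengths(2000L, cfg)
  expect_true(all(lens >= 501L))
  frac <- mean(lens < 5000)
  expect_lt(abs(frac - cfg$pav_fraction_below_5kb), 0.02)
})

test_that("read simulation hits coverage, uniformity and error contracts", {
  g <- setNames(random_dna(100000, seed = 8), "chr1")
  reads <- simulate_reads(g, coverage = 30, read_length = 100, seed = 2)
  expect_lt(abs(sum(nchar(reads)) - 30 * 100000) / (30 * 100000), 0.01)
  expect_equal(length(reads), 30000L)
  # error-free reads are exact substrings (spot-check both strands)
  for (r in reads[seq(1, 3000, by = 157)]) {
    expect_true(grepl(r, g[[1]], fixed = TRUE) ||
                  grepl(oracle_revcomp(r), g[[1]], fixed = TRUE))
  }
  expect_error(simulate_reads(g, coverage = 30, read_length = 2e5), "read_length")
  expect_error(simulate_reads(g, coverage = 0, read_length = 100), "coverage")
})

test_that("truth files round-trip byte-identically and stay replayable", {
  s <- small_sim(seed = 3)
  pre <- file.path(tempfile("truth"), "t")
  write_truth(s$truth, pre)
  t2 <- read_truth(pre)
  pre2 <- file.path(tempfile("truth"), "t")
  write_truth(t2, pre2)
  for (suffix in c(".pav.bed", ".sv.tsv", ".variants.tsv", ".blocks.tsv",
                   ".novel.tsv", ".seed.json")) {
    f1 <- paste0(pre, suffix); f2 <- paste0(pre2, suffix)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)), label = suffix)
  }
  expect_identical(replay_truth(s$a, t2), s$b)
  # variant rows mirror the truth tables
  v <- read.table(paste0(pre, ".variants.tsv"), header = TRUE, sep = "\t")
  expect_equal(sum(v$TYPE == "SNP"), nrow(s$truth$snps))
  expect_equal(sum(v$TYPE != "SNP"), nrow(s$truth$indels))
})

test_that("an empty truth set writes valid empty files with headers", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 20000,
                    snp_rate_background = 0, indel_rate = 0,
                    n_pav_insertions = 0, n_pav_deletions = 0, n_inversions = 0,
                    n_intra_translocations = 0, n_inter_translocations = 0,
                    enriched_fraction = 0, seed = 2)
  a <- simulate_ancestor(cfg)
  d <- derive_cultivar(a, cfg)
  pre <- file.path(tempfile("empty"), "t")
  write_truth(d$truth, pre)
  v <- read.table(paste0(pre, ".variants.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(v), 0L)
  expect_true(all(c("CHROM", "POS", "REF", "ALT", "TYPE") %in% colnames(v)))
  t2 <- read_truth(pre)
  expect_identical(replay_truth(a, t2), a)
})
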