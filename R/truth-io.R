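# Plain-text persistence of truth sets: BED (0-based half-open) for intervals,
# VCF-like TSV (1-based POS) for SNPs/indels, TSV for the block map and novel
# sequences, JSON for the seed.  write -> read -> write is byte-identical.

write_tsv_file <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = "\t"), con, sep = "\n")
  if (nrow(df)) {
    cols <- lapply(df, function(x) {
      if (is.numeric(x)) format(x, scientific = FALSE, trim = TRUE) else as.character(x)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con, sep = "\n")
  }
  invisible(path)
}

read_tsv_file <- function(path) {
  read.table(path, header = TRUE, sep = "\t", colClasses = NA,
             stringsAsFactors = FALSE, comment.char = "", quote = "")
}

#' Write a truth set to plain-text files
#'
#' Emits `<prefix>.pav.bed` and `<prefix>.sv.tsv` (0-based half-open
#' intervals), `<prefix>.variants.tsv` (VCF-like: CHROM, POS 1-based, REF,
#' ALT, TYPE and the derived-genome anchor), `<prefix>.blocks.tsv` (the
#' liftover block map), `<prefix>.novel.tsv` (inserted sequences) and
#' `<prefix>.seed.json`.
#'
#' @param truth A `truth_set`.
#' @param out_prefix Path prefix for the emitted files.
#' @return The vector of written paths, invisibly.
#' @export
write_truth <- function(truth, out_prefix) {
  stopifnot(inherits(truth, "truth_set"))
  dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)
  p <- character(0)

  pav <- truth$pav_segments
  bed <- data.frame(chrom = pav$chrom, start = pav$start, end = pav$end,
                    name = if (nrow(pav)) paste0(pav$genome, "_specific_", pav$origin)
                           else character())
  p[length(p) + 1L] <- write_tsv_file(bed, paste0(out_prefix, ".pav.bed"))

  p[length(p) + 1L] <- write_tsv_file(truth$svs, paste0(out_prefix, ".sv.tsv"))

  sn <- truth$snps
  ind <- truth$indels
  var <- rbind(
    if (nrow(sn)) data.frame(CHROM = sn$chromA, POS = sn$posA + 1, REF = sn$baseA,
                             ALT = sn$baseB, TYPE = "SNP", QCHROM = sn$chromB,
                             QPOS = sn$posB + 1, LEN = 1, QSTRAND = sn$strandB),
    if (nrow(ind)) data.frame(CHROM = ind$a_chrom, POS = ind$a_start + 1, REF = ".",
                              ALT = ".", TYPE = ind$kind, QCHROM = ind$b_chrom,
                              QPOS = ind$b_start + 1, LEN = ind$length, QSTRAND = "+"))
  if (is.null(var))
    var <- data.frame(CHROM = character(), POS = numeric(), REF = character(),
                      ALT = character(), TYPE = character(), QCHROM = character(),
                      QPOS = numeric(), LEN = numeric(), QSTRAND = character())
  p[length(p) + 1L] <- write_tsv_file(var, paste0(out_prefix, ".variants.tsv"))

  p[length(p) + 1L] <- write_tsv_file(truth$liftover, paste0(out_prefix, ".blocks.tsv"))
  nov <- data.frame(id = if (length(truth$novel_seqs)) names(truth$novel_seqs) else character(),
                    seq = unname(truth$novel_seqs))
  p[length(p) + 1L] <- write_tsv_file(nov, paste0(out_prefix, ".novel.tsv"))

  con <- file(paste0(out_prefix, ".seed.json"), open = "wb")
  writeLines(jsonlite::toJSON(list(seed = truth$seed), auto_unbox = TRUE), con, sep = "\n")
  close(con)
  p[length(p) + 1L] <- paste0(out_prefix, ".seed.json")
  invisible(p)
}

#' Read a truth set written by [write_truth()]
#'
#' The enriched-region table is not round-tripped (it is simulation metadata,
#' not an edit); everything needed for [replay_truth()] is.
#'
#' @param out_prefix Prefix used in [write_truth()].
#' @return A `truth_set`.
#' @export
read_truth <- function(out_prefix) {
  bed <- read_tsv_file(paste0(out_prefix, ".pav.bed"))
  pav <- data.frame(genome = sub("_specific_.*$", "", bed$name),
                    chrom = bed$chrom, start = bed$start, end = bed$end,
                    origin = sub("^._specific_", "", bed$name))
  svs <- read_tsv_file(paste0(out_prefix, ".sv.tsv"))
  var <- read_tsv_file(paste0(out_prefix, ".variants.tsv"))
  sn <- var[var$TYPE == "SNP", , drop = FALSE]
  snps <- data.frame(chromA = sn$CHROM, posA = sn$POS - 1, chromB = sn$QCHROM,
                     posB = sn$QPOS - 1, strandB = sn$QSTRAND, baseA = sn$REF,
                     baseB = sn$ALT)
  ind <- var[var$TYPE != "SNP", , drop = FALSE]
  indels <- data.frame(kind = ind$TYPE, a_chrom = ind$CHROM, a_start = ind$POS - 1,
                       a_end = ind$POS - 1 + ifelse(ind$TYPE == "deletion", ind$LEN, 0),
                       b_chrom = ind$QCHROM, b_start = ind$QPOS - 1,
                       b_end = ind$QPOS - 1 + ifelse(ind$TYPE == "insertion", ind$LEN, 0),
                       length = ind$LEN)
  lift <- read_tsv_file(paste0(out_prefix, ".blocks.tsv"))
  nov <- read_tsv_file(paste0(out_prefix, ".novel.tsv"))
  novel <- setNames(as.character(nov$seq), nov$id)
  seed <- jsonlite::fromJSON(paste0(out_prefix, ".seed.json"))$seed
  truth <- list(snps = snps, indels = indels, pav_segments = pav, svs = svs,
                enriched_regions = data.frame(chrom = character(), start = numeric(),
                                              end = numeric()),
                liftover = lift, novel_seqs = novel, seed = seed)
  class(truth) <- "truth_set"
  truth
}

#' Write intervals as BED
#' @param df Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"), colnames(df))
  write_tsv_file(df[, cols, drop = FALSE], path)
}
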