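# CDS- and protein-level difference calling between two alleles of a gene
# (e.g. the herbicide-target AHAS alleles of two cultivars), and in-silico
# PCR with exact primer matching.

#' Translate a coding sequence
#'
#' Standard genetic code; the trailing stop codon is removed.  A CDS not
#' starting with ATG gives a warning; an internal stop is an error naming
#' the codon index; codons with ambiguous bases translate to `X` with a
#' warning.
#'
#' @param cds Coding sequence (length divisible by 3).
#' @return Protein string (one-letter code).
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length must be divisible by 3")
  if (substr(cds, 1L, 3L) != "ATG") warning("CDS does not start with ATG")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  amb <- is.na(aa)
  if (any(amb)) {
    warning(sprintf("%d codon(s) with ambiguous bases translated to X", sum(amb)))
    aa[amb] <- "X"
  }
  stops <- which(aa == "*")
  if (length(stops) && any(stops < length(aa)))
    stop(sprintf("internal stop codon at codon index %d", stops[stops < length(aa)][1L]))
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

# global pairwise alignment of two sequences (same unit scoring as the gap
# closer), returning the two gapped strings
align_pair <- function(a, b) {
  ac <- strsplit(toupper(a), "")[[1]]
  bc <- strsplit(toupper(b), "")[[1]]
  alphabet <- unique(c(ac, bc))
  ops <- nw_banded_ops(match(ac, alphabet), match(bc, alphabet),
                       band = max(nchar(a), nchar(b)))
  ga <- character(length(ops)); gb <- character(length(ops))
  ia <- 0L; ib <- 0L
  for (i in seq_along(ops)) {
    if (ops[i] %in% c("M", "X")) {
      ia <- ia + 1L; ib <- ib + 1L; ga[i] <- ac[ia]; gb[i] <- bc[ib]
    } else if (ops[i] == "D") {
      ia <- ia + 1L; ga[i] <- ac[ia]; gb[i] <- "-"
    } else {
      ib <- ib + 1L; ga[i] <- "-"; gb[i] <- bc[ib]
    }
  }
  list(a = paste(ga, collapse = ""), b = paste(gb, collapse = ""))
}

#' Nucleotide substitutions between two CDS alleles
#'
#' Equal-length sequences are compared column by column; unequal lengths are
#' globally aligned first (unit scores) and substitution columns read off.
#' Positions are 1-based in the first sequence.
#'
#' @param a,b CDS sequences.
#' @return Data frame: `position`, `from`, `to`.
#' @export
diff_cds <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) {
    al <- align_pair(a, b)
    av <- strsplit(al$a, "")[[1]]; bv <- strsplit(al$b, "")[[1]]
    apos <- cumsum(av != "-")
    sel <- av != "-" & bv != "-" & av != bv
    return(data.frame(position = apos[sel], from = av[sel], to = bv[sel]))
  }
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  sel <- which(av != bv)
  data.frame(position = sel, from = av[sel], to = bv[sel])
}

#' Amino-acid substitutions between two proteins
#'
#' One call per differing alignment column, labelled in the standard
#' "S626N" style (1-based position in the first protein).
#'
#' @param a,b Protein sequences.
#' @return Data frame: `position`, `from_aa`, `to_aa`, `label`.
#' @export
diff_proteins <- function(a, b) {
  d <- diff_cds(a, b)  # same column-wise logic; sequences are generic strings
  data.frame(position = d$position, from_aa = d$from, to_aa = d$to,
             label = paste0(d$from, d$position, d$to),
             stringsAsFactors = FALSE)
}

#' In-silico PCR with exact primer matching
#'
#' Finds exact forward-primer matches with an exact reverse-complemented
#' reverse-primer match downstream on the same strand; both strands are
#' searched.  The amplicon runs from the forward-primer start through the
#' end of the reverse-primer binding site, inclusive.
#'
#' @param genome Genome (named character vector).
#' @param fwd,rev Primer sequences (>= 15 bp).
#' @param max_product Maximum amplicon length considered, bp.
#' @return Data frame: `chrom`, `start`, `end` (0-based half-open, forward
#'   strand), `amplicon_length`, `strand`.
#' @export
in_silico_pcr <- function(genome, fwd, rev, max_product = 20000L) {
  genome <- as_genome(genome)
  fwd <- toupper(fwd); rev <- toupper(rev)
  if (nchar(fwd) < 15L || nchar(rev) < 15L) stop("primers must be >= 15 bp")
  out <- list()
  scan_strand <- function(seqs, strand) {
    for (ch in names(seqs)) {
      s <- Biostrings::DNAString(seqs[[ch]])
      fhits <- Biostrings::start(Biostrings::matchPattern(fwd, s))
      rhits <- Biostrings::end(Biostrings::matchPattern(revcomp(rev), s))
      if (!length(fhits) || !length(rhits)) next
      for (f in fhits) {
        ok <- rhits[rhits >= f + nchar(fwd) + nchar(rev) - 1L &
                      rhits - f + 1L <= max_product]
        for (r in ok) {
          len <- r - f + 1L
          # report on forward-strand coordinates of the original genome
          L <- nchar(seqs[[ch]])
          if (strand == "+") {
            st <- f - 1L; en <- r
          } else {
            st <- L - r; en <- L - f + 1L
          }
          out[[length(out) + 1L]] <<- data.frame(
            chrom = ch, start = st, end = en, amplicon_length = len,
            strand = strand, stringsAsFactors = FALSE)
        }
      }
    }
  }
  scan_strand(genome, "+")
  scan_strand(setNames(revcomp(genome), names(genome)), "-")
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      amplicon_length = integer(), strand = character()))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start, res$strand), , drop = FALSE]
}
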