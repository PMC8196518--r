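#' @import data.table
#' @importFrom methods is
#' @importFrom stats phyper p.adjust rbinom rgeom runif setNames filter cor
#' @importFrom utils head tail write.table read.table
NULL

# A "genome" throughout this package is a named character vector of upper-case
# DNA sequences (one element per chromosome), coordinates 0-based half-open
# internally and in BED output, 1-based in VCF-like output.

DNA_BASES <- c("A", "C", "G", "T")

#' Coerce input to the internal genome representation
#'
#' Accepts a named character vector or a [Biostrings::DNAStringSet] and
#' returns a named upper-case character vector, one element per chromosome.
#'
#' @param x Named character vector or `DNAStringSet`.
#' @return Named character vector of upper-case sequences.
#' @export
as_genome <- function(x) {
  if (is(x, "DNAStringSet")) x <- as.character(x)
  if (!is.character(x) || is.null(names(x)) || anyNA(names(x)) || any(names(x) == ""))
    stop("a genome must be a named character vector or DNAStringSet")
  toupper(x)
}

#' Read a genome from a FASTA file
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_genome <- function(path) {
  as_genome(Biostrings::readDNAStringSet(path))
}

#' Write a genome to FASTA (wrapped at 60 columns)
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  genome <- as_genome(genome)
  con <- file(path, open = "wb")  # binary: byte-identical across platforms
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con, sep = "\n")
    s <- genome[[nm]]
    n <- nchar(s)
    starts <- seq(1L, n, by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, n)), con, sep = "\n")
  }
  invisible(path)
}

#' Reverse complement
#' @param x Character vector of DNA sequences.
#' @return Reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# sequence string -> integer codes A=0 C=1 G=2 T=3, anything else NA
seq_to_int <- function(s) {
  lut <- rep(NA_integer_, 256L)
  lut[utf8ToInt("A")] <- 0L; lut[utf8ToInt("C")] <- 1L
  lut[utf8ToInt("G")] <- 2L; lut[utf8ToInt("T")] <- 3L
  lut[utf8ToInt(s)]
}

int_to_seq <- function(v) {
  intToUtf8(utf8ToInt("ACGT")[v + 1L])
}

# Rolling k-mer values (base-4, most-significant first) for a coded sequence.
# Returns a double vector of length n-k+1; windows containing NA (i.e. N) are NA.
# Exact for 4^k <= 2^53 (k <= 26).
kmer_values <- function(codes, k) {
  n <- length(codes)
  if (n < k) return(numeric(0))
  coef <- 4^(seq_len(k) - 1)           # filter coefs: y[i] = sum coef[j]*x[i-j+1]
  y <- stats::filter(as.numeric(codes), coef, method = "convolution", sides = 1)
  as.numeric(y[k:n])
}

# random DNA with given GC content
random_seq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# substring by 0-based half-open interval
substr0 <- function(s, start, end) substring(s, start + 1L, end)

# stopifnot-style validator that names the offending field
check_field <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}
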