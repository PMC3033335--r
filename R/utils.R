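# Low-level sequence utilities shared by all modules. Sequences are handled
# either as character strings (interfaces) or as integer vectors with
# A,C,G,T encoded as 1..4 (hot paths); NA marks ambiguous bases.

BASES <- c("A", "C", "G", "T")

.base_lut <- local({
  lut <- rep(NA_integer_, 128L)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("a")] <- 1L
  lut[utf8ToInt("C")] <- 2L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("g")] <- 3L
  lut[utf8ToInt("T")] <- 4L; lut[utf8ToInt("t")] <- 4L
  lut[utf8ToInt("U")] <- 4L; lut[utf8ToInt("u")] <- 4L
  lut
})

#' @noRd
seq_to_int <- function(s) {
  stopifnot(length(s) == 1L)
  if (nchar(s) == 0L) return(integer(0))
  .base_lut[utf8ToInt(s)]
}

#' @noRd
int_to_seq <- function(v) {
  if (length(v) == 0L) return("")
  codes <- c(65L, 67L, 71L, 84L)[v]
  codes[is.na(codes)] <- 78L  # N
  intToUtf8(codes)
}

# complement of 1..4 coding is 5 - x; reverse complement of an int vector
#' @noRd
revcomp_int <- function(v) rev(5L - v)

#' @noRd
revcomp <- function(s) {
  vapply(s, function(x) int_to_seq(revcomp_int(seq_to_int(x))), character(1),
         USE.NAMES = FALSE)
}

# Rolling k-mer indices (1-based, first base most significant) for every
# window of width k in v. Windows containing NA get index NA.
#' @noRd
kmer_indices <- function(v, k) {
  n <- length(v)
  if (n < k) return(integer(0))
  idx <- v[seq_len(n - k + 1L)] - 1L
  if (k > 1L) {
    for (j in 2:k) idx <- idx * 4L + (v[j:(n - k + j)] - 1L)
  }
  idx + 1L
}

#' @noRd
kmer_names <- function(k) {
  g <- expand.grid(rep(list(BASES), k))[, k:1, drop = FALSE]
  do.call(paste0, g)
}

# All k-mer indices of a set of sequences (character vector), concatenated.
#' @noRd
count_kmers <- function(seqs, k) {
  counts <- numeric(4^k)
  for (s in seqs) {
    v <- seq_to_int(s)
    id <- kmer_indices(v, k)
    id <- id[!is.na(id)]
    if (length(id)) {
      tb <- tabulate(id, nbins = 4^k)
      counts <- counts + tb
    }
  }
  names(counts) <- kmer_names(k)
  counts
}

# Genome-wide mononucleotide background, symmetrised over both strands.
#' Compute a strand-symmetric mononucleotide background
#'
#' Returns the A/C/G/T frequencies of a set of sequences averaged with the
#' frequencies of their reverse complements, so that the background is
#' invariant to which strand was annotated.
#'
#' @param seqs a character vector, `DNAString` or `DNAStringSet`.
#' @return named numeric vector of length 4 summing to 1.
#' @export
base_background <- function(seqs) {
  if (inherits(seqs, "DNAString")) seqs <- Biostrings::DNAStringSet(seqs)
  if (inherits(seqs, "DNAStringSet")) {
    cnt <- colSums(Biostrings::letterFrequency(seqs, BASES))
  } else {
    cnt <- numeric(4)
    for (s in seqs) {
      v <- seq_to_int(s)
      cnt <- cnt + tabulate(v[!is.na(v)], nbins = 4)
    }
  }
  sym <- (cnt + rev(cnt)) / 2  # A<->T, C<->G
  out <- sym / sum(sym)
  names(out) <- BASES
  out
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
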