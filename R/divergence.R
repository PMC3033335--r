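# Inter-species divergences of the five intron-recognition features.
#
# All three measures are symmetrised Kullback-Leibler style sums in which
# each species' feature distribution is weighed against the other species'
# distribution *and* both genomic backgrounds, so that a term equals the
# difference between the expected motif score under the cognate log-odds
# and under the heterologous log-odds. The motif and composition measures
# are not guaranteed non-negative; negative values are reported as-is and
# clipped (with a warning) only when a distance matrix is handed to UPGMA.

#' Divergence between two motif profiles
#'
#' `sum_j sum_k f log2(f G / (F g)) + g log2(F g / (f G))` over the
#' retained columns, with `f`, `g` the two profiles' column frequencies
#' and `F`, `G` the two species' background base frequencies. Frequencies
#' are epsilon-smoothed with the profiles' pseudo counts, so the
#' self-divergence is exactly zero and the value is symmetric under
#' argument swap.
#'
#' @param pwmA,pwmB [pwm_profile()]s of equal width (each carries its own
#'   species background).
#' @param exclude integer vector of column indices to omit, typically the
#'   invariant terminal dinucleotide columns (see [terminal_columns()]).
#' @return divergence in bits (possibly negative).
#' @export
motif_distance <- function(pwmA, pwmB, exclude = NULL) {
  stopifnot(inherits(pwmA, "pwm_profile"), inherits(pwmB, "pwm_profile"))
  if (pwmA$width != pwmB$width) stop("profile widths differ")
  keep <- setdiff(seq_len(pwmA$width), exclude)
  eps <- max(pwmA$pseudo, pwmB$pseudo)
  sm <- function(x) (x + eps) / (1 + 4 * eps)
  f <- sm(pwmA$freqs[, keep, drop = FALSE])
  g <- sm(pwmB$freqs[, keep, drop = FALSE])
  F_ <- sm(pwmA$background)
  G_ <- sm(pwmB$background)
  lr <- log2((f * G_) / (F_ * g))  # backgrounds recycle down columns
  sum(f * lr - g * lr)
}

#' Divergence between two oligomer composition models
#'
#' The motif measure summed over all 1024 5-mers, with `f`, `g` the
#' intronic 5-mer probabilities and `F`, `G` the genomic ones.
#'
#' @param intronA,genomeA intron and genome [markov_model()]s of species A.
#' @param intronB,genomeB the same for species B.
#' @return divergence in bits (possibly negative).
#' @export
composition_distance <- function(intronA, genomeA, intronB, genomeB) {
  f <- markov_fivemer_probs(intronA); F_ <- markov_fivemer_probs(genomeA)
  g <- markov_fivemer_probs(intronB); G_ <- markov_fivemer_probs(genomeB)
  lr <- log2((f * G_) / (F_ * g))
  sum(f * lr - g * lr)
}

#' Divergence between two intron length models
#'
#' Symmetric Kullback-Leibler divergence of the two discrete fitted
#' densities over the common length range
#' `[L_min, min(L_max(A), L_max(B)))`, each renormalised on that range.
#'
#' @param modelA,modelB [length_model()]s.
#' @return divergence in bits (non-negative).
#' @export
length_distance <- function(modelA, modelB) {
  stopifnot(inherits(modelA, "length_model"), inherits(modelB, "length_model"))
  lo <- max(modelA$L_min, modelB$L_min)
  hi <- min(modelA$L_max, modelB$L_max)
  if (hi <= lo) stop("length models share no common support")
  lens <- seq.int(lo, hi - 1L)
  pick <- function(m) {
    d <- m$density[as.character(lens)]
    d <- pmax(d, 1e-300)
    d / sum(d)
  }
  f <- pick(modelA); g <- pick(modelB)
  sum(f * log2(f / g) + g * log2(g / f))
}

#' Terminal dinucleotide columns of a splice-site profile
#'
#' Donor profiles (width 9, offsets -3..+6) carry the invariant +1/+2
#' dinucleotide in columns 4:5; acceptor profiles (width 14, offsets
#' -13..+1) carry -2/-1 in columns 12:13.
#'
#' @param side `"donor"` or `"acceptor"`.
#' @return integer vector of column indices.
#' @export
terminal_columns <- function(side = c("donor", "acceptor")) {
  side <- match.arg(side)
  if (side == "donor") 4:5 else 12:13
}

#' Pairwise feature distance matrix across species
#'
#' @param profiles named list of per-species profile bundles as returned
#'   by [build_profiles()].
#' @param feature one of `"5ss"`, `"3ss"`, `"BP"`, `"length"`,
#'   `"composition"`.
#' @return symmetric numeric matrix with species labels; negative entries
#'   (possible for the motif and composition measures) are retained.
#' @export
feature_distance_matrix <- function(profiles,
                                    feature = c("5ss", "3ss", "BP",
                                                "length", "composition")) {
  feature <- match.arg(feature)
  sp <- names(profiles)
  n <- length(sp)
  D <- matrix(0, n, n, dimnames = list(sp, sp))
  pairval <- function(a, b) {
    switch(feature,
      "5ss" = motif_distance(a$donor, b$donor, exclude = terminal_columns("donor")),
      "3ss" = motif_distance(a$acceptor, b$acceptor, exclude = terminal_columns("acceptor")),
      "BP" = motif_distance(a$bp, b$bp),
      "length" = length_distance(a$length_model, b$length_model),
      "composition" = composition_distance(a$markov_intron, a$markov_genome,
                                           b$markov_intron, b$markov_genome))
  }
  if (n >= 2L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      v <- pairval(profiles[[i]], profiles[[j]])
      D[i, j] <- v; D[j, i] <- v
    }
  }
  D
}

#' Write a distance matrix in PHYLIP format
#'
#' @param D symmetric labelled matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(D, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(D)), con)
  lab <- sprintf("%-10s", substr(rownames(D), 1, 10))
  for (i in seq_len(nrow(D)))
    writeLines(paste0(lab[i], paste(sprintf("%.6f", D[i, ]), collapse = " ")),
               con)
  invisible(path)
}
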