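# Homogeneous fourth-order Markov models of nucleotide composition.
#
# A model is stored as the joint distribution of 5-mers (4^5 = 1024 cells);
# all lower-order marginals and conditionals are derived from it by summing
# over trailing bases. The first four positions of a sequence are scored
# with the order 0..3 ramp implied by those marginals, so both intron and
# genome models assign a proper probability to any sequence.

#' Construct a Markov composition model from a 5-mer distribution
#'
#' @param p5 numeric vector of length 1024 (5-mer probabilities, first base
#'   most significant in A,C,G,T = 1..4 coding); normalised internally.
#' @param iid logical flag marking a model whose 5-mer distribution is the
#'   product of identical mononucleotide distributions (enables a fast
#'   sampling path).
#' @return object of class `markov_model` with elements `order` (4), `joint`
#'   (list of marginal distributions for k = 1..5) and `cond_log2` (list of
#'   conditional log2 tables used for scoring).
#' @export
markov_model <- function(p5, iid = FALSE) {
  if (length(p5) != 1024L) stop("'p5' must have length 4^5")
  if (any(p5 < 0)) stop("negative probabilities")
  p5 <- p5 / sum(p5)
  joint <- vector("list", 5L)
  joint[[5L]] <- p5
  # marginalise over the last (least significant) base:
  # joint[[k]][i] = sum_b joint[[k+1]][(i-1)*4 + b]
  for (k in 4:1) {
    joint[[k]] <- colSums(matrix(joint[[k + 1L]], nrow = 4L))
  }
  cond_log2 <- vector("list", 5L)
  cond_log2[[1L]] <- log2(joint[[1L]])
  for (k in 2:5) {
    prefix <- rep(joint[[k - 1L]], each = 4L)
    cond_log2[[k]] <- log2(joint[[k]] / prefix)
  }
  structure(list(order = 4L, joint = joint, cond_log2 = cond_log2, iid = iid),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("markov_model: order %d%s; base distribution %s\n", x$order,
              if (isTRUE(x$iid)) " (iid)" else "",
              paste(sprintf("%s=%.3f", BASES, x$joint[[1]]), collapse = " ")))
  invisible(x)
}

#' Independent-base Markov model
#'
#' Convenience constructor for a model whose bases are i.i.d. draws from
#' `base_probs`. Useful as a planted generator truth and for closed-form
#' checks.
#'
#' @param base_probs length-4 distribution over A, C, G, T.
#' @return a [markov_model()].
#' @export
iid_markov <- function(base_probs) {
  stopifnot(length(base_probs) == 4L)
  base_probs <- base_probs / sum(base_probs)
  p <- base_probs
  for (k in 2:5) p <- as.vector(outer(base_probs, p))  # new base most significant
  markov_model(p, iid = TRUE)
}

#' Fit a fourth-order Markov model to sequences
#'
#' Counts 5-mers over all supplied sequences (optionally together with their
#' reverse complements) with a pseudo count per cell.
#'
#' @param seqs character vector, `DNAString` or `DNAStringSet`.
#' @param pseudo pseudo count added to every 5-mer cell (default 1).
#' @param both_strands if `TRUE` (default for genome backgrounds) counts are
#'   symmetrised with the reverse-complement strand.
#' @return a [markov_model()].
#' @export
fit_markov <- function(seqs, pseudo = 1, both_strands = FALSE) {
  if (inherits(seqs, "DNAString")) seqs <- Biostrings::DNAStringSet(seqs)
  if (inherits(seqs, "DNAStringSet")) {
    cnt <- colSums(Biostrings::oligonucleotideFrequency(seqs, 5L))
    # oligonucleotideFrequency orders k-mers with LAST base fastest, which
    # matches the first-base-most-significant indexing used here.
  } else {
    cnt <- count_kmers(seqs, 5L)
  }
  if (sum(cnt) < 10 * 1024)
    warning("fewer than 10x4^5 5-mers; Markov estimates may be unstable")
  if (both_strands) cnt <- cnt + cnt[.rc_kmer_perm(5L)]
  markov_model(cnt + pseudo)
}

# permutation sending each 5-mer index to its reverse complement's index
#' @noRd
.rc_kmer_perm <- function(k) {
  n <- 4^k
  idx <- seq_len(n) - 1L
  out <- integer(n)
  for (i in seq_len(n)) {
    x <- idx[i]
    digits <- integer(k)
    for (j in k:1) { digits[j] <- x %% 4L; x <- x %/% 4L }
    rc <- rev(3L - digits)
    y <- 0L
    for (j in seq_len(k)) y <- y * 4L + rc[j]
    out[i] <- y + 1L
  }
  out
}

#' Log2 probability of sequences under a Markov model
#'
#' @param seqs character vector of sequences (each of length >= 1).
#' @param model a [markov_model()].
#' @return numeric vector of log2 probabilities.
#' @export
markov_log2prob <- function(seqs, model) {
  stopifnot(inherits(model, "markov_model"))
  vapply(seqs, function(s) {
    v <- seq_to_int(s)
    l <- length(v)
    if (l == 0L) stop("empty sequence")
    if (anyNA(v)) stop("ambiguous base in sequence")
    tot <- 0
    idx <- 0L
    for (j in seq_len(min(l, 4L))) {
      idx <- idx * 4L + (v[j] - 1L)
      tot <- tot + model$cond_log2[[j]][idx + 1L]
    }
    if (l >= 5L) {
      id5 <- kmer_indices(v, 5L)
      tot <- tot + sum(model$cond_log2[[5L]][id5])
    }
    tot
  }, numeric(1), USE.NAMES = FALSE)
}

#' Oligomer composition information score
#'
#' Per-nucleotide log-odds of a sequence having intronic versus genomic
#' composition: `(log2 P_I(s) - log2 P_G(s)) / length(s)`.
#'
#' @param seqs character vector of sequences.
#' @param model_intron,model_genome [markov_model()] objects for intron and
#'   genome composition.
#' @return numeric vector, bits per nucleotide.
#' @export
composition_score <- function(seqs, model_intron, model_genome) {
  l <- nchar(seqs)
  if (any(l == 0L)) stop("empty sequence")
  (markov_log2prob(seqs, model_intron) -
     markov_log2prob(seqs, model_genome)) / l
}

#' Stationary 5-mer distribution of a model
#' @param model a [markov_model()].
#' @return named numeric vector of length 1024.
#' @export
markov_fivemer_probs <- function(model) {
  p <- model$joint[[5L]]
  names(p) <- kmer_names(5L)
  p
}

#' Sample sequences from a Markov model
#'
#' Generates `length(lengths)` independent sequences whose positions advance
#' in lock-step across sequences, so runtime scales with the longest
#' requested length rather than the total.
#'
#' @param model a [markov_model()].
#' @param lengths integer vector of sequence lengths (0 allowed).
#' @return character vector of sequences.
#' @export
markov_sample <- function(model, lengths) {
  n <- length(lengths)
  if (n == 0L) return(character(0))
  lmax <- max(lengths)
  if (lmax == 0L) return(rep("", n))
  if (isTRUE(model$iid)) {
    p1 <- model$joint[[1L]]
    draws <- sample.int(4L, sum(lengths), replace = TRUE, prob = p1)
    grp <- rep(seq_len(n), lengths)
    out <- vapply(split(draws, factor(grp, levels = seq_len(n))),
                  int_to_seq, character(1))
    names(out) <- NULL
    return(out)
  }
  # cumulative conditional tables per order
  cum <- vector("list", 5L)
  for (k in 1:5) {
    cp <- matrix(2^model$cond_log2[[k]], ncol = 4L, byrow = TRUE)
    cp <- cp / rowSums(cp)
    cum[[k]] <- cbind(cp[, 1L], cp[, 1L] + cp[, 2L], cp[, 1L] + cp[, 2L] + cp[, 3L])
  }
  out <- matrix(0L, n, lmax)
  state <- rep(0L, n)  # prefix index - 1 within current order
  for (j in seq_len(lmax)) {
    active <- which(lengths >= j)
    k <- min(j, 5L)
    tab <- cum[[k]]
    st <- state[active] + 1L
    u <- stats::runif(length(active))
    b <- 1L + (u > tab[st, 1L]) + (u > tab[st, 2L]) + (u > tab[st, 3L])
    out[cbind(active, j)] <- b
    ns <- state[active] * 4L + (b - 1L)
    if (j >= 4L) ns <- ns %% 256L
    state[active] <- ns
  }
  vapply(seq_len(n), function(i) {
    if (lengths[i] == 0L) "" else int_to_seq(out[i, seq_len(lengths[i])])
  }, character(1))
}
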