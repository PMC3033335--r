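# Independent brute-force oracles and fixture builders. The oracles are
# written against the documented contracts (plain character operations and
# explicit loops) and deliberately share no code with the implementation.

BASES4 <- c("A", "C", "G", "T")

rand_dna <- function(n, probs = rep(0.25, 4)) {
  paste(sample(BASES4, n, replace = TRUE, prob = probs), collapse = "")
}

rand_pwm <- function(w, background = rep(0.25, 4), conc = 1) {
  f <- matrix(stats::rgamma(4 * w, conc), 4)
  f <- sweep(f, 2, colSums(f), "/")
  pwm_profile(f, background = background)
}

# --- PPT scan oracle -------------------------------------------------------

oracle_ppt <- function(intron, window = 50, exclude_terminal = 2) {
  ch <- strsplit(intron, "")[[1]]
  L <- length(ch)
  hi <- L - exclude_terminal
  lo <- max(1, hi - window + 1)
  no <- list(present = FALSE)
  if (hi < lo + 1) return(no)
  ispy <- function(b) b %in% c("C", "T")
  e <- NA
  for (p in seq(hi, lo + 1)) {
    if (ispy(ch[p]) && ispy(ch[p - 1])) { e <- p; break }
  }
  if (is.na(e)) return(no)
  best <- -Inf; best_t <- NA; run <- 0; runmax <- -Inf; t <- 0
  for (p in seq(e, lo)) {
    t <- t + 1
    run <- run + if (ispy(ch[p])) 1.0 else -1.5
    if (run >= best) { best <- run; best_t <- t }  # ties -> 5'-most
    runmax <- max(runmax, run)
    if (runmax - run >= 2) break
  }
  start <- e - best_t + 1
  ct <- mean(vapply(ch[start:e], ispy, logical(1)))
  if (ct < 0.5) return(no)
  list(present = TRUE, start = start - (L + 1), end = e - (L + 1),
       ppt_score = best, length = best_t, ct_fraction = ct)
}

# --- BP scan oracle --------------------------------------------------------

oracle_bp <- function(intron, core, ppt, max_from_3p = 100,
                      threshold = 1.85) {
  no <- list(present = FALSE)
  if (!ppt$present) return(no)
  ch <- strsplit(intron, "")[[1]]
  L <- length(ch)
  ppt_start_pos <- L + 1 + ppt$start
  p_hi <- min(ppt_start_pos - 1, L - 4)
  p_lo <- max(3, L - max_from_3p + 1)
  if (p_hi < p_lo) return(no)
  lom <- log2((core$freqs + core$pseudo) /
                (core$background + core$pseudo))
  best <- -Inf; bestp <- NA
  for (p in p_lo:p_hi) {
    sc <- 0
    for (j in 0:4) sc <- sc + lom[match(ch[p + j], BASES4), j + 1]
    if (sc >= best) { best <- sc; bestp <- p }   # ties -> 3'-most
  }
  if (best <= threshold) return(no)
  list(present = TRUE, position = bestp - (L + 1),
       heptamer = paste(ch[(bestp - 2):(bestp + 4)], collapse = ""),
       core_score = best)
}

# --- candidate enumeration oracle -----------------------------------------

oracle_candidates <- function(region, ts, te, range = c(31, 250),
                              margin = 100) {
  ch <- strsplit(region, "")[[1]]
  n <- length(ch)
  dons <- integer(0); accs <- integer(0)
  out <- NULL
  for (d in max(1, ts - margin):min(n - 1, te + margin)) {
    dd <- paste0(ch[d], ch[d + 1])
    if (!(dd %in% c("GT", "GC", "AT"))) next
    for (a in (d + 1):min(n - 1, te + margin)) {
      aa <- paste0(ch[a - 1], ch[a])
      ok <- (dd %in% c("GT", "GC") && aa == "AG") ||
        (dd == "AT" && aa == "AC")
      if (!ok) next
      len <- a - d + 1
      if (len < range[1] || len > range[2]) next
      out <- rbind(out, c(d, a))
    }
  }
  out
}

# --- nodal matrix oracle ---------------------------------------------------

oracle_nodal <- function(tree) {
  n <- length(tree$tip.label)
  M <- matrix(0L, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    p <- ape::nodepath(tree, a, b)
    M[a, b] <- M[b, a] <- length(p) - 2L
  }
  M
}

# --- fixtures --------------------------------------------------------------

# a profile bundle whose every feature score is identically zero
zero_profiles <- function(len_range = c(31L, 250L)) {
  unif9 <- pwm_profile(matrix(0.25, 4, 9), offsets = c(-3:-1, 1:6))
  unif14 <- pwm_profile(matrix(0.25, 4, 14), offsets = c(-13:-1, 1))
  unif7 <- pwm_profile(matrix(0.25, 4, 7), offsets = c(-2:-1, 1:5))
  m <- iid_markov(rep(0.25, 4))
  structure(list(species = "zero", background = rep(0.25, 4),
                 donor = unif9, acceptor = unif14, bp = unif7,
                 core_bp = default_core_bp(),
                 length_model = length_model_from_density(
                   rep(1, diff(len_range) + 1L), L_min = len_range[1]),
                 markov_intron = m, markov_genome = m, n_introns = 0L),
            class = "species_profiles")
}

# hand-rolled intron records
make_records <- function(sequence, upstream = NULL, downstream = NULL,
                         species = "sp", contig = "c1", start = NULL,
                         strand = "+") {
  n <- length(sequence)
  if (is.null(upstream)) upstream <- vapply(seq_len(n), function(i)
    rand_dna(50), character(1))
  if (is.null(downstream)) downstream <- vapply(seq_len(n), function(i)
    rand_dna(50), character(1))
  if (is.null(start)) start <- cumsum(c(0L, utils::head(nchar(sequence), -1L)))
  data.frame(species = species, contig = contig, start = as.integer(start),
             end = as.integer(start + nchar(sequence)), strand = strand,
             sequence = sequence, upstream_flank = upstream,
             downstream_flank = downstream,
             subtype = intron_subtype(sequence),
             length = nchar(sequence), stringsAsFactors = FALSE)
}

# a random intron with plausible architecture for scan tests
rand_intron <- function(min_len = 33, max_len = 120, gc = 0.4) {
  n <- sample(min_len:max_len, 1)
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste0("GT", rand_dna(n - 4, probs), "AG")
}

expect_pwm_equal <- function(a, b, tol = 1e-12) {
  expect_equal(unname(a$freqs), unname(b$freqs), tolerance = tol)
}
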