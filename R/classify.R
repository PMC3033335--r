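# Downstream classification: U12-type intron calls, subtype-stratified
# profiling, and PCA + k-means clustering of contribution patterns.

#' Build U12 reference profiles from verified intron sequences
#'
#' Constructs the U12 donor (width 9, -3..+6) and branch-point (width 7)
#' reference weight matrices from user-supplied sets of aligned segments,
#' e.g. from experimentally verified U12-type introns. No default matrix
#' is shipped; synthetic analyses plant their own references.
#'
#' @param donor_segments character vector of 9-mers (3 exonic + 6 intronic
#'   nucleotides around the donor site).
#' @param bp_segments character vector of 7-mers (branch-point heptamers).
#' @param background background base distribution.
#' @param pseudo pseudo count.
#' @return list with `donor` and `bp` [pwm_profile()]s.
#' @export
build_u12_reference <- function(donor_segments, bp_segments,
                                background = rep(0.25, 4), pseudo = 1e-4) {
  list(donor = pwm_from_segments(donor_segments, background, pseudo,
                                 offsets = c(-3:-1, 1:6), feature = "U12_5ss"),
       bp = pwm_from_segments(bp_segments, background, pseudo,
                              offsets = c(-2:-1, 1:5), feature = "U12_BP"))
}

#' Classify introns as U12-type
#'
#' Applies the three empirical criteria: (i) U12 donor motif score
#' strictly greater than `donor_threshold` bits, (ii) best U12 BP motif
#' score within the last `bp_window` nucleotides strictly greater than
#' `bp_threshold` bits (no core-score gate; the bit threshold replaces
#' it), (iii) intron length strictly less than `max_length`. An intron is
#' called U12-type when all three hold.
#'
#' @param introns intron record data frame.
#' @param u12_donor_pwm,u12_bp_pwm U12 reference profiles (see
#'   [build_u12_reference()]).
#' @param donor_threshold donor criterion in bits (default 9).
#' @param bp_threshold BP criterion in bits (default 6).
#' @param max_length length criterion in nt (default 20000).
#' @param bp_window 3'-terminal window scanned for the BP heptamer
#'   (default 100 nt).
#' @return list with `calls` (per-intron data frame: scores, the three
#'   criterion flags, `is_u12`) and `tally` (counts of all eight
#'   criterion combinations, the Venn table).
#' @export
classify_u12 <- function(introns, u12_donor_pwm, u12_bp_pwm,
                         donor_threshold = 9, bp_threshold = 6,
                         max_length = 20000L, bp_window = 100L) {
  stopifnot(inherits(u12_donor_pwm, "pwm_profile"),
            inherits(u12_bp_pwm, "pwm_profile"))
  don_seg <- paste0(substr(introns$upstream_flank,
                           nchar(introns$upstream_flank) - 2L,
                           nchar(introns$upstream_flank)),
                    substr(introns$sequence, 1L, 6L))
  s5 <- pwm_score(don_seg, u12_donor_pwm)
  lo <- log_odds(u12_bp_pwm)
  sbp <- vapply(introns$sequence, function(s) {
    v <- seq_to_int(s)
    L <- length(v)
    p_lo <- max(1L, L - bp_window + 1L)
    p_hi <- L - 2L - 6L  # heptamer upstream of the terminal dinucleotide
    if (p_hi < p_lo) return(-Inf)
    pos <- p_lo:p_hi
    sc <- numeric(length(pos))
    for (j in 0:6) {
      b <- v[pos + j]
      ok <- !is.na(b)
      sc[ok] <- sc[ok] + lo[cbind(b[ok], j + 1L)]
    }
    max(sc)
  }, numeric(1), USE.NAMES = FALSE)
  crit1 <- s5 > donor_threshold
  crit2 <- sbp > bp_threshold
  crit3 <- introns$length < max_length
  calls <- data.frame(fivess_score = s5, bp_score = sbp,
                      length = introns$length,
                      crit_5ss = crit1, crit_bp = crit2, crit_len = crit3,
                      is_u12 = crit1 & crit2 & crit3)
  tally <- as.data.frame(table(crit_5ss = crit1, crit_bp = crit2,
                               crit_len = crit3))
  list(calls = calls, tally = tally)
}

#' Subtype-stratified profiles and feature trees
#'
#' For every (species, subtype) stratum with more than `min_n` introns,
#' builds donor/acceptor/BP profiles and an intron composition model, then
#' computes per-feature distance matrices across all strata (terminal
#' dinucleotide columns excluded, so GT-AG and GC-AG strata are compared
#' on the variable positions only) and UPGMA trees. Length models are
#' fitted for GT-AG and GC-AG strata only; AT-AC length data are too
#' sparse to support a mixture fit and are excluded from the length
#' feature tree.
#'
#' @param intron_sets named list (per species) of intron record data
#'   frames.
#' @param genome_seqs named list of genome sequences (or `NULL` to use
#'   flanks), parallel to `intron_sets`.
#' @param core_bp core BP matrix.
#' @param min_n minimal stratum size (default 100, strict).
#' @return list with `profiles` (per stratum), `distances` (per feature)
#'   and `trees` (per feature).
#' @export
subtype_stratified_profiles <- function(intron_sets, genome_seqs = NULL,
                                        core_bp = default_core_bp(),
                                        min_n = 100L) {
  strata <- list()
  for (sp in names(intron_sets)) {
    recs <- intron_sets[[sp]]
    gseq <- if (is.null(genome_seqs)) NULL else genome_seqs[[sp]]
    for (st in CANONICAL_SUBTYPES) {
      sub <- recs[recs$subtype == st, , drop = FALSE]
      if (nrow(sub) <= min_n) next
      fit_len <- st != "AT-AC"
      prof <- build_profiles(sub, genome_seqs = gseq, core_bp = core_bp,
                             fit_length = fit_len)
      strata[[paste0(sp, ".", st)]] <- prof
    }
  }
  if (length(strata) < 2L) {
    warning("fewer than 2 strata pass the size threshold")
    return(list(profiles = strata, distances = list(), trees = list()))
  }
  feats <- c("5ss", "3ss", "BP", "composition")
  distances <- lapply(stats::setNames(feats, feats), function(f)
    feature_distance_matrix(strata, f))
  with_len <- strata[vapply(strata, function(p) !is.null(p$length_model),
                            logical(1))]
  if (length(with_len) >= 2L)
    distances$length <- feature_distance_matrix(with_len, "length")
  trees <- lapply(distances, function(D)
    if (nrow(D) >= 2L) suppressWarnings(upgma(D)) else NULL)
  list(profiles = strata, distances = distances, trees = trees)
}

#' Cluster species by their contribution patterns
#'
#' Principal component analysis of the raw six-column contribution table
#' (five features plus information deficit), followed by k-means on the
#' first two components with multiple restarts; the best-inertia solution
#' is kept and the run is deterministic under a fixed seed.
#'
#' @param contributions data frame or matrix, one row per species, six
#'   numeric columns (5ss, 3ss, BP, length, composition, deficit); row
#'   names are species labels.
#' @param k number of clusters (default 6).
#' @param seed RNG seed.
#' @param nstart k-means restarts (default 50).
#' @return data frame with species, the first two PCA coordinates and the
#'   cluster id; the `prcomp` object is attached as attribute `"pca"`.
#' @export
cluster_contributions <- function(contributions, k = 6L, seed = NULL,
                                  nstart = 50L) {
  X <- as.matrix(contributions)
  if (ncol(X) != 6L)
    stop("'contributions' must have six columns (five features + deficit)")
  if (k > nrow(X)) stop("more clusters than species")
  if (!is.null(seed)) set.seed(seed)
  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  coords <- pca$x[, seq_len(min(2L, ncol(pca$x))), drop = FALSE]
  km <- stats::kmeans(coords, centers = k, nstart = nstart)
  out <- data.frame(species = rownames(X) %||% paste0("s", seq_len(nrow(X))),
                    PC1 = coords[, 1L],
                    PC2 = if (ncol(coords) > 1L) coords[, 2L] else 0,
                    cluster = km$cluster)
  rownames(out) <- NULL
  attr(out, "pca") <- pca
  out
}
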