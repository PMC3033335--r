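# Decomposition of short-intron recognition accuracy into per-feature
# contributions.
#
# For every true short intron, all candidate donor/acceptor dinucleotide
# pairs within 100 nt of the true boundaries are enumerated (GY paired
# with AG, AT with AC, implied length within the short-intron range). The
# candidate with the highest "splicing score" -- the sum of the selected
# features' information scores -- is the predicted intron. Accuracy Ac
# over a set of introns transforms to TAc = -log2(1 - Ac); differences in
# TAc between feature subsets quantify each feature's contribution in
# bits.

#' Enumerate candidate splice pairs in a region
#'
#' The region must contain the true intron with up to `margin` nt of
#' context on each side plus 3 extra upstream and 1 extra downstream
#' nucleotide for motif scoring (see [recognition_regions()]). Candidates
#' obey the GY-AG / AT-AC pairing rule (GT or GC donors pair with AG
#' acceptors; AT donors with AC) and the implied intron length range.
#'
#' @param region single character string.
#' @param true_start,true_end 1-based positions of the true intron's first
#'   and last base within `region`.
#' @param length_range allowed implied intron lengths (inclusive),
#'   default `c(31, 250)`.
#' @param margin how far from the true boundaries candidates may lie
#'   (default 100).
#' @return data frame: `donor` (intron start), `acceptor` (intron end),
#'   `length`, `subtype`, `is_true`.
#' @export
enumerate_candidates <- function(region, true_start, true_end,
                                 length_range = c(31L, 250L),
                                 margin = 100L) {
  v <- seq_to_int(region)
  n <- length(v)
  dlo <- max(2L, true_start - margin)
  dhi <- min(n - 1L, true_end + margin)
  pos <- dlo:(dhi - 1L)
  b1 <- v[pos]; b2 <- v[pos + 1L]
  don_gy <- pos[!is.na(b1) & !is.na(b2) & b1 == 3L & (b2 == 4L | b2 == 2L)]
  don_at <- pos[!is.na(b1) & !is.na(b2) & b1 == 1L & b2 == 4L]
  acc_ag <- pos[!is.na(b1) & !is.na(b2) & b1 == 1L & b2 == 3L] + 1L
  acc_ac <- pos[!is.na(b1) & !is.na(b2) & b1 == 1L & b2 == 2L] + 1L
  pair_up <- function(dons, accs) {
    if (!length(dons) || !length(accs)) return(NULL)
    g <- expand.grid(donor = dons, acceptor = accs)
    g$length <- g$acceptor - g$donor + 1L
    g[g$length >= length_range[1] & g$length <= length_range[2], ,
      drop = FALSE]
  }
  out <- rbind(pair_up(don_gy, acc_ag), pair_up(don_at, acc_ac))
  if (is.null(out) || !nrow(out)) {
    out <- data.frame(donor = integer(0), acceptor = integer(0),
                      length = integer(0))
  }
  # restrict to the +/- margin window around the true boundaries
  out <- out[out$donor >= true_start - margin &
               out$acceptor <= true_end + margin, , drop = FALSE]
  first2 <- substr(region, out$donor, out$donor + 1L)
  last2 <- substr(region, out$acceptor - 1L, out$acceptor)
  out$subtype <- paste0(first2, "-", last2)
  out$is_true <- out$donor == true_start & out$acceptor == true_end
  rownames(out) <- NULL
  out
}

#' Build recognition regions from intron records
#'
#' Concatenates `margin + 3` upstream flank nucleotides, the intron, and
#' `margin + 1` downstream flank nucleotides. Records with shorter flanks
#' are rejected.
#'
#' @param introns intron record data frame.
#' @param margin candidate window half-width (default 100).
#' @return data frame with `region`, `true_start`, `true_end`.
#' @export
recognition_regions <- function(introns, margin = 100L) {
  need_up <- margin + 3L; need_dn <- margin + 1L
  if (any(nchar(introns$upstream_flank) < need_up) ||
      any(nchar(introns$downstream_flank) < need_dn))
    stop("flanks shorter than margin + scoring context; regenerate with longer flanks or supply genome-derived regions")
  up <- substr(introns$upstream_flank,
               nchar(introns$upstream_flank) - need_up + 1L,
               nchar(introns$upstream_flank))
  dn <- substr(introns$downstream_flank, 1L, need_dn)
  data.frame(region = paste0(up, introns$sequence, dn),
             true_start = need_up + 1L,
             true_end = need_up + introns$length,
             stringsAsFactors = FALSE)
}

# Feature scores for all candidates of one region. Returns a matrix with
# columns IS_5ss, IS_3ss, IS_BP, IS_len, IS_comp.
#' @noRd
.candidate_scores <- function(region, cands, profiles, length_range) {
  v <- seq_to_int(region)
  n <- length(v)
  nc <- nrow(cands)
  out <- matrix(0, nc, 5L,
                dimnames = list(NULL, c("IS_5ss", "IS_3ss", "IS_BP",
                                        "IS_len", "IS_comp")))
  if (!nc) return(out)

  seg_score <- function(starts, pwm) {
    w <- pwm$width
    lo <- log_odds(pwm)
    sc <- numeric(length(starts))
    for (j in 0:(w - 1L)) {
      p <- starts + j
      ok <- p >= 1L & p <= n
      b <- rep(NA_integer_, length(starts))
      b[ok] <- v[p[ok]]
      use <- !is.na(b)
      sc[use] <- sc[use] + lo[cbind(b[use], j + 1L)]
    }
    sc
  }
  out[, "IS_5ss"] <- seg_score(cands$donor - 3L, profiles$donor)
  out[, "IS_3ss"] <- seg_score(cands$acceptor - 12L, profiles$acceptor)

  # branch point: core 5-mer scores precomputed across the region
  core_lo <- log_odds(profiles$core_bp)
  bp_lo <- log_odds(profiles$bp)
  npos <- n - 4L
  core_sc <- numeric(npos)
  for (j in 0:4) {
    b <- v[seq_len(npos) + j]
    ok <- !is.na(b)
    core_sc[ok] <- core_sc[ok] + core_lo[cbind(b[ok], j + 1L)]
  }
  hept_sc <- rep(NA_real_, npos)
  hok <- seq_len(npos) >= 3L
  hs <- numeric(sum(hok))
  for (j in -2:4) {
    b <- v[which(hok) + j]
    ok <- !is.na(b)
    hs[ok] <- hs[ok] + bp_lo[cbind(b[ok], j + 3L)]
  }
  hept_sc[hok] <- hs
  py <- !is.na(v) & (v == 2L | v == 4L)

  for (i in seq_len(nc)) {
    d <- cands$donor[i]; a <- cands$acceptor[i]
    hi <- a - 2L
    lo_w <- max(d, hi - 49L)
    if (hi < lo_w + 1L) next
    ppt <- .ppt_scan(py[lo_w:hi])
    if (is.null(ppt) || ppt$ct_fraction < 0.5) next
    ppt_start <- lo_w + ppt$start - 1L
    p_hi <- min(ppt_start - 1L, a - 4L, npos)
    p_lo <- max(d + 2L, a - 99L, 3L)
    if (p_hi < p_lo) next
    sc <- core_sc[p_lo:p_hi]
    best <- max(sc)
    if (best <= 1.85) next
    p <- (p_lo:p_hi)[max(which(sc == best))]
    out[i, "IS_BP"] <- hept_sc[p]
  }

  out[, "IS_len"] <- as.numeric(length_score(cands$length,
                                             profiles$length_model))

  # composition via cumulative per-position log ratios (order ramp for the
  # first four candidate positions, order 4 beyond)
  mi <- profiles$markov_intron; mg <- profiles$markov_genome
  ramp <- function(model, k, at) {
    # log2 conditional of order k-1 at positions `at` (uses k-1 preceding bases)
    idx <- v[at] - 1L
    if (k > 1L) for (j in 1:(k - 1L)) idx <- idx + (v[at - j] - 1L) * 4L^j
    model$cond_log2[[k]][idx + 1L]
  }
  id5 <- kmer_indices(v, 5L)  # index for window ending at position p+4
  r4 <- mi$cond_log2[[5L]][id5] - mg$cond_log2[[5L]][id5]
  # r4[t] corresponds to sequence position t + 4
  cum <- c(0, cumsum(r4))
  d <- cands$donor; a <- cands$acceptor
  head_sum <- numeric(nc)
  for (k in 1:4) {
    at <- d + k - 1L
    head_sum <- head_sum + ramp(mi, k, at) - ramp(mg, k, at)
  }
  # order-4 part covers positions d+4 .. a  =>  r4 indices d .. a-4
  out[, "IS_comp"] <- (head_sum + cum[a - 3L] - cum[d]) / cands$length
  out
}

#' Intron recognition accuracy for a feature subset
#'
#' For each intron the candidate with the highest splicing score (sum of
#' the selected features' information scores) is predicted; ties are
#' broken towards the 5'-most donor, then the 5'-most acceptor. Accuracy
#' is the fraction of introns whose true pair is predicted.
#'
#' @param regions data frame from [recognition_regions()] (or compatible).
#' @param profiles a [build_profiles()] bundle.
#' @param features subset of `c("5ss","3ss","BP","length","composition")`;
#'   must contain both splicing signals.
#' @param length_range allowed candidate lengths, default `c(31, 250)`.
#' @return accuracy in `[0, 1]`; attribute `"n"` is the intron count.
#' @export
recognition_accuracy <- function(regions, profiles,
                                 features = c("5ss", "3ss"),
                                 length_range = c(31L, 250L)) {
  if (!nrow(regions)) stop("no introns to evaluate")
  cols <- c("5ss" = "IS_5ss", "3ss" = "IS_3ss", "BP" = "IS_BP",
            "length" = "IS_len", "composition" = "IS_comp")[features]
  hits <- logical(nrow(regions))
  for (r in seq_len(nrow(regions))) {
    cand <- enumerate_candidates(regions$region[r], regions$true_start[r],
                                 regions$true_end[r], length_range)
    sc <- .candidate_scores(regions$region[r], cand, profiles, length_range)
    tot <- rowSums(sc[, cols, drop = FALSE])
    pick <- order(-tot, cand$donor, cand$acceptor)[1L]
    hits[r] <- cand$is_true[pick]
  }
  structure(mean(hits), n = nrow(regions))
}

#' Transformed accuracy
#'
#' `TAc = -log2(1 - Ac)`, in bits; `Ac = 1` is capped at `cap` (the
#' necessary amount of contribution) to keep saturated runs finite.
#'
#' @param ac accuracy values in `[0, 1]`.
#' @param cap cap applied at `ac = 1` (default `-log2(0.02)`).
#' @return numeric vector of transformed accuracies.
#' @export
transformed_accuracy <- function(ac, cap = -log2(0.02)) {
  out <- -log2(1 - ac)
  pmin(out, cap)
}

#' Decompose short-intron recognition into feature contributions
#'
#' Evaluates recognition accuracy for every feature subset containing both
#' splicing signals, transforms to TAc, and reports: the contribution of
#' BP, length and composition as the (non-negative) TAc gain over the
#' 5'ss+3'ss baseline; the 5'ss and 3'ss contributions as the baseline TAc
#' split in proportion to the two motifs' information contents (an
#' explicit convention, since every evaluated subset contains both); the
#' information deficit (necessary amount minus the maximal TAc, floored at
#' 0); and information shares (contributions over the necessary amount,
#' with the deficit share defined as the residual so shares sum to 1).
#'
#' @param regions data frame from [recognition_regions()].
#' @param profiles a [build_profiles()] bundle.
#' @param length_range allowed candidate lengths.
#' @param target_ac accuracy regarded as complete recognition (default
#'   0.98); the necessary amount of contribution is `-log2(1-target_ac)`.
#' @return object of class `contribution_result`: list with `ac` and `tac`
#'   (named per subset), `contributions` (5 features, bits),
#'   `necessary_amount`, `deficit`, `shares` (6 entries incl. deficit).
#' @export
contribution_decomposition <- function(regions, profiles,
                                       length_range = c(31L, 250L),
                                       target_ac = 0.98) {
  extras <- c("BP", "length", "composition")
  subsets <- list(character(0))
  for (k in 1:3) {
    cmb <- utils::combn(extras, k, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  subset_name <- vapply(subsets, function(s)
    paste(c("5ss", "3ss", s), collapse = "+"), character(1))

  # score all candidates once per intron, then evaluate subsets from cache
  cols <- c("5ss" = "IS_5ss", "3ss" = "IS_3ss", "BP" = "IS_BP",
            "length" = "IS_len", "composition" = "IS_comp")
  cache <- vector("list", nrow(regions))
  for (r in seq_len(nrow(regions))) {
    cand <- enumerate_candidates(regions$region[r], regions$true_start[r],
                                 regions$true_end[r], length_range)
    sc <- .candidate_scores(regions$region[r], cand, profiles, length_range)
    cache[[r]] <- list(cand = cand, sc = sc)
  }
  ac <- vapply(subsets, function(s) {
    use <- cols[c("5ss", "3ss", s)]
    mean(vapply(cache, function(x) {
      tot <- rowSums(x$sc[, use, drop = FALSE])
      x$cand$is_true[order(-tot, x$cand$donor, x$cand$acceptor)[1L]]
    }, logical(1)))
  }, numeric(1))
  names(ac) <- subset_name
  necessary <- -log2(1 - target_ac)
  tac <- transformed_accuracy(ac, cap = necessary)

  base <- tac[["5ss+3ss"]]
  gain <- function(feat) max(0, tac[[paste0("5ss+3ss+", feat)]] - base)
  ic5 <- information_content(profiles$donor)
  ic3 <- information_content(profiles$acceptor)
  w5 <- if (ic5 + ic3 > 0) ic5 / (ic5 + ic3) else 0.5
  contributions <- c(
    "5ss" = base * w5,
    "3ss" = base * (1 - w5),
    "BP" = gain("BP"),
    "length" = gain("length"),
    "composition" = gain("composition"))
  deficit <- max(0, necessary - max(tac))
  shares <- contributions / necessary
  deficit_share <- max(0, 1 - sum(shares))
  shares <- c(shares, deficit = deficit_share)
  if (sum(shares) > 1) shares <- shares / sum(shares)
  structure(list(species = profiles$species, ac = ac, tac = tac,
                 contributions = contributions,
                 necessary_amount = necessary, deficit = deficit,
                 shares = shares, n = nrow(regions)),
            class = "contribution_result")
}

#' @export
print.contribution_result <- function(x, ...) {
  cat(sprintf("contribution_result[%s]: n = %d, Ac(all) = %.3f, deficit = %.2f bits\n",
              x$species %||% "?", x$n, x$ac[[length(x$ac)]], x$deficit))
  print(round(x$shares, 3))
  invisible(x)
}
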