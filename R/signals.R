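# Detection of the polypyrimidine tract (PPT) and branch point (BP) in
# individual introns, and construction of species-level donor (5'ss),
# acceptor (3'ss) and BP motif profiles.

# --- PPT ------------------------------------------------------------------

# Core PPT scan on a logical pyrimidine vector ordered 5'->3'. Returns NULL
# or list(start, end) as indices into `py`, plus score/length/ct stats.
# Scoring: +1.0 per C/T, -1.5 per A/G, accumulated 3'->5' from the last
# pyrimidine dinucleotide; the scan stops once the running score drops 2 or
# more below its running maximum; the PPT start is the position attaining
# the maximal score (ties resolved to the 5'-most, i.e. the longest tract).
#' @noRd
.ppt_scan <- function(py) {
  n <- length(py)
  if (n < 2L) return(NULL)
  dinuc <- which(py[-n] & py[-1L])  # positions i with py[i] & py[i+1]
  if (!length(dinuc)) return(NULL)
  e <- max(dinuc) + 1L              # 3'-most pyrimidine of the last dinucleotide
  idx <- ifelse(py[e:1L], 1.0, -1.5)  # scan order: 3' -> 5'
  s <- cumsum(idx)
  runmax <- cummax(s)
  stop_at <- which(runmax - s >= 2)[1L]
  upto <- if (is.na(stop_at)) length(s) else stop_at
  tmax <- max(which(s[seq_len(upto)] == max(s[seq_len(upto)])))  # 5'-most max
  start <- e - tmax + 1L
  seg <- py[start:e]
  list(start = start, end = e, score = s[tmax], length = tmax,
       ct_fraction = mean(seg))
}

#' Locate the polypyrimidine tract of an intron
#'
#' Scans the `window` nucleotides upstream of the 3' splice site (the
#' terminal `exclude_terminal` nucleotides, by default the invariant AG/AC
#' dinucleotide, are excluded from the window). The tract end is the last
#' pyrimidine dinucleotide in the window; the score accumulates +1.0 for
#' C/T and -1.5 for A/G scanning 5'-wards, stopping once it falls 2 or more
#' below its running maximum; the tract start is the position of maximal
#' score. An intron lacks a PPT when no pyrimidine dinucleotide exists in
#' the window or when the C+T fraction of the candidate tract is below 0.5.
#'
#' @param intron intron sequence (single character string, 5'->3').
#' @param window scan window size in nt (default 50).
#' @param exclude_terminal number of terminal 3' nucleotides excluded from
#'   the window (default 2).
#' @return object of class `ppt_annotation`: list with `present`, `start`,
#'   `end` (offsets relative to the intron 3' end, -1 = last base),
#'   `ppt_score`, `length` and `ct_fraction`.
#' @export
find_ppt <- function(intron, window = 50L, exclude_terminal = 2L) {
  v <- seq_to_int(intron)
  L <- length(v)
  hi <- L - exclude_terminal
  lo <- max(1L, hi - window + 1L)
  absent <- structure(list(present = FALSE, start = NA_integer_,
                           end = NA_integer_, ppt_score = NA_real_,
                           length = NA_integer_, ct_fraction = NA_real_),
                      class = "ppt_annotation")
  if (hi < lo + 1L) return(absent)
  py <- !is.na(v) & (v == 2L | v == 4L)
  res <- .ppt_scan(py[lo:hi])
  if (is.null(res)) return(absent)
  if (res$ct_fraction < 0.5) return(absent)
  start_pos <- lo + res$start - 1L
  end_pos <- lo + res$end - 1L
  structure(list(present = TRUE,
                 start = start_pos - (L + 1L),
                 end = end_pos - (L + 1L),
                 ppt_score = res$score,
                 length = res$length,
                 ct_fraction = res$ct_fraction),
            class = "ppt_annotation")
}

# --- BP -------------------------------------------------------------------

#' Scan for the branch point of an intron
#'
#' Scores every 5-mer lying upstream of the detected PPT start and within
#' `max_from_3p` nucleotides of the 3' splice site with the core BP weight
#' matrix. If the maximal score exceeds `threshold` bits the 5-mer plus its
#' upstream 2-mer (a heptamer) is reported as the BP signal; ties at the
#' maximal score resolve to the 3'-most position. By default no BP is
#' reported when the intron lacks a PPT (a functional BP is assumed to be
#' followed by a functional tract); set `require_ppt = FALSE` to scan the
#' full window instead.
#'
#' @param intron intron sequence (single string).
#' @param core_pwm 4 x 5 [pwm_profile()] for the core BP motif.
#' @param ppt a [find_ppt()] annotation for the same intron (computed
#'   internally when missing).
#' @param max_from_3p window from the 3' end within which the 5-mer must
#'   start (default 100).
#' @param threshold acceptance threshold in bits (default 1.85).
#' @param require_ppt skip the scan when no PPT was found (default TRUE).
#' @return object of class `bp_annotation`: list with `present`, `position`
#'   (offset of the 5-mer start relative to the 3' end), `heptamer` and
#'   `core_score`.
#' @export
scan_bp <- function(intron, core_pwm, ppt = NULL, max_from_3p = 100L,
                    threshold = 1.85, require_ppt = TRUE) {
  stopifnot(inherits(core_pwm, "pwm_profile"), core_pwm$width == 5L)
  if (is.null(ppt)) ppt <- find_ppt(intron)
  absent <- structure(list(present = FALSE, position = NA_integer_,
                           heptamer = NA_character_, core_score = NA_real_),
                      class = "bp_annotation")
  v <- seq_to_int(intron)
  L <- length(v)
  if (require_ppt && !ppt$present) return(absent)
  # candidate 5-mer START positions lie upstream of the PPT start (the
  # 5-mer may overhang into the tract; without a PPT it must end before
  # the terminal dinucleotide)
  p_hi <- if (ppt$present) min((L + 1L + ppt$start) - 1L, L - 4L) else L - 6L
  p_lo <- max(3L, L - max_from_3p + 1L)     # heptamer needs 2 nt upstream
  if (p_hi < p_lo) return(absent)
  pos <- p_lo:p_hi
  lo <- log_odds(core_pwm)
  sc <- numeric(length(pos))
  for (j in 0:4) {
    b <- v[pos + j]
    ok <- !is.na(b)
    sc[ok] <- sc[ok] + lo[cbind(b[ok], j + 1L)]
  }
  if (!length(sc)) return(absent)
  best <- max(sc)
  if (best <= threshold) return(absent)
  p <- pos[max(which(sc == best))]          # 3'-most among ties
  structure(list(present = TRUE, position = p - (L + 1L),
                 heptamer = int_to_seq(v[(p - 2L):(p + 4L)]),
                 core_score = best),
            class = "bp_annotation")
}

#' Packaged default core branch-point matrix
#'
#' A 4 x 5 profile encoding the canonical CURAY-type core branch motif
#' (consensus CTAAC with the branch adenosine at position 4). This is a
#' package default intended as a reasonable generic prior; substitute an
#' organism-specific matrix via [read_pwm()] where one is available.
#'
#' @return a [pwm_profile()] of width 5.
#' @export
default_core_bp <- function() {
  read_pwm(system.file("extdata", "core_bp_default.tsv",
                       package = "splicescape"))
}

# --- species-level profiles ------------------------------------------------

#' Build a splice-site PWM from an intron collection
#'
#' Donor profiles cover positions -3..+6 around the exon-intron junction
#' (3 exonic, 6 intronic columns, width 9); acceptor profiles cover
#' -13..+1 around the intron-exon junction (13 intronic columns and one
#' exonic, width 14). Records classified as subtype "other", or lacking the
#' required flank/intron lengths, are skipped (their count is reported in
#' the `"skipped"` attribute).
#'
#' @param introns intron record data frame (see [extract_introns()]).
#' @param side `"donor"` or `"acceptor"`.
#' @param background genome background base frequencies.
#' @param pseudo pseudo count for the resulting profile.
#' @return a [pwm_profile()] of width 9 (donor) or 14 (acceptor).
#' @export
build_ss_pwm <- function(introns, side = c("donor", "acceptor"),
                         background = rep(0.25, 4), pseudo = 1e-4) {
  side <- match.arg(side)
  keep <- introns$subtype != "other"
  introns <- introns[keep, , drop = FALSE]
  if (side == "donor") {
    ok <- nchar(introns$upstream_flank) >= 3L & introns$length >= 6L
    segs <- paste0(substr(introns$upstream_flank[ok],
                          nchar(introns$upstream_flank[ok]) - 2L,
                          nchar(introns$upstream_flank[ok])),
                   substr(introns$sequence[ok], 1L, 6L))
    offsets <- c(-3:-1, 1:6)
    feature <- "5ss"
  } else {
    ok <- nchar(introns$downstream_flank) >= 1L & introns$length >= 13L
    segs <- paste0(substr(introns$sequence[ok], introns$length[ok] - 12L,
                          introns$length[ok]),
                   substr(introns$downstream_flank[ok], 1L, 1L))
    offsets <- c(-13:-1, 1)
    feature <- "3ss"
  }
  if (!length(segs)) stop("no usable records for ", side, " profile")
  if (any(!ok))
    warning(sum(!ok), " record(s) skipped for insufficient flank/length")
  pwm <- pwm_from_segments(segs, background = background, pseudo = pseudo,
                           offsets = offsets, feature = feature)
  attr(pwm, "skipped") <- sum(!ok)
  pwm
}

#' Build a species branch-point profile
#'
#' Runs [find_ppt()] and [scan_bp()] over every intron and tallies the
#' accepted heptamers into a 4 x 7 profile.
#'
#' @param introns intron record data frame.
#' @param core_pwm 4 x 5 core BP matrix (default [default_core_bp()]).
#' @param background genome background base frequencies.
#' @param pseudo pseudo count for the resulting profile.
#' @param ... passed to [scan_bp()].
#' @return a [pwm_profile()] of width 7; attribute `"n_accepted"` records
#'   the number of BP-positive introns.
#' @export
build_bp_profile <- function(introns, core_pwm = default_core_bp(),
                             background = rep(0.25, 4), pseudo = 1e-4, ...) {
  keep <- introns$subtype != "other"
  seqs <- introns$sequence[keep]
  hepts <- character(0)
  for (s in seqs) {
    ppt <- find_ppt(s)
    bp <- scan_bp(s, core_pwm, ppt, ...)
    if (bp$present) hepts[length(hepts) + 1L] <- bp$heptamer
  }
  if (!length(hepts)) stop("no branch points accepted; cannot build profile")
  if (length(hepts) < 100L)
    warning("only ", length(hepts), " BP-positive introns; profile may be noisy")
  pwm <- pwm_from_segments(hepts, background = background, pseudo = pseudo,
                           offsets = c(-2:-1, 1:5), feature = "BP")
  attr(pwm, "n_accepted") <- length(hepts)
  pwm
}

#' Summarise PPT statistics over an intron collection
#'
#' @param introns intron record data frame.
#' @param ... passed to [find_ppt()].
#' @return one-row data frame: fraction of introns with a PPT, mean PPT
#'   length and mean C+T fraction among PPT-positive introns.
#' @export
ppt_statistics <- function(introns, ...) {
  res <- lapply(introns$sequence, find_ppt, ...)
  present <- vapply(res, `[[`, logical(1), "present")
  data.frame(
    n = length(res),
    ppt_fraction = mean(present),
    mean_length = mean(vapply(res[present], `[[`, integer(1), "length")),
    mean_ct_fraction = mean(vapply(res[present], `[[`, numeric(1), "ct_fraction")))
}
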