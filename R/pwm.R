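# Position weight matrix profiles for splice-site and branch-point motifs.
#
# A profile stores per-position base frequencies f[k, j] (column-stochastic,
# rows A/C/G/T) together with a background base distribution F and a pseudo
# count epsilon. Log-odds entries are log2((f + eps) / (F + eps)); the
# per-intron motif score is the sum of log-odds entries along a segment.

#' Construct a position weight matrix profile
#'
#' @param freqs 4 x w numeric matrix of per-position base frequencies; rows
#'   must be in A, C, G, T order (rownames are set accordingly) and every
#'   column must sum to 1.
#' @param background background base frequencies (length-4, sums to 1).
#'   Defaults to the uniform distribution.
#' @param pseudo pseudo count added to both motif and background frequencies
#'   when forming log-odds entries. Default `1e-4`.
#' @param offsets optional integer vector of length w giving each column's
#'   position relative to the junction (negative = exonic/upstream). Stored
#'   as column names.
#' @param feature optional label such as `"5ss"`, `"3ss"`, `"BP"`.
#' @return an object of class `pwm_profile`.
#' @export
pwm_profile <- function(freqs, background = rep(0.25, 4), pseudo = 1e-4,
                        offsets = NULL, feature = NULL) {
  freqs <- as.matrix(freqs)
  if (nrow(freqs) != 4L) stop("'freqs' must have 4 rows (A, C, G, T)")
  cs <- colSums(freqs)
  if (any(abs(cs - 1) > 1e-6)) stop("every column of 'freqs' must sum to 1")
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-6)
    stop("'background' must be a length-4 distribution")
  rownames(freqs) <- BASES
  background <- as.numeric(background)
  names(background) <- BASES
  if (!is.null(offsets)) {
    if (length(offsets) != ncol(freqs))
      stop("'offsets' length must match the number of columns")
    colnames(freqs) <- as.character(offsets)
  }
  structure(
    list(freqs = freqs, background = background, pseudo = pseudo,
         offsets = offsets, feature = feature, width = ncol(freqs)),
    class = "pwm_profile")
}

#' @export
print.pwm_profile <- function(x, ...) {
  cat(sprintf("pwm_profile%s: 4 x %d, pseudo = %g\n",
              if (is.null(x$feature)) "" else paste0(" [", x$feature, "]"),
              x$width, x$pseudo))
  print(round(x$freqs, 3))
  invisible(x)
}

#' Log-odds matrix of a profile
#'
#' Entries are `log2((f + eps) / (F + eps))` with the profile's own pseudo
#' count.
#'
#' @param pwm a [pwm_profile()].
#' @return 4 x w numeric matrix in bits.
#' @export
log_odds <- function(pwm) {
  stopifnot(inherits(pwm, "pwm_profile"))
  log2((pwm$freqs + pwm$pseudo) / (pwm$background + pwm$pseudo))
}

#' Score sequence segments against a profile
#'
#' Sums the log-odds entries of `pwm` along each segment. Segments must have
#' exactly the profile width; ambiguous bases (N) contribute 0 bits at their
#' column.
#'
#' @param segments character vector of segments, or an n x w integer matrix
#'   with bases coded 1..4 (NA = ambiguous).
#' @param pwm a [pwm_profile()].
#' @return numeric vector of scores in bits.
#' @export
pwm_score <- function(segments, pwm) {
  stopifnot(inherits(pwm, "pwm_profile"))
  w <- pwm$width
  if (is.character(segments)) {
    if (any(nchar(segments) != w))
      stop("all segments must have width ", w)
    m <- matrix(NA_integer_, length(segments), w)
    for (i in seq_along(segments)) m[i, ] <- seq_to_int(segments[i])
  } else {
    m <- segments
    if (ncol(m) != w) stop("segment matrix must have ", w, " columns")
  }
  lo <- log_odds(pwm)
  out <- numeric(nrow(m))
  for (j in seq_len(w)) {
    b <- m[, j]
    ok <- !is.na(b)
    out[ok] <- out[ok] + lo[cbind(b[ok], j)]
  }
  out
}

#' Information content of a motif profile
#'
#' Relative entropy (in bits) of the motif distribution against the
#' background, summed over positions. Under positional independence this
#' equals the relative entropy between the distributions over all length-w
#' sequences. Zero-frequency motif cells contribute 0 (the `0 log 0`
#' convention); a zero background frequency is guarded by the profile's
#' pseudo count.
#'
#' @param pwm a [pwm_profile()].
#' @return information content in bits (non-negative up to the pseudo-count
#'   guard).
#' @export
information_content <- function(pwm) {
  stopifnot(inherits(pwm, "pwm_profile"))
  f <- pwm$freqs
  F_ <- pmax(pwm$background, pwm$pseudo)
  term <- ifelse(f > 0, f * log2(f / F_), 0)
  sum(term)
}

#' Consensus sequence of a profile
#' @param pwm a [pwm_profile()].
#' @return single character string, the per-column argmax bases.
#' @export
pwm_consensus <- function(pwm) {
  paste(BASES[apply(pwm$freqs, 2, which.max)], collapse = "")
}

#' Build a profile from observed segments
#'
#' Tallies per-column base frequencies of equal-width segments.
#'
#' @param segments character vector of equal-width sequences, or an integer
#'   matrix coded 1..4.
#' @inheritParams pwm_profile
#' @return a [pwm_profile()].
#' @export
pwm_from_segments <- function(segments, background = rep(0.25, 4),
                              pseudo = 1e-4, offsets = NULL, feature = NULL) {
  if (is.character(segments)) {
    w <- unique(nchar(segments))
    if (length(w) != 1L) stop("segments must share one width")
    m <- matrix(NA_integer_, length(segments), w)
    for (i in seq_along(segments)) m[i, ] <- seq_to_int(segments[i])
  } else m <- segments
  if (nrow(m) == 0L) stop("no segments supplied")
  f <- apply(m, 2, function(col) tabulate(col[!is.na(col)], nbins = 4))
  n <- colSums(f)
  if (any(n == 0)) stop("a column has no unambiguous bases")
  f <- sweep(f, 2, n, "/")
  pwm_profile(f, background = background, pseudo = pseudo, offsets = offsets,
              feature = feature)
}

#' Write / read a profile as TSV
#'
#' The exchange format has a header row of position offsets and four data
#' rows labelled A, C, G, T. The background distribution and pseudo count
#' are stored in `#`-prefixed header lines.
#'
#' @param pwm a [pwm_profile()].
#' @param path file path.
#' @return `write_pwm` returns `path` invisibly; `read_pwm` returns a
#'   [pwm_profile()].
#' @export
write_pwm <- function(pwm, path) {
  stopifnot(inherits(pwm, "pwm_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# background\t", paste(format(pwm$background, digits = 15), collapse = "\t")),
    paste0("# pseudo\t", format(pwm$pseudo, digits = 15)),
    paste0("# feature\t", pwm$feature %||% "NA")), con)
  off <- pwm$offsets %||% seq_len(pwm$width)
  writeLines(paste(c("base", off), collapse = "\t"), con)
  for (k in 1:4) {
    writeLines(paste(c(BASES[k], format(pwm$freqs[k, ], digits = 15)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_pwm
#' @export
read_pwm <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, "\t"), hdr)]
    if (!length(ln)) return(NULL)
    strsplit(ln, "\t")[[1]][-1]
  }
  bg <- as.numeric(get("background") %||% rep(0.25, 4))
  ps <- as.numeric(get("pseudo") %||% 1e-4)
  feat <- get("feature")
  if (!is.null(feat) && feat == "NA") feat <- NULL
  off <- suppressWarnings(as.integer(strsplit(body[1], "\t")[[1]][-1]))
  rows <- strsplit(body[-1], "\t")
  f <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(off))))
  pwm_profile(f, background = bg, pseudo = ps,
              offsets = if (anyNA(off)) NULL else off, feature = feat)
}
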