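# Extraction, quality filtering, de-duplication and subtype tallying of
# introns from genome + exon-structure input, plus the FASTA/TSV exchange
# format for intron collections.
#
# Intron records are plain data frames with columns: species, contig,
# start, end (0-based half-open genomic span), strand, sequence (spliced
# strand orientation), upstream_flank, downstream_flank (exonic context),
# subtype, length.

CANONICAL_SUBTYPES <- c("GT-AG", "GC-AG", "AT-AC")

#' Classify intron subtype from terminal dinucleotides
#' @param seqs character vector of intron sequences.
#' @return character vector: `"GT-AG"`, `"GC-AG"`, `"AT-AC"` or `"other"`.
#' @export
intron_subtype <- function(seqs) {
  first2 <- substr(seqs, 1L, 2L)
  last2 <- substr(seqs, nchar(seqs) - 1L, nchar(seqs))
  out <- rep("other", length(seqs))
  out[first2 == "GT" & last2 == "AG"] <- "GT-AG"
  out[first2 == "GC" & last2 == "AG"] <- "GC-AG"
  out[first2 == "AT" & last2 == "AC"] <- "AT-AC"
  out
}

#' @noRd
new_intron_records <- function(species, contig, start, end, strand, sequence,
                               upstream_flank, downstream_flank) {
  data.frame(species = species, contig = contig,
             start = as.integer(start), end = as.integer(end),
             strand = strand, sequence = sequence,
             upstream_flank = upstream_flank,
             downstream_flank = downstream_flank,
             subtype = intron_subtype(sequence),
             length = nchar(sequence),
             stringsAsFactors = FALSE)
}

#' Extract introns from a genome and exon structures
#'
#' One record is emitted per internal gap between consecutive exons of a
#' transcript. Minus-strand transcripts yield reverse-complemented,
#' transcript-oriented sequences and flanks. Exonic flanks are taken from
#' the adjacent exon ends (up to `flank` nt).
#'
#' @param genome named `DNAStringSet` (or named character vector) of contig
#'   sequences.
#' @param exons data frame with columns `transcript_id`, `contig`, `start`,
#'   `end` (1-based inclusive), `strand`; or a GFF3/BED12-derived object
#'   from [read_exon_annotation()].
#' @param species species label stored in the records.
#' @param flank exonic flank length to record (default 50).
#' @return intron record data frame.
#' @export
extract_introns <- function(genome, exons, species = "species", flank = 50L) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  stopifnot(inherits(genome, "DNAStringSet"))
  need <- c("transcript_id", "contig", "start", "end", "strand")
  if (!all(need %in% names(exons)))
    stop("'exons' must have columns ", paste(need, collapse = ", "))
  widths <- stats::setNames(Biostrings::width(genome), names(genome))
  bad <- exons$start < 1L | exons$end > widths[exons$contig] |
    is.na(widths[exons$contig])
  if (any(bad)) stop("exon coordinates outside contig bounds")

  out <- list()
  for (tid in unique(exons$transcript_id)) {
    ex <- exons[exons$transcript_id == tid, , drop = FALSE]
    if (nrow(ex) < 2L) next
    ex <- ex[order(ex$start), , drop = FALSE]
    if (any(ex$start[-1L] <= ex$end[-nrow(ex)])) {
      warning("overlapping exons in transcript ", tid, "; skipped")
      next
    }
    contig <- ex$contig[1L]
    strand <- ex$strand[1L]
    cs <- genome[[contig]]
    for (i in seq_len(nrow(ex) - 1L)) {
      g1 <- ex$end[i] + 1L       # intron first base (1-based, genomic)
      g2 <- ex$start[i + 1L] - 1L
      if (g2 < g1) next
      sq <- as.character(Biostrings::subseq(cs, g1, g2))
      lf <- as.character(Biostrings::subseq(
        cs, max(1L, ex$start[i], ex$end[i] - flank + 1L), ex$end[i]))
      rf <- as.character(Biostrings::subseq(
        cs, ex$start[i + 1L],
        min(ex$end[i + 1L], ex$start[i + 1L] + flank - 1L)))
      if (strand == "-") {
        tmp <- revcomp(lf); lf <- revcomp(rf); rf <- tmp
        sq <- revcomp(sq)
      }
      out[[length(out) + 1L]] <- list(contig = contig, start = g1 - 1L,
                                      end = g2, strand = strand,
                                      sequence = sq, up = lf, dn = rf)
    }
  }
  if (!length(out))
    return(new_intron_records(character(0), character(0), integer(0),
                              integer(0), character(0), character(0),
                              character(0), character(0)))
  new_intron_records(
    species = species,
    contig = vapply(out, `[[`, character(1), "contig"),
    start = vapply(out, function(x) as.integer(x$start), integer(1)),
    end = vapply(out, function(x) as.integer(x$end), integer(1)),
    strand = vapply(out, `[[`, character(1), "strand"),
    sequence = vapply(out, `[[`, character(1), "sequence"),
    upstream_flank = vapply(out, `[[`, character(1), "up"),
    downstream_flank = vapply(out, `[[`, character(1), "dn"))
}

#' Read exon structures from a GFF3 file
#'
#' Thin wrapper over [rtracklayer::import()] keeping `exon` features and
#' deriving `transcript_id` from the `Parent` (or `transcript_id`)
#' attribute.
#'
#' @param path GFF3 file path.
#' @return data frame with columns `transcript_id`, `contig`, `start`,
#'   `end`, `strand` (1-based inclusive coordinates).
#' @export
read_exon_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  tid <- if (!is.null(gr$Parent) && any(lengths(gr$Parent) > 0)) {
    vapply(as.list(gr$Parent), function(p) as.character(p)[1], character(1))
  } else as.character(gr$transcript_id)
  data.frame(transcript_id = tid,
             contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Quality-filter intron records
#'
#' Applies the three acceptance criteria: (i) canonical terminal
#' dinucleotides (GT-AG, GC-AG or AT-AC), (ii) length strictly greater
#' than `min_length`, and (iii) at most `max_mismatch` mismatches and at
#' most `max_gap` gaps within the 10 alignment positions flanking each
#' side of the intron. Criterion (iii) is evaluated against an optional
#' per-junction error table; records without an entry pass (error-free
#' synthetic data needs no sidecar).
#'
#' @param records intron record data frame.
#' @param junction_errors optional data frame with columns `contig`,
#'   `start`, `end`, `mismatch_left`, `mismatch_right`, `gap_left`,
#'   `gap_right`.
#' @param min_length minimal retained length (exclusive bound; default 30).
#' @param max_mismatch,max_gap per-side tolerances for criterion (iii).
#' @return the surviving records; attribute `"rejections"` holds named
#'   per-criterion rejection counts (a record failing several criteria is
#'   counted once per criterion).
#' @export
quality_filter <- function(records, junction_errors = NULL, min_length = 30L,
                           max_mismatch = 1L, max_gap = 0L) {
  crit1 <- records$subtype %in% CANONICAL_SUBTYPES
  crit2 <- records$length > min_length
  crit3 <- rep(TRUE, nrow(records))
  if (!is.null(junction_errors) && nrow(records)) {
    key <- paste(records$contig, records$start, records$end)
    ekey <- paste(junction_errors$contig, junction_errors$start,
                  junction_errors$end)
    m <- match(key, ekey)
    has <- !is.na(m)
    je <- junction_errors[m[has], , drop = FALSE]
    crit3[has] <- je$mismatch_left <= max_mismatch &
      je$mismatch_right <= max_mismatch &
      je$gap_left <= max_gap & je$gap_right <= max_gap
  }
  keep <- crit1 & crit2 & crit3
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- c(noncanonical = sum(!crit1),
                               too_short = sum(!crit2),
                               alignment = sum(!crit3))
  out
}

# ungapped percent identity between two equal-length strings
#' @noRd
.identity_frac <- function(a, b) {
  va <- utf8ToInt(a); vb <- utf8ToInt(b)
  mean(va == vb)
}

# 100-nt context of one junction: 50 exonic + 50 intronic nt, padded with
# '-' placeholders where flank or intron is shorter
#' @noRd
.junction_context <- function(records, which = c("donor", "acceptor")) {
  which <- match.arg(which)
  pad <- function(x, n, left) {
    d <- n - nchar(x)
    filler <- strrep("-", pmax(d, 0))
    x <- ifelse(d > 0, if (left) paste0(filler, x) else paste0(x, filler), x)
    if (left) substr(x, nchar(x) - n + 1L, nchar(x)) else substr(x, 1L, n)
  }
  if (which == "donor") {
    paste0(pad(records$upstream_flank, 50L, left = TRUE),
           pad(records$sequence, 50L, left = FALSE))
  } else {
    paste0(pad(records$sequence, 50L, left = TRUE),
           pad(records$downstream_flank, 50L, left = FALSE))
  }
}

#' De-duplicate highly similar exon-intron junctions
#'
#' Groups records whose 100-nt junction contexts (50 exonic + 50 intronic
#' nucleotides, at both the donor and the acceptor junction) exceed the
#' identity threshold, and keeps one representative per group. Identity is
#' ungapped, position-by-position; both junctions must exceed the
#' threshold for two records to be merged. The representative is the
#' lexicographically smallest (species, contig, start) record, or a random
#' group member when `random = TRUE`.
#'
#' @param records intron record data frame.
#' @param threshold identity above which two junction contexts are deemed
#'   redundant (default 0.75, strict inequality).
#' @param random choose the representative at random (requires a seeded
#'   RNG for reproducibility) instead of lexicographically.
#' @return the representative records; attribute `"n_removed"` counts the
#'   discarded duplicates.
#' @export
deduplicate <- function(records, threshold = 0.75, random = FALSE) {
  n <- nrow(records)
  if (n <= 1L) {
    attr(records, "n_removed") <- 0L
    return(records)
  }
  don <- .junction_context(records, "donor")
  acc <- .junction_context(records, "acceptor")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (find(i) == find(j)) next
      if (.identity_frac(don[i], don[j]) > threshold &&
          .identity_frac(acc[i], acc[j]) > threshold) {
        parent[find(j)] <- find(i)
      }
    }
  }
  grp <- vapply(seq_len(n), find, integer(1))
  keep <- vapply(split(seq_len(n), grp), function(idx) {
    if (length(idx) == 1L) return(idx)
    if (random) return(sample(idx, 1L))
    ord <- order(records$species[idx], records$contig[idx],
                 records$start[idx])
    idx[ord[1L]]
  }, integer(1))
  out <- records[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- n - length(keep)
  out
}

#' Tally intron subtypes
#'
#' @param records intron record data frame.
#' @return data frame with one row per (species, subtype): count and the
#'   fraction among that species' records.
#' @export
subtype_tally <- function(records) {
  if (!nrow(records))
    return(data.frame(species = character(0), subtype = character(0),
                      count = integer(0), fraction = numeric(0)))
  tab <- as.data.frame(table(species = records$species,
                             subtype = records$subtype),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "count"
  tab <- tab[tab$count > 0L, , drop = FALSE]
  tot <- tapply(tab$count, tab$species, sum)
  tab$fraction <- tab$count / as.numeric(tot[tab$species])
  rownames(tab) <- NULL
  tab
}

# --- exchange format -------------------------------------------------------

#' Write / read the intron exchange format
#'
#' `write_introns` produces `<prefix>.fa` (intron sequences; ids encode
#' species, contig, 0-based half-open span and strand) and `<prefix>.tsv`
#' (all record columns). `read_introns` restores an identical data frame.
#'
#' @param records intron record data frame.
#' @param prefix output path prefix.
#' @return `write_introns` returns `prefix` invisibly; `read_introns`
#'   returns the record data frame.
#' @export
write_introns <- function(records, prefix) {
  utils::write.table(records, paste0(prefix, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ids <- sprintf("%s|%s|%d-%d|%s", records$species, records$contig,
                 records$start, records$end, records$strand)
  dss <- Biostrings::DNAStringSet(records$sequence)
  names(dss) <- ids
  Biostrings::writeXStringSet(dss, paste0(prefix, ".fa"))
  invisible(prefix)
}

#' @rdname write_introns
#' @export
read_introns <- function(prefix) {
  df <- utils::read.table(paste0(prefix, ".tsv"), sep = "\t", header = TRUE,
                          colClasses = c(species = "character",
                                         contig = "character",
                                         strand = "character",
                                         sequence = "character",
                                         upstream_flank = "character",
                                         downstream_flank = "character",
                                         subtype = "character"))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$length <- as.integer(df$length)
  df
}
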