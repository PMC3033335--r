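# Intron extraction, quality filtering, de-duplication, tallying and the
# exchange format.

make_toy_genome <- function() {
  # one contig: 60 nt pad | exon1 (40) | intron (40) | exon2 (40) | pad
  set.seed(77)
  pad1 <- rand_dna(60); pad2 <- rand_dna(60)
  exon1 <- paste0(rand_dna(37), "CAG")
  intron <- paste0("GTAAGT", rand_dna(13), "TACTAAC", strrep("T", 11), "CAG")
  exon2 <- paste0("G", rand_dna(39))
  genome <- Biostrings::DNAStringSet(paste0(pad1, exon1, intron, exon2, pad2))
  names(genome) <- "chr1"
  exons <- data.frame(transcript_id = "t1", contig = "chr1",
                      start = c(61, 141), end = c(100, 180), strand = "+")
  list(genome = genome, exons = exons, intron = intron, exon1 = exon1,
       exon2 = exon2)
}

test_that("a two-exon gene yields one canonical intron record", {
  toy <- make_toy_genome()
  recs <- extract_introns(toy$genome, toy$exons)
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$sequence, toy$intron)
  expect_equal(recs$subtype, "GT-AG")
  expect_equal(recs$start, 100L)   # 0-based half-open
  expect_equal(recs$end, 140L)
  expect_equal(recs$upstream_flank, substr(toy$exon1, 1, 40))
  expect_equal(recs$downstream_flank, toy$exon2)
  expect_equal(recs$length, 40L)
})

test_that("extraction is strand-invariant", {
  toy <- make_toy_genome()
  plus <- extract_introns(toy$genome, toy$exons)
  # reverse-complement the contig and mirror the exon coordinates
  glen <- Biostrings::width(toy$genome)[1]
  rcg <- Biostrings::reverseComplement(toy$genome)
  names(rcg) <- "chr1"
  ex <- toy$exons
  ex2 <- data.frame(transcript_id = "t1", contig = "chr1",
                    start = glen - ex$end + 1, end = glen - ex$start + 1,
                    strand = "-")
  minus <- extract_introns(rcg, ex2)
  expect_equal(minus$sequence, plus$sequence)
  expect_equal(minus$upstream_flank, plus$upstream_flank)
  expect_equal(minus$downstream_flank, plus$downstream_flank)
  expect_equal(minus$subtype, plus$subtype)
  expect_equal(minus$strand, "-")
})

test_that("a five-exon transcript yields four gap-length introns", {
  set.seed(31)
  glen <- 2000
  genome <- Biostrings::DNAStringSet(rand_dna(glen))
  names(genome) <- "c"
  starts <- c(101, 301, 641, 901, 1401)
  ends <- c(200, 420, 700, 1000, 1480)
  exons <- data.frame(transcript_id = "t", contig = "c",
                      start = starts, end = ends, strand = "+")
  recs <- extract_introns(genome, exons)
  expect_equal(nrow(recs), 4L)
  # independent coordinate arithmetic for the gaps
  expect_equal(recs$length, starts[-1] - ends[-5] - 1L)
  expect_equal(recs$start, ends[-5])
  expect_equal(recs$end, starts[-1] - 1L)
})

test_that("extraction from generated species reproduces the planted records", {
  sp <- species_spec(n_introns = 80, seed = 19,
                     length_mixture = length_model(shape = c(3, 3),
                                                   scale = c(60, 90),
                                                   loc = c(30, 40),
                                                   weight = 0.5))
  g <- generate_species(sp)
  got <- extract_introns(g$genome, g$exons, species = sp$name)
  key <- function(d) paste(d$contig, d$start, d$end, d$strand, d$sequence,
                           d$upstream_flank, d$downstream_flank)
  expect_setequal(key(got), key(g$introns))
})

test_that("the three quality criteria reject the documented violations", {
  good <- paste0("GT", strrep("ACGT", 10), "AG")     # 44 nt GT-AG
  recs <- make_records(sequence = c(
    good,                                            # 1 passes
    paste0("GT", strrep("A", 21), "AG"),             # 2 too short (25 nt)
    paste0("CT", strrep("ACGT", 10), "AG"),          # 3 non-canonical
    paste0("GC", strrep("ACGT", 10), "AG"),          # 4 GC-AG passes
    paste0("AT", strrep("ACGT", 10), "AC"),          # 5 AT-AC passes
    paste0("GT", strrep("ACGT", 10), "AC"),          # 6 non-canonical pair
    good,                                            # 7 bad alignment left
    good,                                            # 8 bad alignment right
    good,                                            # 9 gapped alignment
    paste0("GT", strrep("G", 27), "AG"),             # 10 31 nt passes
    paste0("GT", strrep("G", 26), "AG"),             # 11 30 nt fails (strict)
    paste0("AT", strrep("ACGT", 10), "AG")))         # 12 AT-AG non-canonical
  je <- data.frame(contig = "c1",
                   start = recs$start[7:9], end = recs$end[7:9],
                   mismatch_left = c(2L, 0L, 1L),
                   mismatch_right = c(0L, 3L, 1L),
                   gap_left = c(0L, 0L, 1L), gap_right = 0L)
  out <- quality_filter(recs, junction_errors = je)
  expect_equal(out$start, recs$start[c(1, 4, 5, 10)])
  rej <- attr(out, "rejections")
  expect_equal(unname(rej["noncanonical"]), 3L)
  expect_equal(unname(rej["too_short"]), 2L)
  expect_equal(unname(rej["alignment"]), 3L)
})

test_that("deduplication merges by junction-context identity", {
  set.seed(55)
  up <- rand_dna(50); dn <- rand_dna(50)
  intron <- paste0("GT", rand_dna(96), "AG")
  mutate <- function(s, at, alt = 1) {
    ch <- strsplit(s, "")[[1]]
    for (p in at) ch[p] <- setdiff(BASES4, ch[p])[alt]
    paste(ch, collapse = "")
  }
  # 80% identity at both junctions: 20 mismatches inside each context half
  intron80 <- mutate(intron, c(11:30, 61:80))
  # 60% identity to BOTH others: 40 mismatches per junction, using a
  # different substitution so overlapping positions still mismatch intron80
  intron60 <- mutate(intron, c(3:42, 55:94), alt = 2)
  recs <- make_records(sequence = c(intron, intron, intron80, intron60),
                       upstream = rep(up, 4), downstream = rep(dn, 4),
                       start = c(0L, 500L, 1000L, 1500L))
  # identical pair collapses
  out1 <- deduplicate(recs[1:2, ])
  expect_equal(nrow(out1), 1L)
  expect_equal(out1$start, 0L)   # lexicographically smallest representative
  # 80% > 75%: merged; 60% retained
  out2 <- deduplicate(recs)
  expect_setequal(out2$start, c(0L, 1500L))
  expect_equal(attr(out2, "n_removed"), 2L)
})

test_that("subtype tallies are per-species fractions", {
  recs <- make_records(sequence = c(
    rep(paste0("GT", strrep("A", 40), "AG"), 98),
    rep(paste0("GC", strrep("A", 40), "AG"), 2)))
  tab <- subtype_tally(recs)
  expect_equal(tab$fraction[tab$subtype == "GT-AG"], 0.98)
  expect_equal(tab$fraction[tab$subtype == "GC-AG"], 0.02)
  expect_equal(nrow(subtype_tally(recs[0, ])), 0L)
})

test_that("the intron exchange format round-trips losslessly", {
  sp <- species_spec(n_introns = 25, seed = 3)
  g <- generate_species(sp, genome = FALSE)
  prefix <- tempfile()
  write_introns(g$introns, prefix)
  back <- read_introns(prefix)
  expect_equal(back, g$introns)
  fa <- Biostrings::readDNAStringSet(paste0(prefix, ".fa"))
  expect_equal(as.character(fa), g$introns$sequence, ignore_attr = TRUE)
})

test_that("written genome + GFF3 re-extract the planted introns", {
  sp <- species_spec(n_introns = 20, seed = 77)
  g <- generate_species(sp)
  d <- file.path(tempdir(), "gff-roundtrip")
  write_species(g, d)
  ex <- read_exon_annotation(file.path(d, "annotation.gff3"))
  expect_equal(nrow(ex), nrow(g$exons))
  genome <- Biostrings::readDNAStringSet(file.path(d, "genome.fa"))
  recs <- extract_introns(genome, ex, species = sp$name)
  expect_setequal(recs$sequence, g$introns$sequence)
  unlink(d, recursive = TRUE)
})
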