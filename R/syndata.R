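# Synthetic species generator. Every downstream stage of the pipeline is
# validated against species generated here with fully known ("planted")
# signal parameters: donor/acceptor/BP weight matrices, PPT length and
# pyrimidine content, a two-component Frechet length mixture, intron and
# genome composition models, and subtype fractions.
#
# Intron architecture (5'->3'): 6 nt sampled from the donor profile's
# intronic columns | interior sampled from the intron Markov model | 7 nt
# branch-point heptamer from the BP profile | polypyrimidine tract |
# 13 nt from the acceptor profile's intronic columns. The first and last
# two intron bases are overridden by the sampled subtype's dinucleotides.

# helper: a soft consensus column distribution
#' @noRd
.soft_col <- function(major, p) {
  col <- rep((1 - sum(p)) / (4 - length(major)), 4)
  col[match(major, BASES)] <- p
  col
}

#' Default planted donor/acceptor/BP profiles
#'
#' Vertebrate-style profiles: donor consensus (C)AG|GTAAGT, pyrimidine-rich
#' acceptor ending in AG, and a CTAAC-core branch motif within a TACTAAC
#' style heptamer. `strength` scales how concentrated each informative
#' column is.
#'
#' @param strength consensus probability of the most informative columns
#'   (default 0.75).
#' @param background background distribution stored in the profile.
#' @return a [pwm_profile()].
#' @name default_profiles
NULL

#' @rdname default_profiles
#' @export
default_donor_pwm <- function(strength = 0.75, background = rep(0.25, 4)) {
  s <- strength
  f <- cbind(.soft_col("C", 0.40), .soft_col("A", 0.55), .soft_col("G", 0.75),
             .soft_col("G", 0.995), .soft_col("T", 0.995),
             .soft_col("A", s), .soft_col("A", s), .soft_col("G", s),
             .soft_col("T", 0.45))
  pwm_profile(f, background = background, offsets = c(-3:-1, 1:6),
              feature = "5ss")
}

#' @rdname default_profiles
#' @export
default_acceptor_pwm <- function(strength = 0.84, background = rep(0.25, 4)) {
  # strength = C+T fraction of the pyrimidine-rich columns (-13..-5)
  py <- .soft_col(c("C", "T"), rep(strength / 2, 2))
  f <- cbind(py, py, py, py, py, py, py, py, py,          # -13..-5
             .soft_col("C", 0.55),                        # -4
             .soft_col("A", 0.20),                        # -3 (weak)
             .soft_col("A", 0.995), .soft_col("G", 0.995),# -2,-1
             .soft_col("G", 0.5))                         # +1 exonic
  pwm_profile(f, background = background, offsets = c(-13:-1, 1),
              feature = "3ss")
}

#' @rdname default_profiles
#' @export
default_bp_pwm <- function(strength = 0.9, background = rep(0.25, 4)) {
  # a strong, fungal-style conserved branch motif: the planted truth is
  # only recoverable downstream when the scan re-finds the heptamer, which
  # requires a well-conserved core
  s <- strength
  f <- cbind(.soft_col("T", 0.5), .soft_col("A", 0.4),    # upstream 2-mer
             .soft_col("C", s), .soft_col("T", s), .soft_col("A", s),
             .soft_col("A", max(s, 0.95)), .soft_col("C", s))
  pwm_profile(f, background = background, offsets = c(-2:-1, 1:5),
              feature = "BP")
}

#' Specify a synthetic species
#'
#' Collects the planted truth for one synthetic species. Defaults are
#' chosen to resemble a compact vertebrate-like genome: 98.6/1.3/0.1%
#' GT-AG/GC-AG/AT-AC subtype fractions, an 18 nt PPT at 87% pyrimidine
#' content, a short length component around 70-150 nt plus a long
#' component in the few-kilobase range, and a mildly AT-rich intron
#' interior over a 45% G+C genome.
#'
#' @param name species label.
#' @param n_introns number of introns to generate.
#' @param subtype_fractions named simplex over GT-AG, GC-AG, AT-AC.
#' @param donor_pwm,acceptor_pwm,bp_pwm planted [pwm_profile()]s (widths
#'   9, 14, 7).
#' @param ppt_length_mean,ppt_ct_fraction planted PPT geometry; the C+T
#'   fraction must exceed 0.5.
#' @param length_mixture planted [length_model()].
#' @param intron_markov,genome_markov planted [markov_model()]s.
#' @param genome_gc genomic G+C fraction (used for the default genome
#'   model).
#' @param seed integer seed owned by this species.
#' @return object of class `species_spec`.
#' @export
species_spec <- function(name = "synth",
                         n_introns = 1000L,
                         subtype_fractions = c("GT-AG" = 0.986,
                                               "GC-AG" = 0.013,
                                               "AT-AC" = 0.001),
                         donor_pwm = default_donor_pwm(),
                         acceptor_pwm = default_acceptor_pwm(),
                         bp_pwm = default_bp_pwm(),
                         ppt_length_mean = 18,
                         ppt_ct_fraction = 0.87,
                         length_mixture = length_model(
                           shape = c(3, 2), scale = c(40, 800),
                           loc = c(30, 2000), weight = 0.8),
                         intron_markov = NULL,
                         genome_markov = NULL,
                         genome_gc = 0.45,
                         seed = 1L) {
  if (n_introns < 0) stop("'n_introns' must be non-negative")
  if (abs(sum(subtype_fractions) - 1) > 1e-9)
    stop("'subtype_fractions' must sum to 1")
  if (!all(CANONICAL_SUBTYPES %in% names(subtype_fractions)))
    stop("'subtype_fractions' must be named GT-AG, GC-AG, AT-AC")
  if (any(subtype_fractions < 0)) stop("negative subtype fraction")
  if (ppt_ct_fraction <= 0.5 || ppt_ct_fraction > 1)
    stop("'ppt_ct_fraction' must lie in (0.5, 1]")
  stopifnot(inherits(donor_pwm, "pwm_profile"), donor_pwm$width == 9L,
            inherits(acceptor_pwm, "pwm_profile"), acceptor_pwm$width == 14L,
            inherits(bp_pwm, "pwm_profile"), bp_pwm$width == 7L,
            inherits(length_mixture, "length_model"))
  gc2 <- genome_gc / 2
  if (is.null(genome_markov))
    genome_markov <- iid_markov(c(0.5 - gc2, gc2, gc2, 0.5 - gc2))
  if (is.null(intron_markov)) {
    gci <- max(0.05, genome_gc - 0.10) / 2
    intron_markov <- iid_markov(c(0.5 - gci, gci, gci, 0.5 - gci))
  }
  structure(list(name = name, n_introns = as.integer(n_introns),
                 subtype_fractions = subtype_fractions[CANONICAL_SUBTYPES],
                 donor_pwm = donor_pwm, acceptor_pwm = acceptor_pwm,
                 bp_pwm = bp_pwm, ppt_length_mean = ppt_length_mean,
                 ppt_ct_fraction = ppt_ct_fraction,
                 length_mixture = length_mixture,
                 intron_markov = intron_markov,
                 genome_markov = genome_markov,
                 genome_gc = genome_gc, seed = as.integer(seed)),
            class = "species_spec")
}

# sample n rows from a pwm: integer matrix n x w
#' @noRd
.sample_pwm <- function(pwm, n) {
  w <- pwm$width
  m <- matrix(0L, n, w)
  for (j in seq_len(w))
    m[, j] <- sample.int(4L, n, replace = TRUE, prob = pwm$freqs[, j])
  m
}

#' Generate a synthetic species
#'
#' Draws `spec$n_introns` introns with the planted signal architecture and
#' (optionally) embeds them in two-exon genes on a single contig, separated
#' by intergenic spacers, so that candidate-enumeration windows never cross
#' gene boundaries. All randomness is governed by `seed`; identical seeds
#' yield byte-identical output.
#'
#' @param spec a [species_spec()].
#' @param genome if `TRUE` (default) build the genome sequence and exon
#'   annotation; if `FALSE` emit intron records (with generated flanks)
#'   only, which is considerably faster for large simulations.
#' @param flank exonic/intergenic flank length stored in the records
#'   (default 50; recognition analyses need >= 103).
#' @param exon_length exon length used in genome mode (default 150).
#' @param intergenic intergenic spacer length in genome mode (default 200).
#' @param max_intron_length draws above this are resampled, keeping genome
#'   sizes finite despite the heavy Frechet tail (default 50000).
#' @param seed overrides `spec$seed`.
#' @return list with elements `spec`, `introns` (record data frame),
#'   `genome` (`DNAStringSet` or `NULL`), `exons` (annotation data frame or
#'   `NULL`).
#' @export
generate_species <- function(spec, genome = TRUE, flank = 50L,
                             exon_length = 150L, intergenic = 200L,
                             max_intron_length = 50000L, seed = NULL) {
  stopifnot(inherits(spec, "species_spec"))
  set.seed(seed %||% spec$seed)
  n <- spec$n_introns
  flank <- max(flank, 4L)
  if (genome) flank <- min(flank, exon_length)

  if (n == 0L) {
    recs <- new_intron_records(character(0), character(0), integer(0),
                               integer(0), character(0), character(0),
                               character(0), character(0))
    gen <- NULL; exdf <- NULL
    if (genome) {
      gen <- Biostrings::DNAStringSet(
        markov_sample(spec$genome_markov, intergenic))
      names(gen) <- "chr1"
      exdf <- data.frame(transcript_id = character(0), contig = character(0),
                         start = integer(0), end = integer(0),
                         strand = character(0))
    }
    return(list(spec = spec, introns = recs, genome = gen, exons = exdf))
  }

  subtype <- sample(CANONICAL_SUBTYPES, n, replace = TRUE,
                    prob = spec$subtype_fractions)

  # intron lengths from the planted mixture, truncated by resampling
  lm <- spec$length_mixture
  draw_len <- function(k) {
    if (is.null(lm$shape)) {
      # non-parametric planted table (e.g. a uniform control)
      lens <- as.integer(names(lm$density))
      return(sample(lens, k, replace = TRUE, prob = lm$density))
    }
    comp <- stats::runif(k) < lm$weight
    l <- numeric(k)
    l[comp] <- rfrechet(sum(comp), lm$shape[1], lm$scale[1], lm$loc[1])
    l[!comp] <- rfrechet(sum(!comp), lm$shape[2], lm$scale[2], lm$loc[2])
    round(l)
  }
  len <- draw_len(n)
  for (it in 1:100) {
    bad <- len < 31 | len > max_intron_length
    if (!any(bad)) break
    len[bad] <- draw_len(sum(bad))
  }
  len <- as.integer(pmin(pmax(len, 31L), max_intron_length))

  # signal regions
  donor <- .sample_pwm(spec$donor_pwm, n)      # cols 1:3 exonic, 4:9 intronic
  accep <- .sample_pwm(spec$acceptor_pwm, n)   # cols 1:13 intronic, 14 exonic
  bp7 <- .sample_pwm(spec$bp_pwm, n)
  dints <- list("GT-AG" = c(3L, 4L), "GC-AG" = c(3L, 2L), "AT-AC" = c(1L, 4L))
  aints <- list("GT-AG" = c(1L, 3L), "GC-AG" = c(1L, 3L), "AT-AC" = c(1L, 2L))
  for (st in CANONICAL_SUBTYPES) {
    rows <- subtype == st
    donor[rows, 4L] <- dints[[st]][1L]; donor[rows, 5L] <- dints[[st]][2L]
    accep[rows, 12L] <- aints[[st]][1L]; accep[rows, 13L] <- aints[[st]][2L]
  }

  # PPT: length fits within len - 26 (6 donor + 7 BP + 13 acceptor nt)
  avail <- len - 26L
  ppt_len <- as.integer(pmax(pmin(
    round(stats::rnorm(n, spec$ppt_length_mean, spec$ppt_length_mean / 4)),
    avail), 2L))
  interior_len <- avail - ppt_len
  pyr <- stats::runif(sum(ppt_len)) < spec$ppt_ct_fraction
  ppt_base <- integer(sum(ppt_len))
  ppt_base[pyr] <- sample(c(2L, 4L), sum(pyr), replace = TRUE)
  ppt_base[!pyr] <- sample(c(1L, 3L), sum(!pyr), replace = TRUE)
  ppt_seq <- vapply(split(ppt_base, rep(seq_len(n), ppt_len)),
                    int_to_seq, character(1))
  names(ppt_seq) <- NULL

  interior <- markov_sample(spec$intron_markov, interior_len)

  donor_in <- apply(donor[, 4:9, drop = FALSE], 1L, int_to_seq)
  accep_in <- apply(accep[, 1:13, drop = FALSE], 1L, int_to_seq)
  bp_seq <- apply(bp7, 1L, int_to_seq)
  intron_seq <- paste0(donor_in, interior, bp_seq, ppt_seq, accep_in)

  donor_ex <- apply(donor[, 1:3, drop = FALSE], 1L, int_to_seq)
  accep_ex <- int_to_seq(accep[, 14L])
  accep_ex <- substring(accep_ex, seq_len(n), seq_len(n))

  if (!genome) {
    up <- paste0(markov_sample(spec$genome_markov, rep(flank - 3L, n)),
                 donor_ex)
    dn <- paste0(accep_ex,
                 markov_sample(spec$genome_markov, rep(flank - 1L, n)))
    start <- cumsum(c(0L, utils::head(len, -1L)))
    recs <- new_intron_records(spec$name, "synthetic", start, start + len,
                               "+", intron_seq, up, dn)
    return(list(spec = spec, introns = recs, genome = NULL, exons = NULL))
  }

  # genome mode: [intergenic] exon1 intron exon2 ... trailing intergenic
  exon1_body <- markov_sample(spec$genome_markov, rep(exon_length - 3L, n))
  exon2_body <- markov_sample(spec$genome_markov, rep(exon_length - 1L, n))
  exon1 <- paste0(exon1_body, donor_ex)
  exon2 <- paste0(accep_ex, exon2_body)
  spacers <- markov_sample(spec$genome_markov, rep(intergenic, n + 1L))
  gene_plus <- paste0(exon1, intron_seq, exon2)
  strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
  gene_out <- ifelse(strand == "+", gene_plus, revcomp(gene_plus))

  gene_len <- nchar(gene_plus)
  gstart <- cumsum(c(1L, utils::head(gene_len, -1L) + intergenic)) + intergenic
  contig_seq <- paste0(paste0(spacers[seq_len(n)], gene_out, collapse = ""),
                       spacers[n + 1L])
  gen <- Biostrings::DNAStringSet(contig_seq)
  names(gen) <- "chr1"

  # exon coordinates (1-based inclusive); for minus-strand genes the
  # transcript's first exon sits at the right end of the gene span
  e1s <- ifelse(strand == "+", gstart, gstart + gene_len - exon_length)
  e1e <- ifelse(strand == "+", gstart + exon_length - 1L,
                gstart + gene_len - 1L)
  e2s <- ifelse(strand == "+", gstart + gene_len - exon_length, gstart)
  e2e <- ifelse(strand == "+", gstart + gene_len - 1L,
                gstart + exon_length - 1L)
  tid <- sprintf("%s_t%06d", spec$name, seq_len(n))
  exdf <- data.frame(
    transcript_id = rep(tid, each = 2L),
    contig = "chr1",
    start = as.integer(as.vector(rbind(pmin(e1s, e2s), pmax(e1s, e2s)))),
    end = as.integer(as.vector(rbind(pmin(e1e, e2e), pmax(e1e, e2e)))),
    strand = rep(strand, each = 2L),
    stringsAsFactors = FALSE)

  istart0 <- ifelse(strand == "+", gstart + exon_length - 1L,
                    gstart + exon_length - 1L)  # 0-based intron start
  recs <- new_intron_records(
    species = spec$name, contig = "chr1",
    start = as.integer(istart0), end = as.integer(istart0 + len),
    strand = strand, sequence = intron_seq,
    upstream_flank = substr(exon1, exon_length - flank + 1L, exon_length),
    downstream_flank = substr(exon2, 1L, flank))
  list(spec = spec, introns = recs, genome = gen, exons = exdf)
}

#' Write a generated species to disk
#'
#' Emits `genome.fa`, `annotation.gff3` (1-based inclusive coordinates,
#' exon features grouped under mRNA parents), the intron exchange files
#' and a planted-truth sidecar directory with the spec's profiles and
#' scalar parameters as TSV.
#'
#' @param species result of [generate_species()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_species <- function(species, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(species$genome)) {
    Biostrings::writeXStringSet(species$genome, file.path(outdir, "genome.fa"))
    ex <- species$exons
    gr <- GenomicRanges::GRanges(
      seqnames = ex$contig,
      ranges = IRanges::IRanges(ex$start, ex$end),
      strand = ex$strand, type = "exon", Parent = ex$transcript_id)
    rtracklayer::export(gr, file.path(outdir, "annotation.gff3"),
                        format = "gff3")
  }
  write_introns(species$introns, file.path(outdir, "introns"))
  truth <- file.path(outdir, "truth")
  dir.create(truth, showWarnings = FALSE)
  sp <- species$spec
  write_pwm(sp$donor_pwm, file.path(truth, "donor_pwm.tsv"))
  write_pwm(sp$acceptor_pwm, file.path(truth, "acceptor_pwm.tsv"))
  write_pwm(sp$bp_pwm, file.path(truth, "bp_pwm.tsv"))
  scal <- data.frame(
    key = c("name", "n_introns", "frac_GT-AG", "frac_GC-AG", "frac_AT-AC",
            "ppt_length_mean", "ppt_ct_fraction", "genome_gc", "seed",
            "len_shape1", "len_shape2", "len_scale1", "len_scale2",
            "len_loc1", "len_loc2", "len_weight"),
    value = c(sp$name, sp$n_introns, sp$subtype_fractions,
              sp$ppt_length_mean, sp$ppt_ct_fraction, sp$genome_gc, sp$seed,
              sp$length_mixture$shape, sp$length_mixture$scale,
              sp$length_mixture$loc, sp$length_mixture$weight))
  utils::write.table(scal, file.path(truth, "parameters.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

# --- clades ----------------------------------------------------------------

# jitter a column-stochastic matrix in log space
#' @noRd
.perturb_freqs <- function(f, d) {
  if (d == 0) return(f)
  lf <- log(f + 1e-9) + matrix(stats::rnorm(length(f), 0, d), nrow(f))
  ef <- exp(lf)
  sweep(ef, 2, colSums(ef), "/")
}

#' Perturb a species spec
#'
#' Applies one evolutionary "drift step" of magnitude `d`: log-space jitter
#' of all three motif profiles and of the intron 5-mer distribution, and
#' log-normal jitter of the PPT and length-mixture parameters. `d = 0`
#' returns the spec unchanged.
#'
#' @param spec a [species_spec()].
#' @param d drift magnitude (standard deviation of the log-space jitter).
#' @return a perturbed [species_spec()].
#' @export
perturb_spec <- function(spec, d) {
  if (d == 0) return(spec)
  jit <- function(x, s) x * exp(stats::rnorm(length(x), 0, s))
  pw <- function(p) pwm_profile(.perturb_freqs(p$freqs, d), p$background,
                                p$pseudo, p$offsets, p$feature)
  lm <- spec$length_mixture
  new_lm <- length_model(shape = jit(lm$shape, 0.2 * d),
                         scale = jit(lm$scale, 0.2 * d),
                         loc = jit(lm$loc, 0.05 * d),
                         weight = stats::plogis(stats::qlogis(lm$weight) +
                                                  stats::rnorm(1, 0, 0.5 * d)))
  ct <- 0.5 + 0.5 * stats::plogis(
    stats::qlogis((spec$ppt_ct_fraction - 0.5) / 0.5 * 0.999) +
      stats::rnorm(1, 0, 0.5 * d))
  p5 <- markov_fivemer_probs(spec$intron_markov)
  p5 <- exp(log(p5) + stats::rnorm(1024, 0, d))
  species_spec(name = spec$name, n_introns = spec$n_introns,
               subtype_fractions = spec$subtype_fractions,
               donor_pwm = pw(spec$donor_pwm),
               acceptor_pwm = pw(spec$acceptor_pwm),
               bp_pwm = pw(spec$bp_pwm),
               ppt_length_mean = jit(spec$ppt_length_mean, 0.2 * d),
               ppt_ct_fraction = ct,
               length_mixture = new_lm,
               intron_markov = markov_model(p5 / sum(p5)),
               genome_markov = spec$genome_markov,
               genome_gc = spec$genome_gc, seed = spec$seed)
}

#' Generate a clade of related synthetic species
#'
#' Walks a guide topology from the root, applying [perturb_spec()] along
#' each edge with drift equal to the edge length; tips become species
#' specs named after the tip labels. Species sharing a recent ancestor
#' therefore have more similar planted profiles than distant pairs, and
#' zero-length edges propagate profiles unchanged.
#'
#' @param base_spec ancestral [species_spec()].
#' @param guide an `ape::phylo` guide topology whose edge lengths are drift
#'   magnitudes.
#' @param seed seed for the perturbation walk (per-species generation seeds
#'   are derived from it).
#' @return named list of [species_spec()] objects, one per tip, with the
#'   guide tree attached as attribute `"guide"`.
#' @export
generate_clade <- function(base_spec, guide, seed = base_spec$seed) {
  if (!inherits(guide, "phylo") || is.null(guide$edge.length))
    stop("'guide' must be a phylo object with edge lengths (drift magnitudes)")
  set.seed(seed)
  ntip <- length(guide$tip.label)
  root <- ntip + 1L
  specs_at <- vector("list", ntip + guide$Nnode)
  specs_at[[root]] <- base_spec
  # parents precede children in a preorder edge walk
  ord <- ape::reorder.phylo(guide, "cladewise")$edge
  elen <- guide$edge.length[match(paste(ord[, 1], ord[, 2]),
                                  paste(guide$edge[, 1], guide$edge[, 2]))]
  for (i in seq_len(nrow(ord))) {
    par <- ord[i, 1L]; chd <- ord[i, 2L]
    specs_at[[chd]] <- perturb_spec(specs_at[[par]], elen[i])
  }
  out <- list()
  for (t in seq_len(ntip)) {
    sp <- specs_at[[t]]
    sp$name <- guide$tip.label[t]
    sp$seed <- as.integer((seed + 7919 * t) %% .Machine$integer.max)
    out[[sp$name]] <- sp
  }
  attr(out, "guide") <- guide
  out
}
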