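# Per-species profile bundles: everything the scoring, divergence and
# recognition stages need about one species in one list.

#' Build all per-species feature profiles
#'
#' Estimates the donor/acceptor/BP weight matrices, the Frechet length
#' mixture, the intron and genome composition models and the genomic base
#' background from an intron collection plus genome (or genome-like)
#' sequence.
#'
#' @param introns intron record data frame for one species.
#' @param genome_seqs `DNAStringSet` or character vector of genomic
#'   sequence used for the background base composition and the genome
#'   Markov model. For genome-free synthetic collections the exonic flanks
#'   are a reasonable surrogate; pass `NULL` to use them.
#' @param core_bp core branch-point matrix (default [default_core_bp()]).
#' @param fit_length fit the length mixture (default TRUE; skip for very
#'   small collections).
#' @param pseudo pseudo count for motif profiles.
#' @return object of class `species_profiles`: list with `species`,
#'   `background`, `donor`, `acceptor`, `bp`, `length_model`,
#'   `markov_intron`, `markov_genome`, `n_introns`.
#' @export
build_profiles <- function(introns, genome_seqs = NULL,
                           core_bp = default_core_bp(), fit_length = TRUE,
                           pseudo = 1e-4) {
  if (!nrow(introns)) stop("empty intron collection")
  if (is.null(genome_seqs))
    genome_seqs <- c(introns$upstream_flank, introns$downstream_flank)
  bg <- base_background(genome_seqs)
  donor <- build_ss_pwm(introns, "donor", background = bg, pseudo = pseudo)
  acceptor <- build_ss_pwm(introns, "acceptor", background = bg,
                           pseudo = pseudo)
  bp <- build_bp_profile(introns, core_pwm = core_bp, background = bg,
                         pseudo = pseudo)
  lenmod <- if (fit_length) {
    fit_length_model(introns$length[introns$subtype != "other"])
  } else NULL
  mi <- fit_markov(introns$sequence[introns$subtype != "other"])
  mg <- fit_markov(genome_seqs, both_strands = TRUE)
  structure(list(species = introns$species[1], background = bg,
                 donor = donor, acceptor = acceptor, bp = bp,
                 core_bp = core_bp, length_model = lenmod,
                 markov_intron = mi, markov_genome = mg,
                 n_introns = nrow(introns)),
            class = "species_profiles")
}

#' @export
print.species_profiles <- function(x, ...) {
  cat(sprintf("species_profiles[%s]: %d introns; IC 5'ss %.2f, 3'ss %.2f, BP %.2f bits\n",
              x$species, x$n_introns, information_content(x$donor),
              information_content(x$acceptor), information_content(x$bp)))
  invisible(x)
}

#' Per-intron information score table
#'
#' Scores every intron of a collection with the five features: donor and
#' acceptor motif scores, BP motif score (0 when no BP is detected),
#' length score and composition score.
#'
#' @param introns intron record data frame.
#' @param profiles a [build_profiles()] bundle.
#' @return data frame with one row per intron: `IS_5ss`, `IS_3ss`,
#'   `IS_BP`, `IS_len`, `IS_comp`.
#' @export
score_introns <- function(introns, profiles) {
  don_seg <- paste0(substr(introns$upstream_flank,
                           nchar(introns$upstream_flank) - 2L,
                           nchar(introns$upstream_flank)),
                    substr(introns$sequence, 1L, 6L))
  acc_seg <- paste0(substr(introns$sequence, introns$length - 12L,
                           introns$length),
                    substr(introns$downstream_flank, 1L, 1L))
  is5 <- pwm_score(don_seg, profiles$donor)
  is3 <- pwm_score(acc_seg, profiles$acceptor)
  isbp <- vapply(introns$sequence, function(s) {
    bp <- scan_bp(s, profiles$core_bp)
    if (bp$present) pwm_score(bp$heptamer, profiles$bp) else 0
  }, numeric(1), USE.NAMES = FALSE)
  islen <- as.numeric(length_score(introns$length, profiles$length_model))
  iscomp <- composition_score(introns$sequence, profiles$markov_intron,
                              profiles$markov_genome)
  data.frame(IS_5ss = is5, IS_3ss = is3, IS_BP = isbp, IS_len = islen,
             IS_comp = iscomp)
}
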