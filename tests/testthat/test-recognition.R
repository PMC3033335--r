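# Candidate enumeration, recognition accuracy and the contribution
# decomposition.

test_that("candidate enumeration matches a double-loop oracle", {
  set.seed(30)
  for (i in 1:60) {
    intron <- rand_intron(33, 60, stats::runif(1, 0.3, 0.6))
    region <- paste0(rand_dna(43), intron, rand_dna(41))
    ts <- 44L; te <- 43L + nchar(intron)
    got <- enumerate_candidates(region, ts, te, length_range = c(31, 80),
                                margin = 40L)
    ora <- oracle_candidates(region, ts, te, range = c(31, 80), margin = 40)
    expect_equal(nrow(got), NROW(ora))
    if (NROW(ora)) {
      key_got <- sort(paste(got$donor, got$acceptor))
      key_ora <- sort(paste(ora[, 1], ora[, 2]))
      expect_equal(key_got, key_ora)
    }
    expect_equal(sum(got$is_true), 1L)
    expect_true(all(got$length == got$acceptor - got$donor + 1L))
  }
})

test_that("AT donors never pair with AG acceptors", {
  # region offering AT donors, AG and AC acceptors
  region <- paste0(strrep("C", 40), "AT", strrep("C", 20), "CAG",
                   strrep("C", 16), "AC", strrep("C", 40))
  cands <- enumerate_candidates(region, 41L, 83L, length_range = c(31, 60),
                                margin = 40L)
  expect_true(all(cands$subtype %in% c("AT-AC")))
  expect_false(any(substr(cands$subtype, 1, 2) == "AT" &
                     substr(cands$subtype, 4, 5) == "AG"))
})

test_that("a single-candidate region is always recognised", {
  # only one GT...AG pair in range; all feature scores identically zero
  intron <- paste0("GT", strrep("C", 36), "AG")
  region <- paste0(strrep("C", 103), intron, strrep("C", 101))
  regions <- data.frame(region = region, true_start = 104L,
                        true_end = 103L + nchar(intron))
  prof <- zero_profiles()
  expect_equal(as.numeric(recognition_accuracy(regions, prof)), 1)
})

test_that("with all-zero scores the deterministic tie-break decides", {
  set.seed(31)
  prof <- zero_profiles()
  for (i in 1:20) {
    intron <- rand_intron(35, 70, 0.5)
    region <- paste0(rand_dna(103), intron, rand_dna(101))
    regions <- data.frame(region = region, true_start = 104L,
                          true_end = 103L + nchar(intron))
    cands <- enumerate_candidates(region, 104L, 103L + nchar(intron))
    pick <- cands[order(cands$donor, cands$acceptor)[1], ]  # brute tie-break
    expect_equal(as.numeric(recognition_accuracy(regions, prof)),
                 as.numeric(pick$is_true))
  }
})

test_that("transformed accuracy follows -log2(1 - Ac) with saturation", {
  acs <- c(0, 0.25, 0.5, 0.9, 0.98, 0.999)
  expect_equal(transformed_accuracy(acs)[-6], -log2(1 - acs)[-6])
  expect_equal(transformed_accuracy(0), 0)
  expect_equal(transformed_accuracy(1), -log2(0.02))
  expect_equal(transformed_accuracy(0.999), -log2(0.02))  # capped
  # strictly increasing below the cap
  grid <- seq(0, 0.97, by = 0.01)
  expect_true(all(diff(transformed_accuracy(grid)) > 0))
})

test_that("a misleading feature yields a clipped zero contribution", {
  # one region, two candidates sharing the donor: the true (first) AG and
  # a decoy AG preceded by a strong branch motif and tract. With splice
  # signals alone the tie-break picks the true pair; adding BP prefers
  # the decoy, so the BP gain is negative and must clip to zero.
  inner <- paste0(strrep("G", 33))
  tail7 <- "TACTAAC"
  region <- paste0(strrep("C", 103),
                   "GT", inner, "AG",
                   strrep("G", 5), tail7, strrep("T", 8), "AG",
                   strrep("C", 101))
  ts <- 104L; te <- 103L + 2L + nchar(inner) + 2L
  regions <- data.frame(region = region, true_start = ts, true_end = te)
  prof <- zero_profiles()
  prof$bp <- default_bp_pwm(0.9)
  cr <- contribution_decomposition(regions, prof)
  expect_equal(unname(cr$ac[["5ss+3ss"]]), 1)
  expect_lt(cr$ac[["5ss+3ss+BP"]], 1)
  expect_equal(unname(cr$contributions[["BP"]]), 0)
  expect_equal(sum(cr$shares), 1, tolerance = 1e-9)
  expect_gte(cr$deficit, 0)
})

test_that("recognition accuracy rises with planted signal sharpness", {
  mk <- function(strength, seed) {
    sp <- species_spec(n_introns = 700, seed = seed,
                       donor_pwm = default_donor_pwm(strength),
                       acceptor_pwm = default_acceptor_pwm(
                         0.6 + 0.35 * (strength > 0.8)),
                       length_mixture = length_model(shape = c(4, 3),
                                                     scale = c(50, 120),
                                                     loc = c(35, 80),
                                                     weight = 0.7,
                                                     L_max = 260))
    g <- generate_species(sp, genome = FALSE, flank = 120)
    prof <- suppressWarnings(build_profiles(g$introns))
    keep <- g$introns$length <= 250
    reg <- recognition_regions(g$introns[keep, ][seq_len(400), ])
    as.numeric(recognition_accuracy(reg, prof))
  }
  expect_gt(mk(0.95, 51), mk(0.5, 51))
})

test_that("decomposition bookkeeping is internally consistent", {
  sp <- species_spec(n_introns = 700, seed = 61,
                     length_mixture = length_model(shape = c(4, 3),
                                                   scale = c(50, 120),
                                                   loc = c(35, 80),
                                                   weight = 0.7, L_max = 260))
  g <- generate_species(sp, genome = FALSE, flank = 120)
  prof <- suppressWarnings(build_profiles(g$introns))
  reg <- recognition_regions(g$introns[g$introns$length <= 250, ][1:300, ])
  cr <- contribution_decomposition(reg, prof)
  expect_equal(length(cr$ac), 8L)
  expect_equal(cr$tac, transformed_accuracy(cr$ac), tolerance = 1e-12)
  expect_true(all(cr$contributions >= 0))
  expect_equal(cr$necessary_amount, -log2(0.02), tolerance = 1e-12)
  expect_equal(cr$deficit, max(0, cr$necessary_amount - max(cr$tac)),
               tolerance = 1e-12)
  expect_equal(sum(cr$shares), 1, tolerance = 1e-9)
  # the 5'ss/3'ss split preserves the baseline TAc
  expect_equal(unname(cr$contributions[["5ss"]] + cr$contributions[["3ss"]]),
               unname(cr$tac[["5ss+3ss"]]), tolerance = 1e-12)
})
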