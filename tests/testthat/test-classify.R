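# U12-type intron calls, subtype-stratified profiling, and clustering of
# contribution patterns.

u12_refs <- function() {
  # sharp references around the canonical U12 donor and branch consensus
  onehot <- function(cons, off) {
    f <- vapply(strsplit(cons, "")[[1]], function(b) {
      col <- rep(0.01, 4); col[match(b, BASES4)] <- 0.97; col
    }, numeric(4))
    pwm_profile(f, offsets = off)
  }
  list(donor = onehot("CAGATATCC", c(-3:-1, 1:6)),
       bp = onehot("CCTTAAC", c(-2:-1, 1:5)))
}

test_that("U12 criteria use strict thresholds and all three must hold", {
  refs <- u12_refs()
  good <- paste0("ATATCC", strrep("G", 60), "CCTTAAC", strrep("T", 10),
                 strrep("G", 20), "AC")
  recs <- make_records(sequence = c(good, good),
                       upstream = rep(paste0(rand_dna(47), "CAG"), 2))
  recs$length[2] <- 25000L   # pretend a long intron (criterion iii)
  out <- classify_u12(recs, refs$donor, refs$bp)
  expect_true(out$calls$is_u12[1])
  expect_false(out$calls$is_u12[2])
  expect_true(out$calls$crit_5ss[2])   # only the length criterion fails
  expect_false(out$calls$crit_len[2])
  # boundary semantics: a score exactly at the threshold is rejected
  s5 <- out$calls$fivess_score[1]
  out2 <- classify_u12(recs[1, ], refs$donor, refs$bp, donor_threshold = s5)
  expect_false(out2$calls$is_u12[1])
  expect_false(out2$calls$crit_5ss[1])
})

test_that("sharpening the donor toward the consensus never loses a call", {
  refs <- u12_refs()
  set.seed(41)
  cons <- "ATATCC"
  for (i in 1:30) {
    # random donor region, then step it toward the consensus
    don <- rand_dna(6)
    s <- paste0(don, strrep("G", 50), "CCTTAAC", strrep("T", 10), "AC")
    recs <- make_records(sequence = s,
                         upstream = paste0(rand_dna(47), "CAG"))
    prev <- classify_u12(recs, refs$donor, refs$bp)$calls$is_u12
    for (j in 1:6) {
      substr(don, j, j) <- substr(cons, j, j)
      s <- paste0(don, strrep("G", 50), "CCTTAAC", strrep("T", 10), "AC")
      recs <- make_records(sequence = s,
                           upstream = paste0(rand_dna(47), "CAG"))
      cur <- classify_u12(recs, refs$donor, refs$bp)$calls$is_u12
      expect_gte(cur, prev)   # TRUE never reverts to FALSE
      prev <- cur
    }
    expect_true(prev)  # full consensus always called
  }
})

test_that("planted U12-like introns are called; GT-AG controls are not", {
  refs <- u12_refs()
  set.seed(42)
  onehot_sp <- function(cons, off) {
    f <- vapply(strsplit(cons, "")[[1]], function(b) {
      col <- rep(0.01, 4); col[match(b, BASES4)] <- 0.97; col
    }, numeric(4))
    pwm_profile(f, offsets = off)
  }
  sp_u12 <- species_spec(
    n_introns = 400, seed = 43,
    subtype_fractions = c("GT-AG" = 0, "GC-AG" = 0, "AT-AC" = 1),
    donor_pwm = onehot_sp("CAGATATCC", c(-3:-1, 1:6)),
    bp_pwm = onehot_sp("CCTTAAC", c(-2:-1, 1:5)),
    length_mixture = length_model(shape = c(4, 4), scale = c(30, 60),
                                  loc = c(60, 80), weight = 0.5))
  g12 <- generate_species(sp_u12, genome = FALSE)
  out12 <- classify_u12(g12$introns, refs$donor, refs$bp)
  expect_gt(mean(out12$calls$is_u12), 0.95)
  # ordinary GT-AG introns from the default donor profile: no false calls
  gt <- generate_species(species_spec(n_introns = 400, seed = 44),
                         genome = FALSE)
  outgt <- classify_u12(gt$introns, refs$donor, refs$bp)
  expect_equal(sum(outgt$calls$is_u12), 0L)
  expect_equal(sum(out12$tally$Freq), 400)
})

test_that("subtype strata need more than the minimum count", {
  set.seed(45)
  mix <- function(n_gt, n_gc, seed) {
    a <- generate_species(species_spec(
      n_introns = n_gt, seed = seed,
      subtype_fractions = c("GT-AG" = 1, "GC-AG" = 0, "AT-AC" = 0)),
      genome = FALSE)$introns
    b <- generate_species(species_spec(
      n_introns = n_gc, seed = seed + 1,
      subtype_fractions = c("GT-AG" = 0, "GC-AG" = 1, "AT-AC" = 0)),
      genome = FALSE)$introns
    rbind(a, b)
  }
  sets <- list(spA = mix(150, 50, 100), spB = mix(150, 140, 200))
  res <- suppressWarnings(
    subtype_stratified_profiles(sets, min_n = 100))
  expect_setequal(names(res$profiles),
                  c("spA.GT-AG", "spB.GT-AG", "spB.GC-AG"))
  expect_true(all(c("5ss", "3ss", "BP", "composition") %in%
                    names(res$distances)))
})

test_that("shared subtype profiles cluster strata by subtype, not species", {
  set.seed(46)
  don_gt_A <- default_donor_pwm(0.9)
  don_gt_B <- perturb_spec(species_spec(donor_pwm = don_gt_A, seed = 1),
                           0.25)$donor_pwm
  don_gc <- perturb_spec(species_spec(seed = 2), 2.5)$donor_pwm
  don_gc_B <- perturb_spec(species_spec(donor_pwm = don_gc, seed = 3),
                           0.25)$donor_pwm
  gen <- function(don, frac, seed) {
    generate_species(species_spec(n_introns = 400, seed = seed,
                                  donor_pwm = don,
                                  subtype_fractions = frac),
                     genome = FALSE)$introns
  }
  only <- function(st) stats::setNames(as.numeric(CANONICAL_SUBTYPES == st),
                                       CANONICAL_SUBTYPES)
  sets <- list(
    spA = rbind(gen(don_gt_A, only("GT-AG"), 11),
                gen(don_gc, only("GC-AG"), 12)),
    spB = rbind(gen(don_gt_B, only("GT-AG"), 13),
                gen(don_gc_B, only("GC-AG"), 14)))
  res <- suppressWarnings(subtype_stratified_profiles(sets, min_n = 100))
  tr <- res$trees[["5ss"]]
  expect_true(ape::is.monophyletic(tr, c("spA.GT-AG", "spB.GT-AG")))
  expect_true(ape::is.monophyletic(tr, c("spA.GC-AG", "spB.GC-AG")))
})

test_that("contribution clustering recovers planted archetypes exactly", {
  set.seed(47)
  arch <- matrix(stats::runif(36, 0, 2), 6)   # six archetype rows
  arch <- arch * 3
  X <- arch[rep(1:6, each = 5), ] + matrix(stats::rnorm(180, 0, 0.02), 30)
  rownames(X) <- paste0("s", 1:30)
  colnames(X) <- c("5ss", "3ss", "BP", "length", "composition", "deficit")
  out <- cluster_contributions(X, k = 6, seed = 1)
  planted <- rep(1:6, each = 5)
  # perfect agreement: each planted group maps to exactly one cluster
  tab <- table(planted, out$cluster)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  # determinism under a fixed seed
  out2 <- cluster_contributions(X, k = 6, seed = 1)
  expect_identical(out$cluster, out2$cluster)
  # invariance to column order
  out3 <- cluster_contributions(X[, c(3, 1, 2, 6, 5, 4)], k = 6, seed = 1)
  tab3 <- table(out$cluster, out3$cluster)
  expect_true(all(rowSums(tab3 > 0) == 1))
  # k = 1 puts everything together; k > n errors
  expect_true(all(cluster_contributions(X, k = 1, seed = 1)$cluster == 1))
  expect_error(cluster_contributions(X[1:4, ], k = 6), "clusters")
})
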