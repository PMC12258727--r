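test_that("hand-checked windows match the motif grammar", {
  # positions 1,2,5,9 apolar (A); 6-8 = K,E,K is "+ - +"
  ch <- detect_motifs("AAEKAKEKAEK")
  expect_equal(ch$starts, 1L)
  expect_equal(ch$n_motifs, 1L)

  # "+ Q +" middle arrangement also matches
  expect_equal(detect_motifs("AAEKAKQKAEK")$n_motifs, 1L)

  # glycine is not apolar under the default rule
  expect_equal(detect_motifs(strrep("G", 33))$n_motifs, 0L)

  # histidine is not a charged residue under the default rule
  expect_equal(detect_motifs("AAEKAHEKAEK")$n_motifs, 0L)

  # figure6 preset tolerates one deviation at motif position 1 only
  f6 <- motif_rule_preset("figure6")
  expect_equal(detect_motifs("GAEKAKEKAEK", f6)$n_motifs, 1L)   # pos 1 off
  expect_equal(detect_motifs("GAEKAKEKAEK")$n_motifs, 0L)       # strict
  expect_equal(detect_motifs("AGEKAKEKAEK", f6)$n_motifs, 0L)   # pos 2 off

  # short sequence: empty chain with a warning
  expect_warning(ch0 <- detect_motifs("AAEK"), "shorter")
  expect_equal(ch0$n_motifs, 0L)
})

test_that("detector equals brute-force grammar scan plus greedy selection", {
  set.seed(61)
  # enriched alphabet so motifs actually occur by chance
  alph <- c(AA20, rep(c("A", "K", "E", "Q", "T"), 4))
  for (i in 1:300) {
    s <- random_aa(sample(11:200, 1), alphabet = alph)
    expect_identical(detect_motifs(s)$starts, oracle_detect(s))
  }
  # and under the figure6 preset
  f6 <- motif_rule_preset("figure6")
  for (i in 1:100) {
    s <- random_aa(sample(11:150, 1), alphabet = alph)
    expect_identical(detect_motifs(s, f6)$starts,
                     oracle_detect(s, allow = 1L, allow_at = 1L))
  }
})

test_that("motif positions shift exactly with prepended flanks", {
  set.seed(67)
  pg <- gen_motif_proteome(5, 5, 3, 0, seed = 71)
  for (i in 1:5) {
    s <- pg$proteins$sequence[i]
    base <- detect_motifs(s)$starts
    k <- sample(1:20, 1)
    shifted <- detect_motifs(paste0(strrep("G", k), s))$starts
    expect_equal(shifted, base + k)
  }
})

test_that("planted six-consecutive and insertion-split architectures are called", {
  # architecture of the fully regular ortholog: six consecutive motifs
  pg6 <- gen_motif_proteome(3, 3, 6, 0, seed = 81)
  arch6 <- detect_motifs_all(pg6$proteins)
  expect_true(all(arch6$n_motifs == 6))
  expect_true(all(arch6$max_run == 6))

  # disrupted ortholog: four motifs, one 15-residue inter-motif insertion
  pg4 <- gen_motif_proteome(3, 3, 4, 15, seed = 82)
  arch4 <- detect_motifs_all(pg4$proteins)
  expect_true(all(arch4$n_motifs == 4))
  for (g in arch4$gaps) {
    expect_equal(sum(g == 15), 1)
    expect_true(all(g %in% c(0L, 15L)))
  }
})

test_that("hydropathy windows average the scale as defined", {
  # poly-A with window 11: single defined score, the Ala scale value
  p <- hydropathy(strrep("A", 11))
  expect_equal(sum(!is.na(p$score)), 1)
  expect_equal(p$score[6], 1.8)

  # window 1 returns raw per-residue values
  s <- "ARNDC"
  p1 <- hydropathy(s, window = 1)
  expect_equal(p1$score, unname(hydropathy_scale("kyte_doolittle")[
    strsplit(s, "")[[1]]]))

  # windowed values bounded by raw residue values in the window
  set.seed(91)
  sc <- hydropathy_scale("kyte_doolittle")
  for (i in 1:20) {
    s <- random_aa(sample(15:60, 1))
    pr <- hydropathy(s, window = 5)
    raw <- unname(sc[strsplit(s, "")[[1]]])
    for (pos in which(!is.na(pr$score))) {
      win <- raw[(pos - 2):(pos + 2)]
      expect_gte(pr$score[pos], min(win))
      expect_lte(pr$score[pos], max(win))
    }
  }

  expect_error(hydropathy("AXA", window = 1), "absent")
  expect_equal(hydropathy("AXA", window = 1, on_missing = "skip")$score[2],
               NaN)
  expect_error(hydropathy("AAA", window = 2), "odd")
})

test_that("position-class statistics recover periodic structure", {
  # constant profile: every class mean is the constant
  prof <- tibble::tibble(position = 1:66, score = 2.5)
  class(prof) <- c("hydropathy_profile", class(prof))
  st <- position_class_stats(prof, c(1, 66), frame_start = 1,
                             positions = 1:11)
  expect_true(all(st$mean_score == 2.5))

  # period-11 sawtooth recovered exactly
  saw <- tibble::tibble(position = 1:44, score = rep(1:11, 4))
  class(saw) <- c("hydropathy_profile", class(saw))
  st2 <- position_class_stats(saw, c(1, 44), frame_start = 1,
                              positions = 1:11)
  expect_equal(st2$mean_score, as.numeric(1:11))

  # frame offset moves the classes
  st3 <- position_class_stats(saw, c(12, 44), frame_start = 12,
                              positions = 1)
  expect_equal(st3$mean_score, 1)

  # region shorter than 11: some classes undefined, no crash
  st4 <- position_class_stats(saw, c(1, 5), frame_start = 1,
                              positions = 1:11)
  expect_equal(sum(is.na(st4$mean_score)), 6)
})

test_that("profile comparison computes paired deltas and pattern correlation", {
  mkprof <- function(score) {
    p <- tibble::tibble(position = seq_along(score), score = score)
    class(p) <- c("hydropathy_profile", class(p))
    p
  }
  ident <- tibble::tibble(pos_a = 1:20, pos_b = 1:20)
  a <- mkprof(sin(1:20))
  out <- compare_profiles(a, a, ident, c(1, 20))
  expect_equal(out$delta_hydro, 0)
  expect_equal(out$pattern_r, 1)

  b <- mkprof(-sin(1:20))
  expect_equal(compare_profiles(a, b, ident, c(1, 20))$pattern_r, -1)

  # brute-force mean/Pearson oracle on random paired vectors
  set.seed(101)
  x <- rnorm(30); y <- rnorm(30)
  out2 <- compare_profiles(mkprof(x), mkprof(y),
                           tibble::tibble(pos_a = 1:30, pos_b = 1:30),
                           c(5, 25))
  expect_equal(out2$delta_hydro, mean(x[5:25] - y[5:25]))
  expect_equal(out2$pattern_r,
               sum(scale(x[5:25]) * scale(y[5:25])) / 20)

  expect_error(compare_profiles(a, b, ident[1:2, ], c(1, 20)),
               "fewer than 3")
  expect_error(compare_profiles(mkprof(rep(1, 10)), mkprof(rnorm(10)),
                                tibble::tibble(pos_a = 1:10, pos_b = 1:10),
                                c(1, 10)),
               "zero variance")
})

test_that("global alignment matches identity, hand-traced and enumerated cases", {
  # identical sequences: identity pairing
  p <- align_pair("ACDEFGHIK", "ACDEFGHIK")
  expect_equal(p$pos_a, 1:9)
  expect_equal(p$pos_b, 1:9)

  # single deletion: pairing skips the deleted position
  p2 <- align_pair("ACDEFG", "ACEFG")
  expect_equal(p2$pos_a, c(1, 2, 4, 5, 6))
  expect_equal(p2$pos_b, c(1, 2, 3, 4, 5))

  # alignment score equals exhaustive enumeration on short sequences
  set.seed(103)
  for (i in 1:10) {
    a <- random_aa(sample(3:7, 1))
    b <- random_aa(sample(3:7, 1))
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1)
    expect_equal(Biostrings::score(aln), oracle_align_score(a, b))
  }

  # round trip through an aligned-FASTA pairing
  pr <- pairing_from_strings("AC-DE", "ACQD-")
  expect_equal(pr$pos_a, c(1, 2, 3))
  expect_equal(pr$pos_b, c(1, 2, 4))
})

test_that("hydropathy profile autoplot builds", {
  pg <- gen_motif_proteome(1, 1, 6, 0, seed = 7)
  prof <- hydropathy(pg$proteins$sequence[1])
  expect_s3_class(ggplot2::ggplot_build(autoplot(prof))$plot, "ggplot")
})
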