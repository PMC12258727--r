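test_that("exact peptide mapping equals a brute-force substring scan", {
  prot <- tibble::tibble(protein_id = c("t1", "t2"),
                         sequence = c("AAMKVA", "MKVMKV"))
  hits <- map_peptides_exact("MKV", prot)
  expect_equal(nrow(hits), 3)  # one in t1, two occurrences in t2
  expect_equal(hits$pident, rep(100, 3))
  expect_equal(hits$bitscore, rep(6, 3))
  expect_equal(hits$sstart[hits$subject == "t1"], 3L)

  expect_equal(nrow(map_peptides_exact("WWW", prot)), 0)

  # random peptides cut from a synthetic proteome always hit their source
  set.seed(19)
  proteome <- tibble::tibble(
    protein_id = sprintf("t%03d", 1:20),
    sequence = vapply(1:20, function(i) random_aa(60), character(1)))
  peps <- tibble::tibble(
    peptide_id = sprintf("pep%03d", 1:30),
    src = sample(proteome$protein_id, 30, replace = TRUE))
  peps$sequence <- vapply(peps$src, function(s) {
    full <- proteome$sequence[proteome$protein_id == s]
    st <- sample(1:(60 - 9), 1)
    substr(full, st, st + 8)
  }, character(1))
  hits <- map_peptides_exact(peps, proteome)
  found <- dplyr::distinct(hits[c("query", "subject")])
  expect_true(all(paste(peps$peptide_id, peps$src) %in%
                    paste(found$query, found$subject)))
  # hit set equals an independent substring scan
  oracle <- do.call(rbind, lapply(seq_len(nrow(peps)), function(i) {
    do.call(rbind, lapply(seq_len(nrow(proteome)), function(j) {
      st <- gregexpr(peps$sequence[i], proteome$sequence[j],
                     fixed = TRUE)[[1]]
      if (st[1] == -1) return(NULL)
      data.frame(query = peps$peptide_id[i],
                 subject = proteome$protein_id[j], sstart = as.integer(st))
    }))
  }))
  got <- as.data.frame(hits[c("query", "subject", "sstart")])
  expect_equal(got[order(got$query, got$subject, got$sstart), ],
               oracle[order(oracle$query, oracle$subject, oracle$sstart), ],
               ignore_attr = TRUE)
})

test_that("tie-break ladder decides at the documented tiers", {
  mk <- function(src, pep, tgt, bits, pid = 100) tibble::tibble(
    peptide_id = pep, source_protein = src, subject = tgt,
    pident = pid, bitscore = bits)

  # tier 1: more distinct peptides beats a larger bitscore sum
  h1 <- dplyr::bind_rows(
    mk("s", c("a", "b", "c"), "A", c(30, 30, 30)),
    mk("s", c("a", "b"), "B", c(250, 250)))
  r1 <- reassign(h1)
  expect_equal(r1$chosen_target, "A")
  expect_equal(r1$decided_at_tier, 1L)

  # tier 2: equal counts, larger bitscore sum wins
  h2 <- dplyr::bind_rows(
    mk("s", c("a", "b"), "A", c(60, 60)),
    mk("s", c("a", "b"), "B", c(55, 55)))
  r2 <- reassign(h2)
  expect_equal(r2$chosen_target, "A")
  expect_equal(r2$decided_at_tier, 2L)

  # tier 3: equal counts and sums, larger median pident wins
  h3 <- dplyr::bind_rows(
    mk("s", c("a", "b"), "A", c(60, 60), pid = 98),
    mk("s", c("a", "b"), "B", c(60, 60), pid = 95))
  r3 <- reassign(h3)
  expect_equal(r3$chosen_target, "A")
  expect_equal(r3$decided_at_tier, 3L)

  # tier 4: full tie, lexicographically smallest target
  h4 <- dplyr::bind_rows(
    mk("s", c("a", "b"), "B", c(60, 60)),
    mk("s", c("a", "b"), "A", c(60, 60)))
  r4 <- reassign(h4)
  expect_equal(r4$chosen_target, "A")
  expect_equal(r4$decided_at_tier, 4L)
})

test_that("reassignment equals the brute-force lexicographic-key oracle", {
  set.seed(37)
  for (rep in 1:5) {
    n_src <- 40
    hits <- do.call(dplyr::bind_rows, lapply(1:n_src, function(i) {
      n_tgt <- sample(1:4, 1)
      do.call(dplyr::bind_rows, lapply(1:n_tgt, function(j) {
        k <- sample(1:5, 1)
        tibble::tibble(
          peptide_id = sprintf("s%02d_p%d", i, sample(1:6, k)),
          source_protein = sprintf("s%02d", i),
          subject = sprintf("t%02d", sample(1:8, 1)),
          pident = sample(c(90, 95, 100), k, replace = TRUE),
          bitscore = sample(c(20, 40, 60), k, replace = TRUE))
      }))
    }))
    got <- reassign(hits)
    oracle <- oracle_reassign(hits)
    expect_equal(got$chosen_target,
                 oracle$chosen_target[match(got$source_protein,
                                            oracle$source_protein)])
  }
})

test_that("reassignment is invariant to hit row order and honours filters", {
  sc <- gen_peptide_scenario(25, 4, 0.5, seed = 44)
  base <- reassign(sc$hits)
  shuffled <- reassign(sc$hits[sample(nrow(sc$hits)), ])
  expect_equal(base, shuffled)

  # filtering all hits out leaves sources unassigned, not dropped
  r <- reassign(sc$hits, min_pident = 1000)
  expect_true(all(r$chosen_target == "unassigned"))
  expect_setequal(r$source_protein, unique(sc$truth$source_protein))
})

test_that("recovery degrades as decoys strengthen", {
  rec <- vapply(c(0, 0.3, 0.7, 1), function(p) {
    hits <- mean(vapply(1:20, function(seed) {
      sc <- gen_peptide_scenario(20, 4, p, seed = seed)
      ra <- reassign(sc$hits)
      mean(ra$chosen_target ==
             sc$truth$true_target[match(ra$source_protein,
                                        sc$truth$source_protein)])
    }, numeric(1)))
  }, numeric(1))
  expect_equal(rec[1], 1)
  expect_true(all(diff(rec) <= 0.05))  # non-increasing within noise
})

test_that("regenerated summaries preserve and conserve intensity", {
  m <- make_matrix(matrix(c(10, 5, 2, NA, 3, 7), nrow = 3),
                   protein_ids = c("s1", "s2", "s3"))
  re <- tibble::tibble(
    source_protein = c("s1", "s2", "s3"),
    chosen_target = c("T1", "T1", "unassigned"),
    n_distinct_peptides = c(3L, 2L, 0L), bitscore_sum = c(1, 1, 0),
    median_pident = c(100, 100, NA), decided_at_tier = c(1L, 1L, NA))
  out <- regenerate_summaries(m, re)
  expect_equal(out$assigned$s1, 15)        # 10 + 5
  expect_equal(out$assigned$s2, 3)         # NA + 3 = 3
  expect_equal(out$assigned$n_sources, 2L)
  expect_equal(out$unassigned$protein_id, "s3")

  # conservation on random inputs
  set.seed(53)
  vals <- matrix(runif(60), nrow = 10)
  vals[runif(60) < 0.2] <- NA
  m2 <- make_matrix(vals, protein_ids = sprintf("s%02d", 1:10))
  re2 <- tibble::tibble(
    source_protein = m2$protein_id,
    chosen_target = sample(c("T1", "T2", "T3", "unassigned"), 10,
                           replace = TRUE),
    n_distinct_peptides = 1L, bitscore_sum = 1, median_pident = 100,
    decided_at_tier = 1L)
  out2 <- regenerate_summaries(m2, re2)
  total <- sum(vals, na.rm = TRUE)
  got <- sum(as.matrix(out2$assigned[setdiff(names(out2$assigned),
                                             c("protein_id", "n_sources"))]),
             na.rm = TRUE) +
    sum(as.matrix(out2$unassigned[-1]), na.rm = TRUE)
  expect_equal(got, total)

  # bijective reassignment is a pure relabelling
  re3 <- tibble::tibble(
    source_protein = m2$protein_id,
    chosen_target = paste0("T_", m2$protein_id),
    n_distinct_peptides = 1L, bitscore_sum = 1, median_pident = 100,
    decided_at_tier = 1L)
  out3 <- regenerate_summaries(m2, re3)
  back <- out3$assigned[match(paste0("T_", m2$protein_id),
                              out3$assigned$protein_id), ]
  expect_equal(as.matrix(back[names(m2)[-1]]), as.matrix(m2[-1]),
               ignore_attr = TRUE)

  # a matrix row with no reassignment record is an error
  expect_error(regenerate_summaries(m2, re2[-1, ]), "without a reassignment")
})
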