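params <- scoring_params()

test_that("pairwise chain scores equal the exhaustive oracle", {
  withr::with_seed(271, {
    for (rep_i in 1:25) {
      n <- sample(2:8, 1)
      an <- random_pair_anchors(n, 400, 500, params$k)
      for (mode in c("global", "free")) {
        ch <- chain_anchors_pairwise(an, 500, params, mode)
        want <- oracle_chain_pair(an, 500, params, global = mode == "global")
        expect_equal(ch$f, want$f)
        expect_equal(ch$total, want$total)
      }
    }
  })
})

test_that("exact alignments score full matches with identity 1", {
  withr::with_seed(8, t <- rand_dna(300))
  aln <- align_to_template(t, t, mode = "global")
  expect_equal(aln$score, 300 * params$match)
  expect_equal(aln$identity, 1)
  expect_equal(aln$matches, 300)
  expect_equal(aln$strand, "+")
  # reverse-complement query maps on the minus strand with the same score
  aln_rc <- align_to_template(revcomp(t), t, mode = "global")
  expect_equal(aln_rc$score, 300)
  expect_equal(aln_rc$strand, "-")
})

test_that("pinned small alignments: one mismatch, one gap, dovetail clip", {
  withr::with_seed(9, t <- rand_dna(150))
  # one mismatch: 149 matches - 2
  q1 <- paste0(substr(t, 1, 74),
               chartr("ACGT", "TGCA", substr(t, 75, 75)), substr(t, 76, 150))
  expect_equal(align_to_template(q1, t, mode = "global")$score, 147)
  # one deleted base: 149 matches - 3
  q2 <- paste0(substr(t, 1, 74), substr(t, 76, 150))
  expect_equal(align_to_template(q2, t, mode = "global")$score, 146)
  # dovetail: a read overhanging both template ends pays nothing for the
  # overhangs and matches the full template
  withr::with_seed(10, {
    pre <- rand_dna(40)
    post <- rand_dna(40)
  })
  q3 <- paste0(pre, t, post)
  aln <- align_to_template(q3, t, mode = "free")
  expect_equal(aln$score, 150)
  expect_equal(c(aln$t_begin, aln$t_end), c(0, 150))
  expect_equal(c(aln$q_begin, aln$q_end), c(40, 190))
})

test_that("joined alignment score equals the full-matrix affine DP oracle", {
  withr::with_seed(1618, {
    for (rep_i in 1:15) {
      a <- rand_dna(sample(60:200, 1))
      b <- perturb_seq(a)
      got <- align_to_template(a, b, mode = "global")$score
      want <- max(biostrings_global_score(a, b),
                  biostrings_global_score(revcomp(a), b))
      expect_equal(got, want)
    }
  })
})

test_that("anchorless join_anchors equals the plain DP on both modes", {
  a <- "ACGTACGTAA"
  b <- "ACGTTACGTAA"
  g <- join_anchors(a, b, NULL, params, mode = "global")
  expect_equal(g$score, 10 - 3) # 10 matches, one 1-base gap
  ops <- rep.int(g$ops[, 1], g$ops[, 2])
  expect_equal(sum(ops == 4), 1)
  f <- join_anchors("TTTT", "CCCCTTTT", NULL, params, mode = "free")
  expect_equal(f$score, 4) # leading template overhang is free
})

test_that("alignment ops reconstruct the query and template spans", {
  withr::with_seed(12, t <- rand_dna(120))
  q <- perturb_seq(t)
  aln <- align_to_template(q, t, mode = "global")
  ops <- rep.int(aln$ops[, 1], aln$ops[, 2])
  expect_equal(sum(ops != 4), nchar(q))       # query-consuming ops
  expect_equal(sum(ops != 3), nchar(t))       # template-consuming ops
  expect_equal(aln$q_end - aln$q_begin, nchar(q))
  expect_equal(aln$t_end - aln$t_begin, nchar(t))
})

test_that("circular templates align rotation-invariantly", {
  withr::with_seed(13, t <- rand_dna(240))
  rot <- paste0(substr(t, 101, 240), substr(t, 1, 100))
  read <- substr(rot, 61, 200) # spans the origin of t
  lin <- align_to_template(read, t, mode = "free")
  circ <- align_to_template(read, t, mode = "free", circular = TRUE)
  expect_lt(lin$score, circ$score)
  expect_equal(circ$score, nchar(read))
  expect_lt(circ$t_begin, nchar(t))
})

test_that("unmappable queries yield the null alignment", {
  withr::with_seed(14, t <- rand_dna(100))
  aln <- align_to_template(strrep("A", 60), t)
  expect_equal(aln$score, -Inf)
  expect_equal(aln$matches, 0)
})
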