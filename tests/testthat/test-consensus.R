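# hand-built pileup scenario: template ACGTACGT, three exact reads plus one
# read carrying a SNP, a deletion, and an insertion
make_hand_pileup <- function(reads_seqs, template, mode = "global") {
  idx <- build_index(data.frame(id = "t_1", seq = template, locus = "t",
                                allele = "1", stringsAsFactors = FALSE),
                     k = 4)
  params <- scoring_params(k = 4)
  reads <- data.frame(id = paste0("r", seq_along(reads_seqs)),
                      seq = reads_seqs,
                      qual = strrep("I", nchar(reads_seqs)),
                      stringsAsFactors = FALSE)
  alns <- lapply(reads_seqs, align_to_template, template = template,
                 params = params, mode = mode)
  names(alns) <- reads$id
  assignment <- setNames(rep(1L, nrow(reads)), reads$id)
  list(piles = build_pileup(assignment, alns, reads, idx), idx = idx)
}

test_that("pileup counts, depth and breadth tally a hand example", {
  template <- "ACGTAACGGT"
  h <- make_hand_pileup(c(template, template, "ACGTACCGGT"), template)
  pile <- h$piles[["1"]]
  expect_equal(pile$n_reads, 3)
  expect_equal(pile$depth, 3)
  expect_equal(pile$breadth, 1)
  expect_equal(unname(pile$counts["A", 1]), 3)
  expect_equal(unname(pile$counts["A", 6]), 2) # read 3 has C at column 6
  expect_equal(unname(pile$counts["C", 6]), 1)
  expect_equal(sum(pile$counts), 30)
})

test_that("consensus takes the majority, ties resolve to the template base", {
  template <- "ACGTAACGGT"
  # 2 exact vs 1 SNP read: template base wins
  h <- make_hand_pileup(c(template, template, "ACGTACCGGT"), template)
  cons <- call_consensus(h$piles[["1"]], template)
  expect_equal(cons$seq, template)
  expect_true(cons$perfect)
  # 2 SNP reads vs 1 exact: the variant wins
  h2 <- make_hand_pileup(c(template, "ACGTACCGGT", "ACGTACCGGT"), template)
  cons2 <- call_consensus(h2$piles[["1"]], template)
  expect_equal(cons2$seq, "ACGTACCGGT")
  expect_false(cons2$perfect)
  # 1 vs 1 tie resolves to the template base
  h3 <- make_hand_pileup(c(template, "ACGTACCGGT"), template)
  expect_equal(call_consensus(h3$piles[["1"]], template)$seq, template)
})

test_that("gap majorities delete columns and insertions need a strict majority", {
  template <- "ACGTAAACGGTACGT"
  del_read <- "ACGTAACGGTACGT"  # one A of the run deleted
  h <- make_hand_pileup(c(del_read, del_read, template), template)
  cons <- call_consensus(h$piles[["1"]], template)
  expect_equal(cons$seq, del_read)
  ins_read <- "ACGTAAACGGTTACGT" # one T inserted
  h2 <- make_hand_pileup(c(ins_read, ins_read, template), template)
  expect_equal(call_consensus(h2$piles[["1"]], template)$seq, ins_read)
  # insertion in only 1 of 2 reads is not a strict majority
  h3 <- make_hand_pileup(c(ins_read, template), template)
  expect_equal(call_consensus(h3$piles[["1"]], template)$seq, template)
})

test_that("zero-coverage columns are omitted from the consensus", {
  template <- "ACGTAACGGTCCATGCAAGG"
  prefix_read <- substr(template, 1, 12)
  h <- make_hand_pileup(c(prefix_read, prefix_read), template, mode = "free")
  cons <- call_consensus(h$piles[["1"]], template)
  expect_equal(cons$seq, prefix_read)
  expect_false(cons$perfect)
  expect_lt(h$piles[["1"]]$breadth, 1)
})

test_that("imperfect consensus reassigns only on exact database equality", {
  withr::with_seed(31, {
    a <- rand_dna(60)
  })
  b <- paste0(substr(a, 1, 29), chartr("ACGT", "TGCA", substr(a, 30, 30)),
              substr(a, 31, 60))
  idx <- build_index(data.frame(id = c("x_1", "x_2"), seq = c(a, b),
                                locus = "x", allele = c("1", "2")), k = 16)
  cons <- structure(list(template = 1L, seq = b, perfect = FALSE),
                    class = "consensus_record")
  r <- reassign_imperfect(cons, idx)
  expect_true(r$reassigned)
  expect_equal(r$template, 2L)
  expect_false(r$ambiguous)
  # no exact match anywhere: keep the original assignment
  cons2 <- structure(list(template = 1L, seq = substr(a, 1, 59),
                          perfect = FALSE), class = "consensus_record")
  r2 <- reassign_imperfect(cons2, idx)
  expect_false(r2$reassigned)
  expect_equal(r2$template, 1L)
  # perfect consensus is a caller error
  cons3 <- structure(list(template = 1L, seq = a, perfect = TRUE),
                     class = "consensus_record")
  expect_error(reassign_imperfect(cons3, idx), "perfectly")
})

test_that("locus calls pick max depth above the identity floor", {
  stats <- data.frame(allele = c("2", "10", "3"),
                      depth = c(30, 30, 80),
                      breadth_pct = c(100, 100, 100),
                      identity_pct = c(100, 100, 90))
  call <- call_locus("adk", stats, min_identity = 95)
  # allele 3 has top depth but fails identity; 2 and 10 tie -> numeric order
  expect_equal(call$allele, "2")
  expect_true(call$tie)
  expect_equal(call$consistency, 30 / 140) # total includes the excluded allele
  # nothing passes the floor -> uncalled
  none <- call_locus("adk", transform(stats, identity_pct = 50))
  expect_true(is.na(none$allele))
  expect_true(is.na(none$consistency))
})

test_that("strict truth matching requires allele, breadth and identity", {
  mk <- function(allele, breadth, ident) {
    structure(list(locus = "adk", allele = allele, depth = 10,
                   breadth_pct = breadth, identity_pct = ident,
                   consistency = 1, tie = FALSE), class = "locus_call")
  }
  expect_true(score_against_truth(mk("5", 100, 100), "5"))
  expect_false(score_against_truth(mk("5", 100, 100), "6"))
  expect_false(score_against_truth(mk("5", 99.9, 100), "5"))
  expect_false(score_against_truth(mk("5", 100, 99.9), "5"))
  expect_false(score_against_truth(mk(NA, 0, 0), "5"))
})
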