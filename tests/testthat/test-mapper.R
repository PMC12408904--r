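make_two_locus_index <- function(seed = 5) {
  withr::with_seed(seed, {
    a1 <- rand_dna(200)
    b1 <- rand_dna(200)
  })
  a2 <- paste0(substr(a1, 1, 99), # one SNP at position 100
               chartr("ACGT", "TGCA", substr(a1, 100, 100)),
               substr(a1, 101, 200))
  build_index(data.frame(id = c("la_1", "la_2", "lb_1"),
                         seq = c(a1, a2, b1),
                         locus = c("la", "la", "lb"),
                         allele = c("1", "2", "1"),
                         stringsAsFactors = FALSE))
}

test_that("anchors from an exact read cover it with the right template set", {
  idx <- make_two_locus_index()
  read <- substr(idx$templates$seq[3], 21, 140)
  an <- extract_anchors(read, idx)
  expect_gt(nrow(an), 0)
  expect_true(all(vapply(an$set, function(s) 3L %in% s, TRUE)))
  # a perfect read collapses to few anchors spanning the whole read
  expect_equal(min(an$q_start), 0)
  expect_equal(max(an$q_start + an$length), nchar(read))
})

test_that("map_query finds the true template for exact and mutated reads", {
  idx <- make_two_locus_index()
  read <- substr(idx$templates$seq[1], 31, 170) # spans the SNP at 100
  m <- map_query(read, idx)
  expect_true(1L %in% m$template)
  expect_false(3L %in% m$template)
  # reverse-strand read maps identically (canonical seeds)
  m_rc <- map_query(revcomp(read), idx)
  expect_equal(m_rc$template, m$template)
  # random sequence maps nowhere
  withr::with_seed(99, junk <- rand_dna(150))
  expect_equal(nrow(map_query(junk, idx)), 0)
})

test_that("chain scores equal the exhaustive oracle on random anchor sets", {
  params <- scoring_params()
  withr::with_seed(314, {
    for (rep_i in 1:25) {
      n <- sample(2:8, 1)
      an <- random_query_anchors(n, 400, params)
      got <- proxitype:::chain_scores(an, 400, params)
      want <- oracle_chain_query(an, 400, params)
      expect_equal(got$f, want$f)
      expect_equal(got$total, want$total)
    }
  })
})

test_that("chain extraction respects the minimum score and uses anchors once", {
  idx <- make_two_locus_index()
  read <- substr(idx$templates$seq[1], 1, 120)
  an <- extract_anchors(read, idx)
  chains <- chain_anchors(an, nchar(read), scoring_params(k = idx$k))
  expect_gt(length(chains), 0)
  members <- unlist(lapply(chains, `[[`, "anchors"))
  expect_equal(anyDuplicated(members), 0)
  for (ch in chains) {
    expect_gte(ch$score, scoring_params(k = idx$k)$chain_min_score)
    expect_true(all(ch$set %in% 1:3))
  }
})

test_that("overlap filtering yields a query-interval antichain", {
  chains <- list(
    list(anchors = 1L, score = 50, q_span = c(0, 60), set = 2L),
    list(anchors = 2L, score = 40, q_span = c(50, 100), set = 1L), # overlaps 1st
    list(anchors = 3L, score = 30, q_span = c(70, 120), set = 3L)) # disjoint from 1st
  kept <- filter_overlapping_chains(chains)
  expect_equal(vapply(kept, `[[`, 0, "score"), c(50, 30))
  # ties broken by lower template id
  tie <- list(
    list(anchors = 1L, score = 50, q_span = c(0, 60), set = 5L),
    list(anchors = 2L, score = 50, q_span = c(10, 70), set = 2L))
  expect_equal(filter_overlapping_chains(tie)[[1]]$set, 2L)
})

test_that("a read spanning two fragments yields candidates from both", {
  idx <- make_two_locus_index()
  chimeric <- paste0(substr(idx$templates$seq[1], 101, 200),
                     substr(idx$templates$seq[3], 1, 100))
  m <- map_query(chimeric, idx)
  expect_true(all(c(1L, 3L) %in% m$template))
})
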