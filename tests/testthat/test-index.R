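test_that("revcomp is an involution and handles ambiguity", {
  expect_equal(revcomp("ACGT"), "ACGT")
  expect_equal(revcomp("AACGTN"), "NACGTT")
  expect_equal(revcomp(character(0)), character(0))
  withr::with_seed(1, s <- rand_dna(200))
  expect_equal(revcomp(revcomp(s)), s)
})

test_that("signature index collapses identical template sets", {
  withr::with_seed(42, {
    a <- rand_dna(60)
    b <- rand_dna(60)
  })
  refs <- data.frame(id = c("t1", "t2", "t3"), seq = c(a, a, b),
                     stringsAsFactors = FALSE)
  idx <- build_index(refs, k = 16)
  # every seed of t1 is shared with t2, so one signature covers both
  km <- substr(a, 1, 16)
  expect_equal(lookup_templates(idx, km), c(1L, 2L))
  # signatures are collapsed: far fewer signatures than distinct seeds
  expect_lt(length(idx$signature_table), length(idx$seed_keys))
  expect_true(all(vapply(idx$signature_table, function(s) !is.unsorted(s), TRUE)))
})

test_that("lookups are strand-canonical", {
  withr::with_seed(7, s <- rand_dna(80))
  idx <- build_index(data.frame(id = "t", seq = s), k = 16)
  km <- substr(s, 11, 26)
  expect_equal(lookup_templates(idx, km), 1L)
  expect_equal(lookup_templates(idx, revcomp(km)), 1L)
  expect_equal(lookup_templates(idx, strrep("A", 16)), integer(0))
  expect_error(lookup_templates(idx, "ACGT"), "length")
})

test_that("positional index returns exact occurrence positions", {
  s <- paste0("ACGTACGTACGTACGTAC", strrep("G", 10), "ACGTACGTACGTACGTAC")
  idx <- build_index(data.frame(id = "t", seq = s), k = 16)
  pidx <- build_positional_index(idx, 1L)
  km <- substr(s, 1, 16)
  pos <- template_positions(pidx, 1L, km)
  # verify against direct string search
  truth <- integer(0)
  for (i in 0:(nchar(s) - 16)) {
    if (substr(s, i + 1, i + 16) == km) truth <- c(truth, i)
  }
  expect_equal(pos, truth)
  expect_gte(length(pos), 2) # the repeat occurs twice
  expect_error(build_positional_index(idx, 5L), "unknown")
})

test_that("minimizer mode selects a seed from every k-long window", {
  withr::with_seed(11, s <- rand_dna(300))
  k <- 16L; m <- 12L
  pos <- proxitype:::seed_positions(s, k, m)
  expect_true(all(diff(pos) > 0))
  # every window of (k - m + 1) consecutive m-mer positions holds a seed
  w <- k - m + 1L
  for (st in 0:(nchar(s) - k)) {
    expect_true(any(pos >= st & pos <= st + w - 1L))
  }
  # selected seeds are the canonical lexicographic minimum of their window
  can <- proxitype:::canonical_kmers(s, m)
  for (p in pos) {
    lo <- max(0L, p - w + 1L)
    hi <- min(nchar(s) - m, p + w - 1L)
    expect_true(can[p + 1L] %in% vapply(lo:hi, function(q) {
      min(can[(max(0L, q)):(min(q + w - 1L, nchar(s) - m)) + 1L])
    }, ""))
  }
})

test_that("index save/load round-trips exactly", {
  withr::with_seed(3, s <- rand_dna(100))
  refs <- data.frame(id = c("adk_1", "adk_2"),
                     seq = c(s, paste0(substr(s, 1, 50), substr(s, 52, 100))),
                     locus = "adk", allele = c("1", "2"),
                     stringsAsFactors = FALSE)
  idx <- build_index(refs, k = 16)
  path <- withr::local_tempfile(fileext = ".rds")
  save_index(idx, path)
  back <- load_index(path)
  expect_equal(back$templates, idx$templates)
  expect_equal(back$signature_table, idx$signature_table)
  expect_equal(back$seed_keys, idx$seed_keys)
  expect_equal(back$seed_sig, idx$seed_sig)
  km <- substr(s, 1, 16)
  expect_equal(lookup_templates(back, km), lookup_templates(idx, km))
})

test_that("build_index rejects bad input and warns on short templates", {
  expect_error(build_index(data.frame(id = character(0), seq = character(0))),
               "empty")
  expect_warning(
    idx <- build_index(data.frame(id = c("ok", "tiny"),
                                  seq = c(strrep("ACGT", 10), "ACG"))),
    "shorter than k")
  expect_equal(nrow(idx$templates), 1)
})
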