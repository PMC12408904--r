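test_that("schemes are deterministic, unique, and within the SNP range", {
  s1 <- simulate_scheme(seed = 17)
  s2 <- simulate_scheme(seed = 17)
  expect_identical(s1, s2)
  s3 <- simulate_scheme(seed = 18)
  expect_false(identical(s1$records$seq, s3$records$seq))
  expect_equal(nrow(s1$records), 70)
  expect_equal(anyDuplicated(s1$records$seq), 0)
  expect_true(all(nchar(s1$records$seq) == 450))
  # distance from allele 1 matches the recorded truth and stays in range
  for (lo in unique(s1$records$locus)) {
    sub <- s1$records[s1$records$locus == lo, ]
    base <- strsplit(sub$seq[sub$allele == "1"], "")[[1]]
    for (i in seq_len(nrow(sub))) {
      d <- sum(strsplit(sub$seq[i], "")[[1]] != base)
      expect_equal(d, s1$truth$snps_from_first[s1$truth$locus == lo &
                                                 s1$truth$allele == sub$allele[i]])
    }
    expect_true(all(s1$truth$snps_from_first[s1$truth$locus == lo][-1] %in% 1:5))
  }
})

test_that("samples embed the chosen allele exactly once between flanks", {
  scheme <- simulate_scheme(seed = 19)
  smp <- simulate_sample(scheme, flank = 100, seed = 19)
  expect_equal(nrow(smp$fragments), 7)
  for (i in seq_len(nrow(smp$fragments))) {
    lo <- smp$fragments$locus[i]
    allele <- smp$truth$allele[smp$truth$locus == lo]
    aseq <- scheme$records$seq[scheme$records$locus == lo &
                                 scheme$records$allele == allele]
    frag <- smp$fragments$seq[i]
    expect_equal(nchar(frag), 650)
    hits <- gregexpr(aseq, frag, fixed = TRUE)[[1]]
    expect_equal(as.integer(hits), 101) # exactly one copy, after the flank
  }
  # a fixed profile is honored
  fixed <- simulate_sample(scheme, profile = c(adk = "3"), flank = 0, seed = 1)
  expect_equal(fixed$fragments$seq,
               scheme$records$seq[scheme$records$locus == "adk" &
                                    scheme$records$allele == "3"])
})

test_that("error-free reads are exact fragment substrings at the truth coords", {
  frag <- data.frame(id = "f", seq = strrep("ACGTTGCA", 60),
                     stringsAsFactors = FALSE)
  prof <- error_profile("custom") # all error rates zero
  sim <- simulate_reads(frag, prof, depth = 5, seed = 23)
  expect_gte(sum(nchar(sim$reads$seq)), 5 * nchar(frag$seq))
  for (i in seq_len(nrow(sim$reads))) {
    tr <- sim$truth[i, ]
    raw <- substr(frag$seq, tr$start + 1, tr$end)
    if (tr$strand == "-") raw <- revcomp(raw)
    expect_equal(sim$reads$seq[i], raw)
  }
  expect_true(all(c("+", "-") %in% sim$truth$strand))
})

test_that("paired mode emits proper /1 and /2 mates", {
  frag <- data.frame(id = "f", seq = strrep("ACGTTGCA", 80),
                     stringsAsFactors = FALSE)
  prof <- error_profile("illumina", substitution = 0)
  sim <- simulate_reads(frag, prof, depth = 3, seed = 29)
  expect_true(all(grepl("/[12]$", sim$reads$id)))
  r1 <- sim$reads[grepl("/1$", sim$reads$id), ]
  r2 <- sim$reads[grepl("/2$", sim$reads$id), ]
  expect_equal(nrow(r1), nrow(r2))
  expect_true(all(nchar(r1$seq) == 150))
  # /2 is the reverse complement of the fragment at its truth coords
  tr2 <- sim$truth[match(r2$id, sim$truth$id), ]
  expect_equal(r2$seq, revcomp(substring(frag$seq, tr2$start + 1, tr2$end)))
})

test_that("error profiles hit their target rates approximately", {
  withr::with_seed(37, s <- rand_dna(200000))
  prof <- error_profile("custom", substitution = 0.03)
  withr::with_seed(38, mutated <- proxitype:::apply_errors(s, prof))
  d <- sum(strsplit(mutated, "")[[1]] != strsplit(s, "")[[1]])
  expect_equal(d / nchar(s), 0.03, tolerance = 0.1)
  # homopolymer deletions are amplified by run length up to the cap
  hp <- strrep("A", 200000)
  prof_d <- error_profile("custom", deletion = 0.01, hp_cap = 5)
  withr::with_seed(39, contracted <- proxitype:::apply_errors(hp, prof_d))
  lost <- 1 - nchar(contracted) / nchar(hp)
  expect_equal(lost, 0.05, tolerance = 0.1) # 0.01 * cap 5
})

test_that("read simulation is reproducible and respects validation", {
  frag <- data.frame(id = "f", seq = strrep("ACGT", 200))
  a <- simulate_reads(frag, error_profile("ont-r9"), depth = 2, seed = 41)
  b <- simulate_reads(frag, error_profile("ont-r9"), depth = 2, seed = 41)
  expect_identical(a, b)
  expect_error(simulate_reads(frag, depth = 0), "depth")
  expect_error(error_profile("custom", substitution = 1.2))
  expect_error(error_profile("custom", hp_cap = 0))
})
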