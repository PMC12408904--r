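toy_scores <- list(q1 = c(`1` = 100, `2` = 100),
                   q2 = c(`1` = 100),
                   q3 = c(`1` = 95, `2` = 100))

test_that("candidate sets follow the proximity rule", {
  expect_equal(candidate_templates(c(`1` = 100, `2` = 100, `3` = 80), 1),
               c(1L, 2L))
  expect_equal(candidate_templates(c(`1` = 100, `2` = 95, `3` = 80), 0.9),
               c(1L, 2L))
  expect_equal(candidate_templates(numeric(0), 0.9), integer(0))
  # decreasing epsilon never shrinks the set
  withr::with_seed(21, {
    for (i in 1:50) {
      s <- setNames(runif(6, 0, 100), 1:6)
      wide <- candidate_templates(s, 0.8)
      narrow <- candidate_templates(s, 0.95)
      expect_true(all(narrow %in% wide))
    }
  })
})

test_that("the three-read toy accumulates C(1)=295, C(2)=200 at epsilon 0.9", {
  st <- resolve_conclave(toy_scores, conclave_params(epsilon = 0.9))
  expect_equal(unname(st$C["1"]), 295)
  expect_equal(unname(st$C["2"]), 200)
  expect_equal(unname(st$assignment), c(1L, 1L, 1L))
  # tau = 96 excludes q3's 95 on template 1
  st96 <- resolve_conclave(toy_scores, conclave_params(epsilon = 0.9, tau = 96))
  expect_equal(unname(st96$C["1"]), 200)
  expect_equal(unname(st96$C["2"]), 200)
})

test_that("epsilon 1 assigns q3 to template 2 and breaks q1's tie low", {
  st <- resolve_conclave(toy_scores, conclave_params(epsilon = 1))
  expect_equal(st$candidates$q3, 2L)
  expect_equal(unname(st$assignment["q3"]), 2L)
  expect_equal(unname(st$assignment["q1"]), 1L) # C ties at 200, lower ID wins
})

test_that("score conservation: sum of C equals sum of contributions", {
  withr::with_seed(22, {
    scores <- lapply(1:40, function(i) {
      nt <- sample(1:5, 1)
      setNames(round(runif(nt, 0, 100)), sample(1:8, nt))
    })
  })
  names(scores) <- paste0("q", seq_along(scores))
  st <- resolve_conclave(scores, conclave_params(epsilon = 0.9, tau = 10))
  contrib <- sum(vapply(seq_along(scores), function(q) {
    s <- scores[[q]]
    cand <- st$candidates[[q]]
    sum(s[as.character(cand)][s[as.character(cand)] >= 10])
  }, 0))
  expect_equal(sum(st$C), contrib)
})

test_that("assignments are invariant to query input order", {
  withr::with_seed(23, {
    scores <- lapply(1:30, function(i) setNames(runif(4, 0, 100), 1:4))
    names(scores) <- paste0("q", 1:30)
    perm <- sample(30)
  })
  a <- resolve_conclave(scores, conclave_params(epsilon = 0.9))$assignment
  b <- resolve_conclave(scores[perm], conclave_params(epsilon = 0.9))$assignment
  expect_equal(a, b[names(a)])
})

test_that("reads below tau contribute nothing and stay unassigned", {
  scores <- list(lo = c(`1` = 5), hi = c(`1` = 50))
  st <- resolve_conclave(scores, conclave_params(tau = 10))
  expect_equal(unname(st$C["1"]), 50)
  expect_true(is.na(st$assignment["lo"]))
  expect_equal(unname(st$assignment["hi"]), 1L)
})
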