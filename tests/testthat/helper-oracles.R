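# Independent oracles and scenario builders shared by the unit and acceptance
# tests. The chaining oracles enumerate every collinear anchor subset instead
# of using the package's dynamic programmes; the alignment oracle is
# Biostrings' full-matrix affine DP.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random point mutations / short indels of a sequence (for alignment pairs)
perturb_seq <- function(seq, sub = 0.05, del = 0.02, ins = 0.02) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  keep <- runif(length(chars)) >= del
  sm <- runif(length(chars)) < sub
  chars[sm] <- vapply(chars[sm], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, "")
  pieces <- ifelse(keep, chars, "")
  im <- runif(length(chars)) < ins
  pieces[im] <- paste0(pieces[im],
                       sample(c("A", "C", "G", "T"), sum(im), replace = TRUE))
  paste(pieces, collapse = "")
}

# ---- stage-1 chaining oracle -------------------------------------------------
# exhaustive maximum over all collinear subsets ending at each anchor; mirrors
# the documented feasibility rules (strictly increasing starts and ends, gap
# >= 1 - k, consecutive signature sets must share a template, empty set is a
# wildcard)
oracle_chain_query <- function(anchors, qlen, params) {
  n <- nrow(anchors)
  qs <- anchors$q_start
  qe <- anchors$q_start + anchors$length
  w <- anchors$weight
  sets <- lapply(anchors$set, as.integer)
  link_ok <- function(j, i) {
    if (qs[j] >= qs[i] || qe[j] >= qe[i]) return(FALSE)
    g <- qs[i] - qe[j]
    if (g < 1 - params$k) return(FALSE)
    if (length(sets[[i]]) && length(sets[[j]]) &&
        !length(intersect(sets[[i]], sets[[j]]))) return(FALSE)
    TRUE
  }
  f <- rep(-Inf, n)
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(idx) > 1) {
      ok <- all(vapply(seq_len(length(idx) - 1L), function(r) {
        link_ok(idx[r], idx[r + 1L])
      }, logical(1)))
      if (!ok) next
    }
    s <- chain_opening_cost(qs[idx[1]], params) + sum(w[idx])
    if (length(idx) > 1) {
      g <- qs[idx[-1]] - qe[idx[-length(idx)]]
      s <- s + sum(chain_extension_cost(g, params))
    }
    last <- idx[length(idx)]
    if (s > f[last]) f[last] <- s
  }
  list(f = f, total = f + chain_opening_cost(qlen - qe, params))
}

# ---- stage-2 chaining oracle -------------------------------------------------
# exhaustive maximum over collinear (query, template) subsets; strictly
# increasing starts in both coordinates, non-negative gaps in both
oracle_chain_pair <- function(anchors, tlen, params, global = TRUE) {
  n <- nrow(anchors)
  qs <- anchors[, 1]; ts <- anchors[, 2]; len <- anchors[, 3]
  qe <- qs + len; te <- ts + len
  link_ok <- function(j, i) {
    qs[j] < qs[i] && ts[j] < ts[i] &&
      (qs[i] - qe[j]) >= 0 && (ts[i] - te[j]) >= 0
  }
  f <- rep(-Inf, n)
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(idx) > 1) {
      ok <- all(vapply(seq_len(length(idx) - 1L), function(r) {
        link_ok(idx[r], idx[r + 1L])
      }, logical(1)))
      if (!ok) next
    }
    s <- sum(len[idx]) * params$match
    if (global) s <- s + new_chain_cost(ts[idx[1]], params)
    if (length(idx) > 1) {
      dq <- qs[idx[-1]] - qe[idx[-length(idx)]]
      dt <- ts[idx[-1]] - te[idx[-length(idx)]]
      s <- s + sum(anchor_mismatch_cost(pmin(dq, dt), params) +
                     anchor_gap_cost(dq - dt, params))
    }
    last <- idx[length(idx)]
    if (s > f[last]) f[last] <- s
  }
  list(f = f,
       total = f + if (global) new_chain_cost(tlen - te, params) else 0)
}

# random stage-1 anchor set (sorted by q_start, valid invariants)
random_query_anchors <- function(n, qlen, params, n_templates = 6L) {
  starts <- sort(sample.int(qlen - params$k, n, replace = FALSE)) - 1L
  len <- params$k + sample.int(10, n, replace = TRUE) - 1L
  len <- pmin(len, qlen - starts)
  out <- data.frame(q_start = starts, length = len,
                    weight = len * params$match, sig = seq_len(n))
  out$set <- lapply(seq_len(n), function(i) {
    if (runif(1) < 0.15) integer(0) else
      sort(sample.int(n_templates, sample.int(3, 1)))
  })
  out
}

# random stage-2 anchor matrix (sorted by q_start)
random_pair_anchors <- function(n, qlen, tlen, k) {
  qs <- sort(sample.int(qlen - k, n, replace = FALSE)) - 1L
  ts <- sort(sample.int(tlen - k, n, replace = FALSE)) - 1L
  len <- k + sample.int(8, n, replace = TRUE) - 1L
  len <- pmin(len, qlen - qs, tlen - ts)
  cbind(qs, ts, len)
}

# ---- alignment oracle --------------------------------------------------------
# full-matrix global affine DP score from Biostrings; a gap of length g costs
# -(gapOpening + g * gapExtension), matching gap_open = -3 / gap_extend = -1
# with gapOpening = 2, gapExtension = 1
biostrings_global_score <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  Biostrings::pairwiseAlignment(a, b, type = "global",
                                substitutionMatrix = mat,
                                gapOpening = 2, gapExtension = 1,
                                scoreOnly = TRUE)
}

# ---- end-to-end scenario builders -------------------------------------------

# one simulated typing replicate: scheme + sample + reads for one seed
make_replicate <- function(seed, profile, depth, flank = 100L) {
  scheme <- simulate_scheme(seed = seed)
  sample_ <- simulate_sample(scheme, flank = flank, seed = seed)
  sim <- simulate_reads(sample_$fragments, profile, depth = depth, seed = seed)
  index <- build_index(scheme$records)
  list(scheme = scheme, sample = sample_, sim = sim, index = index,
       flank = flank)
}

# fraction of quality-passing reads, whose source interval overlaps the allele
# region of their fragment by at least k bases, that were assigned to the true
# source allele
read_level_accuracy <- function(result, rep) {
  index <- rep$index
  truth <- rep$sim$truth
  state <- result$state
  assigned <- state$assignment
  tmap <- index$templates
  alen <- nchar(rep$scheme$records$seq[1])
  lo <- sub("^frag_", "", truth$fragment)
  overlap <- pmin(truth$end, rep$flank + alen) - pmax(truth$start, rep$flank)
  eligible <- truth$id %in% names(assigned) & overlap >= index$k
  tru <- truth[eligible, , drop = FALSE]
  tru_locus <- lo[eligible]
  tru_allele <- rep$sample$truth$allele[match(tru_locus,
                                              rep$sample$truth$locus)]
  got <- assigned[tru$id]
  got_locus <- tmap$locus[match(got, tmap$tid)]
  got_allele <- tmap$allele[match(got, tmap$tid)]
  mean(!is.na(got) & got_locus == tru_locus & got_allele == tru_allele)
}

# boundary-extended decoy scenario: the decoy (listed first, so ties resolve
# to it) is the true allele plus 12 upstream bases; sample flanks avoid the
# decoy-prefix alphabet so boundary reads tie between decoy and true allele
make_decoy_replicate <- function(seed, allele_len = 450L, flank = 100L) {
  withr::with_seed(seed * 100L, {
    allele <- rand_dna(allele_len)
    fl <- paste(sample(c("A", "G", "T"), flank, replace = TRUE), collapse = "")
    fr <- rand_dna(flank)
  })
  decoy <- paste0(strrep("C", 12), allele)
  db <- data.frame(id = c("purA_489", "purA_7"),
                   seq = c(decoy, allele),
                   locus = "purA", allele = c("489", "7"),
                   stringsAsFactors = FALSE)
  frag <- data.frame(id = "frag_purA", seq = paste0(fl, allele, fr),
                     stringsAsFactors = FALSE)
  sim <- simulate_reads(frag, error_profile("illumina"), depth = 20,
                        seed = seed)
  list(index = build_index(db), reads = sim$reads, true_allele = "7",
       decoy_allele = "489")
}

# deletion-biased homopolymer scenario: a 7-base A run between A-free flanks
make_homopolymer_replicate <- function(seed, flank = 200L) {
  withr::with_seed(seed * 100L, {
    fl <- paste(sample(c("C", "G", "T"), flank, replace = TRUE), collapse = "")
    fr <- paste(sample(c("C", "G", "T"), flank, replace = TRUE), collapse = "")
  })
  tmpl <- paste0(fl, strrep("A", 7), fr)
  db <- data.frame(id = "arcC_755", seq = tmpl, locus = "arcC",
                   allele = "755", stringsAsFactors = FALSE)
  prof <- error_profile("custom", deletion = 0.04, hp_cap = 4,
                        mean_length = 10000, sdlog = 0)
  frag <- data.frame(id = "frag_arcC", seq = tmpl, stringsAsFactors = FALSE)
  sim <- simulate_reads(frag, prof, depth = 10, seed = seed)
  list(index = build_index(db), reads = sim$reads, template = tmpl)
}

# longest A-run in a string (0 when absent)
longest_a_run <- function(seq) {
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  runs <- r$lengths[r$values == "A"]
  if (length(runs)) max(runs) else 0L
}
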