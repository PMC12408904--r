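# Stage-1 mapping: maximal exact matches of k-mer signatures are chained with
# a collinear DP over query coordinates; non-overlapping top chains are kept
# and their signature sets, expanded to template IDs, form the candidate set.

#' Extract signature anchors from a query
#'
#' Maximal runs of consecutive query seeds carrying the same k-mer signature
#' are merged into single anchors. Anchors are 0-based and sorted by `q_start`;
#' each carries its signature's template-ID set and weight `length * match`.
#'
#' @param query a DNA string (one read).
#' @param index a [build_index()] result.
#' @param params a [scoring_params()] object (supplies the match reward).
#' @return data.frame with columns q_start, length, weight, sig and a list
#'   column `set` of sorted template IDs; zero rows when nothing matches.
#' @export
extract_anchors <- function(query, index, params = scoring_params(k = index$k)) {
  empty <- data.frame(q_start = integer(0), length = integer(0),
                      weight = numeric(0), sig = integer(0))
  empty$set <- list()
  if (nchar(query) < index$k) return(empty)
  sd <- seeds_of(query, index$k, index$minimizer_size)
  sig <- lookup_sigs(index, sd$seed)
  hit <- !is.na(sig)
  if (!any(hit)) return(empty)
  pos <- sd$pos[hit]
  sig <- sig[hit]
  slen <- index$seed_len
  # run break: signature changes, or the next seed is farther than one
  # selection step (1 when dense, the minimizer window width otherwise)
  step <- index$k - slen + 1L
  brk <- c(TRUE, diff(sig) != 0 | diff(pos) > step)
  run <- cumsum(brk)
  first <- pos[brk]
  last <- vapply(split(pos, run), max, 0L, USE.NAMES = FALSE)
  rsig <- sig[brk]
  len <- last + slen - first
  out <- data.frame(q_start = first, length = len,
                    weight = len * params$match, sig = rsig)
  out$set <- index$signature_table[rsig]
  out[order(out$q_start, out$length), , drop = FALSE]
}

#' Chain stage-1 anchors
#'
#' Dynamic program over query coordinates: each anchor's chain score is its
#' weight plus the best of extending a previous compatible anchor (signature
#' sets must share a template) at the [chain_extension_cost()] or opening a new
#' chain at the [chain_opening_cost()]; a mirror opening term penalizes
#' unmatched trailing query, so a chain's score reflects global containment.
#' Chains scoring at least `params$chain_min_score` are returned, extracted by
#' backtracking in descending score with each anchor used at most once.
#'
#' @param anchors data.frame from [extract_anchors()].
#' @param qlen query length in bases.
#' @param params a [scoring_params()] object.
#' @return list of chains; each is a list with elements `anchors` (row indices
#'   into `anchors`), `score`, `q_span` (half-open 0-based), `set` (sorted
#'   union of member template IDs).
#' @export
chain_anchors <- function(anchors, qlen, params = scoring_params()) {
  n <- nrow(anchors)
  if (!n) return(list())
  sets <- lapply(anchors$set, as.integer)
  dp <- cpp_chain_query(as.integer(anchors$q_start), as.integer(anchors$length),
                        as.numeric(anchors$weight), sets,
                        params$k, params$match, params$mismatch,
                        params$gap_open, params$gap_extend, params$open_cap,
                        as.integer(qlen))
  used <- logical(n)
  chains <- list()
  for (i in order(dp$total, decreasing = TRUE)) {
    if (used[i] || dp$total[i] < params$chain_min_score) next
    members <- integer(0)
    j <- i
    clash <- FALSE
    while (j > 0) {
      if (used[j]) { clash <- TRUE; break }
      members <- c(j, members)
      j <- dp$prev[j]
    }
    if (clash) next
    used[members] <- TRUE
    qs <- anchors$q_start[members[1]]
    qe <- anchors$q_start[members[length(members)]] +
      anchors$length[members[length(members)]]
    chains[[length(chains) + 1L]] <- list(
      anchors = members, score = dp$total[i], f = dp$f[i],
      q_span = c(qs, qe),
      set = sort(unique(unlist(sets[members]))))
  }
  chains
}

# per-anchor DP scores f(i) without chain extraction (oracle-test hook)
chain_scores <- function(anchors, qlen, params = scoring_params()) {
  if (!nrow(anchors)) return(list(f = numeric(0), total = numeric(0)))
  dp <- cpp_chain_query(as.integer(anchors$q_start), as.integer(anchors$length),
                        as.numeric(anchors$weight),
                        lapply(anchors$set, as.integer),
                        params$k, params$match, params$mismatch,
                        params$gap_open, params$gap_extend, params$open_cap,
                        as.integer(qlen))
  list(f = dp$f, total = dp$total, prev = dp$prev)
}

#' Discard overlapping chains
#'
#' Greedy selection in descending score (ties: lower template ID, then lower
#' query start): a chain is accepted iff its query interval overlaps no
#' previously accepted chain's interval. The result is an antichain under
#' query-interval overlap.
#'
#' @param chains list of chains from [chain_anchors()].
#' @return The accepted subset, in acceptance order.
#' @export
filter_overlapping_chains <- function(chains) {
  if (!length(chains)) return(chains)
  score <- vapply(chains, `[[`, 0, "score")
  min_id <- vapply(chains, function(ch) {
    if (length(ch$set)) min(ch$set) else .Machine$integer.max
  }, 0)
  qs <- vapply(chains, function(ch) ch$q_span[1], 0)
  ord <- order(-score, min_id, qs)
  acc <- list()
  iv <- matrix(numeric(0), ncol = 2)
  for (i in ord) {
    s <- chains[[i]]$q_span
    if (nrow(iv) && any(s[1] < iv[, 2] & iv[, 1] < s[2])) next
    iv <- rbind(iv, s)
    acc[[length(acc) + 1L]] <- chains[[i]]
  }
  acc
}

#' Stage-1 candidate templates for one query
#'
#' Composition of anchor extraction, chaining, and overlap filtering; the
#' candidate set is the union of the accepted chains' template sets, each
#' candidate scored with the best accepted chain score that supports it.
#'
#' @param query a DNA string (one read).
#' @param index a [build_index()] result.
#' @param params a [scoring_params()] object.
#' @return data.frame with columns template (integer ID) and score, sorted by
#'   ascending template ID; zero rows when no chain passes the threshold.
#' @export
map_query <- function(query, index, params = scoring_params(k = index$k)) {
  anchors <- extract_anchors(query, index, params)
  chains <- filter_overlapping_chains(
    chain_anchors(anchors, nchar(query), params))
  if (!length(chains)) {
    return(data.frame(template = integer(0), score = numeric(0)))
  }
  tab <- do.call(rbind, lapply(chains, function(ch) {
    data.frame(template = ch$set, score = ch$score)
  }))
  agg <- tapply(tab$score, tab$template, max)
  data.frame(template = as.integer(names(agg)), score = as.numeric(agg),
             row.names = NULL)
}
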