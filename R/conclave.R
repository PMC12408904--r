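# ConClave resolution of multi-mapping queries: per-query candidate sets
# (optionally widened by proximity), template score accumulation, and the
# final per-query assignment to the highest-accumulating candidate.

#' Per-query candidate template set
#'
#' Templates whose score is within the proximity fraction of the query's best
#' score: `{t : f(q,t) >= epsilon * max_r f(q,r)}`. With `epsilon = 1` this is
#' the plain argmax set.
#'
#' @param scores named numeric vector of template scores f(q, t) for one query
#'   (names are template IDs).
#' @param epsilon proximity fraction in (0, 1].
#' @return Sorted integer vector of candidate template IDs (empty input gives
#'   an empty set).
#' @export
candidate_templates <- function(scores, epsilon = 1) {
  stopifnot(epsilon > 0, epsilon <= 1)
  scores <- scores[is.finite(scores)]
  if (!length(scores)) return(integer(0))
  best <- max(scores)
  cut <- if (best >= 0) epsilon * best else best / epsilon
  sort(as.integer(names(scores)[scores >= cut]))
}

#' Accumulate ConClave template scores
#'
#' Each query adds its own alignment score f(q, t) to every template in its
#' candidate set, provided that score reaches `tau`; lower-scoring proximity
#' members contribute their own, lower scores.
#'
#' @param state a `conclave_state` (see [resolve_conclave()]) with candidate
#'   sets computed.
#' @param tau minimum contributing score.
#' @return Named numeric vector C(t) over all templates seen in any candidate
#'   map (0 for templates receiving no contribution).
#' @export
conclave_scores <- function(state, tau = state$params$tau) {
  all_t <- sort(unique(unlist(lapply(state$scores, function(s) as.integer(names(s))))))
  C <- setNames(numeric(length(all_t)), all_t)
  for (q in seq_along(state$scores)) {
    s <- state$scores[[q]]
    cand <- state$candidates[[q]]
    keep <- cand[s[as.character(cand)] >= tau]
    if (length(keep)) {
      key <- as.character(keep)
      C[key] <- C[key] + s[key]
    }
  }
  C
}

#' Assign each query to its highest-accumulating candidate
#'
#' `S_q = argmax over t in the candidate set of C(t)`, ties broken by
#' ascending template ID. Queries whose candidate set is empty (all scores
#' below `tau`, or no alignment) receive NA.
#'
#' @param state a `conclave_state` with `C` computed.
#' @return Integer vector of assigned template IDs, one per query (NA for
#'   unassigned), named by query ID.
#' @export
assign_queries <- function(state) {
  out <- setNames(rep(NA_integer_, length(state$scores)), names(state$scores))
  for (q in seq_along(state$scores)) {
    cand <- state$eligible[[q]]
    if (!length(cand)) next
    cv <- state$C[as.character(cand)]
    cv[is.na(cv)] <- 0
    out[q] <- cand[which.max(cv)] # which.max takes the first (lowest ID) tie
  }
  out
}

#' Resolve multi-mapping queries with ConClave
#'
#' Three steps: per-query candidate sets via [candidate_templates()]
#' (proximity fraction `params$epsilon`), template score accumulation via
#' [conclave_scores()] (threshold `params$tau`), and per-query assignment via
#' [assign_queries()]. Queries are independent; input order does not affect
#' any assignment.
#'
#' @param scores list (one element per query, named by query ID) of named
#'   numeric vectors of template alignment scores f(q, t).
#' @param params a [conclave_params()] object.
#' @return A `conclave_state`: list with `scores`, `candidates` (per-query
#'   proximity sets), `eligible` (candidates passing `tau`, the assignment
#'   domain), `C` (template totals), `assignment` (per-query template ID or
#'   NA), `params`.
#' @export
resolve_conclave <- function(scores, params = conclave_params()) {
  candidates <- lapply(scores, candidate_templates, epsilon = params$epsilon)
  state <- structure(list(scores = scores, candidates = candidates,
                          params = params),
                     class = "conclave_state")
  state$eligible <- lapply(seq_along(scores), function(q) {
    cand <- candidates[[q]]
    cand[scores[[q]][as.character(cand)] >= params$tau]
  })
  state$C <- conclave_scores(state, params$tau)
  state$assignment <- assign_queries(state)
  state
}

#' @export
print.conclave_state <- function(x, ...) {
  cat(sprintf(
    "conclave_state: %d queries, %d templates scored, %d assigned (epsilon=%g, tau=%g)\n",
    length(x$scores), length(x$C), sum(!is.na(x$assignment)),
    x$params$epsilon, x$params$tau))
  invisible(x)
}
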