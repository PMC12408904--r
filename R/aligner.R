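# Stage-2 mapping and alignment: re-map the query against each candidate
# template with the positional index, chain (query, template) anchors with the
# pairwise DP, and join the chained anchors into a full affine-gap alignment.

# anchors of `query` (forward strand) against one template via a positional
# index; maximal exact matches, extended greedily against the sequences
pairwise_anchors <- function(query, template, pidx, template_id,
                             k = pidx$k) {
  km <- seq_kmers(query, k)
  if (!length(km)) return(matrix(integer(0), ncol = 3))
  hits <- positional_hits(pidx, km)
  sel <- hits$tid == template_id
  if (!any(sel)) return(matrix(integer(0), ncol = 3))
  merged <- cpp_merge_hits(hits$qpos[sel], hits$tpos[sel], k)
  cpp_extend_anchors(merged, query, template)
}

#' Chain pairwise anchors against one template
#'
#' Dynamic program over (query, template) coordinates: each anchor's score is
#' its weight plus the best of extending a compatible previous anchor at the
#' [anchor_mismatch_cost()] + [anchor_gap_cost()] estimate, or opening a new
#' chain at the [new_chain_cost()] over the template prefix (global mode). The
#' best chain is extracted by backtracking; in global mode its score includes
#' the new-chain estimate over the remaining template suffix.
#'
#' @param anchors integer matrix with columns q_start, t_start, length
#'   (0-based), sorted by q_start.
#' @param template_len template length in bases.
#' @param params a [scoring_params()] object.
#' @param mode "global" penalizes unmatched template ends; "free" leaves both
#'   ends unpenalized (dovetail semantics).
#' @return NULL when no anchors; else a list with `anchors` (matrix of member
#'   rows), `score`, `f` (per-anchor DP scores, for verification).
#' @export
chain_anchors_pairwise <- function(anchors, template_len,
                                   params = scoring_params(),
                                   mode = c("global", "free")) {
  mode <- match.arg(mode)
  if (!nrow(anchors)) return(NULL)
  ord <- order(anchors[, 1], anchors[, 2])
  anchors <- anchors[ord, , drop = FALSE]
  dp <- cpp_chain_pair(as.integer(anchors[, 1]), as.integer(anchors[, 2]),
                       as.integer(anchors[, 3]),
                       params$k, params$match, params$mismatch,
                       params$gap_open, params$gap_extend,
                       as.integer(template_len), mode == "global")
  end <- which.max(dp$total)
  members <- integer(0)
  j <- end
  while (j > 0) {
    members <- c(j, members)
    j <- dp$prev[j]
  }
  list(anchors = anchors[members, , drop = FALSE],
       score = dp$total[end], f = dp$f, total = dp$total)
}

#' Join a chained anchor set into a full alignment
#'
#' Anchor cores (trimmed by `trim` bases on each side, leaving at least one
#' base) are kept as forced matches; every inter-core region and the two
#' terminal regions are aligned with a global affine-gap DP (match
#' `params$match`, mismatch `params$mismatch`, gap of length n costing
#' `gap_open + (n-1) * gap_extend`). With no anchors the whole pair is aligned
#' by the DP directly.
#'
#' @param query,template DNA strings.
#' @param chain a [chain_anchors_pairwise()] result (or NULL for plain DP).
#' @param params a [scoring_params()] object.
#' @param mode "global" aligns end-to-end; "free" leaves both sequences' ends
#'   unpenalized (dovetail).
#' @param trim anchor-core trim width.
#' @return An `alignment_result`: list with score, ops (run-length matrix; op
#'   1 match, 2 mismatch, 3 insertion, 4 deletion), matches, q_begin, q_end,
#'   t_begin, t_end (0-based half-open), identity (matches / template length).
#' @export
join_anchors <- function(query, template, chain = NULL,
                         params = scoring_params(),
                         mode = c("global", "free"), trim = 8L) {
  mode <- match.arg(mode)
  anchors <- if (is.null(chain)) matrix(integer(0), ncol = 3) else chain$anchors
  r <- cpp_join(query, template, anchors,
                params$match, params$mismatch, params$gap_open,
                params$gap_extend, as.integer(trim), mode == "free")
  structure(list(score = r$score, ops = r$ops, matches = r$matches,
                 q_begin = r$q_begin, q_end = r$q_end,
                 t_begin = r$t_begin, t_end = r$t_end,
                 identity = r$matches / nchar(template)),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "alignment_result: score %g, identity %.4f, q [%d,%d), t [%d,%d)%s\n",
    x$score, x$identity, x$q_begin, x$q_end, x$t_begin, x$t_end,
    if (!is.null(x$strand)) paste0(", strand ", x$strand) else ""))
  invisible(x)
}

#' End-to-end global alignment of two sequences
#'
#' Full-matrix affine-gap DP with no anchoring; intended for short pairs
#' (consensus reassignment, tests).
#'
#' @param a,b DNA strings.
#' @param params a [scoring_params()] object.
#' @return An `alignment_result` (see [join_anchors()]).
#' @export
align_global <- function(a, b, params = scoring_params()) {
  join_anchors(a, b, NULL, params, mode = "global")
}

# null alignment: below any score threshold, empty edit path
null_alignment <- function(template) {
  structure(list(score = -Inf, ops = matrix(integer(0), ncol = 2,
                                            dimnames = list(NULL, c("op", "len"))),
                 matches = 0, q_begin = 0L, q_end = 0L,
                 t_begin = 0L, t_end = 0L, identity = 0, strand = NA_character_),
            class = "alignment_result")
}

# seed-chain-align of one oriented query against one template (internal);
# circular templates are handled by the caller via doubling
align_one_strand <- function(query, template, pidx, template_id, params,
                             mode, trim) {
  anchors <- pairwise_anchors(query, template, pidx, template_id, pidx$k)
  if (!nrow(anchors)) return(NULL)
  chain <- chain_anchors_pairwise(anchors, nchar(template), params, mode)
  join_anchors(query, template, chain, params, mode, trim)
}

#' Align a query to one template (seed-chain-align)
#'
#' Composition of positional re-indexing, maximal-exact-match extension,
#' pairwise chaining, and anchor joining. Both query orientations are tried;
#' the better-scoring one is returned with its strand. For circular templates
#' the template is doubled internally so anchors and gaps may span the origin;
#' reported template coordinates are taken modulo the template length.
#'
#' @param query a DNA string (one read).
#' @param template a DNA string, or a template ID when `index` is given.
#' @param index optional `signature_index` (resolves template IDs).
#' @param params a [scoring_params()] object.
#' @param mode "free" (dovetail, the mapping default) or "global".
#' @param circular treat the template as circular.
#' @param trim anchor-core trim width for [join_anchors()].
#' @return An `alignment_result` with a `strand` field ("+"/"-"). In "free"
#'   mode a query with no anchors on either strand yields the null alignment
#'   (score `-Inf`); in "global" mode anchorless strands fall back to the
#'   plain full-matrix DP, so a global score is always defined.
#' @export
align_to_template <- function(query, template, index = NULL,
                              params = scoring_params(),
                              mode = c("free", "global"),
                              circular = FALSE, trim = 8L) {
  mode <- match.arg(mode)
  if (!is.null(index) && is.numeric(template)) {
    template <- index$templates$seq[index$templates$tid == template]
  }
  tlen <- nchar(template)
  tseq <- if (circular) paste0(template, template) else template
  refs <- data.frame(id = "t", seq = tseq, stringsAsFactors = FALSE)
  idx <- build_index(refs, k = min(params$k, nchar(tseq)))
  pidx <- build_positional_index(idx, 1L)
  cmode <- if (circular) "free" else mode
  fwd <- align_one_strand(query, tseq, pidx, 1L, params, cmode, trim)
  rev <- align_one_strand(revcomp(query), tseq, pidx, 1L, params, cmode, trim)
  if (cmode == "global") {
    # a global alignment is always defined: strands without any anchor fall
    # back to the plain full-matrix DP
    if (is.null(fwd)) fwd <- join_anchors(query, tseq, NULL, params, cmode, trim)
    if (is.null(rev)) {
      rev <- join_anchors(revcomp(query), tseq, NULL, params, cmode, trim)
    }
  }
  best <- NULL
  strand <- NA_character_
  if (!is.null(fwd) && (is.null(rev) || fwd$score >= rev$score)) {
    best <- fwd; strand <- "+"
  } else if (!is.null(rev)) {
    best <- rev; strand <- "-"
  }
  if (is.null(best)) return(null_alignment(template))
  if (circular) {
    span <- best$t_end - best$t_begin
    best$t_begin <- best$t_begin %% tlen
    best$t_end <- best$t_begin + min(span, tlen)
    best$identity <- best$matches / tlen
  } else {
    best$identity <- best$matches / tlen
  }
  best$strand <- strand
  best
}
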