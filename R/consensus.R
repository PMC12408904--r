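# Consensus typing: per-template pileups from assigned reads, majority-vote
# consensus sequences, reassignment of imperfect consensus matches against the
# whole database, and per-locus allele calls with depth / breadth / identity /
# consistency statistics.

BASES <- c("A", "C", "G", "T", "-")

# expand one alignment's run-length ops into per-column tallies:
# returns list(tpos (0-based template column), base (query base or "-"),
# ins = data.frame(tpos = column before which the insertion sits, seq))
expand_alignment <- function(aln, oriented_query) {
  ops <- aln$ops
  if (!nrow(ops)) {
    return(list(tpos = integer(0), base = character(0),
                ins = data.frame(tpos = integer(0), seq = character(0))))
  }
  op <- rep.int(ops[, 1], ops[, 2])
  n <- length(op)
  dq <- op != 4L # ops consuming query: match, mismatch, insertion
  dt <- op != 3L # ops consuming template: match, mismatch, deletion
  qpos <- aln$q_begin + cumsum(dq) - dq # 0-based query position per op
  tpos <- aln$t_begin + cumsum(dt) - dt
  base <- rep("-", n)
  qb <- strsplit(oriented_query, "", fixed = TRUE)[[1]]
  base[dq] <- qb[qpos[dq] + 1L]
  aligned <- op != 3L
  ins <- data.frame(tpos = integer(0), seq = character(0))
  if (any(op == 3L)) {
    ii <- which(op == 3L)
    grp <- cumsum(c(TRUE, diff(ii) != 1L))
    ins <- data.frame(
      tpos = tpos[ii][!duplicated(grp)],
      seq = vapply(split(base[ii], grp), paste, "", collapse = ""),
      stringsAsFactors = FALSE)
  }
  list(tpos = tpos[aligned], base = base[aligned], ins = ins)
}

#' Build per-template pileups from assigned reads
#'
#' Each query contributes only to the template it was assigned to. Column
#' counts tally the query base (or a gap symbol for deletions) at every
#' aligned template column; insertions are tallied separately, keyed by the
#' column they precede. Depth is total aligned query bases divided by template
#' length; breadth is the fraction of columns with at least one aligned base.
#'
#' @param assignment named integer vector (query ID -> template ID, NA =
#'   unassigned), as from [resolve_conclave()].
#' @param alignments named list (by query ID) of `alignment_result`s against
#'   the assigned template, each with a `strand` field.
#' @param reads data.frame with columns id, seq (original orientation).
#' @param index a `signature_index` (template sequences and lengths).
#' @return Named list (by template ID) of `pileup` objects: counts (5 x L
#'   matrix over A/C/G/T/-), insertions (data.frame tpos, seq, count), depth,
#'   breadth, n_reads, template id.
#' @export
build_pileup <- function(assignment, alignments, reads, index) {
  assigned <- assignment[!is.na(assignment)]
  out <- list()
  for (tid in sort(unique(assigned))) {
    tlen <- index$templates$length[index$templates$tid == tid]
    ins_all <- list()
    tally_base <- list()
    tally_tpos <- list()
    qids <- names(assigned)[assigned == tid]
    for (qid in qids) {
      aln <- alignments[[qid]]
      if (is.null(aln) || !nrow(aln$ops)) next
      if (aln$t_end > tlen) {
        stop("alignment exceeds template length for template ", tid)
      }
      q <- reads$seq[match(qid, reads$id)]
      if (identical(aln$strand, "-")) q <- revcomp(q)
      ex <- expand_alignment(aln, q)
      ok <- ex$base %in% BASES
      tally_base[[length(tally_base) + 1L]] <- ex$base[ok]
      tally_tpos[[length(tally_tpos) + 1L]] <- ex$tpos[ok]
      if (nrow(ex$ins)) ins_all[[length(ins_all) + 1L]] <- ex$ins
    }
    bi <- match(unlist(tally_base, use.names = FALSE), BASES)
    tp <- unlist(tally_tpos, use.names = FALSE)
    counts <- matrix(tabulate(bi + 5L * tp, nbins = 5L * tlen),
                     nrow = 5, dimnames = list(BASES, NULL))
    ins <- if (length(ins_all)) do.call(rbind, ins_all) else
      data.frame(tpos = integer(0), seq = character(0))
    if (nrow(ins)) {
      ins <- aggregate(list(count = rep(1L, nrow(ins))),
                       by = list(tpos = ins$tpos, seq = ins$seq), FUN = sum)
    } else {
      ins$count <- integer(0)
    }
    base_cov <- colSums(counts[1:4, , drop = FALSE])
    out[[as.character(tid)]] <- structure(list(
      template = tid, counts = counts, insertions = ins,
      depth = sum(base_cov) / tlen,
      breadth = mean(base_cov > 0),
      n_reads = length(qids)), class = "pileup")
  }
  out
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("pileup: template %d, %d reads, depth %.2f, breadth %.3f\n",
              x$template, x$n_reads, x$depth, x$breadth))
  invisible(x)
}

#' Call a consensus sequence from a pileup
#'
#' Per column, the majority symbol among A/C/G/T/gap wins; ties resolve toward
#' the template base; a gap majority deletes the column; an insertion is
#' emitted between columns when one inserted sequence is observed in a strict
#' majority of the reads covering the preceding column. Columns with zero
#' coverage are omitted: the consensus reports only read-supported sequence,
#' so a partially covered template yields an imperfect (shorter) consensus.
#'
#' @param pileup a `pileup` object.
#' @param template_seq the template DNA string.
#' @return A `consensus_record`: list with template id, seq, perfect (exact
#'   equality with the template), depth, breadth.
#' @export
call_consensus <- function(pileup, template_seq) {
  counts <- pileup$counts
  tlen <- ncol(counts)
  tb <- strsplit(template_seq, "", fixed = TRUE)[[1]]
  stopifnot(length(tb) == tlen)
  cov <- colSums(counts)
  # majority with tie -> template base: add half a vote to the template base
  boost <- counts
  idx <- cbind(match(tb, BASES), seq_len(tlen))
  boost[idx] <- boost[idx] + 0.5
  win <- BASES[max.col(t(boost), ties.method = "first")]
  pieces <- ifelse(win == "-" | cov == 0, "", win)
  if (nrow(pileup$insertions)) {
    ins <- pileup$insertions
    ins <- ins[order(-ins$count, ins$seq), , drop = FALSE]
    ins <- ins[!duplicated(ins$tpos), , drop = FALSE]
    cov_before <- ifelse(ins$tpos > 0, cov[ins$tpos], cov[1])
    ins <- ins[ins$count * 2 > cov_before, , drop = FALSE]
    for (r in seq_len(nrow(ins))) {
      p <- ins$tpos[r]
      if (p == 0) {
        pieces[1] <- paste0(ins$seq[r], pieces[1])
      } else {
        pieces[p] <- paste0(pieces[p], ins$seq[r])
      }
    }
  }
  seq <- paste(pieces, collapse = "")
  structure(list(template = pileup$template, seq = seq,
                 perfect = identical(seq, template_seq),
                 depth = pileup$depth, breadth = pileup$breadth),
            class = "consensus_record")
}

#' @export
print.consensus_record <- function(x, ...) {
  cat(sprintf("consensus_record: template %d, %d bp, perfect=%s\n",
              x$template, nchar(x$seq), x$perfect))
  invisible(x)
}

#' Reassign an imperfect consensus to a perfectly matching allele
#'
#' The consensus is compared against every template in the database; if some
#' template matches it at 100% identity over its full length (which, under
#' the template-length identity definition, means exact sequence equality),
#' the lowest-ID such template is returned with `reassigned = TRUE`; otherwise
#' the original assignment is kept.
#'
#' @param consensus a `consensus_record` with `perfect = FALSE`.
#' @param index a `signature_index`.
#' @return list(template, reassigned, ambiguous).
#' @export
reassign_imperfect <- function(consensus, index) {
  if (isTRUE(consensus$perfect)) {
    stop("consensus already matches its template perfectly; nothing to reassign")
  }
  hits <- index$templates$tid[index$templates$seq == consensus$seq]
  if (!length(hits)) {
    return(list(template = consensus$template, reassigned = FALSE,
                ambiguous = FALSE))
  }
  list(template = min(hits), reassigned = TRUE, ambiguous = length(hits) > 1)
}

#' Call the allele at one locus
#'
#' The chosen allele is the one with the highest depth among alleles whose
#' identity is at least `min_identity` percent; ties break to the ascending
#' allele ID. Consistency is the chosen allele's depth divided by the total
#' depth over all alleles of the locus with nonzero depth.
#'
#' @param locus locus name.
#' @param stats data.frame with one row per allele of the locus: columns
#'   allele (ID or name), depth, breadth_pct, identity_pct.
#' @param min_identity identity floor in percent.
#' @return A `locus_call`: list with locus, allele (NA when uncalled), depth,
#'   breadth_pct, identity_pct, consistency, tie flag.
#' @export
call_locus <- function(locus, stats, min_identity = 95) {
  total_depth <- sum(stats$depth[stats$depth > 0])
  ok <- stats$identity_pct >= min_identity & stats$depth > 0
  if (!any(ok)) {
    return(structure(list(locus = locus, allele = NA, depth = 0,
                          breadth_pct = 0, identity_pct = 0,
                          consistency = NA_real_, tie = FALSE),
                     class = "locus_call"))
  }
  cand <- stats[ok, , drop = FALSE]
  key <- suppressWarnings(as.numeric(cand$allele))
  cand <- cand[if (anyNA(key)) order(cand$allele) else order(key), ,
               drop = FALSE]
  best <- which.max(cand$depth)
  tie <- sum(cand$depth == cand$depth[best]) > 1
  structure(list(locus = locus, allele = cand$allele[best],
                 depth = cand$depth[best],
                 breadth_pct = cand$breadth_pct[best],
                 identity_pct = cand$identity_pct[best],
                 consistency = cand$depth[best] / total_depth,
                 tie = tie), class = "locus_call")
}

#' Strict truth matching for a locus call
#'
#' A call matches the truth iff the chosen allele equals the true allele AND
#' the call has 100% breadth of coverage AND 100% identity.
#'
#' @param call a `locus_call`.
#' @param truth_allele the true allele ID/name.
#' @return TRUE or FALSE.
#' @export
score_against_truth <- function(call, truth_allele) {
  !is.na(call$allele) && call$allele == truth_allele &&
    isTRUE(all.equal(call$breadth_pct, 100)) &&
    isTRUE(all.equal(call$identity_pct, 100))
}
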