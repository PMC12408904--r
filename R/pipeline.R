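# End-to-end typing pipeline: quality filter -> stage-1 candidates -> stage-2
# alignment -> ConClave resolution -> pileup/consensus -> reassignment ->
# per-locus allele calls; plus evaluation against a known truth profile.

# hot-path variant of chain_anchors_pairwise: anchors already sorted by
# (q_start, t_start) as produced by cpp_extend_anchors; free (dovetail) ends
chain_pair_fast <- function(anchors, template_len, params) {
  dp <- cpp_chain_pair(anchors[, 1], anchors[, 2], anchors[, 3],
                       params$k, params$match, params$mismatch,
                       params$gap_open, params$gap_extend,
                       template_len, FALSE)
  end <- which.max(dp$total)
  members <- integer(0)
  j <- end
  while (j > 0) {
    members <- c(j, members)
    j <- dp$prev[j]
  }
  list(anchors = anchors[members, , drop = FALSE], score = dp$total[end])
}

# stage-2 scores and alignments of one read against its candidate templates;
# returns list(scores = named numeric, alns = named list of alignment_result)
score_read <- function(query, cand, pidx, index, params, trim = 8L) {
  scores <- setNames(numeric(0), character(0))
  alns <- list()
  if (!length(cand)) return(list(scores = scores, alns = alns))
  qf <- query
  qr <- revcomp(query)
  hits_f <- positional_hits(pidx, seq_kmers(qf, pidx$k))
  hits_r <- positional_hits(pidx, seq_kmers(qr, pidx$k))
  for (tid in cand) {
    tseq <- index$templates$seq[index$templates$tid == tid]
    # chain both strands (cheap), join only the better-chaining one
    chains <- list(`+` = NULL, `-` = NULL)
    for (s in c("+", "-")) {
      h <- if (s == "+") hits_f else hits_r
      q <- if (s == "+") qf else qr
      sel <- h$tid == tid
      if (!any(sel)) next
      anchors <- cpp_extend_anchors(
        cpp_merge_hits(h$qpos[sel], h$tpos[sel], pidx$k), q, tseq)
      chains[[s]] <- chain_pair_fast(anchors, nchar(tseq), params)
    }
    cs <- vapply(chains, function(ch) if (is.null(ch)) -Inf else ch$score, 0)
    if (all(!is.finite(cs))) next
    strand <- names(cs)[which.max(cs)]
    q <- if (strand == "+") qf else qr
    best <- join_anchors(q, tseq, chains[[strand]], params, "free", trim)
    best$strand <- strand
    key <- as.character(tid)
    scores[key] <- best$score
    alns[[key]] <- best
  }
  list(scores = scores, alns = alns)
}

#' Type a sample from raw reads
#'
#' Full pipeline: reads are quality-filtered, mapped to stage-1 candidates,
#' aligned to each candidate (dovetail, both strands), resolved with ConClave
#' (proximity `epsilon`, threshold `tau`), piled up on their assigned
#' templates, consensus-called, optionally reassigned when the consensus
#' perfectly matches a different allele, and summarized as one call per locus.
#'
#' @param reads data.frame with columns id, seq, qual (see [read_fastq()]).
#' @param index a [build_index()] result over the allele database.
#' @param epsilon proximity fraction in (0, 1] (see [conclave_params()]).
#' @param tau minimum alignment score for a read to count.
#' @param min_q mean-Phred quality floor for reads.
#' @param min_identity identity floor (percent) for allele calls.
#' @param params a [scoring_params()]; defaults to the index k.
#' @param reassign reassign imperfect consensus sequences.
#' @param sample sample name echoed into the report.
#' @return A `typing_result`: list with `report` (data.frame sample, locus,
#'   allele, score, depth, breadth_pct, identity_pct, consistency, reassigned),
#'   `state` (the `conclave_state`), `consensus` (per-template records),
#'   `stats` (per-template table before locus reduction), `n_reads_used`.
#' @export
run_type <- function(reads, index, epsilon = 1, tau = 0, min_q = 10,
                     min_identity = 95, params = scoring_params(k = index$k),
                     reassign = TRUE, sample = "sample") {
  filtered <- quality_filter(reads, min_q)
  if (!nrow(filtered)) {
    warning("no reads pass the quality filter")
    return(empty_typing_result(index, sample))
  }
  cands <- lapply(filtered$seq, function(q) map_query(q, index, params)$template)
  names(cands) <- filtered$id
  all_cand <- sort(unique(unlist(cands)))
  if (!length(all_cand)) {
    warning("no reads map to any template")
    return(empty_typing_result(index, sample))
  }
  pidx <- build_positional_index(index, all_cand)
  scored <- lapply(seq_len(nrow(filtered)), function(i) {
    score_read(filtered$seq[i], cands[[i]], pidx, index, params)
  })
  scores <- setNames(lapply(scored, `[[`, "scores"), filtered$id)
  state <- resolve_conclave(scores, conclave_params(epsilon, tau))
  aln_assigned <- setNames(lapply(seq_along(scored), function(i) {
    tid <- state$assignment[i]
    if (is.na(tid)) NULL else scored[[i]]$alns[[as.character(tid)]]
  }), filtered$id)
  piles <- build_pileup(state$assignment, aln_assigned, filtered, index)
  stats <- per_template_stats(piles, index, state, reassign)
  report <- locus_report(stats, index, min_identity, sample)
  structure(list(report = report, state = state,
                 consensus = attr(stats, "consensus"), stats = stats,
                 n_reads_used = nrow(filtered)),
            class = "typing_result")
}

empty_typing_result <- function(index, sample) {
  structure(list(report = data.frame(
    sample = character(0), locus = character(0), allele = character(0),
    score = numeric(0), depth = numeric(0), breadth_pct = numeric(0),
    identity_pct = numeric(0), consistency = numeric(0),
    reassigned = logical(0)), state = NULL, consensus = list(),
    stats = NULL, n_reads_used = 0L), class = "typing_result")
}

# per original template: consensus, identity, optional reassignment
per_template_stats <- function(piles, index, state, reassign) {
  rows <- list()
  consensus <- list()
  for (key in names(piles)) {
    pile <- piles[[key]]
    tid <- pile$template
    trow <- index$templates[index$templates$tid == tid, ]
    cons <- call_consensus(pile, trow$seq)
    consensus[[key]] <- cons
    if (cons$perfect) {
      identity_pct <- 100
    } else if (!nchar(cons$seq)) {
      identity_pct <- 0
    } else {
      identity_pct <- 100 * align_global(cons$seq, trow$seq)$matches /
        trow$length
    }
    final_tid <- tid
    was_reassigned <- FALSE
    if (!cons$perfect && reassign) {
      r <- reassign_imperfect(cons, index)
      if (r$reassigned) {
        final_tid <- r$template
        was_reassigned <- TRUE
        # the consensus equals the new template exactly, and every consensus
        # base is read-supported, so identity and breadth are complete
        identity_pct <- 100
      }
    }
    frow <- index$templates[index$templates$tid == final_tid, ]
    rows[[key]] <- data.frame(
      template = final_tid, original_template = tid,
      locus = frow$locus, allele = frow$allele,
      score = unname(state$C[as.character(tid)]),
      depth = pile$depth * trow$length / frow$length,
      breadth_pct = if (was_reassigned) 100 else 100 * pile$breadth,
      identity_pct = identity_pct, reassigned = was_reassigned,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "consensus") <- consensus
  out
}

# reduce per-template stats to one call per locus
locus_report <- function(stats, index, min_identity, sample) {
  loci <- sort(unique(index$templates$locus))
  loci <- loci[!is.na(loci)]
  rows <- lapply(loci, function(lo) {
    st <- stats[!is.na(stats$locus) & stats$locus == lo, , drop = FALSE]
    if (nrow(st)) {
      # merge rows that reassigned onto the same allele
      agg <- lapply(split(st, st$allele), function(g) {
        g <- g[order(-g$identity_pct, -g$depth), , drop = FALSE]
        out <- g[1, , drop = FALSE]
        out$depth <- sum(g$depth)
        out
      })
      st <- do.call(rbind, c(agg, make.row.names = FALSE))
    }
    call <- call_locus(lo, st, min_identity)
    reass <- if (!is.na(call$allele)) {
      any(st$reassigned[st$allele == call$allele])
    } else FALSE
    data.frame(sample = sample, locus = lo,
               allele = if (is.na(call$allele)) NA_character_ else
                 as.character(call$allele),
               score = if (!is.na(call$allele))
                 st$score[st$allele == call$allele][1] else NA_real_,
               depth = call$depth, breadth_pct = call$breadth_pct,
               identity_pct = call$identity_pct,
               consistency = call$consistency, reassigned = reass,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' @export
print.typing_result <- function(x, ...) {
  cat(sprintf("typing_result: %d reads used, %d loci\n", x$n_reads_used,
              nrow(x$report)))
  print(x$report)
  invisible(x)
}

#' Evaluate a typing report against a truth profile
#'
#' Applies the strict matching criterion per locus (correct allele AND 100%
#' breadth AND 100% identity) and summarizes consistency and reassignments.
#'
#' @param report data.frame as in `run_type()$report`.
#' @param truth data.frame with columns locus, allele.
#' @return list with `accuracy` (fraction of loci strictly matched),
#'   `n_correct`, `n_loci`, `per_locus` (data.frame with a `match` column),
#'   `mean_consistency`, `n_reassigned`.
#' @export
run_eval <- function(report, truth) {
  missing <- setdiff(truth$locus, report$locus)
  extra <- setdiff(report$locus, truth$locus)
  if (length(missing) || length(extra)) {
    stop("locus mismatch between report and truth: missing [",
         paste(missing, collapse = ", "), "], extra [",
         paste(extra, collapse = ", "), "]")
  }
  per <- merge(report, truth, by = "locus", suffixes = c("", "_truth"))
  per$match <- vapply(seq_len(nrow(per)), function(i) {
    call <- list(allele = per$allele[i], breadth_pct = per$breadth_pct[i],
                 identity_pct = per$identity_pct[i])
    class(call) <- "locus_call"
    score_against_truth(call, per$allele_truth[i])
  }, logical(1))
  list(accuracy = mean(per$match), n_correct = sum(per$match),
       n_loci = nrow(per),
       per_locus = per[, c("locus", "allele", "allele_truth", "match",
                           "consistency", "reassigned")],
       mean_consistency = mean(per$consistency, na.rm = TRUE),
       n_reassigned = sum(per$reassigned))
}
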