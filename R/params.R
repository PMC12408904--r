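#' Alignment and chaining parameters
#'
#' Bundles the scoring constants used by both chaining stages and the final
#' anchor-joining alignment: a positive match reward and negative penalties for
#' mismatches and affine gaps (a gap of length n costs `gap_open +
#' (n-1) * gap_extend`). `open_cap` bounds the stage-1 chain-opening penalty, so
#' a read that starts far into a query (e.g. an allele contained in a longer
#' read) is not penalized without limit. `chain_min_score` is the acceptance
#' threshold for valid stage-1 chains; the default keeps any chain worth at
#' least one full k-mer of matches.
#'
#' @param k k-mer size used for seeding (>= 4).
#' @param match match reward M (> 0).
#' @param mismatch mismatch penalty E (< 0).
#' @param gap_open gap opening penalty W (< 0, at most `gap_extend`).
#' @param gap_extend gap extension penalty U (< 0).
#' @param open_cap maximum stage-1 chain opening penalty L (< 0).
#' @param chain_min_score minimum score for a stage-1 chain to be kept.
#' @return An object of class `scoring_params`.
#' @examples
#' p <- scoring_params()
#' p$match
#' @export
scoring_params <- function(k = 16L, match = 1, mismatch = -2, gap_open = -3,
                           gap_extend = -1, open_cap = -6,
                           chain_min_score = k * match) {
  k <- as.integer(k)
  stopifnot(k >= 4L, match > 0, mismatch < 0, gap_open < 0, gap_extend < 0,
            open_cap < 0, gap_open <= gap_extend)
  structure(list(k = k, match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 open_cap = open_cap, chain_min_score = chain_min_score),
            class = "scoring_params")
}

#' @export
print.scoring_params <- function(x, ...) {
  cat(sprintf(
    "scoring_params: k=%d M=%g E=%g W=%g U=%g L=%g chain_min_score=%g\n",
    x$k, x$match, x$mismatch, x$gap_open, x$gap_extend, x$open_cap,
    x$chain_min_score))
  invisible(x)
}

#' Multi-mapping resolution parameters
#'
#' `epsilon` is the proximity fraction: a template enters a read's candidate
#' set when its alignment score is at least `epsilon` times the read's best
#' score. `epsilon = 1` reduces to the plain argmax candidate set. `tau` is the
#' minimum alignment score for a read to contribute to any template's ConClave
#' score.
#'
#' @param epsilon proximity fraction in (0, 1].
#' @param tau minimum contributing alignment score (>= 0).
#' @return An object of class `conclave_params`.
#' @examples
#' conclave_params(epsilon = 0.95)
#' @export
conclave_params <- function(epsilon = 1, tau = 0) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0,
            epsilon <= 1, is.numeric(tau), length(tau) == 1L, tau >= 0)
  structure(list(epsilon = epsilon, tau = tau), class = "conclave_params")
}

#' Convert a command-line proximity option to a proximity fraction
#'
#' The command-line convention mirrors the field's tooling: a negative value -x
#' denotes fraction mode with epsilon = x. Non-negative values are rejected
#' (only fraction mode is supported).
#'
#' @param proxi a negative number; `-0.98` means epsilon 0.98.
#' @return The proximity fraction epsilon.
#' @export
proxi_to_epsilon <- function(proxi) {
  stopifnot(is.numeric(proxi), length(proxi) == 1L)
  if (proxi >= 0) {
    stop("`proxi` must be negative: -x denotes fractional proximity epsilon = x")
  }
  eps <- -proxi
  if (eps > 1) stop("fractional proximity must lie in (0, 1]")
  eps
}
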