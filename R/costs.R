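#' Stage-1 chain extension cost
#'
#' Cost of linking two collinear anchors given the signed query gap `g` between
#' them. `g = 1 - k` is a perfect (k-1)-base overlap of adjacent seeds, whose
#' already-counted matching bases are subtracted; other negative gaps indicate
#' a deletion in the query and are charged as an affine gap plus the
#' double-counted matches; positive gaps are charged the cheaper of a minimal
#' mismatch estimate (at least one mismatch per k bases, relaxed with the same
#' number of matches up to k) and a single affine gap.
#'
#' @param g signed query gap (must be >= 1 - k).
#' @param params a [scoring_params()] object.
#' @return Numeric score contribution (<= 0 except for the overlap branch).
#' @examples
#' chain_extension_cost(0, scoring_params())   # abutting anchors: 0
#' chain_extension_cost(-15, scoring_params()) # perfect 15-base overlap at k=16
#' @export
chain_extension_cost <- function(g, params = scoring_params()) {
  k <- params$k; M <- params$match; E <- params$mismatch
  W <- params$gap_open; U <- params$gap_extend
  if (any(g < 1 - k)) stop("gap below 1 - k: anchors are not chainable")
  cfrac <- ceiling(g / k)
  mm <- cfrac * E + pmin(g - cfrac, cfrac, k) * M
  gp <- W + (g - 1) * U
  out <- pmax(mm, gp)
  out[g < 0] <- (g * M + (abs(g) - 1) * U + W)[g < 0]
  out[g == 1 - k] <- (1 - k) * M
  out
}

#' Stage-1 chain opening cost
#'
#' Penalty for starting a chain at distance `g_hat` from the query boundary,
#' charged as an affine gap capped at `open_cap` so containment of a shorter
#' reference inside a long read stays affordable.
#'
#' @param g_hat non-negative distance from the query boundary.
#' @inheritParams chain_extension_cost
#' @return Numeric score contribution (0 when `g_hat` is 0).
#' @export
chain_opening_cost <- function(g_hat, params = scoring_params()) {
  if (any(g_hat < 0)) stop("`g_hat` must be non-negative")
  W <- params$gap_open; U <- params$gap_extend; L <- params$open_cap
  out <- pmax(L, W + (g_hat - 1) * U)
  out[g_hat == 0] <- 0
  out
}

#' Stage-2 anchor-join mismatch estimate
#'
#' Estimated (mis)match cost of joining two anchors whose closest coordinate
#' distance is `m`: at least one mismatch per k bases and never fewer than two,
#' relaxed with the same number of matches up to a maximum of k.
#'
#' @param m non-negative distance between anchors (min of query and template
#'   gaps).
#' @inheritParams chain_extension_cost
#' @return Numeric score contribution (0 when `m` is 0).
#' @examples
#' anchor_mismatch_cost(5, scoring_params())
#' @export
anchor_mismatch_cost <- function(m, params = scoring_params()) {
  if (any(m < 0)) stop("`m` must be non-negative")
  k <- params$k; M <- params$match; E <- params$mismatch
  cfrac <- ceiling(m / k)
  out <- pmax(cfrac, 2) * E + pmin(m - cfrac, cfrac, k) * M
  out[m == 0] <- 0
  out
}

#' Stage-2 anchor-join gap estimate
#'
#' Estimated gap cost of joining two anchors whose query and template gaps
#' differ by `g`: a single affine gap of that length; match rewards are
#' subtracted when the difference is negative (overlapping estimates).
#'
#' @param g signed difference between query gap and template gap.
#' @inheritParams chain_extension_cost
#' @return Numeric score contribution (0 when `g` is 0).
#' @export
anchor_gap_cost <- function(g, params = scoring_params()) {
  M <- params$match; W <- params$gap_open; U <- params$gap_extend
  out <- W + (g - 1) * U
  neg <- g < 0
  out[neg] <- (W + (abs(g) - 1) * U + g * M)[neg]
  out[g == 0] <- 0
  out
}

#' Stage-2 new-chain cost
#'
#' Penalty for opening a chain at distance `g_hat` from the template boundary:
#' the cheaper of a single affine gap and the per-k-mer mismatch estimate.
#'
#' @param g_hat non-negative distance from the template boundary.
#' @inheritParams chain_extension_cost
#' @return Numeric score contribution (0 when `g_hat` is 0).
#' @export
new_chain_cost <- function(g_hat, params = scoring_params()) {
  if (any(g_hat < 0)) stop("`g_hat` must be non-negative")
  k <- params$k; M <- params$match; E <- params$mismatch
  W <- params$gap_open; U <- params$gap_extend
  cfrac <- ceiling(g_hat / k)
  mm <- cfrac * E + pmin(g_hat - cfrac, cfrac, k) * M
  gp <- W + (g_hat - 1) * U
  out <- pmax(mm, gp)
  out[g_hat == 0] <- 0
  out
}
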