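# Stage-1 k-mer signature index: each seed maps to the set of template IDs
# containing it; identical sets are collapsed to one stored signature. The
# stage-2 positional index stores seed positions for matched templates only.

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA strings (ACGTN).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  cpp_revcomp(as.character(x))
}

# all k-mers of a sequence, in order (character(0) if too short)
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, 1:(n - k + 1), k:n)
}

# canonical form (lexicographic min of k-mer and reverse complement) of every
# k-mer of `seq`; one reverse complement of the whole sequence is reused
canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  kf <- substring(seq, 1:(n - k + 1), k:n)
  rc <- revcomp(seq)
  kr <- substring(rc, 1:(n - k + 1), k:n)
  kr <- kr[(n - k + 1):1] # kr[i] is now the reverse complement of kf[i]
  ifelse(kf <= kr, kf, kr)
}

# positions (0-based) of the seeds used for a sequence: all positions in dense
# mode, minimizer-selected positions when a minimizer size is set (window
# w = k - m + 1, lexicographic order on the canonical m-mer)
seed_positions <- function(seq, k, minimizer_size = NULL) {
  n <- nchar(seq)
  if (is.null(minimizer_size)) {
    if (n < k) return(integer(0))
    return(0:(n - k))
  }
  m <- as.integer(minimizer_size)
  if (n < k) return(integer(0))
  cpp_minimizer_positions(seq, m, k - m + 1L)
}

# seed strings (canonical) at the selected positions
seeds_of <- function(seq, k, minimizer_size = NULL) {
  sl <- if (is.null(minimizer_size)) k else as.integer(minimizer_size)
  pos <- seed_positions(seq, k, minimizer_size)
  if (!length(pos)) return(list(pos = integer(0), seed = character(0)))
  if (is.null(minimizer_size)) {
    seed <- canonical_kmers(seq, sl)
  } else {
    all_can <- canonical_kmers(seq, sl)
    seed <- all_can[pos + 1L]
  }
  list(pos = pos, seed = seed)
}

#' Build the stage-1 k-mer signature index
#'
#' Every seed of every reference (canonical over both strands) maps to the
#' sorted set of template IDs containing it; identical sets are collapsed into
#' one stored signature, which is what makes the index compact for databases of
#' near-identical alleles. Template IDs are dense integers in input order.
#'
#' With `minimizer_size = m < k`, seeds are the canonical m-mers selected as
#' lexicographic minimizers over windows of `k - m + 1` consecutive positions
#' (so every k-long window contributes a seed); this is the long-read preset.
#'
#' @param references data.frame from [read_fasta()] (columns id, seq).
#' @param k seed k-mer size (>= 4).
#' @param minimizer_size optional minimizer size m <= k.
#' @return An object of class `signature_index`.
#' @export
build_index <- function(references, k = 16L, minimizer_size = NULL) {
  k <- as.integer(k)
  stopifnot(k >= 4L)
  if (!is.null(minimizer_size)) {
    minimizer_size <- as.integer(minimizer_size)
    stopifnot(minimizer_size >= 4L, minimizer_size <= k)
  }
  if (!nrow(references)) stop("empty reference set")
  too_short <- nchar(references$seq) < k
  if (any(too_short)) {
    warning("skipping template(s) shorter than k: ",
            paste(references$id[too_short], collapse = ", "))
    references <- references[!too_short, , drop = FALSE]
    if (!nrow(references)) stop("no template of length >= k")
  }
  seed_len <- if (is.null(minimizer_size)) k else minimizer_size
  per <- lapply(references$seq, seeds_of, k = k, minimizer_size = minimizer_size)
  seeds <- unlist(lapply(per, `[[`, "seed"), use.names = FALSE)
  tids <- rep(seq_len(nrow(references)),
              vapply(per, function(x) length(x$seed), 0L))
  keep <- !grepl("N", seeds, fixed = TRUE)
  sets <- lapply(split(tids[keep], seeds[keep]), function(v) sort(unique(v)))
  keyset <- vapply(sets, paste, "", collapse = ",")
  ukeys <- unique(keyset)
  sig_of_seed <- match(keyset, ukeys)
  signature_table <- sets[match(ukeys, keyset)]
  names(signature_table) <- NULL
  structure(list(
    k = k, seed_len = as.integer(seed_len), minimizer_size = minimizer_size,
    templates = data.frame(tid = seq_len(nrow(references)),
                           name = references$id,
                           length = nchar(references$seq),
                           seq = references$seq,
                           locus = if ("locus" %in% names(references)) references$locus else NA,
                           allele = if ("allele" %in% names(references)) references$allele else NA,
                           stringsAsFactors = FALSE),
    # plain key/value vectors with hashed fmatch() lookups: an environment map
    # keyed by k-mer strings would intern every queried k-mer as a permanent
    # symbol, leaking memory across queries
    seed_keys = names(sets),
    seed_sig = sig_of_seed,
    signature_table = signature_table
  ), class = "signature_index")
}

#' @export
print.signature_index <- function(x, ...) {
  cat(sprintf(
    "signature_index: %d templates, k=%d%s, %d distinct seeds, %d signatures\n",
    nrow(x$templates), x$k,
    if (!is.null(x$minimizer_size)) sprintf(" (minimizer %d)", x$minimizer_size) else "",
    length(x$seed_keys), length(x$signature_table)))
  invisible(x)
}

#' Look up the template set of one seed
#'
#' @param index a `signature_index`.
#' @param kmer a string of length `index$seed_len` (canonicalized internally).
#' @return Sorted integer vector of template IDs (empty if absent).
#' @export
lookup_templates <- function(index, kmer) {
  if (nchar(kmer) != index$seed_len) {
    stop("seed length must be ", index$seed_len, ", got ", nchar(kmer))
  }
  rc <- revcomp(kmer)
  can <- if (kmer <= rc) kmer else rc
  i <- fastmatch::fmatch(can, index$seed_keys)
  if (is.na(i)) return(integer(0))
  index$signature_table[[index$seed_sig[i]]]
}

# signature ids (NA where absent) for a vector of canonical seeds
lookup_sigs <- function(index, seeds) {
  if (!length(seeds)) return(integer(0))
  index$seed_sig[fastmatch::fmatch(seeds, index$seed_keys)]
}

#' Build the stage-2 positional index for matched templates
#'
#' For each listed template, every (forward-strand) k-mer is mapped to all of
#' its 0-based occurrence positions. Built at runtime, only for templates the
#' stage-1 index matched.
#'
#' @param index a `signature_index` (carries the template sequences).
#' @param template_ids integer vector of template IDs to include.
#' @param k k-mer size (defaults to the index k).
#' @return An object of class `positional_index`.
#' @export
build_positional_index <- function(index, template_ids = index$templates$tid,
                                   k = index$k) {
  template_ids <- as.integer(template_ids)
  unknown <- setdiff(template_ids, index$templates$tid)
  if (length(unknown)) stop("unknown template id(s): ", paste(unknown, collapse = ", "))
  k <- as.integer(k)
  # combined map: kmer -> integer vector c(tid1, pos1, tid2, pos2, ...)
  parts <- lapply(template_ids, function(tid) {
    seq <- index$templates$seq[index$templates$tid == tid]
    km <- seq_kmers(seq, k)
    if (!length(km)) return(NULL)
    ok <- !grepl("N", km, fixed = TRUE)
    data.frame(kmer = km[ok], tid = tid, pos = which(ok) - 1L,
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, parts)
  # key/value vectors (fmatch lookups), not an environment: env keys would
  # intern every queried k-mer as a permanent symbol
  keys <- character(0)
  vals <- list()
  if (!is.null(all) && nrow(all)) {
    pair <- rbind(all$tid, all$pos)
    sp <- split(seq_len(nrow(all)), all$kmer)
    keys <- names(sp)
    vals <- unname(lapply(sp, function(i) as.integer(pair[, i])))
  }
  structure(list(k = k, template_ids = template_ids, keys = keys, vals = vals,
                 template_len = setNames(index$templates$length,
                                         index$templates$tid)),
            class = "positional_index")
}

#' Occurrence positions of a k-mer in one indexed template
#'
#' @param pidx a `positional_index`.
#' @param template_id one template ID present in the index.
#' @param kmer a string of length `pidx$k` (forward strand).
#' @return Sorted integer vector of 0-based positions.
#' @export
template_positions <- function(pidx, template_id, kmer) {
  if (!template_id %in% pidx$template_ids) {
    stop("template ", template_id, " is not in the positional index")
  }
  if (nchar(kmer) != pidx$k) stop("k-mer length must be ", pidx$k)
  i <- fastmatch::fmatch(kmer, pidx$keys)
  if (is.na(i)) return(integer(0))
  v <- pidx$vals[[i]]
  m <- matrix(v, nrow = 2)
  sort(m[2, m[1, ] == template_id])
}

# all (tid, tpos, qpos) hits of a query's k-mers against the positional index
positional_hits <- function(pidx, query_kmers) {
  if (!length(query_kmers)) {
    return(list(tid = integer(0), tpos = integer(0), qpos = integer(0)))
  }
  idx <- fastmatch::fmatch(query_kmers, pidx$keys)
  v <- pidx$vals[idx]
  lens <- lengths(v) %/% 2L
  flat <- unlist(v, use.names = FALSE)
  if (is.null(flat)) {
    return(list(tid = integer(0), tpos = integer(0), qpos = integer(0)))
  }
  m <- matrix(flat, nrow = 2)
  list(tid = m[1, ], tpos = m[2, ],
       qpos = rep.int(0:(length(query_kmers) - 1L), lens))
}

#' Save / load a signature index
#'
#' The index is serialized as a plain R list (version-tagged), so the
#' round-trip is exact.
#'
#' @param index a `signature_index`.
#' @param path file path.
#' @return `save_index` returns `path` invisibly; `load_index` the index.
#' @export
save_index <- function(index, path) {
  obj <- list(version = 1L, k = index$k, seed_len = index$seed_len,
              minimizer_size = index$minimizer_size,
              templates = index$templates,
              seed_keys = index$seed_keys,
              seed_sig = index$seed_sig,
              signature_table = index$signature_table)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, 1L)) stop("unsupported index version")
  structure(list(k = obj$k, seed_len = obj$seed_len,
                 minimizer_size = obj$minimizer_size,
                 templates = obj$templates,
                 seed_keys = obj$seed_keys,
                 seed_sig = obj$seed_sig,
                 signature_table = obj$signature_table),
            class = "signature_index")
}
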