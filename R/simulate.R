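# Synthetic fixtures: MLST-like allele schemes, sample genomes with known
# profiles, and reads with short-read-like and long-read-like error models
# (including elevated homopolymer indels). Everything is deterministic under
# the supplied seed.

LOCUS_POOL <- c("adk", "fumC", "gyrB", "icd", "mdh", "purA", "recA")

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute `n_snps` distinct positions of `seq` with different bases
mutate_snps <- function(seq, n_snps) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(length(chars), n_snps)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Simulate an MLST-like allele scheme
#'
#' Each locus gets `alleles_per_locus` alleles: allele 1 is random; every other
#' allele differs from allele 1 by a number of substitutions drawn uniformly
#' from `snp_range`. All alleles are unique. Records are named
#' `<locus>_<allele>`.
#'
#' @param n_loci number of loci.
#' @param alleles_per_locus alleles per locus.
#' @param allele_length allele length in bp.
#' @param snp_range integer range (min, max) of substitutions from allele 1.
#' @param seed RNG seed.
#' @return list with `records` (data.frame id, seq, locus, allele) and `truth`
#'   (data.frame locus, allele, snps_from_first).
#' @export
simulate_scheme <- function(n_loci = 7L, alleles_per_locus = 10L,
                            allele_length = 450L, snp_range = c(1L, 5L),
                            seed = 1L) {
  stopifnot(n_loci >= 1, alleles_per_locus >= 1, allele_length >= 20)
  snp_range <- as.integer(range(snp_range))
  if (snp_range[1] < 1 && alleles_per_locus > 1) {
    stop("snp_range must start at >= 1: alleles within a locus must differ")
  }
  loci <- c(LOCUS_POOL, sprintf("locus%02d", seq_len(max(0, n_loci - length(LOCUS_POOL)))))
  loci <- loci[seq_len(n_loci)]
  withr::with_seed(seed, {
    recs <- list()
    truth <- list()
    for (lo in loci) {
      base <- random_dna(allele_length)
      seqs <- base
      dists <- 0L
      for (a in seq_len(alleles_per_locus - 1L)) {
        repeat {
          d <- sample(seq(snp_range[1], snp_range[2]), 1)
          s <- mutate_snps(base, d)
          if (!s %in% seqs) break
        }
        seqs <- c(seqs, s)
        dists <- c(dists, d)
      }
      recs[[lo]] <- data.frame(
        id = paste0(lo, "_", seq_along(seqs)), seq = seqs, locus = lo,
        allele = as.character(seq_along(seqs)), stringsAsFactors = FALSE)
      truth[[lo]] <- data.frame(locus = lo, allele = as.character(seq_along(seqs)),
                                snps_from_first = dists, stringsAsFactors = FALSE)
    }
    list(records = do.call(rbind, c(recs, make.row.names = FALSE)),
         truth = do.call(rbind, c(truth, make.row.names = FALSE)))
  })
}

#' Simulate a sample genome with a known allele profile
#'
#' One fragment per locus: the chosen allele embedded verbatim between random
#' flanks (exercising containment and chain-opening costs). Flanks are
#' regenerated if they would create a second exact copy of the allele.
#'
#' @param scheme a [simulate_scheme()] result (or its `records` data.frame).
#' @param profile named character vector locus -> allele; NULL draws one
#'   allele per locus at random.
#' @param flank flank length in bp (0 makes fragments equal alleles).
#' @param seed RNG seed.
#' @return list with `fragments` (data.frame id, seq, locus) and `truth`
#'   (data.frame locus, allele).
#' @export
simulate_sample <- function(scheme, profile = NULL, flank = 100L, seed = 1L) {
  records <- if (is.data.frame(scheme)) scheme else scheme$records
  loci <- unique(records$locus)
  withr::with_seed(seed, {
    if (is.null(profile)) {
      profile <- vapply(loci, function(lo) {
        sample(records$allele[records$locus == lo], 1)
      }, "")
    }
    stopifnot(all(names(profile) %in% loci))
    frags <- lapply(names(profile), function(lo) {
      sel <- records$locus == lo & records$allele == profile[[lo]]
      if (!any(sel)) stop("unknown allele ", profile[[lo]], " at locus ", lo)
      allele_seq <- records$seq[sel][1]
      for (try in 1:100) {
        frag <- paste0(random_dna(flank), allele_seq, random_dna(flank))
        n_hit <- length(gregexpr(allele_seq, frag, fixed = TRUE)[[1]])
        if (n_hit == 1) return(frag)
      }
      stop("could not generate flanks without duplicating the allele")
    })
    list(fragments = data.frame(id = paste0("frag_", names(profile)),
                                seq = unlist(frags), locus = names(profile),
                                stringsAsFactors = FALSE),
         truth = data.frame(locus = names(profile),
                            allele = unname(unlist(profile)),
                            stringsAsFactors = FALSE))
  })
}

#' Sequencing error profiles
#'
#' Named presets: `illumina` (150 bp pairs, 0.2% substitutions, no indels),
#' `ont-r9` (single long reads, ~5% total error), `ont-r10` (~1% total error).
#' Any field can be overridden. The homopolymer model multiplies the per-base
#' indel probabilities by the base's run length, capped at `hp_cap`
#' (`hp_cap = 1` disables it).
#'
#' @param preset preset name, or "custom".
#' @param substitution,insertion,deletion per-base error rates.
#' @param hp_cap homopolymer indel multiplier cap (>= 1).
#' @param paired emit 150 bp read pairs instead of single long reads.
#' @param read_length fixed read length for paired mode.
#' @param mean_length,sdlog lognormal read-length model for single-read mode.
#' @return An `error_profile` object.
#' @export
error_profile <- function(preset = c("illumina", "ont-r9", "ont-r10", "custom"),
                          substitution = NULL, insertion = NULL,
                          deletion = NULL, hp_cap = NULL, paired = NULL,
                          read_length = NULL, mean_length = NULL,
                          sdlog = NULL) {
  preset <- match.arg(preset)
  base <- switch(preset,
    "illumina" = list(substitution = 0.002, insertion = 0, deletion = 0,
                      hp_cap = 1, paired = TRUE, read_length = 150L,
                      mean_length = 300, sdlog = 0),
    "ont-r9" = list(substitution = 0.03, insertion = 0.01, deletion = 0.01,
                    hp_cap = 6, paired = FALSE, read_length = NA_integer_,
                    mean_length = 500, sdlog = 0.35),
    "ont-r10" = list(substitution = 0.006, insertion = 0.002, deletion = 0.002,
                     hp_cap = 4, paired = FALSE, read_length = NA_integer_,
                     mean_length = 500, sdlog = 0.35),
    "custom" = list(substitution = 0, insertion = 0, deletion = 0, hp_cap = 1,
                    paired = FALSE, read_length = NA_integer_,
                    mean_length = 500, sdlog = 0.35))
  ovr <- list(substitution = substitution, insertion = insertion,
              deletion = deletion, hp_cap = hp_cap, paired = paired,
              read_length = read_length, mean_length = mean_length,
              sdlog = sdlog)
  for (nm in names(ovr)) if (!is.null(ovr[[nm]])) base[[nm]] <- ovr[[nm]]
  with(base, stopifnot(substitution >= 0, insertion >= 0, deletion >= 0,
                       substitution < 1, insertion < 1, deletion < 1,
                       substitution + insertion + deletion < 1, hp_cap >= 1))
  structure(c(base, list(preset = preset)), class = "error_profile")
}

#' @export
print.error_profile <- function(x, ...) {
  cat(sprintf(
    "error_profile (%s): sub %.4f, ins %.4f, del %.4f, hp_cap %g, %s\n",
    x$preset, x$substitution, x$insertion, x$deletion, x$hp_cap,
    if (x$paired) sprintf("paired %d bp", x$read_length) else
      sprintf("single, lognormal(%g, %g)", x$mean_length, x$sdlog)))
  invisible(x)
}

# per-base Phred-like quality character for a profile
profile_qual_char <- function(profile) {
  p <- profile$substitution + profile$insertion + profile$deletion
  q <- if (p <= 0) 41L else as.integer(round(-10 * log10(p)))
  intToUtf8(33L + max(2L, min(41L, q)))
}

# apply the error model to one (sub)sequence; returns the mutated string
apply_errors <- function(seq, profile) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (!n) return("")
  r <- rle(chars)
  hp <- pmin(rep.int(r$lengths, r$lengths), profile$hp_cap)
  keep <- runif(n) >= profile$deletion * hp
  subm <- runif(n) < profile$substitution
  insm <- runif(n) < profile$insertion * hp
  if (any(subm)) {
    alt <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T", "A", "C", "G"),
                  nrow = 4, dimnames = list(c("A", "C", "G", "T"), NULL))
    wi <- which(subm & chars %in% rownames(alt))
    chars[wi] <- alt[cbind(match(chars[wi], rownames(alt)),
                           sample.int(3, length(wi), replace = TRUE))]
  }
  pieces <- ifelse(keep, chars, "")
  if (any(insm)) {
    wi <- which(insm)
    pieces[wi] <- paste0(pieces[wi],
                         sample(c("A", "C", "G", "T"), length(wi), replace = TRUE))
  }
  paste(pieces, collapse = "")
}

#' Simulate reads from sample fragments
#'
#' Single-read mode draws lognormal read lengths, a uniform start, and a
#' uniform strand, then applies the error model per base (substitutions at the
#' flat rate; insertions/deletions scaled by the homopolymer run length up to
#' `hp_cap`). Paired mode draws ~`2 x read_length` inserts and emits the two
#' ends as `/1` (forward) and `/2` (reverse complement). Reads are generated
#' until each fragment's total read bases reach `depth` times its length.
#'
#' @param fragments data.frame with columns id, seq (e.g. from
#'   [simulate_sample()]).
#' @param profile an [error_profile()].
#' @param depth target mean per-base depth (> 0).
#' @param seed RNG seed.
#' @return list with `reads` (data.frame id, seq, qual) and `truth`
#'   (data.frame id, fragment, start, end, strand) — coordinates are 0-based
#'   half-open on the fragment, pre-error.
#' @export
simulate_reads <- function(fragments, profile = error_profile("ont-r9"),
                           depth = 50, seed = 1L) {
  stopifnot(depth > 0)
  if (!nrow(fragments)) stop("no fragments to simulate from")
  qc <- profile_qual_char(profile)
  withr::with_seed(seed, {
    reads <- list()
    truth <- list()
    for (fi in seq_len(nrow(fragments))) {
      frag <- fragments$seq[fi]
      flen <- nchar(frag)
      target <- depth * flen
      got <- 0
      ri <- 0L
      while (got < target) {
        ri <- ri + 1L
        base_id <- sprintf("%s_r%04d", fragments$id[fi], ri)
        if (profile$paired) {
          ilen <- min(flen, max(2L * profile$read_length,
                                as.integer(round(rnorm(1, 2.2 * profile$read_length,
                                                       0.2 * profile$read_length)))))
          start <- sample.int(flen - ilen + 1L, 1) - 1L
          insert <- substr(frag, start + 1L, start + ilen)
          rl <- min(profile$read_length, ilen)
          r1 <- apply_errors(substr(insert, 1L, rl), profile)
          r2 <- apply_errors(revcomp(substr(insert, ilen - rl + 1L, ilen)), profile)
          reads[[length(reads) + 1L]] <- data.frame(
            id = paste0(base_id, c("/1", "/2")), seq = c(r1, r2),
            qual = c(strrep(qc, nchar(r1)), strrep(qc, nchar(r2))),
            stringsAsFactors = FALSE)
          truth[[length(truth) + 1L]] <- data.frame(
            id = paste0(base_id, c("/1", "/2")), fragment = fragments$id[fi],
            start = c(start, start + ilen - rl),
            end = c(start + rl, start + ilen), strand = c("+", "-"),
            stringsAsFactors = FALSE)
          got <- got + nchar(r1) + nchar(r2)
        } else {
          rl <- min(flen, max(50L, as.integer(round(
            rlnorm(1, log(min(profile$mean_length, flen)), profile$sdlog)))))
          start <- sample.int(flen - rl + 1L, 1) - 1L
          strand <- sample(c("+", "-"), 1)
          raw <- substr(frag, start + 1L, start + rl)
          if (strand == "-") raw <- revcomp(raw)
          seq <- apply_errors(raw, profile)
          if (!nchar(seq)) next
          reads[[length(reads) + 1L]] <- data.frame(
            id = base_id, seq = seq, qual = strrep(qc, nchar(seq)),
            stringsAsFactors = FALSE)
          truth[[length(truth) + 1L]] <- data.frame(
            id = base_id, fragment = fragments$id[fi], start = start,
            end = start + rl, strand = strand, stringsAsFactors = FALSE)
          got <- got + nchar(seq)
        }
      }
    }
    list(reads = do.call(rbind, c(reads, make.row.names = FALSE)),
         truth = do.call(rbind, c(truth, make.row.names = FALSE)))
  })
}
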