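---
title: "Methods: proximity-scored assembly-free typing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proximity-scored assembly-free typing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxitype)
```

`proxitype` types a sample directly from raw reads: no assembly, no variant
calling. This vignette describes the scoring model and each pipeline stage,
with small runnable examples.

## Scoring model

All stages share one parameter bundle: match reward $M > 0$, mismatch penalty
$E < 0$, and affine gaps where a gap of length $n$ costs $W + (n-1)U$
($W \le U < 0$). Defaults are $M=1$, $E=-2$, $W=-3$, $U=-1$, seed size
$k = 16$.

```{r}
scoring_params()
```

## Stage 1: signature index and candidate mapping

Every canonical $k$-mer (the lexicographic minimum of the $k$-mer and its
reverse complement) of every template maps to the sorted set of template IDs
containing it. Identical sets are collapsed to a single stored *signature*:
for databases of near-identical alleles most seeds share a handful of
signatures, so the index stays compact and a seed lookup immediately yields
the full template set.

```{r}
scheme <- simulate_scheme(n_loci = 2, seed = 7)
index <- build_index(scheme$records, k = 16)
index
```

A query's seeds are grouped into *anchors*: maximal runs of consecutive seed
positions carrying the same signature. Anchors are chained with a dynamic
programme over query coordinates. Writing $w_i$ for anchor $i$'s weight
(its length times $M$), the chain score is

$$f(i) = w_i + \max\Big\{ \max_{j} \big[f(j) + p(g_{ij})\big],\; o(\hat g_i) \Big\}$$

where $g_{ij}$ is the signed query gap between anchors $j$ and $i$ (anchors
must also share a template in their signature sets), and:

* the **extension cost** `chain_extension_cost()` $p(g)$ charges, for a
  positive gap, the cheaper of a mismatch estimate (at least one mismatch per
  $k$ bases, relaxed by up to the same number of matches) and a single affine
  gap; negative gaps (overlaps) pay back the double-counted matches plus an
  affine gap; a perfect $(k-1)$-overlap of adjacent seeds just subtracts the
  re-counted matches;
* the **opening cost** `chain_opening_cost()` $o(\hat g)$ charges an affine
  gap over the distance $\hat g$ to the query boundary, capped at $L$
  (default $-6$), so a reference contained deep inside a long read is not
  penalized without bound. A mirror term over the trailing query closes each
  chain's *total* score.

```{r}
p <- scoring_params()
chain_extension_cost(c(-3, 0, 5), p)
chain_opening_cost(c(0, 2, 100), p)
```

Chains above `chain_min_score` are extracted by backtracking (each anchor used
once), filtered to a non-overlapping set on the query, and their template sets
form the read's candidates (`map_query()`).

## Stage 2: positional re-mapping and anchored alignment

Only the matched templates are re-indexed positionally (`k`-mer to occurrence
positions). Maximal exact matches between read and template are extended and
chained in both coordinates:

$$f(i) = \ell_i M + \max\Big\{\max_j\big[f(j) + \alpha(\min(d_q, d_t)) +
\beta(d_q - d_t)\big],\; \gamma(t_i)\Big\}$$

with $d_q, d_t \ge 0$ the query/template gaps between consecutive anchors;
$\alpha$ (`anchor_mismatch_cost()`) estimates at least one mismatch per $k$
bases and never fewer than two; $\beta$ (`anchor_gap_cost()`) charges one
affine gap over the length difference; $\gamma$ (`new_chain_cost()`) opens a
chain against the template boundary (used, with a mirror closing term, in
global mode; dovetail mode leaves ends free).

```{r}
anchor_mismatch_cost(c(5, 40), p)
anchor_gap_cost(c(2, -2), p)
new_chain_cost(c(1, 3), p)
```

The best chain's anchors are trimmed to cores, kept as forced matches, and
the regions between cores (plus the two terminal regions) are aligned with a
full affine-gap DP (`join_anchors()`), yielding a complete alignment whose
score equals the unanchored full-matrix DP on the same pair — anchoring is a
speed device, not an approximation (this equivalence is test-pinned against
an independent implementation). The pipeline aligns with *dovetail* ends:
overhangs of either sequence past the other are unpenalized, matching the
semantics of read mapping.

```{r}
t <- scheme$records$seq[1]
read <- paste0("AAAA", substr(t, 1, 120)) # read with a 4 bp adapter overhang
align_to_template(read, t, mode = "free")
```

## ConClave resolution with proximity scoring

Let $f(q,t)$ be read $q$'s alignment score against template $t$. Resolution
has three steps (`resolve_conclave()`):

1. **Candidate sets.** $T_m(q) = \{t : f(q,t) \ge \varepsilon \cdot \max_r
   f(q,r)\}$ with the proximity fraction $\varepsilon \in (0,1]$;
   $\varepsilon = 1$ is the plain argmax set.
2. **Template scores.** $C(t) = \sum_q f(q,t) \,[\,\tau \le f(q,t) \wedge t
   \in T_m(q)\,]$ — every candidate receives the read's *own* score against
   it, so lower-scoring proximity members contribute their lower scores.
3. **Assignment.** $S_q = \arg\max_{t \in T_m(q)} C(t)$, ties to the lowest
   template ID. Reads are independent; input order never matters.

With $M=1, E=-2$, a 150 bp read with one mismatch scores 147 against its
true template versus 150 for a perfect neighbour; $\varepsilon = 0.98$ is the
largest fraction that still admits it ($147 = 0.98 \times 150$):

```{r}
candidate_templates(c(`1` = 150, `2` = 147), epsilon = 0.98)
candidate_templates(c(`1` = 150, `2` = 147), epsilon = 0.981)
```

Why this helps noisy long reads: with ~5% error, most reads carry enough
errors that their *best* hit is occasionally a near-identical wrong allele.
Under plain argmax those reads scatter across neighbours. With
$\varepsilon < 1$ each such read still lists the true allele, which
accumulates the largest $C(t)$ and pulls the whole population to itself.

```{r, eval = FALSE}
smp <- simulate_sample(scheme, flank = 100, seed = 7)
sim <- simulate_reads(smp$fragments, error_profile("ont-r9"), depth = 75,
                      seed = 7)
res <- run_type(sim$reads, index, epsilon = 0.95)
run_eval(res$report, smp$truth)
```

## Consensus, reassignment, and locus calls

Assigned reads are piled up on their template (`build_pileup()`): per-column
counts over A/C/G/T/gap, plus insertion tallies keyed by the column they
precede. `call_consensus()` takes the column majority (ties to the template
base), deletes gap-majority columns, emits an insertion only on a strict
majority of the covering reads, and **omits zero-coverage columns** — the
consensus reports only read-supported sequence, and breadth records what was
left uncovered.

A consensus that is not identical to its template is compared against the
whole database (`reassign_imperfect()`): 100% identity over the full length
is exact string equality, so an exact match to a *different* allele
reassigns the pileup to it. This rescues the classic boundary artifact where
a decoy allele, identical to the true allele except for a short extension,
wins the initial vote on ties: its extension stays uncovered, the consensus
drops it, and the result equals the true allele exactly.

Per locus, `call_locus()` picks the deepest allele among those at or above
the identity floor (default 95%); *consistency* is the chosen allele's share
of the locus's total depth. The strict truth criterion (`score_against_truth()`)
demands the correct allele **and** 100% breadth **and** 100% identity — a
deletion-biased homopolymer contraction at low depth (the known long-read
failure mode) therefore produces an honest non-call rather than a silent
wrong call.

## Simulator

`simulate_scheme()` (allele 1 random, others 1–5 SNPs away, all unique),
`simulate_sample()` (alleles embedded between random flanks),
`simulate_reads()` (lognormal single reads or 150 bp pairs; per-base
substitution/insertion/deletion with indel rates multiplied by the
homopolymer run length up to a cap). Presets: `illumina` (0.2%
substitutions), `ont-r9` (~5% total), `ont-r10` (~1% total). Everything is
deterministic under the supplied seed.

```{r}
error_profile("ont-r9")
```
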