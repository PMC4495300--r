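#' Cumulative binomial tail probability
#'
#' Probability of observing `k` or more successes in `n` independent trials
#' with per-trial success probability `p`:
#' `f(k+; n; p) = 1 - sum_{i<k} C(n,i) p^i (1-p)^(n-i)`. For `k = 1` this
#' reduces to `1 - (1-p)^n`. Evaluated through the upper binomial tail so it
#' stays accurate for very small `p` and large `n`.
#'
#' @param k Minimum number of successes (>= 0; `k > n` gives 0, `k = 0`
#'   gives 1).
#' @param n Number of trials (>= 0).
#' @param p Per-trial success probability in \[0, 1\].
#' @return Probability in \[0, 1\].
#' @examples
#' cumulative_binomial(2, 3, 0.5)  # 0.5
#' @export
cumulative_binomial <- function(k, n, p) {
  stopifnot(k >= 0, n >= 0)
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  if (k == 0) return(1)
  if (k > n) return(0)
  pbinom(k - 1, size = n, prob = p, lower.tail = FALSE)
}

#' Per-site probability of a motif occurrence
#'
#' Product over the motif's defined positions of the summed background
#' frequencies of the allowed residues; wildcard spacers contribute a factor
#' of 1.
#'
#' @param motif Motif object or pattern string.
#' @param aa_freqs Named numeric vector of residue frequencies (normalised).
#' @return Probability of the motif matching at one site.
#' @export
site_probability <- function(motif, aa_freqs) {
  m <- parse_motif(motif)
  p <- 1
  for (s in m$sets) {
    f <- aa_freqs[s]
    if (any(is.na(f)) || sum(f) == 0) {
      warning("residue(s) with zero or absent frequency in motif ",
              format(m), "; site probability is 0", call. = FALSE)
      return(0)
    }
    p <- p * sum(f)
  }
  p
}

#' Probability that a motif occurs at least once in a UPC
#'
#' `p1+ = 1 - (1 - p_site)^sites`, the first binomial cycle of the
#' significance model, with the number of candidate sites in the cluster as
#' the number of trials.
#'
#' @param p_site Per-site occurrence probability.
#' @param sites Number of candidate sites in the cluster (>= 0).
#' @return Probability in \[0, 1\].
#' @export
upc_p1 <- function(p_site, sites) {
  stopifnot(all(sites >= 0), length(p_site) == 1)
  if (p_site <= 0) return(rep(0, length(sites)))
  if (p_site >= 1) return(as.numeric(sites > 0))
  out <- -expm1(sites * log1p(-p_site))
  out[sites == 0] <- 0
  unname(out)
}

#' Probability of the observed (or greater) UPC support
#'
#' Second binomial cycle: `f(k+; n; mean(p1))` where `n` is the number of
#' unrelated protein clusters and the trial probability is the arithmetic
#' mean of the per-cluster occurrence probabilities.
#'
#' @param k Observed support (number of clusters containing the motif).
#' @param p1_list Numeric vector of per-cluster `p1+` values.
#' @return Probability in \[0, 1\].
#' @export
support_probability <- function(k, p1_list) {
  if (length(p1_list) == 0 && k >= 1) {
    stop("no clusters to support the motif", call. = FALSE)
  }
  if (k > length(p1_list)) return(0)
  cumulative_binomial(k, length(p1_list), mean(p1_list))
}

#' Significance of a motif given the size of the motif space
#'
#' Third binomial cycle: the probability that any of the `M` patterns in the
#' searched motif space attains the observed support probability or smaller,
#' `Sig = 1 - (1 - Prob)^M`.
#'
#' @param Prob Support probability for the motif.
#' @param M Motif space size for the motif's defined length (>= 1).
#' @return Significance estimate in \[0, 1\].
#' @export
significance <- function(Prob, M) {
  stopifnot(M >= 1)
  if (Prob >= 1) return(1)
  -expm1(M * log1p(-Prob))
}

#' Query-mode support bookkeeping
#'
#' In query mode the query's cluster seeds the motif space and is removed
#' from the search dataset, so a motif supported by `k` of `n` clusters is
#' assessed as `k - 1` of `n - 1`: one cluster and one occurrence are
#' sacrificed in exchange for the much smaller query-restricted motif space.
#'
#' @param k Observed support including the query's cluster (>= 1).
#' @param n Number of clusters including the query's (>= k).
#' @param query_in_support Must be `TRUE`: a candidate motif occurs in the
#'   query by construction.
#' @return List with `k` and `n` adjusted.
#' @examples
#' query_adjust(7, 74)  # k = 6, n = 73
#' @export
query_adjust <- function(k, n, query_in_support = TRUE) {
  if (k < 1) {
    stop("a query-mode candidate must occur in the query (k >= 1)",
         call. = FALSE)
  }
  if (!isTRUE(query_in_support)) {
    stop("motif absent from the query cluster is not a query-mode candidate",
         call. = FALSE)
  }
  list(k = k - 1L, n = n - 1L)
}

#' Residue frequencies from the unmasked residues of a dataset
#'
#' @param records Masked records tibble.
#' @param exclude_ids Record ids to leave out (e.g. the query's cluster in
#'   query mode).
#' @return Named numeric vector over the 20-residue alphabet, summing to 1.
#' @export
aa_frequencies <- function(records, exclude_ids = character()) {
  records <- ensure_masked(records)
  seqs <- records$masked_sequence[!records$id %in% exclude_ids]
  aa <- unlist(strsplit(seqs, "", fixed = TRUE))
  aa <- aa[aa %in% AA_ALPHABET]
  if (length(aa) == 0) stop("no unmasked residues in dataset", call. = FALSE)
  tab <- table(factor(aa, levels = AA_ALPHABET))
  setNames(as.numeric(tab) / sum(tab), AA_ALPHABET)
}

# Maximal unmasked segment lengths per sequence (list of integer vectors).
unmasked_segments <- function(masked_sequences) {
  lapply(strsplit(masked_sequences, "", fixed = TRUE), function(aa) {
    r <- rle(aa != "X")
    r$lengths[r$values]
  })
}

# Candidate site counts per UPC for a motif of total span `span`: for each
# member sequence the number of windows of that span fitting inside unmasked
# segments, taking the maximum over the cluster's members (homologues mostly
# duplicate each other's sequence content).
upc_site_counts <- function(segments, upc, span) {
  per_seq <- vapply(segments, function(seg) {
    sum(pmax(0L, seg - span + 1L))
  }, numeric(1))
  vapply(split(per_seq, upc), max, numeric(1))
}
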