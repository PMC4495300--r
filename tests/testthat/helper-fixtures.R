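# Shared fixture builders; everything is generated in code at test time.

aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_seq <- function(len) paste(sample(aa20, len, replace = TRUE),
                                  collapse = "")

make_records <- function(seqs, ids = paste0("P", seq_along(seqs))) {
  tibble::tibble(id = ids, sequence = seqs)
}

# Independent brute-force oracle for run-length smoothing: flip the first
# too-short run, recompute, repeat. Implemented from scratch over explicit
# run extraction so it does not share code with smooth_mask().
oracle_smooth <- function(mask, min_region = 5L) {
  runs_of <- function(x) {
    runs <- list()
    i <- 1L
    while (i <= length(x)) {
      j <- i
      while (j < length(x) && x[j + 1L] == x[i]) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    }
    runs
  }
  repeat {
    runs <- runs_of(mask)
    if (length(runs) <= 1L) return(mask)
    flipped <- FALSE
    for (r in runs) {
      if (r[2] - r[1] + 1L < min_region) {
        mask[r[1]:r[2]] <- !mask[r[1]]
        flipped <- TRUE
        break
      }
    }
    if (!flipped) return(mask)
  }
}

# Brute-force enumeration of all patterns of a region: choose every ordered
# subset of unmasked positions with consecutive spacing <= W + 1 via combn.
oracle_query_space <- function(region, L, W) {
  aa <- strsplit(region, "", fixed = TRUE)[[1]]
  idx <- which(aa != "X")
  out <- list()
  for (l in 2:L) {
    if (length(idx) < l) next
    combos <- utils::combn(idx, l, simplify = FALSE)
    pats <- character(0)
    for (cc in combos) {
      gaps <- diff(cc) - 1L
      if (any(gaps > W)) next
      pat <- aa[cc[1]]
      for (k in seq_along(gaps)) {
        pat <- paste0(pat, strrep(".", gaps[k]), aa[cc[k + 1L]])
      }
      pats <- c(pats, pat)
    }
    if (length(pats)) {
      out[[length(out) + 1L]] <- tibble::tibble(length = l,
                                                pattern = sort(unique(pats)))
    }
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(length = integer(), pattern = character())
}

# Exhaustive-outcome oracle for the cumulative binomial: enumerate all 2^n
# success/failure vectors.
oracle_binomial_tail <- function(k, n, p) {
  if (k == 0) return(1)
  if (n == 0) return(0)
  grid <- expand.grid(rep(list(c(0L, 1L)), n))
  probs <- apply(grid, 1, function(x) prod(ifelse(x == 1, p, 1 - p)))
  sum(probs[rowSums(grid) >= k])
}

# Union-find oracle for connected components.
oracle_components <- function(ids, edges) {
  parent <- setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  if (nrow(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      ra <- find(edges$id_a[i]); rb <- find(edges$id_b[i])
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  roots <- vapply(ids, find, character(1))
  match(roots, unique(roots))
}

# Fixed disorder profile: fully disordered (scores 0.9) except where stated.
flat_disorder <- function(records, score = 0.9) {
  records$disorder <- lapply(nchar(records$sequence),
                             function(n) rep(score, n))
  records
}
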