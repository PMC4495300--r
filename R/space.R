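.datatable.aware <- TRUE

#' Size of the motif search space
#'
#' Number of distinct fixed-position patterns with `L` defined positions and
#' wildcard spacers of length at most `W` between consecutive defined
#' positions: `20^L * (W+1)^(L-1)`. This is the multiple-testing denominator
#' applied to each motif length independently.
#'
#' @param L Number of defined positions (>= 1).
#' @param W Maximum wildcard spacer length (>= 0).
#' @return Numeric count of patterns.
#' @examples
#' motif_space_size(4, 2)  # 4,320,000
#' @export
motif_space_size <- function(L, W) {
  stopifnot(L >= 1, W >= 0)
  20^L * (W + 1)^(L - 1)
}

# Long residue table for a set of masked sequences.
residue_table <- function(ids, seqs, upc = NULL) {
  dt <- data.table::rbindlist(purrr::map2(ids, seqs, function(id, s) {
    aa <- strsplit(s, "", fixed = TRUE)[[1]]
    data.table::data.table(id = id, pos = seq_along(aa), aa = aa)
  }))
  dt <- dt[dt$aa != "X", ]
  if (!is.null(upc)) dt$upc <- upc[dt$id]
  dt
}

# Levelwise enumeration of fixed-position patterns over masked sequences.
#
# ids/seqs: parallel vectors; upc: named integer vector id -> cluster (may be
# NULL for unclustered enumeration); min_support: prune patterns supported by
# fewer clusters (0 = keep everything); allowed: optional list, one character
# vector of permitted patterns per defined length (prefix-closed restriction
# used for query-mode support counting).
enumerate_patterns <- function(ids, seqs, upc = NULL, L = 5L, W = 2L,
                               min_support = 0L, allowed = NULL) {
  res <- residue_table(ids, seqs, upc)
  if (nrow(res) == 0) {
    return(list(space = empty_space(), occurrences = empty_occurrences()))
  }
  has_upc <- !is.null(upc)
  support_of <- function(occ) {
    if (has_upc) {
      occ[, list(support = data.table::uniqueN(upc)), by = "pattern"]
    } else {
      occ[, list(support = data.table::uniqueN(id)), by = "pattern"]
    }
  }
  seed <- res[, c("id", "pos", "aa"), drop = FALSE]
  data.table::setnames(seed, c("id", "end", "aa1"))
  # occ carries: id, (upc), start, end, pattern
  occ <- data.table::copy(res)
  data.table::setnames(occ, "pos", "end")
  occ$start <- occ$end
  occ$pattern <- occ$aa
  occ$aa <- NULL
  spaces <- list()
  occs <- list()
  for (len in 2:L) {
    parts <- vector("list", W + 1L)
    for (g in 0:W) {
      ext <- data.table::copy(occ)
      ext$nxt <- ext$end + g + 1L
      m <- merge(ext, seed[, c("id", "end", "aa1")],
                 by.x = c("id", "nxt"), by.y = c("id", "end"))
      if (nrow(m) == 0) { parts[[g + 1L]] <- NULL; next }
      m$pattern <- paste0(m$pattern, strrep(".", g), m$aa1)
      m$end <- m$nxt
      m$nxt <- NULL
      m$aa1 <- NULL
      parts[[g + 1L]] <- m
    }
    occ <- data.table::rbindlist(parts[!vapply(parts, is.null, logical(1))])
    if (is.null(occ) || nrow(occ) == 0) break
    if (!is.null(allowed)) {
      keep <- allowed[[as.character(len)]]
      occ <- occ[occ$pattern %in% keep, ]
      if (nrow(occ) == 0) break
    }
    sup <- support_of(occ)
    if (min_support > 0L) {
      sup <- sup[sup$support >= min_support, ]
      occ <- occ[occ$pattern %in% sup$pattern, ]
      if (nrow(occ) == 0) break
    }
    sup$length <- len
    spaces[[length(spaces) + 1L]] <- sup
    keep <- data.table::copy(occ)
    occs[[length(occs) + 1L]] <- keep
  }
  space <- if (length(spaces)) {
    tibble::as_tibble(data.table::rbindlist(spaces))[
      , c("length", "pattern", "support")]
  } else empty_space()
  occurrences <- if (length(occs)) {
    o <- tibble::as_tibble(data.table::rbindlist(occs))
    cols <- c("pattern", "id", if (has_upc) "upc", "start", "end")
    o[, cols]
  } else empty_occurrences()
  list(space = space, occurrences = occurrences)
}

empty_space <- function() {
  tibble::tibble(length = integer(), pattern = character(),
                 support = integer())
}
empty_occurrences <- function() {
  tibble::tibble(pattern = character(), id = character(),
                 start = integer(), end = integer())
}

#' Enumerate the motif space of a query region
#'
#' Empirically enumerates all distinct fixed-position patterns contained in a
#' (masked) query region: for each defined length 2..L, every choice of that
#' many unmasked residues in order with consecutive spacing at most `W + 1`.
#' Duplicate patterns collapse, so the per-length count `M` is the number of
#' distinct patterns — the query-restricted motif space used for the
#' significance correction in query mode.
#'
#' @param region Masked query subsequence (string; masked residues as `X`).
#' @param L Maximum number of defined positions (default 5).
#' @param W Maximum wildcard spacer (default 2).
#' @return A list with `space` (tibble `length`, `pattern`) and `M` (named
#'   integer vector of distinct pattern counts per defined length).
#' @examples
#' enumerate_query_motifs("AAAA", L = 2, W = 2)$space
#' @export
enumerate_query_motifs <- function(region, L = 5L, W = 2L) {
  stopifnot(is.character(region), length(region) == 1)
  n_unmasked <- sum(strsplit(region, "", fixed = TRUE)[[1]] != "X")
  if (nchar(region) < 2 || n_unmasked < 2) {
    stop("query region must contain at least 2 unmasked residues",
         call. = FALSE)
  }
  enum <- enumerate_patterns("query", region, upc = NULL, L = L, W = W,
                             min_support = 0L)
  space <- dplyr::distinct(enum$space[, c("length", "pattern")])
  M <- table(factor(space$length, levels = 2:L))
  list(space = space,
       M = setNames(as.integer(M), names(M)))
}

#' Enumerate over-represented candidate motifs in a dataset
#'
#' Builds all fixed-position patterns with 2..L defined positions and
#' wildcard spacers up to `W` that occur in at least `min_support` distinct
#' unrelated protein clusters. Construction is levelwise: patterns of length
#' `l + 1` are extensions of surviving length-`l` patterns, which is safe
#' because support never increases under extension.
#'
#' @param records Masked records tibble (see [disorder_mask()]; unmasked
#'   records are used as-is).
#' @param partition UPC tibble from [build_upcs()].
#' @param L,W Motif space parameters (defaults 5 and 2).
#' @param min_support Minimum number of supporting UPCs (default 3).
#' @return List with `space` (tibble `length`, `pattern`, `support`) and
#'   `occurrences` (tibble `pattern`, `id`, `upc`, `start`, `end`).
#' @export
enumerate_dataset_motifs <- function(records, partition, L = 5L, W = 2L,
                                     min_support = 3L) {
  records <- ensure_masked(check_records(records))
  if (!all(records$id %in% partition$id)) {
    stop("partition does not cover all records", call. = FALSE)
  }
  upc <- setNames(partition$upc, partition$id)
  enumerate_patterns(records$id, records$masked_sequence, upc = upc,
                     L = L, W = W, min_support = min_support)
}

#' Add ambiguous patterns from an equivalence list
#'
#' Combines fixed patterns that differ at a single defined position into a
#' degenerate pattern with an ambiguity set, when the residues involved all
#' belong to one permitted equivalence group and the merged pattern's UPC
#' support strictly exceeds that of every contributing fixed variant.
#'
#' @param enum Enumeration result from [enumerate_dataset_motifs()].
#' @param equivalences Character vector of permitted groups (default
#'   `c("ILMVF", "FYW", "FYH", "KRH", "DE", "ST")`).
#' @param max_aa Maximum ambiguity set size (default 5).
#' @return The enumeration result with degenerate patterns appended to
#'   `space` (flagged by an `ambiguous` column) and their occurrences added.
#' @export
extend_ambiguity <- function(enum, equivalences = DEFAULT_EQUIVALENCES,
                             max_aa = 5L) {
  groups <- strsplit(equivalences, "", fixed = TRUE)
  for (g in groups) {
    bad <- setdiff(g, AA_ALPHABET)
    if (length(bad) > 0) {
      stop("equivalence group contains non-amino-acid letter(s): ",
           paste(bad, collapse = ""), call. = FALSE)
    }
  }
  space <- enum$space
  occ <- enum$occurrences
  if (nrow(space) == 0) {
    space$ambiguous <- logical(0)
    return(list(space = space, occurrences = occ))
  }
  space$ambiguous <- FALSE
  upc_sets <- split(occ$upc, occ$pattern)
  added_space <- list()
  added_occ <- list()
  for (len in unique(space$length)) {
    all_pats <- space$pattern[space$length == len & !space$ambiguous]
    if (length(all_pats) < 2) next
    # patterns can only merge when they share the same wildcard shape, hence
    # the same rendered width
    for (width in unique(nchar(all_pats))) {
    pats <- all_pats[nchar(all_pats) == width]
    if (length(pats) < 2) next
    cols <- strsplit(pats, "", fixed = TRUE)
    # template = pattern with one defined position blanked
    for (p_idx in seq_len(width)) {
      ch <- vapply(cols, `[`, character(1), p_idx)
      if (all(ch == ".")) next
      same_shape <- ch != "."
      if (!any(same_shape)) next
      templ <- vapply(cols, function(cc) {
        cc2 <- cc; cc2[p_idx] <- "?"; paste(cc2, collapse = "")
      }, character(1))
      for (tmpl in unique(templ[same_shape])) {
        members <- which(templ == tmpl & same_shape)
        if (length(members) < 2) next
        residues <- ch[members]
        for (grp in groups) {
          in_grp <- members[residues %in% grp]
          if (length(in_grp) < 2 || length(in_grp) > max_aa) next
          set <- sort(residues[residues %in% grp])
          merged <- sub("?", paste0("[", paste(set, collapse = ""), "]"),
                        tmpl, fixed = TRUE)
          var_pats <- pats[in_grp]
          var_sup <- vapply(var_pats,
                            function(p) length(unique(upc_sets[[p]])),
                            integer(1))
          merged_sup <- length(unique(unlist(upc_sets[var_pats])))
          if (merged_sup > max(var_sup)) {
            added_space[[length(added_space) + 1L]] <- tibble::tibble(
              length = len, pattern = merged,
              support = as.integer(merged_sup), ambiguous = TRUE)
            mo <- occ[occ$pattern %in% var_pats, , drop = FALSE]
            mo$pattern <- merged
            added_occ[[length(added_occ) + 1L]] <- dplyr::distinct(mo)
          }
        }
      }
    }
    }
  }
  if (length(added_space)) {
    space <- dplyr::bind_rows(space,
                              dplyr::distinct(dplyr::bind_rows(added_space)))
    space <- dplyr::distinct(space, .data$length, .data$pattern,
                             .keep_all = TRUE)
    occ <- dplyr::bind_rows(occ, dplyr::bind_rows(added_occ))
    occ <- dplyr::distinct(occ)
  }
  list(space = space, occurrences = occ)
}
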