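#' Reduce one alignment column to a position definition
#'
#' Applies the specificity-signal rules used to re-derive motif definitions
#' from aligned instances: a residue is accepted when it occurs in at least
#' `min_occ` instances; the position becomes the accepted set only when the
#' accepted residues jointly cover at least `min_freq` of the instances and
#' number at most `max_aa`, otherwise it is a wildcard.
#'
#' @param counts Named integer vector of residue counts for the column.
#' @param n Number of instances in the alignment.
#' @param min_occ Minimum occurrences per accepted residue (default 3).
#' @param min_freq Minimum summed frequency of accepted residues (default
#'   0.75).
#' @param max_aa Maximum residues per defined position (default 5).
#' @return Character vector of accepted residues (sorted), or `"."` for a
#'   wildcard.
#' @examples
#' reduce_position(c(K = 1, R = 4, S = 5, T = 8), 18)  # [RST]
#' @export
reduce_position <- function(counts, n, min_occ = 3L, min_freq = 0.75,
                            max_aa = 5L) {
  if (n == 0) stop("empty alignment column (n = 0)", call. = FALSE)
  stopifnot(sum(counts) <= n)
  accepted <- names(counts)[counts >= min_occ]
  if (length(accepted) == 0 || length(accepted) > max_aa ||
      sum(counts[accepted]) / n < min_freq) {
    return(".")
  }
  sort(accepted)
}

render_columns <- function(cols, nterm = FALSE, cterm = FALSE) {
  body <- vapply(cols, function(s) {
    if (length(s) == 1 && s == ".") "." else
      if (length(s) == 1) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1))
  paste0(if (nterm) "^" else "", paste(body, collapse = ""),
         if (cterm) "$" else "")
}

instance_matches_cols <- function(instance, cols, offset) {
  aa <- strsplit(instance, "", fixed = TRUE)[[1]]
  for (j in seq_along(cols)) {
    s <- cols[[j]]
    if (length(s) == 1 && s == ".") next
    if (!aa[offset + j] %in% s) return(FALSE)
  }
  TRUE
}

#' Induce a motif definition from aligned peptide instances
#'
#' Iterative regex induction: each column of the (gap-free) alignment is
#' reduced with [reduce_position()], leading and trailing wildcards are
#' trimmed, instances that no longer match the reduced motif are removed,
#' and the procedure repeats on the retained subset until every retained
#' instance matches the motif (a fixpoint, reached in at most as many
#' iterations as there are instances). Terminal anchors are added when all
#' retained instances sit at a protein terminus.
#'
#' @param instances Character vector of aligned peptides, all the same
#'   length, over the 20-letter alphabet.
#' @param min_occ,min_freq,max_aa Column reduction parameters (see
#'   [reduce_position()]).
#' @param nterm,cterm Optional logical vectors: does each instance start/end
#'   at its protein's terminus? Anchors `^`/`$` are emitted only when all
#'   retained instances do.
#' @return A list with `pattern` (string, `NA` if irreducible), `retained`
#'   (character vector), `iterations` and `irreducible` (logical: no column
#'   kept a defined position).
#' @examples
#' slimmaker(rep("QTSLF", 18))$pattern
#' @export
slimmaker <- function(instances, min_occ = 3L, min_freq = 0.75, max_aa = 5L,
                      nterm = NULL, cterm = NULL) {
  stopifnot(length(instances) >= 1)
  width <- unique(nchar(instances))
  if (length(width) != 1) {
    stop("aligned instances must all have the same length", call. = FALSE)
  }
  if (is.null(nterm)) nterm <- rep(FALSE, length(instances))
  if (is.null(cterm)) cterm <- rep(FALSE, length(instances))
  retained <- seq_along(instances)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    peps <- instances[retained]
    mat <- do.call(rbind, strsplit(peps, "", fixed = TRUE))
    cols <- lapply(seq_len(width), function(j) {
      tab <- table(mat[, j])
      reduce_position(setNames(as.integer(tab), names(tab)), length(peps),
                      min_occ, min_freq, max_aa)
    })
    is_wild <- vapply(cols, function(s) length(s) == 1 && s == ".",
                      logical(1))
    if (all(is_wild)) {
      return(list(pattern = NA_character_, retained = instances[retained],
                  iterations = iter, irreducible = TRUE))
    }
    first_def <- which(!is_wild)[1]
    last_def <- utils::tail(which(!is_wild), 1)
    anchor_n <- all(nterm[retained]) && length(retained) > 0
    anchor_c <- all(cterm[retained]) && length(retained) > 0
    lo <- if (anchor_n) 1L else first_def
    hi <- if (anchor_c) width else last_def
    trimmed <- cols[lo:hi]
    keep <- retained[vapply(instances[retained], instance_matches_cols,
                            logical(1), cols = trimmed, offset = lo - 1L)]
    if (length(keep) == length(retained)) {
      return(list(pattern = render_columns(trimmed, anchor_n, anchor_c),
                  retained = instances[retained],
                  iterations = iter, irreducible = FALSE))
    }
    if (length(keep) == 0) {
      return(list(pattern = NA_character_, retained = character(0),
                  iterations = iter, irreducible = TRUE))
    }
    retained <- keep
  }
}

#' Compare two motifs by shared information content
#'
#' Slides one motif over the other through every ungapped relative offset
#' (wildcards occupy one column each). At each offset a pair of defined
#' positions matches when their allowed residue sets intersect; the match
#' information content is the summed positional information content of the
#' intersections. The best offset maximises MatchIC. NormIC is MatchIC
#' scaled by the information content of the less informative motif, capped
#' at 1.
#'
#' @param a,b Motif objects or pattern strings.
#' @return One-row tibble: `motif_a`, `motif_b`, `matched_positions`,
#'   `match_ic`, `norm_ic`, `offset`.
#' @export
compare_motifs <- function(a, b) {
  ma <- parse_motif(a); mb <- parse_motif(b)
  ca <- motif_columns(ma); cb <- motif_columns(mb)
  na <- length(ca); nb <- length(cb)
  best <- list(match_ic = 0, matched = 0L, offset = NA_integer_)
  for (off in seq(-(nb - 1L), na - 1L)) {
    ic <- 0; matched <- 0L
    for (i in seq_len(na)) {
      j <- i - off
      if (j < 1 || j > nb) next
      sa <- ca[[i]]; sb <- cb[[j]]
      if (is.null(sa) || is.null(sb)) next
      inter <- intersect(sa, sb)
      if (length(inter) > 0) {
        matched <- matched + 1L
        ic <- ic + position_ic(inter)
      }
    }
    if (ic > best$match_ic ||
        (ic == best$match_ic && matched > best$matched)) {
      best <- list(match_ic = ic, matched = matched, offset = off)
    }
  }
  ic_a <- motif_ic(ma); ic_b <- motif_ic(mb)
  norm <- if (best$match_ic > 0 && min(ic_a, ic_b) > 0) {
    min(1, best$match_ic / min(ic_a, ic_b))
  } else 0
  tibble::tibble(motif_a = format(ma), motif_b = format(mb),
                 matched_positions = best$matched,
                 match_ic = best$match_ic, norm_ic = norm,
                 offset = best$offset)
}

#' Does a comparison qualify as a motif match?
#'
#' A hit counts as a motif match when at least two defined positions match
#' with MatchIC >= 1.5 and NormIC >= 0.5 (at least half the smaller motif
#' matched).
#'
#' @param cmp One-row comparison tibble from [compare_motifs()].
#' @param min_positions,min_match_ic,min_norm_ic Match thresholds.
#' @return Logical.
#' @export
is_motif_match <- function(cmp, min_positions = 2L, min_match_ic = 1.5,
                           min_norm_ic = 0.5) {
  cmp$matched_positions >= min_positions &
    cmp$match_ic >= min_match_ic &
    cmp$norm_ic >= min_norm_ic
}

#' Rate a predicted motif against a motif library
#'
#' Classifies a prediction as TP, OT or FP. The prediction is compared with
#' every library motif; hits matching at least two positions with
#' MatchIC >= 1.5 and NormIC >= 0.5 are motif matches. A match to the motif
#' used to construct the dataset is a true positive (TP). Otherwise the
#' prediction is off-target (OT) when it was registered as a TP in a
#' different dataset, or matches some other library motif under the stricter
#' criteria MatchIC >= 2.5 or NormIC >= 1.0. Everything else is a false
#' positive (FP).
#'
#' @param pattern Predicted pattern string.
#' @param dataset_motif Name of the library motif the dataset was built
#'   from.
#' @param motif_library Tibble with columns `name` and `pattern`.
#' @param tp_registry Character vector of patterns already rated TP in
#'   other datasets (default none).
#' @return A list with `rating` (`"TP"`, `"OT"` or `"FP"`) and `matches`
#'   (comparison tibble of qualifying motif matches).
#' @export
rate_prediction <- function(pattern, dataset_motif, motif_library,
                            tp_registry = character()) {
  stopifnot(nrow(motif_library) > 0,
            all(c("name", "pattern") %in% names(motif_library)))
  cmps <- purrr::map_dfr(seq_len(nrow(motif_library)), function(i) {
    cmp <- compare_motifs(pattern, motif_library$pattern[i])
    cmp$name <- motif_library$name[i]
    cmp
  })
  hits <- cmps[is_motif_match(cmps), , drop = FALSE]
  rating <- if (any(hits$name == dataset_motif)) {
    "TP"
  } else if (pattern %in% tp_registry ||
             any(hits$match_ic >= 2.5 | hits$norm_ic >= 1.0)) {
    if (nrow(hits) > 0 || pattern %in% tp_registry) "OT" else "FP"
  } else {
    "FP"
  }
  list(rating = rating, matches = hits)
}
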