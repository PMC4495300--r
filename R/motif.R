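#' Motif pattern objects
#'
#' Motifs are short patterns of defined positions (a fixed residue or an
#' ambiguity set of 2–5 residues in square brackets) separated by wildcard
#' spacers rendered as `.`, with optional terminal anchors `^` / `$`, e.g.
#' `"Q.[IL].FF"`. `parse_motif()` converts a pattern string into a motif
#' object; `format()`/`as.character()` render it back.
#'
#' @param pattern Pattern string.
#' @return An object of class `slim_motif` with fields `sets` (list of
#'   character vectors, one per defined position), `gaps` (integer wildcard
#'   run lengths between consecutive defined positions), `nterm`, `cterm`.
#' @examples
#' m <- parse_motif("Q.[IL].FF")
#' motif_ic(m)
#' @export
parse_motif <- function(pattern) {
  if (inherits(pattern, "slim_motif")) return(pattern)
  stopifnot(is.character(pattern), length(pattern) == 1, nchar(pattern) > 0)
  s <- pattern
  nterm <- startsWith(s, "^")
  if (nterm) s <- substring(s, 2)
  cterm <- endsWith(s, "$")
  if (cterm) s <- substring(s, 1, nchar(s) - 1)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  sets <- list()
  wild <- integer()   # wildcards seen since last defined position
  pending <- 0L
  i <- 1L
  first <- TRUE
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == ".") {
      pending <- pending + 1L
      i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      grp <- character()
      while (j <= length(chars) && chars[j] != "]") {
        grp <- c(grp, chars[j]); j <- j + 1L
      }
      if (j > length(chars)) stop("unclosed '[' in pattern: ", pattern,
                                  call. = FALSE)
      check_residues(grp, pattern)
      if (length(grp) < 1) stop("empty ambiguity set in pattern: ", pattern,
                                call. = FALSE)
      sets[[length(sets) + 1L]] <- sort(unique(grp))
      wild <- c(wild, pending); pending <- 0L
      i <- j + 1L
    } else {
      check_residues(ch, pattern)
      sets[[length(sets) + 1L]] <- ch
      wild <- c(wild, pending); pending <- 0L
      i <- i + 1L
    }
  }
  if (length(sets) == 0) stop("pattern has no defined positions: ", pattern,
                              call. = FALSE)
  if (wild[1] != 0 && !nterm) {
    # leading wildcards are meaningless without an anchor; keep them only
    # when anchored, otherwise trim
    wild[1] <- 0L
  }
  if (pending > 0 && !cterm) pending <- 0L
  structure(list(sets = sets, gaps = if (length(sets) > 1)
                   wild[-1] else integer(),
                 lead = wild[1], trail = pending,
                 nterm = nterm, cterm = cterm),
            class = "slim_motif")
}

check_residues <- function(x, pattern) {
  bad <- setdiff(x, AA_ALPHABET)
  if (length(bad) > 0) {
    stop("invalid residue(s) ", paste(bad, collapse = ""),
         " in pattern: ", pattern, call. = FALSE)
  }
}

#' @export
format.slim_motif <- function(x, ...) {
  pos <- vapply(x$sets, function(s) {
    if (length(s) == 1) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1))
  gaps <- c(vapply(x$gaps, function(g) strrep(".", g), character(1)), "")
  body <- paste0(paste0(pos, gaps), collapse = "")
  paste0(if (x$nterm) paste0("^", strrep(".", x$lead)) else "",
         body,
         if (x$cterm) paste0(strrep(".", x$trail), "$") else "")
}

#' @export
print.slim_motif <- function(x, ...) {
  cat("<motif> ", format(x), "  (", length(x$sets), " defined, span ",
      motif_span(x), ", IC ", round(motif_ic(x), 3), ")\n", sep = "")
  invisible(x)
}

#' @export
as.character.slim_motif <- function(x, ...) format(x)

#' Total span of a motif in residues
#'
#' Defined positions plus internal wildcard spacers (anchored leading or
#' trailing wildcards included).
#' @param motif Motif object or pattern string.
#' @return Integer span.
#' @export
motif_span <- function(motif) {
  m <- parse_motif(motif)
  length(m$sets) + sum(m$gaps) + m$lead + m$trail
}

#' Number of defined (non-wildcard) positions of a motif
#' @param motif Motif object or pattern string.
#' @return Integer count.
#' @export
motif_length <- function(motif) length(parse_motif(motif)$sets)

#' Information content of one motif position
#'
#' A fixed position scores 1, a wildcard 0, and an ambiguity set of `a`
#' residues `1 - ln(a)/ln(20)`, so that the scale is anchored at "one fixed
#' position = 1".
#'
#' @param allowed Character vector of allowed residues, or `"."` for a
#'   wildcard.
#' @return Numeric information content in \[0, 1\].
#' @export
position_ic <- function(allowed) {
  if (length(allowed) == 1 && allowed == ".") return(0)
  a <- length(unique(allowed))
  if (a < 1) stop("empty residue set", call. = FALSE)
  1 - log(a) / log(20)
}

#' Information content of a motif
#'
#' Sum of [position_ic()] over defined positions; wildcards contribute 0.
#'
#' @param motif Motif object or pattern string.
#' @return Numeric information content.
#' @export
motif_ic <- function(motif) {
  m <- parse_motif(motif)
  sum(vapply(m$sets, position_ic, numeric(1)))
}

# Full column expansion: one list entry per column, NULL for wildcards.
motif_columns <- function(motif) {
  m <- parse_motif(motif)
  cols <- list()
  if (m$lead > 0) cols <- c(cols, rep(list(NULL), m$lead))
  for (i in seq_along(m$sets)) {
    cols[[length(cols) + 1L]] <- m$sets[[i]]
    if (i <= length(m$gaps) && m$gaps[i] > 0) {
      cols <- c(cols, rep(list(NULL), m$gaps[i]))
    }
  }
  if (m$trail > 0) cols <- c(cols, rep(list(NULL), m$trail))
  cols
}

# Translate a motif into a PCRE with a capturing lookahead so that all
# (overlapping) match start positions are found. Wildcards match any letter
# including the mask character X; defined positions are literal sets, which
# never include X.
motif_regex <- function(motif) {
  m <- parse_motif(motif)
  pos <- vapply(m$sets, function(s) {
    if (length(s) == 1) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1))
  gaps <- c(vapply(m$gaps, function(g) strrep(".", g), character(1)), "")
  body <- paste0(strrep(".", m$lead),
                 paste0(paste0(pos, gaps), collapse = ""),
                 strrep(".", m$trail))
  paste0(if (m$nterm) "^" else "",
         "(?=(", body, if (m$cterm) "$" else "", "))")
}

#' Find all occurrences of a motif in masked sequences
#'
#' Matches a motif against the masked sequences of a records tibble.
#' Overlapping matches are reported; defined positions never fall on a
#' masked (`X`) residue, while wildcard spacers may span masked residues.
#'
#' @param motif Motif object or pattern string.
#' @param records Records tibble; the `masked_sequence` column is used when
#'   present, else `sequence`.
#' @return Tibble with columns `id`, `start`, `end`, `match`, `pattern`.
#' @export
find_occurrences <- function(motif, records) {
  records <- ensure_masked(check_records(records))
  m <- parse_motif(motif)
  rx <- motif_regex(m)
  pat <- format(m)
  res <- purrr::map2_dfr(records$id, records$masked_sequence, function(id, s) {
    g <- gregexpr(rx, s, perl = TRUE)[[1]]
    if (g[1] == -1) return(NULL)
    cs <- attr(g, "capture.start")[, 1]
    cl <- attr(g, "capture.length")[, 1]
    tibble::tibble(id = id, start = as.integer(cs),
                   end = as.integer(cs + cl - 1L),
                   match = substring(s, cs, cs + cl - 1L))
  })
  if (nrow(res) == 0) {
    res <- tibble::tibble(id = character(), start = integer(),
                          end = integer(), match = character())
  }
  res$pattern <- rep(pat, nrow(res))
  res
}
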