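#' Read a protein FASTA file into a records tibble
#'
#' Parses a FASTA file into the tabular record collection used throughout the
#' package: one row per sequence with the header token before the first
#' whitespace as the record id. Sequences are upper-cased and any `*`
#' (stop/terminator) characters are stripped.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (character) and `sequence` (character),
#'   one row per FASTA entry.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 some desc", "ACDEF", ">P2", "GHIKL"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) {
    stop("FASTA file is empty: ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  seqs <- gsub("\\*", "", toupper(as.character(aa)))
  tibble::tibble(id = unname(ids), sequence = unname(seqs))
}

#' Write a records tibble to FASTA
#'
#' @param records Tibble with columns `id` and `sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  check_records(records)
  aa <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read a per-residue disorder score table
#'
#' Reads a tab-separated table of per-residue intrinsic disorder scores
#' (IUPred-style, one row per residue): column 1 = protein id, column 2 =
#' 1-based residue index, column 3 = score in \[0, 1\].
#'
#' @param path Path to the TSV file. Lines starting with `#` are ignored; a
#'   header row is detected and skipped if column 2 is non-numeric.
#' @return A tibble with columns `id`, `pos`, `score`.
#' @export
read_disorder <- function(path) {
  if (!file.exists(path)) {
    stop("disorder score file not found: ", path, call. = FALSE)
  }
  dt <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, header = FALSE,
                          col.names = c("id", "pos", "score"))
  if (is.character(dt$pos)) {
    dt <- dt[-1, , drop = FALSE]
    dt$pos <- as.integer(dt$pos)
    dt$score <- as.numeric(dt$score)
  }
  if (any(dt$score < 0 | dt$score > 1, na.rm = TRUE)) {
    stop("disorder scores must lie in [0, 1]", call. = FALSE)
  }
  tibble::as_tibble(dt)
}

#' Write per-residue disorder scores for a records tibble
#'
#' @param records Tibble with `id` and a `disorder` list-column of numeric
#'   score vectors.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_disorder <- function(records, path) {
  check_records(records, need_disorder = TRUE)
  rows <- purrr::map2_dfr(records$id, records$disorder, function(id, sc) {
    tibble::tibble(id = id, pos = seq_along(sc), score = sc)
  })
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Attach disorder scores to a records tibble
#'
#' Joins a disorder score table (as returned by [read_disorder()]) onto a
#' records tibble as a `disorder` list-column, checking that every record
#' receives exactly one score per residue.
#'
#' @param records Records tibble (`id`, `sequence`).
#' @param scores Tibble with columns `id`, `pos`, `score`.
#' @return The records tibble with a `disorder` list-column.
#' @export
attach_disorder <- function(records, scores) {
  check_records(records)
  records$disorder <- purrr::map2(records$id, nchar(records$sequence),
    function(id, len) {
      sc <- scores[scores$id == id, , drop = FALSE]
      if (nrow(sc) == 0) return(NULL)
      if (nrow(sc) != len || !setequal(sc$pos, seq_len(len))) {
        stop("disorder scores for '", id, "' do not cover residues 1..", len,
             call. = FALSE)
      }
      sc$score[order(sc$pos)]
    })
  records
}

# Validate the minimal records contract used by all dataset-level functions.
check_records <- function(records, need_disorder = FALSE) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  if (anyDuplicated(records$id)) {
    stop("duplicate record id(s): ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(nchar(records$sequence) < 1)) {
    stop("all sequences must have length >= 1", call. = FALSE)
  }
  if (need_disorder &&
      (!"disorder" %in% names(records) ||
       any(vapply(records$disorder, is.null, logical(1))))) {
    stop("records lack per-residue disorder scores; supply scores ",
         "(attach_disorder) or disable disorder masking", call. = FALSE)
  }
  invisible(records)
}

#' Smooth a boolean mask by a minimum run length
#'
#' Enforces a minimum length on maximal runs of identical mask state by
#' flipping, left to right, the first run shorter than `min_region` and
#' recomputing runs until no short run remains. A run covering the whole
#' sequence is always allowed.
#'
#' @param mask Logical vector (`TRUE` = masked).
#' @param min_region Minimum run length (default 5).
#' @return Logical vector of the same length.
#' @export
smooth_mask <- function(mask, min_region = 5L) {
  repeat {
    r <- rle(mask)
    if (length(r$lengths) <= 1L) return(mask)
    short <- which(r$lengths < min_region)
    if (length(short) == 0L) return(mask)
    i <- short[1L]
    start <- if (i == 1L) 1L else sum(r$lengths[seq_len(i - 1L)]) + 1L
    end <- start + r$lengths[i] - 1L
    mask[start:end] <- !r$values[i]
  }
}

#' Mask ordered residues by intrinsic disorder score
#'
#' Applies IUPred-style disorder masking to each record: residues whose
#' disorder score falls below `threshold` are masked (replaced by `X`), then
#' the raw mask is smoothed so that every (dis)ordered region spans at least
#' `min_region` residues (see [smooth_mask()]). Motif occurrences never place
#' a defined position on a masked residue; wildcards may span them.
#'
#' @param records Records tibble with a `disorder` list-column.
#' @param threshold Scores below this are masked (default 0.2).
#' @param min_region Minimum (dis)ordered region size in residues (default 5).
#' @return The records tibble with added columns `mask` (list of logical),
#'   `masked_sequence` (character) and `unmasked_count` (integer).
#' @export
disorder_mask <- function(records, threshold = 0.2, min_region = 5L) {
  check_records(records, need_disorder = TRUE)
  out <- purrr::pmap(list(records$sequence, records$disorder),
    function(seq, sc) {
      raw <- sc < threshold
      m <- smooth_mask(raw, min_region)
      s <- strsplit(seq, "", fixed = TRUE)[[1]]
      s[m] <- "X"
      list(mask = m, masked = paste(s, collapse = ""),
           n = sum(!m))
    })
  records$mask <- purrr::map(out, "mask")
  records$masked_sequence <- purrr::map_chr(out, "masked")
  records$unmasked_count <- purrr::map_int(out, ~ as.integer(.x$n))
  records
}

# Ensure records carry a masked_sequence column; identity masking if no
# disorder masking was requested or available.
ensure_masked <- function(records) {
  if (!"masked_sequence" %in% names(records)) {
    records$masked_sequence <- records$sequence
    records$unmasked_count <- nchar(records$sequence)
  }
  records
}

#' Select a query region under a flanking strategy
#'
#' Given a record and a known motif instance span, returns the query region
#' for one of the six flanking strategies used to encode decreasing prior
#' knowledge of the interaction site:
#' \describe{
#'   \item{`none`}{the full-length protein;}
#'   \item{`win300`/`win100`/`win50`}{a 300/100/50-residue window centred on
#'     the instance, shifted to the terminal window when the instance lies
#'     within half a window of a protein end;}
#'   \item{`flank5`}{the instance plus five residues each side, clipped at
#'     the termini;}
#'   \item{`site`}{the instance span exactly.}
#' }
#'
#' @param record One-row records tibble (or list) with `id` and `sequence`.
#' @param strategy One of `"none"`, `"win300"`, `"win100"`, `"win50"`,
#'   `"flank5"`, `"site"`.
#' @param instance Integer vector `c(start, end)`, 1-based inclusive.
#' @return A tibble with columns `id`, `start`, `end`, `strategy`.
#' @export
select_query_region <- function(record, strategy, instance) {
  strategy <- match.arg(strategy,
    c("none", "win300", "win100", "win50", "flank5", "site"))
  id <- record$id[[1]]
  len <- nchar(record$sequence[[1]])
  start <- as.integer(instance[[1]])
  end <- as.integer(instance[[2]])
  if (start < 1 || end > len || start > end) {
    stop("instance (", start, ",", end, ") outside protein '", id,
         "' of length ", len, call. = FALSE)
  }
  reg <- switch(strategy,
    none = c(1L, len),
    site = c(start, end),
    flank5 = c(max(1L, start - 5L), min(len, end + 5L)),
    {
      n <- as.integer(sub("^win", "", strategy))
      if (len <= n) {
        c(1L, len)
      } else {
        centre <- (start + end) %/% 2L
        lo <- centre - n %/% 2L + 1L
        hi <- centre + n %/% 2L
        if (lo < 1L) { lo <- 1L; hi <- n }
        if (hi > len) { hi <- len; lo <- len - n + 1L }
        c(lo, hi)
      }
    })
  tibble::tibble(id = id, start = reg[1], end = reg[2], strategy = strategy)
}

# Parse "PROTID:START-END" query strings used on the command line.
parse_query_spec <- function(spec) {
  m <- regmatches(spec, regexec("^([^:]+)(:([0-9]+)-([0-9]+))?$", spec))[[1]]
  if (length(m) == 0 || m[2] == "") {
    stop("cannot parse query spec '", spec, "' (expected PROTID[:START-END])",
         call. = FALSE)
  }
  list(id = m[2],
       start = if (m[4] == "") NA_integer_ else as.integer(m[4]),
       end = if (m[5] == "") NA_integer_ else as.integer(m[5]))
}
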