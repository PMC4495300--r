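# sample one element of a vector (safe for length-1 vectors, unlike sample())
sample_one <- function(x) x[sample.int(length(x), 1L)]

sample_sequence <- function(len, aa_freqs = AA_BACKGROUND) {
  paste(sample(names(aa_freqs), len, replace = TRUE, prob = aa_freqs),
        collapse = "")
}

mutate_sequence <- function(seq, rate, aa_freqs = AA_BACKGROUND) {
  aa <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(aa)) < rate
  if (any(hit)) {
    aa[hit] <- sample(names(aa_freqs), sum(hit), replace = TRUE,
                      prob = aa_freqs)
  }
  paste(aa, collapse = "")
}

sample_disorder <- function(len, ordered_range = c(20L, 60L),
                            disordered_range = c(15L, 50L)) {
  scores <- numeric(0)
  disordered <- runif(1) < 0.5
  while (length(scores) < len) {
    rng <- if (disordered) disordered_range else ordered_range
    bl <- sample_one(rng[1]:rng[2])
    scores <- c(scores,
                if (disordered) runif(bl, 0.2, 1) else runif(bl, 0, 0.1999))
    disordered <- !disordered
  }
  scores[seq_len(len)]
}

#' Generate a synthetic proteome with disorder annotation
#'
#' Creates a reproducible collection of random protein sequences emulating
#' the background proteome used to assemble benchmark datasets: residues
#' drawn from a Swiss-Prot-like composition, lengths uniform over a range,
#' per-residue disorder scores generated from an alternating block model
#' (ordered blocks scoring below 0.2, disordered blocks at or above 0.2),
#' and optional homologous families created by point-mutating a parent
#' sequence (so that the built-in relatedness scorer clusters them).
#'
#' @param n_proteins Number of singleton proteins (default 100).
#' @param length_range Integer range of sequence lengths (default 150–400).
#' @param aa_freqs Residue frequency profile.
#' @param n_families Number of homologous families to add (default 0).
#' @param family_size Members per family (default 3).
#' @param mutation_rate Per-site substitution rate within a family
#'   (default 0.05).
#' @param ordered_range,disordered_range Block length ranges for the
#'   disorder model.
#' @param seed Integer seed; the proteome is a pure function of the
#'   parameters and this seed.
#' @return Records tibble with `id`, `sequence`, `disorder` (list-column)
#'   and `family` (NA for singletons).
#' @export
generate_proteome <- function(n_proteins = 100L,
                              length_range = c(150L, 400L),
                              aa_freqs = AA_BACKGROUND,
                              n_families = 0L, family_size = 3L,
                              mutation_rate = 0.05,
                              ordered_range = c(20L, 60L),
                              disordered_range = c(15L, 50L),
                              seed = 1L) {
  stopifnot(n_proteins >= 0, n_families >= 0, mutation_rate >= 0,
            mutation_rate <= 1)
  withr::with_seed(seed, {
    rows <- list()
    for (i in seq_len(n_proteins)) {
      len <- sample_one(length_range[1]:length_range[2])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = sprintf("SYN%04d", i),
        sequence = sample_sequence(len, aa_freqs),
        family = NA_character_)
    }
    for (f in seq_len(n_families)) {
      len <- sample_one(length_range[1]:length_range[2])
      parent <- sample_sequence(len, aa_freqs)
      for (m in seq_len(family_size)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          id = sprintf("FAM%02d_%d", f, m),
          sequence = if (m == 1) parent else
            mutate_sequence(parent, mutation_rate, aa_freqs),
          family = sprintf("FAM%02d", f))
      }
    }
    recs <- dplyr::bind_rows(rows)
    recs$disorder <- lapply(nchar(recs$sequence), sample_disorder,
                            ordered_range = ordered_range,
                            disordered_range = disordered_range)
    recs[, c("id", "sequence", "disorder", "family")]
  })
}

#' Implant a concrete motif instance into a disordered region
#'
#' Samples a peptide matching the pattern (ambiguity sets uniformly, each
#' wildcard from the background composition) and writes it over a uniformly
#' chosen position lying wholly inside one disordered block (scores >= 0.2)
#' of the record, recording the instance span.
#'
#' @param record One-row records tibble with `sequence` and `disorder`.
#' @param pattern Motif pattern string.
#' @param aa_freqs Background composition for wildcard positions.
#' @return The record with the instance implanted and columns
#'   `instance_start`, `instance_end` added.
#' @export
implant_instance <- function(record, pattern, aa_freqs = AA_BACKGROUND) {
  m <- parse_motif(pattern)
  span <- motif_span(m)
  sc <- record$disorder[[1]]
  r <- rle(sc >= 0.2)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= span)
  if (length(ok) == 0) {
    stop("record '", record$id, "' has no disordered block of length >= ",
         span, call. = FALSE)
  }
  blk <- sample_one(ok)
  pos <- sample_one(starts[blk]:(ends[blk] - span + 1L))
  cols <- motif_columns(m)
  pep <- vapply(cols, function(s) {
    if (is.null(s)) sample(names(aa_freqs), 1, prob = aa_freqs)
    else s[sample.int(length(s), 1)]
  }, character(1))
  aa <- strsplit(record$sequence, "", fixed = TRUE)[[1]]
  aa[pos:(pos + span - 1L)] <- pep
  record$sequence <- paste(aa, collapse = "")
  record$instance_start <- as.integer(pos)
  record$instance_end <- as.integer(pos + span - 1L)
  record
}

parse_ratio <- function(ratio) {
  if (is.numeric(ratio)) return(as.integer(ratio))
  m <- regmatches(ratio, regexec("^1:([0-9]+)$", ratio))[[1]]
  if (length(m) == 0) {
    stop("signal:noise ratio must be of the form '1:N'", call. = FALSE)
  }
  as.integer(m[2])
}

# Greedily pick `n` mutually unrelated proteins (at most one per family,
# confirmed with the built-in relatedness scorer) from shuffled candidates.
pick_unrelated <- function(records, n, evalue_threshold = 1e-4) {
  chosen <- integer(0)
  fams <- character(0)
  for (i in sample.int(nrow(records))) {
    fam <- records$family[i]
    if (!is.na(fam) && fam %in% fams) next
    ok <- all(vapply(chosen, function(j) {
      !pairwise_related(records$sequence[i], records$sequence[j],
                        evalue_threshold)$related
    }, logical(1)))
    if (ok) {
      chosen <- c(chosen, i)
      if (!is.na(fam)) fams <- c(fams, fam)
      if (length(chosen) == n) return(chosen)
    }
  }
  stop("insufficient unrelated eligible proteins (needed ", n, ")",
       call. = FALSE)
}

#' Build one simulated benchmark dataset pair
#'
#' Assembles a positive dataset of `signal` mutually unrelated
#' motif-implanted proteins (one of which is the query) completed with
#' `noise = signal * multiplier` random proteins, and its paired true
#' negative: the same query with the same total number of randomly selected
#' proteins and no further implants.
#'
#' @param motif Pattern string to implant.
#' @param proteome Records tibble from [generate_proteome()].
#' @param signal Number of motif-bearing proteins including the query
#'   (5 or 10 in the benchmark design).
#' @param ratio Signal-to-noise ratio as `"1:N"` (one of 1:0, 1:1, 1:4,
#'   1:9, 1:19) or the integer multiplier `N`.
#' @param seed Integer seed for this dataset.
#' @return List with `positive` and `negative` records tibbles (columns
#'   `role`, `instance_start`, `instance_end` where applicable), `query`
#'   (id), `motif`, `seed`.
#' @export
build_simbench <- function(motif, proteome, signal = 10L, ratio = "1:0",
                           seed = 1L) {
  mult <- parse_ratio(ratio)
  span <- motif_span(motif)
  withr::with_seed(seed, {
    eligible <- proteome[vapply(proteome$disorder, function(sc) {
      r <- rle(sc >= 0.2)
      any(r$values & r$lengths >= span)
    }, logical(1)), , drop = FALSE]
    if (nrow(eligible) < signal) {
      stop("insufficient unrelated eligible proteins (needed ", signal, ")",
           call. = FALSE)
    }
    sig_idx <- pick_unrelated(eligible, signal)
    sig <- eligible[sig_idx, , drop = FALSE]
    sig <- dplyr::bind_rows(lapply(seq_len(nrow(sig)), function(i) {
      implant_instance(sig[i, , drop = FALSE], motif)
    }))
    query_id <- sample_one(sig$id)
    sig$role <- ifelse(sig$id == query_id, "query", "signal")
    n_noise <- signal * mult
    pool <- proteome[!proteome$id %in% sig$id, , drop = FALSE]
    if (nrow(pool) < n_noise) {
      stop("proteome too small for ", n_noise, " noise proteins",
           call. = FALSE)
    }
    noise <- pool[sample.int(nrow(pool), n_noise), , drop = FALSE]
    if (nrow(noise) > 0) noise$role <- "noise"
    positive <- dplyr::bind_rows(sig, noise)

    total <- signal * (1L + mult)
    qrow <- sig[sig$id == query_id, , drop = FALSE]
    pool_neg <- proteome[proteome$id != query_id, , drop = FALSE]
    others <- pool_neg[sample.int(nrow(pool_neg), total - 1L), , drop = FALSE]
    if (nrow(others) > 0) others$role <- "random"
    negative <- dplyr::bind_rows(qrow, others)
    list(positive = positive, negative = negative, query = query_id,
         motif = motif, seed = seed)
  })
}

#' Expand an annotated dataset into benchmark search jobs
#'
#' For datasets of known motif-bearing proteins, every record is taken in
#' turn as the query and expanded across the requested flanking strategies,
#' yielding one search job description per (query, strategy).
#'
#' @param records Records tibble with `instance_start` / `instance_end`
#'   annotation columns.
#' @param strategies Flanking strategies (default all six).
#' @return Tibble with columns `query_id`, `strategy`, `start`, `end`.
#' @export
build_elmbench <- function(records,
                           strategies = c("none", "win300", "win100",
                                          "win50", "flank5", "site")) {
  check_records(records)
  if (!all(c("instance_start", "instance_end") %in% names(records)) ||
      any(is.na(records$instance_start))) {
    stop("every record needs an annotated motif instance span", call. = FALSE)
  }
  purrr::map_dfr(seq_len(nrow(records)), function(i) {
    rec <- records[i, , drop = FALSE]
    purrr::map_dfr(strategies, function(st) {
      reg <- select_query_region(rec, st,
                                 c(rec$instance_start, rec$instance_end))
      tibble::tibble(query_id = rec$id, strategy = st,
                     start = reg$start, end = reg$end)
    })
  })
}

#' Run a search over one benchmark dataset and rate the outcome
#'
#' Executes [slim_search()] on a dataset, takes the top-ranked cloud's
#' representative motif (the benchmark convention) and rates it against a
#' motif library.
#'
#' @param dataset Records tibble.
#' @param dataset_motif Name of the library motif the dataset was built
#'   from.
#' @param motif_library Tibble (`name`, `pattern`).
#' @param query Query spec passed to [slim_search()] (`NULL` for dataset
#'   mode).
#' @param tp_registry Patterns already rated TP in other datasets.
#' @param ... Further arguments to [slim_search()].
#' @return One-row tibble: `rating` (`"TP"`/`"OT"`/`"FP"`/`"none"`),
#'   `pattern`, `sig`, `n_significant`.
#' @export
rate_search <- function(dataset, dataset_motif, motif_library, query = NULL,
                        tp_registry = character(), ...) {
  fit <- slim_search(dataset, query = query, ...)
  if (nrow(fit$clouds) == 0) {
    return(tibble::tibble(rating = "none", pattern = NA_character_,
                          sig = NA_real_, n_significant = 0L))
  }
  rep_pat <- fit$clouds$representative[fit$clouds$cloud == 1]
  r <- rate_prediction(rep_pat, dataset_motif, motif_library, tp_registry)
  tibble::tibble(rating = r$rating, pattern = rep_pat,
                 sig = fit$significant$sig[fit$significant$pattern == rep_pat][1],
                 n_significant = nrow(fit$significant))
}

#' Sensitivity and false-positive metrics over rated datasets
#'
#' SN is the proportion of positive datasets whose rated outcome is a true
#' positive; FPX is the proportion of negative datasets returning a false
#' positive. Off-target (OT) outcomes count in neither numerator. With
#' `normalise_by`, values are first computed per group (e.g. per motif) and
#' then averaged, so motifs with unequal dataset counts weigh equally.
#'
#' @param ratings Tibble with at least `type` (`"positive"`/`"negative"`)
#'   and `rating` (`"TP"`/`"OT"`/`"FP"`/`"none"`).
#' @param group_vars Character vector of grouping columns for the output
#'   cells (default none: one overall row).
#' @param normalise_by Optional column (e.g. `"motif"`) to average over
#'   after computing per-group values.
#' @return Tibble with columns `sn`, `fpx`, `n_positive`, `n_negative` per
#'   group. Cells with no datasets of the relevant type are `NA`.
#' @export
compute_metrics <- function(ratings, group_vars = character(),
                            normalise_by = NULL) {
  cell <- function(d) {
    pos <- d[d$type == "positive", , drop = FALSE]
    neg <- d[d$type == "negative", , drop = FALSE]
    tibble::tibble(
      sn = if (nrow(pos) == 0) NA_real_ else mean(pos$rating == "TP"),
      fpx = if (nrow(neg) == 0) NA_real_ else mean(neg$rating == "FP"),
      n_positive = nrow(pos), n_negative = nrow(neg))
  }
  if (!is.null(normalise_by)) {
    per <- dplyr::group_modify(
      dplyr::group_by(ratings,
                      dplyr::across(dplyr::all_of(c(group_vars,
                                                    normalise_by)))),
      ~ cell(.x))
    per <- dplyr::ungroup(per)
    out <- dplyr::summarise(
      dplyr::group_by(per, dplyr::across(dplyr::all_of(group_vars))),
      sn = mean(.data$sn, na.rm = TRUE),
      fpx = mean(.data$fpx, na.rm = TRUE),
      n_positive = sum(.data$n_positive),
      n_negative = sum(.data$n_negative),
      .groups = "drop")
    return(out)
  }
  if (length(group_vars) == 0) return(cell(ratings))
  dplyr::ungroup(dplyr::group_modify(
    dplyr::group_by(ratings, dplyr::across(dplyr::all_of(group_vars))),
    ~ cell(.x)))
}
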