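# Prefix of a fixed pattern string truncated to its first `l` defined
# positions (patterns here are letters and '.' wildcards only).
pattern_prefix <- function(pats, l) {
  vapply(pats, function(p) {
    ch <- strsplit(p, "", fixed = TRUE)[[1]]
    idx <- which(ch != ".")
    paste(ch[seq_len(idx[l])], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Search a protein dataset for over-represented short linear motifs
#'
#' Runs the full discovery pipeline: disorder masking (when scores are
#' present), clustering into unrelated protein clusters, candidate motif
#' enumeration, support counting, the three-cycle binomial significance
#' model, filtering at the significance cutoff, and clustering of
#' overlapping results into clouds.
#'
#' Two modes are available. In dataset mode (no `query`) candidates are all
#' patterns reaching `min_support` clusters and the motif space `M` per
#' defined length is `motif_space_size(l, W)`. In query mode a query protein
#' (or region) defines the candidate space: only patterns occurring in the
#' query region are assessed, `M` is the number of distinct query patterns
#' of each length, and the query's cluster is removed from the dataset, so
#' support `k` of `n` becomes `k - 1` of `n - 1`.
#'
#' @param records Records tibble (`id`, `sequence`, optional `disorder`
#'   list-column).
#' @param query `NULL` for dataset mode, else a query spec: a string
#'   `"PROTID"` or `"PROTID:START-END"`, or a list with `id`, `start`,
#'   `end`. Without coordinates the whole protein is the query region.
#' @param L Maximum defined positions per motif (default 5).
#' @param W Maximum wildcard spacer length (default 2).
#' @param min_support Minimum UPC support for a reportable motif, counted
#'   including the query's cluster in query mode (default 3).
#' @param sig_cutoff Significance cutoff for reported motifs (default 0.1).
#' @param ambiguity Merge fixed patterns into ambiguous ones using the
#'   default equivalence groups (default `FALSE`).
#' @param cloudfix Drop clouds whose significant members are all ambiguous
#'   (default `FALSE`).
#' @param mask `"disorder"` to apply disorder masking when scores are
#'   present, `"none"` to search unmasked sequences (default `"disorder"`).
#' @param disorder_threshold,min_region Masking parameters passed to
#'   [disorder_mask()].
#' @param edges Optional precomputed relatedness edge tibble; computed with
#'   the built-in scorer when `NULL`.
#' @param evalue_threshold Relatedness threshold for the built-in scorer.
#' @param equivalences Equivalence groups for `ambiguity = TRUE`.
#' @param seed Optional integer recorded with the run (the search itself is
#'   deterministic).
#' @return An object of class `slim_search`; see [tidy.slim_search()],
#'   [glance.slim_search()], [autoplot.slim_search()].
#' @examples
#' recs <- tibble::tibble(
#'   id = paste0("P", 1:4),
#'   sequence = paste0(c("AAAGG", "CCWGG", "TTAGG", "MMKGG"), "DWFCT",
#'                     c("HHHH", "EEEE", "RRRR", "KKKK")))
#' fit <- slim_search(recs, min_support = 4, sig_cutoff = 1)
#' head(tidy(fit))
#' @export
slim_search <- function(records, query = NULL, L = 5L, W = 2L,
                        min_support = 3L, sig_cutoff = 0.1,
                        ambiguity = FALSE, cloudfix = FALSE,
                        mask = c("disorder", "none"),
                        disorder_threshold = 0.2, min_region = 5L,
                        edges = NULL, evalue_threshold = 1e-4,
                        equivalences = DEFAULT_EQUIVALENCES, seed = NULL) {
  mask <- match.arg(mask)
  stopifnot(sig_cutoff > 0, sig_cutoff <= 1)
  check_records(records)
  has_disorder <- "disorder" %in% names(records) &&
    !any(vapply(records$disorder, is.null, logical(1)))
  if (mask == "disorder" && has_disorder) {
    records <- disorder_mask(records, disorder_threshold, min_region)
  } else {
    records <- ensure_masked(records)
  }
  if (all(records$unmasked_count == 0)) {
    stop("all residues are masked; no searchable sequence remains",
         call. = FALSE)
  }
  if (is.null(edges)) {
    edges <- relatedness_edges(records, evalue_threshold)
  }
  partition <- build_upcs(records, edges)
  n_upc_total <- max(partition$upc)

  mode <- if (is.null(query)) "slimfinder" else "qslimfinder"
  if (mode == "slimfinder") {
    enum <- enumerate_dataset_motifs(records, partition, L, W, min_support)
    if (ambiguity) enum <- extend_ambiguity(enum, equivalences)
    space <- enum$space
    stat_records <- records
    stat_partition <- partition
    M_of <- function(l) motif_space_size(l, W)
    query_info <- NULL
  } else {
    query_info <- normalise_query(query, records)
    q_id <- query_info$id
    if (!q_id %in% records$id) {
      stop("query id '", q_id, "' not found in dataset", call. = FALSE)
    }
    q_row <- records[records$id == q_id, ]
    q_start <- query_info$start
    q_end <- query_info$end
    if (is.na(q_start)) { q_start <- 1L; q_end <- nchar(q_row$sequence) }
    region <- substring(q_row$masked_sequence, q_start, q_end)
    qspace <- enumerate_query_motifs(region, L, W)
    q_upc <- partition$upc[partition$id == q_id]
    rest_ids <- partition$id[partition$upc != q_upc]
    if (length(rest_ids) == 0) {
      stop("no clusters remain after removing the query's cluster",
           call. = FALSE)
    }
    stat_records <- records[records$id %in% rest_ids, ]
    stat_partition <- partition[partition$id %in% rest_ids, ]
    upc_map <- setNames(stat_partition$upc, stat_partition$id)
    allowed <- lapply(split(qspace$space$pattern, qspace$space$length),
                      identity)
    enum <- enumerate_patterns(
      stat_records$id, stat_records$masked_sequence, upc = upc_map,
      L = L, W = W, min_support = max(0L, min_support - 1L),
      allowed = allowed)
    if (ambiguity) enum <- extend_ambiguity(enum, equivalences)
    space <- enum$space
    M_of <- function(l) {
      m <- qspace$M[as.character(l)]
      if (is.na(m) || m < 1) 1L else m
    }
  }

  results <- score_space(space, enum$occurrences, stat_records,
                         stat_partition, M_of, W)
  results$mode <- mode
  results <- rank_results(results)
  significant <- results[results$sig <= sig_cutoff, , drop = FALSE]
  occ_sig <- enum$occurrences[
    enum$occurrences$pattern %in% significant$pattern, , drop = FALSE]
  clouds <- build_clouds(significant, occ_sig)
  if (cloudfix) {
    clouds <- apply_cloudfix(clouds, significant, sig_cutoff)
  }
  significant <- dplyr::left_join(significant, clouds$membership,
                                  by = "pattern")
  if (cloudfix) {
    significant <- significant[!is.na(significant$cloud), , drop = FALSE]
  }
  structure(list(
    results = results,
    significant = significant,
    clouds = clouds$clouds,
    occurrences = enum$occurrences,
    partition = partition,
    n_upc_total = n_upc_total,
    query = query_info,
    params = list(L = L, W = W, min_support = min_support,
                  sig_cutoff = sig_cutoff, ambiguity = ambiguity,
                  cloudfix = cloudfix, mask = mask,
                  disorder_threshold = disorder_threshold,
                  min_region = min_region,
                  evalue_threshold = evalue_threshold, seed = seed,
                  mode = mode)),
    class = "slim_search")
}

normalise_query <- function(query, records) {
  if (is.character(query)) query <- parse_query_spec(query)
  stopifnot(!is.null(query$id))
  list(id = query$id,
       start = if (is.null(query$start)) NA_integer_ else
         as.integer(query$start),
       end = if (is.null(query$end)) NA_integer_ else as.integer(query$end))
}

# Attach the significance model to an enumerated space.
score_space <- function(space, occurrences, records, partition, M_of, W) {
  if (nrow(space) == 0) {
    return(tibble::tibble(pattern = character(), length = integer(),
                          span = integer(), support = integer(),
                          n_upc = integer(), p_site = numeric(),
                          mean_p1 = numeric(), prob = numeric(),
                          M = numeric(), sig = numeric()))
  }
  records <- ensure_masked(records)
  freqs <- aa_frequencies(records)
  segs <- unmasked_segments(records$masked_sequence)
  upc <- partition$upc[match(records$id, partition$id)]
  n_upc <- length(unique(upc))
  spans <- vapply(space$pattern, motif_span, numeric(1), USE.NAMES = FALSE)
  p_sites <- vapply(space$pattern, site_probability, numeric(1),
                    aa_freqs = freqs, USE.NAMES = FALSE)
  sites_by_span <- lapply(
    setNames(unique(spans), unique(spans)),
    function(s) upc_site_counts(segs, upc, s))
  mean_p1 <- numeric(nrow(space))
  prob <- numeric(nrow(space))
  for (i in seq_len(nrow(space))) {
    sites <- sites_by_span[[as.character(spans[i])]]
    p1 <- upc_p1(p_sites[i], sites)
    mean_p1[i] <- mean(p1)
    prob[i] <- support_probability(space$support[i], p1)
  }
  M <- vapply(space$length, M_of, numeric(1))
  sig <- mapply(significance, prob, M)
  tibble::tibble(pattern = space$pattern,
                 length = as.integer(space$length),
                 span = as.integer(spans),
                 support = as.integer(space$support),
                 n_upc = as.integer(n_upc),
                 p_site = p_sites, mean_p1 = mean_p1, prob = prob,
                 M = as.numeric(M), sig = as.numeric(sig))
}

# Deterministic ranking: Sig ascending, then support desc, defined length
# desc, span desc, pattern lexicographic.
rank_results <- function(results) {
  o <- order(results$sig, -results$support, -results$length,
             -results$span, results$pattern, method = "radix")
  results <- results[o, , drop = FALSE]
  results$rank <- seq_len(nrow(results))
  results
}

#' Cluster overlapping result motifs into clouds
#'
#' Two motifs share a cloud edge when one pattern contains the other as a
#' sub-pattern (rendered string containment) or their occurrence sets share
#' at least two (protein, overlapping interval) instances. Clouds are the
#' connected components of that graph; each cloud's representative is its
#' top-ranked member.
#'
#' @param results Ranked results tibble (needs `pattern`, `rank`).
#' @param occurrences Occurrence tibble for those patterns.
#' @return List with `clouds` (tibble `cloud`, `representative`, `size`,
#'   `has_fixed`) and `membership` (tibble `pattern`, `cloud`).
#' @export
build_clouds <- function(results, occurrences) {
  pats <- results$pattern
  if (length(pats) == 0) {
    return(list(
      clouds = tibble::tibble(cloud = integer(), representative = character(),
                              size = integer(), has_fixed = logical()),
      membership = tibble::tibble(pattern = character(), cloud = integer())))
  }
  occ_by <- split(occurrences[, c("id", "start", "end")], occurrences$pattern)
  n <- length(pats)
  edges <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      a <- pats[i]; b <- pats[j]
      linked <- grepl(a, b, fixed = TRUE) || grepl(b, a, fixed = TRUE)
      if (!linked) {
        oa <- occ_by[[a]]; ob <- occ_by[[b]]
        if (!is.null(oa) && !is.null(ob)) {
          jj <- dplyr::inner_join(oa, ob, by = "id",
                                  relationship = "many-to-many")
          ov <- jj[jj$start.x <= jj$end.y & jj$start.y <= jj$end.x, ,
                   drop = FALSE]
          shared_a <- nrow(dplyr::distinct(ov[, c("id", "start.x")]))
          shared_b <- nrow(dplyr::distinct(ov[, c("id", "start.y")]))
          linked <- min(shared_a, shared_b) >= 2
        }
      }
      if (linked) edges[[length(edges) + 1L]] <- c(i, j)
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) {
    g <- igraph::add_edges(g, unlist(edges))
  }
  comp <- igraph::components(g)$membership
  # order clouds by best (lowest) rank of their members
  best_rank <- vapply(split(results$rank, comp), min, numeric(1))
  cloud_order <- order(best_rank)
  renum <- match(comp, as.integer(names(best_rank))[cloud_order])
  membership <- tibble::tibble(pattern = pats, cloud = renum)
  clouds <- dplyr::summarise(
    dplyr::group_by(dplyr::left_join(results, membership, by = "pattern"),
                    .data$cloud),
    representative = .data$pattern[which.min(.data$rank)],
    size = dplyr::n(),
    has_fixed = any(!grepl("[", .data$pattern, fixed = TRUE)),
    .groups = "drop")
  clouds <- clouds[order(clouds$cloud), , drop = FALSE]
  list(clouds = clouds, membership = membership)
}

#' Remove clouds with no significant fixed-position member
#'
#' Implements the `cloudfix` filter: ambiguous motifs are retained only when
#' a fixed-position pattern in the same cloud is itself significant.
#'
#' @param clouds Cloud structure from [build_clouds()].
#' @param results Significant results tibble.
#' @param sig_cutoff Significance cutoff.
#' @return The filtered cloud structure.
#' @export
apply_cloudfix <- function(clouds, results, sig_cutoff = 0.1) {
  if (nrow(clouds$clouds) == 0) return(clouds)
  mem <- dplyr::left_join(clouds$membership, results[, c("pattern", "sig")],
                          by = "pattern")
  keep <- vapply(split(mem, mem$cloud), function(d) {
    any(!grepl("[", d$pattern, fixed = TRUE) & d$sig <= sig_cutoff,
        na.rm = TRUE)
  }, logical(1))
  keep_ids <- as.integer(names(keep))[keep]
  list(clouds = clouds$clouds[clouds$clouds$cloud %in% keep_ids, ,
                              drop = FALSE],
       membership = clouds$membership[clouds$membership$cloud %in% keep_ids, ,
                                      drop = FALSE])
}

#' @export
print.slim_search <- function(x, ...) {
  cat("Short linear motif search (", x$params$mode, ")\n", sep = "")
  cat("  proteins: ", nrow(x$partition), " in ", x$n_upc_total,
      " unrelated clusters\n", sep = "")
  if (!is.null(x$query)) {
    cat("  query: ", x$query$id,
        if (!is.na(x$query$start))
          paste0(":", x$query$start, "-", x$query$end), "\n", sep = "")
  }
  cat("  candidates assessed: ", nrow(x$results), "; significant (Sig <= ",
      x$params$sig_cutoff, "): ", nrow(x$significant), " in ",
      nrow(x$clouds), " cloud(s)\n", sep = "")
  if (nrow(x$significant) > 0) {
    print(utils::head(x$significant[, c("rank", "pattern", "support",
                                        "n_upc", "prob", "sig", "cloud")],
                      10))
  }
  invisible(x)
}

#' Tidy a motif search into a tibble of per-motif results
#'
#' @param x A `slim_search` object.
#' @param all Return all assessed candidates (`TRUE`) or only significant
#'   ones with cloud assignments (default).
#' @param ... Unused.
#' @return A tibble with one row per motif: pattern, defined length, span,
#'   support `k`, cluster count `n`, per-site probability, mean `p1+`,
#'   support probability `Prob`, motif space `M`, significance `Sig`, rank
#'   and (for significant motifs) cloud id.
#' @export
tidy.slim_search <- function(x, all = FALSE, ...) {
  if (all) x$results else x$significant
}

#' One-row summary of a motif search
#'
#' @param x A `slim_search` object.
#' @param ... Unused.
#' @return A one-row tibble: mode, protein and cluster counts, candidate,
#'   significant and cloud counts, and the best significance reached.
#' @export
glance.slim_search <- function(x, ...) {
  tibble::tibble(
    mode = x$params$mode,
    n_proteins = nrow(x$partition),
    n_upc = x$n_upc_total,
    n_candidates = nrow(x$results),
    n_significant = nrow(x$significant),
    n_clouds = nrow(x$clouds),
    best_sig = if (nrow(x$results)) min(x$results$sig) else NA_real_)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot the significance profile of a motif search
#'
#' Ranked motifs against their significance estimate on a log scale, with
#' the cutoff drawn and significant motifs highlighted by cloud.
#'
#' @param object A `slim_search` object.
#' @param max_motifs Cap on the number of top-ranked motifs drawn (default
#'   50).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.slim_search <- function(object, max_motifs = 50, ...) {
  d <- utils::head(tidy(object, all = TRUE), max_motifs)
  if (nrow(d) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "No candidate motifs assessed"))
  }
  mem <- object$significant[, c("pattern", "cloud")]
  d <- dplyr::left_join(d, mem, by = "pattern")
  d$cloud <- ifelse(is.na(d$cloud), "ns", as.character(d$cloud))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = pmax(.data$sig, 1e-300),
                                  colour = .data$cloud)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$params$sig_cutoff,
                        linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "rank", y = "Sig", colour = "cloud",
                  title = paste0("Motif significance (",
                                 object$params$mode, ")")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write search results to tab-separated files
#'
#' Writes `results.tsv` (all assessed candidates with significance and cloud
#' columns), `occurrences.tsv` and `run.log` (parameter echo) into a
#' directory.
#'
#' @param x A `slim_search` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_search <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- dplyr::left_join(
    tidy(x, all = TRUE),
    x$significant[, c("pattern", "cloud")], by = "pattern")
  write_tsv_c <- function(d, path) {
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_tsv_c(res, file.path(dir, "results.tsv"))
  write_tsv_c(x$occurrences, file.path(dir, "occurrences.tsv"))
  p <- x$params
  writeLines(c(
    paste0("# slimq ", as.character(utils::packageVersion("slimq"))),
    paste0("mode = ", p$mode),
    paste0("L = ", p$L), paste0("W = ", p$W),
    paste0("min_support = ", p$min_support),
    paste0("sig_cutoff = ", p$sig_cutoff),
    paste0("ambiguity = ", p$ambiguity),
    paste0("cloudfix = ", p$cloudfix),
    paste0("mask = ", p$mask),
    paste0("seed = ", if (is.null(p$seed)) "NA" else p$seed),
    if (!is.null(x$query)) paste0(
      "query = ", x$query$id,
      if (!is.na(x$query$start)) paste0(":", x$query$start, "-",
                                        x$query$end) else "")),
    file.path(dir, "run.log"))
  invisible(dir)
}
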