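# A small implanted dataset used across the discovery tests: unrelated
# random proteins all carrying a fixed 5-mer in a disordered context.
implanted_dataset <- function(n = 8, len = 120, motif = "DWFCT", seed = 71) {
  withr::with_seed(seed, {
    recs <- make_records(replicate(n, random_seq(len)))
    recs$disorder <- lapply(seq_len(n), function(i) rep(0.9, len))
    pos <- sample(20:(len - 20), n)
    recs$sequence <- vapply(seq_len(n), function(i) {
      aa <- strsplit(recs$sequence[i], "", fixed = TRUE)[[1]]
      aa[pos[i]:(pos[i] + 4)] <- strsplit(motif, "", fixed = TRUE)[[1]]
      paste(aa, collapse = "")
    }, character(1))
    recs$instance_start <- pos
    recs$instance_end <- pos + 4L
    recs
  })
}

test_that("an implanted motif is recovered at rank 1 in query mode", {
  recs <- implanted_dataset()
  q <- recs[1, ]
  fit <- slim_search(recs,
                     query = sprintf("%s:%d-%d", q$id, q$instance_start,
                                     q$instance_end),
                     sig_cutoff = 0.1)
  expect_equal(fit$params$mode, "qslimfinder")
  top <- tidy(fit)[1, ]
  expect_equal(top$pattern, "DWFCT")
  expect_lte(top$sig, 0.1)
  # the query UPC is sacrificed: support and clusters drop by one
  expect_equal(top$support, 7L)
  expect_equal(top$n_upc, 7L)
  # hand-check the binomial pipeline for the top pattern
  expect_equal(top$prob,
               cumulative_binomial(7, 7, top$mean_p1), tolerance = 1e-12)
  expect_equal(top$sig, significance(top$prob, top$M), tolerance = 1e-12)
  # every reported motif matches the query region
  qreg <- substring(q$sequence, q$instance_start, q$instance_end)
  for (p in tidy(fit)$pattern) {
    expect_gte(nrow(find_occurrences(p, make_records(qreg))), 1)
  }
})

test_that("patterns absent from the query are not candidates", {
  recs <- implanted_dataset()
  # replace the query's instance so the motif is absent from the query
  aa <- strsplit(recs$sequence[1], "", fixed = TRUE)[[1]]
  aa[recs$instance_start[1]:(recs$instance_end[1])] <- c("P", "P", "G", "P", "G")
  recs$sequence[1] <- paste(aa, collapse = "")
  fit <- slim_search(recs,
                     query = sprintf("%s:%d-%d", recs$id[1],
                                     recs$instance_start[1],
                                     recs$instance_end[1]),
                     sig_cutoff = 1)
  expect_false("DWFCT" %in% tidy(fit, all = TRUE)$pattern)
})

test_that("dataset mode recovers the implant with the full space correction", {
  recs <- implanted_dataset()
  fit <- slim_search(recs, sig_cutoff = 0.1)
  res <- tidy(fit, all = TRUE)
  top <- res[res$pattern == "DWFCT", ]
  expect_equal(top$support, 8L)
  expect_equal(top$n_upc, 8L)
  expect_equal(top$M, motif_space_size(5, 2))
  # query mode reaches a better significance despite losing an occurrence
  q <- recs[1, ]
  qfit <- slim_search(recs, query = sprintf("%s:%d-%d", q$id,
                                            q$instance_start,
                                            q$instance_end))
  qs <- tidy(qfit, all = TRUE)
  expect_lte(qs$sig[qs$pattern == "DWFCT"], top$sig)
})

test_that("ranking is monotone in Sig with deterministic tie-breaks", {
  recs <- implanted_dataset()
  fit <- slim_search(recs)
  res <- tidy(fit, all = TRUE)
  expect_true(all(diff(res$sig) >= 0))
  expect_equal(res$rank, seq_len(nrow(res)))
})

test_that("repeated runs are identical", {
  recs <- implanted_dataset()
  f1 <- slim_search(recs, seed = 99)
  f2 <- slim_search(recs, seed = 99)
  expect_identical(tidy(f1, all = TRUE), tidy(f2, all = TRUE))
  expect_identical(f1$clouds, f2$clouds)
})

test_that("zero remaining clusters is an error", {
  recs <- make_records(c("ACDEFGHIKLMNP", "ACDEFGHIKLMNP"),
                       ids = c("A", "B"))
  edges <- tibble::tibble(id_a = "A", id_b = "B", evalue = 0)
  expect_error(slim_search(recs, query = "A", edges = edges), "cluster")
  expect_error(slim_search(recs, query = "ZZ", edges = edges), "ZZ")
})

test_that("clouds join sub-patterns and overlapping instances", {
  res <- tibble::tibble(pattern = c("LIG", "LIGE", "WWW"),
                        rank = 1:3, sig = c(1e-6, 1e-5, 1e-4))
  occ <- tibble::tibble(
    pattern = c("LIG", "LIG", "LIGE", "LIGE", "WWW", "WWW"),
    id = c("P1", "P2", "P1", "P2", "P3", "P4"),
    start = c(5L, 9L, 5L, 9L, 2L, 2L),
    end = c(7L, 11L, 8L, 12L, 4L, 4L))
  cl <- build_clouds(res, occ)
  expect_equal(nrow(cl$clouds), 2)
  m <- setNames(cl$membership$cloud, cl$membership$pattern)
  expect_equal(m[["LIG"]], m[["LIGE"]])
  expect_false(m[["WWW"]] == m[["LIG"]])
  expect_equal(cl$clouds$representative[cl$clouds$cloud == m[["LIG"]]],
               "LIG")
})

test_that("chained overlaps form one cloud", {
  res <- tibble::tibble(pattern = c("AB.D", "ABC", "BCD"),
                        rank = 1:3, sig = rep(1e-4, 3))
  # A~B and B~C share >= 2 overlapping instances; A and C do not directly
  occ <- tibble::tibble(
    pattern = rep(c("AB.D", "ABC", "BCD"), each = 2),
    id = rep(c("P1", "P2"), 3),
    start = c(1L, 1L, 1L, 1L, 2L, 2L),
    end = c(4L, 4L, 3L, 3L, 4L, 4L))
  cl <- build_clouds(res, occ)
  expect_equal(nrow(cl$clouds), 1)
  expect_equal(cl$clouds$size, 3L)
})

test_that("cloudfix removes all-ambiguous clouds", {
  res <- tibble::tibble(pattern = c("[LM]IG", "LIG"), rank = 1:2,
                        sig = c(0.01, 0.02))
  occ <- tibble::tibble(pattern = c("[LM]IG", "LIG"), id = c("P1", "P1"),
                        start = c(3L, 3L), end = c(5L, 5L))
  cl <- build_clouds(res, occ)
  kept <- apply_cloudfix(cl, res, 0.1)
  expect_equal(nrow(kept$clouds), 1)

  res2 <- res[1, ]
  cl2 <- build_clouds(res2, occ[1, ])
  kept2 <- apply_cloudfix(cl2, res2, 0.1)
  expect_equal(nrow(kept2$clouds), 0)

  res3 <- tibble::tibble(pattern = c("LIG", "[LM]IG"), rank = 1:2,
                         sig = c(0.01, 0.5))
  cl3 <- build_clouds(res3, occ)
  kept3 <- apply_cloudfix(cl3, res3, 0.1)
  expect_equal(nrow(kept3$clouds), 1)
})

test_that("tidy, glance and autoplot work on fitted searches", {
  recs <- implanted_dataset()
  fit <- slim_search(recs)
  g <- glance(fit)
  expect_equal(g$n_proteins, 8L)
  expect_equal(g$mode, "slimfinder")
  expect_s3_class(tidy(fit), "tbl_df")
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("search results round-trip to TSV output", {
  recs <- implanted_dataset()
  fit <- slim_search(recs)
  dir <- withr::local_tempdir()
  write_search(fit, dir)
  expect_true(file.exists(file.path(dir, "results.tsv")))
  res <- utils::read.table(file.path(dir, "results.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  expect_equal(nrow(res), nrow(tidy(fit, all = TRUE)))
  expect_true("DWFCT" %in% res$pattern)
})
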