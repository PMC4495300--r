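test_that("proteome generation is reproducible and respects its parameters", {
  p1 <- generate_proteome(n_proteins = 10, seed = 81)
  p2 <- generate_proteome(n_proteins = 10, seed = 81)
  expect_identical(p1, p2)
  p3 <- generate_proteome(n_proteins = 10, seed = 82)
  expect_false(identical(p1$sequence, p3$sequence))
  expect_true(all(nchar(p1$sequence) >= 150 & nchar(p1$sequence) <= 400))
  expect_true(all(vapply(seq_len(10), function(i) {
    length(p1$disorder[[i]]) == nchar(p1$sequence[i])
  }, logical(1))))
  expect_true(all(unlist(p1$disorder) >= 0 & unlist(p1$disorder) < 1))
})

test_that("singleton proteins are mutually unrelated, families cluster", {
  prot <- generate_proteome(n_proteins = 10, n_families = 1,
                            family_size = 3, mutation_rate = 0.05,
                            seed = 83)
  part <- build_upcs(prot, relatedness_edges(prot))
  fam <- part$upc[grepl("^FAM", part$id)]
  expect_equal(length(unique(fam)), 1)
  singles <- part$upc[!grepl("^FAM", part$id)]
  expect_equal(length(unique(singles)), 10)
})

test_that("implanted instances sit in disordered blocks and match the pattern", {
  prot <- generate_proteome(n_proteins = 5, seed = 84)
  withr::with_seed(85, {
    for (pat in c("DWFCT", "Q.[IL].FF")) {
      rec <- implant_instance(prot[1, ], pat)
      span <- rec$instance_start:rec$instance_end
      pep <- substring(rec$sequence, rec$instance_start, rec$instance_end)
      expect_gte(nrow(find_occurrences(pat, make_records(pep))), 1)
      expect_true(all(rec$disorder[[1]][span] >= 0.2))
      expect_equal(nchar(rec$sequence), nchar(prot$sequence[1]))
    }
  })
  # no eligible block
  rec <- prot[1, ]
  rec$disorder <- list(rep(0, nchar(rec$sequence)))
  expect_error(implant_instance(rec, "DWFCT"), "disordered block")
})

test_that("simulated dataset pairs have the designed composition", {
  prot <- generate_proteome(n_proteins = 60, seed = 86)
  ds <- build_simbench("DWFCT", prot, signal = 5, ratio = "1:0", seed = 87)
  expect_equal(nrow(ds$positive), 5)
  expect_equal(sum(ds$positive$role == "query"), 1)
  expect_equal(nrow(ds$negative), 5)
  expect_equal(ds$negative$id[ds$negative$role == "query"], ds$query)
  # signal proteins pairwise unrelated
  part <- build_upcs(ds$positive, relatedness_edges(ds$positive))
  expect_equal(max(part$upc), 5)
  # every signal protein carries the implant
  for (i in seq_len(nrow(ds$positive))) {
    expect_gte(nrow(find_occurrences("DWFCT", ds$positive[i, ])), 1)
  }
  # noise sizing: 10 signal at 1:9 gives 100 proteins
  prot2 <- generate_proteome(n_proteins = 120, seed = 88)
  ds2 <- build_simbench("DWFCT", prot2, signal = 10, ratio = "1:9",
                        seed = 89)
  expect_equal(nrow(ds2$positive), 100)
  expect_equal(nrow(ds2$negative), 100)
  expect_equal(sum(ds2$positive$role %in% c("query", "signal")), 10)
})

test_that("ratio parsing accepts the benchmark grid", {
  prot <- generate_proteome(n_proteins = 30, seed = 90)
  ds <- build_simbench("DWFCT", prot, signal = 5, ratio = "1:1", seed = 91)
  expect_equal(nrow(ds$positive), 10)
  expect_error(build_simbench("DWFCT", prot, signal = 5, ratio = "2:1"),
               "1:N")
})

test_that("insufficient eligible proteins raise an error", {
  prot <- generate_proteome(n_proteins = 3, seed = 92)
  expect_error(build_simbench("DWFCT", prot, signal = 5, ratio = "1:0",
                              seed = 93),
               "insufficient unrelated")
})

test_that("benchmark jobs expand each record across the six strategies", {
  prot <- generate_proteome(n_proteins = 7, seed = 94)
  withr::with_seed(95, {
    recs <- dplyr::bind_rows(lapply(seq_len(7), function(i) {
      implant_instance(prot[i, ], "DWFCT")
    }))
  })
  jobs <- build_elmbench(recs)
  expect_equal(nrow(jobs), 42)
  site <- jobs[jobs$strategy == "site", ]
  expect_equal(site$start, recs$instance_start)
  expect_equal(site$end, recs$instance_end)
  none <- jobs[jobs$strategy == "none", ]
  expect_equal(none$start, rep(1L, 7))
  expect_equal(none$end, nchar(recs$sequence))
  expect_error(build_elmbench(prot), "instance")
})

test_that("metrics aggregate ratings with OT ignored", {
  ratings <- tibble::tibble(
    type = c(rep("positive", 10), rep("negative", 10)),
    rating = c(rep("TP", 7), "OT", "FP", "none",
               rep("none", 9), "OT"))
  m <- compute_metrics(ratings)
  expect_equal(m$sn, 0.7)
  expect_equal(m$fpx, 0)
  # per-motif normalisation is a mean of means
  ratings2 <- tibble::tibble(
    motif = c(rep("A", 4), rep("B", 2)),
    type = "positive",
    rating = c("TP", "TP", "TP", "TP", "TP", "none"))
  m2 <- compute_metrics(ratings2, normalise_by = "motif")
  expect_equal(m2$sn, 0.75)
  # empty cells are NA, not zero
  m3 <- compute_metrics(ratings2)
  expect_true(is.na(m3$fpx))
})

test_that("rate_search rates the top cloud of a search", {
  recs <- {
    withr::with_seed(96, {
      prot <- generate_proteome(n_proteins = 40, seed = 96)
      build_simbench("DWFCT", prot, signal = 8, ratio = "1:0", seed = 97)
    })
  }
  lib <- tibble::tibble(name = "MOT_A", pattern = "DWFCT")
  q <- recs$positive[recs$positive$role == "query", ]
  out <- rate_search(recs$positive, dataset_motif = "MOT_A",
                     motif_library = lib,
                     query = sprintf("%s:%d-%d", q$id, q$instance_start,
                                     q$instance_end),
                     sig_cutoff = 0.05)
  expect_equal(out$rating, "TP")
  expect_lte(out$sig, 0.05)
})
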