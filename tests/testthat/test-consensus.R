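test_that("center-star alignment handles identical and gapped inputs", {
  a <- build_msa_center_star(c(x = "ACGTACGTAA", y = "ACGTACGTAA",
                               z = "ACGTACGTAA"))
  expect_true(all(!grepl("-", a$rows, fixed = TRUE)))
  expect_equal(length(unique(nchar(a$rows))), 1)

  # a 4-base insertion in one member forces a gap block in the frame
  base <- "ACGTTTACGGATCCA"
  ins <- paste0(substr(base, 1, 7), "GGGG", substr(base, 8, nchar(base)))
  b <- build_msa_center_star(c(m = base, n = ins, o = base))
  expect_equal(length(unique(nchar(b$rows))), 1)
  expect_true(any(grepl("-", b$rows, fixed = TRUE)))
  expect_error(build_msa_center_star(c(only = "ACGT")), "at least 2")
})

test_that("majority consensus applies the tie order and drops gappy columns", {
  aln <- structure(list(family_id = "f", ids = c("a", "b", "c"),
                        rows = c(a = "AAC", b = "AAC", c = "ACC"),
                        center = "a"), class = "copy_alignment")
  expect_equal(majority_consensus(aln)$seq, "AAC")

  # two-way tie in a column resolves A < C < G < T
  tie <- structure(list(family_id = "f", ids = c("a", "b"),
                        rows = c(a = "AT", b = "CT"), center = "a"),
                   class = "copy_alignment")
  expect_equal(majority_consensus(tie)$seq, "AT")

  # a column with >50% gaps is dropped
  gappy <- structure(list(family_id = "f", ids = c("a", "b", "c"),
                          rows = c(a = "A-G", b = "A-G", c = "ACG"),
                          center = "a"), class = "copy_alignment")
  expect_equal(majority_consensus(gappy)$seq, "AG")
})

test_that("majority consensus is invariant to row order", {
  set.seed(71)
  master <- random_dna(150)
  seqs <- setNames(vapply(1:8, function(i) mutate_copy_k2p(master, 0.08),
                          character(1)), paste0("s", 1:8))
  c1 <- majority_consensus(build_msa_center_star(seqs))
  c2 <- majority_consensus(build_msa_center_star(rev(seqs)))
  expect_identical(c1$seq, c2$seq)
})

test_that("consensus reconstruction recovers the master sequence", {
  set.seed(81)
  for (rep in 1:12) {
    master <- random_dna(263)
    d <- runif(1, 0.02, 0.10)
    seqs <- setNames(vapply(1:20, function(i) mutate_copy_k2p(master, d),
                            character(1)), sprintf("c%02d", 1:20))
    aln <- build_msa_center_star(seqs)
    # substitution-only copies: the frame should stay near the master length
    expect_lte(abs(nchar(aln$rows[[1]]) - 263) / 263, 0.05)
    cons <- majority_consensus(aln)
    k <- min(nchar(cons$seq), 263)
    matches <- sum(strsplit(cons$seq, "")[[1]][seq_len(k)] ==
                     strsplit(master, "")[[1]][seq_len(k)])
    expect_gte(matches / 263, 0.99)
  }
})

test_that("empty-site refinement recovers boundaries and the TSD verbatim", {
  set.seed(91)
  L <- random_dna(500)
  R <- random_dna(500)
  tsd <- random_dna(13)
  sine <- random_dna(263)
  filled <- paste0(L, tsd, sine, tsd, R)
  empty <- paste0(L, tsd, R)
  res <- refine_boundaries_empty_site(filled, empty)
  expect_equal(res$status, "ok")
  expect_equal(unname(res$element["start"]), 513)
  expect_equal(unname(res$element["end"]), 513 + 263)
  expect_equal(res$tsd$length, 13)
  expect_equal(res$tsd$left, tsd)
  expect_equal(res$tsd$right, tsd)
  expect_equal(res$tsd$mismatches, 0)
})

test_that("empty-site refinement handles no-insertion and unrelated sites", {
  set.seed(92)
  site <- random_dna(1200)
  res <- refine_boundaries_empty_site(site, site)
  expect_equal(res$status, "ok")
  expect_null(res$tsd)
  expect_equal(unname(res$element["end"] - res$element["start"]), 0)

  unrelated <- random_dna(1200)
  filled <- paste0(random_dna(500), random_dna(263), random_dna(500))
  res2 <- refine_boundaries_empty_site(filled, unrelated)
  expect_equal(res2$status, "no_orthologous_site")
  expect_null(res2$element)
})

test_that("TSD detection finds the longest near-exact duplication", {
  up <- paste0(random_dna(30), "GGATTCACTAAG")
  down <- paste0("GGATTCACTAAG", random_dna(30))
  set.seed(93)
  t1 <- detect_tsd(up, down)
  expect_equal(t1$length, 12)
  expect_equal(t1$mismatches, 0)

  expect_null(detect_tsd(random_dna(40), random_dna(40)))

  # a 4-bp duplication is below the minimum length
  up4 <- paste0(random_dna(30), "GGAT")
  down4 <- paste0("GGAT", random_dna(30))
  expect_null(detect_tsd(up4, down4))
})

test_that("TSD detection agrees with the brute-force oracle", {
  set.seed(94)
  for (rep in 1:60) {
    up <- random_dna(40)
    down <- random_dna(40)
    if (rep %% 2 == 0) {
      k <- sample(5:15, 1)
      dup <- random_dna(k)
      up <- paste0(substr(up, 1, 40 - k), dup)
      down <- paste0(dup, substr(down, k + 1, 40))
    }
    got <- detect_tsd(up, down)
    want <- oracle_tsd_len(up, down)
    if (is.null(want)) expect_null(got)
    else expect_equal(got$length, want)
  }
})
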