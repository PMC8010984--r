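make_implant_genome <- function(bg_len, query, positions, d = 0,
                                strands = NULL, seed = 1) {
  set.seed(seed)
  bg <- random_dna(bg_len)
  if (length(positions) == 0) return(c(chr1 = bg))
  if (is.null(strands)) strands <- rep("+", length(positions))
  segs <- character(0)
  prev <- 0
  for (k in order(positions)) {
    copy <- mutate_copy_k2p(query, d)
    if (strands[k] == "-") copy <- revcomp(copy)
    segs <- c(segs, substr(bg, prev + 1, positions[k]), copy)
    prev <- positions[k]
  }
  c(chr1 = paste(c(segs, substr(bg, prev + 1, bg_len)), collapse = ""))
}

test_that("an exact implant is found once with exact boundaries", {
  set.seed(11)
  q <- random_dna(200)
  gen <- make_implant_genome(50000, q, 10000, seed = 12)
  h <- seed_and_extend_search(q, gen, min_id = 0.8, min_len = 100)
  expect_equal(nrow(h), 1)
  expect_equal(h$identity, 1.0)
  expect_equal(h$strand, "+")
  expect_lte(abs(h$start - 10000), 2)
  expect_lte(abs(h$end - 10200), 2)

  # same implant reverse-complemented: same locus, minus strand
  gen2 <- make_implant_genome(50000, q, 10000, strands = "-", seed = 12)
  h2 <- seed_and_extend_search(q, gen2, min_id = 0.8, min_len = 100)
  expect_equal(nrow(h2), 1)
  expect_equal(h2$strand, "-")
  expect_lte(abs(h2$start - 10000), 2)
})

test_that("a random genome yields no qualifying hits", {
  set.seed(21)
  q <- random_dna(263)
  gen <- c(chr1 = random_dna(50000))
  h <- seed_and_extend_search(q, gen, min_id = 0.80, min_len = 100)
  expect_equal(nrow(h), 0)
})

test_that("queries shorter than the seed word are rejected", {
  expect_error(seed_and_extend_search("ACGTACGT", c(chr = random_dna(1000)),
                                      min_id = 0.8, min_len = 5),
               "word_size")
})

test_that("search matches the exhaustive local-alignment oracle", {
  for (seed in c(31, 32)) {
    set.seed(seed)
    q <- random_dna(263)
    npos <- sample(0:3, 1)
    pos <- sort(sample(seq(2000, 18000, by = 600), npos))
    gen <- make_implant_genome(20000, q, pos,
                               d = runif(1, 0, 0.12),
                               strands = sample(c("+", "-"), npos, TRUE),
                               seed = seed + 100)
    mine <- seed_and_extend_search(q, gen, min_id = 0.8, min_len = 100)
    oracle <- oracle_local_hits(q, gen, min_id = 0.8, min_len = 100)
    expect_equal(nrow(mine), nrow(oracle))
    if (nrow(mine) > 0) {
      expect_true(all(abs(mine$start - oracle$start) <= 2))
      expect_true(all(abs(mine$end - oracle$end) <= 2))
      expect_true(all(abs(mine$identity - oracle$identity) <= 0.01))
      expect_identical(mine$strand, oracle$strand)
    }
  }
})

test_that("results are invariant to contig order and genome orientation", {
  set.seed(41)
  q <- random_dna(200)
  g1 <- make_implant_genome(15000, q, 5000, d = 0.05, seed = 42)[[1]]
  g2 <- make_implant_genome(12000, q, 3000, d = 0.05, strands = "-",
                            seed = 43)[[1]]
  gen <- c(a = g1, b = g2)
  h <- seed_and_extend_search(q, gen, min_id = 0.8, min_len = 100)
  h_perm <- seed_and_extend_search(q, gen[c("b", "a")],
                                   min_id = 0.8, min_len = 100)
  expect_equal(h[order(h$contig, h$start), ],
               h_perm[order(h_perm$contig, h_perm$start), ])

  # reverse-complementing a contig flips strands and mirrors coordinates
  rc <- c(a = revcomp(g1))
  h_a <- h[h$contig == "a", ]
  h_rc <- seed_and_extend_search(q, rc, min_id = 0.8, min_len = 100)
  expect_equal(nrow(h_rc), nrow(h_a))
  expect_true(all(h_rc$strand != h_a$strand))
  expect_equal(sort(nchar(g1) - h_a$end), sort(h_rc$start))
  expect_equal(h_rc$identity, h_a$identity, tolerance = 1e-9)
})

test_that("overlap merging keeps the higher-identity hit", {
  base <- data.frame(contig = "c", strand = "+", qcov = 1,
                     qstart = 0L, qend = 100L, seq = "A")
  two <- rbind(
    cbind(base, start = 100L, end = 300L, identity = 0.9, aln_len = 200L),
    cbind(base, start = 150L, end = 350L, identity = 0.85, aln_len = 200L))
  m <- merge_overlapping_hits(two)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 100L)

  dup <- rbind(two[1, ], two[1, ])
  expect_equal(nrow(merge_overlapping_hits(dup)), 1)
})

test_that("overlap merging equals brute-force greedy resolution", {
  set.seed(51)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    start <- sample.int(2000, n)
    len <- sample(80:250, n, TRUE)
    hits <- data.frame(contig = sample(c("c1", "c2"), n, TRUE),
                       start = start, end = start + len,
                       strand = sample(c("+", "-"), n, TRUE),
                       identity = round(runif(n, 0.8, 1), 4),
                       aln_len = len, qcov = 1, qstart = 0L, qend = 100L,
                       seq = "A")
    got <- merge_overlapping_hits(hits)
    # brute force: drop hits contained in a longer same-strand hit, then
    # accept by decreasing identity unless >50%-of-shorter overlap with an
    # accepted hit on the same contig+strand
    drop <- vapply(seq_len(nrow(hits)), function(i) any(
      hits$contig == hits$contig[i] & hits$strand == hits$strand[i] &
        hits$start <= hits$start[i] & hits$end >= hits$end[i] &
        hits$aln_len > hits$aln_len[i]), logical(1))
    hits <- hits[!drop, , drop = FALSE]
    ord <- order(-hits$identity, -hits$aln_len, hits$start)
    acc <- list()
    for (i in ord) {
      ok <- TRUE
      for (a in acc) {
        if (hits$contig[i] != hits$contig[a] ||
            hits$strand[i] != hits$strand[a]) next
        ov <- min(hits$end[i], hits$end[a]) - max(hits$start[i], hits$start[a])
        sh <- min(hits$end[i] - hits$start[i], hits$end[a] - hits$start[a])
        if (ov > 0.5 * sh) { ok <- FALSE; break }
      }
      if (ok) acc <- c(acc, i)
    }
    want <- hits[unlist(acc), ]
    want <- want[order(want$contig, want$start, want$end), ]
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("copy counting enforces length and ambiguous-head exclusion", {
  set.seed(61)
  cons <- random_dna(263)
  bg <- random_dna(30000)
  # one full copy, one 90-bp fragment, one 120-bp head-only fragment,
  # one 180-bp fragment extending past the ambiguous head
  gen <- c(chr1 = paste0(substr(bg, 1, 5000), cons,
                         substr(bg, 5001, 12000), substr(cons, 1, 90),
                         substr(bg, 12001, 19000), substr(cons, 1, 120),
                         substr(bg, 19001, 26000), substr(cons, 1, 180),
                         substr(bg, 26001, 30000)))
  cc <- count_copies(cons, gen, ambiguous_region = c(0L, 120L))
  # full copy and the [0,180) fragment survive; the 90-bp hit fails the
  # length rule and the head-only hit falls inside the ambiguous region
  # (alignment ends may wobble a base or two into the flanks)
  expect_equal(cc$n, 2)
  lens <- sort(cc$copies$aln_len)
  expect_lte(abs(lens[1] - 180L), 3)
  expect_lte(abs(lens[2] - 263L), 3)

  cc_no_excl <- count_copies(cons, gen)
  expect_equal(cc_no_excl$n, 3)
  expect_error(count_copies(substr(cons, 1, 90), gen), ">= 100")
})

test_that("divergence-set selection applies both identity and coverage", {
  copies <- data.frame(contig = "c", start = c(0L, 300L), end = c(263L, 510L),
                       strand = "+", identity = c(0.95, 0.95),
                       aln_len = c(263L, 208L), qcov = c(1.0, 0.79),
                       qstart = 0L, qend = c(263L, 208L), seq = "A")
  kept <- select_divergence_set("x", copies)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$qcov, 1.0)
  low_id <- copies[1, ]
  low_id$identity <- 0.79
  expect_equal(nrow(select_divergence_set("x", low_id)), 0)
})
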