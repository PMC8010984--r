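# plant motif instances into a random head at known offsets
plant <- function(len, at, motifs) {
  s <- strsplit(random_dna(len), "")[[1]]
  for (i in seq_along(at)) {
    m <- strsplit(motifs[i], "")[[1]]
    s[(at[i] + 1):(at[i] + length(m))] <- m
  }
  paste(s, collapse = "")
}

# motif-free background: every default box motif mismatches a CCA repeat at
# >= 3 informative positions in every phase, so a planted (possibly mutated)
# box is the unique best-scoring candidate
plant_clean <- function(len, at, motifs) {
  s <- strsplit(substr(strrep("CCA", ceiling(len / 3)), 1, len), "")[[1]]
  for (i in seq_along(at)) {
    m <- strsplit(motifs[i], "")[[1]]
    s[(at[i] + 1):(at[i] + length(m))] <- m
  }
  paste(s, collapse = "")
}

A_BOX <- "TGGCTCAATGCG"   # instance of TRGCNNARYNNG
B_BOX <- "GTTCGAACC"      # instance of GWTCRANNC
IE_BOX <- "GATTGGG"       # instance of GRYTGGG
C_BOX <- "AGGTCGATGC"     # instance of RGGTCGANNC

test_that("planted promoter boxes are recovered at exact coordinates", {
  set.seed(111)
  head2 <- plant(300, c(8, 55), c(A_BOX, B_BOX))
  r2 <- scan_pol3_boxes(head2)
  expect_equal(r2$type, "pol3_type2")
  expect_equal(r2$boxes$start, c(8, 55))

  head1 <- plant(300, c(10, 35, 55), c(A_BOX, IE_BOX, C_BOX))
  r1 <- scan_pol3_boxes(head1)
  expect_equal(r1$type, "pol3_type1")
  expect_equal(r1$boxes$start, c(10, 35, 55))
})

test_that("boxes survive up to two informative-position mismatches", {
  set.seed(112)
  for (rep in 1:20) {
    a <- strsplit(A_BOX, "")[[1]]
    # mutate 2 informative positions of the A box (positions of exact bases)
    inf <- c(1, 3, 4, 7, 12)
    pick <- sample(inf, 2)
    for (p in pick) a[p] <- sample(setdiff(c("A", "C", "G", "T"), a[p]), 1)
    head2 <- plant_clean(300, c(8, 55), c(paste(a, collapse = ""), B_BOX))
    r <- scan_pol3_boxes(head2)
    expect_equal(r$type, "pol3_type2")
    expect_equal(r$boxes$start[1], 8)
  }
})

test_that("random sequences rarely produce a promoter architecture", {
  set.seed(113)
  n_none <- 0
  trials <- 300
  for (i in seq_len(trials)) {
    r <- scan_pol3_boxes(random_dna(300))
    if (r$type == "none") n_none <- n_none + 1
  }
  expect_gte(n_none / trials, 0.95)
})

test_that("head classification uses identity with a box-agreement rescue", {
  refs <- synthetic_head_refs()
  set.seed(114)
  body <- random_dna(150)
  cons_t <- paste0(refs$seq[refs$class == "tRNA"], body)
  call_t <- classify_head(cons_t, refs)
  expect_equal(call_t$origin, "tRNA")
  expect_equal(call_t$head_identity, 1.0)

  # heavily mutated 5S head: ~37% of sites substituted, mirrors a ~63%
  # identity call
  head5 <- strsplit(refs$seq[refs$class == "5S_rRNA"], "")[[1]]
  idx <- sample(length(head5), round(0.37 * length(head5)))
  for (p in idx) head5[p] <- sample(setdiff(c("A", "C", "G", "T"), head5[p]), 1)
  cons_5 <- paste0(paste(head5, collapse = ""), body)
  call_5 <- classify_head(cons_5, refs)
  expect_equal(call_5$origin, "5S_rRNA")
  expect_gt(call_5$head_identity, 0.5)
  expect_lt(call_5$head_identity, 0.8)

  # unrelated head without boxes stays unknown
  call_u <- classify_head(paste0(random_dna(150), body), refs)
  expect_equal(call_u$origin, "unknown")
})

test_that("head classification is invariant to reference order and labels", {
  refs <- synthetic_head_refs()
  set.seed(115)
  cons <- paste0(refs$seq[1], random_dna(150))
  a <- classify_head(cons, refs)
  b <- classify_head(cons, refs[2:1, ])
  expect_equal(a$origin, b$origin)
  expect_equal(a$head_identity, b$head_identity)

  swapped <- refs
  swapped$class <- rev(swapped$class)
  # identity >= floor, so the call follows the (now swapped) class label
  expect_equal(classify_head(cons, swapped)$origin, "5S_rRNA")
})

test_that("tail repeats are reported as canonical primitive units", {
  set.seed(116)
  gt <- detect_tail_repeat(paste0(random_dna(200), "ACTGTGTGTGTGT"))
  expect_equal(gt$unit, "GT")
  expect_gte(gt$n_units, 5)

  atgt <- detect_tail_repeat(paste0(random_dna(200), "ATGTATGTATGTATGT"))
  expect_equal(atgt$unit, "ATGT")
  expect_equal(atgt$n_units, 4)

  expect_null(detect_tail_repeat(random_dna(260)))

  # a non-primitive unit collapses to its period
  atat <- detect_tail_repeat(paste0(random_dna(200), "ATATATATATAT"))
  expect_equal(atat$unit, "AT")
})

test_that("tail detection equals the exhaustive brute-force search", {
  set.seed(117)
  units <- c("G", "GT", "TAT", "ATGT", "TGTTA", "CGAAAT")
  for (rep in 1:80) {
    s <- random_dna(200)
    if (rep %% 2 == 0) {
      u <- sample(units, 1)
      k <- sample(3:8, 1)
      s <- paste0(s, paste(rep(u, k), collapse = ""), random_dna(sample(0:4, 1)))
    }
    got <- detect_tail_repeat(s)
    want <- oracle_tail(s)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$length, want$len)
      expect_equal(got$purity, want$pur)
    }
  }
})
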