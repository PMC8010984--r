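test_that("p-distance matrix is symmetric with a zero diagonal", {
  set.seed(141)
  a <- random_dna(150)
  b <- a
  substr(b, 11, 12) <- "TT"  # at most 2 differences
  D <- consensus_p_distance_matrix(c(x = a, y = a, z = b))
  expect_equal(D["x", "y"], 0)
  expect_true(isSymmetric(D))
  expect_equal(unname(diag(D)), c(0, 0, 0))
  expect_lte(D["x", "z"], 2 / 150)

  # hand-built pair: 2 differences over 10 aligned sites
  p <- "ACGTACGTAC"
  q <- "ACGTACGTGG"
  D2 <- consensus_p_distance_matrix(c(p = p, q = q))
  expect_equal(D2["p", "q"], 0.2)
})

test_that("p-distance matrix equals a brute-force per-pair recount", {
  set.seed(142)
  root <- random_dna(180)
  cons <- setNames(vapply(1:6, function(i)
    mutate_copy_k2p(root, runif(1, 0, 0.25)), character(1)),
    paste0("f", 1:6))
  D <- consensus_p_distance_matrix(cons)
  for (i in 1:5) for (j in (i + 1):6) {
    # no indels: global alignment is the identity mapping
    x <- strsplit(cons[[i]], "")[[1]]
    y <- strsplit(cons[[j]], "")[[1]]
    expect_equal(D[i, j], mean(x != y))
  }
})

test_that("NJ recovers additive and clonal topologies", {
  # additive distances on ((a,b),(c,d))
  D <- matrix(c(0, 3, 9, 9,
                3, 0, 10, 10,
                9, 10, 0, 4,
                9, 10, 4, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tree <- nj_tree_with_bootstrap(D)
  expect_identical(tree_bipartitions(tree),
                   canonicalize_splits(list(c("a", "b")), letters[1:4]))

  set.seed(143)
  root <- random_dna(200)
  clone <- root
  far1 <- mutate_copy_k2p(root, 0.25)
  far2 <- mutate_copy_k2p(far1, 0.25)
  seqs <- c(c1 = root, c2 = clone, o1 = far1, o2 = far2)
  tr <- nj_tree_with_bootstrap(seqs, n_boot = 100, seed = 5)
  expect_identical(tree_bipartitions(tr),
                   canonicalize_splits(list(c("c1", "c2")), names(seqs)))
  expect_true(all(tr$node.label >= 0.99, na.rm = TRUE))
})

test_that("NJ topology matches an independent implementation", {
  set.seed(144)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    labs <- paste0("t", seq_len(n))
    # random tree-free dissimilarities, symmetrized
    M <- matrix(runif(n * n, 0.05, 1), n, n)
    D <- (M + t(M)) / 2
    diag(D) <- 0
    dimnames(D) <- list(labs, labs)
    tree <- nj_tree_with_bootstrap(D)
    expect_identical(tree_bipartitions(tree), oracle_nj_bipartitions(D))
  }
})

test_that("partner-LINE search finds a tail-sharing ORF-bearing element", {
  cfg <- simulation_config(
    genome_bp = 300000, n_genes = 5,
    families = list(family_spec(n_copies = 5, age = list(type = "burst", d = 0.03))),
    partner_line = list(family = "fam1", identity = 0.84, tail_bp = 43),
    seed = 145)
  sim <- generate_genome_with_families(cfg)
  master <- sim$masters[["fam1"]]
  tailq <- substr(master, nchar(master) - 49, nchar(master))
  cands <- find_partner_line_candidates(tailq, sim$genome)
  # the implanted LINE: >= 2 kb upstream of its tail, long ORF
  line_truth <- sim$truth[sim$truth$family == ".partner_line", ]
  ok <- cands$contig == line_truth$contig &
    abs(cands$end - line_truth$end) < 60
  expect_true(any(ok))
  best <- cands[which(ok)[1], ]
  expect_gte(best$tail_identity, 0.75)
  expect_lte(best$tail_identity, 0.95)
  expect_true(best$orf_ok)
  expect_gte(best$length, 2000)

  # a genome without shared tails yields nothing
  set.seed(146)
  empty <- find_partner_line_candidates(tailq,
                                        c(chr = random_dna(50000)))
  expect_equal(nrow(empty), 0)
})

test_that("ORF screening separates intact from frame-disrupted elements", {
  set.seed(147)
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  open <- setdiff(codons, c("TAA", "TAG", "TGA"))
  orf <- paste0("ATG", paste(sample(open, 249, TRUE), collapse = ""))
  expect_gte(sinescout:::longest_orf_codons(orf), 200)
  # a stop codon every 30 codons caps every frame-0 open run below 200
  broken <- orf
  for (at in seq(91, nchar(orf) - 3, by = 90))
    substr(broken, at, at + 2) <- "TAA"
  expect_lt(sinescout:::longest_orf_codons(broken), 200)
})

test_that("HTT flagging combines identity and host relatedness", {
  tax <- data.frame(
    species = c("moth_a", "moth_b", "beetle", "virus_x"),
    genus = c("Plutella", "Plutella", "Tribolium", "Alphabaculovirus"),
    family = c("Plutellidae", "Plutellidae", "Tenebrionidae", "Baculoviridae"),
    order = c("Lepidoptera", "Lepidoptera", "Coleoptera", "Lefavirales"),
    kingdom = c("Animalia", "Animalia", "Animalia", "Viruses"))
  set.seed(148)
  root <- random_dna(263)
  near <- mutate_copy_k2p(root, 0.02)        # ~95% identity
  cons <- data.frame(
    family = c("fA", "fB", "fC"),
    species = c("moth_a", "moth_b", "virus_x"),
    seq = c(root, near, mutate_copy_k2p(root, 0.02)))
  res <- flag_htt_candidates(cons, tax)
  # congeneric pair at ~95%: not flagged; insect-virus pair: flagged
  congeneric <- res[res$species_a == "moth_a" & res$species_b == "moth_b", ]
  expect_false(congeneric$flagged)
  expect_equal(congeneric$relatedness, "same_genus")
  cross <- res[res$species_b == "virus_x" & res$species_a == "moth_a", ]
  expect_true(cross$flagged)
  expect_equal(cross$relatedness, "cross_kingdom")
  expect_equal(cross$empty_site_evidence, "not_tested")

  expect_error(
    flag_htt_candidates(data.frame(family = "f", species = "nobody",
                                   seq = root), tax),
    "unknown species")
  expect_error(host_relatedness_rank("moth_a", "nobody", tax),
               "unknown species")
})

test_that("empty-site evidence requires adjacent flank matches", {
  set.seed(149)
  fl <- random_dna(500)
  fr <- random_dna(500)
  element <- random_dna(1000)
  filled <- paste0(fl, element, fr)
  related <- c(
    joined = paste0(random_dna(300), fl, fr, random_dna(300)),
    absent = random_dna(2000),
    separated = paste0(random_dna(300), fl, random_dna(1000), fr,
                       random_dna(300)))
  ev <- orthologous_empty_site_check(filled, related)
  expect_equal(ev$evidence[ev$genome == "joined"], "found")
  expect_equal(ev$evidence[ev$genome == "absent"], "not_found")
  expect_equal(ev$evidence[ev$genome == "separated"], "not_found")
})
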