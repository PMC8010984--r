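#' Built-in synthetic head references
#'
#' Deterministic synthetic head sequences used by the simulator and as
#' classification references: a 72-bp tRNA-like head carrying exact instances
#' of the default A and B boxes, and a 90-bp 5S-like head carrying A, IE and
#' C boxes in order. These are synthetic constructions, not biological
#' tRNA/5S genes.
#'
#' @return data.frame with columns `id`, `class`, `seq`.
#' @export
synthetic_head_refs <- function() {
  a_box <- "TGGCTCAATGCG"   # instance of TRGCNNARYNNG
  b_box <- "GTTCGAACC"      # instance of GWTCRANNC
  ie_box <- "GATTGGG"       # instance of GRYTGGG
  c_box <- "AGGTCGATGC"     # instance of RGGTCGANNC
  # fixed fillers (arbitrary but hard-coded for determinism)
  trna <- paste0("CCGGATAC", a_box, "ACCTTAGCGTGATCCAGTAACGGCTTAG",
                 b_box, "TGCACGGATGCACTT")
  fives <- paste0("ACGGTTCAT", a_box, "CCTGAGTATCGAT", ie_box,
                  "TACCGATTACGTAG", c_box, "GCTTAACGGTCATAA")
  stopifnot(nchar(trna) == 72)
  data.frame(id = c("tRNA_synth", "5S_synth"),
             class = c("tRNA", "5S_rRNA"),
             seq = c(trna, fives), stringsAsFactors = FALSE)
}

#' Specification of one synthetic SINE family
#'
#' @param name family name.
#' @param head_class "tRNA" (type 2 promoter) or "5S_rRNA" (type 1).
#' @param body_bp central-region length (bp); `body_seq` overrides with an
#'   explicit sequence (used to share bodies between families).
#' @param body_seq optional explicit body sequence.
#' @param tail_unit simple-repeat tail unit (e.g. "GT").
#' @param tail_n number of tail units.
#' @param n_copies copies implanted.
#' @param age list: `list(type = "burst", d = 0.05)` or
#'   `list(type = "mixture", d = c(...), w = c(...))` with per-copy target
#'   K2P divergences.
#' @param truncation_prob probability a copy is 5'-truncated.
#' @param truncation_maxfrac maximum truncated fraction of the element.
#' @param tsd_len_range inclusive TSD length range (default 5-15 bp).
#' @param context_weights named weights over the insertion categories
#'   (intron, downstream_5k, upstream_5k, intergenic, CDS, UTR3); must sum
#'   to 1.
#' @return list of class `family_spec`.
#' @export
family_spec <- function(name = "fam1", head_class = "tRNA",
                        body_bp = 175L, body_seq = NULL,
                        tail_unit = "GT", tail_n = 8L,
                        n_copies = 50L,
                        age = list(type = "burst", d = 0.05),
                        truncation_prob = 0.1, truncation_maxfrac = 0.5,
                        tsd_len_range = c(5L, 15L),
                        context_weights = c(intron = 0.45,
                                            downstream_5k = 0.30,
                                            upstream_5k = 0.05,
                                            intergenic = 0.15,
                                            CDS = 0.02, UTR3 = 0.03)) {
  if (abs(sum(context_weights) - 1) > 1e-8)
    stop("context_weights must sum to 1")
  if (any(unlist(age[names(age) == "d"]) < 0) ||
      any(unlist(age[names(age) == "d"]) > 0.3))
    stop("divergence targets must lie in [0, 0.3]")
  structure(list(name = name, head_class = head_class, body_bp = body_bp,
                 body_seq = body_seq, tail_unit = tail_unit, tail_n = tail_n,
                 n_copies = as.integer(n_copies), age = age,
                 truncation_prob = truncation_prob,
                 truncation_maxfrac = truncation_maxfrac,
                 tsd_len_range = as.integer(tsd_len_range),
                 context_weights = context_weights),
            class = "family_spec")
}

#' Simulation configuration
#'
#' Defaults emulate the reported study conditions: multi-family tRNA/5S-like
#' SINE implants with box-bearing heads, simple-repeat tails, 5-15 bp TSDs,
#' transition-biased divergence (kappa = 2), insertions biased toward introns
#' and 5-kb-downstream regions, one optional partner LINE sharing a family's
#' 3' tail at ~84% identity, and one optional near-identical copy in a small
#' "virus" record as an HTT event (with two related virus records holding the
#' joined empty site).
#'
#' @param genome_bp host genome length.
#' @param gc background GC fraction.
#' @param n_genes number of gene models.
#' @param families list of [family_spec()] objects.
#' @param kappa transition:transversion ratio of the mutation process.
#' @param partner_line NULL or list(family =, identity = 0.84, tail_bp = 43)
#'   naming the family whose tail the LINE shares.
#' @param htt_event NULL or list(family =, d = 0.01, virus_bp = 20000).
#' @param seed integer RNG seed; same seed gives byte-identical outputs.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(genome_bp = 1e6, gc = 0.40, n_genes = 20L,
                              families = list(family_spec()),
                              kappa = 2, partner_line = NULL,
                              htt_event = NULL, seed = 1L) {
  stopifnot(kappa > 0)
  structure(list(genome_bp = as.integer(genome_bp), gc = gc,
                 n_genes = as.integer(n_genes), families = families,
                 kappa = kappa, partner_line = partner_line,
                 htt_event = htt_event, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Mutate a master sequence under the K2P model
#'
#' Applies substitutions with exact per-site K2P probabilities for target
#' distance `d` and transition:transversion count ratio `kappa`, so the K2P
#' estimator recovers `d` in expectation (multiple hits included). Draws from
#' the current RNG stream. No indels.
#'
#' @param master DNA string.
#' @param d target K2P divergence in `[0, 0.3]`.
#' @param kappa transition:transversion ratio.
#' @return mutated DNA string of the same length.
#' @export
mutate_copy_k2p <- function(master, d, kappa = 2) {
  if (d < 0 || d > 0.3) stop("d must lie in [0, 0.3]")
  if (d == 0) return(master)
  pq <- k2p_expected_pq(d, kappa)
  ch <- str2chars(master)
  n <- length(ch)
  u <- stats::runif(n)
  TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")
  TRANSVERSIONS <- list(A = c("C", "T"), G = c("C", "T"),
                        C = c("A", "G"), T = c("A", "G"))
  do_ts <- u < pq$P & ch %in% BASES
  do_tv <- u >= pq$P & u < pq$P + pq$Q & ch %in% BASES
  if (any(do_ts)) ch[do_ts] <- TRANSITION[ch[do_ts]]
  if (any(do_tv)) {
    pick <- stats::runif(sum(do_tv)) < 0.5
    ch[do_tv] <- mapply(function(b, first) TRANSVERSIONS[[b]][if (first) 1 else 2],
                        ch[do_tv], pick)
  }
  paste(ch, collapse = "")
}

# build the master element sequence for one family spec
build_family_master <- function(fs, refs = synthetic_head_refs()) {
  head <- refs$seq[refs$class == if (fs$head_class == "tRNA") "tRNA" else "5S_rRNA"][1]
  body <- if (!is.null(fs$body_seq)) fs$body_seq else random_dna(fs$body_bp, 0.45)
  tail <- paste(rep(fs$tail_unit, fs$tail_n), collapse = "")
  paste0(head, body, tail)
}

# draw a per-copy target divergence from the family's age model
draw_divergence <- function(age, n) {
  if (age$type == "burst") rep(age$d, n)
  else if (age$type == "mixture") {
    comp <- sample.int(length(age$d), n, replace = TRUE, prob = age$w)
    age$d[comp]
  } else stop("unknown age model type: ", age$type)
}

# lay out n_genes non-overlapping gene models on one contig, leaving >= 11 kb
# between spans so the 5-kb flank categories of neighboring genes never
# overlap; returns list of gene models (0-based half-open)
layout_genes <- function(genome_bp, n_genes, contig = "chr1") {
  if (n_genes == 0) return(list())
  slot <- genome_bp %/% n_genes
  if (slot < 18000)
    stop("genome too small for ", n_genes, " genes (need >= 18 kb per gene)")
  genes <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    lo <- (i - 1L) * slot + 6000L
    n_ex <- sample(2:4, 1)
    ex_len <- sample(300:700, n_ex, replace = TRUE)
    in_len <- sample(500:1500, n_ex - 1, replace = TRUE)
    glen <- sum(ex_len) + sum(in_len)
    gstart <- lo + sample.int(max(1L, slot - 12000L - glen), 1)
    strand <- sample(c("+", "-"), 1)
    exons <- matrix(0L, n_ex, 2, dimnames = list(NULL, c("start", "end")))
    pos <- gstart
    for (e in seq_len(n_ex)) {
      exons[e, ] <- c(pos, pos + ex_len[e])
      pos <- pos + ex_len[e] + if (e < n_ex) in_len[e] else 0L
    }
    gend <- exons[n_ex, 2]
    # UTRs in transcript coordinates: 100 bp 5', 200 bp 3'
    u5 <- 100L
    u3 <- 200L
    if (strand == "+") {
      utr5 <- matrix(c(exons[1, 1], exons[1, 1] + u5), 1, 2)
      utr3 <- matrix(c(gend - u3, gend), 1, 2)
      cds_lo <- exons[1, 1] + u5
      cds_hi <- gend - u3
    } else {
      utr5 <- matrix(c(gend - u5, gend), 1, 2)
      utr3 <- matrix(c(exons[1, 1], exons[1, 1] + u3), 1, 2)
      cds_lo <- exons[1, 1] + u3
      cds_hi <- gend - u5
    }
    cds <- exons
    cds[, 1] <- pmax(cds[, 1], cds_lo)
    cds[, 2] <- pmin(cds[, 2], cds_hi)
    cds <- cds[cds[, 2] > cds[, 1], , drop = FALSE]
    colnames(utr5) <- colnames(utr3) <- c("start", "end")
    genes[[i]] <- list(gene_id = sprintf("g%03d", i), contig = contig,
                       strand = strand,
                       span = c(start = unname(exons[1, 1]),
                                end = unname(gend)),
                       exons = exons, cds = cds, utr5 = utr5, utr3 = utr3)
  }
  genes
}

# pick a background-coordinate insertion point for a category, or NA when the
# category has no room; margin keeps the point away from feature edges
pick_insertion_point <- function(category, genes, genome_bp, used,
                                 min_sep = 60L) {
  if (length(genes) == 0 && category != "intergenic") category <- "intergenic"
  ok_point <- function(p) {
    !is.na(p) && p > 100 && p < genome_bp - 100 &&
      (length(used) == 0 || min(abs(used - p)) >= min_sep)
  }
  runif_int <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1) - 1L
  g <- NULL
  for (attempt in 1:50) {
    p <- NA_integer_
    if (category == "intergenic") {
      p <- sample.int(genome_bp - 200L, 1) + 100L
      near <- any(vapply(genes, function(g)
        p > g$span[["start"]] - 5200 && p < g$span[["end"]] + 5200, logical(1)))
      if (isTRUE(near)) p <- NA_integer_
    } else if (category %in% c("downstream_5k", "upstream_5k")) {
      # offsets stay well inside the 5-kb window so coordinate inflation
      # from neighboring implants cannot push a flank site out of it
      g <- genes[[sample.int(length(genes), 1)]]
      offset <- runif_int(200L, 3400L)
      p <- if ((category == "downstream_5k") == (g$strand == "+"))
        g$span[["end"]] + offset else g$span[["start"]] - offset
    } else if (category == "intron") {
      g <- genes[[sample.int(length(genes), 1)]]
      if (nrow(g$exons) < 2) next
      k <- sample.int(nrow(g$exons) - 1L, 1)
      lo <- g$exons[k, 2] + 50L
      hi <- g$exons[k + 1L, 1] - 50L
      if (hi > lo) p <- runif_int(lo, hi)
    } else if (category %in% c("CDS", "UTR3")) {
      g <- genes[[sample.int(length(genes), 1)]]
      m <- if (category == "CDS") g$cds else g$utr3
      if (nrow(m) == 0) next
      k <- sample.int(nrow(m), 1)
      lo <- m[k, 1] + 10L
      hi <- m[k, 2] - 10L
      if (hi > lo) p <- runif_int(lo, hi)
    }
    if (ok_point(p)) {
      gid <- if (category == "intergenic") NA_character_ else g$gene_id
      return(list(point = as.integer(p), gene_id = gid, category = category))
    }
  }
  NULL
}

# map background coordinates to final coordinates after all insertions:
# a boundary b gains the length of every insertion at a point strictly
# before b (a feature containing an insertion point thereby grows, since its
# start stays and its end shifts)
make_bg2final <- function(points, lengths) {
  if (length(points) == 0) return(function(b) b)
  ord <- order(points)
  pts <- points[ord]
  cum <- c(0L, cumsum(lengths[ord]))
  function(b) b + cum[findInterval(b - 0.5, pts) + 1L]
}

map_gene <- function(g, bg2final) {
  mi <- function(m) {
    if (nrow(m) == 0) return(m)
    m[, 1] <- bg2final(m[, 1])
    m[, 2] <- bg2final(m[, 2])
    m
  }
  g$exons <- mi(g$exons)
  g$cds <- mi(g$cds)
  g$utr5 <- mi(g$utr5)
  g$utr3 <- mi(g$utr3)
  g$span <- c(start = bg2final(g$span[["start"]]),
              end = bg2final(g$span[["end"]]))
  g
}

#' Generate a synthetic genome with implanted SINE families
#'
#' Builds an i.i.d. background contig, lays out gene models, implants mutated
#' family copies with fresh TSDs duplicated from the insertion point
#' according to per-family context weights, and (optionally) implants one
#' partner LINE sharing a family tail and one horizontal-transfer event into
#' a separate small virus record (plus two related virus records carrying the
#' joined empty site). All coordinates in the truth table refer to the final
#' genome. Deterministic given `cfg$seed`.
#'
#' @param cfg a [simulation_config()].
#' @return list of class `sine_simulation`: `genome` (named character),
#'   `genes` (final-coordinate gene models), `truth` (per-implant data.frame:
#'   family, contig, start, end, strand, d, tsd, category, gene_id),
#'   `masters` (named character of family master sequences), `line` (NULL or
#'   list with locus/identity details), `htt` (NULL or list with virus
#'   records and truth), `taxonomy` (lineage table), `config`.
#' @export
generate_genome_with_families <- function(cfg) {
  set.seed(cfg$seed)
  contig <- "chr1"
  background <- random_dna(cfg$genome_bp, cfg$gc)
  genes0 <- layout_genes(cfg$genome_bp, cfg$n_genes, contig)

  refs <- synthetic_head_refs()
  masters <- character(0)
  plan <- list()  # one row per implant, background coordinates
  used <- integer(0)
  for (fs in cfg$families) {
    master <- build_family_master(fs, refs)
    masters[fs$name] <- master
    if (fs$n_copies == 0) next
    cats <- sample(names(fs$context_weights), fs$n_copies, replace = TRUE,
                   prob = fs$context_weights)
    ds <- draw_divergence(fs$age, fs$n_copies)
    for (i in seq_len(fs$n_copies)) {
      site <- pick_insertion_point(cats[i], genes0, cfg$genome_bp, used)
      if (is.null(site)) stop("genome too small to place all implants")
      used <- c(used, site$point)
      copy <- mutate_copy_k2p(master, ds[i], cfg$kappa)
      if (stats::runif(1) < fs$truncation_prob) {
        cut <- floor(nchar(copy) * stats::runif(1, 0.1, fs$truncation_maxfrac))
        copy <- substr(copy, cut + 1L, nchar(copy))
      }
      strand <- sample(c("+", "-"), 1)
      tsd_len <- sample(fs$tsd_len_range[1]:fs$tsd_len_range[2], 1)
      plan[[length(plan) + 1L]] <- list(
        family = fs$name, point = site$point, strand = strand,
        d = ds[i], tsd_len = tsd_len, seq = copy,
        category = site$category, gene_id = site$gene_id)
    }
  }

  line_info <- NULL
  if (!is.null(cfg$partner_line)) {
    pl <- cfg$partner_line
    fam_master <- masters[[pl$family]]
    tail_bp <- if (!is.null(pl$tail_bp)) pl$tail_bp else 43L
    target_id <- if (!is.null(pl$identity)) pl$identity else 0.84
    fam_tail <- substr(fam_master, nchar(fam_master) - tail_bp + 1L,
                       nchar(fam_master))
    # substitute an exact number of positions to hit the target identity
    n_sub <- round((1 - target_id) * tail_bp)
    ch <- str2chars(fam_tail)
    pos <- sample.int(tail_bp, n_sub)
    for (p in pos) ch[p] <- sample(setdiff(BASES, ch[p]), 1)
    line_tail <- paste(ch, collapse = "")
    orf_codons <- 700L
    codon_pool <- setdiff(apply(expand.grid(BASES, BASES, BASES), 1, paste,
                                collapse = ""), c("TAA", "TAG", "TGA"))
    orf <- paste0("ATG", paste(sample(codon_pool, orf_codons - 1, replace = TRUE),
                               collapse = ""))
    line_seq <- paste0(random_dna(120, 0.45), orf, random_dna(40, 0.45),
                       line_tail)
    site <- pick_insertion_point("intergenic", genes0, cfg$genome_bp, used)
    if (is.null(site)) stop("no room for the partner LINE")
    used <- c(used, site$point)
    plan[[length(plan) + 1L]] <- list(
      family = ".partner_line", point = site$point, strand = "+",
      d = 0, tsd_len = 13L, seq = line_seq,
      category = "intergenic", gene_id = NA_character_)
    line_info <- list(family = pl$family, tail_bp = tail_bp,
                      target_identity = target_id, length = nchar(line_seq))
  }

  # splice implants into the background in one pass (5' to 3'); the target
  # site [point, point+tsd_len) stays in place and is duplicated after the
  # element
  ord <- order(vapply(plan, `[[`, integer(1), "point"))
  segs <- character(0)
  prev <- 0L
  for (k in ord) {
    im <- plan[[k]]
    p <- im$point
    tsd <- substr(background, p + 1L, p + im$tsd_len)
    insert <- if (im$strand == "+") im$seq else revcomp(im$seq)
    segs <- c(segs, substr(background, prev + 1L, p + im$tsd_len),
              insert, tsd)
    prev <- p + im$tsd_len
    plan[[k]]$tsd <- tsd
    plan[[k]]$len <- nchar(insert)
  }
  genome_seq <- paste(c(segs, substr(background, prev + 1L, nchar(background))),
                      collapse = "")

  # final coordinates: element of implant i starts at point + tsd_len plus the
  # lengths of all insertions at smaller points
  pts <- vapply(plan, `[[`, integer(1), "point")
  lens <- vapply(plan, function(x) x$len + x$tsd_len, integer(1))
  bg2final <- make_bg2final(pts, lens)
  truth_rows <- list()
  for (k in seq_along(plan)) {
    im <- plan[[k]]
    start <- bg2final(im$point) + im$tsd_len
    truth_rows[[k]] <- data.frame(
      family = im$family, contig = contig,
      start = start, end = start + im$len, strand = im$strand,
      d = im$d, tsd = im$tsd, category = im$category,
      gene_id = ifelse(is.na(im$gene_id), NA_character_, im$gene_id),
      seq = if (im$strand == "+") im$seq else revcomp(im$seq),
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth_rows)
  if (is.null(truth))
    truth <- data.frame(family = character(0), contig = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), d = numeric(0),
                        tsd = character(0), category = character(0),
                        gene_id = character(0), seq = character(0))

  # lift gene models into final coordinates
  genes <- lapply(genes0, map_gene, bg2final = bg2final)

  # re-check flank categories: an intervening implant can push a 5-kb flank
  # site past the window; such implants become intergenic in truth
  if (nrow(truth) > 0) {
    spans <- do.call(rbind, lapply(genes, function(g)
      data.frame(gene_id = g$gene_id, start = g$span[["start"]],
                 end = g$span[["end"]], stringsAsFactors = FALSE)))
    for (k in seq_len(nrow(truth))) {
      if (!truth$category[k] %in% c("downstream_5k", "upstream_5k")) next
      mid <- truth$start[k] + (truth$end[k] - truth$start[k]) %/% 2
      sp <- spans[spans$gene_id == truth$gene_id[k], ]
      dist <- max(sp$start - mid - 1, mid - sp$end + 1, 0)
      if (dist > 5000) {
        truth$category[k] <- "intergenic"
        truth$gene_id[k] <- NA_character_
      }
    }
  }

  genome <- setNames(genome_seq, contig)

  taxonomy <- data.frame(
    species = "host_moth", genus = "Hostgenus", family = "Hostidae",
    order = "Lepidoptera", kingdom = "Animalia", stringsAsFactors = FALSE)

  htt <- NULL
  if (!is.null(cfg$htt_event)) {
    htt <- implant_htt_event(cfg, masters, genome)
    genome <- c(genome, htt$records)
    taxonomy <- rbind(taxonomy, htt$taxonomy)
  }

  structure(list(genome = genome, genes = genes, truth = truth,
                 masters = masters, line = line_info, htt = htt,
                 taxonomy = taxonomy, config = cfg),
            class = "sine_simulation")
}

#' Implant a horizontal-transfer event into a virus record
#'
#' Copies one family master at low divergence into a small virus genome with
#' no target site duplication (blunt insertion), and builds two related virus
#' records carrying the directly joined empty site. Uses the current RNG
#' stream (called from [generate_genome_with_families()]).
#'
#' @param cfg the [simulation_config()] (its `htt_event` field names the
#'   family, divergence `d`, and `virus_bp`).
#' @param masters named character vector of family masters.
#' @param host_genome host genome (unused, kept for signature clarity).
#' @return list: `records` (virus + two related virus sequences), `truth`
#'   (family, contig, start, end, d), `taxonomy` rows for the virus species.
#' @export
implant_htt_event <- function(cfg, masters, host_genome = NULL) {
  ev <- cfg$htt_event
  if (!ev$family %in% names(masters)) stop("unknown family: ", ev$family)
  d <- if (!is.null(ev$d)) ev$d else 0.01
  virus_bp <- if (!is.null(ev$virus_bp)) ev$virus_bp else 20000L
  vbg <- random_dna(virus_bp, 0.42)
  copy <- mutate_copy_k2p(masters[[ev$family]], d, cfg$kappa)
  p <- virus_bp %/% 2L
  virus <- paste0(substr(vbg, 1, p), copy, substr(vbg, p + 1L, virus_bp))
  empty <- vbg  # joined empty site, no TSD to collapse
  related1 <- mutate_copy_k2p(empty, 0.02, cfg$kappa)
  related2 <- mutate_copy_k2p(empty, 0.03, cfg$kappa)
  records <- c(virus_1 = virus, related_virus_1 = related1,
               related_virus_2 = related2)
  taxonomy <- data.frame(
    species = c("virus_1", "related_virus_1", "related_virus_2"),
    genus = c("Alphabaculovirus", "Alphabaculovirus", "Alphabaculovirus"),
    family = rep("Baculoviridae", 3), order = rep("Lefavirales", 3),
    kingdom = rep("Viruses", 3), stringsAsFactors = FALSE)
  list(records = records,
       truth = data.frame(family = ev$family, contig = "virus_1",
                          start = p, end = p + nchar(copy), d = d,
                          stringsAsFactors = FALSE),
       taxonomy = taxonomy)
}

#' Write simulator outputs to files
#'
#' @param sim a `sine_simulation`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written (genome.fa, genes.gff3, truth.tsv,
#'   and virus.fa when an HTT event was simulated).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             genes = file.path(dir, "genes.gff3"),
             truth = file.path(dir, "truth.tsv"))
  host <- sim$genome[setdiff(names(sim$genome),
                             c("virus_1", "related_virus_1", "related_virus_2"))]
  write_fasta(host, paths[["genome"]])
  write_gff3(sim$genes, paths[["genes"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(sim$htt)) {
    paths <- c(paths, virus = file.path(dir, "virus.fa"))
    write_fasta(sim$htt$records, paths[["virus"]])
  }
  invisible(paths)
}
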