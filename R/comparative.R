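#' Pairwise p-distance matrix between family consensus sequences
#'
#' Each pair is aligned globally; columns with a gap or N in either sequence
#' are dropped (pairwise deletion) and the entry is base differences per
#' compared site. Pairs with zero comparable sites are NA.
#'
#' @param consensi named character vector of >= 2 consensus sequences.
#' @return symmetric numeric matrix with zero diagonal, dimnames = family
#'   ids.
#' @export
consensus_p_distance_matrix <- function(consensi) {
  n <- length(consensi)
  if (n < 2) stop("need >= 2 consensus sequences")
  if (is.null(names(consensi))) stop("consensi must be named")
  D <- matrix(0, n, n, dimnames = list(names(consensi), names(consensi)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    al <- align_pair(sanitize_dna(consensi[[i]]), sanitize_dna(consensi[[j]]),
                     type = "global")
    x <- str2chars(al$pat)
    y <- str2chars(al$sub)
    keep <- x %in% BASES & y %in% BASES
    sites <- sum(keep)
    D[i, j] <- D[j, i] <- if (sites == 0) NA_real_ else
      sum(x[keep] != y[keep]) / sites
  }
  D
}

# K2P distance matrix from rows of an MSA (pairwise deletion); saturated
# pairs fall back to the p-distance upper transform being undefined -> NA
k2p_matrix_from_alignment <- function(rows, cols = NULL) {
  n <- length(rows)
  m <- do.call(rbind, strsplit(unname(rows), "", fixed = TRUE))
  if (!is.null(cols)) m <- m[, cols, drop = FALSE]
  D <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- tryCatch(
      kimura2p_distance(paste(m[i, ], collapse = ""),
                        paste(m[j, ], collapse = ""), aligned = TRUE)$d,
      sinescout_saturated = function(e) NA_real_,
      sinescout_no_sites = function(e) NA_real_)
  }
  D
}

#' Neighbor-joining tree of family consensi with bootstrap support
#'
#' Aligns the consensi (center-star), computes K2P distances under pairwise
#' deletion, and builds an unrooted neighbor-joining topology. Support values
#' are the fraction of site-resampling bootstrap replicates containing each
#' internal bipartition, attached as node labels. Given a precomputed
#' distance matrix instead of sequences, the topology is returned without
#' supports.
#'
#' @param consensi named character vector of >= 3 sequences, or a symmetric
#'   distance matrix.
#' @param n_boot bootstrap replicates (sequences input only).
#' @param seed integer seed for the resampling.
#' @return an [ape::phylo] tree; `node.label` holds support fractions when
#'   bootstrapping was performed.
#' @export
nj_tree_with_bootstrap <- function(consensi, n_boot = 1000L, seed = 1L) {
  if (is.matrix(consensi)) {
    if (any(is.na(consensi))) stop("distance matrix has missing entries")
    if (nrow(consensi) < 3) stop("need >= 3 taxa")
    return(ape::nj(stats::as.dist(consensi)))
  }
  if (length(consensi) < 3) stop("need >= 3 taxa")
  aln <- build_msa_center_star(consensi, family_id = "consensi")
  D <- k2p_matrix_from_alignment(aln$rows)
  if (any(is.na(D))) stop("distance matrix has missing entries")
  tree <- ape::nj(stats::as.dist(D))
  if (n_boot > 0) {
    L <- nchar(aln$rows[[1]])
    set.seed(seed)
    boots <- vector("list", n_boot)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(L, L, replace = TRUE)
      Db <- k2p_matrix_from_alignment(aln$rows, cols = idx)
      if (any(is.na(Db))) next
      boots[[b]] <- ape::nj(stats::as.dist(Db))
    }
    boots <- boots[!vapply(boots, is.null, logical(1))]
    counts <- ape::prop.clades(tree, boots, rooted = FALSE)
    counts[is.na(counts)] <- 0
    tree$node.label <- counts / length(boots)
  }
  tree
}

#' Find partner-LINE candidates sharing a SINE 3' tail
#'
#' Searches the genome with the 3'-terminal tail fragment of a SINE family
#' (trailing simple repeats retained). Hits are extended to candidate element
#' spans by requiring at least `min_upstream` bp upstream (5') of the matched
#' tail on the same contig; candidates are annotated with the longest open
#' reading frame on both strands of the span and with TSD detection on the
#' span flanks, and sorted by decreasing tail identity.
#'
#' @param tail_query 3'-end fragment of the SINE consensus (typically 50 bp).
#' @param genome named character vector of contigs.
#' @param params a [search_params()] object.
#' @param min_tail_id minimum identity over the matched tail segment.
#' @param min_len minimum tail alignment length (bp).
#' @param min_upstream minimum sequence upstream of the tail (bp).
#' @param span_bp candidate element span measured back from the tail end.
#' @param min_orf_codons ORF length (codons) for `orf_ok`.
#' @return data.frame: contig, start, end, strand, length, tail_identity,
#'   orf_codons, orf_ok, tsd_len (NA when none).
#' @export
find_partner_line_candidates <- function(tail_query, genome,
                                         params = search_params(),
                                         min_tail_id = 0.8, min_len = 30L,
                                         min_upstream = 2000L,
                                         span_bp = 3000L,
                                         min_orf_codons = 200L) {
  hits <- seed_and_extend_search(tail_query, genome, params,
                                 min_id = min_tail_id, min_len = min_len)
  out <- list()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    clen <- nchar(genome[[h$contig]])
    if (h$strand == "+") {
      if (h$end < min_upstream) next
      s0 <- max(0L, h$end - span_bp)
      e0 <- h$end
    } else {
      if (clen - h$start < min_upstream) next
      s0 <- h$start
      e0 <- min(clen, h$start + span_bp)
    }
    span_seq <- substr(genome[[h$contig]], s0 + 1L, e0)
    if (h$strand == "-") span_seq <- revcomp(span_seq)
    orf <- longest_orf_codons(span_seq)
    upstream <- substr(genome[[h$contig]], max(1L, s0 - 29L), s0)
    downstream <- substr(genome[[h$contig]], e0 + 1L, min(clen, e0 + 30L))
    tsd <- if (nchar(upstream) >= 20 && nchar(downstream) >= 20)
      detect_tsd(upstream, downstream) else NULL
    out[[length(out) + 1L]] <- data.frame(
      contig = h$contig, start = s0, end = e0, strand = h$strand,
      length = e0 - s0, tail_identity = h$identity,
      orf_codons = orf, orf_ok = orf >= min_orf_codons,
      tsd_len = if (is.null(tsd)) NA_integer_ else tsd$length,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      length = integer(0), tail_identity = numeric(0),
                      orf_codons = integer(0), orf_ok = logical(0),
                      tsd_len = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(-res$tail_identity, res$contig, res$start), ]
  rownames(res) <- NULL
  res
}

# longest run of non-stop codons over the six reading frames, in codons
longest_orf_codons <- function(seq) {
  best <- 0L
  for (s in c(seq, revcomp(seq))) {
    ch <- str2chars(s)
    n <- length(ch)
    for (frame in 0:2) {
      k <- (n - frame) %/% 3
      if (k < 1) next
      codons <- paste0(ch[frame + 3 * (seq_len(k) - 1) + 1],
                       ch[frame + 3 * (seq_len(k) - 1) + 2],
                       ch[frame + 3 * (seq_len(k) - 1) + 3])
      stop_at <- codons %in% c("TAA", "TAG", "TGA")
      runs <- rle(!stop_at)
      open <- runs$lengths[runs$values]
      if (length(open) > 0) best <- max(best, max(open))
    }
  }
  best
}

#' Relatedness rank between two host species
#'
#' Ranks: 1 = same genus, 2 = same family, 3 = cross-family (same kingdom),
#' 4 = cross-kingdom, from a user-supplied lineage table.
#'
#' @param sp1,sp2 species labels.
#' @param taxonomy data.frame with columns `species`, `genus`, `family`,
#'   `order`, `kingdom`.
#' @return integer rank with a descriptive name.
#' @export
host_relatedness_rank <- function(sp1, sp2, taxonomy) {
  row <- function(sp) {
    i <- match(sp, taxonomy$species)
    if (is.na(i)) stop("unknown species label: ", sp)
    taxonomy[i, ]
  }
  a <- row(sp1)
  b <- row(sp2)
  if (a$genus == b$genus) return(c(same_genus = 1L))
  if (a$family == b$family) return(c(same_family = 2L))
  if (a$kingdom == b$kingdom) return(c(cross_family = 3L))
  c(cross_kingdom = 4L)
}

RELATEDNESS_RANKS <- c(same_genus = 1L, same_family = 2L,
                       cross_family = 3L, cross_kingdom = 4L)

#' Flag horizontal-transfer candidate pairs across species
#'
#' Scores every cross-species pair of family consensi: identity is
#' 1 - p-distance under a global alignment with pairwise deletion. A pair is
#' flagged when identity >= `id_threshold` and the hosts are at least
#' `min_rank` apart (default cross-family); the verdict stays provisional
#' (`empty_site_evidence = "not_tested"`) until evidence from
#' [orthologous_empty_site_check()] is attached.
#'
#' @param consensi data.frame with columns `family`, `species`, `seq`.
#' @param taxonomy lineage table (see [host_relatedness_rank()]).
#' @param id_threshold consensus identity threshold.
#' @param min_rank minimum relatedness rank name ("same_genus",
#'   "same_family", "cross_family", "cross_kingdom").
#' @return data.frame of cross-species pairs: family_a, family_b, species_a,
#'   species_b, identity, relatedness, flagged, empty_site_evidence.
#' @export
flag_htt_candidates <- function(consensi, taxonomy, id_threshold = 0.90,
                                min_rank = "cross_family") {
  stopifnot(all(c("family", "species", "seq") %in% names(consensi)))
  min_rank_val <- RELATEDNESS_RANKS[[min_rank]]
  missing_sp <- setdiff(unique(consensi$species), taxonomy$species)
  if (length(missing_sp) > 0)
    stop("unknown species label: ", missing_sp[1])
  n <- nrow(consensi)
  out <- list()
  for (i in seq_len(max(0, n - 1))) for (j in (i + 1):n) {
    if (consensi$species[i] == consensi$species[j]) next
    rk <- host_relatedness_rank(consensi$species[i], consensi$species[j],
                                taxonomy)
    al <- align_pair(sanitize_dna(consensi$seq[i]),
                     sanitize_dna(consensi$seq[j]), type = "global")
    x <- str2chars(al$pat)
    y <- str2chars(al$sub)
    keep <- x %in% BASES & y %in% BASES
    ident <- if (sum(keep) == 0) NA_real_ else
      sum(x[keep] == y[keep]) / sum(keep)
    flagged <- !is.na(ident) && ident >= id_threshold && rk >= min_rank_val
    out[[length(out) + 1L]] <- data.frame(
      family_a = consensi$family[i], family_b = consensi$family[j],
      species_a = consensi$species[i], species_b = consensi$species[j],
      identity = ident, relatedness = names(rk), flagged = flagged,
      empty_site_evidence = "not_tested", stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(family_a = character(0), family_b = character(0),
                      species_a = character(0), species_b = character(0),
                      identity = numeric(0), relatedness = character(0),
                      flagged = logical(0),
                      empty_site_evidence = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Check related genomes for the orthologous empty site of an insertion
#'
#' For each related genome, both flanks of the filled locus are searched;
#' the evidence is "found" when both flanks align at >= `min_identity`
#' adjacent to each other (gap <= `max_gap` bp, overlap up to the TSD length
#' allowed) in the same orientation without an intervening element, and
#' "not_found" otherwise.
#'
#' @param filled_locus DNA string: left flank + element + right flank.
#' @param related_genomes named character vector of genome sequences.
#' @param flank_bp flank length included in `filled_locus` (>= 100).
#' @param min_identity minimum flank alignment identity.
#' @param min_flank_aln minimum flank alignment length (bp); shorter chance
#'   matches never count.
#' @param max_gap maximum distance between the two flank matches (bp).
#' @param max_overlap maximum allowed overlap of the two matches (bp).
#' @return data.frame: genome, evidence ("found"/"not_found"), gap.
#' @export
orthologous_empty_site_check <- function(filled_locus, related_genomes,
                                         flank_bp = 500L, min_identity = 0.70,
                                         min_flank_aln = 100L,
                                         max_gap = 50L, max_overlap = 30L) {
  filled_locus <- sanitize_dna(filled_locus)
  n <- nchar(filled_locus)
  if (flank_bp < 100) stop("flanks must be >= 100 bp")
  left <- substr(filled_locus, 1, flank_bp)
  right <- substr(filled_locus, n - flank_bp + 1L, n)
  res <- data.frame(genome = names(related_genomes),
                    evidence = "not_found", gap = NA_integer_,
                    stringsAsFactors = FALSE)
  for (gi in seq_along(related_genomes)) {
    for (orient in c("+", "-")) {
      g <- sanitize_dna(related_genomes[[gi]])
      if (orient == "-") g <- revcomp(g)
      al <- align_pair(left, g, type = "local")
      ar <- align_pair(right, g, type = "local")
      stl <- aln_stats(al$pat, al$sub)
      str <- aln_stats(ar$pat, ar$sub)
      if (is.na(stl$identity) || is.na(str$identity) ||
          stl$identity < min_identity || str$identity < min_identity ||
          stl$columns < min_flank_aln || str$columns < min_flank_aln) next
      gap <- ar$sstart - al$send - 1L
      if (gap <= max_gap && gap >= -max_overlap) {
        res$evidence[gi] <- "found"
        res$gap[gi] <- gap
        break
      }
    }
  }
  res
}
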