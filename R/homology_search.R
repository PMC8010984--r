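#' Search parameters for seed-and-extend homology search
#'
#' Scoring follows a conventional nucleotide local-alignment scheme
#' (match +1, mismatch -2, affine gaps). Seeding uses exact k-mer word
#' matches chained on near-identical diagonals.
#'
#' @param word_size k-mer seed length (>= 4).
#' @param match,mismatch,gap_open,gap_extend alignment scores; penalties are
#'   negative.
#' @param band diagonal tolerance when chaining seeds into one candidate
#'   locus.
#' @param seed_gap maximum genomic distance between chained seeds.
#' @param pad extra subject sequence taken either side of a seed cluster
#'   before alignment.
#' @return list of class `search_params`.
#' @export
search_params <- function(word_size = 11L, match = 1, mismatch = -2,
                          gap_open = -5, gap_extend = -2,
                          band = 25L, seed_gap = 150L, pad = 50L) {
  if (word_size < 4) stop("word_size must be >= 4")
  if (mismatch >= 0 || gap_open >= 0 || gap_extend >= 0)
    stop("penalties must be negative")
  structure(list(word_size = as.integer(word_size), match = match,
                 mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, band = as.integer(band),
                 seed_gap = as.integer(seed_gap), pad = as.integer(pad)),
            class = "search_params")
}

empty_hits <- function() {
  data.frame(contig = character(0), start = integer(0), end = integer(0),
             strand = character(0), identity = numeric(0),
             aln_len = integer(0), qcov = numeric(0),
             qstart = integer(0), qend = integer(0), seq = character(0),
             stringsAsFactors = FALSE)
}

# seed positions of query k-mers on one subject strand.
# returns data.frame(qpos, gpos) of 1-based start positions.
find_seeds <- function(query, subject_dna, word_size) {
  qlen <- nchar(query)
  n_k <- qlen - word_size + 1L
  if (n_k < 1) return(data.frame(qpos = integer(0), gpos = integer(0)))
  kmers <- substring(query, 1:n_k, word_size:qlen)
  ok <- !grepl("N", kmers, fixed = TRUE)
  if (!any(ok)) return(data.frame(qpos = integer(0), gpos = integer(0)))
  # PDict needs unique handling done by us: map duplicates back to positions
  uk <- unique(kmers[ok])
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(uk))
  m <- Biostrings::matchPDict(pd, subject_dna)
  st <- Biostrings::startIndex(m)
  idx <- match(kmers, uk)  # NA where kmer skipped
  res_q <- integer(0); res_g <- integer(0)
  for (qp in which(ok)) {
    g <- st[[idx[qp]]]
    if (!is.null(g) && length(g) > 0) {
      res_q <- c(res_q, rep.int(qp, length(g)))
      res_g <- c(res_g, g)
    }
  }
  data.frame(qpos = res_q, gpos = res_g)
}

# chain seeds (sorted by genomic position) into clusters on a near-constant
# diagonal; returns list of data.frames
cluster_seeds <- function(seeds, band, seed_gap) {
  if (nrow(seeds) == 0) return(list())
  seeds$diag <- seeds$gpos - seeds$qpos
  seeds <- seeds[order(seeds$gpos, seeds$qpos), ]
  clusters <- list()
  cur <- 1L
  cdiag <- seeds$diag[1]
  cstart <- 1L
  for (i in seq_len(nrow(seeds))[-1]) {
    if (seeds$gpos[i] - seeds$gpos[i - 1] > seed_gap ||
        abs(seeds$diag[i] - cdiag) > band) {
      clusters[[cur]] <- seeds[cstart:(i - 1L), ]
      cur <- cur + 1L
      cstart <- i
      cdiag <- seeds$diag[i]
    }
  }
  clusters[[cur]] <- seeds[cstart:nrow(seeds), ]
  clusters
}

# align the query against subject windows around each seed cluster, one
# vectorized pairwiseAlignment call per (contig, strand); windows are the
# patterns so their genomic coordinates come back per alignment
align_clusters <- function(query, subj_seq, clusters, pad, contig, strand,
                           qlen_orig) {
  qlen <- nchar(query)
  slen <- nchar(subj_seq)
  # the seed diagonals place the element: diag + 1 is where query position 1
  # falls, diag + qlen where it ends; pad covers boundary wobble without
  # swallowing a neighboring copy
  w0 <- vapply(clusters, function(cl)
    max(1L, min(cl$gpos - cl$qpos) + 1L - pad), numeric(1))
  w1 <- vapply(clusters, function(cl)
    min(slen, max(cl$gpos - cl$qpos) + qlen + pad), numeric(1))
  wins <- substring(subj_seq, w0, w1)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(wins),
    subject = Biostrings::DNAString(query), type = "local",
    substitutionMatrix = .sub_matrix(), gapOpening = 5, gapExtension = 2)
  patc <- as.character(Biostrings::alignedPattern(pa))
  subc <- as.character(Biostrings::alignedSubject(pa))
  pr_start <- pa@pattern@range@start
  pr_end <- pr_start + pa@pattern@range@width - 1L
  sr_start <- pa@subject@range@start
  sr_end <- sr_start + pa@subject@range@width - 1L
  out <- vector("list", length(wins))
  for (i in seq_along(wins)) {
    st <- aln_stats(patc[i], subc[i])
    gstart <- w0[i] + pr_start[i] - 1L
    gend <- w0[i] + pr_end[i] - 1L
    qs <- sr_start[i]; qe <- sr_end[i]
    if (strand == "-") {
      tmp_s <- qlen_orig - qe + 1L
      tmp_e <- qlen_orig - qs + 1L
      qs <- tmp_s; qe <- tmp_e
    }
    hitseq <- substr(subj_seq, gstart, gend)
    if (strand == "-") hitseq <- revcomp(hitseq)
    out[[i]] <- data.frame(contig = contig, start = gstart - 1L, end = gend,
                           strand = strand, identity = st$identity,
                           aln_len = st$columns,
                           qcov = (qe - qs + 1L) / qlen_orig,
                           qstart = qs - 1L, qend = qe, seq = hitseq,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Seed-and-extend homology search
#'
#' Finds genomic copies of a query element on both strands by exact k-mer
#' seeding, diagonal chaining, and local alignment of each candidate window,
#' keeping hits with `identity >= min_id` and alignment length
#' `>= min_len`. Identity is matches / alignment columns with internal gaps
#' counted as mismatches and terminal gaps excluded (local alignment); N
#' never counts as a match.
#'
#' @param query DNA string (the element or consensus sequence).
#' @param genome named character vector of contig sequences (see
#'   [read_fasta()]).
#' @param params a [search_params()] object.
#' @param min_id minimum identity fraction.
#' @param min_len minimum alignment length (bp).
#' @return data.frame of hits with 0-based half-open `start`/`end`, `strand`,
#'   `identity`, `aln_len`, `qcov`, 0-based half-open `qstart`/`qend` on the
#'   query, and `seq` (hit sequence in query orientation), sorted by contig
#'   then start.
#' @export
seed_and_extend_search <- function(query, genome, params = search_params(),
                                   min_id = 0.70, min_len = 50L) {
  query <- sanitize_dna(query)
  qlen <- nchar(query)
  if (qlen < params$word_size)
    stop("query shorter than word_size (", params$word_size, ")")
  if (qlen < min_len)
    stop("query shorter than min_len")
  if (is.null(names(genome))) stop("genome must be a named character vector")
  rcq <- revcomp(query)
  out <- list()
  for (ci in seq_along(genome)) {
    contig <- names(genome)[ci]
    subj <- sanitize_dna(genome[[ci]])
    subj_dna <- Biostrings::DNAString(subj)
    for (strand in c("+", "-")) {
      q <- if (strand == "+") query else rcq
      seeds <- find_seeds(q, subj_dna, params$word_size)
      clusters <- cluster_seeds(seeds, params$band, params$seed_gap)
      if (length(clusters) == 0) next
      hits <- align_clusters(q, subj, clusters, params$pad, contig, strand,
                             qlen)
      keep <- !is.na(hits$identity) & hits$identity >= min_id &
        hits$aln_len >= min_len
      if (any(keep)) out[[length(out) + 1L]] <- hits[keep, , drop = FALSE]
    }
  }
  if (length(out) == 0) return(empty_hits())
  hits <- do.call(rbind, out)
  hits <- hits[!duplicated(hits[, c("contig", "start", "end", "strand")]), ]
  hits <- hits[order(hits$contig, hits$start, hits$end), ]
  rownames(hits) <- NULL
  hits
}

#' Merge overlapping hits into a non-redundant set
#'
#' A hit whose genomic interval lies entirely inside a longer hit on the same
#' contig and strand is a shadow of that hit (simple-repeat tails seed such
#' partial re-alignments) and is removed first. Remaining hits overlapping by
#' more than 50% of the shorter hit on the same strand are resolved by
#' keeping the higher-identity one (ties: longer alignment, then lower
#' start).
#'
#' @param hits data.frame of hits from one query.
#' @return non-redundant data.frame of hits, sorted by contig then start.
#' @export
merge_overlapping_hits <- function(hits) {
  if (nrow(hits) <= 1) return(hits)
  contained <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    inside <- hits$contig == hits$contig[i] & hits$strand == hits$strand[i] &
      hits$start <= hits$start[i] & hits$end >= hits$end[i] &
      hits$aln_len > hits$aln_len[i]
    if (any(inside)) contained[i] <- TRUE
  }
  hits <- hits[!contained, , drop = FALSE]
  if (nrow(hits) <= 1) return(hits)
  ord <- order(-hits$identity, -hits$aln_len, hits$start)
  hits <- hits[ord, ]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    hi <- hits[i, ]
    ok <- TRUE
    for (j in which(keep)) {
      hj <- hits[j, ]
      if (hi$contig != hj$contig || hi$strand != hj$strand) next
      ov <- min(hi$end, hj$end) - max(hi$start, hj$start)
      shorter <- min(hi$end - hi$start, hj$end - hj$start)
      if (ov > 0.5 * shorter) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  res <- hits[keep, ]
  res <- res[order(res$contig, res$start, res$end), ]
  rownames(res) <- NULL
  res
}

#' Count genomic copies of a family consensus
#'
#' Applies the copy-counting regime: identity >= `min_id` (default 0.80) over
#' at least `min_len` bp (default 100). Hits whose query interval lies
#' entirely within `ambiguous_region` (a 5' segment shared between families,
#' e.g. a common 120-bp head) are excluded so head-only fragments are not
#' attributed to this family; `ambiguous_slack` widens the region a few
#' bases so a chance one-base extension of a head-only alignment does not
#' evade the rule. Overlapping hits are merged.
#'
#' @param consensus family consensus sequence (>= 100 bp).
#' @param genome named character vector of contigs.
#' @param params a [search_params()] object.
#' @param ambiguous_region NULL or 0-based half-open `c(start, end)` interval
#'   on the consensus.
#' @param ambiguous_slack slack (bp) added around `ambiguous_region`.
#' @param min_id,min_len copy-counting thresholds.
#' @return list with `copies` (hit data.frame) and `n` (integer copy number).
#' @export
count_copies <- function(consensus, genome, params = search_params(),
                         ambiguous_region = NULL, ambiguous_slack = 5L,
                         min_id = 0.80, min_len = 100L) {
  if (nchar(consensus) < 100) stop("consensus must be >= 100 bp")
  hits <- seed_and_extend_search(consensus, genome, params,
                                 min_id = min_id, min_len = min_len)
  if (!is.null(ambiguous_region) && nrow(hits) > 0) {
    inside <- hits$qstart >= ambiguous_region[1] - ambiguous_slack &
      hits$qend <= ambiguous_region[2] + ambiguous_slack
    hits <- hits[!inside, , drop = FALSE]
  }
  hits <- merge_overlapping_hits(hits)
  list(copies = hits, n = nrow(hits))
}

#' Select the divergence-estimation subset of copies
#'
#' Retains copies with identity >= `min_id` covering at least `min_lenfrac`
#' of the consensus length.
#'
#' @param consensus family consensus sequence.
#' @param copies hit data.frame from [count_copies()].
#' @param min_id,min_lenfrac divergence-set thresholds.
#' @return filtered data.frame of copies.
#' @export
select_divergence_set <- function(consensus, copies,
                                  min_id = 0.80, min_lenfrac = 0.80) {
  keep <- copies$identity >= min_id & copies$qcov >= min_lenfrac
  res <- copies[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}
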