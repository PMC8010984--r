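#' Center-star multiple alignment of family copies
#'
#' The center is the sequence maximizing the summed pairwise alignment score
#' against all others (ends-free pairwise alignments, so 5'-truncated copies
#' are not penalized; under the match/mismatch scoring used throughout, the
#' score-maximizing sequence is the most central copy); ties are broken by
#' lexicographically smallest sequence id. Every other sequence is then
#' aligned to the center with a global pairwise alignment (truncations
#' appear as end-gap runs) and the gaps are merged into one common
#' coordinate frame.
#'
#' @param seqs named character vector of >= 2 DNA sequences.
#' @param family_id family label carried through to the result.
#' @return list of class `copy_alignment` with `family_id`, `ids`,
#'   `rows` (aligned strings, equal length, over \{A,C,G,T,N,-\}),
#'   `center` (id of the center sequence).
#' @export
build_msa_center_star <- function(seqs, family_id = "fam") {
  n <- length(seqs)
  if (n < 2) stop("need at least 2 sequences to align")
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%03d", seq_len(n))
  seqs <- vapply(seqs, sanitize_dna, character(1))
  ids <- names(seqs)

  if (n == 2) {
    sums <- c(0, 0)
  } else {
    sums <- vapply(seq_len(n), function(j) {
      sc <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAStringSet(seqs[-j]),
        subject = Biostrings::DNAString(seqs[[j]]), type = "overlap",
        substitutionMatrix = .sub_matrix(), gapOpening = 5, gapExtension = 2,
        scoreOnly = TRUE)
      sum(sc)
    }, numeric(1))
  }
  ord <- order(-sums, ids)
  cidx <- ord[1]
  center <- seqs[[cidx]]
  clen <- nchar(center)

  others <- setdiff(seq_len(n), cidx)
  # one batched alignment of all members against the center
  star <- if (length(others) > 0) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(seqs[others]),
      subject = Biostrings::DNAString(center), type = "global",
      substitutionMatrix = .sub_matrix(), gapOpening = 5, gapExtension = 2)
    list(mem = as.character(Biostrings::alignedPattern(pa)),
         cen = as.character(Biostrings::alignedSubject(pa)))
  }
  # per alignment: insertions keyed by number of center chars consumed
  ins_len <- matrix(0L, nrow = length(others), ncol = clen + 1L)
  aln_center <- vector("list", length(others))
  aln_member <- vector("list", length(others))
  for (k in seq_along(others)) {
    # global alignment strings carry the full sequences (end gaps included)
    cp <- str2chars(star$cen[k])
    mp <- str2chars(star$mem[k])
    stopifnot(sum(cp != "-") == clen,
              sum(mp != "-") == nchar(seqs[[others[k]]]))
    # record insertions (center gap runs) by center position consumed
    consumed <- 0L
    run <- 0L
    for (pos in seq_along(cp)) {
      if (cp[pos] == "-") run <- run + 1L
      else {
        if (run > 0) { ins_len[k, consumed + 1L] <- run; run <- 0L }
        consumed <- consumed + 1L
      }
    }
    if (run > 0) ins_len[k, consumed + 1L] <- run
    aln_center[[k]] <- cp
    aln_member[[k]] <- mp
  }
  maxins <- if (length(others) > 0) apply(ins_len, 2, max) else rep(0L, clen + 1L)

  build_row <- function(cp, mp) {
    out <- character(0)
    consumed <- 0L
    buf <- character(0)
    flush <- function(out, buf, consumed) {
      pad <- maxins[consumed + 1L] - length(buf)
      c(out, buf, rep("-", pad))
    }
    for (pos in seq_along(cp)) {
      if (cp[pos] == "-") buf <- c(buf, mp[pos])
      else {
        out <- flush(out, buf, consumed)
        buf <- character(0)
        out <- c(out, mp[pos])
        consumed <- consumed + 1L
      }
    }
    out <- flush(out, buf, consumed)
    paste(out, collapse = "")
  }

  rows <- character(n)
  center_chars <- str2chars(center)
  crow <- character(0)
  for (p in 0:clen) {
    crow <- c(crow, rep("-", maxins[p + 1L]),
              if (p < clen) center_chars[p + 1L] else character(0))
  }
  rows[cidx] <- paste(crow, collapse = "")
  for (k in seq_along(others))
    rows[others[k]] <- build_row(aln_center[[k]], aln_member[[k]])

  stopifnot(length(unique(nchar(rows))) == 1)
  structure(list(family_id = family_id, ids = ids, rows = setNames(rows, ids),
                 center = ids[cidx]),
            class = "copy_alignment")
}

#' Majority-rule consensus from a copy alignment
#'
#' Columns with more than 50% gaps are dropped; in the remaining columns the
#' consensus base is the most frequent of A/C/G/T (N is ignored), with ties
#' broken in the fixed order A < C < G < T. Support is the fraction of all
#' members matching the consensus base in that column.
#'
#' @param aln a `copy_alignment` from [build_msa_center_star()].
#' @param max_gap_frac gap fraction above which a column is dropped.
#' @return list of class `consensus_model` with `family_id`, `seq`,
#'   `support` (numeric per consensus position), `n_members`.
#' @export
majority_consensus <- function(aln, max_gap_frac = 0.5) {
  m <- do.call(rbind, strsplit(unname(aln$rows), "", fixed = TRUE))
  n <- nrow(m)
  keep <- colMeans(m == "-") <= max_gap_frac
  m <- m[, keep, drop = FALSE]
  seq <- character(ncol(m))
  supp <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    cnt <- c(A = sum(m[, j] == "A"), C = sum(m[, j] == "C"),
             G = sum(m[, j] == "G"), T = sum(m[, j] == "T"))
    if (all(cnt == 0)) { seq[j] <- "N"; supp[j] <- 0; next }
    b <- names(cnt)[which.max(cnt)]  # which.max takes first -> A<C<G<T ties
    seq[j] <- b
    supp[j] <- cnt[[b]] / n
  }
  structure(list(family_id = aln$family_id, seq = paste(seq, collapse = ""),
                 support = supp, n_members = n),
            class = "consensus_model")
}

#' Reconstruct a family consensus from genomic copies
#'
#' Convenience wrapper: selects a reconstruction set (coverage >= `min_qcov`
#' of the query, capped at `max_members` members by coverage then identity),
#' aligns it by center-star, and returns the majority consensus.
#'
#' @param copies hit data.frame (with `seq`, `qcov`, `identity` columns).
#' @param family_id family label.
#' @param min_qcov minimum query coverage for the reconstruction set.
#' @param max_members cap on the number of copies aligned.
#' @return a `consensus_model` (see [majority_consensus()]).
#' @export
reconstruct_consensus <- function(copies, family_id = "fam",
                                  min_qcov = 0.9, max_members = 60L) {
  set <- copies[copies$qcov >= min_qcov, , drop = FALSE]
  if (nrow(set) < 2) stop("fewer than 2 full-length copies to align")
  set <- set[order(-set$qcov, -set$identity, set$contig, set$start), ]
  set <- utils::head(set, max_members)
  seqs <- setNames(set$seq, paste0(family_id, ".", seq_len(nrow(set))))
  majority_consensus(build_msa_center_star(seqs, family_id))
}

#' Refine element boundaries against an empty site
#'
#' Aligns the left and right flanks of a filled locus (element plus flanking
#' host sequence) to the orthologous/paralogous empty-site sequence. Element
#' boundaries are the innermost positions where the flank alignments end. If
#' the two flank alignments overlap on the empty site by k >= `min_tsd` bp,
#' that duplicated segment is the target site duplication.
#'
#' @param filled_locus DNA string: left flank + element + right flank.
#' @param empty_site DNA string of the empty (element-free) locus.
#' @param flank_bp length of the flanks included in `filled_locus` (>= 100
#'   each side).
#' @param overhang extra bases of `filled_locus` past each nominal flank
#'   included in the alignment, so boundaries can move inward or outward;
#'   the default (NULL) spans the whole candidate element plus 60 bp, which
#'   lets the boundaries collapse to zero when the locus carries no
#'   insertion at all.
#' @param min_identity flank alignments below this identity give a
#'   `"no_orthologous_site"` status.
#' @param min_flank_aln minimum flank alignment length (bp); shorter chance
#'   matches do not count as an orthologous site.
#' @param min_tsd minimum reported TSD length.
#' @return list with `status` ("ok" or "no_orthologous_site"), `element`
#'   (0-based half-open interval on `filled_locus`, or NULL), and `tsd`
#'   (list(left, right, length, mismatches) or NULL).
#' @export
refine_boundaries_empty_site <- function(filled_locus, empty_site,
                                         flank_bp = 500L, overhang = NULL,
                                         min_identity = 0.70,
                                         min_flank_aln = 100L,
                                         min_tsd = 5L) {
  filled_locus <- sanitize_dna(filled_locus)
  empty_site <- sanitize_dna(empty_site)
  n <- nchar(filled_locus)
  if (flank_bp < 100) stop("flanks must be >= 100 bp")
  if (n < 2 * flank_bp) stop("filled locus shorter than its two flanks")
  if (is.null(overhang)) overhang <- max(60L, n - 2L * flank_bp + 60L)

  lf_end <- min(n, flank_bp + overhang)
  left <- substr(filled_locus, 1, lf_end)
  rf_start <- max(1L, n - flank_bp - overhang + 1L)
  right <- substr(filled_locus, rf_start, n)

  all <- align_pair(left, empty_site, type = "local")
  alr <- align_pair(right, empty_site, type = "local")
  stl <- aln_stats(all$pat, all$sub)
  str <- aln_stats(alr$pat, alr$sub)
  if (is.na(stl$identity) || is.na(str$identity) ||
      stl$identity < min_identity || str$identity < min_identity ||
      stl$columns < min_flank_aln || str$columns < min_flank_aln)
    return(list(status = "no_orthologous_site", element = NULL, tsd = NULL))

  a_f <- all$pend                      # last filled pos matching empty (1-based)
  b_f <- rf_start + alr$pstart - 1L    # first filled pos matching empty
  a_e <- all$send
  b_e <- alr$sstart

  el_start0 <- a_f
  el_end0 <- b_f - 1L
  if (el_end0 <= el_start0)
    return(list(status = "ok", element = c(start = el_start0, end = el_start0),
                tsd = NULL))

  tsd <- NULL
  k <- a_e - b_e + 1L
  if (k >= min_tsd) {
    left_copy <- substr(filled_locus, a_f - k + 1L, a_f)
    right_copy <- substr(filled_locus, b_f, b_f + k - 1L)
    mm <- sum(str2chars(left_copy) != str2chars(right_copy))
    tsd <- list(left = left_copy, right = right_copy, length = k,
                mismatches = mm)
  }
  list(status = "ok", element = c(start = el_start0, end = el_end0), tsd = tsd)
}

#' Detect a target site duplication from insertion flanks
#'
#' Finds the longest suffix of the upstream flank matching a prefix of the
#' downstream flank with at most one mismatch, with length between `min_len`
#' and `max_len`. Longest wins; among equal lengths the fewer-mismatch match
#' wins. N never matches.
#'
#' @param upstream_flank sequence immediately 5' of the element.
#' @param downstream_flank sequence immediately 3' of the element.
#' @param max_len,min_len TSD length bounds.
#' @return list(left, right, length, mismatches) or NULL when no qualifying
#'   duplication exists.
#' @export
detect_tsd <- function(upstream_flank, downstream_flank,
                       max_len = 20L, min_len = 5L) {
  upstream_flank <- sanitize_dna(upstream_flank)
  downstream_flank <- sanitize_dna(downstream_flank)
  nu <- nchar(upstream_flank)
  nd <- nchar(downstream_flank)
  if (nu < max_len || nd < max_len)
    stop("flanks must be at least max_len (", max_len, ") bp")
  for (L in seq(max_len, min_len)) {
    up <- str2chars(substr(upstream_flank, nu - L + 1L, nu))
    dn <- str2chars(substr(downstream_flank, 1L, L))
    mm <- sum(!(up == dn & up %in% BASES))
    if (mm <= 1)
      return(list(left = paste(up, collapse = ""),
                  right = paste(dn, collapse = ""),
                  length = L, mismatches = mm))
  }
  NULL
}
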