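#' Default Pol III internal-promoter box motifs
#'
#' Degenerate consensus motifs (IUPAC) for the two internal promoter
#' architectures: type 2 (tRNA-like, A box + B box) and type 1 (5S-like,
#' A box + intermediate element + C box). Internal-promoter consensi vary
#' across lineages, so every motif is a plain argument that can be replaced;
#' the defaults are shaped on the canonical box consensi (the B box core
#' GTTCGANNC and its C-box relative, a shared A box, and a short
#' G-rich intermediate element).
#'
#' @return named list of IUPAC motif strings: `a_box`, `b_box`, `ie_box`,
#'   `c_box`.
#' @export
pol3_box_motifs <- function() {
  list(
    a_box = "TRGCNNARYNNG",
    b_box = "GWTCRANNC",
    ie_box = "GRYTGGG",
    c_box = "RGGTCGANNC"
  )
}

# all matches of an IUPAC motif within a sequence allowing <= max_mm
# mismatches at non-N positions; returns data.frame(start0, end0, mismatches,
# score) where score = informative positions matched
iupac_scan <- function(seq, motif, max_mm = 2L) {
  s <- str2chars(seq)
  m <- str2chars(motif)
  L <- length(m)
  n <- length(s)
  empty <- data.frame(start0 = integer(0), end0 = integer(0),
                      mismatches = integer(0), score = integer(0))
  if (n < L) return(empty)
  informative <- vapply(m, function(ch) length(IUPAC[[ch]]) < 4, logical(1))
  allowed <- IUPAC[m]
  n_win <- n - L + 1L
  # ok[w, k]: window w matches motif position k
  ok <- matrix(TRUE, n_win, L)
  for (k in seq_len(L))
    ok[, k] <- s[seq(k, k + n_win - 1L)] %in% allowed[[k]]
  # a sequence N at a degenerate-N motif position fails the class test; such
  # windows are rejected rather than counted as mismatches
  bad_n <- if (any(!informative))
    rowSums(!ok[, !informative, drop = FALSE]) > 0 else rep(FALSE, n_win)
  mm <- rowSums(!ok[, informative, drop = FALSE])
  keep <- !bad_n & mm <= max_mm
  if (!any(keep)) return(empty)
  st <- which(keep) - 1L
  data.frame(start0 = st, end0 = st + L, mismatches = mm[keep],
             score = sum(informative) - mm[keep])
}

#' Scan a consensus for RNA Pol III internal-promoter boxes
#'
#' Scans the 5' `scan_bp` bases for the type 2 (A + B box) and type 1
#' (A + IE + C box) architectures using degenerate motifs with at most
#' `max_mm` mismatches at non-degenerate positions summed over the boxes of
#' an architecture (the whole architecture shares the mismatch budget, which
#' keeps the false-positive rate on random sequence low). Spacing
#' constraints: the B box must start 25-60 bp after the A box end; for type
#' 1 the boxes must occur in order A < IE < C with gaps of `type1_gap` bp.
#' The best-scoring architecture wins (score = matched informative positions
#' summed over boxes); type 2 wins exact ties.
#'
#' @param consensus DNA string (>= 100 bp).
#' @param motifs motif list as from [pol3_box_motifs()].
#' @param scan_bp length of the 5' window scanned.
#' @param max_mm mismatches tolerated per box at informative positions.
#' @param type2_gap allowed `B.start - A.end` range (bp).
#' @param type1_gap allowed gap range for A->IE and IE->C (bp).
#' @return list of class `promoter_boxes`: `type` one of "pol3_type2",
#'   "pol3_type1", "none"; `boxes` data.frame (box, start, end, mismatches,
#'   score; 0-based half-open); `score` total.
#' @export
scan_pol3_boxes <- function(consensus, motifs = pol3_box_motifs(),
                            scan_bp = 120L, max_mm = 2L,
                            type2_gap = c(25L, 60L), type1_gap = c(1L, 40L)) {
  consensus <- sanitize_dna(consensus)
  if (nchar(consensus) < 100) stop("consensus must be >= 100 bp")
  win <- substr(consensus, 1, min(nchar(consensus), scan_bp))

  a <- iupac_scan(win, motifs$a_box, max_mm)
  b <- iupac_scan(win, motifs$b_box, max_mm)
  ie <- iupac_scan(win, motifs$ie_box, max_mm)
  cc <- iupac_scan(win, motifs$c_box, max_mm)

  best <- list(type = "none", boxes = NULL, score = -Inf)

  # type 2: A + B with spacing constraint
  if (nrow(a) > 0 && nrow(b) > 0) {
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
      gap <- b$start0[j] - a$end0[i]
      if (gap < type2_gap[1] || gap > type2_gap[2]) next
      if (a$mismatches[i] + b$mismatches[j] > max_mm) next
      sc <- a$score[i] + b$score[j]
      if (sc > best$score) {
        best <- list(type = "pol3_type2", score = sc, boxes = data.frame(
          box = c("A", "B"),
          start = c(a$start0[i], b$start0[j]),
          end = c(a$end0[i], b$end0[j]),
          mismatches = c(a$mismatches[i], b$mismatches[j]),
          score = c(a$score[i], b$score[j]), stringsAsFactors = FALSE))
      }
    }
  }

  # type 1: A < IE < C in order with gap windows
  if (nrow(a) > 0 && nrow(ie) > 0 && nrow(cc) > 0) {
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(ie))) {
      g1 <- ie$start0[j] - a$end0[i]
      if (g1 < type1_gap[1] || g1 > type1_gap[2]) next
      for (k in seq_len(nrow(cc))) {
        g2 <- cc$start0[k] - ie$end0[j]
        if (g2 < type1_gap[1] || g2 > type1_gap[2]) next
        if (a$mismatches[i] + ie$mismatches[j] + cc$mismatches[k] > max_mm)
          next
        sc <- a$score[i] + ie$score[j] + cc$score[k]
        if (sc > best$score) {  # strict ">" so type 2 wins exact ties
          best <- list(type = "pol3_type1", score = sc, boxes = data.frame(
            box = c("A", "IE", "C"),
            start = c(a$start0[i], ie$start0[j], cc$start0[k]),
            end = c(a$end0[i], ie$end0[j], cc$end0[k]),
            mismatches = c(a$mismatches[i], ie$mismatches[j], cc$mismatches[k]),
            score = c(a$score[i], ie$score[j], cc$score[k]),
            stringsAsFactors = FALSE))
        }
      }
    }
  }

  if (!is.finite(best$score)) best$score <- NA_real_
  structure(best, class = "promoter_boxes")
}

#' Classify a family head as tRNA- or 5S rRNA-derived
#'
#' Each reference head is aligned globally to the 5' `head_bp` bases of the
#' consensus (reference fully aligned, head region locally); the best
#' identity wins. The origin is the class of the best reference when its
#' identity reaches `floor` (default 0.55, below the 63-66% head identities
#' typical of real calls so those classify positively) or when the promoter
#' box architecture agrees with that class (type 2 for tRNA, type 1 for 5S);
#' otherwise "unknown".
#'
#' @param consensus family consensus sequence.
#' @param head_refs data.frame with columns `id`, `class` ("tRNA" or
#'   "5S_rRNA"), `seq`.
#' @param head_bp length of the 5' head region searched.
#' @param floor identity floor for a call on alignment alone.
#' @param boxes optional precomputed [scan_pol3_boxes()] result.
#' @return list of class `head_call`: `origin` ("tRNA", "5S_rRNA",
#'   "unknown"), `best_ref`, `head_identity`, `head_span` (0-based half-open
#'   on the consensus), `boxes`.
#' @export
classify_head <- function(consensus, head_refs, head_bp = 150L, floor = 0.55,
                          boxes = NULL) {
  if (nrow(head_refs) == 0) stop("head_refs must be non-empty")
  consensus <- sanitize_dna(consensus)
  head <- substr(consensus, 1, min(nchar(consensus), head_bp))
  ids <- numeric(nrow(head_refs))
  spans <- matrix(0L, nrow(head_refs), 2)
  for (i in seq_len(nrow(head_refs))) {
    al <- align_pair(sanitize_dna(head_refs$seq[i]), head, "global-local")
    ids[i] <- aln_stats(al$pat, al$sub)$identity
    spans[i, ] <- c(al$sstart - 1L, al$send)
  }
  ord <- order(-ids, head_refs$id)
  bi <- ord[1]
  best_id <- ids[bi]
  best_class <- head_refs$class[bi]
  if (is.null(boxes)) boxes <- scan_pol3_boxes(consensus)
  box_class <- switch(boxes$type, pol3_type2 = "tRNA", pol3_type1 = "5S_rRNA",
                      NA_character_)
  origin <- if (!is.na(best_id) &&
                (best_id >= floor ||
                 (!is.na(box_class) && box_class == best_class))) {
    best_class
  } else "unknown"
  structure(list(origin = origin, best_ref = head_refs$id[bi],
                 head_identity = best_id,
                 head_span = c(start = spans[bi, 1], end = spans[bi, 2]),
                 boxes = boxes),
            class = "head_call")
}

# lexicographically smallest rotation of a repeat unit
canonical_rotation <- function(unit) {
  n <- nchar(unit)
  rots <- vapply(seq_len(n), function(i)
    paste0(substr(unit, i, n), substr(unit, 1, i - 1)), character(1))
  min(rots)
}

# reduce a unit to its primitive period (ATAT -> AT)
primitive_unit <- function(unit) {
  n <- nchar(unit)
  for (p in seq_len(n - 1)) {
    if (n %% p == 0 &&
        unit == paste(rep(substr(unit, 1, p), n / p), collapse = ""))
      return(substr(unit, 1, p))
  }
  unit
}

#' Detect the simple-repeat 3' tail of a consensus
#'
#' Within the 3' `window` bases, searches all unit lengths 1-6 and phases
#' for the longest tandem run with at least `min_units` complete units,
#' at least `min_run_bp` bases, and purity >= `min_purity`, whose end
#' reaches within `end_slack` bp of the 3' end. Candidates are ranked by
#' matched bases (run length weighted by purity), then purity, then unit
#' length, then the 5'-most start, so a pure dinucleotide run beats a
#' sloppier longer-unit tiling that happens to stretch further.
#' The unit is reported as the canonical (lexicographically smallest)
#' rotation of its primitive period.
#'
#' @param consensus DNA string (>= `window` bp).
#' @param window 3' window length scanned.
#' @param min_units minimum number of complete units.
#' @param min_run_bp minimum run length in bases (filters the short chance
#'   runs any random window contains).
#' @param min_purity minimum fraction of run positions matching a perfect
#'   tiling of the unit.
#' @param end_slack maximum distance (bp) between run end and the 3' end.
#' @param max_unit largest unit length considered.
#' @return list of class `tail_repeat` (`unit`, `n_units`, `tail_start`
#'   0-based on the consensus, `purity`, `length`) or NULL when no tail
#'   qualifies.
#' @export
detect_tail_repeat <- function(consensus, window = 60L, min_units = 3L,
                               min_run_bp = 8L, min_purity = 0.8,
                               end_slack = 5L, max_unit = 6L) {
  consensus <- sanitize_dna(consensus)
  n <- nchar(consensus)
  if (n < window) stop("consensus shorter than tail window")
  off <- n - window  # 0-based offset of window on consensus
  w <- str2chars(substr(consensus, off + 1L, n))
  wl <- length(w)

  best <- NULL
  for (u in seq_len(max_unit)) {
    for (s in seq_len(wl - min_units * u + 1L)) {
      unit <- w[s:(s + u - 1L)]
      if (any(!(unit %in% BASES))) next
      kmax <- (wl - s + 1L) %/% u
      for (k in seq(min_units, kmax)) {
        e <- s + k * u - 1L
        if (wl - e > end_slack) next
        run <- w[s:e]
        tiled <- rep(unit, k)
        matches <- sum(run == tiled & run %in% BASES)
        purity <- matches / (k * u)
        if (purity < min_purity) next
        len <- k * u
        if (len < min_run_bp) next
        better <- is.null(best) || matches > best$matches ||
          (matches == best$matches && purity > best$purity + 1e-12) ||
          (matches == best$matches && abs(purity - best$purity) <= 1e-12 &&
             u > nchar(best$raw_unit)) ||
          (matches == best$matches && abs(purity - best$purity) <= 1e-12 &&
             u == nchar(best$raw_unit) && s < best$s)
        if (better) {
          best <- list(raw_unit = paste(unit, collapse = ""), n_units = k,
                       s = s, length = len, purity = purity,
                       matches = matches)
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  prim <- primitive_unit(best$raw_unit)
  n_units <- best$length %/% nchar(prim)
  structure(list(unit = canonical_rotation(prim), n_units = n_units,
                 tail_start = off + best$s - 1L, purity = best$purity,
                 length = best$length),
            class = "tail_repeat")
}
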