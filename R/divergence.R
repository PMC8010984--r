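#' Kimura two-parameter distance between two sequences
#'
#' Columns containing a gap or N in either sequence are dropped (pairwise
#' deletion). With transition proportion P and transversion proportion Q over
#' the retained sites, the distance is
#' `d = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))`.
#'
#' @param a,b DNA strings; if `aligned = TRUE` they must have equal length
#'   (gaps as "-"), otherwise a pairwise global alignment is computed first.
#' @param aligned whether `a` and `b` are already aligned.
#' @return list of class `k2p_distance` with `P`, `Q`, `d`, `sites`.
#' @section Errors:
#' A condition of class `"sinescout_saturated"` is signalled when
#' `1 - 2P - Q <= 0` or `1 - 2Q <= 0`; class `"sinescout_no_sites"` when no
#' comparable sites remain.
#' @export
kimura2p_distance <- function(a, b, aligned = FALSE) {
  if (!aligned) {
    al <- align_pair(sanitize_dna(a), sanitize_dna(b), type = "global")
    a <- al$pat
    b <- al$sub
  } else if (nchar(a) != nchar(b)) {
    stop("aligned sequences must have equal length")
  }
  x <- str2chars(toupper(a))
  y <- str2chars(toupper(b))
  keep <- x %in% BASES & y %in% BASES
  x <- x[keep]
  y <- y[keep]
  sites <- length(x)
  if (sites == 0)
    stop(errorCondition("no comparable sites",
                        class = c("sinescout_no_sites", "error", "condition")))
  diff <- x != y
  ts <- sum(diff & is_transition(x, y))
  tv <- sum(diff) - ts
  P <- ts / sites
  Q <- tv / sites
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop(errorCondition(
      sprintf("saturated distance (P=%.3f, Q=%.3f)", P, Q),
      class = c("sinescout_saturated", "error", "condition")))
  d <- -0.5 * log(w1) - 0.25 * log(w2)
  structure(list(P = P, Q = Q, d = d, sites = sites), class = "k2p_distance")
}

#' Integer percent identity of a copy to its consensus
#'
#' Identity is matches / alignment columns with terminal gaps excluded
#' (ends-free alignment), times 100, rounded half-up to an integer.
#'
#' @param copy copy sequence (query-oriented), or an already-computed
#'   identity fraction in `[0,1]`.
#' @param consensus consensus sequence (ignored when `copy` is numeric).
#' @return integer percent in `[0, 100]`.
#' @export
copy_identity <- function(copy, consensus = NULL) {
  frac <- if (is.numeric(copy)) {
    copy
  } else {
    if (is.null(consensus)) stop("consensus required for a sequence copy")
    pair_identity(copy, consensus, type = "overlap")
  }
  as.integer(round_half_up(frac * 100))
}

#' Mean K2P divergence of a family's copies to the consensus
#'
#' Copies must be pre-filtered with [select_divergence_set()]. Copies whose
#' distance is saturated or has no comparable sites are excluded from the
#' mean and counted separately.
#'
#' @param copies hit data.frame with a `seq` column, or character vector of
#'   copy sequences.
#' @param consensus consensus sequence.
#' @return list with `mean_d`, `n_used`, `n_excluded`, `d` (per-copy vector,
#'   NA for excluded copies).
#' @export
family_divergence_summary <- function(copies, consensus) {
  seqs <- if (is.data.frame(copies)) copies$seq else copies
  if (length(seqs) == 0) stop("empty copy set")
  al <- align_many(vapply(seqs, sanitize_dna, character(1)),
                   sanitize_dna(consensus), type = "global")
  d <- rep(NA_real_, length(seqs))
  for (i in seq_along(seqs)) {
    d[i] <- tryCatch(kimura2p_distance(al$pat[i], al$sub[i], aligned = TRUE)$d,
                     sinescout_saturated = function(e) NA_real_,
                     sinescout_no_sites = function(e) NA_real_)
  }
  used <- !is.na(d)
  if (!any(used)) stop("no copies with a defined K2P distance")
  list(mean_d = mean(d[used]), n_used = sum(used),
       n_excluded = sum(!used), d = d)
}

#' Relative-age distribution of a family
#'
#' Histogram of copy-to-consensus integer percent identities over the bins
#' 80..100 (zero-count bins retained). Identities are taken from the same
#' alignments used for copy counting (the `identity` column of the hits), so
#' no realignment happens here.
#'
#' @param copies hit data.frame (with `identity` column) or numeric vector of
#'   identity fractions.
#' @param family_id family label.
#' @return list of class `age_profile`: `family_id`, `bins` (named integer
#'   vector, names "80".."100"), `n_total`.
#' @export
age_distribution <- function(copies, family_id = "fam") {
  fr <- if (is.data.frame(copies)) copies$identity else copies
  pct <- vapply(fr, copy_identity, integer(1))
  pct <- pmin(pmax(pct, 80L), 100L)
  bins <- table(factor(pct, levels = 80:100))
  bins <- setNames(as.integer(bins), names(bins))
  structure(list(family_id = family_id, bins = bins, n_total = length(pct)),
            class = "age_profile")
}
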