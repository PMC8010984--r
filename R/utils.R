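#' @importFrom Biostrings DNAString DNAStringSet pairwiseAlignment reverseComplement
#' @importFrom Biostrings nucleotideSubstitutionMatrix aligned pattern subject
#' @importFrom methods is
#' @importFrom stats runif setNames
NULL

BASES <- c("A", "C", "G", "T")

# IUPAC degeneracy map used for promoter-box motifs
IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"), S = c("C", "G"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of a DNA string
#'
#' @param x character scalar over \{A,C,G,T,N\}.
#' @return character scalar, the reverse complement.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Random DNA sequence
#'
#' i.i.d. background sequence at a given GC content, drawn from the current RNG
#' stream (seed it with `set.seed()` for reproducibility).
#'
#' @param n length in bp.
#' @param gc GC fraction in (0,1).
#' @return character scalar of length `n`.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc > 0, gc < 1)
  if (n == 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

# split a DNA string into a character vector of single bases
str2chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# uppercase and map any symbol outside {A,C,G,T,N} to N
sanitize_dna <- function(x) {
  x <- toupper(x)
  gsub("[^ACGTN]", "N", x)
}

# round half-up to integer (base round() is half-even)
round_half_up <- function(x) floor(x + 0.5)

# scoring matrix over ACGTN: +1 match, -2 mismatch, N scores -1 vs anything
# (N never counts as a match anywhere in the package)
.sub_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      bases <- c(BASES, "N")
      mm <- matrix(-2, 5, 5, dimnames = list(bases, bases))
      diag(mm) <- 1
      mm["N", ] <- -1
      mm[, "N"] <- -1
      m <<- mm
    }
    m
  }
})

# alignment statistics from two equal-length aligned strings (with '-')
# matches count only equal A/C/G/T; terminal-gap columns can be trimmed first
aln_stats <- function(pa, sa) {
  p <- str2chars(pa)
  s <- str2chars(sa)
  stopifnot(length(p) == length(s))
  cols <- length(p)
  matches <- sum(p == s & p %in% BASES)
  list(matches = matches, columns = cols,
       identity = if (cols > 0) matches / cols else NA_real_)
}

# pairwise alignment wrapper returning aligned strings plus coordinates.
# type: "local", "global", "overlap", "global-local" (Biostrings semantics)
align_pair <- function(a, b, type = "global") {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(a), subject = Biostrings::DNAString(b),
    type = type, substitutionMatrix = .sub_matrix(),
    gapOpening = 5, gapExtension = 2
  )
  list(
    pat = as.character(Biostrings::alignedPattern(pa)),
    sub = as.character(Biostrings::alignedSubject(pa)),
    pstart = pa@pattern@range@start,
    pend = pa@pattern@range@start + pa@pattern@range@width - 1L,
    sstart = pa@subject@range@start,
    send = pa@subject@range@start + pa@subject@range@width - 1L,
    score = pa@score
  )
}

# identity between two sequences under a given alignment type;
# columns = full alignment length (internal gaps count as mismatch; for
# "overlap"/"local" types terminal gaps are not part of the alignment)
pair_identity <- function(a, b, type = "overlap") {
  al <- align_pair(a, b, type)
  aln_stats(al$pat, al$sub)$identity
}

# batched pairwise alignment of many sequences against one reference;
# returns list(pat, sub) of aligned string vectors (same alignment
# conventions as align_pair)
align_many <- function(seqs, ref, type = "global") {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(seqs),
    subject = Biostrings::DNAString(ref), type = type,
    substitutionMatrix = .sub_matrix(), gapOpening = 5, gapExtension = 2)
  list(pat = as.character(Biostrings::alignedPattern(pa)),
       sub = as.character(Biostrings::alignedSubject(pa)))
}

# identities of many sequences against one reference (vectorized DP)
batch_identity <- function(seqs, ref, type = "overlap") {
  al <- align_many(seqs, ref, type)
  vapply(seq_along(seqs), function(i)
    aln_stats(al$pat[i], al$sub[i])$identity, numeric(1))
}

# expected transition (P) and transversion (Q) proportions after evolving a
# site for K2P distance d with transition:transversion count ratio kappa
#' Expected K2P substitution proportions
#'
#' For a Kimura two-parameter process run to total distance `d` with
#' transition:transversion count ratio `kappa`, returns the expected observed
#' transition proportion P and transversion proportion Q between the start and
#' end sequences (multiple hits accounted for).
#'
#' @param d K2P distance (substitutions/site), `0 <= d`.
#' @param kappa transition:transversion ratio (> 0).
#' @return list with elements `P` and `Q`.
#' @export
k2p_expected_pq <- function(d, kappa = 2) {
  stopifnot(d >= 0, kappa > 0)
  at <- d * kappa / (kappa + 1)      # alpha * t
  bt <- d / (2 * (kappa + 1))        # beta * t
  P <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  Q <- 0.5 - 0.5 * exp(-4 * bt)
  list(P = P, Q = Q)
}

is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}
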