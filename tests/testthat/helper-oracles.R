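# Independent oracles used across the suite. These deliberately re-derive
# results by brute force or by a different algorithm than the package.

oracle_submat <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      b <- c("A", "C", "G", "T", "N")
      mm <- matrix(-2, 5, 5, dimnames = list(b, b))
      diag(mm) <- 1
      mm["N", ] <- -1
      mm[, "N"] <- -1
      m <<- mm
    }
    m
  }
})

# exhaustive local-alignment hit enumeration by iterative best-hit masking,
# one full Smith-Waterman against the whole contig per iteration
oracle_local_hits <- function(query, genome, min_id, min_len) {
  acgt <- c("A", "C", "G", "T")
  res <- list()
  for (ci in seq_along(genome)) {
    contig <- names(genome)[ci]
    for (strand in c("+", "-")) {
      q <- if (strand == "+") query else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(query)))
      subj <- genome[[ci]]
      repeat {
        pa <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(q), Biostrings::DNAString(subj),
          type = "local", substitutionMatrix = oracle_submat(),
          gapOpening = 5, gapExtension = 2)
        p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
        s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
        cols <- length(p)
        if (cols == 0) break
        ident <- sum(p == s & p %in% acgt) / cols
        sstart <- pa@subject@range@start
        send <- sstart + pa@subject@range@width - 1L
        if (ident < min_id || cols < min_len) break
        res[[length(res) + 1L]] <- data.frame(
          contig = contig, start = sstart - 1L, end = send,
          strand = strand, identity = ident, aln_len = cols,
          stringsAsFactors = FALSE)
        # mask the matched subject region and look for the next hit
        substr(subj, sstart, send) <- paste(rep("N", send - sstart + 1L),
                                            collapse = "")
      }
    }
  }
  if (length(res) == 0)
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      identity = numeric(0), aln_len = integer(0)))
  out <- do.call(rbind, res)
  out[order(out$contig, out$start), ]
}

# brute-force insertion-context classification: enumerate every feature of
# every gene, collect all hits of the copy midpoint, apply the precedence
# list, break gene ties by smaller gene_id
oracle_context <- function(copies, genes, downstream_bp = 5000L) {
  levels <- c("CDS", "UTR5", "UTR3", "exon_nc", "intron",
              "downstream_5k", "upstream_5k", "intergenic")
  n <- nrow(copies)
  out_cat <- character(n)
  out_gene <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    mid <- copies$start[i] + (copies$end[i] - copies$start[i]) %/% 2
    hits <- list()
    for (g in genes) {
      if (g$contig != copies$contig[i]) next
      inside <- function(m) nrow(m) > 0 &&
        any(mid >= m[, 1] & mid < m[, 2])
      if (inside(g$cds)) hits[[length(hits) + 1]] <- c("CDS", g$gene_id)
      if (inside(g$utr5)) hits[[length(hits) + 1]] <- c("UTR5", g$gene_id)
      if (inside(g$utr3)) hits[[length(hits) + 1]] <- c("UTR3", g$gene_id)
      if (inside(g$exons)) hits[[length(hits) + 1]] <- c("exon_nc", g$gene_id)
      ex <- g$exons[order(g$exons[, 1]), , drop = FALSE]
      if (nrow(ex) > 1) {
        introns <- cbind(ex[-nrow(ex), 2], ex[-1, 1])
        if (any(mid >= introns[, 1] & mid < introns[, 2]))
          hits[[length(hits) + 1]] <- c("intron", g$gene_id)
      }
      gs <- g$span[["start"]]; ge <- g$span[["end"]]
      down <- if (g$strand == "+") c(ge, ge + downstream_bp)
              else c(max(0, gs - downstream_bp), gs)
      up <- if (g$strand == "+") c(max(0, gs - downstream_bp), gs)
            else c(ge, ge + downstream_bp)
      if (mid >= down[1] && mid < down[2])
        hits[[length(hits) + 1]] <- c("downstream_5k", g$gene_id)
      if (mid >= up[1] && mid < up[2])
        hits[[length(hits) + 1]] <- c("upstream_5k", g$gene_id)
    }
    if (length(hits) == 0) {
      out_cat[i] <- "intergenic"
    } else {
      hm <- do.call(rbind, hits)
      rank <- match(hm[, 1], levels)
      ord <- order(rank, hm[, 2])
      out_cat[i] <- hm[ord[1], 1]
      out_gene[i] <- hm[ord[1], 2]
    }
  }
  data.frame(category = out_cat, gene_id = out_gene, stringsAsFactors = FALSE)
}

# naive tandem-repeat search: all (unit, phase, extent) candidates, same
# objective ordering as the package documents (matched bases, purity, unit
# length, start)
oracle_tail <- function(seq, window = 60L, min_units = 3L, min_run_bp = 8L,
                        min_purity = 0.8, end_slack = 5L, max_unit = 6L) {
  acgt <- c("A", "C", "G", "T")
  n <- nchar(seq)
  w <- strsplit(substr(seq, n - window + 1L, n), "")[[1]]
  wl <- length(w)
  best <- NULL
  for (u in seq_len(max_unit)) for (s in seq_len(wl)) {
    if (s + min_units * u - 1L > wl) next
    unit <- w[s:(s + u - 1L)]
    if (any(!(unit %in% acgt))) next
    for (k in min_units:((wl - s + 1L) %/% u)) {
      e <- s + k * u - 1L
      if (wl - e > end_slack) next
      run <- w[s:e]
      mt <- sum(run == rep(unit, k) & run %in% acgt)
      pur <- mt / (k * u)
      if (pur < min_purity) next
      len <- k * u
      if (len < min_run_bp) next
      repl <- is.null(best) || mt > best$mt ||
        (mt == best$mt && pur > best$pur + 1e-12) ||
        (mt == best$mt && abs(pur - best$pur) <= 1e-12 && u > best$u) ||
        (mt == best$mt && abs(pur - best$pur) <= 1e-12 && u == best$u &&
           s < best$s)
      if (repl) best <- list(unit = paste(unit, collapse = ""), len = len,
                             pur = pur, u = u, s = s, mt = mt)
    }
  }
  best
}

# brute-force TSD: every length from max down, suffix-vs-prefix comparison
oracle_tsd_len <- function(up, down, max_len = 20L, min_len = 5L) {
  acgt <- c("A", "C", "G", "T")
  nu <- nchar(up)
  for (L in max_len:min_len) {
    a <- strsplit(substr(up, nu - L + 1L, nu), "")[[1]]
    b <- strsplit(substr(down, 1L, L), "")[[1]]
    if (sum(!(a == b & a %in% acgt)) <= 1) return(L)
  }
  NULL
}

# textbook neighbor-joining, independent of ape; returns canonical internal
# bipartitions (the side not containing the first label, sorted)
oracle_nj_bipartitions <- function(D) {
  labels <- rownames(D)
  all_l <- labels
  clusters <- as.list(labels)
  bips <- list()
  while (length(clusters) > 3) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    newset <- c(clusters[[i]], clusters[[j]])
    bips[[length(bips) + 1L]] <- newset
    keep <- setdiff(seq_len(n), c(i, j))
    newd <- 0.5 * (D[i, keep] + D[j, keep] - D[i, j])
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd),
               c(newd, 0))
    clusters <- c(clusters[keep], list(newset))
  }
  canonicalize_splits(bips, sort(all_l))
}

canonicalize_splits <- function(sides, all_labels) {
  out <- character(0)
  for (s in sides) {
    side <- if (all_labels[1] %in% s) setdiff(all_labels, s) else s
    if (length(side) < 2 || length(side) > length(all_labels) - 2) next
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  sort(unique(out))
}

# canonical bipartitions of an ape tree
tree_bipartitions <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  sides <- lapply(pp, function(idx) labs[idx])
  canonicalize_splits(sides, sort(labs))
}

# small convenience: seeded random DNA via the package generator
rdna <- function(n, gc = 0.5) sinescout::random_dna(n, gc)
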