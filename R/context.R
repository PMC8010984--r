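CONTEXT_LEVELS <- c("CDS", "UTR5", "UTR3", "exon_nc", "intron",
                    "downstream_5k", "upstream_5k", "intergenic")

# flatten gene models into one feature table (0-based half-open)
gene_feature_table <- function(genes, downstream_bp = 5000L,
                               upstream_bp = 5000L) {
  rows <- list()
  add <- function(gene, type, m) {
    if (is.null(m) || nrow(m) == 0) return()
    m <- m[m[, 2] > m[, 1], , drop = FALSE]
    if (nrow(m) == 0) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      contig = gene$contig, start = m[, 1], end = m[, 2], type = type,
      gene_id = gene$gene_id, stringsAsFactors = FALSE)
  }
  for (g in genes) {
    add(g, "CDS", g$cds)
    add(g, "UTR5", g$utr5)
    add(g, "UTR3", g$utr3)
    add(g, "exon_nc", g$exons)   # precedence resolves CDS/UTR inside exons
    # introns: gaps between consecutive exons within the span
    if (nrow(g$exons) > 1) {
      ex <- g$exons[order(g$exons[, 1]), , drop = FALSE]
      istart <- ex[-nrow(ex), 2]
      iend <- ex[-1, 1]
      ok <- iend > istart
      if (any(ok)) add(g, "intron", cbind(istart[ok], iend[ok]))
    }
    gs <- g$span[["start"]]
    ge <- g$span[["end"]]
    if (g$strand == "+") {
      add(g, "downstream_5k", cbind(ge, ge + downstream_bp))
      add(g, "upstream_5k", cbind(max(0L, gs - upstream_bp), gs))
    } else {
      add(g, "downstream_5k", cbind(max(0L, gs - downstream_bp), gs))
      add(g, "upstream_5k", cbind(ge, ge + upstream_bp))
    }
  }
  if (length(rows) == 0)
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), type = character(0),
                      gene_id = character(0)))
  do.call(rbind, rows)
}

#' Classify insertion contexts of copies relative to gene models
#'
#' Each copy is classified by its midpoint with precedence
#' CDS > UTR5 > UTR3 > exon_nc > intron > downstream_5k > upstream_5k >
#' intergenic when features of several (possibly nested) genes overlap; the
#' reported gene is the one contributing the winning feature, ties broken by
#' the smaller gene_id. Downstream/upstream windows extend `downstream_bp`
#' from the gene span, respecting strand. `distance_to_gene` is 0 for genic
#' categories, the distance from the midpoint to the gene span for flank
#' categories, and the distance to the nearest gene on the contig (NA when
#' none) for intergenic copies.
#'
#' @param copies data.frame with `contig`, `start`, `end` (0-based
#'   half-open).
#' @param genes list of gene models (see [read_gff3()]).
#' @param downstream_bp flank window size (bp).
#' @param known_contigs optional character vector; copies on contigs outside
#'   it (or outside the genes' contigs when NULL and no gene shares the
#'   contig... always supply for strict checking) raise an error.
#' @return the `copies` data.frame with added `category` (factor over the
#'   eight categories), `gene_id`, `distance_to_gene`.
#' @export
classify_insertion_context <- function(copies, genes, downstream_bp = 5000L,
                                       known_contigs = NULL) {
  if (!is.null(known_contigs)) {
    bad <- setdiff(unique(copies$contig), known_contigs)
    if (length(bad) > 0) stop("copy on unknown contig: ", bad[1])
  }
  feats <- gene_feature_table(genes, downstream_bp, downstream_bp)
  mid <- copies$start + (copies$end - copies$start) %/% 2L

  category <- rep("intergenic", nrow(copies))
  gene_id <- rep(NA_character_, nrow(copies))
  distance <- rep(NA_real_, nrow(copies))

  if (nrow(feats) > 0 && nrow(copies) > 0) {
    fgr <- GenomicRanges::GRanges(feats$contig,
                                  IRanges::IRanges(feats$start + 1L, feats$end))
    mgr <- GenomicRanges::GRanges(copies$contig, IRanges::IRanges(mid + 1L, mid + 1L))
    ov <- GenomicRanges::findOverlaps(mgr, fgr)
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    if (length(qh) > 0) {
      rank <- match(feats$type[sh], CONTEXT_LEVELS)
      ord <- order(qh, rank, feats$gene_id[sh])
      first <- !duplicated(qh[ord])
      pick_q <- qh[ord][first]
      pick_s <- sh[ord][first]
      category[pick_q] <- feats$type[pick_s]
      gene_id[pick_q] <- feats$gene_id[pick_s]
    }
  }

  # distances
  spans <- data.frame(
    contig = vapply(genes, `[[`, character(1), "contig"),
    start = vapply(genes, function(g) g$span[["start"]], numeric(1)),
    end = vapply(genes, function(g) g$span[["end"]], numeric(1)),
    gene_id = vapply(genes, `[[`, character(1), "gene_id"),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(copies))) {
    cat_i <- category[i]
    if (cat_i %in% c("CDS", "UTR5", "UTR3", "exon_nc", "intron")) {
      distance[i] <- 0
    } else {
      sp <- spans[spans$contig == copies$contig[i], , drop = FALSE]
      if (nrow(sp) == 0) next
      d <- pmax(sp$start - mid[i] - 1, mid[i] - sp$end + 1, 0)
      if (cat_i == "intergenic") {
        distance[i] <- min(d)
      } else {
        j <- which(sp$gene_id == gene_id[i])
        distance[i] <- d[j]
      }
    }
  }

  copies$category <- factor(category, levels = CONTEXT_LEVELS)
  copies$gene_id <- gene_id
  copies$distance_to_gene <- distance
  copies
}

#' Per-gene insertion counts and per-family category summary
#'
#' Summarizes classified insertion contexts: per-family counts and fractions
#' over the eight categories, per-gene copy counts per family (genic
#' categories only: CDS, UTR5, UTR3, exon_nc, intron), and the genes carrying
#' at least `threshold` copies in total.
#'
#' @param contexts data.frame from [classify_insertion_context()], with a
#'   `family` column (a single family name is assumed when absent).
#' @param threshold minimum total copies for the highlighted gene list.
#' @return list of class `gene_association_report`: `category_summary`
#'   (family, category, n, fraction), `per_gene` (gene_id, family, n),
#'   `genes_at_threshold` (gene_id, total).
#' @export
per_gene_insertion_counts <- function(contexts, threshold = 10L) {
  if (!"family" %in% names(contexts)) contexts$family <- "fam"
  fams <- unique(contexts$family)
  cs <- do.call(rbind, lapply(fams, function(f) {
    sub <- contexts[contexts$family == f, ]
    tab <- table(factor(sub$category, levels = CONTEXT_LEVELS))
    data.frame(family = f, category = names(tab), n = as.integer(tab),
               fraction = as.integer(tab) / nrow(sub),
               stringsAsFactors = FALSE)
  }))
  genic <- contexts[contexts$category %in%
                      c("CDS", "UTR5", "UTR3", "exon_nc", "intron") &
                      !is.na(contexts$gene_id), , drop = FALSE]
  if (nrow(genic) > 0) {
    per_gene <- stats::aggregate(list(n = rep(1L, nrow(genic))),
                                 by = list(gene_id = genic$gene_id,
                                           family = genic$family), FUN = sum)
    totals <- stats::aggregate(list(total = per_gene$n),
                               by = list(gene_id = per_gene$gene_id), FUN = sum)
    hot <- totals[totals$total >= threshold, , drop = FALSE]
    hot <- hot[order(-hot$total, hot$gene_id), ]
  } else {
    per_gene <- data.frame(gene_id = character(0), family = character(0),
                           n = integer(0))
    hot <- data.frame(gene_id = character(0), total = integer(0))
  }
  structure(list(category_summary = cs, per_gene = per_gene,
                 genes_at_threshold = hot),
            class = "gene_association_report")
}
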