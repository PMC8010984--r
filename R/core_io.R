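#' Run configuration
#'
#' Central container for the pipeline's thresholds. The discovery regime
#' (70% identity over at least 50 bp), the copy-counting regime (80% identity
#' over at least 100 bp), and the divergence-set regime (80% identity over at
#' least 80% of the consensus length) are three distinct filters applied at
#' different stages; flank extraction is 500 bp and the gene-flank window
#' 5 kb.
#'
#' @param discovery_id minimum identity fraction for discovery search.
#' @param discovery_len minimum alignment length (bp) for discovery search.
#' @param copy_id minimum identity for copy counting.
#' @param copy_len minimum alignment length (bp) for copy counting.
#' @param div_id minimum identity for the divergence set.
#' @param div_lenfrac minimum consensus-length fraction covered for the
#'   divergence set.
#' @param flank_bp flanking sequence extracted around hits (bp).
#' @param downstream_bp gene flank window (bp) for insertion-context calls.
#' @param seed integer seed for any stochastic step.
#' @return a list of class `run_config`.
#' @export
run_config <- function(discovery_id = 0.70, discovery_len = 50L,
                       copy_id = 0.80, copy_len = 100L,
                       div_id = 0.80, div_lenfrac = 0.80,
                       flank_bp = 500L, downstream_bp = 5000L,
                       seed = 1L) {
  ids <- c(discovery_id, copy_id, div_id, div_lenfrac)
  if (any(ids <= 0 | ids > 1)) stop("identity thresholds must lie in (0, 1]")
  lens <- c(discovery_len, copy_len, flank_bp, downstream_bp)
  if (any(lens <= 0)) stop("length thresholds must be positive")
  structure(list(
    discovery_id = discovery_id, discovery_len = as.integer(discovery_len),
    copy_id = copy_id, copy_len = as.integer(copy_len),
    div_id = div_id, div_lenfrac = div_lenfrac,
    flank_bp = as.integer(flank_bp), downstream_bp = as.integer(downstream_bp),
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a FASTA file into genome records
#'
#' Sequences are uppercased on ingest and any symbol outside \{A,C,G,T,N\} is
#' mapped to N. Record order is preserved; multiline sequences are
#' concatenated.
#'
#' @param path path to a FASTA file.
#' @return a named character vector (names = sequence ids). Use
#'   [genome_records()] for a structured view.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) stop("duplicate FASTA id: ", dup[1])
  seqs <- sanitize_dna(as.character(ss))
  names(seqs) <- ids
  seqs
}

#' Structured view of a set of sequences
#'
#' @param seqs named character vector as returned by [read_fasta()].
#' @return data.frame with columns `id`, `seq`, `length`.
#' @export
genome_records <- function(seqs) {
  data.frame(id = names(seqs), seq = unname(seqs),
             length = nchar(unname(seqs)), stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), filepath = path, width = width
  )
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon/CDS features (1-based inclusive on disk) into gene
#' models with 0-based half-open internal coordinates. When a gene has several
#' mRNAs the longest one is kept. UTRs are taken from five_prime_UTR /
#' three_prime_UTR features when present, otherwise inferred as the exonic
#' sequence outside the CDS (5' vs 3' assigned by strand).
#'
#' @param path path to a GFF3 file.
#' @param contig_lengths optional named vector of contig lengths; coordinates
#'   beyond a contig's end are an error.
#' @return list of gene models; each is a list with `gene_id`, `contig`,
#'   `strand`, `span`, and interval matrices `exons`, `cds`, `utr5`, `utr3`
#'   (columns `start`, `end`; 0-based half-open, sorted).
#' @export
read_gff3 <- function(path, contig_lengths = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$ID <- as.character(df$ID)
  parent <- vapply(df$Parent, function(p)
    if (length(p) == 0) NA_character_ else as.character(p[1]), character(1))
  df$parent1 <- parent

  if (!is.null(contig_lengths)) {
    cl <- contig_lengths[as.character(df$seqnames)]
    bad <- which(!is.na(cl) & df$end > cl)
    if (length(bad) > 0)
      stop("GFF3 coordinate beyond contig end at line for feature ",
           df$type[bad[1]], " ", df$start[bad[1]], "-", df$end[bad[1]])
  }

  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  known_parents <- c(genes$ID, mrnas$ID)
  child <- df[df$type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR"), ,
              drop = FALSE]
  orphan <- is.na(child$parent1) | !(child$parent1 %in% known_parents)
  if (any(orphan)) {
    warning(sum(orphan), " child feature(s) without a known parent skipped")
    child <- child[!orphan, , drop = FALSE]
  }

  iv <- function(d) {
    if (nrow(d) == 0) return(matrix(integer(0), 0, 2,
                                    dimnames = list(NULL, c("start", "end"))))
    m <- cbind(start = d$start - 1L, end = d$end)  # to 0-based half-open
    m <- m[order(m[, 1]), , drop = FALSE]
    m
  }

  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gm <- mrnas[!is.na(mrnas$parent1) & mrnas$parent1 == g$ID, , drop = FALSE]
    if (nrow(gm) > 0) {
      pick <- gm$ID[which.max(gm$end - gm$start)]
      kids <- child[child$parent1 == pick, , drop = FALSE]
    } else {
      kids <- child[child$parent1 == g$ID, , drop = FALSE]
    }
    exons <- iv(kids[kids$type == "exon", , drop = FALSE])
    cds <- iv(kids[kids$type == "CDS", , drop = FALSE])
    utr5 <- iv(kids[kids$type == "five_prime_UTR", , drop = FALSE])
    utr3 <- iv(kids[kids$type == "three_prime_UTR", , drop = FALSE])
    strand <- as.character(g$strand)
    if (nrow(utr5) == 0 && nrow(utr3) == 0 && nrow(cds) > 0 && nrow(exons) > 0) {
      u <- infer_utrs(exons, cds, strand)
      utr5 <- u$utr5
      utr3 <- u$utr3
    }
    gene_id <- if (!is.na(g$ID)) g$ID else paste0("gene", i)
    out[[i]] <- list(
      gene_id = gene_id, contig = as.character(g$seqnames), strand = strand,
      span = c(start = g$start - 1L, end = g$end),
      exons = exons, cds = cds, utr5 = utr5, utr3 = utr3
    )
  }
  out
}

# exonic-minus-CDS intervals, split into 5'/3' sides by strand
infer_utrs <- function(exons, cds, strand) {
  ex <- IRanges::IRanges(exons[, 1] + 1L, exons[, 2])
  cd <- IRanges::IRanges(cds[, 1] + 1L, cds[, 2])
  non <- IRanges::setdiff(ex, cd)
  m <- cbind(start = IRanges::start(non) - 1L, end = IRanges::end(non))
  if (nrow(m) == 0) {
    empty <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end")))
    return(list(utr5 = empty, utr3 = empty))
  }
  cds_lo <- min(cds[, 1])
  cds_hi <- max(cds[, 2])
  before <- m[m[, 2] <= cds_lo, , drop = FALSE]
  after <- m[m[, 1] >= cds_hi, , drop = FALSE]
  if (strand == "-") list(utr5 = after, utr3 = before)
  else list(utr5 = before, utr3 = after)
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gff3()] for generator output: one gene + one mRNA per
#' model, with exon and CDS children. Internal 0-based half-open coordinates
#' are written 1-based inclusive.
#'
#' @param genes list of gene models (see [read_gff3()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (g in genes) {
    a <- function(type, s0, e0, attr)
      paste(g$contig, "sinescout", type, s0 + 1L, e0, ".", g$strand, ".", attr,
            sep = "\t")
    mid <- paste0(g$gene_id, ".t1")
    lines <- c(lines,
      a("gene", g$span[["start"]], g$span[["end"]], paste0("ID=", g$gene_id)),
      a("mRNA", g$span[["start"]], g$span[["end"]],
        paste0("ID=", mid, ";Parent=", g$gene_id)))
    for (j in seq_len(nrow(g$exons)))
      lines <- c(lines, a("exon", g$exons[j, 1], g$exons[j, 2],
                          paste0("ID=", mid, ".e", j, ";Parent=", mid)))
    for (j in seq_len(nrow(g$cds)))
      lines <- c(lines, a("CDS", g$cds[j, 1], g$cds[j, 2],
                          paste0("ID=", mid, ".c", j, ";Parent=", mid)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write copy hits as BED6
#'
#' 0-based half-open BED with `name = family:copy_index`,
#' `score = round(identity * 1000)` and the strand column set.
#'
#' @param copies data.frame of hits (see [seed_and_extend_search()]) with an
#'   optional `family` column (default family name "fam").
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_copies_bed <- function(copies, path) {
  if (nrow(copies) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  fam <- if ("family" %in% names(copies)) copies$family else "fam"
  lines <- paste(copies$contig, copies$start, copies$end,
                 paste0(fam, ":", seq_len(nrow(copies))),
                 round_half_up(copies$identity * 1000),
                 copies$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 file written by [write_copies_bed()]
#'
#' @param path path to a BED6 file.
#' @return data.frame with `contig`, `start`, `end`, `name`, `score`, `strand`
#'   (0-based half-open).
#' @export
read_copies_bed <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), strand = character(0)))
  d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(d) <- c("contig", "start", "end", "name", "score", "strand")
  d
}
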