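#' Read a genome FASTA into a DNAStringSet
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that truncates FASTA
#' headers at the first whitespace so sequence ids match GFF3 seqids.
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Locate each gene's first-exon anchor
#'
#' Parses gene/transcript/exon features from GFF3 and returns, per gene, the
#' 0-based genomic position of the 5' end of its first exon. "First exon" is
#' the 5'-most exon of the gene's 5'-most transcript; ties are broken by the
#' longest exon, then by lexicographic transcript id. Exons parented
#' directly to a gene are treated as a single unnamed transcript. Genes
#' without exons are skipped with a warning.
#'
#' @param gff3 Path to a GFF3 file, or a [GenomicRanges::GRanges] as
#'   returned by `rtracklayer::import`.
#' @param genome Optional [Biostrings::DNAStringSet]; when supplied, every
#'   annotated contig must be present (error otherwise) and anchors are
#'   checked against contig bounds.
#' @param species Optional species label copied into the result.
#' @return data.frame with columns `gene_id`, `species`, `seq_id`, `strand`,
#'   `anchor` (0-based position of the first exon's 5' base).
#' @export
gene_anchors <- function(gff3, genome = NULL, species = NA_character_) {
  gr <- if (is.character(gff3)) rtracklayer::import(gff3, format = "gff3") else gff3
  stopifnot(inherits(gr, "GRanges"))
  type <- as.character(gr$type)
  md <- S4Vectors::mcols(gr)
  first_parent <- function(p) vapply(p, function(x) if (length(x)) x[[1L]] else NA_character_, "")
  parent <- if ("Parent" %in% names(md)) first_parent(md$Parent) else rep(NA_character_, length(gr))
  id <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA_character_, length(gr))

  genes <- which(type == "gene")
  tx <- which(type %in% c("mRNA", "transcript"))
  ex <- which(type == "exon")
  tx_gene <- stats::setNames(parent[tx], id[tx])

  if (!is.null(genome)) {
    missing_ctg <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))), names(genome))
    if (length(missing_ctg))
      stop("contig(s) in annotation absent from genome: ", paste(missing_ctg, collapse = ", "))
  }

  out <- lapply(genes, function(gi) {
    gid <- id[gi]
    strand <- as.character(GenomicRanges::strand(gr[gi]))
    if (!strand %in% c("+", "-")) strand <- "+"
    # exons whose parent is one of this gene's transcripts, or the gene itself
    gene_tx <- id[tx][tx_gene[id[tx]] %in% gid]
    exi <- ex[parent[ex] %in% c(gene_tx, gid)]
    if (length(exi) == 0L) {
      warning("gene '", gid, "' has no exons; skipped")
      return(NULL)
    }
    ex_tx <- parent[exi]
    ex_tx[ex_tx %in% gid] <- "."  # direct-parented exons: one pseudo-transcript
    starts <- GenomicRanges::start(gr[exi])  # 1-based
    ends <- GenomicRanges::end(gr[exi])
    five_prime <- if (strand == "+") starts else ends
    # 5'-most transcript = transcript owning the globally 5'-most exon end
    tx_5p <- tapply(five_prime, ex_tx, function(v) if (strand == "+") min(v) else max(v))
    best_val <- if (strand == "+") min(tx_5p) else max(tx_5p)
    cand_tx <- sort(names(tx_5p)[tx_5p == best_val])
    sel <- which(ex_tx %in% cand_tx)
    sel_5p <- five_prime[sel]
    best_5p <- if (strand == "+") min(sel_5p) else max(sel_5p)
    sel <- sel[sel_5p == best_5p]
    if (length(sel) > 1L) {  # tie: longest exon, then lexicographic transcript id
      len <- ends[sel] - starts[sel] + 1L
      sel <- sel[order(-len, ex_tx[sel])][1L]
    }
    anchor <- if (strand == "+") starts[sel] - 1L else ends[sel] - 1L
    data.frame(gene_id = gid, species = species,
               seq_id = as.character(GenomicRanges::seqnames(gr[gi])),
               strand = strand, anchor = as.integer(anchor),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene_id = character(0), species = character(0),
                      seq_id = character(0), strand = character(0),
                      anchor = integer(0), stringsAsFactors = FALSE)
  if (!is.null(genome) && nrow(res)) {
    lens <- Biostrings::width(genome)[match(res$seq_id, names(genome))]
    bad <- res$anchor < 0L | res$anchor >= lens
    if (any(bad))
      stop("anchor outside contig bounds for gene(s): ",
           paste(res$gene_id[bad], collapse = ", "))
  }
  res
}

#' Extract the gene-anchored scan window
#'
#' Cuts the window spanning gene-relative positions -`upstream` .. +`downstream`
#' around a first-exon anchor (anchor base = +1; there is no position 0) and
#' orients it 5'->3' relative to the gene, so minus-strand windows are
#' reverse complemented. The genomic interval is `[anchor - upstream,
#' anchor + downstream)` for plus-strand genes and the strand mirror
#' `[anchor - downstream + 1, anchor + upstream + 1)` for minus-strand
#' genes, clipped to the contig; clipping is flagged per side.
#'
#' @param anchor One row of the [gene_anchors()] data.frame (or any list with
#'   `gene_id`, `seq_id`, `strand`, `anchor`).
#' @param genome [Biostrings::DNAStringSet] containing `anchor$seq_id`.
#' @param upstream,downstream Window extents in bp (defaults 20000/10000).
#' @return An object of class `anchored_window`: list with `gene_id`,
#'   `seq_id`, `strand`, `g_start`/`g_end` (0-based half-open, plus strand),
#'   `seq` (oriented character string), `upstream_extent`,
#'   `downstream_extent`, `clipped_upstream`, `clipped_downstream`, `anchor`.
#' @export
extract_window <- function(anchor, genome, upstream = 20000L, downstream = 10000L) {
  stopifnot(anchor$seq_id %in% names(genome), upstream >= 0L, downstream >= 0L)
  a <- as.integer(anchor$anchor)
  len <- Biostrings::width(genome)[match(anchor$seq_id, names(genome))]
  stopifnot(a >= 0L, a < len)
  if (anchor$strand == "+") {
    g_start <- max(0L, a - as.integer(upstream))
    g_end <- min(len, a + as.integer(downstream))
    up_ext <- a - g_start
    down_ext <- g_end - a
  } else {
    g_start <- max(0L, a - as.integer(downstream) + 1L)
    g_end <- min(len, a + as.integer(upstream) + 1L)
    up_ext <- g_end - a - 1L
    down_ext <- a - g_start + 1L
  }
  s <- as.character(Biostrings::subseq(genome[[anchor$seq_id]], g_start + 1L, g_end))
  if (anchor$strand == "-") s <- revcomp(s)
  structure(list(
    gene_id = anchor$gene_id, seq_id = anchor$seq_id, strand = anchor$strand,
    g_start = g_start, g_end = g_end, seq = s,
    upstream_extent = up_ext, downstream_extent = down_ext,
    clipped_upstream = up_ext < upstream,
    clipped_downstream = down_ext < downstream,
    anchor = a
  ), class = "anchored_window")
}

#' @export
print.anchored_window <- function(x, ...) {
  cat("<anchored_window> ", x$gene_id, " ", x$seq_id, ":", x$g_start, "-", x$g_end,
      " (", x$strand, ") -", x$upstream_extent, "..+", x$downstream_extent, "\n", sep = "")
  invisible(x)
}

#' Convert an oriented window position to a gene-relative offset
#'
#' The first base at/after the anchor is +1, the base immediately upstream
#' is -1; there is no position 0 (GenBank-like convention).
#'
#' @param start 0-based start position(s) within the oriented window (e.g.
#'   the `start` column of [scan_motif()] run on `window$seq`).
#' @param window An `anchored_window`.
#' @return Signed integer offset(s).
#' @export
to_gene_relative <- function(start, window) {
  stopifnot(inherits(window, "anchored_window"))
  start <- as.integer(start)
  n <- nchar(window$seq)
  if (any(start < 0L | start >= n))
    stop("position outside window [0, ", n, ")")
  ifelse(start >= window$upstream_extent,
         start - window$upstream_extent + 1L,
         start - window$upstream_extent)
}

#' Map an oriented window position back to genomic plus-strand coordinates
#'
#' @param start 0-based start within the oriented window.
#' @param length Feature length in bp.
#' @param window An `anchored_window`.
#' @return 0-based plus-strand genomic start of the feature.
#' @export
to_genomic <- function(start, length, window) {
  stopifnot(inherits(window, "anchored_window"))
  if (window$strand == "+") window$g_start + as.integer(start)
  else window$g_end - as.integer(start) - as.integer(length)
}
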