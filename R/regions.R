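#' Derive per-gene genomic region sets
#'
#' From validated gene models, derives strand-aware region intervals per
#' gene: the gene body (TSS to TES), the promoter (\code{promoter_bp}
#' upstream of the oriented gene start, 2 kb by default), the merged
#' exons and the introns (gene body minus exon union). TE models
#' (\code{is_te}) contribute a single \code{te} region spanning the body.
#'
#' The promoter is clipped at chromosome position 1; a gene starting at
#' position 1 on the + strand gets a zero-length promoter (kept as a
#' width-0 row so the degenerate case stays visible). No high-end
#' clipping is done because the GTF does not carry chromosome lengths.
#'
#' @param genes a \code{meg_genes} object from \code{\link{parse_gtf}}.
#' @param promoter_bp promoter length in bp (default 2000).
#' @return \code{data.table} of class \code{meg_regions} with columns
#'   \code{gene_id}, \code{chrom}, \code{strand}, \code{region_type}
#'   (genebody/promoter/exon/intron/te), \code{start}, \code{end}
#'   (1-based inclusive).
#' @export
derive_regions <- function(genes, promoter_bp = 2000L) {
  stopifnot(inherits(genes, "meg_genes"), promoter_bp >= 1)
  g <- genes$genes
  ex <- genes$exons
  te <- g[is_te == TRUE]
  g <- g[is_te == FALSE]
  parts <- list()
  if (nrow(te)) {
    parts$te <- te[, .(gene_id, chrom, strand, region_type = "te",
                       start, end)]
  }
  if (nrow(g)) {
    parts$body <- g[, .(gene_id, chrom, strand, region_type = "genebody",
                        start, end)]
    prom <- copy(g)
    prom[, `:=`(
      pstart = ifelse(strand == "-", end + 1L, pmax(1L, start - promoter_bp)),
      pend   = ifelse(strand == "-", end + promoter_bp, start - 1L)
    )]
    # width-0 rows (pend < pstart) mark clipped-away promoters
    prom[pend < pstart - 1L, pend := pstart - 1L]
    parts$promoter <- prom[, .(gene_id, chrom, strand,
                               region_type = "promoter",
                               start = pstart, end = pend)]
    exg <- ex[gene_id %chin% g$gene_id]
    parts$exon <- exg[, .(gene_id, chrom, strand, region_type = "exon",
                          start, end)]
    # introns: gaps between consecutive merged exons
    setorder(exg, gene_id, start)
    intr <- exg[, {
      if (.N > 1L) {
        list(start = end[-.N] + 1L, end = start[-1L] - 1L,
             chrom = chrom[1], strand = strand[1])
      } else {
        list(start = integer(0), end = integer(0),
             chrom = character(0), strand = character(0))
      }
    }, by = gene_id]
    if (nrow(intr)) {
      parts$intron <- intr[, .(gene_id, chrom, strand,
                               region_type = "intron", start, end)]
    }
  }
  rs <- rbindlist(parts, use.names = TRUE)
  setorder(rs, chrom, start, end, gene_id)
  setattr(rs, "promoter_bp", as.integer(promoter_bp))
  setattr(rs, "class", c("meg_regions", class(rs)))
  rs[]
}

#' Export a region set to BED6
#'
#' Converts 1-based inclusive intervals to 0-based half-open BED
#' coordinates, sorted by chromosome then start; zero-width rows are
#' omitted. The name column carries the gene identifier.
#'
#' @param regions a \code{meg_regions} table.
#' @param region_type one of genebody, promoter, exon, intron, te.
#' @param path output BED file.
#' @return \code{path}, invisibly.
#' @export
export_bed <- function(regions, region_type, path) {
  stopifnot(inherits(regions, "meg_regions"))
  if (!region_type %in% c("genebody", "promoter", "exon", "intron", "te"))
    stop("unknown region_type: ", region_type, call. = FALSE)
  rt <- region_type
  sub <- regions[regions$region_type == rt & regions$end >= regions$start]
  bed <- data.table(chrom = sub$chrom, start = sub$start - 1L,
                    end = sub$end, name = sub$gene_id, score = ".",
                    strand = sub$strand)
  setorder(bed, chrom, start, end)
  fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
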