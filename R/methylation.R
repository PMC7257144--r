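#' Average methylation per gene, context and region
#'
#' Aggregates per-cytosine calls into a gene x context x region table of
#' mean methylation levels. Cytosines with fewer than \code{min_coverage}
#' reads are excluded first. Two estimators are available:
#' \describe{
#'   \item{weighted}{the weighted methylation level,
#'     sum(methylated reads) / sum(total reads) over the region's
#'     cytosines of the context (default; robust to shallow sites).}
#'   \item{site_mean}{the unweighted mean of per-site levels.}
#' }
#' Region membership ignores strand (cytosines on either strand inside
#' the interval count) and a cytosine inside k overlapping regions
#' contributes to each. A cell is reported only when it retains at least
#' \code{min_sites} cytosines; absent cells are missing values.
#'
#' The chromosome namespaces of calls and regions must overlap; if fewer
#' than half of the genes have any cytosine coverage the run aborts with
#' an overlap report (this catches "1" vs "Chr1" naming mismatches).
#'
#' @param records \code{meg_records} from \code{\link{read_cgmap}}.
#' @param regions \code{meg_regions} from \code{\link{derive_regions}}.
#' @param min_coverage minimum reads per cytosine (default 4).
#' @param estimator \code{"weighted"} or \code{"site_mean"}.
#' @param min_sites minimum retained cytosines per cell (default 1).
#' @return \code{data.table} of class \code{meg_methtable} with columns
#'   \code{gene_id}, \code{context}, \code{region_type}, \code{level},
#'   \code{n_sites}, \code{total_cov}.
#' @export
average_region_methylation <- function(records, regions,
                                       min_coverage = 4L,
                                       estimator = c("weighted",
                                                     "site_mean"),
                                       min_sites = 1L) {
  estimator <- match.arg(estimator)
  stopifnot(min_coverage >= 1, min_sites >= 1)
  rchrom <- unique(records$chrom)
  gchrom <- unique(regions$chrom)
  if (!length(intersect(rchrom, gchrom))) {
    stop("no chromosome shared between methylation calls [",
         paste(head(rchrom, 5), collapse = ","), "] and annotation [",
         paste(head(gchrom, 5), collapse = ","), "]", call. = FALSE)
  }
  rec <- records[, .(chrom, pos, meth, total, context)]
  reg <- regions[regions$end >= regions$start,
                 .(gene_id, chrom, region_type, start, end)]
  rec[, `:=`(start = pos, end = pos)]
  setkey(reg, chrom, start, end)
  ov <- foverlaps(rec, reg, type = "within", nomatch = NULL)
  # naming-mismatch diagnostic runs before the coverage filter
  covered <- uniqueN(ov[region_type == "genebody" | region_type == "te",
                        gene_id])
  n_genes <- uniqueN(regions$gene_id)
  if (covered < 0.5 * n_genes) {
    stop(sprintf(paste0("only %d of %d genes have any cytosine coverage; ",
                        "check chromosome naming between inputs"),
                 covered, n_genes), call. = FALSE)
  }
  ov <- ov[total >= min_coverage]
  tab <- ov[, .(
    level = if (estimator == "weighted") sum(meth) / sum(total)
            else mean(meth / total),
    n_sites = .N,
    total_cov = sum(total)
  ), by = .(gene_id, context, region_type)]
  tab <- tab[n_sites >= min_sites]
  setorder(tab, gene_id, context, region_type)
  setattr(tab, "estimator", estimator)
  setattr(tab, "min_coverage", as.integer(min_coverage))
  setattr(tab, "class", c("meg_methtable", class(tab)))
  tab[]
}

#' Write per-context methylation tracks as bigWig files
#'
#' One bigWig per context, with the per-site methylation level (recomputed
#' from counts; multiple records at one position are pooled by counts) as
#' the track value. Chromosome sizes are taken as the maximum observed
#' position per chromosome unless supplied. The bigWig files are a
#' convenience cache for genome browsers; all analyses in this package
#' consume the exact count-based tables instead. A context with no sites
#' is skipped with a warning (the UCSC kent library cannot encode an
#' interval-less bigwig) and reported as an NA path.
#'
#' @param records \code{meg_records}.
#' @param out_prefix path prefix; files are written as
#'   \code{<prefix>.<context>.bw}.
#' @param contexts contexts to export (default all three).
#' @param seqlengths optional named vector of chromosome lengths.
#' @return named character vector of written paths, invisibly.
#' @export
write_context_bigwig <- function(records, out_prefix,
                                 contexts = VALID_CONTEXTS,
                                 seqlengths = NULL) {
  if (is.null(seqlengths)) {
    sl <- records[, .(len = max(pos)), by = chrom]
    seqlengths <- setNames(sl$len, sl$chrom)
  }
  paths <- character(0)
  for (ctx in contexts) {
    sub <- records[records$context == ctx,
                   .(meth = sum(meth), total = sum(total)),
                   by = .(chrom, pos)]
    if (nrow(sub) == 0L) {
      # the UCSC kent library cannot encode a zero-interval bigwig
      warning("no ", ctx, " sites; bigwig not written")
      paths[ctx] <- NA_character_
      next
    }
    setorder(sub, chrom, pos)
    gr <- GenomicRanges::GRanges(
      seqnames = sub$chrom,
      ranges = IRanges::IRanges(start = sub$pos, width = 1L),
      score = sub$meth / sub$total,
      seqlengths = seqlengths)
    path <- paste0(out_prefix, ".", ctx, ".bw")
    rtracklayer::export.bw(gr, path)
    paths[ctx] <- path
  }
  invisible(paths)
}
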