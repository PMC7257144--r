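#' @import data.table
#' @importFrom stats cor pchisq pnorm pt quantile rbinom rnorm rpois runif
#'   sd cov mahalanobis dist hclust kmeans median setNames dnorm
#' @importFrom utils head tail
NULL

VALID_CONTEXTS <- c("CG", "CHG", "CHH")

# Read a possibly gzip-compressed tab-delimited file into a character
# data.table without type coercion; ragged lines padded with NA.
.read_tab_raw <- function(path, skip = 0L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    lines <- readLines(con)
    if (skip > 0L && length(lines) >= skip) lines <- lines[-seq_len(skip)]
    if (length(lines) == 0L) return(data.table())
    data.table::fread(text = lines, header = FALSE, sep = "\t",
                      fill = TRUE, colClasses = "character", quote = "")
  } else {
    if (file.size(path) == 0L) return(data.table())
    data.table::fread(path, header = FALSE, sep = "\t", skip = skip,
                      fill = TRUE, colClasses = "character", quote = "")
  }
}

.is_number <- function(x) !is.na(suppressWarnings(as.numeric(x)))

#' Read a CGmap methylation-call file
#'
#' CGmap is the 8-column per-cytosine format written by BS-Seeker-family
#' aligners: chromosome, nucleotide (C for the + strand, G for the -
#' strand), 1-based position, context (CG/CHG/CHH or \code{--}),
#' dinucleotide context, methylation level, methylated read count, total
#' read count. The stored level is rounded, so the canonical level is
#' recomputed here as \code{meth_reads / total_reads}.
#'
#' Lines with context \code{--} (or any unrecognised context), zero total
#' reads, or a malformed field are skipped and counted; the counts are
#' attached as the \code{"skipped"} attribute. More than 1\% malformed
#' lines is treated as a corrupt file and raises an error.
#'
#' @param path path to a CGmap file, optionally gzip-compressed.
#' @return A \code{data.table} of class \code{meg_records} with columns
#'   \code{chrom}, \code{pos}, \code{strand}, \code{context},
#'   \code{dinuc}, \code{level}, \code{meth}, \code{total}.
#' @export
read_cgmap <- function(path) {
  raw <- .read_tab_raw(path)
  if (nrow(raw) == 0L) stop("zero valid records in ", path, call. = FALSE)
  n_in <- nrow(raw)
  if (ncol(raw) < 8L) {
    # every line short of 8 fields is malformed
    stop(sprintf("CGmap file %s: %d/%d lines malformed (>1%%)",
                 path, n_in, n_in), call. = FALSE)
  }
  pos <- suppressWarnings(as.integer(raw[[3]]))
  meth <- suppressWarnings(as.numeric(raw[[7]]))
  total <- suppressWarnings(as.numeric(raw[[8]]))
  ok_form <- !is.na(pos) & pos >= 1L & raw[[2]] %chin% c("C", "G") &
    !is.na(meth) & !is.na(total) & meth >= 0 & meth <= total
  n_malformed <- sum(!ok_form)
  if (n_malformed > 0.01 * n_in) {
    stop(sprintf("CGmap file %s: %d/%d lines malformed (>1%%)",
                 path, n_malformed, n_in), call. = FALSE)
  }
  ctx_ok <- raw[[4]] %chin% VALID_CONTEXTS
  n_context <- sum(ok_form & !ctx_ok)
  zero_tot <- total == 0
  n_zero <- sum(ok_form & ctx_ok & zero_tot, na.rm = TRUE)
  keep <- ok_form & ctx_ok & !zero_tot
  if (!any(keep)) stop("zero valid records in ", path, call. = FALSE)
  rec <- data.table(
    chrom = raw[[1]][keep],
    pos = pos[keep],
    strand = ifelse(raw[[2]][keep] == "C", "+", "-"),
    context = raw[[4]][keep],
    dinuc = raw[[5]][keep],
    meth = as.integer(round(meth[keep])),
    total = as.integer(round(total[keep]))
  )
  rec[, level := meth / total]
  setcolorder(rec, c("chrom", "pos", "strand", "context", "dinuc",
                     "level", "meth", "total"))
  setattr(rec, "skipped", c(malformed = n_malformed,
                            unknown_context = n_context,
                            zero_coverage = n_zero))
  setattr(rec, "class", c("meg_records", class(rec)))
  rec[]
}

# Collapse a trinucleotide (or longer) sequence context starting at the
# cytosine into CG / CHG / CHH; NA when unclassifiable.
.collapse_context <- function(ctx) {
  out <- rep(NA_character_, length(ctx))
  out[ctx %chin% c("CG", "CpG")] <- "CG"
  out[ctx %chin% c("CHG", "CHH")] <- ctx[ctx %chin% c("CHG", "CHH")]
  tri <- is.na(out) & nchar(ctx) >= 3L & substr(ctx, 1, 1) == "C"
  c2 <- substr(ctx, 2, 2)
  c3 <- substr(ctx, 3, 3)
  out[tri & c2 == "G"] <- "CG"
  out[tri & c2 %chin% c("A", "C", "T") & c3 == "G"] <- "CHG"
  out[tri & c2 %chin% c("A", "C", "T") & c3 %chin% c("A", "C", "T")] <- "CHH"
  out
}

.write_cgmap <- function(dt, out) {
  # CGmap stores the level rounded to two decimals; counts are canonical
  emit <- data.table(
    chrom = dt$chrom,
    nuc = ifelse(dt$strand == "+", "C", "G"),
    pos = dt$pos,
    context = dt$context,
    dinuc = dt$dinuc,
    level = sprintf("%.2f", dt$meth / dt$total),
    meth = dt$meth,
    total = dt$total
  )
  fwrite(emit, out, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Convert foreign methylation-call formats to CGmap
#'
#' Supported dialects:
#' \describe{
#'   \item{bismark_cx}{Bismark cytosine (CX) report: chrom, pos, strand,
#'     count methylated, count unmethylated, context (CpG/CHG/CHH),
#'     trinucleotide.}
#'   \item{bsmap}{BSMAP methratio.py output (header line): chr, pos,
#'     strand, context, ratio, eff_CT, C_count, CT_count, ...}
#'   \item{allc}{methylpy allc: chrom, pos, strand, trinucleotide
#'     context, mc, cov, methylated flag.}
#'   \item{methimpute}{METHimpute TSV export: chrom, pos, strand,
#'     context, counts.methylated, counts.total (header optional).}
#' }
#' Context strings are normalised to CG/CHG/CHH (trinucleotides collapsed
#' by CG* -> CG, C[ACT]G -> CHG, otherwise CHH); lines with zero coverage
#' or unclassifiable context are skipped and counted (attribute
#' \code{"skipped"} on the returned path).
#'
#' @param path input file in the given dialect.
#' @param dialect one of \code{"bismark_cx"}, \code{"bsmap"},
#'   \code{"allc"}, \code{"methimpute"}.
#' @param out path of the CGmap file to write.
#' @return \code{out}, invisibly, with attribute \code{"skipped"}.
#' @export
convert_to_cgmap <- function(path,
                             dialect = c("bismark_cx", "bsmap", "allc",
                                         "methimpute"),
                             out) {
  dialect <- match.arg(dialect)
  skip <- 0L
  if (dialect == "bsmap") skip <- 1L
  raw <- .read_tab_raw(path, skip = skip)
  if (dialect == "methimpute" && nrow(raw) > 0L && !.is_number(raw[[2]][1]))
    raw <- raw[-1L]
  if (nrow(raw) == 0L) stop("zero valid records in ", path, call. = FALSE)
  dt <- switch(dialect,
    bismark_cx = {
      m <- suppressWarnings(as.integer(raw[[4]]))
      u <- suppressWarnings(as.integer(raw[[5]]))
      data.table(chrom = raw[[1]],
                 pos = suppressWarnings(as.integer(raw[[2]])),
                 strand = raw[[3]],
                 context = .collapse_context(raw[[6]]),
                 dinuc = substr(raw[[7]], 1, 2),
                 meth = m, total = m + u)
    },
    bsmap = {
      ctx <- raw[[4]]
      # methratio context may be a 5-mer centred on the cytosine
      five <- nchar(ctx) == 5L
      ctx[five] <- substr(ctx[five], 3, 5)
      data.table(chrom = raw[[1]],
                 pos = suppressWarnings(as.integer(raw[[2]])),
                 strand = raw[[3]],
                 context = .collapse_context(ctx),
                 dinuc = ifelse(nchar(ctx) >= 2, substr(ctx, 1, 2), ctx),
                 meth = suppressWarnings(as.integer(raw[[7]])),
                 total = suppressWarnings(as.integer(raw[[8]])))
    },
    allc = {
      data.table(chrom = raw[[1]],
                 pos = suppressWarnings(as.integer(raw[[2]])),
                 strand = raw[[3]],
                 context = .collapse_context(raw[[4]]),
                 dinuc = substr(raw[[4]], 1, 2),
                 meth = suppressWarnings(as.integer(raw[[5]])),
                 total = suppressWarnings(as.integer(raw[[6]])))
    },
    methimpute = {
      data.table(chrom = raw[[1]],
                 pos = suppressWarnings(as.integer(raw[[2]])),
                 strand = raw[[3]],
                 context = .collapse_context(raw[[4]]),
                 dinuc = raw[[4]],
                 meth = suppressWarnings(as.integer(raw[[5]])),
                 total = suppressWarnings(as.integer(raw[[6]])))
    })
  n_in <- nrow(dt)
  bad_ctx <- is.na(dt$context)
  zero_cov <- is.na(dt$total) | dt$total == 0L
  bad_form <- is.na(dt$pos) | !dt$strand %chin% c("+", "-") |
    is.na(dt$meth) | (!zero_cov & dt$meth > dt$total)
  keep <- !(bad_ctx | zero_cov | bad_form)
  if (!any(keep)) stop("zero valid records in ", path, call. = FALSE)
  .write_cgmap(dt[keep], out)
  skipped <- c(unknown_context = sum(bad_ctx),
               zero_coverage = sum(zero_cov & !bad_ctx),
               malformed = sum(bad_form & !bad_ctx & !zero_cov))
  attr(out, "skipped") <- skipped
  invisible(out)
}

#' Read a two-column gene expression table
#'
#' Tab-delimited text with gene name and a non-negative expression value
#' (RPKM/FPKM/CPM-like; unit-agnostic). A header row is auto-detected:
#' if the second field of the first row is not numeric it is skipped.
#'
#' @param path path to the expression file.
#' @return \code{data.table} of class \code{meg_expr} with columns
#'   \code{gene_id}, \code{expr}.
#' @export
read_expression <- function(path) {
  raw <- .read_tab_raw(path)
  if (nrow(raw) == 0L) stop("empty expression file: ", path, call. = FALSE)
  if (ncol(raw) < 2L)
    stop("expression file must have 2 tab-separated columns: ", path,
         call. = FALSE)
  if (!.is_number(raw[[2]][1])) raw <- raw[-1L]
  if (nrow(raw) == 0L) stop("empty expression file: ", path, call. = FALSE)
  val <- suppressWarnings(as.numeric(raw[[2]]))
  if (anyNA(val) || any(!is.finite(val))) {
    bad <- raw[[1]][is.na(val) | !is.finite(val)]
    stop("non-numeric/NaN expression for gene(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (any(val < 0)) {
    bad <- raw[[1]][val < 0]
    stop("negative expression for gene(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  dup <- unique(raw[[1]][duplicated(raw[[1]])])
  if (length(dup))
    stop("duplicate gene name(s) in expression file: ",
         paste(head(dup, 5), collapse = ", "), call. = FALSE)
  et <- data.table(gene_id = raw[[1]], expr = val)
  setattr(et, "class", c("meg_expr", class(et)))
  et[]
}

#' Parse gene (or TE) models from a GTF annotation
#'
#' Builds one model per gene from the exon features: the gene body spans
#' the minimum to the maximum exon coordinate, exons are the merged union
#' over all transcripts, and the strand orients the TSS (for the minus
#' strand the TSS is the higher genomic coordinate). Transposable-element
#' annotations are handled identically with \code{feature_kind = "te"}.
#'
#' Genes whose exons fall on several chromosomes or strands are dropped
#' with a warning.
#'
#' @param path GTF file (9 columns; attributes must carry \code{gene_id}
#'   or \code{gene_name}; \code{gene_id} preferred).
#' @param feature_kind \code{"gene"} or \code{"te"}.
#' @return list of class \code{meg_genes} with elements \code{genes}
#'   (data.table: gene_id, chrom, strand, start, end, tss, tes, is_te)
#'   and \code{exons} (data.table of merged exon intervals per gene).
#' @export
parse_gtf <- function(path, feature_kind = c("gene", "te")) {
  feature_kind <- match.arg(feature_kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (length(gr) == 0L) stop("no exon features in ", path, call. = FALSE)
  ids <- S4Vectors::mcols(gr)$gene_id
  if (is.null(ids) || all(is.na(ids))) ids <- S4Vectors::mcols(gr)$gene_name
  if (is.null(ids)) stop("GTF attributes carry neither gene_id nor gene_name",
                         call. = FALSE)
  ex <- data.table(gene_id = as.character(ids),
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   strand = as.character(GenomicRanges::strand(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr))
  ex <- ex[!is.na(gene_id)]
  chk <- ex[, .(nc = uniqueN(chrom), ns = uniqueN(strand)), by = gene_id]
  bad <- chk[nc > 1L | ns > 1L, gene_id]
  if (length(bad)) {
    warning(length(bad), " gene(s) with exons on multiple chromosomes or ",
            "strands dropped: ", paste(head(bad, 5), collapse = ", "))
    ex <- ex[!gene_id %chin% bad]
  }
  if (nrow(ex) == 0L) stop("no usable gene models in ", path, call. = FALSE)
  # merge exon union per gene
  setorder(ex, gene_id, start, end)
  ex[, grp := cumsum(start > shift(cummax(end), fill = -1L) + 1L),
     by = gene_id]
  merged <- ex[, .(chrom = chrom[1], strand = strand[1],
                   start = min(start), end = max(end)),
               by = .(gene_id, grp)][, grp := NULL][]
  genes <- merged[, .(chrom = chrom[1], strand = strand[1],
                      start = min(start), end = max(end)),
                  by = gene_id]
  genes[, tss := ifelse(strand == "-", end, start)]
  genes[, tes := ifelse(strand == "-", start, end)]
  genes[, is_te := feature_kind == "te"]
  out <- list(genes = genes[], exons = merged[, .(gene_id, chrom, strand,
                                                  start, end)])
  class(out) <- "meg_genes"
  out
}

#' @export
print.meg_genes <- function(x, ...) {
  cat("meg_genes:", nrow(x$genes), "genes,", nrow(x$exons),
      "merged exons\n")
  invisible(x)
}
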