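# Merge one (context, region) slice of a methylation table with
# expression values; one row per gene carrying both.
.meth_expr_pairs <- function(meth, expr, context, region_type) {
  stopifnot(context %in% VALID_CONTEXTS)
  .ctx <- context; .rt <- region_type
  ms <- meth[context == .ctx & region_type == .rt, .(gene_id, level)]
  merged <- merge(ms, expr[, .(gene_id, expr)], by = "gene_id")
  n_dropped <- uniqueN(c(ms$gene_id, expr$gene_id)) - nrow(merged)
  setattr(merged, "n_dropped", n_dropped)
  merged
}

# t-based two-sided p-value for a correlation coefficient, n-2 df
.cor_p <- function(r, n) {
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(t), df = n - 2)
}

# 2D Gaussian product-kernel density on a grid, Scott's rule bandwidth
# h_j = sd_j * n^(-1/6). Plotting-only; never feeds statistics.
.kde2d_scott <- function(x, y, n_grid = 100L) {
  n <- length(x)
  hx <- sd(x) * n^(-1 / 6)
  hy <- sd(y) * n^(-1 / 6)
  if (hx == 0 || hy == 0) return(NULL)
  gx <- seq(min(x), max(x), length.out = n_grid)
  gy <- seq(min(y), max(y), length.out = n_grid)
  zx <- outer(gx, x, function(g, v) dnorm((g - v) / hx))
  zy <- outer(gy, y, function(g, v) dnorm((g - v) / hy))
  list(x = gx, y = gy, z = (zx %*% t(zy)) / (n * hx * hy),
       bandwidth = c(x = hx, y = hy))
}

#' Correlate region methylation with gene expression
#'
#' Pearson and Spearman correlation between per-gene methylation levels
#' (one context, one region type) and expression values, over the genes
#' carrying both. P-values come from the two-sided Student t test on the
#' coefficient, \eqn{t = r \sqrt{(n-2)/(1-r^2)}} with n-2 degrees of
#' freedom; Spearman uses average ranks for ties. A 2D kernel density
#' estimate (Scott's rule) of the pairs is attached for plotting.
#'
#' @param meth \code{meg_methtable}.
#' @param expr \code{meg_expr}.
#' @param context CG, CHG or CHH.
#' @param region_type genebody, promoter, exon, intron or te.
#' @return list of class \code{meg_correlation}: \code{pearson_r},
#'   \code{pearson_p}, \code{spearman_rho}, \code{spearman_p},
#'   \code{n_genes}, \code{pairs} (data.table), \code{kde},
#'   \code{message} (set when a coefficient is undefined).
#' @export
correlate_meth_expr <- function(meth, expr, context, region_type) {
  pairs <- .meth_expr_pairs(meth, expr, context, region_type)
  n <- nrow(pairs)
  if (n < 3L)
    stop("need >= 3 genes with both methylation and expression; got ", n,
         call. = FALSE)
  res <- list(pearson_r = NA_real_, pearson_p = NA_real_,
              spearman_rho = NA_real_, spearman_p = NA_real_,
              n_genes = n, pairs = pairs, kde = NULL, message = NULL)
  if (sd(pairs$level) == 0 || sd(pairs$expr) == 0) {
    res$message <- "zero variance in methylation or expression; correlation undefined"
  } else {
    r <- cor(pairs$level, pairs$expr)
    rho <- cor(rank(pairs$level), rank(pairs$expr))
    res$pearson_r <- r
    res$pearson_p <- .cor_p(r, n)
    res$spearman_rho <- rho
    res$spearman_p <- .cor_p(rho, n)
    res$kde <- .kde2d_scott(pairs$expr, pairs$level)
  }
  class(res) <- "meg_correlation"
  res
}

#' @export
print.meg_correlation <- function(x, ...) {
  cat(sprintf("methylation-expression correlation (n = %d genes)\n",
              x$n_genes))
  if (!is.null(x$message)) cat(" ", x$message, "\n") else
    cat(sprintf("  Pearson r = %.4f (p = %.3g); Spearman rho = %.4f (p = %.3g)\n",
                x$pearson_r, x$pearson_p, x$spearman_rho, x$spearman_p))
  invisible(x)
}

#' Ordinal (rank-based) association of methylation with expression
#'
#' Genes are ranked by expression from low to high (ties broken by gene
#' name for determinism); methylation is plotted against the rank and
#' smoothed by a centred moving average whose window shrinks at the
#' edges. Unexpressed genes (expression exactly 0) occupy the left block;
#' their boundary index is returned for the separator line.
#'
#' @inheritParams correlate_meth_expr
#' @param ma_window moving-average window in ranks (default 200).
#' @return list of class \code{meg_ordinal}: \code{ranked} (data.table
#'   gene_id, expr, level, rank), \code{curve} (smoothed levels),
#'   \code{boundary_index} (number of unexpressed genes),
#'   \code{ma_window}.
#' @export
ordinal_association <- function(meth, expr, context, region_type,
                                ma_window = 200L) {
  pairs <- .meth_expr_pairs(meth, expr, context, region_type)
  n <- nrow(pairs)
  if (ma_window < 1L || ma_window > n)
    stop("ma_window must be in [1, n_genes]; n_genes = ", n, call. = FALSE)
  setorder(pairs, expr, gene_id)
  pairs[, rank := .I]
  h1 <- (ma_window - 1L) %/% 2L
  h2 <- ma_window - 1L - h1
  cs <- c(0, cumsum(pairs$level))
  lo <- pmax(1L, seq_len(n) - h1)
  hi <- pmin(n, seq_len(n) + h2)
  curve <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  out <- list(ranked = pairs[], curve = curve,
              boundary_index = sum(pairs$expr == 0),
              ma_window = as.integer(ma_window))
  class(out) <- "meg_ordinal"
  out
}

# Deterministic expression grouping: group 0 = unexpressed (expr == 0,
# optional), groups 1..k = near-equal rank-based quantile bins of the
# expressed genes, low to high; extras go to the lowest bins.
.expression_groups <- function(pairs, n_quantiles,
                               include_unexpressed = TRUE) {
  stopifnot(n_quantiles >= 1)
  zero <- pairs[expr == 0]
  pos <- pairs[expr > 0]
  if (nrow(pos) < n_quantiles)
    stop("only ", nrow(pos), " expressed genes for ", n_quantiles,
         " quantile bins; use fewer bins", call. = FALSE)
  setorder(pos, expr, gene_id)
  base <- nrow(pos) %/% n_quantiles
  extra <- nrow(pos) %% n_quantiles
  sizes <- rep(base, n_quantiles) + c(rep(1L, extra),
                                      rep(0L, n_quantiles - extra))
  pos[, group := rep(seq_len(n_quantiles), times = sizes)]
  if (include_unexpressed && nrow(zero)) {
    zero[, group := 0L]
    pos <- rbind(zero, pos)
  }
  pos[]
}

#' Methylation distribution by expression group
#'
#' Genes are grouped as non-expressed genes (expression exactly 0; group
#' 0) and \code{n_quantiles} rank-based quantiles of the expressed genes
#' from low (group 1) to high. Per group, descriptive statistics of the
#' methylation level and the within-group Pearson correlation with
#' expression are reported, matching the spreadsheet companion of the
#' box/violin plots.
#'
#' @inheritParams correlate_meth_expr
#' @param n_quantiles number of quantile bins for expressed genes
#'   (default 5).
#' @param include_unexpressed keep group 0 (default TRUE); when FALSE,
#'   zero-expression genes are excluded and their count reported.
#' @return list of class \code{meg_groupstats}: \code{stats} (data.table:
#'   group, n, mean, sd, median, q1, q3, pearson_r, pearson_p),
#'   \code{assignments} (gene_id, expr, level, group),
#'   \code{n_unexpressed_excluded}.
#' @export
grouping_statistics <- function(meth, expr, context, region_type,
                                n_quantiles = 5L,
                                include_unexpressed = TRUE) {
  stopifnot(n_quantiles >= 2)
  pairs <- .meth_expr_pairs(meth, expr, context, region_type)
  n_zero <- sum(pairs$expr == 0)
  grp <- .expression_groups(pairs, n_quantiles, include_unexpressed)
  stats <- grp[, {
    r <- if (.N >= 3 && sd(level) > 0 && sd(expr) > 0)
      cor(level, expr) else NA_real_
    list(n = .N, mean = mean(level), sd = sd(level),
         median = median(level),
         q1 = unname(quantile(level, 0.25)),
         q3 = unname(quantile(level, 0.75)),
         pearson_r = r,
         pearson_p = if (is.na(r)) NA_real_ else .cor_p(r, .N))
  }, by = group]
  setorder(stats, group)
  out <- list(stats = stats[], assignments = grp,
              n_unexpressed_excluded = if (include_unexpressed) 0L
                                       else n_zero)
  class(out) <- "meg_groupstats"
  out
}

# Shared metagene machinery: aggregate per-(gene, window) weighted levels
# and average over genes within expression groups.
.metagene_profile <- function(winlev, groups, n_windows) {
  m <- merge(winlev, groups[, .(gene_id, group)], by = "gene_id")
  prof <- m[, .(level = mean(level)), by = .(group, win)]
  grps <- sort(unique(groups$group))
  mat <- matrix(NA_real_, nrow = length(grps), ncol = n_windows,
                dimnames = list(group = as.character(grps), window = NULL))
  mat[cbind(match(prof$group, grps), prof$win)] <- prof$level
  n_genes <- groups[gene_id %chin% unique(winlev$gene_id), .N, by = group]
  setorder(n_genes, group)
  list(matrix = mat, n_genes = n_genes)
}

#' Metagene methylation profile over scaled gene bodies
#'
#' Each gene body is divided into \code{n_body_windows} windows of equal
#' fractional length; the flanks span half of that gene's body length on
#' each side, divided into \code{n_flank_windows} windows. Window levels
#' are read-count-weighted within a gene; the group profile is the
#' unweighted mean over genes (each gene counts once), so long or deeply
#' covered genes do not dominate. Minus-strand genes are reversed so
#' window 1 is always 5'. Genes shorter than \code{n_body_windows} bp are
#' excluded and counted.
#'
#' @param records \code{meg_records}.
#' @param genes \code{meg_genes}.
#' @param expr \code{meg_expr}.
#' @param context CG, CHG or CHH.
#' @param n_body_windows windows across the gene body (default 30).
#' @param n_flank_windows windows per flank (default 15).
#' @param n_groups expression quantile groups (default 5).
#' @param include_unexpressed keep the expression-0 group (default TRUE).
#' @param min_coverage minimum reads per cytosine (default 4).
#' @return list of class \code{meg_metagene}: \code{matrix}
#'   (group x window), \code{n_genes} per group, \code{axis} (window
#'   annotation), \code{n_short_excluded}, \code{mode = "region"}.
#' @export
metagene_region <- function(records, genes, expr, context,
                            n_body_windows = 30L, n_flank_windows = 15L,
                            n_groups = 5L, include_unexpressed = TRUE,
                            min_coverage = 4L) {
  stopifnot(inherits(genes, "meg_genes"), context %in% VALID_CONTEXTS)
  g <- copy(genes$genes)
  g[, len := end - start + 1L]
  n_short <- g[len < n_body_windows, .N]
  g <- g[len >= n_body_windows]
  if (nrow(g) == 0L) stop("no gene passes the body-length filter",
                          call. = FALSE)
  g[, flank := len %/% 2L]
  .ctx <- context
  rec <- records[context == .ctx & total >= min_coverage,
                 .(chrom, pos, meth, total)]
  span <- g[, .(gene_id, chrom, strand, gstart = start, gend = end,
                len, flank, start = start - flank, end = end + flank)]
  setkey(span, chrom, start, end)
  rec[, `:=`(start = pos, end = pos)]
  ov <- foverlaps(rec, span, type = "within", nomatch = NULL)
  nb <- as.integer(n_body_windows)
  nf <- as.integer(n_flank_windows)
  W <- 2L * nf + nb
  ov[, win := {
    w <- integer(.N)
    up <- pos < gstart
    dn <- pos > gend
    bd <- !up & !dn
    w[up] <- 1L + pmin(nf - 1L,
      as.integer(floor((pos[up] - (gstart[up] - flank[up])) * nf /
                       flank[up])))
    w[bd] <- nf + 1L + pmin(nb - 1L,
      as.integer(floor((pos[bd] - gstart[bd]) * nb / len[bd])))
    w[dn] <- nf + nb + 1L + pmin(nf - 1L,
      as.integer(floor((pos[dn] - gend[dn] - 1L) * nf / flank[dn])))
    w
  }]
  ov[strand == "-", win := W + 1L - win]
  winlev <- ov[, .(level = sum(meth) / sum(total)), by = .(gene_id, win)]
  pairs <- merge(g[, .(gene_id)], expr[, .(gene_id, expr)], by = "gene_id")
  groups <- .expression_groups(pairs, n_groups, include_unexpressed)
  prof <- .metagene_profile(winlev, groups, W)
  out <- list(matrix = prof$matrix, n_genes = prof$n_genes,
              axis = c(rep("upstream", nf), rep("body", nb),
                       rep("downstream", nf)),
              n_short_excluded = n_short, mode = "region")
  class(out) <- "meg_metagene"
  out
}

#' Metagene methylation profile around TSS or TES
#'
#' Windows of width \code{flank_bp / n_windows} bp on each side of the
#' oriented anchor (TSS or TES); 2 kb flanks in 10 windows by default.
#' Setting \code{n_windows = flank_bp} yields single-base resolution.
#' Orientation follows the strand: profile window 1 is always the far 5'
#' upstream window. Group averaging is gene-weighted as in
#' \code{\link{metagene_region}}.
#'
#' @inheritParams metagene_region
#' @param anchor \code{"TSS"} or \code{"TES"}.
#' @param flank_bp flank span in bp on each side (default 2000).
#' @param n_windows windows per side (default 10).
#' @return list of class \code{meg_metagene} with \code{mode = "site"}.
#' @export
metagene_site <- function(records, genes, expr, context,
                          anchor = c("TSS", "TES"), flank_bp = 2000L,
                          n_windows = 10L, n_groups = 5L,
                          include_unexpressed = TRUE, min_coverage = 4L) {
  anchor <- match.arg(anchor)
  stopifnot(n_windows >= 1, flank_bp >= n_windows)
  g <- copy(genes$genes)
  g[, a := if (anchor == "TSS") tss else tes]
  .ctx <- context
  rec <- records[context == .ctx & total >= min_coverage,
                 .(chrom, pos, meth, total)]
  span <- g[, .(gene_id, chrom, strand, a,
                start = a - flank_bp, end = a + flank_bp)]
  setkey(span, chrom, start, end)
  rec[, `:=`(start = pos, end = pos)]
  ov <- foverlaps(rec, span, type = "within", nomatch = NULL)
  w_bp <- flank_bp / n_windows
  # oriented offset: 0 = anchor base, increasing downstream (3')
  ov[, off := ifelse(strand == "-", a - pos, pos - a)]
  ov <- ov[off >= -flank_bp & off <= flank_bp - 1L]
  ov[, win := 1L + as.integer(floor((off + flank_bp) / w_bp))]
  winlev <- ov[, .(level = sum(meth) / sum(total)), by = .(gene_id, win)]
  pairs <- merge(g[, .(gene_id)], expr[, .(gene_id, expr)], by = "gene_id")
  groups <- .expression_groups(pairs, n_groups, include_unexpressed)
  W <- 2L * as.integer(n_windows)
  prof <- .metagene_profile(winlev, groups, W)
  out <- list(matrix = prof$matrix, n_genes = prof$n_genes,
              axis = c(rep("upstream", n_windows),
                       rep("downstream", n_windows)),
              anchor = anchor, window_bp = w_bp,
              n_short_excluded = 0L, mode = "site")
  class(out) <- "meg_metagene"
  out
}

#' @export
print.meg_metagene <- function(x, ...) {
  cat(sprintf("meg_metagene (%s mode): %d groups x %d windows\n",
              x$mode, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}
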