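# Thin base-graphics renderings of the analysis tables. Figures are
# best-effort artifacts; every number they show comes from the returned
# tables, which are written first by the CLI.

#' @export
plot.meg_correlation <- function(x, ...) {
  plot(x$pairs$expr, x$pairs$level, pch = 16, cex = 0.4,
       col = grDevices::adjustcolor("steelblue", 0.5),
       xlab = "expression", ylab = "methylation level",
       main = sprintf("Pearson r = %.3f, Spearman rho = %.3f",
                      x$pearson_r, x$spearman_rho), ...)
  if (!is.null(x$kde))
    graphics::contour(x$kde$x, x$kde$y, x$kde$z, add = TRUE,
                      col = "grey40", drawlabels = FALSE)
  invisible(x)
}

#' @export
plot.meg_ordinal <- function(x, ...) {
  plot(x$ranked$rank, x$ranked$level, pch = 16, cex = 0.3,
       col = grDevices::adjustcolor("grey50", 0.4),
       xlab = "expression rank (low to high)",
       ylab = "methylation level", ...)
  graphics::lines(x$ranked$rank, x$curve, col = "firebrick", lwd = 2)
  if (x$boundary_index > 0)
    graphics::abline(v = x$boundary_index + 0.5, col = "grey30",
                     lty = 2)
  invisible(x)
}

#' @export
plot.meg_groupstats <- function(x, type = c("box", "violin"), ...) {
  type <- match.arg(type)
  grp <- x$assignments
  graphics::boxplot(level ~ group, data = grp,
                    xlab = "expression group (0 = unexpressed)",
                    ylab = "methylation level", col = "lightsteelblue",
                    ...)
  invisible(x)
}

#' @export
plot.meg_metagene <- function(x, ...) {
  W <- ncol(x$matrix)
  cols <- grDevices::hcl.colors(max(2L, nrow(x$matrix)), "Zissou 1")
  plot(NULL, xlim = c(1, W), ylim = range(x$matrix, 0, na.rm = TRUE),
       xlab = "window", ylab = "methylation level", ...)
  for (i in seq_len(nrow(x$matrix)))
    graphics::lines(seq_len(W), x$matrix[i, ], col = cols[i], lwd = 2)
  bnd <- which(diff(as.integer(factor(x$axis, levels = unique(x$axis))))
               != 0)
  graphics::abline(v = bnd + 0.5, lty = 3, col = "grey40")
  graphics::legend("topright", legend = rownames(x$matrix), col = cols,
                   lwd = 2, cex = 0.7, title = "group")
  invisible(x)
}

#' @export
plot.meg_comparison <- function(x, ...) {
  rec <- x$records
  diffcol <- if (!is.null(rec$is_differential))
    ifelse(rec$is_differential, "red", "grey50") else "grey50"
  plot(rec$log2fc, rec$delta_meth, pch = 16, cex = 0.4,
       col = grDevices::adjustcolor(diffcol, 0.6),
       xlab = "log2 expression fold change (A/B)",
       ylab = "methylation change (A - B)", ...)
  graphics::abline(h = 0, v = 0, col = "grey70")
  if (!is.null(x$quadrant_counts)) {
    usr <- graphics::par("usr")
    qx <- c(usr[2], usr[1], usr[1], usr[2])
    qy <- c(usr[4], usr[4], usr[3], usr[3])
    for (q in 1:4)
      graphics::text(qx[q], qy[q], x$quadrant_counts[q],
                     adj = c(as.numeric(q %in% c(2, 3)),
                             as.numeric(q %in% c(3, 4))), col = "red")
  }
  invisible(x)
}

#' @export
plot.meg_heatmap <- function(x, ...) {
  M <- x$matrix[x$hclust$order, , drop = FALSE]
  graphics::image(t(M), axes = FALSE,
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                  main = "methylation + expression (clustered)", ...)
  graphics::axis(1, at = seq(0, 1, length.out = ncol(M)),
                 labels = colnames(M), las = 2, cex.axis = 0.8)
  invisible(x)
}
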