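#' Configuration for the synthetic fixture generator
#'
#' Describes a small genome with planted methylation-expression
#' coupling. Per-gene latent log-expression-like scores are standard
#' normal; promoter and gene-body methylation targets are driven by
#' Gaussian-copula latents correlated with the expression score at
#' \code{promoter_rho} and \code{body_rho}. Marginal maps are kept
#' near-linear (truncated linear transforms with negligible clipping
#' mass) so the planted rho survives as a Pearson coefficient on the
#' emitted values. Read-level noise is binomial: per cytosine,
#' total reads ~ Poisson(coverage_mean) + 1 and methylated reads ~
#' Binomial(total, target level), emulating WGBS sampling.
#'
#' Defaults follow the conditions used throughout the test-bed: 2000
#' genes, promoter rho -0.5, gene-body rho +0.2, 10\% unexpressed
#' genes, mean coverage 5x.
#'
#' @param seed RNG seed (mandatory; the whole fixture is a deterministic
#'   function of the config).
#' @param n_chroms,n_genes genome layout.
#' @param gene_length_range,intergenic_range bp ranges (uniform).
#' @param exons_per_gene_range exon count range per gene.
#' @param coverage_mean mean reads per cytosine.
#' @param context_density cytosines per bp for CG, CHG, CHH.
#' @param promoter_rho,body_rho planted correlations in [-1, 1].
#' @param zero_expr_frac fraction of genes forced to expression 0 (the
#'   lowest-latent genes).
#' @param expr_mean,expr_sd linear marginal of the expression values.
#' @param meth_base,meth_slope linear marginal of methylation targets.
#' @param context_scale multiplies targets per context (CG full, CHG and
#'   CHH lower, as in plant methylomes).
#' @param background_level methylation target outside promoters/bodies.
#' @param two_group also emit a second sample group.
#' @param n_differential genes receiving \code{group_effect} in group A.
#' @param group_effect c(dmeth, dlfc): methylation-target shift and
#'   log2 expression fold change planted on the differential subset.
#' @return list of class \code{meg_synth_config}.
#' @export
synth_config <- function(seed,
                         n_chroms = 2L, n_genes = 2000L,
                         gene_length_range = c(900L, 3000L),
                         intergenic_range = c(2600L, 4000L),
                         exons_per_gene_range = c(1L, 4L),
                         coverage_mean = 5,
                         context_density = c(CG = 0.04, CHG = 0.03,
                                             CHH = 0.08),
                         promoter_rho = -0.5, body_rho = 0.2,
                         zero_expr_frac = 0.1,
                         expr_mean = 100, expr_sd = 30,
                         meth_base = 0.45, meth_slope = 0.15,
                         context_scale = c(CG = 1, CHG = 0.6,
                                           CHH = 0.35),
                         background_level = 0.1,
                         two_group = FALSE,
                         n_differential = 20L,
                         group_effect = c(dmeth = -0.3, dlfc = -2)) {
  stopifnot(!missing(seed), abs(promoter_rho) <= 1, abs(body_rho) <= 1,
            all(gene_length_range > 0), all(intergenic_range > 0),
            coverage_mean > 0, zero_expr_frac >= 0, zero_expr_frac < 1)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  class(cfg) <- "meg_synth_config"
  cfg
}

# one chromosome's gene layout; cursor leaves room for 2 kb promoters
.synth_layout <- function(cfg, gene_ids) {
  n <- length(gene_ids)
  lens <- sample(cfg$gene_length_range[1]:cfg$gene_length_range[2], n,
                 replace = TRUE)
  gaps <- sample(cfg$intergenic_range[1]:cfg$intergenic_range[2], n,
                 replace = TRUE)
  starts <- 3500L + cumsum(c(0L, (lens + gaps)[-n]))
  data.table(gene_id = gene_ids, start = starts,
             end = starts + lens - 1L, len = lens,
             strand = sample(c("+", "-"), n, replace = TRUE))
}

.synth_exons <- function(layout, cfg) {
  layout[, {
    e <- sample(cfg$exons_per_gene_range[1]:cfg$exons_per_gene_range[2],
                1L)
    nseg <- 2L * e - 1L
    if (len < nseg * 20L) { e <- 1L; nseg <- 1L }
    if (nseg == 1L) {
      list(ex_start = start, ex_end = end)
    } else {
      cuts <- sort(sample((start + 1L):(end - 1L), nseg - 1L))
      s <- c(start, cuts)
      en <- c(cuts - 1L, end)
      keep <- seq(1L, nseg, by = 2L)  # odd segments are exons
      list(ex_start = s[keep], ex_end = en[keep])
    }
  }, by = .(gene_id, chrom, strand)]
}

.write_gtf <- function(exons, path) {
  lines <- sprintf(
    "%s\tsynth\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s.t1\";",
    exons$chrom, exons$ex_start, exons$ex_end, exons$strand,
    exons$gene_id, exons$gene_id)
  writeLines(lines, path)
  invisible(path)
}

# binomial read sampling over laid-out cytosines for one sample
.synth_cgmap <- function(sites, target, cfg, path) {
  n <- nrow(sites)
  total <- rpois(n, cfg$coverage_mean) + 1L
  meth <- rbinom(n, total, target)
  dt <- data.table(chrom = sites$chrom, pos = sites$pos,
                   strand = sites$strand, context = sites$context,
                   dinuc = ifelse(sites$context == "CG", "CG",
                                  substr(sites$context, 1, 2)),
                   meth = meth, total = total)
  setorder(dt, chrom, pos)
  .write_cgmap(dt, path)
}

#' Generate a synthetic CGmap + GTF + expression fixture set
#'
#' Writes, under \code{out_dir}: \code{annotation.gtf},
#' \code{expression.txt} and \code{sample.cgmap} (single-group mode) or
#' \code{expression_A/B.txt} and \code{group_A/B.cgmap} (two-group
#' mode), plus \code{truth.tsv} recording every latent value for
#' recovery tests. Identical configs give byte-identical outputs.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @param out_dir output directory (created).
#' @return list with file paths and the \code{truth} data.table.
#' @export
synth_generate <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "meg_synth_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  n <- cfg$n_genes
  gene_ids <- sprintf("g%05d", seq_len(n))
  chrom_of <- rep(paste0("Chr", seq_len(cfg$n_chroms)), length.out = n)
  layout <- rbindlist(lapply(seq_len(cfg$n_chroms), function(i) {
    ids <- gene_ids[chrom_of == paste0("Chr", i)]
    lay <- .synth_layout(cfg, ids)
    lay[, chrom := paste0("Chr", i)]
    lay
  }))
  exons <- .synth_exons(layout, cfg)
  gtf_path <- file.path(out_dir, "annotation.gtf")
  .write_gtf(exons, gtf_path)

  # planted latents: Gaussian copula against the expression score
  z_e <- rnorm(n)
  z_p <- cfg$promoter_rho * z_e +
    sqrt(1 - cfg$promoter_rho^2) * rnorm(n)
  z_b <- cfg$body_rho * z_e + sqrt(1 - cfg$body_rho^2) * rnorm(n)
  clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  m_prom <- clamp(cfg$meth_base + cfg$meth_slope * z_p, 0.02, 0.98)
  m_body <- clamp(cfg$meth_base + cfg$meth_slope * z_b, 0.02, 0.98)
  expr <- clamp(cfg$expr_mean + cfg$expr_sd * z_e, 0.01, Inf)
  n_zero <- floor(cfg$zero_expr_frac * n)
  is_zero <- rep(FALSE, n)
  if (n_zero > 0) {
    is_zero[order(z_e)[seq_len(n_zero)]] <- TRUE
    expr[is_zero] <- 0
  }
  truth <- data.table(gene_id = gene_ids, chrom = chrom_of,
                      z_expr = z_e, expr = expr,
                      target_promoter = m_prom, target_body = m_body,
                      is_unexpressed = is_zero,
                      is_differential = FALSE)
  truth <- merge(truth,
                 layout[, .(gene_id, start, end, strand)],
                 by = "gene_id")
  setorder(truth, gene_id)

  # cytosine layout (shared across groups): uniform positions per context
  lay2 <- merge(layout, truth[, .(gene_id, m_prom = target_promoter,
                                  m_body = target_body)],
                by = "gene_id")
  chrom_len <- layout[, .(len = max(end) + 3500L), by = chrom]
  sites <- rbindlist(lapply(seq_len(nrow(chrom_len)), function(i) {
    cl <- chrom_len$len[i]
    rbindlist(lapply(names(cfg$context_density), function(ctx) {
      ns <- round(cfg$context_density[[ctx]] * cl)
      data.table(chrom = chrom_len$chrom[i],
                 pos = sort(sample.int(cl, min(ns, cl))),
                 context = ctx)
    }))
  }))
  sites[, strand := sample(c("+", "-"), .N, replace = TRUE)]
  # map sites to promoter/body targets
  reg <- rbind(
    lay2[, .(gene_id, chrom,
             start = ifelse(strand == "-", end + 1L,
                            pmax(1L, start - 2000L)),
             end = ifelse(strand == "-", end + 2000L, start - 1L),
             t_base = m_prom, what = "promoter")],
    lay2[, .(gene_id, chrom, start, end, t_base = m_body,
             what = "body")])
  reg <- reg[end >= start]
  setkey(reg, chrom, start, end)
  sites[, `:=`(start = pos, end = pos)]
  ov <- foverlaps(sites, reg, type = "within", mult = "first")
  sites[, `:=`(gene_id = ov$gene_id, t_base = ov$t_base, what = ov$what,
               start = NULL, end = NULL)]
  sites[is.na(t_base), `:=`(t_base = cfg$background_level,
                            what = "background")]
  sites[, target := t_base * cfg$context_scale[context]]
  setorder(sites, chrom, pos, context)

  write_expr <- function(e, path) {
    fwrite(data.table(gene_id = gene_ids, expr = round(e, 4)), path,
           sep = "\t", col.names = FALSE, quote = FALSE)
    path
  }
  out <- list(gtf = gtf_path, truth = truth)
  if (!cfg$two_group) {
    out$cgmap <- .synth_cgmap(sites, sites$target, cfg,
                              file.path(out_dir, "sample.cgmap"))
    out$expression <- write_expr(expr,
                                 file.path(out_dir, "expression.txt"))
  } else {
    expressed <- which(!is_zero)
    diff_idx <- sample(expressed, min(cfg$n_differential,
                                      length(expressed)))
    truth[diff_idx, is_differential := TRUE]
    dmeth <- cfg$group_effect[["dmeth"]]
    dlfc <- cfg$group_effect[["dlfc"]]
    shift <- setNames(rep(0, n), gene_ids)
    shift[gene_ids[diff_idx]] <- dmeth
    targetA <- clamp(sites$target +
                       ifelse(is.na(sites$gene_id), 0,
                              shift[sites$gene_id]) *
                       cfg$context_scale[sites$context], 0, 1)
    exprA <- expr
    exprA[diff_idx] <- expr[diff_idx] * 2^dlfc
    out$cgmapA <- .synth_cgmap(sites, targetA, cfg,
                               file.path(out_dir, "group_A.cgmap"))
    out$cgmapB <- .synth_cgmap(sites, sites$target, cfg,
                               file.path(out_dir, "group_B.cgmap"))
    out$expressionA <- write_expr(exprA,
                                  file.path(out_dir, "expression_A.txt"))
    out$expressionB <- write_expr(expr,
                                  file.path(out_dir, "expression_B.txt"))
  }
  truth_path <- file.path(out_dir, "truth.tsv")
  fwrite(truth, truth_path, sep = "\t", quote = FALSE)
  out$truth_path <- truth_path
  out
}
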