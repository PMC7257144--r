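test_that("correlate_meth_expr recovers exact and planted correlations", {
  # perfect anticorrelation
  meth <- make_methtable(c("a", "b", "c"), c(0, 0.5, 1))
  expr <- make_expr(c("a", "b", "c"), c(10, 5, 0))
  res <- correlate_meth_expr(meth, expr, "CG", "genebody")
  expect_equal(res$pearson_r, -1)
  expect_equal(res$spearman_rho, -1)
  expect_equal(res$n_genes, 3L)
  # planted rho = -0.5 at n = 2000: estimate within the Fisher-z 99% CI
  set.seed(123)
  n <- 2000
  z <- rnorm(n)
  lev <- 0.5 + 0.1 * (-0.5 * z + sqrt(1 - 0.25) * rnorm(n))
  ex <- 100 + 20 * z
  res2 <- correlate_meth_expr(make_methtable(sprintf("g%04d", 1:n), lev),
                              make_expr(sprintf("g%04d", 1:n), ex),
                              "CG", "genebody")
  ci <- atanh(-0.5) + c(-1, 1) * qnorm(0.995) / sqrt(n - 3)
  expect_gt(atanh(res2$pearson_r), ci[1])
  expect_lt(atanh(res2$pearson_r), ci[2])
  # p-value matches the t construction (oracle: cor.test)
  ct <- cor.test(lev, ex)
  expect_equal(res2$pearson_p, ct$p.value, tolerance = 1e-10)
})

test_that("zero variance yields missing coefficients with a message", {
  meth <- make_methtable(c("a", "b", "c"), c(0.3, 0.3, 0.3))
  expr <- make_expr(c("a", "b", "c"), c(1, 2, 3))
  res <- correlate_meth_expr(meth, expr, "CG", "genebody")
  expect_true(is.na(res$pearson_r))
  expect_match(res$message, "zero variance")
  expect_error(correlate_meth_expr(make_methtable("a", 0.1),
                                   make_expr("a", 1), "CG", "genebody"),
               ">= 3 genes")
})

test_that("Pearson is affine-invariant and Spearman monotone-invariant", {
  set.seed(5)
  n <- 200
  lev <- runif(n)
  ex <- 50 + 30 * lev + rnorm(n, sd = 5)
  ids <- sprintf("g%03d", 1:n)
  base <- correlate_meth_expr(make_methtable(ids, lev),
                              make_expr(ids, ex), "CG", "genebody")
  aff <- correlate_meth_expr(make_methtable(ids, lev),
                             make_expr(ids, 3 * ex + 7), "CG", "genebody")
  expect_equal(aff$pearson_r, base$pearson_r, tolerance = 1e-12)
  mono <- correlate_meth_expr(make_methtable(ids, lev),
                              make_expr(ids, exp(ex / 20)), "CG",
                              "genebody")
  expect_equal(mono$spearman_rho, base$spearman_rho, tolerance = 1e-12)
})

test_that("ordinal association ranks, marks the zero boundary and smooths", {
  ids <- letters[1:5]
  meth <- make_methtable(ids, c(0.9, 0.7, 0.5, 0.3, 0.1))
  expr <- make_expr(ids, c(0, 0, 1, 2, 3))
  res <- ordinal_association(meth, expr, "CG", "genebody", ma_window = 1)
  expect_equal(res$boundary_index, 2L)
  # ma_window = 1 reproduces the raw ranked series
  expect_equal(res$curve, res$ranked$level)
  # ties in expression break by gene name
  expect_equal(res$ranked$gene_id[1:2], c("a", "b"))
  # constant methylation gives a constant curve at any window
  m2 <- make_methtable(ids, rep(0.4, 5))
  r2 <- ordinal_association(m2, expr, "CG", "genebody", ma_window = 3)
  expect_equal(r2$curve, rep(0.4, 5))
  expect_error(ordinal_association(meth, expr, "CG", "genebody", 6),
               "ma_window")
  # moving average equals the brute-force windowed mean
  set.seed(9)
  ids3 <- sprintf("g%02d", 1:30)
  lev <- runif(30)
  ex3 <- runif(30, 1, 9)
  r3 <- ordinal_association(make_methtable(ids3, lev),
                            make_expr(ids3, ex3), "CG", "genebody",
                            ma_window = 7)
  lev_sorted <- lev[order(ex3, ids3)]
  brute <- sapply(1:30, function(i)
    mean(lev_sorted[max(1, i - 3):min(30, i + 3)]))
  expect_equal(r3$curve, brute)
})

test_that("grouping splits expressed genes into near-equal ordered bins", {
  ids <- sprintf("g%02d", 1:13)
  expr <- make_expr(ids, c(0, 0, 0, seq(1, 10)))
  meth <- make_methtable(ids, seq(0.9, 0.3, length.out = 13))
  res <- grouping_statistics(meth, expr, "CG", "genebody",
                             n_quantiles = 5)
  st <- res$stats
  expect_equal(st$group, 0:5)
  expect_equal(st$n, c(3L, 2L, 2L, 2L, 2L, 2L))
  # methylation decreasing in expression -> strictly decreasing means
  expect_true(all(diff(st$mean[-1]) < 0))
  # no gene lost or duplicated
  expect_setequal(res$assignments$gene_id, ids)
  # excluding unexpressed genes
  res2 <- grouping_statistics(meth, expr, "CG", "genebody", 5,
                              include_unexpressed = FALSE)
  expect_equal(res2$stats$group, 1:5)
  expect_equal(res2$n_unexpressed_excluded, 3L)
  expect_error(grouping_statistics(meth, expr, "CG", "genebody", 11),
               "fewer bins")
})

test_that("group stats match a brute-force oracle on a random fixture", {
  set.seed(31)
  n <- 57
  ids <- sprintf("g%03d", 1:n)
  lev <- runif(n)
  ex <- c(rep(0, 5), runif(n - 5, 0.5, 80))
  res <- grouping_statistics(make_methtable(ids, lev),
                             make_expr(ids, ex), "CG", "genebody", 4)
  ord <- order(ex[ex > 0], ids[ex > 0])
  sizes <- c(13, 13, 13, 13)
  grp_levels <- split(lev[ex > 0][ord], rep(1:4, times = sizes))
  for (g in 1:4) {
    expect_equal(res$stats$mean[res$stats$group == g],
                 mean(grp_levels[[g]]))
    expect_equal(res$stats$median[res$stats$group == g],
                 median(grp_levels[[g]]))
  }
  expect_equal(res$stats$mean[res$stats$group == 0], mean(lev[ex == 0]))
})

# -- metagene ----------------------------------------------------------------

# dense per-base fixture over one gene: level l(pos) with full coverage
dense_gene_records <- function(chrom, positions, levels, total = 10L) {
  make_records(chrom, positions, context = "CG",
               meth = as.integer(round(levels * total)), total = total)
}

test_that("constant methylation gives constant metagene profiles", {
  genes <- make_genes(data.table(gene_id = c("g1", "g2"), chrom = "Chr1",
                                 strand = c("+", "-"),
                                 start = c(3000L, 9000L),
                                 end = c(3599L, 9599L)))
  pos <- seq(2000L, 10800L, by = 7L)
  rec <- dense_gene_records("Chr1", pos, rep(0.6, length(pos)))
  expr <- make_expr(c("g1", "g2"), c(5, 50))
  mg <- metagene_region(rec, genes, expr, "CG", n_groups = 2)
  expect_true(all(abs(mg$matrix - 0.6) < 1e-12, na.rm = TRUE))
  ms <- metagene_site(rec, genes, expr, "CG", "TSS", flank_bp = 500,
                      n_windows = 5, n_groups = 2)
  expect_true(all(abs(ms$matrix - 0.6) < 1e-12, na.rm = TRUE))
})

test_that("mirror-image genes on opposite strands give identical profiles", {
  C <- 30000L
  len <- 600L  # divisible by 30 body and 15 flank windows
  genes <- make_genes(data.table(
    gene_id = c("fwd", "rev"), chrom = c("ChrF", "ChrR"),
    strand = c("+", "-"),
    start = c(5000L, C - 5000L - len + 1L),
    end = c(5000L + len - 1L, C - 5000L)))
  set.seed(11)
  posF <- seq(4000L, 6600L, by = 3L)
  levF <- round(runif(length(posF)), 1)
  posR <- C - posF
  recs <- rbind(dense_gene_records("ChrF", posF, levF),
                dense_gene_records("ChrR", posR, levF))
  expr <- make_expr(c("fwd", "rev"), c(10, 10))
  mg <- metagene_region(recs, genes, expr, "CG", n_groups = 1,
                        include_unexpressed = FALSE)
  # both genes land in the same group; per-gene profiles must mirror
  # exactly, so test with each gene alone in its own run
  mgF <- metagene_region(recs[chrom == "ChrF"],
                         make_genes(genes$genes[gene_id == "fwd"]),
                         make_expr("fwd", 10), "CG", n_groups = 1,
                         include_unexpressed = FALSE)
  mgR <- metagene_region(recs[chrom == "ChrR"],
                         make_genes(genes$genes[gene_id == "rev"]),
                         make_expr("rev", 10), "CG", n_groups = 1,
                         include_unexpressed = FALSE)
  expect_equal(mgF$matrix, mgR$matrix, tolerance = 1e-12)
  msF <- metagene_site(recs[chrom == "ChrF"],
                       make_genes(genes$genes[gene_id == "fwd"]),
                       make_expr("fwd", 10), "CG", "TSS", 900, 9,
                       n_groups = 1, include_unexpressed = FALSE)
  msR <- metagene_site(recs[chrom == "ChrR"],
                       make_genes(genes$genes[gene_id == "rev"]),
                       make_expr("rev", 10), "CG", "TSS", 900, 9,
                       n_groups = 1, include_unexpressed = FALSE)
  expect_equal(msF$matrix, msR$matrix, tolerance = 1e-12)
})

test_that("site mode at n_windows = flank_bp reproduces per-base levels", {
  genes <- make_genes(data.table(gene_id = "g1", chrom = "Chr1",
                                 strand = "+", start = 1000L,
                                 end = 1499L))
  off <- -50:49
  lv <- rep(c(0.2, 0.8), 50)
  rec <- dense_gene_records("Chr1", 1000L + off, lv)
  expr <- make_expr("g1", 3)
  ms <- metagene_site(rec, genes, expr, "CG", "TSS", flank_bp = 50,
                      n_windows = 50, n_groups = 1,
                      include_unexpressed = FALSE)
  expect_equal(as.numeric(ms$matrix[1, ]), lv, tolerance = 1e-12)
  expect_equal(ms$window_bp, 1)
})

test_that("metagene windows conserve the gene mean under uniform coverage", {
  # one site per base, constant depth, length divisible by 30:
  # the mean of the 30 body windows equals the gene-body site mean
  genes <- make_genes(data.table(gene_id = "g1", chrom = "Chr1",
                                 strand = "+", start = 2000L,
                                 end = 2599L))
  pos <- 2000:2599
  lv <- round(runif(600), 1)
  set.seed(4)
  rec <- dense_gene_records("Chr1", pos, lv)
  mg <- metagene_region(rec, genes, make_expr("g1", 2), "CG",
                        n_groups = 1, include_unexpressed = FALSE)
  body <- mg$matrix[1, 16:45]
  expect_equal(mean(body), mean(lv), tolerance = 1e-12)
})

test_that("short genes are excluded and counted; flanks follow gene length", {
  genes <- make_genes(data.table(gene_id = c("ok", "tiny"),
                                 chrom = "Chr1", strand = "+",
                                 start = c(1000L, 5000L),
                                 end = c(4599L, 5019L)))
  pos <- seq(1L, 7000L, by = 11L)
  rec <- dense_gene_records("Chr1", pos, rep(0.5, length(pos)))
  expr <- make_expr(c("ok", "tiny"), c(1, 2))
  mg <- metagene_region(rec, genes, expr, "CG", n_groups = 1,
                        include_unexpressed = FALSE)
  expect_equal(mg$n_short_excluded, 1L)
  # gene of body length 3600 -> flank span 1800 bp, windows of 120 bp
  expect_error(metagene_region(rec,
    make_genes(data.table(gene_id = "tiny", chrom = "Chr1",
                          strand = "+", start = 5000L, end = 5019L)),
    expr, "CG"), "length filter")
})
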