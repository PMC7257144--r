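library(data.table)

# --- tiny in-code fixture builders -----------------------------------------

# build a meg_records table directly (bypasses file I/O)
make_records <- function(chrom, pos, strand = "+", context = "CG",
                         meth, total) {
  dt <- data.table(chrom = chrom, pos = as.integer(pos), strand = strand,
                   context = context, dinuc = context,
                   level = meth / total, meth = as.integer(meth),
                   total = as.integer(total))
  setattr(dt, "class", c("meg_records", class(dt)))
  dt[]
}

# build a meg_genes object directly from a gene table and optional exons;
# default: single-exon genes spanning the body
make_genes <- function(genes_dt, exons_dt = NULL) {
  g <- as.data.table(genes_dt)
  if (!"is_te" %in% names(g)) g[, is_te := FALSE]
  g[, tss := ifelse(strand == "-", end, start)]
  g[, tes := ifelse(strand == "-", start, end)]
  if (is.null(exons_dt))
    exons_dt <- g[, .(gene_id, chrom, strand, start, end)]
  out <- list(genes = g[], exons = as.data.table(exons_dt))
  class(out) <- "meg_genes"
  out
}

make_expr <- function(gene_id, expr) {
  dt <- data.table(gene_id = gene_id, expr = as.numeric(expr))
  setattr(dt, "class", c("meg_expr", class(dt)))
  dt[]
}

# build a meg_methtable directly
make_methtable <- function(gene_id, level, context = "CG",
                           region_type = "genebody") {
  dt <- data.table(gene_id = gene_id, context = context,
                   region_type = region_type, level = level,
                   n_sites = 1L, total_cov = 4L)
  setattr(dt, "class", c("meg_methtable", class(dt)))
  dt[]
}

write_cgmap_lines <- function(lines, path = tempfile(fileext = ".cgmap")) {
  writeLines(lines, path)
  path
}

# a small random fixture: <=10 genes on a <=5 kb chromosome plus random
# cytosines; returns records + regions (via derive_regions)
rand_tiny_fixture <- function(seed, n_genes = NULL) {
  set.seed(seed)
  if (is.null(n_genes)) n_genes <- sample(2:10, 1)
  starts <- sort(sample(200:4500, n_genes))
  g <- data.table(gene_id = sprintf("g%02d", seq_len(n_genes)),
                  chrom = "Chr1", strand = sample(c("+", "-"), n_genes,
                                                  replace = TRUE),
                  start = starts,
                  end = pmin(5000L, starts + sample(60:400, n_genes,
                                                    replace = TRUE)))
  # random multi-exon structure for about half of the genes
  exons <- g[, {
    if (end - start > 120 && runif(1) < 0.5) {
      m1 <- start + sample(20:40, 1)
      m2 <- m1 + sample(10:30, 1)
      list(start = c(start, min(m2, end - 1L)),
           end = c(m1, end), chrom = chrom, strand = strand)
    } else list(start = start, end = end, chrom = chrom, strand = strand)
  }, by = gene_id]
  genes <- make_genes(g, exons[, .(gene_id, chrom, strand, start, end)])
  n_sites <- sample(100:400, 1)
  total <- rpois(n_sites, 5) + 1L
  rec <- make_records(chrom = "Chr1",
                      pos = sample(1:5000, n_sites),
                      strand = sample(c("+", "-"), n_sites,
                                      replace = TRUE),
                      context = sample(c("CG", "CHG", "CHH"), n_sites,
                                       replace = TRUE),
                      meth = rbinom(n_sites, total, runif(n_sites)),
                      total = total)
  list(records = rec, genes = genes,
       regions = derive_regions(genes, promoter_bp = 150L))
}

# --- independent naive oracle ----------------------------------------------

# brute-force per-base region averaging: loops over genes, intervals and
# sites without any interval index; deliberately independent of the
# implementation under test
naive_region_methylation <- function(records, regions, min_coverage = 4,
                                     estimator = "weighted",
                                     min_sites = 1) {
  rec <- as.data.frame(records[records$total >= min_coverage])
  out <- list()
  keyset <- unique(as.data.frame(regions[, c("gene_id", "region_type")]))
  for (i in seq_len(nrow(keyset))) {
    gid <- keyset$gene_id[i]; rt <- keyset$region_type[i]
    ivs <- as.data.frame(regions[regions$gene_id == gid &
                                   regions$region_type == rt])
    ivs <- ivs[ivs$end >= ivs$start, , drop = FALSE]
    for (ctx in c("CG", "CHG", "CHH")) {
      hits <- integer(0)
      for (j in seq_len(nrow(ivs))) {
        hits <- c(hits, which(rec$context == ctx &
                                rec$chrom == ivs$chrom[j] &
                                rec$pos >= ivs$start[j] &
                                rec$pos <= ivs$end[j]))
      }
      hits <- sort(unique(hits))
      # a site inside two intervals of one region counts once per region
      # set because merged exons/introns are disjoint; duplicates cannot
      # arise within one (gene, region_type)
      if (length(hits) >= min_sites) {
        lev <- if (estimator == "weighted")
          sum(rec$meth[hits]) / sum(rec$total[hits])
        else mean(rec$meth[hits] / rec$total[hits])
        out[[length(out) + 1L]] <- data.frame(
          gene_id = gid, context = ctx, region_type = rt, level = lev,
          n_sites = length(hits), total_cov = sum(rec$total[hits]))
      }
    }
  }
  res <- do.call(rbind, out)
  res[order(res$gene_id, res$context, res$region_type), ]
}

expect_table_equals_oracle <- function(tab, oracle) {
  t2 <- as.data.frame(tab)
  t2 <- t2[order(t2$gene_id, t2$context, t2$region_type), ]
  expect_equal(nrow(t2), nrow(oracle))
  expect_equal(t2$gene_id, oracle$gene_id)
  expect_equal(t2$context, oracle$context)
  expect_equal(t2$region_type, oracle$region_type)
  expect_equal(t2$level, oracle$level, tolerance = 1e-12)
  expect_equal(t2$n_sites, oracle$n_sites)
}
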