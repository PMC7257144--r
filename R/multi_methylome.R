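#' Average methylation tables and expression tables within a group
#'
#' Per-gene unweighted mean across the samples of a group. A gene's
#' methylation cell is present if present in at least one sample (the
#' mean is over the samples carrying it; \code{n} records how many).
#'
#' @param meths list of \code{meg_methtable} (one per sample).
#' @param exprs list of \code{meg_expr} (one per sample).
#' @return list with elements \code{meth} (meg_methtable-like with
#'   column \code{n}) and \code{expr} (meg_expr-like with column
#'   \code{n}).
#' @export
group_average <- function(meths, exprs) {
  stopifnot(length(meths) >= 1, length(exprs) >= 1)
  gsets <- lapply(exprs, function(e) e$gene_id)
  if (length(gsets) > 1L && !length(Reduce(intersect, gsets)))
    stop("disjoint gene sets across samples: no gene shared by all ",
         "expression tables", call. = FALSE)
  mall <- rbindlist(lapply(meths, function(m)
    m[, .(gene_id, context, region_type, level)]))
  meth <- mall[, .(level = mean(level), n = .N),
               by = .(gene_id, context, region_type)]
  setattr(meth, "class", c("meg_methtable", class(meth)))
  eall <- rbindlist(lapply(exprs, function(e) e[, .(gene_id, expr)]))
  expr <- eall[, .(expr = mean(expr), n = .N), by = gene_id]
  setattr(expr, "class", c("meg_expr", class(expr)))
  list(meth = meth[], expr = expr[])
}

#' Per-gene methylation change versus expression fold change
#'
#' For each gene present in both groups: \code{delta_meth} = group A mean
#' level minus group B mean level, and \code{log2fc} =
#' log2((exprA + pseudocount) / (exprB + pseudocount)). The overall
#' Pearson correlation of the two change axes is attached.
#'
#' @param groupA,groupB lists with \code{meth} and \code{expr} entries as
#'   returned by \code{\link{group_average}} (a single sample's tables
#'   work too).
#' @param context,region_type the methylation slice to compare.
#' @param pseudocount added to both expression means before the ratio
#'   (default 1), guarding zero expression.
#' @return list of class \code{meg_comparison}: \code{records}
#'   (data.table gene_id, meanA_meth, meanB_meth, delta_meth, exprA,
#'   exprB, log2fc), \code{pearson_r}, \code{pearson_p}, \code{n_genes}.
#' @export
compare_groups <- function(groupA, groupB, context, region_type,
                           pseudocount = 1.0) {
  .ctx <- context; .rt <- region_type
  sl <- function(g) {
    m <- g$meth[context == .ctx & region_type == .rt,
                .(gene_id, level)]
    merge(m, g$expr[, .(gene_id, expr)], by = "gene_id")
  }
  a <- sl(groupA); b <- sl(groupB)
  rec <- merge(a, b, by = "gene_id", suffixes = c("A", "B"))
  if (nrow(rec) < 3L)
    stop("need >= 3 genes with methylation and expression in both groups",
         call. = FALSE)
  setnames(rec, c("levelA", "levelB"), c("meanA_meth", "meanB_meth"))
  rec[, delta_meth := meanA_meth - meanB_meth]
  rec[, log2fc := log2((exprA + pseudocount) / (exprB + pseudocount))]
  r <- NA_real_; p <- NA_real_
  if (sd(rec$delta_meth) > 0 && sd(rec$log2fc) > 0) {
    r <- cor(rec$log2fc, rec$delta_meth)
    p <- .cor_p(r, nrow(rec))
  }
  out <- list(records = rec[], pearson_r = r, pearson_p = p,
              n_genes = nrow(rec), pseudocount = pseudocount)
  class(out) <- "meg_comparison"
  out
}

# quadrant by signs of (x = log2fc, y = delta_meth); NA on either axis
.quadrant <- function(x, y) {
  q <- rep(NA_integer_, length(x))
  q[x > 0 & y > 0] <- 1L
  q[x < 0 & y > 0] <- 2L
  q[x < 0 & y < 0] <- 3L
  q[x > 0 & y < 0] <- 4L
  q
}

# k-means++ seeding followed by standard EM for a full-covariance
# bivariate Gaussian mixture; deterministic for a fixed seed.
.fit_gmm <- function(X, k, seed, max_iter = 200L, tol = 1e-8) {
  set.seed(seed)
  n <- nrow(X)
  centers <- matrix(NA_real_, k, 2)
  centers[1, ] <- X[sample.int(n, 1L), ]
  if (k > 1L) for (j in 2:k) {
    d2 <- Reduce(pmin, lapply(seq_len(j - 1L), function(i)
      rowSums(sweep(X, 2, centers[i, ])^2)))
    centers[j, ] <- X[sample.int(n, 1L, prob = d2 / sum(d2)), ]
  }
  km <- kmeans(X, centers = centers, iter.max = 50L)
  w <- tabulate(km$cluster, k) / n
  mu <- lapply(seq_len(k), function(j) colMeans(X[km$cluster == j, ,
                                                  drop = FALSE]))
  Sg <- lapply(seq_len(k), function(j) {
    S <- cov(X[km$cluster == j, , drop = FALSE]) * 1.0
    if (!is.finite(determinant(S)$modulus) || det(S) < 1e-12)
      S <- S + diag(1e-6, 2)
    S
  })
  dens_comp <- function(mu, S) {
    Si <- solve(S)
    dX <- sweep(X, 2, mu)
    d2 <- rowSums((dX %*% Si) * dX)
    exp(-d2 / 2) / (2 * pi * sqrt(det(S)))
  }
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    D <- vapply(seq_len(k), function(j) w[j] * dens_comp(mu[[j]], Sg[[j]]),
                numeric(n))
    rs <- rowSums(D)
    ll <- sum(log(rs))
    R <- D / rs
    w <- colMeans(R)
    for (j in seq_len(k)) {
      rj <- R[, j]
      mu[[j]] <- colSums(X * rj) / sum(rj)
      dX <- sweep(X, 2, mu[[j]])
      S <- crossprod(dX * sqrt(rj)) / sum(rj)
      if (det(S) < 1e-12) S <- S + diag(1e-8, 2)
      Sg[[j]] <- S
    }
    if (abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  list(weights = w, means = mu, covs = Sg)
}

.gmm_density <- function(fit, X) {
  n <- nrow(X)
  rowSums(vapply(seq_along(fit$weights), function(j) {
    Si <- solve(fit$covs[[j]])
    dX <- sweep(X, 2, fit$means[[j]])
    d2 <- rowSums((dX %*% Si) * dX)
    fit$weights[j] * exp(-d2 / 2) / (2 * pi * sqrt(det(fit$covs[[j]])))
  }, numeric(n)))
}

.gmm_sample <- function(fit, n) {
  comp <- sample.int(length(fit$weights), n, replace = TRUE,
                     prob = fit$weights)
  out <- matrix(NA_real_, n, 2)
  for (j in seq_along(fit$weights)) {
    idx <- which(comp == j)
    if (!length(idx)) next
    L <- chol(fit$covs[[j]])
    Z <- matrix(rnorm(2L * length(idx)), ncol = 2)
    out[idx, ] <- sweep(Z %*% L, 2, fit$means[[j]], `+`)
  }
  out
}

#' Call differential genes from the change cloud
#'
#' Fits a bivariate Gaussian mixture (full covariance) to the per-gene
#' (log2 fold change, methylation change) cloud and assigns each gene a
#' density-tail p-value: the probability, under the fitted model, of
#' landing in a region of lower density than the gene's point. With one
#' component (the default) this is the chi-square(2 df) survival
#' function at the squared Mahalanobis distance, in closed form; with
#' k > 1 it is a Monte-Carlo tail over at least \code{n_mc} seeded
#' draws from the mixture. A gene is differential when p < \code{alpha}
#' (default 1e-6); quadrant counts over the differential genes are
#' reported, with axis-sitting genes (either change exactly 0) excluded
#' from the counts.
#'
#' @param comparison \code{meg_comparison} from
#'   \code{\link{compare_groups}}.
#' @param alpha significance cut-off on the density-tail p (default
#'   1e-6).
#' @param n_components mixture components (default 1).
#' @param seed RNG seed for the mixture initialisation and Monte-Carlo
#'   tail.
#' @param n_mc Monte-Carlo draws when \code{n_components > 1} (minimum
#'   1e5, enforced).
#' @return the comparison with \code{records} gaining \code{gmm_p},
#'   \code{is_differential}, \code{quadrant}; plus
#'   \code{quadrant_counts} (counts of differential genes in quadrants
#'   1-4), \code{alpha}, \code{fit}.
#' @export
call_differential <- function(comparison, alpha = 1e-6,
                              n_components = 1L, seed = 1L,
                              n_mc = 1e5) {
  stopifnot(inherits(comparison, "meg_comparison"),
            alpha > 0, alpha < 1)
  rec <- copy(comparison$records)
  if (nrow(rec) < 10L)
    stop("need >= 10 genes to fit the mixture; got ", nrow(rec),
         call. = FALSE)
  X <- cbind(rec$log2fc, rec$delta_meth)
  if (n_components == 1L) {
    mu <- colMeans(X)
    S <- cov(X)
    if (det(S) < 1e-12) {
      warning("singular covariance; ridge 1e-8 added")
      S <- S + diag(1e-8, 2)
    }
    d2 <- mahalanobis(X, mu, S)
    rec[, gmm_p := pchisq(d2, df = 2, lower.tail = FALSE)]
    fit <- list(weights = 1, means = list(mu), covs = list(S))
  } else {
    fit <- .fit_gmm(X, as.integer(n_components), seed = seed)
    dens_obs <- .gmm_density(fit, X)
    set.seed(seed + 1L)
    draws <- .gmm_sample(fit, max(1e5, n_mc))
    dens_draw <- .gmm_density(fit, draws)
    ec <- stats::ecdf(dens_draw)
    rec[, gmm_p := ec(dens_obs)]
  }
  rec[, is_differential := gmm_p < alpha]
  rec[, quadrant := .quadrant(log2fc, delta_meth)]
  qc <- setNames(integer(4), as.character(1:4))
  tabq <- rec[is_differential == TRUE & !is.na(quadrant),
              .N, by = quadrant]
  qc[as.character(tabq$quadrant)] <- tabq$N
  out <- comparison
  out$records <- rec[]
  out$quadrant_counts <- qc
  out$alpha <- alpha
  out$fit <- fit
  class(out) <- c("meg_differential", "meg_comparison")
  out
}

#' Differential-gene table
#'
#' Rows are the differential genes sorted by ascending p-value, with
#' both groups' methylation levels and expression values, the changes,
#' the density-tail p and the quadrant. Written as TSV when \code{path}
#' is given.
#'
#' @param comparison output of \code{\link{call_differential}}.
#' @param path optional TSV output path.
#' @return the table, invisibly when written.
#' @export
differential_table <- function(comparison, path = NULL) {
  stopifnot(inherits(comparison, "meg_differential"))
  tab <- comparison$records[is_differential == TRUE,
    .(gene = gene_id, meanA_meth, meanB_meth, delta_meth,
      exprA, exprB, log2fc, gmm_p, quadrant)]
  setorder(tab, gmm_p, gene)
  if (!is.null(path)) {
    fwrite(tab, path, sep = "\t", quote = FALSE)
    return(invisible(tab))
  }
  tab[]
}

#' Joint methylome-transcriptome hierarchical clustering
#'
#' Builds a gene x 4 matrix (methylation A, methylation B, expression A,
#' expression B). Methylation columns stay on their native [0,1] scale;
#' the two expression cells of each gene are log2(x + pseudocount)
#' transformed then z-scored across the pair so both data types share a
#' colour scale (a constant pair z-scores to 0, not NaN). Genes are
#' clustered on the 4-column rows; the ordered gene list, dendrogram and
#' scaled matrix are returned.
#'
#' @param methA,methB \code{meg_methtable} group means.
#' @param exprA,exprB \code{meg_expr} group means.
#' @param context,region_type methylation slice to use.
#' @param genes optional subset of gene ids.
#' @param linkage \code{"average"} (default), \code{"complete"} or
#'   \code{"ward"} (ward.D2).
#' @param metric \code{"euclidean"} (default) or \code{"manhattan"}.
#' @param pseudocount for the expression log transform (default 1).
#' @return list of class \code{meg_heatmap}: \code{order} (clustered
#'   gene ids), \code{hclust}, \code{matrix} (scaled, rownames = genes).
#' @export
heatmap_cluster <- function(methA, methB, exprA, exprB, context,
                            region_type, genes = NULL,
                            linkage = c("average", "complete", "ward"),
                            metric = c("euclidean", "manhattan"),
                            pseudocount = 1.0) {
  linkage <- match.arg(linkage)
  metric <- match.arg(metric)
  .ctx <- context; .rt <- region_type
  sl <- function(m, suff) {
    out <- m[context == .ctx & region_type == .rt, .(gene_id, level)]
    setnames(out, "level", paste0("meth", suff))
    out
  }
  tab <- Reduce(function(a, b) merge(a, b, by = "gene_id"),
                list(sl(methA, "A"), sl(methB, "B"),
                     exprA[, .(gene_id, exprA = expr)],
                     exprB[, .(gene_id, exprB = expr)]))
  if (!is.null(genes)) tab <- tab[gene_id %chin% genes]
  tab <- tab[stats::complete.cases(tab)]
  if (nrow(tab) < 2L)
    stop("need >= 2 genes with complete methylation and expression rows",
         call. = FALSE)
  la <- log2(tab$exprA + pseudocount)
  lb <- log2(tab$exprB + pseudocount)
  mu <- (la + lb) / 2
  s <- sqrt((la - mu)^2 + (lb - mu)^2)  # sd over the pair (n divisor)
  za <- ifelse(s > 0, (la - mu) / s, 0)
  zb <- ifelse(s > 0, (lb - mu) / s, 0)
  M <- cbind(methA = tab$methA, methB = tab$methB,
             exprA = za, exprB = zb)
  rownames(M) <- tab$gene_id
  hc <- hclust(dist(M, method = metric),
               method = if (linkage == "ward") "ward.D2" else linkage)
  out <- list(order = tab$gene_id[hc$order], hclust = hc, matrix = M)
  class(out) <- "meg_heatmap"
  out
}
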