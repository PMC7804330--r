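# Expression dynamics over the timepoint series: the >= 100 mean-RPM
# expression filter, one-way ANOVA plus pairwise pooled-variance t-tests
# with Benjamini-Hochberg correction, hierarchical clustering of z-scored
# timepoint profiles (1 - Pearson, complete linkage), PCA of libraries and
# the thresholded Pearson co-expression network.

#' Per-timepoint means of a normalized count matrix
#'
#' @param norm matrix of normalized values (rows = miRNAs/tags, columns =
#'   libraries in design order).
#' @param design library design data.frame.
#' @return matrix rows x timepoints of arithmetic replicate means.
#' @export
timepoint_means <- function(norm, design) {
  tps <- sort(unique(design$timepoint_daa))
  out <- sapply(tps, function(tp)
    rowMeans(norm[, design$timepoint_daa == tp, drop = FALSE]))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  colnames(out) <- as.character(tps)
  rownames(out) <- rownames(norm)
  out
}

#' Expression filter: mean normalized reads >= threshold at some timepoint
#'
#' A profile is retained iff the maximum over timepoints of its mean
#' normalized read number reaches the threshold (inclusive).
#'
#' @param norm normalized matrix (rows named by miRNA/tag id).
#' @param design library design data.frame.
#' @param threshold minimum mean normalized reads (default 100).
#' @return an `expression_profiles` list: `ids`, `norm` (filtered matrix),
#'   `tp_means`, `design`.
#' @export
expression_filter <- function(norm, design, threshold = 100) {
  tpm <- timepoint_means(norm, design)
  keep <- apply(tpm, 1, max) >= threshold
  structure(list(ids = rownames(norm)[keep],
                 norm = norm[keep, , drop = FALSE],
                 tp_means = tpm[keep, , drop = FALSE],
                 design = design),
            class = "expression_profiles")
}

#' @export
print.expression_profiles <- function(x, ...) {
  cat(sprintf("expression profiles: %d miRNAs x %d libraries (%d timepoints)\n",
              length(x$ids), ncol(x$norm), ncol(x$tp_means)))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment (order-preserving, monotone,
#' capped at 1).
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' log2 fold change with pseudocount
#'
#' `log2((mean_b + c) / (mean_a + c))`.
#'
#' @param mean_a,mean_b non-negative mean normalized reads.
#' @param pseudocount additive constant (default 1).
#' @return log2 fold change (b over a).
#' @export
log2fc <- function(mean_a, mean_b, pseudocount = 1) {
  if (any(mean_a < 0) || any(mean_b < 0))
    stopf("means must be non-negative")
  log2((mean_b + pseudocount) / (mean_a + pseudocount))
}

one_way_anova_p <- function(values, groups) {
  gm <- tapply(values, groups, mean)
  ssb <- sum(tapply(values, groups, length) * (gm - mean(values))^2)
  ssw <- sum((values - gm[as.character(groups)])^2)
  if (ssb < 1e-12 && ssw < 1e-12) return(1)   # all values identical
  if (ssb < 1e-12) return(1)                  # no between-group signal
  if (ssw < 1e-12) return(0)                  # perfect separation
  fit <- stats::anova(stats::lm(values ~ factor(groups)))
  p <- fit[["Pr(>F)"]][1]
  if (is.na(p)) 1 else p
}

pooled_t_p <- function(a, b) {
  if (stats::var(a) < 1e-24 && stats::var(b) < 1e-24) {
    if (abs(mean(a) - mean(b)) < 1e-12) return(1)
    return(0)
  }
  stats::t.test(a, b, var.equal = TRUE)$p.value
}

#' Differential expression across timepoints
#'
#' One-way fixed-effects ANOVA over the timepoints on normalized values,
#' Benjamini-Hochberg adjusted across miRNAs, followed by pairwise
#' pooled-variance Student t-tests for the consecutive timepoint pairs plus
#' first-vs-last, BH-adjusted within each comparison across miRNAs.
#' Zero variance within and between groups yields p = 1 by convention.
#'
#' @param profiles an `expression_profiles` object.
#' @return list with `anova` (data.frame `mirna_id`, `anova_p`,
#'   `anova_adj_p`) and `pairwise` (data.frame `mirna_id`, `tp_a`, `tp_b`,
#'   `log2fc`, `p`, `adj_p`).
#' @export
anova_de <- function(profiles) {
  design <- profiles$design
  tps <- sort(unique(design$timepoint_daa))
  if (length(tps) < 2) stopf("need at least two timepoints")
  counts <- table(design$timepoint_daa)
  if (any(counts < 2))
    stopf("timepoint %s has fewer than 2 replicates",
          names(counts)[counts < 2][1])
  groups <- design$timepoint_daa
  norm <- profiles$norm

  anova_p <- apply(norm, 1, one_way_anova_p, groups = groups)
  anova_tab <- data.frame(mirna_id = profiles$ids, anova_p = anova_p,
                          anova_adj_p = bh_adjust(anova_p),
                          row.names = NULL, stringsAsFactors = FALSE)

  pairs <- cbind(tps[-length(tps)], tps[-1])
  pairs <- rbind(pairs, c(tps[1], tps[length(tps)]))
  pairs <- unique(pairs)
  pw <- list()
  for (k in seq_len(nrow(pairs))) {
    ta <- pairs[k, 1]; tb <- pairs[k, 2]
    ia <- design$timepoint_daa == ta
    ib <- design$timepoint_daa == tb
    p <- apply(norm, 1, function(v) pooled_t_p(v[ia], v[ib]))
    lfc <- log2fc(rowMeans(norm[, ia, drop = FALSE]),
                  rowMeans(norm[, ib, drop = FALSE]))
    pw[[k]] <- data.frame(mirna_id = profiles$ids, tp_a = ta, tp_b = tb,
                          log2fc = lfc, p = p, adj_p = bh_adjust(p),
                          row.names = NULL, stringsAsFactors = FALSE)
  }
  list(anova = anova_tab, pairwise = do.call(rbind, pw))
}

#' Cluster expression profiles into abundance archetypes
#'
#' Rows are per-miRNA z-scored timepoint means; distance is 1 - Pearson
#' correlation; trees are built with complete linkage and cut at `k`
#' clusters, labelled A, B, C, ... in dendrogram order. Zero-variance
#' profiles cannot be z-scored and are assigned the sentinel label `"-"`.
#'
#' @param profiles an `expression_profiles` object.
#' @param k number of clusters (default 6).
#' @return list with `assignment` (data.frame `mirna_id`, `cluster`) and
#'   `tree` (the `hclust` object over variable profiles).
#' @export
cluster_profiles <- function(profiles, k = 6) {
  tpm <- profiles$tp_means
  v <- apply(tpm, 1, stats::sd)
  variable <- v > 0
  if (sum(variable) < k)
    stopf("only %d variable profiles for k = %d; use a smaller k",
          sum(variable), k)
  z <- t(scale(t(tpm[variable, , drop = FALSE])))
  d <- stats::as.dist(1 - stats::cor(t(z)))
  tree <- stats::hclust(d, method = "complete")
  grp <- stats::cutree(tree, k = k)
  # letters in dendrogram order
  first_seen <- unique(grp[tree$order])
  labels <- stats::setNames(LETTERS[seq_len(k)], first_seen)
  cluster <- rep("-", nrow(tpm))
  names(cluster) <- rownames(tpm)
  cluster[names(grp)] <- labels[as.character(grp)]
  list(assignment = data.frame(mirna_id = rownames(tpm),
                               cluster = unname(cluster),
                               stringsAsFactors = FALSE),
       tree = tree)
}

#' PCA of libraries over z-scored miRNA abundances
#'
#' Columns (miRNAs) are z-scored across libraries; scores come from the
#' singular value decomposition. Zero-variance miRNAs are dropped with a
#' warning. The sign of each component is fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param profiles an `expression_profiles` object.
#' @return list with `scores` (libraries x components), `variance_share`,
#'   `loadings`.
#' @export
pca_libraries <- function(profiles) {
  x <- t(profiles$norm)             # libraries x miRNAs
  if (nrow(x) < 2 || ncol(x) < 2)
    stopf("PCA needs at least 2 libraries and 2 miRNAs")
  v <- apply(x, 2, stats::sd)
  if (any(v == 0)) {
    warning(sprintf("dropping %d zero-variance miRNA(s) from PCA",
                    sum(v == 0)))
    x <- x[, v > 0, drop = FALSE]
  }
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  for (j in seq_len(ncol(p$rotation))) {
    i_max <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i_max, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  share <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x, variance_share = share, loadings = p$rotation)
}

#' Thresholded Pearson co-expression network
#'
#' Pairwise Pearson correlation over per-library normalized values with a
#' two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2
#' degrees of freedom. Edges are retained when `|r| >= r_min` and
#' `p <= p_max`; constant profiles are excluded from pairing.
#'
#' @param profiles an `expression_profiles` object.
#' @param r_min absolute correlation threshold (default 0.75).
#' @param p_max p-value threshold (default 0.05).
#' @return data.frame of retained edges: `mirna_a`, `mirna_b` (a < b), `r`,
#'   `p`, `sign`.
#' @export
correlation_network <- function(profiles, r_min = 0.75, p_max = 0.05) {
  x <- t(profiles$norm)
  n <- nrow(x)
  if (n < 4) stopf("need at least 4 libraries")
  keep <- apply(x, 2, stats::sd) > 0
  x <- x[, keep, drop = FALSE]
  ids <- colnames(x)
  if (length(ids) < 2)
    return(data.frame(mirna_a = character(0), mirna_b = character(0),
                      r = numeric(0), p = numeric(0), sign = character(0)))
  cm <- stats::cor(x)
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  r <- cm[ut]
  r_cl <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tstat <- r_cl * sqrt((n - 2) / (1 - r_cl^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  keep_e <- abs(r) >= r_min & p <= p_max
  a <- ids[ut[, 1]]; b <- ids[ut[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  d <- data.frame(mirna_a = a[keep_e], mirna_b = b[keep_e], r = r[keep_e],
                  p = p[keep_e],
                  sign = ifelse(r[keep_e] >= 0, "positive", "negative"),
                  stringsAsFactors = FALSE)
  d[order(d$mirna_a, d$mirna_b), , drop = FALSE]
}
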