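design12 <- library_design()

mk_profiles <- function(norm) {
  rownames(norm) <- rownames(norm) %||% paste0("m", seq_len(nrow(norm)))
  expression_filter(norm, design12, threshold = 0)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("expression filter keeps profiles reaching 100 mean reads", {
  mk <- function(tp_means) {
    v <- rep(tp_means, each = 3)
    matrix(v, 1, 12, dimnames = list("x", design12$library_id))
  }
  expect_length(expression_filter(mk(c(99, 50, 10, 5)), design12)$ids, 0)
  expect_length(expression_filter(mk(c(100, 0, 0, 0)), design12)$ids, 1)
  expect_length(expression_filter(mk(c(99.9, 99.9, 99.9, 100.2)),
                                  design12)$ids, 1)
})

test_that("timepoint means average replicates", {
  set.seed(55)
  norm <- matrix(rpois(24, 100), 2, 12,
                 dimnames = list(c("a", "b"), design12$library_id))
  tpm <- timepoint_means(norm, design12)
  expect_equal(dim(tpm), c(2, 4))
  expect_equal(tpm["a", "10"], mean(norm["a", 1:3]))
  expect_equal(tpm["b", "40"], mean(norm["b", 10:12]))
})

test_that("ANOVA follows the degenerate-variance conventions", {
  flat <- matrix(100, 1, 12, dimnames = list("x", design12$library_id))
  de <- anova_de(mk_profiles(flat))
  expect_equal(de$anova$anova_p, 1)
  # identical group patterns: zero between-group variance
  rep123 <- matrix(rep(c(1, 2, 3), 4), 1, 12,
                   dimnames = list("x", design12$library_id))
  expect_equal(anova_de(mk_profiles(rep123))$anova$anova_p, 1)
})

test_that("ANOVA and t-test p-values match independent computation", {
  set.seed(66)
  norm <- matrix(rpois(36, 120), 3, 12,
                 dimnames = list(paste0("m", 1:3), design12$library_id))
  de <- anova_de(mk_profiles(norm))
  for (i in 1:3) {
    ref <- stats::oneway.test(norm[i, ] ~ factor(design12$timepoint_daa),
                              var.equal = TRUE)
    expect_equal(de$anova$anova_p[i], ref$p.value, tolerance = 1e-12)
  }
  # pooled-variance Student t with df = 4 for a hand-sized fixture
  a <- c(10, 12, 14); b <- c(20, 25, 21)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (2 / 3))
  p_manual <- 2 * pt(-abs(t_manual), df = 4)
  norm2 <- matrix(c(a, b, b, a), 1, 12,
                  dimnames = list("x", design12$library_id))
  de2 <- anova_de(mk_profiles(norm2))
  row <- de2$pairwise[de2$pairwise$tp_a == 10 & de2$pairwise$tp_b == 20, ]
  expect_equal(row$p, p_manual, tolerance = 1e-12)
  # comparisons are the consecutive pairs plus first-vs-last
  expect_setequal(paste(de2$pairwise$tp_a, de2$pairwise$tp_b),
                  c("10 20", "20 30", "30 40", "10 40"))
})

test_that("BH adjustment matches the brute-force step-up on random vectors", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(77)
  for (i in 1:300) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
})

test_that("log2 fold changes use the pseudocount convention", {
  expect_equal(log2fc(50, 50), 0)
  expect_equal(log2fc(0, 0), 0)
  expect_equal(log2fc(99, 799), 3)
  expect_error(log2fc(-1, 5), "non-negative")
})

test_that("clustering recovers duplicated archetypes exactly", {
  templ <- seedmir:::archetype_templates()
  norm <- templ[rep(1:6, each = 3), rep(1:4, each = 3)]
  # small within-group jitter so profiles are not exactly collinear
  set.seed(88)
  norm <- norm * matrix(runif(length(norm), 0.97, 1.03), nrow(norm))
  colnames(norm) <- design12$library_id
  rownames(norm) <- paste0("m", 1:18)
  prof <- expression_filter(norm, design12, threshold = 0)
  cl <- cluster_profiles(prof, k = 6)
  grp <- split(cl$assignment$cluster, rep(1:6, each = 3))
  # every archetype triple lands in one cluster, six clusters in total
  expect_true(all(vapply(grp, function(g) length(unique(g)) == 1, TRUE)))
  expect_length(unique(unlist(grp)), 6)
  expect_setequal(unique(cl$assignment$cluster), LETTERS[1:6])
})

test_that("Pearson distance is invariant to positive affine transforms", {
  templ <- seedmir:::archetype_templates()
  base <- templ[rep(1:6, 2), rep(1:4, each = 3)]
  base[7:12, ] <- 3 * base[7:12, ] + 50   # affine copies of rows 1:6
  colnames(base) <- design12$library_id
  rownames(base) <- paste0("m", 1:12)
  prof <- expression_filter(base, design12, threshold = 0)
  cl <- cluster_profiles(prof, k = 6)
  for (i in 1:6)
    expect_equal(cl$assignment$cluster[i], cl$assignment$cluster[i + 6])
})

test_that("cluster_profiles needs enough variable profiles", {
  norm <- matrix(100, 3, 12, dimnames = list(paste0("m", 1:3),
                                             design12$library_id))
  prof <- expression_filter(norm, design12, threshold = 0)
  expect_error(cluster_profiles(prof, k = 6), "smaller k")
})

test_that("PCA of libraries behaves as a standardized SVD", {
  set.seed(99)
  norm <- matrix(rpois(60, 100), 5, 12,
                 dimnames = list(paste0("m", 1:5), design12$library_id))
  # replicate-identical libraries coincide in score space
  norm[, 2] <- norm[, 1]
  prof <- expression_filter(norm, design12, threshold = 0)
  p <- pca_libraries(prof)
  expect_equal(p$scores[1, ], p$scores[2, ])
  expect_equal(sum(p$variance_share), 1)
  # 2-variable fixture: PC1 share equals the leading eigenvalue ratio of
  # the correlation matrix
  norm2 <- matrix(rpois(24, 100), 2, 12,
                  dimnames = list(c("a", "b"), design12$library_id))
  prof2 <- expression_filter(norm2, design12, threshold = 0)
  p2 <- pca_libraries(prof2)
  ev <- eigen(stats::cor(t(norm2)))$values
  expect_equal(p2$variance_share[1], ev[1] / sum(ev), tolerance = 1e-12)
  # sign convention: the largest-magnitude loading is positive
  expect_true(all(apply(p2$loadings, 2,
                        function(v) v[which.max(abs(v))] > 0)))
})

test_that("correlation network applies the |r| and p thresholds", {
  set.seed(111)
  x <- rnorm(12, 100, 20)
  norm <- rbind(a = x, b = x * 2 + 5, c = -x + 400, d = rnorm(12, 100, 20),
                e = rep(7, 12))
  colnames(norm) <- design12$library_id
  prof <- expression_filter(norm, design12, threshold = 0)
  edges <- correlation_network(prof)
  ab <- edges[edges$mirna_a == "a" & edges$mirna_b == "b", ]
  expect_equal(ab$r, 1)
  expect_equal(ab$sign, "positive")
  ac <- edges[edges$mirna_a == "a" & edges$mirna_b == "c", ]
  expect_equal(ac$r, -1)
  expect_equal(ac$sign, "negative")
  # constant profiles never pair
  expect_false(any(edges$mirna_a == "e" | edges$mirna_b == "e"))
  # p-values agree with cor.test
  for (i in seq_len(nrow(edges))) {
    ct <- stats::cor.test(norm[edges$mirna_a[i], ],
                          norm[edges$mirna_b[i], ])
    expect_equal(edges$p[i], ct$p.value, tolerance = 1e-9)
  }
  # the boundary arithmetic: r = 0.75 at n = 12 gives p about 0.0049
  r <- 0.75; n <- 12
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(tstat, 3.586, tolerance = 1e-3)
  expect_lt(2 * pt(-tstat, n - 2), 0.05)
})

test_that("cluster recovery degrades as count dispersion grows", {
  skip_if_not_installed("mclust")
  ari_at <- function(disp) {
    cfg <- sim_config(seed = 7, n_planted_hairpins = 36L,
                      genome_length = 150000L, nb_dispersion = disp,
                      n_decoy_tags = 0L, depth_per_library = 5e4)
    g <- generate_genome(cfg)
    ph <- plant_hairpins(g, cfg)
    ref <- build_reference(ph$truth, ph$genome, cfg)
    libs <- simulate_libraries(ref$truth, NULL, ph$genome, cfg)
    norm <- sweep(libs$truth_counts, 2, cfg$depth_per_library, "/") * 1e6
    prof <- expression_filter(norm, libs$design, threshold = 0)
    cl <- cluster_profiles(prof, 6)
    truth_lab <- ph$truth$archetype[match(cl$assignment$mirna_id,
                                          ph$truth$mirna_id)]
    mclust::adjustedRandIndex(cl$assignment$cluster, truth_lab)
  }
  a_low <- ari_at(0.05); a_high <- ari_at(2)
  expect_gte(a_low, 0.8)
  expect_gte(a_low, a_high)
})
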