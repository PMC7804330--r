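test_that("fold reproduces hand-computable structures", {
  f <- fold("GGGGAAAACCCC")
  expect_equal(f$mfe_kcal_mol, -12)
  expect_equal(f$dot_bracket, "((((....))))")
  # no pairable partner: open chain, zero energy
  fa <- fold(strrep("A", 30))
  expect_equal(fa$mfe_kcal_mol, 0)
  expect_equal(fa$dot_bracket, strrep(".", 30))
  # purely deterministic
  set.seed(1); s <- rand_seq(120)
  expect_identical(fold(s), fold(s))
  expect_error(fold("ACGT"), "8-400")
  expect_error(fold("ACGTNGGGCCC"), "ACGT")
})

test_that("fold matches exhaustive enumeration on short sequences", {
  set.seed(202)
  for (i in seq_len(120)) {
    s <- rand_seq(sample(10:16, 1))
    f <- fold(s)
    expect_equal(-f$mfe_kcal_mol, oracle_fold_best(s), info = s)
    # reported structure scores its own energy
    pt <- pairing_table(f$dot_bracket)
    opens <- which(pt > seq_along(pt))
    w <- c(GC = 3, CG = 3, AT = 2, TA = 2, GT = 1, TG = 1)
    sc <- if (length(opens) == 0) 0 else
      sum(w[paste0(substring(s, opens, opens),
                   substring(s, pt[opens], pt[opens]))])
    expect_equal(sc, -f$mfe_kcal_mol, info = s)
  }
})

test_that("pairing_table inverts dot-bracket strings", {
  pt <- pairing_table("((((....))))")
  expect_equal(pt[1:4], c(12L, 11L, 10L, 9L))
  expect_equal(pt[5:8], rep(0L, 4))
  expect_error(pairing_table("((..)"), "unbalanced")
})

test_that("extract_windows builds three clipped tag-anchored windows", {
  g <- stats::setNames(rand_seq(1000), "chr1")
  locus <- data.frame(chrom = "chr1", start = 490, end = 510,
                      strand = "+", stringsAsFactors = FALSE)
  w <- extract_windows(g, locus, flank = 80)
  expect_equal(nchar(w$sequence), c(101, 101, 181))
  tag <- substr(g[[1]], 490, 510)
  for (k in 1:3) {
    expect_true(grepl(tag, w$sequence[k], fixed = TRUE))
    expect_equal(substr(w$sequence[k], w$mature_start[k], w$mature_end[k]),
                 tag)
  }
  # near-boundary locus is clipped
  locus2 <- data.frame(chrom = "chr1", start = 10, end = 30, strand = "+")
  w2 <- extract_windows(g, locus2, flank = 80)
  expect_equal(w2$win_start[1], 1)
  expect_equal(nchar(w2$sequence[1]), 30)
  # minus-strand windows carry the reverse-complement tag
  locus3 <- data.frame(chrom = "chr1", start = 490, end = 510, strand = "-")
  w3 <- extract_windows(g, locus3, flank = 80)
  expect_equal(substr(w3$sequence[3], w3$mature_start[3], w3$mature_end[3]),
               revcomp(tag))
})

test_that("locate_arms decomposes a perfect hairpin and rejects branches", {
  stem5 <- strrep("G", 30); stem3 <- strrep("C", 30)
  hp <- paste0(stem5, strrep("A", 6), stem3)
  f <- fold(hp)
  dec <- locate_arms(f, c(1, 21))
  expect_equal(dec$loop, c(31, 36))
  expect_equal(dec$five_arm, c(1, 30))
  expect_equal(dec$three_arm, c(37, 66))
  # star span: pairing partners of a fully paired mature + 2-nt 3' offset,
  # clipped at the sequence end (66 nt here)
  expect_equal(dec$star, c(46, 66))
  hp_ext <- paste0(hp, "AAAA")
  dec_ext <- locate_arms(fold(hp_ext), c(1, 21))
  expect_equal(dec_ext$star, c(46, 68))
  # mature inside the terminal loop is rejected
  expect_null(locate_arms(f, c(32, 35)))
  # two hairpins side by side (cloverleaf-like) are rejected
  two <- paste0("GGGGGGGGAAAACCCCCCCC", "TTTT",
                "GGGGGGGGAAAACCCCCCCC")
  f2 <- fold(two)
  expect_gt(length(seedmir:::innermost_pairs(pairing_table(f2$dot_bracket))), 1)
  expect_null(locate_arms(f2, c(1, 8)))
  # unpaired fold
  expect_null(locate_arms(fold(strrep("A", 20)), c(1, 10)))
})

test_that("compute_features matches the worked constructions", {
  # 22-bp perfect stem, 12-nt loop, 21-nt fully paired mature on the 5' arm
  set.seed(31)
  arm <- paste(sample(c("G", "C"), 22, TRUE), collapse = "")
  hp <- paste0(arm, paste(sample(c("A", "C"), 12, TRUE), collapse = ""),
               revcomp(arm))
  f <- fold(hp)
  dec <- locate_arms(f, c(1, 21))
  fe <- compute_features(f, dec, c(1, 21))
  expect_equal(fe$stem_bp, 22)
  expect_equal(fe$hairpin_len, 56)
  expect_equal(fe$loop_len, 12)
  expect_equal(fe$biased_bulges_mature, 0)
  expect_equal(fe$mature_bp, 21)
  expect_equal(fe$pm, 100)
  # the MFEI arithmetic: AMFE / GC%
  expect_equal(fe$amfe, abs(fe$mfe) / nchar(hp) * 100)
  expect_equal(fe$mfei, fe$amfe / fe$gc_percent)
})

test_that("an asymmetric insertion in the mature counts as one biased bulge", {
  set.seed(33)
  arm <- paste(sample(c("G", "C"), 21, TRUE), collapse = "")
  # mature = arm with one extra base inserted mid-way; opposite strand fully
  # paired
  mat <- paste0(substr(arm, 1, 10), "A", substr(arm, 11, 21))
  hp <- paste0(mat, paste(sample(c("A", "C"), 12, TRUE), collapse = ""),
               revcomp(arm))
  f <- fold(hp)
  dec <- locate_arms(f, c(1, 22))
  fe <- compute_features(f, dec, c(1, 22))
  expect_equal(fe$biased_bulges_mature, 1)
})

test_that("compute_features agrees with the pairing-table brute force", {
  set.seed(44)
  cfg <- small_cfg()
  checked <- 0
  while (checked < 35) {
    mature <- rand_seq(sample(20:22, 1))
    hp <- seedmir:::build_hairpin(mature, cfg)
    span <- c(hp$mature_start, hp$mature_end)
    f <- fold(hp$precursor)
    dec <- locate_arms(f, span)
    if (is.null(dec)) next
    fe <- compute_features(f, dec, span)
    or <- oracle_features(f$dot_bracket, span)
    expect_equal(fe$stem_bp, or$stem_bp, info = hp$precursor)
    expect_equal(fe$mature_bp, or$mature_bp, info = hp$precursor)
    expect_equal(fe$pm, or$pm, info = hp$precursor)
    expect_equal(fe$loop_len, or$loop_len, info = hp$precursor)
    expect_equal(fe$hairpin_len, or$hairpin_len, info = hp$precursor)
    expect_equal(fe$biased_bulges_mature, or$biased_bulges_mature,
                 info = hp$precursor)
    checked <- checked + 1
  }
  expect_equal(checked, 35)
})

test_that("the eight criteria are applied inclusively", {
  at_threshold <- list(stem_bp = 22, mfe = -17, hairpin_len = 56,
                       loop_len = 82, biased_bulges_mature = 2,
                       mature_bp = 14, star_bp = 0, pm = 80,
                       gc_percent = 50, amfe = 17, mfei = 0.80)
  expect_true(all(apply_criteria(at_threshold)))
  f2 <- at_threshold; f2$mfe <- -16.9
  expect_equal(sum(!apply_criteria(f2)), 1)
  expect_false(apply_criteria(f2)[["mfe"]])
  f3 <- at_threshold; f3$mfei <- 0.79
  expect_false(apply_criteria(f3)[["mfei"]])
  expect_equal(sum(apply_criteria(f3)), 7)
  # criterion 6 passes through the star arm as well
  f4 <- at_threshold; f4$mature_bp <- 10; f4$star_bp <- 14
  expect_true(apply_criteria(f4)[["mature_bp"]])
  # undefined MFEI fails criterion 8
  f5 <- at_threshold; f5$mfei <- NA_real_
  expect_false(apply_criteria(f5)[["mfei"]])
})

test_that("discovery recovers planted hairpins, rejects decoys, is deterministic", {
  sim <- small_sim()
  resid <- c(sim$truth$mature_sequence, sim$decoys$sequence)
  calls <- discover(resid, sim$genome)
  novel <- calls$tag[calls$novel]
  expect_gte(sum(sim$truth$mature_sequence %in% novel), 5)  # 6 planted
  expect_equal(sum(sim$decoys$sequence %in% novel), 0)
  # ids run miR_1.. in order of first genome coordinate
  ids <- calls$mirna_id[calls$novel]
  expect_equal(sort(ids), sort(sprintf("miR_%d", seq_along(ids))))
  ord <- order(calls$start[calls$novel])
  expect_equal(calls$mirna_id[calls$novel][ord],
               sprintf("miR_%d", seq_along(ids)))
  # tags without a genome locus are skipped
  expect_equal(nrow(discover("ACGTACGTACGTACGTACGTA", sim$genome)), 0)
  # determinism
  expect_identical(calls, discover(resid, sim$genome))
})

test_that("weakening any single threshold never shrinks the novel set", {
  sim <- small_sim()
  resid <- c(sim$truth$mature_sequence, sim$decoys$sequence)
  base_th <- novel_criteria_thresholds()
  base_calls <- discover(resid, sim$genome)
  base_set <- base_calls$tag[base_calls$novel]
  weaker <- list(stem_bp = 20, mfe = -10, hairpin_len = 40, loop_len = 100,
                 biased_bulges = 4, mature_bp = 10, pm = 60, mfei = 0.5)
  for (nm in names(weaker)) {
    th <- base_th
    th[[nm]] <- weaker[[nm]]
    relaxed <- discover(resid, sim$genome, thresholds = th)
    relaxed_set <- relaxed$tag[relaxed$novel]
    expect_true(all(base_set %in% relaxed_set), info = nm)
  }
})
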