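test_that("expectation scoring follows the seed-weighted penalty table", {
  set.seed(120)
  mirna <- rand_seq(21)
  tx <- paste0(rand_seq(100), revcomp(mirna), rand_seq(100))
  al <- score_site(mirna, tx)
  expect_equal(al$expectation, 0)
  expect_equal(al$site_start, 101)
  expect_equal(al$site_end, 121)
  expect_true(all(al$pair_string == "match"))

  # G:U wobble: 0.5 outside the seed, doubled inside
  put_wobble <- function(mirna, tx, site_start, k) {
    # transcript base opposite miRNA position k becomes the wobble partner
    ch <- strsplit(tx, "")[[1]]
    m <- substr(mirna, k, k)
    pos <- site_start + nchar(mirna) - k
    wob <- c(G = "T", T = "G")[m]
    if (is.na(wob)) return(NULL)
    ch[pos] <- wob
    paste(ch, collapse = "")
  }
  # force a G at miRNA positions 20 and 5 so a wobble is constructible
  m2 <- mirna
  substr(m2, 20, 20) <- "G"; substr(m2, 5, 5) <- "G"
  tx2 <- paste0(rand_seq(100), revcomp(m2), rand_seq(100))
  t_w20 <- put_wobble(m2, tx2, 101, 20)
  expect_equal(score_site(m2, t_w20)$expectation, 0.5)
  t_w5 <- put_wobble(m2, tx2, 101, 5)
  expect_equal(score_site(m2, t_w5)$expectation, 1.0)

  # two seed mismatches: E = 4 > 2, not reported
  ch <- strsplit(tx2, "")[[1]]
  for (k in c(3, 7)) {
    pos <- 101 + nchar(m2) - k
    ch[pos] <- c(A = "C", C = "A", G = "G", T = "C")[substr(m2, k, k)]
    if (ch[pos] == substr(m2, k, k) && ch[pos] == "G") ch[pos] <- "G"
  }
  tx_mm <- paste(ch, collapse = "")
  expect_null(score_site(m2, tx_mm))
})

test_that("expectation recomputes exactly from the stored pair string", {
  set.seed(121)
  for (i in 1:20) {
    mirna <- rand_seq(sample(20:22, 1))
    tx <- paste0(rand_seq(60), revcomp(mirna), rand_seq(60))
    # corrupt a couple of non-seed positions
    for (p in sample(61:80, 2)) substr(tx, p, p) <- sample(c("A", "C"), 1)
    al <- score_site(mirna, tx, cutoff = 10)
    expect_false(is.null(al))
    expect_equal(expectation_from_pairs(al$pair_string), al$expectation)
  }
})

test_that("cleavage is predicted opposite miRNA position 10", {
  al <- list(site_start = 101, pair_string = rep("match", 21))
  expect_equal(predict_cleavage(al), 112)
  al2 <- list(site_start = 102, pair_string = rep("match", 21))
  expect_equal(predict_cleavage(al2), 113)
  gap <- rep("match", 21); gap[10] <- "gap"
  expect_true(is.na(predict_cleavage(list(site_start = 101,
                                          pair_string = gap))))
})

test_that("degradome categories follow the T-plot rules", {
  counts <- integer(50); counts[25] <- 10L
  expect_equal(degradome_category(counts, 25), 0L)
  expect_true(is.na(degradome_category(counts, 10)))
  expect_equal(degradome_category(c(5L, 5L, 2L, 1L), 1), 1L)
  all1 <- rep(1L, 20)
  expect_equal(degradome_category(all1, 7), 4L)
  expect_error(degradome_category(counts, 51), "outside")
})

test_that("degradome_category agrees with exhaustive rule evaluation", {
  set.seed(131)
  for (i in 1:1000) {
    n <- sample(5:40, 1)
    counts <- sample(0:6, n, TRUE, prob = c(0.5, 0.2, 0.1, 0.08, 0.06,
                                            0.04, 0.02))
    pos <- sample(n, 1)
    expect_identical(degradome_category(counts, pos),
                     oracle_category(counts, pos),
                     info = paste(c(counts, ":", pos), collapse = " "))
  }
})

test_that("dinucleotide shuffling preserves the dinucleotide census", {
  set.seed(141)
  for (i in 1:25) {
    s <- rand_seq(21)
    sh <- seedmir:::dinucleotide_shuffle(s)
    expect_equal(nchar(sh), nchar(s))
    dinucs <- function(x) sort(substring(x, 1:(nchar(x) - 1),
                                         2:nchar(x)))
    expect_equal(dinucs(sh), dinucs(s))
  }
})

test_that("T-plot p-values separate planted sites from noise", {
  set.seed(151)
  mirna <- rand_seq(21)
  tx <- paste0(rand_seq(500), revcomp(mirna), rand_seq(479))
  counts <- sample(0:1, 1000, TRUE)
  cleav <- 501 + 21 - 10
  counts[cleav] <- 10L
  p_true <- tplot_pvalue(counts, mirna, tx, observed_e = 0,
                         observed_category = 0, seed = 9)
  expect_lte(p_true, 0.05)
  # with the cutoff effectively disabled on a random profile, shuffles match
  # easily and the p-value is large
  p_null <- tplot_pvalue(sample(0:1, 1000, TRUE), mirna, rand_seq(1000),
                         observed_e = 30, observed_category = 4, seed = 9)
  expect_gt(p_null, 0.5)
  # deterministic under a fixed seed
  expect_identical(p_true,
                   tplot_pvalue(counts, mirna, tx, 0, 0, seed = 9))
})

test_that("filter_hits enforces category, strict p and expression", {
  hits <- data.frame(mirna_id = c("a", "b", "c", "d", "e"),
                     transcript_id = paste0("t", 1:5),
                     category = c(3L, 0L, 1L, 0L, NA),
                     tplot_p = c(0.01, 0.05, 0.01, 0.01, 0.01),
                     stringsAsFactors = FALSE)
  kept <- filter_hits(hits, expressed_ids = c("a", "b", "d"))
  # a: category 3 out; b: p not strictly below 0.05; c: not expressed;
  # e: no category
  expect_equal(kept$mirna_id, "d")
})

test_that("planted degradome pairs survive the full targeting path", {
  sim <- small_sim()
  mirnas <- data.frame(mirna_id = sim$truth$mirna_id,
                       sequence = sim$truth$mature_sequence,
                       stringsAsFactors = FALSE)
  targets <- predict_targets(mirnas, sim$degradome$transcripts, cutoff = 2)
  hits <- degradome_hits(targets, sim$degradome$profiles, mirnas,
                         sim$degradome$transcripts, n_shuffles = 50,
                         seed = 3)
  kept <- filter_hits(hits, mirnas$mirna_id)
  truth_pairs <- paste(sim$degradome$targets$mirna_id,
                       sim$degradome$targets$transcript_id)
  got <- paste(kept$mirna_id, kept$transcript_id)
  expect_true(all(truth_pairs %in% got))
  expect_equal(sum(!got %in% truth_pairs), 0)
})
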