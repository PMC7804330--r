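sub_at <- function(seq, pos) {
  ch <- strsplit(seq, "")[[1]]
  ch[pos] <- c(A = "C", C = "A", G = "T", T = "G")[ch[pos]]
  paste(ch, collapse = "")
}

test_that("match_mature applies the position-constrained mismatch rules", {
  set.seed(7)
  m <- rand_seq(21)
  # identical tag
  hit <- match_mature(m, m)
  expect_equal(hit$n_mismatches, 0)
  expect_equal(c(hit$shift_5p, hit$shift_3p), c(0, 0))
  # the cleavage-pairing core is protected
  expect_null(match_mature(sub_at(m, 10), m))
  expect_null(match_mature(sub_at(m, 11), m))
  # two 5' region mismatches exceed the allowance
  expect_null(match_mature(sub_at(sub_at(m, 3), 5), m))
  # one 5' plus one 3' mismatch is valid
  hit2 <- match_mature(sub_at(sub_at(m, 3), 15), m)
  expect_equal(hit2$n_mismatches, 2)
  expect_setequal(hit2$mismatch_positions, c(3, 15))
  # three mismatches are too many
  expect_null(match_mature(sub_at(sub_at(sub_at(m, 3), 15), 18), m))
  # end shifts of up to 2 nt are tolerated, larger overhangs are not
  expect_false(is.null(match_mature(substr(m, 1, 19), m)))
  expect_null(match_mature(substr(m, 1, 18), m))
})

test_that("match_mature agrees with the brute-force rule checker", {
  set.seed(101)
  n_cases <- 2000
  for (i in seq_len(n_cases)) {
    m <- rand_seq(sample(20:22, 1))
    tag <- m
    # random perturbation: substitutions and/or end trims/extensions
    nsub <- sample(0:3, 1)
    if (nsub > 0)
      for (p in sample(nchar(tag), nsub)) tag <- sub_at(tag, p)
    trim <- sample(0:3, 1)
    if (trim > 0) tag <- substr(tag, 1 + trim %/% 2, nchar(tag) - trim %/% 2)
    got <- match_mature(tag, m)
    want <- oracle_match(tag, m)
    expect_equal(!is.null(got), want$valid,
                 info = sprintf("tag %s vs %s", tag, m))
    if (want$valid)
      expect_equal(got$n_mismatches, want$n_mismatches,
                   info = sprintf("tag %s vs %s", tag, m))
  }
})

test_that("classification requires genome presence and breaks ties lexicographically", {
  sim <- small_sim()
  ref <- sim$reference
  # planted known matures classify with 0 mismatches
  known_seq <- sim$truth$mature_sequence[sim$truth$is_known]
  cls <- classify_tags(known_seq, ref$matures, ref$precursors, sim$genome)
  expect_equal(nrow(cls$assignments), length(known_seq))
  expect_true(all(cls$assignments$n_mismatches == 0))
  expect_true(all(grepl("^pvu-", cls$assignments$assigned_id)))
  expect_true(all(nzchar(cls$assignments$genome_loci)))

  # a tag matching only a decoy reference entry absent from the genome is
  # residual, not known
  decoy_seq <- ref$matures$sequence[ref$matures$family == "MIRDECOY"][1]
  cls2 <- classify_tags(decoy_seq, ref$matures, ref$precursors, sim$genome)
  expect_equal(nrow(cls2$assignments), 0)
  expect_equal(cls2$residuals, decoy_seq)

  # ties between equally good matures resolve to the smaller id
  tag <- sim$truth$mature_sequence[sim$truth$is_known][1]
  dup <- rbind(ref$matures,
               data.frame(mirna_id = "aaa-dup", family = "MIRDUP",
                          sequence = tag, arm = "5p"))
  cls3 <- classify_tags(tag, dup, ref$precursors, sim$genome)
  expect_equal(cls3$assignments$matched_id, "aaa-dup")
})

test_that("cross-species path accepts a tag whose precursor is genomic", {
  sim <- small_sim()
  truth <- sim$truth
  i <- which(truth$is_known)[1]
  # a 1-mismatch variant of the planted mature: absent from the genome
  # itself, but its reference precursor is present
  tag <- sub_at(truth$mature_sequence[i], 20)
  if (nrow(find_genome_loci(tag, sim$genome)) == 0) {
    cls <- classify_tags(tag, sim$reference$matures,
                         sim$reference$precursors, sim$genome)
    expect_equal(nrow(cls$assignments), 1)
    expect_equal(cls$assignments$source, "cross-species")
    expect_equal(cls$assignments$n_mismatches, 1)
  }
})

test_that("opposite_arm_call reports star-arm candidates only", {
  sim <- small_sim()
  truth <- sim$truth[sim$truth$is_known, ][1, ]
  prec <- sim$reference$precursors[
    sim$reference$precursors$sequence == truth$precursor_sequence, ]
  mlen <- nchar(truth$mature_sequence)
  f <- fold(prec$sequence)
  dec <- locate_arms(f, c(truth$mature_offset, truth$mature_offset + mlen - 1))
  # a tag from the star side of the stem
  star_tag <- substr(prec$sequence, dec$star[1], dec$star[2] - 2)
  call <- opposite_arm_call(star_tag, prec)
  expect_false(is.null(call))
  expect_equal(call$arm, "3p")
  # a tag overlapping the annotated mature by far more than 2 nt
  over_tag <- substr(prec$sequence, truth$mature_offset + 2,
                     truth$mature_offset + mlen + 1)
  expect_null(opposite_arm_call(over_tag, prec))
  # a tag sitting in the terminal loop
  cfg_loop <- small_cfg(loop_length = 18L)
  loop_tag <- substr(prec$sequence, dec$loop[1], dec$loop[2])
  if (nchar(loop_tag) >= 15)
    expect_null(opposite_arm_call(loop_tag, prec))
})

test_that("family hints are advisory and bounded by the relaxed allowance", {
  set.seed(13)
  mat <- data.frame(mirna_id = c("xxx-miR1509a", "xxx-miR2000"),
                    family = c("MIR1509", "MIR2000"),
                    sequence = c(rand_seq(21), rand_seq(21)),
                    arm = "5p", stringsAsFactors = FALSE)
  tag3 <- sub_at(sub_at(sub_at(mat$sequence[1], 2), 8), 14)
  expect_equal(family_hint(tag3, mat), "MIR1509")
  far <- rand_seq(21)  # essentially random: beyond 4 mismatches
  expect_null(family_hint(far, mat))
  expect_error(family_hint(tag3, mat, relaxed_mismatches = 2), "exceed")
})
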