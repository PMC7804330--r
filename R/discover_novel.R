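# Novel miRNA discovery: fold tag-anchored genomic windows, decompose the
# structure into the stem-loop unit carrying the candidate mature, measure
# the eight structural descriptors and call a new miRNA when all eight
# criteria hold (stem >= 22 bp, MFE <= -17 kcal/mol, hairpin >= 56 nt,
# terminal loop <= 82 nt, <= 2 biased bulges in the mature, >= 14 pairs in
# the mature or star region, >= 80% of the mature in the stem, MFEI >= 0.8).

#' Structural criteria thresholds for novel miRNA calling
#'
#' All eight thresholds are applied inclusively.
#'
#' @return named list of thresholds.
#' @export
novel_criteria_thresholds <- function() {
  list(stem_bp = 22, mfe = -17, hairpin_len = 56, loop_len = 82,
       biased_bulges = 2, mature_bp = 14, pm = 80, mfei = 0.80)
}

# hairpin loops: opening positions of innermost pairs
innermost_pairs <- function(pt) {
  opens <- which(pt > seq_along(pt))
  opens[vapply(opens, function(i) all(pt[(i + 1):(pt[i] - 1)] == 0), TRUE)]
}

# grow the stem-loop unit of the hairpin closed by pair (i0, pt[i0]) outward
# through stacked pairs, bulges and internal loops, stopping at a multiloop
# junction, the exterior, or an interior loop wider than max_gap on either
# side (a contiguous precursor stem tolerates only small imperfections;
# without the cap, unrelated helices of a random fold would chain into one
# spuriously long "stem"); returns c(I, J)
grow_unit <- function(pt, i0, max_gap = 8L, min_helix = 3L) {
  # length of the contiguous stacked helix starting at pair (a, pt[a]) and
  # growing outward
  helix_run <- function(a) {
    b <- pt[a]; len <- 1L
    while (a - len >= 1L && b + len <= length(pt) &&
           pt[a - len] == b + len) len <- len + 1L
    len
  }
  I <- i0; J <- pt[i0]
  repeat {
    left <- if (I > 1) max(c(0L, which(pt[seq_len(I - 1L)] > 0))) else 0L
    if (left == 0L) break
    q <- pt[left]
    if (q <= J) break                                # sibling helix: junction
    between_left <- if (left + 1L <= I - 1L) pt[(left + 1L):(I - 1L)] else integer(0)
    between_right <- if (J + 1L <= q - 1L) pt[(J + 1L):(q - 1L)] else integer(0)
    if (any(between_left > 0) || any(between_right > 0)) break   # branch
    gapL <- I - left - 1L; gapR <- q - J - 1L
    if (gapL > max_gap || gapR > max_gap) break      # interior loop too wide
    # crossing a loop onto a new helix: only extend across helices of at
    # least min_helix stacked pairs (short chance duplexes do not continue
    # a precursor stem)
    if ((gapL > 0L || gapR > 0L) && helix_run(left) < min_helix) break
    I <- left; J <- q
  }
  c(I, J)
}

#' Locate the stem-loop unit, arms, terminal loop and star of a fold
#'
#' Decomposes a single-hairpin structure around the mature. The terminal
#' loop is the unpaired run enclosed by the innermost pair; the arms flank
#' it within the outermost pair of the stem-loop unit; the star spans the
#' positions pairing with the mature, extended by the canonical 2-nt 3'
#' offset. Branched (multi-loop, cloverleaf-like) structures, folds without
#' pairs, and matures sitting in the terminal loop or outside the unit are
#' rejected.
#'
#' @param fold a `fold_result`.
#' @param mature_span integer `c(start, end)` of the mature within the
#'   folded sequence (1-based inclusive).
#' @return `NULL` when rejected, else a list with `unit`, `five_arm`,
#'   `loop`, `three_arm`, `star` (each `c(start, end)`), and `pt` (the
#'   pairing table).
#' @export
locate_arms <- function(fold, mature_span) {
  pt <- pairing_table(fold$dot_bracket)
  n <- length(pt)
  s <- mature_span[1]; e <- mature_span[2]
  if (s < 1 || e > n || s > e) stopf("mature span outside sequence")
  paired <- which(pt > 0)
  if (length(paired) == 0) return(NULL)

  innermost <- innermost_pairs(pt)
  if (length(innermost) != 1) return(NULL)   # branched: not a hairpin

  i0 <- innermost[1]
  unit <- grow_unit(pt, i0)
  if (!(unit[1] <= s && e <= unit[2])) return(NULL)
  loop <- c(i0 + 1L, pt[i0] - 1L)
  if (s >= loop[1] && e <= loop[2]) return(NULL)   # mature inside the loop
  five_arm <- c(unit[1], i0)
  three_arm <- c(pt[i0], unit[2])
  partners <- pt[s:e]
  partners <- partners[partners > 0]
  star <- if (length(partners) == 0) NULL else
    c(min(partners), min(max(partners) + 2L, n))
  list(unit = unit, five_arm = five_arm, loop = loop,
       three_arm = three_arm, star = star, pt = pt)
}

#' Structural descriptors of a hairpin candidate
#'
#' @param fold a `fold_result`.
#' @param decomposition output of [locate_arms()].
#' @param mature_span `c(start, end)` of the mature within the sequence.
#' @return list of descriptors: `stem_bp`, `mfe`, `hairpin_len`, `loop_len`,
#'   `biased_bulges_mature`, `mature_bp`, `star_bp`, `pm`, `gc_percent`,
#'   `amfe`, `mfei`.
#' @export
compute_features <- function(fold, decomposition, mature_span) {
  pt <- decomposition$pt
  n <- length(pt)
  s <- mature_span[1]; e <- mature_span[2]
  arms <- c(decomposition$five_arm[1]:decomposition$five_arm[2],
            decomposition$three_arm[1]:decomposition$three_arm[2])
  loop_len <- decomposition$loop[2] - decomposition$loop[1] + 1L

  in_arms <- logical(n); in_arms[arms] <- TRUE
  opens <- which(pt > seq_len(n))
  stem_bp <- sum(in_arms[opens] & in_arms[pt[opens]])
  hairpin_len <- decomposition$unit[2] - decomposition$unit[1] + 1L

  span_bp <- function(span) {
    if (is.null(span)) return(0L)
    idx <- span[1]:span[2]
    touches <- opens[opens %in% idx | pt[opens] %in% idx]
    length(touches)
  }
  mature_bp <- span_bp(c(s, e))
  star_bp <- span_bp(decomposition$star)

  # asymmetric (biased) bulges: maximal unpaired runs inside the mature whose
  # opposite strand has no unpaired partner run between the flanking pairs
  biased <- 0L
  mpos <- s:e
  unp <- mpos[pt[mpos] == 0]
  if (length(unp) > 0) {
    runs <- split(unp, cumsum(c(1L, diff(unp) != 1L)))
    for (run in runs) {
      r1 <- run[1]; r2 <- run[length(run)]
      left_paired <- which(pt[seq_len(r1 - 1L)] > 0)
      right_paired <- which(pt > 0)
      right_paired <- right_paired[right_paired > r2]
      if (length(left_paired) == 0 || length(right_paired) == 0) next
      pL <- max(left_paired); pR <- min(right_paired)
      gap <- abs(pt[pL] - pt[pR]) - 1L
      if (gap == 0L) biased <- biased + 1L
    }
  }

  pm <- 100 * sum(in_arms[mpos]) / length(mpos)
  gc <- gc_percent(fold$sequence)
  amfe <- abs(fold$mfe_kcal_mol) / nchar(fold$sequence) * 100
  # MFEI = AMFE / GC%, both on their usual scales (AMFE per 100 nt, GC 0-100)
  mfei <- if (gc > 0) amfe / gc else NA_real_

  list(stem_bp = stem_bp, mfe = fold$mfe_kcal_mol,
       hairpin_len = hairpin_len, loop_len = loop_len,
       biased_bulges_mature = biased, mature_bp = mature_bp,
       star_bp = star_bp, pm = pm, gc_percent = gc, amfe = amfe,
       mfei = mfei)
}

#' Apply the eight structural criteria
#'
#' Thresholds are inclusive. Criterion 6 (paired nucleotides) passes when
#' either the mature or the star region reaches the threshold. An undefined
#' MFEI (zero GC content) fails criterion 8.
#'
#' @param features descriptor list from [compute_features()].
#' @param thresholds threshold list, see [novel_criteria_thresholds()].
#' @return named logical vector of the eight per-criterion flags.
#' @export
apply_criteria <- function(features, thresholds = novel_criteria_thresholds()) {
  th <- thresholds
  c(stem_bp = features$stem_bp >= th$stem_bp,
    mfe = features$mfe <= th$mfe,
    hairpin_len = features$hairpin_len >= th$hairpin_len,
    loop_len = features$loop_len <= th$loop_len,
    biased_bulges = features$biased_bulges_mature <= th$biased_bulges,
    mature_bp = max(features$mature_bp, features$star_bp) >= th$mature_bp,
    pm = features$pm >= th$pm,
    mfei = !is.na(features$mfei) && features$mfei >= th$mfei)
}

#' Tag-anchored candidate windows around a genome locus
#'
#' Three windows on the mapped strand: left-flanked, right-flanked and
#' both-flanked, each clipped at the chromosome ends and each containing the
#' tag.
#'
#' @param genome named chromosome vector.
#' @param locus list/row with `chrom`, `start`, `end`, `strand`.
#' @param flank flank size in nt.
#' @return data.frame with `window`, `win_start`, `win_end`, `sequence`,
#'   `mature_start`, `mature_end` (tag span within the window sequence).
#' @export
extract_windows <- function(genome, locus, flank = 80L) {
  chrom_seq <- genome[[locus$chrom]]
  if (is.null(chrom_seq)) stopf("unknown chromosome '%s'", locus$chrom)
  glen <- nchar(chrom_seq)
  s <- locus$start; e <- locus$end
  wins <- rbind(c(max(1L, s - flank), e),
                c(s, min(glen, e + flank)),
                c(max(1L, s - flank), min(glen, e + flank)))
  out <- lapply(seq_len(nrow(wins)), function(k) {
    a <- wins[k, 1]; b <- wins[k, 2]
    sq <- substr(chrom_seq, a, b)
    if (identical(locus$strand, "-")) {
      sq <- revcomp(sq)
      ms <- b - e + 1L
    } else ms <- s - a + 1L
    data.frame(window = k, win_start = a, win_end = b, sequence = sq,
               mature_start = ms, mature_end = ms + (e - s),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Excise the candidate precursor from an extraction window. The window is
# folded; if the structure is branched, it is trimmed to the stem-loop unit
# overlapping the mature most (union with the mature span) and refolded,
# iterating until the candidate folds into a single clean hairpin (as real
# precursor excision does) or no progress is made. Criteria are then
# measured on the converged candidate, so MFE/MFEI describe the precursor
# hairpin itself rather than the arbitrary extraction window.
evaluate_window <- function(sequence, mature_span, thresholds,
                            max_iter = 6L, margin = 10L) {
  empty <- list(stem_bp = 0L, mfe = 0, hairpin_len = 0L, loop_len = 0L,
                biased_bulges_mature = 0L, mature_bp = 0L, star_bp = 0L,
                pm = 0, gc_percent = gc_percent(sequence), amfe = 0,
                mfei = NA_real_)
  reject <- list(features = empty,
                 flags = stats::setNames(rep(FALSE, 8),
                                         names(apply_criteria(empty, thresholds))),
                 usable = FALSE, sequence = sequence)
  # strict measurement of one candidate: NULL unless it folds into a single
  # clean hairpin carrying the mature
  measure <- function(cand_seq, cand_span) {
    if (nchar(cand_seq) < 8L || cand_span[1] < 1 ||
        cand_span[2] > nchar(cand_seq)) return(NULL)
    f <- fold(cand_seq)
    if (length(innermost_pairs(pairing_table(f$dot_bracket))) != 1)
      return(NULL)
    dec <- locate_arms(f, cand_span)
    if (is.null(dec)) return(NULL)
    feats <- compute_features(f, dec, cand_span)
    list(features = feats, flags = apply_criteria(feats, thresholds),
         usable = TRUE, sequence = cand_seq)
  }
  better <- function(x, y) {     # is candidate x better than y?
    if (is.null(x)) return(FALSE)
    if (is.null(y)) return(TRUE)
    sum(x$flags) > sum(y$flags) ||
      (sum(x$flags) == sum(y$flags) &&
       x$features$stem_bp > y$features$stem_bp)
  }

  off <- 0L                      # offset of cur_seq within sequence
  cur_seq <- sequence
  cur_span <- as.integer(mature_span)
  for (iter in seq_len(max_iter)) {
    if (nchar(cur_seq) < 8L) return(reject)
    f <- fold(cur_seq)
    pt <- pairing_table(f$dot_bracket)
    inner <- innermost_pairs(pt)
    if (length(inner) == 0) return(reject)
    if (length(inner) == 1) {
      res <- measure(cur_seq, cur_span)
      if (is.null(res)) return(reject)
      # a stem-closing helix can lose its partner to an equal-weight tie in
      # the window-level fold and end up just outside the excision; one
      # margin extension around the converged candidate recovers it
      a2 <- max(1L, off + 1L - margin)
      b2 <- min(nchar(sequence), off + nchar(cur_seq) + margin)
      if (a2 != off + 1L || b2 != off + nchar(cur_seq)) {
        res2 <- measure(substr(sequence, a2, b2),
                        as.integer(mature_span) - a2 + 1L)
        if (better(res2, res)) res <- res2
      }
      return(res)
    }
    units <- lapply(inner, grow_unit, pt = pt)
    overlap <- vapply(units, function(u)
      max(0, min(u[2], cur_span[2]) - max(u[1], cur_span[1]) + 1), 0)
    if (max(overlap) <= 0) return(reject)
    u <- units[[which.max(overlap)]]
    a <- max(1L, min(u[1], cur_span[1]))
    b <- min(nchar(cur_seq), max(u[2], cur_span[2]))
    if (a == 1L && b == nchar(cur_seq)) return(reject)   # no progress
    cur_seq <- substr(cur_seq, a, b)
    cur_span <- cur_span - a + 1L
    off <- off + a - 1L
  }
  reject
}

#' Discover novel miRNAs among residual tags
#'
#' For every residual tag with at least one exact genome locus, the three
#' tag-anchored windows (per locus) are folded and scored; the best window
#' (most criteria passed, then larger stem, then 5'-most) represents the
#' candidate. A tag is called novel iff all eight criteria pass; novel ids
#' `miR_1`, `miR_2`, ... are assigned in order of first genome coordinate.
#'
#' @param residual_tags character vector of unassigned tag sequences.
#' @param genome named chromosome vector.
#' @param flank window flank in nt.
#' @param thresholds criteria thresholds, see [novel_criteria_thresholds()].
#' @return data.frame with one row per candidate tag: locus, window, the
#'   structural descriptors, per-criterion `pass_*` flags, `n_criteria`,
#'   `novel` and the assigned `mirna_id` (NA unless novel).
#' @export
discover <- function(residual_tags, genome, flank = 80L,
                     thresholds = novel_criteria_thresholds()) {
  rows <- list()
  for (tag in residual_tags) {
    loci <- find_genome_loci(tag, genome)
    if (nrow(loci) == 0) next
    loci <- loci[order(loci$chrom, loci$start, loci$strand), , drop = FALSE]
    best <- NULL
    for (k in seq_len(nrow(loci))) {
      wins <- extract_windows(genome, loci[k, ], flank)
      for (w in seq_len(nrow(wins))) {
        span <- c(wins$mature_start[w], wins$mature_end[w])
        ev <- evaluate_window(wins$sequence[w], span, thresholds)
        cand <- list(locus = loci[k, ], win = wins[w, ], ev = ev)
        if (is.null(best)) { best <- cand; next }
        b <- best$ev
        better <- sum(ev$flags) > sum(b$flags) ||
          (sum(ev$flags) == sum(b$flags) &&
           (ev$features$stem_bp > b$features$stem_bp ||
            (ev$features$stem_bp == b$features$stem_bp &&
             cand$win$win_start < best$win$win_start)))
        if (better) best <- cand
      }
    }
    fe <- best$ev$features
    fl <- best$ev$flags
    rows[[length(rows) + 1L]] <- data.frame(
      tag = tag, chrom = best$locus$chrom, start = best$locus$start,
      end = best$locus$end, strand = best$locus$strand,
      win_start = best$win$win_start, win_end = best$win$win_end,
      stem_bp = fe$stem_bp, mfe = fe$mfe, hairpin_len = fe$hairpin_len,
      loop_len = fe$loop_len, biased_bulges = fe$biased_bulges_mature,
      mature_bp = fe$mature_bp, star_bp = fe$star_bp, pm = fe$pm,
      gc_percent = fe$gc_percent, amfe = fe$amfe, mfei = fe$mfei,
      pass_stem_bp = fl[["stem_bp"]], pass_mfe = fl[["mfe"]],
      pass_hairpin_len = fl[["hairpin_len"]],
      pass_loop_len = fl[["loop_len"]],
      pass_biased_bulges = fl[["biased_bulges"]],
      pass_mature_bp = fl[["mature_bp"]], pass_pm = fl[["pm"]],
      pass_mfei = fl[["mfei"]], n_criteria = sum(fl),
      novel = all(fl), mirna_id = NA_character_,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(tag = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), novel = logical(0),
                      mirna_id = character(0), stringsAsFactors = FALSE))
  calls <- do.call(rbind, rows)
  idx <- which(calls$novel)
  idx <- idx[order(calls$chrom[idx], calls$start[idx])]
  calls$mirna_id[idx] <- sprintf("miR_%d", seq_along(idx))
  calls
}
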