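# miRNA target prediction by complementarity scoring and degradome
# validation. The expectation score E sums penalties over miRNA positions
# read against the reverse complement of the transcript window: mismatch 1,
# G:U wobble 0.5, gap 2, doubled in the seed (miRNA positions 2-13); a
# perfect complement scores 0. Cleavage is predicted opposite miRNA
# position 10. Degradome support is ranked into the five T-plot categories
# and tested with a dinucleotide-preserving shuffle p-value.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# per-window expectation scores of a miRNA along a transcript (ungapped);
# returns numeric vector over window starts 1 .. (T - L + 1)
window_expectations <- function(mirna, transcript) {
  L <- nchar(mirna)
  Tn <- nchar(transcript)
  if (Tn < L) return(numeric(0))
  mch <- seq_chars(mirna)
  tch <- seq_chars(transcript)
  W <- Tn - L + 1L
  E <- numeric(W)
  for (k in seq_len(L)) {
    # miRNA position k pairs transcript position s + L - k
    ch <- tch[(seq_len(W)) + L - k]
    m <- mch[k]
    pen <- ifelse(ch == COMPLEMENT[[m]], 0,
                  ifelse((m == "G" & ch == "T") | (m == "T" & ch == "G"),
                         0.5, 1))
    if (k >= 2 && k <= 13) pen <- pen * 2
    E <- E + pen
  }
  E
}

pair_string_at <- function(mirna, transcript, site_start) {
  L <- nchar(mirna)
  mch <- seq_chars(mirna)
  tch <- seq_chars(transcript)
  vapply(seq_len(L), function(k) {
    ch <- tch[site_start + L - k]
    m <- mch[k]
    if (ch == COMPLEMENT[[m]]) "match"
    else if ((m == "G" && ch == "T") || (m == "T" && ch == "G")) "GU"
    else "mismatch"
  }, "")
}

#' Recompute the expectation score from a pair string
#'
#' @param pair_string character vector over miRNA positions with values
#'   `"match"`, `"GU"`, `"mismatch"`, `"gap"`.
#' @return the expectation score E.
#' @export
expectation_from_pairs <- function(pair_string) {
  pen <- c(match = 0, GU = 0.5, mismatch = 1, gap = 2)[pair_string]
  seed <- seq_along(pair_string) >= 2 & seq_along(pair_string) <= 13
  sum(pen * ifelse(seed, 2, 1))
}

#' Score the best target site of a miRNA on a transcript
#'
#' @param mirna miRNA sequence (15-32 nt, ACGT).
#' @param transcript transcript sequence.
#' @param cutoff maximum expectation score E for a reported site (default 2).
#' @return `NULL` when no window scores within the cutoff, else a list with
#'   `site_start`, `site_end`, `expectation`, `pair_string`,
#'   `cleavage_position`, `usable`.
#' @export
score_site <- function(mirna, transcript, cutoff = 2) {
  mirna <- canonical_dna(mirna)
  transcript <- canonical_dna(transcript)
  E <- window_expectations(mirna, transcript)
  if (length(E) == 0) return(NULL)
  best <- which.min(E)
  if (E[best] > cutoff) return(NULL)
  L <- nchar(mirna)
  ps <- pair_string_at(mirna, transcript, best)
  al <- list(site_start = best, site_end = best + L - 1L,
             expectation = E[best], pair_string = ps)
  al$cleavage_position <- predict_cleavage(al, L)
  al$usable <- !any(ps[c(10L, 11L)] == "gap")
  al
}

#' Predicted cleavage coordinate of an alignment
#'
#' The transcript nucleotide paired to miRNA position 10 (1-based from the
#' miRNA 5' end): `site_start + L - 10`.
#'
#' @param alignment alignment list with `site_start` and `pair_string`.
#' @param mirna_length miRNA length (defaults to the pair-string length).
#' @return transcript coordinate, or `NA` when position 10 is gapped.
#' @export
predict_cleavage <- function(alignment, mirna_length = length(alignment$pair_string)) {
  if (!is.null(alignment$pair_string) &&
      length(alignment$pair_string) >= 10 &&
      alignment$pair_string[10] == "gap")
    return(NA_integer_)
  alignment$site_start + mirna_length - 10L
}

#' Degradome T-plot category of a cleavage position
#'
#' With `c` the count at the queried position, `M` the maximum count and
#' `med` the median over positions with non-zero counts: category 4 iff
#' c = 1; 0 iff c > 1 and c is the unique maximum; 1 iff c > 1 equals a
#' non-unique maximum; 2 iff 1 < c < M and c > med; 3 iff 1 < c <= med.
#' A zero count is no hit (`NA`).
#'
#' @param counts integer vector of per-position degradome 5'-end counts.
#' @param position queried transcript coordinate.
#' @return integer category 0-4, or `NA` for a zero count.
#' @export
degradome_category <- function(counts, position) {
  if (position < 1 || position > length(counts))
    stopf("position %d outside profile of length %d", position,
          length(counts))
  cc <- counts[position]
  if (cc == 0) return(NA_integer_)
  if (cc == 1) return(4L)
  nz <- counts[counts > 0]
  M <- max(nz)
  med <- stats::median(nz)
  if (cc == M) {
    if (sum(counts == M) == 1L) 0L else 1L
  } else if (cc > med) 2L else 3L
}

# Altschul-Erickson dinucleotide-preserving shuffle
dinucleotide_shuffle <- function(sequence) {
  ch <- seq_chars(sequence)
  n <- length(ch)
  if (n < 3) return(sequence)
  from <- ch[-n]; to <- ch[-1]
  verts <- unique(ch)
  last <- ch[n]
  out_edges <- split(to, factor(from, levels = verts))
  for (attempt in seq_len(1000L)) {
    # choose a random final edge for every vertex except the last symbol
    last_edge <- list()
    ok <- TRUE
    for (v in verts) {
      if (v == last) next
      outs <- out_edges[[v]]
      if (length(outs) == 0) { ok <- FALSE; break }
      last_edge[[v]] <- outs[sample.int(length(outs), 1)]
    }
    if (!ok) next
    # the chosen edges must lead every vertex to `last`
    for (v in verts) {
      if (v == last) next
      cur <- v; steps <- 0L
      while (cur != last && steps <= length(verts)) {
        cur <- last_edge[[cur]]
        if (is.null(cur)) break
        steps <- steps + 1L
      }
      if (!identical(cur, last)) { ok <- FALSE; break }
    }
    if (!ok) next
    # order remaining edges randomly, chosen last edge at the end
    ordered <- list()
    for (v in verts) {
      outs <- out_edges[[v]]
      if (v != last) {
        drop1 <- match(last_edge[[v]], outs)
        rest <- outs[-drop1]
        ordered[[v]] <- c(if (length(rest) > 0) sample(rest, length(rest)),
                          last_edge[[v]])
      } else {
        ordered[[v]] <- if (length(outs) > 0) sample(outs, length(outs))
                        else character(0)
      }
    }
    # walk the Eulerian trail from the first symbol
    ptr <- stats::setNames(rep(1L, length(verts)), verts)
    walk <- character(n)
    walk[1] <- ch[1]
    cur <- ch[1]
    good <- TRUE
    for (i in 2:n) {
      nxt <- ordered[[cur]][ptr[[cur]]]
      if (is.na(nxt) || is.null(nxt)) { good <- FALSE; break }
      ptr[[cur]] <- ptr[[cur]] + 1L
      walk[i] <- nxt
      cur <- nxt
    }
    if (good) return(paste(walk, collapse = ""))
  }
  stopf("dinucleotide shuffle failed")
}

#' Shuffle-based T-plot p-value
#'
#' Empirical p-value of the observed (expectation, category) pair:
#' `(1 + k) / (1 + n_shuffles)` where k counts dinucleotide-preserving
#' shuffles of the miRNA that achieve, anywhere on the transcript, an
#' alignment with E <= the observed E and a site of category <= the
#' observed category.
#'
#' @param counts degradome profile of the transcript.
#' @param mirna miRNA sequence.
#' @param transcript transcript sequence.
#' @param observed_e observed expectation score.
#' @param observed_category observed category (0-4).
#' @param n_shuffles number of shuffles (>= 20, default 100).
#' @param seed integer seed making the shuffle set reproducible.
#' @return empirical p-value in (0, 1].
#' @export
tplot_pvalue <- function(counts, mirna, transcript, observed_e,
                         observed_category, n_shuffles = 100L, seed = 1L) {
  if (n_shuffles < 20) stopf("n_shuffles must be >= 20")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  L <- nchar(mirna)
  hits <- 0L
  for (b in seq_len(n_shuffles)) {
    sh <- dinucleotide_shuffle(mirna)
    E <- window_expectations(sh, transcript)
    cand <- which(E <= observed_e)
    success <- FALSE
    for (s in cand) {
      pos <- s + L - 10L
      if (pos < 1 || pos > length(counts)) next
      cat_s <- degradome_category(counts, pos)
      if (!is.na(cat_s) && cat_s <= observed_category) {
        success <- TRUE
        break
      }
    }
    if (success) hits <- hits + 1L
  }
  (1 + hits) / (1 + n_shuffles)
}

#' Predict targets for a set of miRNAs over a transcriptome
#'
#' Best-scoring site per (miRNA, transcript) with expectation within the
#' cutoff.
#'
#' @param mirnas data.frame with `mirna_id`, `sequence`.
#' @param transcripts transcript data.frame (`transcript_id`, `sequence`).
#' @param cutoff maximum expectation score (default 2).
#' @return data.frame of alignments: `mirna_id`, `transcript_id`,
#'   `site_start`, `site_end`, `expectation`, `cleavage_position`, `usable`.
#' @export
predict_targets <- function(mirnas, transcripts, cutoff = 2) {
  rows <- list()
  for (i in seq_len(nrow(mirnas))) {
    for (j in seq_len(nrow(transcripts))) {
      al <- score_site(mirnas$sequence[i], transcripts$sequence[j], cutoff)
      if (is.null(al)) next
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = mirnas$mirna_id[i],
        transcript_id = transcripts$transcript_id[j],
        site_start = al$site_start, site_end = al$site_end,
        expectation = al$expectation,
        cleavage_position = al$cleavage_position,
        usable = al$usable, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      site_start = integer(0), site_end = integer(0),
                      expectation = numeric(0),
                      cleavage_position = integer(0), usable = logical(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Attach degradome category and T-plot p-value to predicted targets
#'
#' @param targets alignment data.frame from [predict_targets()].
#' @param profiles named list of degradome count vectors.
#' @param mirnas data.frame with `mirna_id`, `sequence`.
#' @param transcripts transcript data.frame.
#' @param n_shuffles shuffles for the T-plot p-value.
#' @param seed base seed; each hit uses a deterministic offset.
#' @return the alignments with `category` and `tplot_p` columns (alignments
#'   lacking a degradome profile or with zero cleavage signal get `NA`).
#' @export
degradome_hits <- function(targets, profiles, mirnas, transcripts,
                           n_shuffles = 100L, seed = 1L) {
  targets$category <- NA_integer_
  targets$tplot_p <- NA_real_
  seq_of <- stats::setNames(mirnas$sequence, mirnas$mirna_id)
  tseq_of <- stats::setNames(transcripts$sequence, transcripts$transcript_id)
  for (i in seq_len(nrow(targets))) {
    prof <- profiles[[targets$transcript_id[i]]]
    if (is.null(prof) || is.na(targets$cleavage_position[i])) next
    cat_i <- degradome_category(prof, targets$cleavage_position[i])
    targets$category[i] <- cat_i
    if (is.na(cat_i)) next
    targets$tplot_p[i] <- tplot_pvalue(
      prof, seq_of[[targets$mirna_id[i]]],
      tseq_of[[targets$transcript_id[i]]],
      targets$expectation[i], cat_i, n_shuffles, seed + i)
  }
  targets
}

#' Filter degradome hits by category, p-value and expression
#'
#' Retains hits with category 0-2, T-plot p strictly below the threshold
#' and an expressed miRNA.
#'
#' @param hits data.frame from [degradome_hits()].
#' @param expressed_ids character vector of expressed miRNA ids.
#' @param max_category highest retained category (default 2).
#' @param p_max strict p-value threshold (default 0.05).
#' @return the retained rows of `hits`.
#' @export
filter_hits <- function(hits, expressed_ids, max_category = 2L,
                        p_max = 0.05) {
  keep <- !is.na(hits$category) & hits$category <= max_category &
    !is.na(hits$tplot_p) & hits$tplot_p < p_max &
    hits$mirna_id %in% expressed_ids
  hits[keep, , drop = FALSE]
}
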