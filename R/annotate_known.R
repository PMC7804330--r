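# Assignment of tags to known miRNAs. A tag matches a reference mature under
# an ungapped comparison after end shifts of at most 2 nt, with at most two
# mismatches in total, at most one in the 5' region (mature positions 1-9),
# none in the cleavage-pairing core (positions 10-11) and at most two in the
# 3' region (positions 12 onwards). Known status additionally requires
# genome presence: the tag itself (same-species) or the matched precursor
# (cross-species) must occur exactly in the genome on either strand.

#' Match a tag against a reference mature miRNA
#'
#' Ungapped comparison over the overlap after an end shift; valid iff total
#' mismatches <= 2, mismatches in mature positions 1-9 <= 1, none at
#' positions 10-11, mismatches at positions >= 12 <= 2, and each end shift
#' is at most 2 nt. Positions are 1-based from the mature 5' end.
#'
#' @param tag tag sequence (ACGT).
#' @param mature mature reference sequence (ACGT).
#' @return `NULL` if no valid alignment, else a list with `n_mismatches`,
#'   `mismatch_positions` (1-based on the mature), `shift_5p`, `shift_3p`.
#' @export
match_mature <- function(tag, mature) {
  lt <- nchar(tag); lm <- nchar(mature)
  tchars <- seq_chars(tag); mchars <- seq_chars(mature)
  best <- NULL
  for (s5 in -2:2) {
    s3 <- s5 + lt - lm
    if (abs(s3) > 2) next
    m_from <- max(1L, 1L + s5)
    m_to <- min(lm, lt + s5)
    if (m_to < m_from) next
    m_idx <- m_from:m_to
    mm <- m_idx[mchars[m_idx] != tchars[m_idx - s5]]
    if (length(mm) > 2) next
    if (sum(mm <= 9) > 1) next
    if (any(mm %in% c(10L, 11L))) next
    if (sum(mm >= 12) > 2) next
    cand <- list(n_mismatches = length(mm), mismatch_positions = mm,
                 shift_5p = s5, shift_3p = s3)
    if (is.null(best) ||
        cand$n_mismatches < best$n_mismatches ||
        (cand$n_mismatches == best$n_mismatches &&
         (abs(s5) + abs(s3) < abs(best$shift_5p) + abs(best$shift_3p) ||
          (abs(s5) + abs(s3) == abs(best$shift_5p) + abs(best$shift_3p) &&
           s5 < best$shift_5p))))
      best <- cand
  }
  best
}

#' Find exact loci of a sequence in the genome
#'
#' @param seq query sequence.
#' @param genome named chromosome vector.
#' @return data.frame of loci (`chrom`, `start`, `end`, `strand`); zero rows
#'   when absent.
#' @export
find_genome_loci <- function(seq, genome) {
  out <- list()
  for (chrom in names(genome)) {
    subj <- Biostrings::DNAString(genome[[chrom]])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") seq else revcomp(seq)
      m <- Biostrings::matchPattern(pat, subj)
      if (length(m) > 0)
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = Biostrings::start(m),
          end = Biostrings::end(m), strand = strand,
          stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  do.call(rbind, out)
}

encode_loci <- function(loci) {
  if (nrow(loci) == 0) return("")
  paste(sprintf("%s:%s:%d-%d", loci$chrom, loci$strand, loci$start,
                loci$end), collapse = ";")
}

#' Classify tags as known miRNAs or discovery residuals
#'
#' A tag becomes known when a valid [match_mature()] alignment exists and
#' the genome-presence requirement holds: the tag occurs in the genome
#' exactly (same-species) or, failing that, the matched reference precursor
#' does (cross-species). Ties between equally good matures are broken by
#' fewest mismatches, smallest total |shift| and lexicographic mature id.
#' Known assignments are renamed with the `pvu-` prefix.
#'
#' @param tag_seqs character vector of tag sequences.
#' @param matures mature reference data.frame (`mirna_id`, `family`,
#'   `sequence`, `arm`).
#' @param precursors precursor reference data.frame with `mature_spans`.
#' @param genome named chromosome vector.
#' @return list with `assignments` (data.frame: `tag`, `assigned_id`,
#'   `matched_id`, `family`, `source`, `n_mismatches`, `genome_loci`) and
#'   `residuals` (unassigned tag sequences, for novel discovery).
#' @export
classify_tags <- function(tag_seqs, matures, precursors, genome) {
  prec_of_mature <- function(mid) {
    for (i in seq_len(nrow(precursors)))
      if (mid %in% precursors$mature_spans[[i]]$mature_id)
        return(precursors$sequence[i])
    NULL
  }
  rows <- list()
  residual <- character(0)
  for (tag in tag_seqs) {
    cands <- list()
    for (i in seq_len(nrow(matures))) {
      if (abs(nchar(tag) - nchar(matures$sequence[i])) > 4) next
      m <- match_mature(tag, matures$sequence[i])
      if (is.null(m)) next
      m$mature_id <- matures$mirna_id[i]
      m$family <- matures$family[i]
      cands[[length(cands) + 1L]] <- m
    }
    if (length(cands) > 0) {
      ord <- order(vapply(cands, `[[`, 0L, "n_mismatches"),
                   vapply(cands, function(m) abs(m$shift_5p) + abs(m$shift_3p), 0),
                   vapply(cands, `[[`, "", "mature_id"))
      cands <- cands[ord]
    }
    hit <- NULL
    for (m in cands) {
      tag_loci <- find_genome_loci(tag, genome)
      if (nrow(tag_loci) > 0) {
        hit <- c(m, list(source = "same-species", loci = tag_loci))
        break
      }
      prec <- prec_of_mature(m$mature_id)
      if (!is.null(prec)) {
        prec_loci <- find_genome_loci(prec, genome)
        if (nrow(prec_loci) > 0) {
          hit <- c(m, list(source = "cross-species", loci = prec_loci))
          break
        }
      }
    }
    if (is.null(hit)) {
      residual <- c(residual, tag)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        tag = tag,
        assigned_id = paste0("pvu-", sub("^[A-Za-z]+-", "", hit$mature_id)),
        matched_id = hit$mature_id,
        family = hit$family,
        source = hit$source,
        n_mismatches = hit$n_mismatches,
        genome_loci = encode_loci(hit$loci),
        stringsAsFactors = FALSE)
    }
  }
  assignments <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(tag = character(0), assigned_id = character(0),
               matched_id = character(0), family = character(0),
               source = character(0), n_mismatches = integer(0),
               genome_loci = character(0), stringsAsFactors = FALSE)
  list(assignments = assignments, residuals = residual)
}

# best ungapped placement of a tag inside a longer sequence under the
# mismatch position rules (counted on the tag); NULL when none is valid
map_tag_in_sequence <- function(tag, sequence) {
  lt <- nchar(tag); ls <- nchar(sequence)
  if (lt > ls) return(NULL)
  tchars <- seq_chars(tag); schars <- seq_chars(sequence)
  best <- NULL
  for (o in 1:(ls - lt + 1L)) {
    mm <- which(tchars != schars[o:(o + lt - 1L)])
    if (length(mm) > 2 || sum(mm <= 9) > 1 || any(mm %in% c(10L, 11L)))
      next
    if (is.null(best) || length(mm) < best$n_mismatches)
      best <- list(start = o, end = o + lt - 1L, n_mismatches = length(mm))
  }
  best
}

#' Star-arm candidate call for a tag on a known precursor
#'
#' A tag that maps inside a reference precursor (same mismatch rules)
#' outside every annotated mature span (overlap <= 2 nt) and within the
#' hairpin arm opposite the annotated mature is reported as a 5p- or
#' 3p-derived candidate; tags in the terminal loop are not candidates.
#'
#' @param tag tag sequence.
#' @param precursor one precursor record (row of the precursor data.frame,
#'   with `sequence` and `mature_spans`).
#' @return `NULL` or a list with `arm` (`"5p"`/`"3p"`), `start`, `end` (tag
#'   span on the precursor).
#' @export
opposite_arm_call <- function(tag, precursor) {
  spans <- precursor$mature_spans[[1]]
  if (nrow(spans) == 0) stopf("precursor has no annotated mature span")
  hit <- map_tag_in_sequence(tag, precursor$sequence)
  if (is.null(hit)) return(NULL)
  overlap <- function(a1, a2, b1, b2) max(0L, min(a2, b2) - max(a1, b1) + 1L)
  for (i in seq_len(nrow(spans)))
    if (overlap(hit$start, hit$end, spans$start[i], spans$end[i]) > 2L)
      return(NULL)
  f <- fold(precursor$sequence)
  dec <- locate_arms(f, c(spans$start[1], spans$end[1]))
  if (is.null(dec)) return(NULL)
  in_region <- function(region)
    !is.null(region) && hit$start >= region[1] && hit$end <= region[2]
  mature_arm <- if (spans$end[1] <= dec$loop[1]) "5p" else "3p"
  star_arm <- if (mature_arm == "5p") "3p" else "5p"
  target_region <- if (star_arm == "5p") dec$five_arm else dec$three_arm
  if (!in_region(target_region)) return(NULL)
  list(arm = star_arm, start = hit$start, end = hit$end)
}

#' Advisory family hint for unassigned tags
#'
#' Reports the best-matching family at a relaxed mismatch allowance,
#' ignoring the position restrictions. Advisory only: never changes a tag's
#' known/novel status and is not emitted for tags already assigned known.
#'
#' @param tag tag sequence.
#' @param matures mature reference data.frame.
#' @param relaxed_mismatches maximum mismatches for a hint (> 2).
#' @return family label or `NULL`.
#' @export
family_hint <- function(tag, matures, relaxed_mismatches = 4L) {
  if (relaxed_mismatches <= 2) stopf("relaxed_mismatches must exceed 2")
  lt <- nchar(tag)
  tchars <- seq_chars(tag)
  best_n <- relaxed_mismatches + 1L
  best_fam <- NULL
  for (i in seq_len(nrow(matures))) {
    lm <- nchar(matures$sequence[i])
    if (abs(lt - lm) > 4) next
    mchars <- seq_chars(matures$sequence[i])
    for (s5 in -2:2) {
      s3 <- s5 + lt - lm
      if (abs(s3) > 2) next
      m_from <- max(1L, 1L + s5); m_to <- min(lm, lt + s5)
      if (m_to < m_from) next
      m_idx <- m_from:m_to
      n_mm <- sum(mchars[m_idx] != tchars[m_idx - s5])
      if (n_mm < best_n) {
        best_n <- n_mm
        best_fam <- matures$family[i]
      }
    }
  }
  if (best_n <= relaxed_mismatches) best_fam else NULL
}
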