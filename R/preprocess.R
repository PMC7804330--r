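# Read preprocessing: collapse raw reads to unique tags, apply the inclusive
# 15-32 nt length window, screen contaminant classes by exact substring
# match, and normalise per library to reads per million mappable reads.

#' Collapse raw reads to unique tags and apply the length window
#'
#' Identical sequences across libraries share one tag with per-library
#' counts. Reads outside the inclusive 15-32 nt window are dropped and
#' tallied; non-ACGT reads are skipped and tallied, never fatal.
#'
#' @param reads list (one element per library, in design order) of either
#'   character vectors of read sequences or data.frames with columns
#'   `sequence` and `count`.
#' @param design library design data.frame from [library_design()].
#' @param min_len,max_len inclusive length window (15 and 32).
#' @return list with `tags` (a `tag_set`: `sequence`, raw `counts` matrix,
#'   `design`) and `stats` (per-library summary data.frame plus a
#'   `length_histogram` matrix over retained tag lengths).
#' @export
collapse_and_filter <- function(reads, design, min_len = 15L, max_len = 32L) {
  if (length(reads) != nrow(design))
    stopf("got %d read sets for %d libraries", length(reads), nrow(design))
  per_lib <- lapply(seq_along(reads), function(li) {
    r <- reads[[li]]
    if (is.character(r)) {
      if (length(r) == 0)
        r <- data.frame(sequence = character(0), count = integer(0))
      else {
        tab <- table(r)
        r <- data.frame(sequence = names(tab), count = as.integer(tab),
                        stringsAsFactors = FALSE)
      }
    }
    r$sequence <- canonical_dna(r$sequence)
    r$library_id <- rep(design$library_id[li], nrow(r))
    r
  })
  all <- data.table::rbindlist(per_lib)
  all <- all[, list(count = sum(count)), by = c("library_id", "sequence")]
  all$len <- nchar(all$sequence)
  all$valid_alpha <- is_acgt(all$sequence)
  all$in_window <- all$len >= min_len & all$len <= max_len

  lib_stat <- function(li) {
    d <- all[all$library_id == design$library_id[li], ]
    raw <- sum(d$count)
    bad_alpha <- sum(d$count[!d$valid_alpha])
    oow <- sum(d$count[d$valid_alpha & !d$in_window])
    data.frame(library_id = design$library_id[li],
               raw_reads = raw,
               dropped_non_acgt = bad_alpha,
               dropped_length = oow,
               mappable_reads = raw - bad_alpha - oow,
               stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, lapply(seq_len(nrow(design)), lib_stat))

  kept <- all[all$valid_alpha & all$in_window, ]
  tag_seqs <- sort(unique(kept$sequence))
  counts <- matrix(0L, length(tag_seqs), nrow(design),
                   dimnames = list(tag_seqs, design$library_id))
  if (nrow(kept) > 0)
    counts[cbind(match(kept$sequence, tag_seqs),
                 match(kept$library_id, design$library_id))] <-
      as.integer(kept$count)

  lens <- sort(unique(nchar(tag_seqs)))
  if (length(lens) == 0) lens <- integer(0)
  hist <- matrix(0L, length(lens), nrow(design),
                 dimnames = list(lens, design$library_id))
  if (length(tag_seqs) > 0) {
    tl <- nchar(tag_seqs)
    for (li in seq_len(nrow(design)))
      hist[, li] <- as.integer(tapply(counts[, li],
                                      factor(tl, levels = lens), sum,
                                      default = 0L))
  }
  tags <- structure(list(sequence = tag_seqs, counts = counts,
                         design = design), class = "tag_set")
  list(tags = tags,
       stats = list(summary = summary, length_histogram = hist))
}

#' Remove contaminant tags by blocklist screening
#'
#' A tag is removed when it occurs as an exact substring of any blocklist
#' sequence on either strand. Classes are screened in the fixed order
#' ncRNA, repeats, mRNA; a tag matching several classes is attributed to the
#' first.
#'
#' @param tags a `tag_set`.
#' @param blocklists named list of character vectors of blocklist sequences;
#'   recognised names are `ncRNA`, `repeats`, `mRNA` (any may be missing or
#'   empty).
#' @return list with the filtered `tags` and a `report` data.frame of
#'   removals per class (tags and reads).
#' @export
remove_contaminants <- function(tags, blocklists = list()) {
  classes <- c("ncRNA", "repeats", "mRNA")
  assigned <- rep(NA_character_, length(tags$sequence))
  for (cls in classes) {
    refs <- canonical_dna(blocklists[[cls]] %||% character(0))
    if (length(refs) == 0) next
    haystack <- paste(c(refs, revcomp(refs)), collapse = "#")
    todo <- which(is.na(assigned))
    if (length(todo) == 0) break
    hit <- vapply(tags$sequence[todo],
                  function(s) grepl(s, haystack, fixed = TRUE), logical(1))
    assigned[todo[hit]] <- cls
  }
  report <- data.frame(
    class = classes,
    tags_removed = vapply(classes, function(cl)
      sum(assigned == cl, na.rm = TRUE), 0L),
    reads_removed = vapply(classes, function(cl) {
      idx <- which(assigned == cl)
      if (length(idx) == 0) 0 else sum(tags$counts[idx, , drop = FALSE])
    }, 0),
    row.names = NULL, stringsAsFactors = FALSE)
  keep <- is.na(assigned)
  tags$sequence <- tags$sequence[keep]
  tags$counts <- tags$counts[keep, , drop = FALSE]
  if (!is.null(tags$norm)) tags$norm <- tags$norm[keep, , drop = FALSE]
  list(tags = tags, report = report)
}

#' Normalise tag counts to reads per million mappable reads
#'
#' @param tags a `tag_set` with raw counts.
#' @param stats preprocessing stats from [collapse_and_filter()] (the
#'   per-library mappable totals are taken from `stats$summary`).
#' @return the `tag_set` with a `norm` matrix added (RPM).
#' @export
normalize_rpm <- function(tags, stats) {
  summary <- stats$summary
  if (!identical(summary$library_id, tags$design$library_id))
    stopf("stats libraries do not match the tag set design")
  if (any(summary$mappable_reads <= 0))
    stopf("zero mappable reads in library %s",
          summary$library_id[summary$mappable_reads <= 0][1])
  tags$norm <- sweep(tags$counts, 2, summary$mappable_reads, "/") * 1e6
  tags
}

#' Length distribution of mappable reads
#'
#' Per-library and pooled percentage of mappable reads at each tag length.
#'
#' @param stats preprocessing stats from [collapse_and_filter()].
#' @return data.frame with columns `library_id` (including `"pooled"`),
#'   `length`, `reads`, `percent`; percentages sum to 100 per library.
#' @export
length_distribution <- function(stats) {
  hist <- stats$length_histogram
  if (nrow(hist) == 0)
    return(data.frame(library_id = character(0), length = integer(0),
                      reads = integer(0), percent = numeric(0)))
  libs <- colnames(hist)
  out <- lapply(libs, function(li) {
    tot <- sum(hist[, li])
    data.frame(library_id = li, length = as.integer(rownames(hist)),
               reads = hist[, li],
               percent = if (tot > 0) 100 * hist[, li] / tot else 0,
               stringsAsFactors = FALSE)
  })
  pooled <- rowSums(hist)
  out <- c(out, list(data.frame(
    library_id = "pooled", length = as.integer(rownames(hist)),
    reads = pooled, percent = 100 * pooled / sum(pooled),
    stringsAsFactors = FALSE)))
  d <- do.call(rbind, out)
  rownames(d) <- NULL
  d
}
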