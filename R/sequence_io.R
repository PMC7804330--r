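# Readers and writers for every external format the pipeline touches:
# FASTA (genome, mature and precursor reference, transcripts), TSV tag-count
# tables, TSV degradome profiles, TSV functional-annotation tables and GFF3
# locus emission. Coordinates are 1-based inclusive both internally and on
# disk.

#' Experimental design of a timepoint series of small-RNA libraries
#'
#' Builds the library table for a timepoint x replicate design. Libraries are
#' ordered by (timepoint, replicate); this order fixes the column order of
#' every count matrix in the pipeline.
#'
#' @param timepoints integer vector of timepoints in days after anthesis.
#' @param n_replicates number of biological replicates per timepoint.
#' @return data.frame with columns `library_id`, `timepoint_daa`, `replicate`.
#' @examples
#' library_design()  # the 4 x 3 developing-seed design
#' @export
library_design <- function(timepoints = c(10L, 20L, 30L, 40L),
                           n_replicates = 3L) {
  timepoints <- sort(unique(as.integer(timepoints)))
  d <- expand.grid(replicate = seq_len(n_replicates),
                   timepoint_daa = timepoints)
  d <- d[order(d$timepoint_daa, d$replicate), c("timepoint_daa", "replicate")]
  d$library_id <- sprintf("T%02d_R%d", d$timepoint_daa, d$replicate)
  rownames(d) <- NULL
  d[, c("library_id", "timepoint_daa", "replicate")]
}

#' Read a FASTA file into pipeline records
#'
#' @param path path to a FASTA file.
#' @param kind one of `"genome"`, `"mature"`, `"precursor"`, `"transcript"`.
#'   Metadata (family, arm, gene, mature spans) is carried in
#'   whitespace-separated `key=value` tokens on the header line.
#' @return for `kind = "genome"`, a named character vector of chromosome
#'   sequences; otherwise a data.frame of records in input order. Sequences
#'   are uppercased and U is normalised to T.
#' @export
read_fasta <- function(path, kind = c("genome", "mature", "precursor",
                                      "transcript")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stopf("malformed FASTA '%s': %s",
                                            path, conditionMessage(e)))
  if (length(set) == 0) stopf("empty FASTA input: %s", path)
  headers <- names(set)
  seqs <- unname(canonical_dna(as.character(set)))
  ids <- unname(sub("\\s.*$", "", headers))
  meta <- lapply(headers, parse_header_meta)
  bad <- which(!is_acgt(seqs))
  if (kind == "genome" && length(bad) > 0)
    stopf("genome record(s) contain non-ACGT characters (N is rejected): %s",
          paste(ids[bad], collapse = ", "))
  if (any(!nzchar(seqs)))
    stopf("empty sequence for record(s): %s",
          paste(ids[!nzchar(seqs)], collapse = ", "))

  switch(kind,
    genome = stats::setNames(seqs, ids),
    mature = {
      len <- nchar(seqs)
      if (any(len < 15 | len > 30))
        stopf("mature record(s) outside 15-30 nt: %s",
              paste(ids[len < 15 | len > 30], collapse = ", "))
      if (anyDuplicated(ids))
        stopf("duplicated mature ids: %s",
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
      data.frame(mirna_id = ids,
                 family = vapply(meta, function(m) m[["family"]] %||% NA_character_, ""),
                 sequence = seqs,
                 arm = vapply(meta, function(m) m[["arm"]] %||% "unknown", ""),
                 stringsAsFactors = FALSE)
    },
    precursor = {
      len <- nchar(seqs)
      if (any(len < 50 | len > 300))
        stopf("precursor record(s) outside 50-300 nt: %s",
              paste(ids[len < 50 | len > 300], collapse = ", "))
      spans <- lapply(seq_along(ids), function(i) {
        s <- parse_spans(meta[[i]][["spans"]] %||% "")
        if (nrow(s) > 0 && (any(s$start < 1) || any(s$end > len[i])))
          stopf("mature span outside precursor '%s'", ids[i])
        if (nrow(s) > 1) {
          o <- order(s$start)
          if (any(s$start[o][-1] <= s$end[o][-nrow(s)]))
            stopf("overlapping mature spans in precursor '%s'", ids[i])
        }
        s
      })
      d <- data.frame(precursor_id = ids, sequence = seqs,
                      stringsAsFactors = FALSE)
      d$mature_spans <- spans
      d
    },
    transcript = data.frame(
      transcript_id = ids,
      gene_id = vapply(meta, function(m) m[["gene"]] %||% NA_character_, ""),
      sequence = seqs,
      annotation = vapply(meta, function(m) m[["desc"]] %||% "", ""),
      stringsAsFactors = FALSE)
  )
}

parse_header_meta <- function(header) {
  toks <- strsplit(header, "\\s+")[[1]][-1]
  toks <- toks[grepl("=", toks, fixed = TRUE)]
  if (length(toks) == 0) return(list())
  kv <- strsplit(toks, "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(p) gsub("_", " ", p[2], fixed = TRUE)),
                  vapply(kv, `[`, "", 1))
}

parse_spans <- function(x) {
  empty <- data.frame(mature_id = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  if (!nzchar(x)) return(empty)
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^(.+):(\\d+)-(\\d+)$", parts))
  if (any(lengths(m) != 4)) stopf("cannot parse mature span '%s'", x)
  data.frame(mature_id = vapply(m, `[`, "", 2),
             start = as.integer(vapply(m, `[`, "", 3)),
             end = as.integer(vapply(m, `[`, "", 4)),
             stringsAsFactors = FALSE)
}

#' Write records to FASTA
#'
#' @param x a named character vector (genome) or a record data.frame as
#'   returned by [read_fasta()].
#' @param path output path.
#' @param rna write the sequence with U instead of T.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, rna = FALSE) {
  if (is.character(x)) {
    ids <- names(x); seqs <- unname(x); meta <- rep("", length(x))
  } else if (!is.null(x$mirna_id)) {
    ids <- x$mirna_id; seqs <- x$sequence
    meta <- sprintf(" family=%s arm=%s", x$family, x$arm)
    meta[is.na(x$family)] <- sprintf(" arm=%s", x$arm[is.na(x$family)])
  } else if (!is.null(x$precursor_id)) {
    ids <- x$precursor_id; seqs <- x$sequence
    meta <- vapply(x$mature_spans, function(s) {
      if (nrow(s) == 0) return("")
      sprintf(" spans=%s",
              paste(sprintf("%s:%d-%d", s$mature_id, s$start, s$end),
                    collapse = ","))
    }, "")
  } else if (!is.null(x$transcript_id)) {
    ids <- x$transcript_id; seqs <- x$sequence
    meta <- sprintf(" gene=%s", x$gene_id)
  } else stopf("unsupported record type for FASTA output")
  if (rna) seqs <- gsub("T", "U", seqs, fixed = TRUE)
  writeLines(paste0(">", ids, meta, "\n", seqs), path)
  invisible(path)
}

#' Read per-transcript degradome 5'-end profiles
#'
#' Reads a TSV with columns `transcript_id`, `position` (1-based) and
#' `count`. Positions absent from the file get count 0; duplicate
#' (transcript, position) rows are summed. Transcript lengths are taken from
#' the companion transcript table.
#'
#' @param path TSV path.
#' @param transcripts transcript data.frame from [read_fasta()].
#' @return named list of integer count vectors, one per transcript present
#'   in the file, each of length `nchar(transcript sequence)`.
#' @export
read_degradome_profiles <- function(path, transcripts) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "position", "count")
  if (!all(need %in% names(d)))
    stopf("degradome TSV must have columns %s", paste(need, collapse = ", "))
  if (nrow(d) == 0) return(stats::setNames(list(), character(0)))
  lens <- stats::setNames(nchar(transcripts$sequence),
                          transcripts$transcript_id)
  unknown <- setdiff(unique(d$transcript_id), names(lens))
  if (length(unknown) > 0)
    stopf("degradome transcript(s) missing from FASTA: %s",
          paste(unknown, collapse = ", "))
  out <- list()
  for (tid in unique(d$transcript_id)) {
    rows <- d[d$transcript_id == tid, ]
    L <- lens[[tid]]
    if (any(rows$position < 1 | rows$position > L))
      stopf("degradome position out of bounds for '%s' (length %d): %d",
            tid, L, rows$position[rows$position < 1 | rows$position > L][1])
    v <- integer(L)
    agg <- tapply(rows$count, rows$position, sum)
    v[as.integer(names(agg))] <- as.integer(agg)
    out[[tid]] <- v
  }
  out
}

#' Write degradome profiles to TSV
#'
#' Inverse of [read_degradome_profiles()]: zero positions are omitted.
#'
#' @param profiles named list of integer vectors.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_degradome_profiles <- function(profiles, path) {
  rows <- lapply(names(profiles), function(tid) {
    v <- profiles[[tid]]
    nz <- which(v > 0)
    if (length(nz) == 0) return(NULL)
    data.frame(transcript_id = tid, position = nz, count = v[nz],
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  if (is.null(d))
    d <- data.frame(transcript_id = character(0), position = integer(0),
                    count = integer(0))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a tag-count table
#'
#' One row per unique small-RNA tag, one count column per library in design
#' order (timepoint, then replicate).
#'
#' @param tags a tag set as returned by [collapse_and_filter()].
#' @param path output TSV path.
#' @param flavor which counts to write, `"raw"` or `"normalized"`.
#' @return `path`, invisibly.
#' @export
write_tag_table <- function(tags, path, flavor = c("raw", "normalized")) {
  flavor <- match.arg(flavor)
  counts <- if (flavor == "raw") tags$counts else tags$norm
  if (is.null(counts)) stopf("tag set has no %s counts", flavor)
  if (ncol(counts) != nrow(tags$design))
    stopf("count columns (%d) do not match design libraries (%d)",
          ncol(counts), nrow(tags$design))
  d <- data.frame(sequence = tags$sequence, counts, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tag-count table written by [write_tag_table()]
#'
#' @param path TSV path.
#' @param design library design data.frame; column order is validated.
#' @param flavor `"raw"` or `"normalized"`.
#' @return a tag set (see [collapse_and_filter()]).
#' @export
read_tag_table <- function(path, design, flavor = c("raw", "normalized")) {
  flavor <- match.arg(flavor)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!identical(names(d)[1], "sequence"))
    stopf("tag table must start with a 'sequence' column")
  if (!identical(names(d)[-1], design$library_id))
    stopf("tag table columns do not match the library design")
  counts <- as.matrix(d[, -1, drop = FALSE])
  rownames(counts) <- d$sequence
  out <- list(sequence = d$sequence, design = design)
  if (flavor == "raw") {
    storage.mode(counts) <- "integer"
    out$counts <- counts
  } else out$norm <- counts
  structure(out, class = "tag_set")
}

#' Read a gene-to-functional-bin annotation table
#'
#' TSV with columns `gene_id` and `mapman_bin`; a gene may carry several
#' bins, duplicated (gene, bin) pairs are dropped.
#'
#' @param path TSV path.
#' @return data.frame with columns `gene_id`, `mapman_bin`.
#' @export
read_annotation <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "mapman_bin") %in% names(d)))
    stopf("annotation TSV must have columns gene_id, mapman_bin")
  unique(d[, c("gene_id", "mapman_bin")])
}

#' Write miRNA loci as GFF3
#'
#' @param loci data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `id` and optionally `type` (default `"miRNA_primary_transcript"`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loci_gff3 <- function(loci, path) {
  if (nrow(loci) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start, end = loci$end),
    strand = loci$strand)
  gr$type <- loci$type %||% "miRNA_primary_transcript"
  gr$ID <- loci$id
  gr$source <- "seedmir"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @export
print.tag_set <- function(x, ...) {
  cat(sprintf("small-RNA tag set: %d tags x %d libraries (%s counts)\n",
              length(x$sequence), nrow(x$design),
              paste(c("raw", "normalized")[c(!is.null(x$counts),
                                             !is.null(x$norm))],
                    collapse = " + ")))
  invisible(x)
}
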