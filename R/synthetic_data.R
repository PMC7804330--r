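# Synthetic small-RNA dataset with planted ground truth: a toy genome with
# planted pre-miRNA hairpins, a miRBase-like reference, timepoint-structured
# libraries with negative-binomial counts, transcripts carrying complementary
# target sites and degradome profiles with cleavage spikes. Every output is a
# pure function of the configuration (seed included): each generator stage
# draws from its own seed derived from `config$seed`.

# Six abundance archetypes over the 10/20/30/40-day timepoints, in reads per
# million. A: high at 10 and 40; B: high at 10, declining; C: lowest at 40;
# D: peak at 30; E: high at 10 and 30; F: high at 30/40.
archetype_templates <- function() {
  m <- rbind(A = c(2000,  200,  200, 2000),
             B = c(3000,  800,  250,  150),
             C = c( 900, 1000, 1100,   40),
             D = c( 200,  200, 2500,  200),
             E = c(2000,  100, 1500,  100),
             F = c( 100,  200, 1500, 2600))
  colnames(m) <- c("10", "20", "30", "40")
  m
}

# Background length mixture over the 15-32 nt window; 24-nt reads dominate at
# 29.9% with a secondary 21-nt mode at 13.5%, mimicking a plant seed sRNA
# length profile.
default_length_weights <- function() {
  w <- c(`15` = 0.010, `16` = 0.012, `17` = 0.015, `18` = 0.020,
         `19` = 0.030, `20` = 0.060, `21` = 0.135, `22` = 0.080,
         `23` = 0.090, `24` = 0.299, `25` = 0.060, `26` = 0.045,
         `27` = 0.035, `28` = 0.030, `29` = 0.025, `30` = 0.022,
         `31` = 0.017, `32` = 0.015)
  stopifnot(abs(sum(w) - 1) < 1e-12)
  w
}

#' Configuration of the synthetic developing-seed dataset
#'
#' @param seed integer seed; all generator stages derive their randomness
#'   from it.
#' @param genome_length toy genome length in nt (>= 1000).
#' @param n_planted_hairpins number of pre-miRNA hairpins planted into the
#'   genome.
#' @param n_known_fraction fraction of planted matures copied into the
#'   miRBase-like reference (those must be recovered as known; the rest as
#'   novel).
#' @param loop_length terminal-loop length of planted hairpins (nt, >= 10).
#'   The loop is drawn from A/C only so it cannot self-pair.
#' @param bulges_per_hairpin single-nucleotide insertions placed in the star
#'   arm of each planted hairpin (<= 2 keeps all eight structural criteria
#'   satisfied).
#' @param ext_stem extra complementary stem nucleotides flanking the
#'   mature/star duplex on each side; lifts the stem above the 22-bp
#'   criterion for 20-22 nt matures.
#' @param n_timepoints,n_replicates experimental design (4 x 3 by default).
#' @param depth_per_library background sequencing depth per library (reads).
#' @param nb_dispersion negative-binomial dispersion of miRNA counts
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param archetype_assignment function or character vector mapping planted
#'   miRNA index to archetype labels A-F; default cycles A..F.
#' @param background_length_weights named probability vector over read
#'   lengths 15-32.
#' @param n_decoy_tags abundantly expressed background tags planted at
#'   non-hairpin loci (must not be called novel).
#' @param n_decoy_refs reference mature entries absent from the genome (must
#'   not be called known).
#' @param decoy_tag_rpm constant abundance of decoy tags, reads per million.
#' @param transcript_length length of each synthetic target transcript.
#' @param site_mispairs mismatches planted in each target site (0-2), at
#'   miRNA positions 14 and beyond so the expectation score stays within the
#'   reporting cutoff.
#' @param degradome_spike degradome count at the true cleavage position
#'   (>= 5 guarantees a category-0 peak over the 0/1 background).
#' @param n_decoy_transcripts transcripts without any planted target site.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 60000L,
                       n_planted_hairpins = 10L,
                       n_known_fraction = 0.5,
                       loop_length = 15L,
                       bulges_per_hairpin = 2L,
                       ext_stem = 6L,
                       n_timepoints = 4L,
                       n_replicates = 3L,
                       depth_per_library = 1e5,
                       nb_dispersion = 0.1,
                       archetype_assignment = NULL,
                       background_length_weights = default_length_weights(),
                       n_decoy_tags = 10L,
                       n_decoy_refs = 5L,
                       decoy_tag_rpm = 500,
                       transcript_length = 1000L,
                       site_mispairs = 1L,
                       degradome_spike = 10L,
                       n_decoy_transcripts = 5L) {
  stopifnot(genome_length >= 1000, depth_per_library > 0,
            n_known_fraction >= 0, n_known_fraction <= 1,
            loop_length >= 10, nb_dispersion >= 0,
            site_mispairs >= 0, site_mispairs <= 2,
            n_timepoints == 4)
  w <- background_length_weights
  if (abs(sum(w) - 1) > 1e-8) stopf("length weights must sum to 1")
  if (is.null(archetype_assignment))
    archetype_assignment <- rep(rownames(archetype_templates()),
                                length.out = n_planted_hairpins)
  if (!all(archetype_assignment %in% rownames(archetype_templates())))
    stopf("unknown archetype label(s): %s",
          paste(setdiff(archetype_assignment,
                        rownames(archetype_templates())), collapse = ", "))
  structure(list(
    seed = as.integer(seed), genome_length = as.integer(genome_length),
    n_planted_hairpins = as.integer(n_planted_hairpins),
    n_known_fraction = n_known_fraction,
    loop_length = as.integer(loop_length),
    bulges_per_hairpin = as.integer(bulges_per_hairpin),
    ext_stem = as.integer(ext_stem),
    n_timepoints = as.integer(n_timepoints),
    n_replicates = as.integer(n_replicates),
    depth_per_library = depth_per_library,
    nb_dispersion = nb_dispersion,
    archetype_assignment = archetype_assignment,
    background_length_weights = w,
    n_decoy_tags = as.integer(n_decoy_tags),
    n_decoy_refs = as.integer(n_decoy_refs),
    decoy_tag_rpm = decoy_tag_rpm,
    transcript_length = as.integer(transcript_length),
    site_mispairs = as.integer(site_mispairs),
    degradome_spike = as.integer(degradome_spike),
    n_decoy_transcripts = as.integer(n_decoy_transcripts)
  ), class = "sim_config")
}

with_stage_seed <- function(config, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(config$seed * 13L + offset)
  force(expr)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate the toy genome
#'
#' @param config a [sim_config()].
#' @return named character vector with one chromosome (`chr1`), uniform base
#'   composition, deterministic for a fixed seed.
#' @export
generate_genome <- function(config) {
  with_stage_seed(config, 1L,
                  stats::setNames(random_dna(config$genome_length), "chr1"))
}

# build one hairpin precursor; returns list(precursor, mature, mature_offset)
build_hairpin <- function(mature, config) {
  ext <- random_dna(config$ext_stem)
  loop <- paste(sample(c("A", "C"), config$loop_length, replace = TRUE),
                collapse = "")
  star <- seq_chars(revcomp(mature))
  if (config$bulges_per_hairpin > 0) {
    ins <- sort(sample(3:(length(star) - 3), config$bulges_per_hairpin))
    for (k in rev(seq_along(ins)))
      star <- append(star, "C", after = ins[k])
  }
  precursor <- paste0(ext, mature, loop, paste(star, collapse = ""),
                      revcomp(ext))
  list(precursor = precursor, mature = mature,
       mature_start = config$ext_stem + 1L,
       mature_end = config$ext_stem + nchar(mature))
}

#' Plant pre-miRNA hairpins into the genome
#'
#' Each precursor is an extended stem + mature + A/C terminal loop + star arm
#' (reverse complement of the mature with `bulges_per_hairpin` single-C
#' insertions) + closing stem. The generator asserts that every planted
#' precursor passes all eight structural criteria under the bundled folding
#' model, regenerating a hairpin if a random draw fails.
#'
#' @param genome named chromosome vector from [generate_genome()].
#' @param config a [sim_config()].
#' @return list with the modified `genome` and a `truth` data.frame (one row
#'   per planted miRNA: id, mature sequence, archetype, precursor and mature
#'   loci) plus a `decoys` data.frame of planted high-abundance background
#'   tags.
#' @export
plant_hairpins <- function(genome, config) {
  with_stage_seed(config, 2L, {
    chrom <- names(genome)[1]
    gseq <- genome[[1]]
    glen <- nchar(gseq)
    n <- config$n_planted_hairpins
    pad <- 200L
    occupied <- matrix(numeric(0), ncol = 2)
    rows <- vector("list", n)
    matures <- character(0)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(200L)) {
        mlen <- sample(20:22, 1)
        mature <- random_dna(mlen)
        if (mature %in% matures) next
        hp <- build_hairpin(mature, config)
        plen <- nchar(hp$precursor)
        f <- fold(hp$precursor)
        dec <- locate_arms(f, c(hp$mature_start, hp$mature_end))
        if (is.null(dec)) next
        feats <- compute_features(f, dec, c(hp$mature_start, hp$mature_end))
        if (!all(apply_criteria(feats))) next
        start <- sample.int(glen - plen - 2L * pad, 1) + pad
        end <- start + plen - 1L
        if (nrow(occupied) > 0 &&
            any(start - pad <= occupied[, 2] & end + pad >= occupied[, 1]))
          next
        strand <- sample(c("+", "-"), 1)
        insert <- if (strand == "+") hp$precursor else revcomp(hp$precursor)
        substr(gseq, start, end) <- insert
        occupied <- rbind(occupied, c(start, end))
        m_start <- if (strand == "+") start + hp$mature_start - 1L
                   else end - hp$mature_end + 1L
        m_end <- m_start + mlen - 1L
        matures <- c(matures, mature)
        rows[[i]] <- data.frame(
          mirna_id = sprintf("simR_%02d", i),
          mature_sequence = mature,
          precursor_sequence = hp$precursor,
          chrom = chrom, start = start, end = end, strand = strand,
          mature_start = m_start, mature_end = m_end,
          mature_offset = hp$mature_start,
          archetype = config$archetype_assignment[i],
          is_known = NA, stringsAsFactors = FALSE)
        ok <- TRUE
        break
      }
      if (!ok) stopf("could not place hairpin %d without overlap", i)
    }
    truth <- do.call(rbind, rows)
    genome[[1]] <- gseq

    # high-abundance decoy tags at non-hairpin loci
    decoys <- NULL
    if (config$n_decoy_tags > 0) {
      drows <- vector("list", config$n_decoy_tags)
      for (i in seq_len(config$n_decoy_tags)) {
        for (try in seq_len(200L)) {
          start <- sample.int(glen - 21L - 2L * pad, 1) + pad
          end <- start + 20L
          if (any(start - 30 <= occupied[, 2] & end + 30 >= occupied[, 1]))
            next
          s <- substr(gseq, start, end)
          if (!is_acgt(s) || s %in% matures) next
          drows[[i]] <- data.frame(
            decoy_id = sprintf("decoy_%02d", i), sequence = s,
            chrom = chrom, start = start, end = end, strand = "+",
            stringsAsFactors = FALSE)
          occupied <- rbind(occupied, c(start, end))
          break
        }
        if (is.null(drows[[i]])) stopf("could not place decoy tag %d", i)
      }
      decoys <- do.call(rbind, drows)
    }
    list(genome = genome, truth = truth, decoys = decoys)
  })
}

#' Build the miRBase-like reference from planted truth
#'
#' `round(n_known_fraction * n)` planted matures (seeded draw) are copied
#' into the reference and flagged `is_known`; the remainder must be
#' rediscovered as novel. Decoy mature entries absent from the genome are
#' appended.
#'
#' @param truth truth data.frame from [plant_hairpins()] (modified copy is
#'   returned).
#' @param genome the planted genome (used to verify decoy absence).
#' @param config a [sim_config()].
#' @return list with `matures`, `precursors` record data.frames and the
#'   updated `truth`.
#' @export
build_reference <- function(truth, genome, config) {
  with_stage_seed(config, 3L, {
    n <- nrow(truth)
    n_known <- round(config$n_known_fraction * n)
    known_idx <- if (n_known > 0) sort(sample.int(n, n_known)) else integer(0)
    truth$is_known <- seq_len(n) %in% known_idx

    matures <- data.frame(
      mirna_id = sub("simR", "ref-miR", truth$mirna_id[known_idx]),
      family = sub("simR_", "MIRSIM", truth$mirna_id[known_idx]),
      sequence = truth$mature_sequence[known_idx],
      arm = rep("5p", length(known_idx)), stringsAsFactors = FALSE)
    precursors <- data.frame(
      precursor_id = sub("simR", "ref-MIR", truth$mirna_id[known_idx]),
      sequence = truth$precursor_sequence[known_idx],
      stringsAsFactors = FALSE)
    precursors$mature_spans <- lapply(known_idx, function(i)
      data.frame(mature_id = sub("simR", "ref-miR", truth$mirna_id[i]),
                 start = truth$mature_offset[i],
                 end = truth$mature_offset[i] +
                   nchar(truth$mature_sequence[i]) - 1L,
                 stringsAsFactors = FALSE))
    if (nrow(precursors) == 0) precursors$mature_spans <- list()

    if (config$n_decoy_refs > 0) {
      gseq <- genome[[1]]
      grc <- revcomp(gseq)
      dec <- character(0)
      while (length(dec) < config$n_decoy_refs) {
        s <- random_dna(21L)
        if (!grepl(s, gseq, fixed = TRUE) && !grepl(s, grc, fixed = TRUE))
          dec <- c(dec, s)
      }
      matures <- rbind(matures, data.frame(
        mirna_id = sprintf("ref-decoy%02d", seq_along(dec)),
        family = "MIRDECOY", sequence = dec, arm = "5p",
        stringsAsFactors = FALSE))
    }
    list(matures = matures, precursors = precursors, truth = truth)
  })
}

#' Simulate the twelve small-RNA libraries
#'
#' miRNA and decoy-tag counts are negative binomial around archetype means
#' scaled to library depth; background reads are drawn from non-planted
#' genome positions with a 24-nt-dominant length mixture.
#'
#' @param truth truth data.frame (with decoys attribute handled separately).
#' @param decoys decoy-tag data.frame from [plant_hairpins()] (or `NULL`).
#' @param genome planted genome.
#' @param config a [sim_config()].
#' @return list with `reads` (per-library data.frames of `sequence`,
#'   `count`), `design`, `truth_counts` (planted-miRNA raw count matrix),
#'   and `background_histogram` (length x library background read counts).
#' @export
simulate_libraries <- function(truth, decoys, genome, config) {
  with_stage_seed(config, 4L, {
    design <- library_design(c(10, 20, 30, 40), config$n_replicates)
    nlib <- nrow(design)
    templ <- archetype_templates()
    depth <- config$depth_per_library
    disp <- config$nb_dispersion
    draw <- function(mu, n) {
      if (disp <= 0) stats::rpois(n, mu)
      else stats::rnbinom(n, mu = mu, size = 1 / disp)
    }
    gseq <- genome[[1]]
    glen <- nchar(gseq)

    # positions covered by planted loci (mask for background sampling)
    covered <- logical(glen)
    for (i in seq_len(nrow(truth)))
      covered[truth$start[i]:truth$end[i]] <- TRUE
    if (!is.null(decoys))
      for (i in seq_len(nrow(decoys)))
        covered[decoys$start[i]:decoys$end[i]] <- TRUE
    cum_cov <- c(0L, cumsum(covered))

    lengths_avail <- as.integer(names(config$background_length_weights))
    truth_counts <- matrix(0L, nrow(truth), nlib,
                           dimnames = list(truth$mirna_id, design$library_id))
    bg_hist <- matrix(0L, length(lengths_avail), nlib,
                      dimnames = list(lengths_avail, design$library_id))
    reads <- vector("list", nlib)
    names(reads) <- design$library_id

    for (li in seq_len(nlib)) {
      tp <- as.character(design$timepoint_daa[li])
      mu_mirna <- templ[truth$archetype, tp] / 1e6 * depth
      cnt <- draw(mu_mirna, nrow(truth))
      truth_counts[, li] <- cnt
      parts <- list(data.frame(sequence = truth$mature_sequence,
                               count = as.numeric(cnt),
                               stringsAsFactors = FALSE))
      if (!is.null(decoys)) {
        dmu <- rep(config$decoy_tag_rpm / 1e6 * depth, nrow(decoys))
        parts <- c(parts, list(data.frame(sequence = decoys$sequence,
                                          count = as.numeric(draw(dmu, nrow(decoys))),
                                          stringsAsFactors = FALSE)))
      }
      # background
      n_bg <- as.integer(depth)
      lens <- sample(lengths_avail, n_bg, replace = TRUE,
                     prob = config$background_length_weights)
      starts <- sample.int(glen - max(lens), n_bg, replace = TRUE)
      # drop reads overlapping planted loci
      ncov <- cum_cov[starts + lens] - cum_cov[starts]
      keep <- ncov == 0L
      lens <- lens[keep]; starts <- starts[keep]
      strand_neg <- sample(c(TRUE, FALSE), length(lens), replace = TRUE)
      sq <- substring(gseq, starts, starts + lens - 1L)
      if (any(strand_neg)) sq[strand_neg] <- revcomp(sq[strand_neg])
      tab <- data.table::as.data.table(table(factor(lens, levels = lengths_avail)))
      bg_hist[, li] <- tab$N
      parts <- c(parts, list(data.frame(sequence = sq, count = 1,
                                        stringsAsFactors = FALSE)))
      all <- data.table::rbindlist(parts)
      agg <- all[, list(count = sum(count)), by = "sequence"]
      agg <- agg[agg$count > 0, ]
      reads[[li]] <- data.frame(sequence = agg$sequence,
                                count = as.integer(agg$count),
                                stringsAsFactors = FALSE)
    }
    list(reads = reads, design = design, truth_counts = truth_counts,
         background_histogram = bg_hist)
  })
}

#' Simulate target transcripts and degradome profiles
#'
#' One transcript per planted miRNA carries a reverse-complement target site
#' with `site_mispairs` substitutions at miRNA positions >= 14; the degradome
#' profile has a count spike at the position opposite miRNA position 10 over
#' a 0/1 background, making the true site a category-0 peak by construction.
#'
#' @param truth truth data.frame.
#' @param config a [sim_config()].
#' @return list with `transcripts`, `profiles`, `targets` (truth),
#'   `annotation` (gene to functional bin).
#' @export
simulate_degradome <- function(truth, config) {
  with_stage_seed(config, 5L, {
    L <- config$transcript_length
    bins <- c("RNA", "Protein", "Stress", "Development", "Transport",
              "Hormone metabolism", "Not assigned")
    other_base <- function(m) {
      # a base that neither Watson-Crick pairs nor G:U wobbles with m
      switch(m, A = "C", C = "A", G = "G", T = "C")
    }
    trows <- list(); prof <- list(); tg <- list(); ann <- list()
    for (i in seq_len(nrow(truth))) {
      mirna <- truth$mature_sequence[i]
      ml <- nchar(mirna)
      site <- seq_chars(revcomp(mirna))
      if (config$site_mispairs > 0) {
        pos <- sample(14:ml, config$site_mispairs)
        for (p in pos) {
          # site index paired with miRNA position p
          si <- ml - p + 1L
          site[si] <- other_base(substr(mirna, p, p))
        }
      }
      site <- paste(site, collapse = "")
      tseq <- random_dna(L)
      start <- sample.int(L - ml - 200L, 1) + 100L
      substr(tseq, start, start + ml - 1L) <- site
      cleav <- start + ml - 10L
      counts <- sample(0:1, L, replace = TRUE)
      counts[cleav] <- config$degradome_spike
      tid <- sprintf("tx_%02d", i)
      gid <- sprintf("gene_%02d", i)
      trows[[i]] <- data.frame(transcript_id = tid, gene_id = gid,
                               sequence = tseq, annotation = "synthetic target",
                               stringsAsFactors = FALSE)
      prof[[tid]] <- counts
      tg[[i]] <- data.frame(mirna_id = truth$mirna_id[i], transcript_id = tid,
                            site_start = start, site_end = start + ml - 1L,
                            cleavage_position = cleav,
                            stringsAsFactors = FALSE)
      ann[[i]] <- data.frame(gene_id = gid,
                             mapman_bin = sample(bins, 1),
                             stringsAsFactors = FALSE)
    }
    nd <- config$n_decoy_transcripts
    for (j in seq_len(nd)) {
      tid <- sprintf("tx_decoy_%02d", j)
      trows[[length(trows) + 1L]] <- data.frame(
        transcript_id = tid, gene_id = sprintf("gene_decoy_%02d", j),
        sequence = random_dna(L), annotation = "synthetic decoy",
        stringsAsFactors = FALSE)
      prof[[tid]] <- sample(0:1, L, replace = TRUE)
    }
    list(transcripts = do.call(rbind, trows), profiles = prof,
         targets = do.call(rbind, tg), annotation = do.call(rbind, ann))
  })
}

#' Generate the full synthetic dataset
#'
#' Runs every generator stage and returns genome, truth, reference,
#' libraries, degradome and annotation in one list.
#'
#' @param config a [sim_config()].
#' @return list with components `config`, `genome`, `truth`, `decoys`,
#'   `reference` (matures + precursors), `libraries`, `degradome`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  genome <- generate_genome(config)
  planted <- plant_hairpins(genome, config)
  ref <- build_reference(planted$truth, planted$genome, config)
  libs <- simulate_libraries(ref$truth, planted$decoys, planted$genome,
                             config)
  deg <- simulate_degradome(ref$truth, config)
  list(config = config, genome = planted$genome, truth = ref$truth,
       decoys = planted$decoys,
       reference = ref[c("matures", "precursors")],
       libraries = libs, degradome = deg)
}
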