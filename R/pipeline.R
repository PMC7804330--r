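# End-to-end orchestration: preprocess -> known annotation -> novel
# discovery -> expression dynamics -> targets/degradome -> networks/report,
# with every threshold collected in one configuration object and all
# randomness flowing from the configured seeds.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with its default:
#' expression filter 100 mean normalized reads, correlation threshold 0.75
#' at p <= 0.05, target expectation cutoff 2, degradome categories 0-2 at
#' T-plot p < 0.05, the eight structural criteria thresholds, and k = 6
#' abundance clusters.
#'
#' @param seed integer seed driving simulation and shuffle tests.
#' @param sim a [sim_config()] used when the pipeline simulates its input;
#'   defaults to `sim_config(seed)`.
#' @param expression_threshold mean normalized-read expression filter.
#' @param r_min absolute Pearson threshold of the co-expression network.
#' @param network_p p-value threshold of the co-expression network.
#' @param e_cutoff maximum target-prediction expectation score.
#' @param max_category highest retained degradome category.
#' @param degradome_p strict T-plot p-value threshold.
#' @param k_clusters number of abundance clusters.
#' @param flank discovery window flank (nt).
#' @param criteria structural criteria thresholds
#'   ([novel_criteria_thresholds()]).
#' @param n_shuffles shuffles per T-plot p-value.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, sim = sim_config(seed = seed),
                            expression_threshold = 100, r_min = 0.75,
                            network_p = 0.05, e_cutoff = 2,
                            max_category = 2L, degradome_p = 0.05,
                            k_clusters = 6L, flank = 80L,
                            criteria = novel_criteria_thresholds(),
                            n_shuffles = 100L) {
  stopifnot(expression_threshold > 0, r_min > 0, network_p > 0,
            e_cutoff >= 0, degradome_p > 0, k_clusters >= 2)
  structure(list(seed = as.integer(seed), sim = sim,
                 expression_threshold = expression_threshold,
                 r_min = r_min, network_p = network_p,
                 e_cutoff = e_cutoff, max_category = max_category,
                 degradome_p = degradome_p, k_clusters = k_clusters,
                 flank = as.integer(flank), criteria = criteria,
                 n_shuffles = as.integer(n_shuffles)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes all stages in order on a dataset (by default a synthetic
#' dataset generated from `config$sim`) and optionally writes every result
#' table under `out_dir`. Identical configuration and seed produce
#' byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param data a dataset list shaped like [simulate_dataset()] output;
#'   `NULL` simulates one from `config$sim`.
#' @param out_dir output directory for TSV/GFF3 artifacts (`NULL`: no
#'   files).
#' @return list with all stage results: `tags`, `stats`, `assignments`,
#'   `novel_calls`, `profiles` (all expressed tags), `mirna_profiles`
#'   (expressed known + novel miRNAs), `de`, `clusters`, `pca`, `edges`,
#'   `family_pct`, `targets`, `hits`, `retained_hits`, `bipartite`,
#'   `report`.
#' @export
run_pipeline <- function(config = pipeline_config(), data = NULL,
                         out_dir = NULL) {
  if (is.null(data)) data <- simulate_dataset(config$sim)
  design <- data$libraries$design

  ## preprocess
  pp <- collapse_and_filter(data$libraries$reads, design)
  tags <- normalize_rpm(pp$tags, pp$stats)
  lengths_tbl <- length_distribution(pp$stats)

  ## expression filter on normalized tags
  prof_all <- expression_filter(tags$norm, design,
                                config$expression_threshold)

  ## known annotation on expressed tags
  cls <- classify_tags(prof_all$ids, data$reference$matures,
                       data$reference$precursors, data$genome)
  assignments <- cls$assignments

  ## novel discovery on residuals
  novel_calls <- discover(cls$residuals, data$genome, config$flank,
                          config$criteria)

  ## expressed miRNA set (known + novel), named profiles
  id_of <- c(stats::setNames(assignments$assigned_id, assignments$tag),
             stats::setNames(novel_calls$mirna_id[novel_calls$novel],
                             novel_calls$tag[novel_calls$novel]))
  mirna_tags <- intersect(prof_all$ids, names(id_of))
  norm_mirna <- prof_all$norm[mirna_tags, , drop = FALSE]
  rownames(norm_mirna) <- unname(id_of[mirna_tags])
  mirna_profiles <- expression_filter(norm_mirna, design,
                                      config$expression_threshold)

  ## dynamics
  de <- anova_de(mirna_profiles)
  clusters <- if (length(mirna_profiles$ids) >= config$k_clusters)
    cluster_profiles(mirna_profiles, config$k_clusters) else NULL
  pca <- if (length(mirna_profiles$ids) >= 2)
    pca_libraries(mirna_profiles) else NULL
  edges <- correlation_network(mirna_profiles, config$r_min,
                               config$network_p)

  ## family shares over known miRNAs
  fam_map <- stats::setNames(assignments$family, assignments$assigned_id)
  known_ids <- intersect(rownames(mirna_profiles$tp_means),
                         assignments$assigned_id)
  family_pct <- if (length(known_ids) > 0)
    family_abundance(mirna_profiles$tp_means[known_ids, , drop = FALSE],
                     fam_map) else NULL

  ## targets and degradome
  seq_of <- c(stats::setNames(assignments$tag, assignments$assigned_id),
              stats::setNames(novel_calls$tag[novel_calls$novel],
                              novel_calls$mirna_id[novel_calls$novel]))
  mirnas <- data.frame(mirna_id = mirna_profiles$ids,
                       sequence = unname(seq_of[mirna_profiles$ids]),
                       stringsAsFactors = FALSE)
  targets <- predict_targets(mirnas, data$degradome$transcripts,
                             config$e_cutoff)
  hits <- degradome_hits(targets, data$degradome$profiles, mirnas,
                         data$degradome$transcripts, config$n_shuffles,
                         config$seed)
  retained <- filter_hits(hits, mirna_profiles$ids, config$max_category,
                          config$degradome_p)

  ## bipartite networks
  gene_of <- stats::setNames(data$degradome$transcripts$gene_id,
                             data$degradome$transcripts$transcript_id)
  links <- unique(data.frame(mirna_id = retained$mirna_id,
                             gene_id = unname(gene_of[retained$transcript_id]),
                             stringsAsFactors = FALSE))
  bipartite <- if (!is.null(clusters))
    build_bipartite(clusters$assignment, links, data$degradome$annotation)
  else NULL

  report <- run_report(pp$stats, assignments, novel_calls, mirna_profiles,
                       de, clusters, edges, retained)

  res <- list(config = config, data = data, tags = tags, stats = pp$stats,
              lengths = lengths_tbl, assignments = assignments,
              novel_calls = novel_calls, profiles = prof_all,
              mirna_profiles = mirna_profiles, de = de,
              clusters = clusters, pca = pca, edges = edges,
              family_pct = family_pct, targets = targets, hits = hits,
              retained_hits = retained, bipartite = bipartite,
              report = report)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write all pipeline result tables to a directory
#'
#' @param res result list from [run_pipeline()].
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_tsv(res$stats$summary, p("library_stats.tsv"))
  write_tsv(res$lengths, p("length_distribution.tsv"))
  write_tsv(res$assignments, p("known_mirnas.tsv"))
  write_tsv(res$novel_calls, p("novel_calls.tsv"))
  nm <- res$mirna_profiles
  write_tsv(data.frame(mirna_id = rownames(nm$norm), nm$norm,
                       check.names = FALSE), p("mirna_expression_rpm.tsv"))
  write_tsv(data.frame(mirna_id = rownames(nm$tp_means), nm$tp_means,
                       check.names = FALSE), p("mirna_timepoint_means.tsv"))
  write_tsv(res$de$anova, p("de_anova.tsv"))
  write_tsv(res$de$pairwise, p("de_pairwise.tsv"))
  if (!is.null(res$clusters))
    write_tsv(res$clusters$assignment, p("clusters.tsv"))
  if (!is.null(res$pca))
    write_tsv(data.frame(library_id = rownames(res$pca$scores),
                         res$pca$scores[, seq_len(min(4, ncol(res$pca$scores))),
                                        drop = FALSE], check.names = FALSE),
              p("pca_scores.tsv"))
  write_tsv(res$edges, p("correlation_edges.tsv"))
  write_tsv(data.frame(source = res$edges$mirna_a,
                       interaction = res$edges$sign,
                       target = res$edges$mirna_b),
            p("correlation_edges.sif"))
  if (!is.null(res$family_pct))
    write_tsv(res$family_pct, p("family_abundance.tsv"))
  write_tsv(res$hits, p("degradome_hits.tsv"))
  write_tsv(res$retained_hits, p("degradome_hits_retained.tsv"))
  if (!is.null(res$bipartite)) {
    write_tsv(res$bipartite, p("bipartite_edges.tsv"))
    write_tsv(data.frame(source = res$bipartite$source,
                         interaction = res$bipartite$via_gene,
                         target = res$bipartite$target),
              p("bipartite_edges.sif"))
  }
  write_tsv(res$report$overview, p("report_overview.tsv"))
  if (!is.null(res$report$de_counts))
    write_tsv(res$report$de_counts, p("report_de_counts.tsv"))
  if (!is.null(res$report$cluster_sizes))
    write_tsv(res$report$cluster_sizes, p("report_cluster_sizes.tsv"))
  novel <- res$novel_calls[res$novel_calls$novel, , drop = FALSE]
  if (nrow(novel) > 0)
    write_loci_gff3(data.frame(chrom = novel$chrom, start = novel$win_start,
                               end = novel$win_end, strand = novel$strand,
                               id = novel$mirna_id,
                               stringsAsFactors = FALSE),
                    p("novel_loci.gff3"))
  invisible(out_dir)
}
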