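# Family-abundance summaries, cluster-wise miRNA-to-function bipartite
# networks and the consolidated run report.

#' Family abundance shares per timepoint
#'
#' The percentage of a family at a timepoint is the sum of the mean
#' normalized reads of its miRNAs divided by the total over all known
#' miRNAs at that timepoint, times 100.
#'
#' @param tp_means matrix of timepoint means (rows = known miRNAs).
#' @param family_map named character vector mapping miRNA id to family.
#' @return data.frame with `family`, `timepoint`, `percent_of_known`;
#'   percentages sum to 100 per timepoint.
#' @export
family_abundance <- function(tp_means, family_map) {
  fams <- family_map[rownames(tp_means)]
  if (any(is.na(fams))) stopf("missing family for: %s",
                              paste(rownames(tp_means)[is.na(fams)],
                                    collapse = ", "))
  totals <- colSums(tp_means)
  if (any(totals <= 0))
    stopf("all-zero abundance at timepoint %s",
          colnames(tp_means)[totals <= 0][1])
  by_fam <- rowsum(tp_means, group = fams)
  pct <- sweep(by_fam, 2, totals, "/") * 100
  d <- expand.grid(family = rownames(pct), timepoint = colnames(pct),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$percent_of_known <- as.vector(pct)
  d[order(d$timepoint, d$family), , drop = FALSE]
}

#' Cluster-wise bipartite miRNA-to-function networks
#'
#' One edge per (miRNA, gene, functional bin) triple, grouped by the
#' miRNA's abundance cluster. Genes lacking annotation are routed to the
#' bin `"Not assigned"`; miRNAs without any target link are absent.
#'
#' @param assignment cluster assignment data.frame (`mirna_id`, `cluster`).
#' @param links data.frame of target links (`mirna_id`, `gene_id`).
#' @param annotation data.frame (`gene_id`, `mapman_bin`).
#' @return data.frame of edges: `source` (miRNA), `target` (bin),
#'   `via_gene`, `cluster`.
#' @export
build_bipartite <- function(assignment, links, annotation) {
  if (nrow(links) == 0)
    return(data.frame(source = character(0), target = character(0),
                      via_gene = character(0), cluster = character(0),
                      stringsAsFactors = FALSE))
  cl <- stats::setNames(assignment$cluster, assignment$mirna_id)
  rows <- list()
  for (i in seq_len(nrow(links))) {
    mid <- links$mirna_id[i]; gid <- links$gene_id[i]
    bins <- annotation$mapman_bin[annotation$gene_id == gid]
    if (length(bins) == 0) bins <- "Not assigned"
    for (b in unique(bins))
      rows[[length(rows) + 1L]] <- data.frame(
        source = mid, target = b, via_gene = gid,
        cluster = if (mid %in% names(cl)) cl[[mid]] else NA_character_,
        stringsAsFactors = FALSE)
  }
  d <- unique(do.call(rbind, rows))
  rownames(d) <- NULL
  d
}

#' Mean reads per library, integer-truncated
#'
#' @param total_reads total read count over all libraries.
#' @param n_libraries number of libraries.
#' @return `trunc(total_reads / n_libraries)`.
#' @export
mean_reads_per_library <- function(total_reads, n_libraries) {
  trunc(total_reads / n_libraries)
}

#' Consolidated run report
#'
#' Headline counts of a pipeline run: tags, known/novel/expressed miRNAs,
#' differential-expression counts per comparison, cluster sizes, network
#' edges and retained degradome hits, plus per-library sequencing stats.
#'
#' @param stats preprocessing stats (or `NULL`).
#' @param assignments known-assignment data.frame (or `NULL`).
#' @param novel_calls discovery data.frame (or `NULL`).
#' @param profiles expression profiles (or `NULL`).
#' @param de differential-expression result from [anova_de()] (or `NULL`).
#' @param clusters cluster result from [cluster_profiles()] (or `NULL`).
#' @param edges correlation-network edge data.frame (or `NULL`).
#' @param hits retained degradome hits (or `NULL`).
#' @param alpha adjusted-p threshold for DE counts (default 0.05).
#' @return list with `overview` (metric/value data.frame), `libraries`
#'   (per-library stats), `de_counts`, `cluster_sizes`.
#' @export
run_report <- function(stats = NULL, assignments = NULL, novel_calls = NULL,
                       profiles = NULL, de = NULL, clusters = NULL,
                       edges = NULL, hits = NULL, alpha = 0.05) {
  metric <- function(name, value) data.frame(metric = name, value = value,
                                             stringsAsFactors = FALSE)
  ov <- list()
  libraries <- NULL
  if (!is.null(stats)) {
    libraries <- stats$summary
    total <- sum(libraries$raw_reads)
    ov <- c(ov, list(
      metric("total_raw_reads", total),
      metric("mean_raw_reads_per_library",
             mean_reads_per_library(total, nrow(libraries))),
      metric("total_mappable_reads", sum(libraries$mappable_reads))))
  }
  if (!is.null(assignments))
    ov <- c(ov, list(metric("known_mirnas",
                            length(unique(assignments$assigned_id)))))
  if (!is.null(novel_calls))
    ov <- c(ov, list(metric("novel_mirnas", sum(novel_calls$novel)),
                     metric("discovery_candidates", nrow(novel_calls))))
  if (!is.null(profiles))
    ov <- c(ov, list(metric("expressed_mirnas", length(profiles$ids))))
  de_counts <- NULL
  if (!is.null(de)) {
    ov <- c(ov, list(metric("de_anova",
                            sum(de$anova$anova_adj_p <= alpha))))
    pw <- de$pairwise
    de_counts <- do.call(rbind, lapply(split(pw, paste(pw$tp_a, pw$tp_b)),
      function(d) data.frame(tp_a = d$tp_a[1], tp_b = d$tp_b[1],
                             n_de = sum(d$adj_p <= alpha),
                             stringsAsFactors = FALSE)))
    rownames(de_counts) <- NULL
  }
  cluster_sizes <- NULL
  if (!is.null(clusters)) {
    tab <- table(clusters$assignment$cluster)
    cluster_sizes <- data.frame(cluster = names(tab),
                                n = as.integer(tab),
                                stringsAsFactors = FALSE)
  }
  if (!is.null(edges))
    ov <- c(ov, list(metric("network_edges", nrow(edges))))
  if (!is.null(hits))
    ov <- c(ov, list(metric("retained_degradome_hits", nrow(hits))))
  overview <- if (length(ov) > 0) do.call(rbind, ov) else
    data.frame(metric = character(0), value = numeric(0))
  list(overview = overview, libraries = libraries, de_counts = de_counts,
       cluster_sizes = cluster_sizes)
}
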