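# Bundled catalogs of miRNAs found expressed in developing common bean
# (Phaseolus vulgaris) seeds across the 10/20/30/40 days-after-anthesis
# series, together with the sequencing summary of the underlying twelve
# small-RNA libraries. The known catalog carries the miRBase-derived family
# assignment; the novel catalog carries the hairpin MFE and MFEI of each
# candidate precursor.

#' Catalog of miRNAs expressed in developing common bean seeds
#'
#' @param type `"known"` (72 miRNAs with family and arm) or `"novel"`
#'   (39 candidate miRNAs with precursor MFE and MFEI).
#' @return data.frame; known: `mirna_id`, `family`, `sequence`,
#'   `length_nt`, `arm`; novel: `mirna_id`, `sequence`, `length_nt`,
#'   `mfe_kcal_mol`, `mfei`.
#' @examples
#' nrow(seed_mirna_catalog("known"))   # 72
#' nrow(seed_mirna_catalog("novel"))   # 39
#' @export
seed_mirna_catalog <- function(type = c("known", "novel")) {
  type <- match.arg(type)
  path <- system.file("extdata",
                      sprintf("pvulgaris_seed_%s_mirnas.tsv", type),
                      package = "seedmir", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Sequencing summary of the developing-seed small-RNA libraries
#'
#' Totals of the twelve-library 4 x 3 design the bundled catalogs derive
#' from: raw and mappable reads and the dominant read-length shares.
#'
#' @return one-row data.frame with `n_libraries`, `total_raw_reads`,
#'   `total_mappable_reads`, `pct_mappable_24nt`, `pct_mappable_21nt`.
#' @export
seed_library_summary <- function() {
  path <- system.file("extdata", "pvulgaris_srna_library_summary.tsv",
                      package = "seedmir", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
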