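#' Reported top-probe signature at the MMACHC/TESK2 locus
#'
#' The published case-control methylation signature the package is built
#' around: the 18 top EWAS probes spanning the CCDC163P-MMACHC
#' bidirectional-promoter CpG island (CpG:33) and the TESK2-promoter CpG
#' island (CpG:51, including the probes flanking its upstream 5' end),
#' with their GRCh37 positions, nominal and Bonferroni-corrected P-values
#' and group mean beta values (17 epi-cblC cases vs 350 controls). Useful
#' as worked-example input for [classify_beta()], [call_island()] and
#' [probe_group_stats()].
#'
#' @return Tibble with columns `probe_id`, `chromosome`, `position`,
#'   `island_id`, `island_relation`, `locus`, `p_nominal`, `p_bonferroni`,
#'   `mean_beta_cases`, `mean_beta_controls`, `delta_beta`.
#' @export
epicblc_signature <- function() {
  path <- system.file("extdata", "mmachc_tesk2_signature.tsv",
                      package = "epimutr", mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  tibble::as_tibble(tab)
}

#' CpG-island intervals of the MMACHC/TESK2 locus
#'
#' CpG:33 uses its published GRCh37 interval
#' (chr1:45,965,587-45,966,049). No interval is published for CpG:51, so
#' its bounds span the reported in-island probes
#' (chr1:45,956,424-45,956,882) rather than the UCSC annotation; with the
#' default 250 bp flank the six "upstream 5' end" probes map as flank
#' probes of CpG:51, matching the reported signature layout.
#'
#' @return A [cpg_island_set()] with the two islands.
#' @export
epicblc_islands <- function() {
  path <- system.file("extdata", "mmachc_tesk2_islands.bed",
                      package = "epimutr", mustWork = TRUE)
  read_islands(path)
}
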