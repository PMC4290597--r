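# Bundled reference data.

#' Published gene census of the 34 reconciliation species
#'
#' The per-species counts of predicted Argonaute- and RdRP-encoding genes
#' for the 34 genomes used in the Argonaute reconciliation and the RdRP
#' conservation analysis (25 fungi, one Oomycete, one bacterium, two
#' archaea, two plants and three animals), together with their
#' kingdom/phylum/subphylum lineages. `N/D` marks lineage levels not
#' determined. This is published census data, not a synthetic fixture.
#'
#' One Fusarium oxysporum RdRP gene (FOXG_00217) carries only a 68-residue
#' polymerase domain region and was excluded from the published alignment
#' set; the count here is the pre-exclusion prediction.
#'
#' @return Data frame with columns `genome_id`, `kingdom`, `phylum`,
#'   `subphylum`, `argonaute_genes`, `rdrp_genes`.
#' @examples
#' census <- rnai_gene_census()
#' sum(census$argonaute_genes)
#' @export
rnai_gene_census <- function() {
  path <- system.file("extdata", "rnai_gene_census_34_species.tsv",
                      package = "rnaikit", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
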