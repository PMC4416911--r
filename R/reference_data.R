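#' Published per-gene summary statistics for the two Cardamine surveys
#'
#' The per-gene statistics reported for the *C. impatiens* and
#' *C. resedifolia* amplicon surveys (19 orthologous gene regions each;
#' intronic columns available for 15): haplotype counts, region lengths,
#' linkage and haplotype diversity over the whole region, and the intronic
#' effective length, segregating sites, diversity, Tajima's D and outgroup
#' divergence.  These rows serve as worked inputs: the intronic `n`/`L_eff`
#' columns define the multi-locus configuration for demographic inference,
#' and the printed values anchor the statistics implementations.
#'
#' @param species `"cimpatiens"` or `"cresedifolia"`.
#' @return Data frame, one row per gene region.
#' @export
reference_gene_stats <- function(species = c("cimpatiens", "cresedifolia")) {
  species <- match.arg(species)
  path <- system.file("extdata", paste0(species, "_gene_stats.tsv"),
                      package = "altipop", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Intron-bearing locus configuration from the published tables
#'
#' @param species Passed to [reference_gene_stats()].
#' @return A [locus_config()] of the 15 intron-bearing loci (haplotype count
#'   and effective intronic length).
#' @export
reference_locus_config <- function(species = "cimpatiens") {
  tab <- reference_gene_stats(species)
  tab <- tab[!is.na(tab$L_eff), ]
  locus_config(tab$n, tab$L_eff)
}
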