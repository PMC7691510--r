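# Bundled SOD1 reference data.

#' Path to a bundled data file
#' @param file file name under the package's `extdata`, or `""` to list.
#' @export
nmdscan_extdata <- function(file = "") {
  system.file("extdata", file, package = "nmdscan", mustWork = nzchar(file))
}

#' The SOD1 transcript model (NM_000454.4)
#'
#' CDS sequence (465 nt; 154 amino acids plus the stop codon) and per-exon
#' CDS lengths (72, 97, 71, 117, 108 nt over five exons; last exon-exon
#' junction at CDS nt 357) transcribed from the RefSeq record. Nucleotide
#' numbering follows the HGVS c. convention: +1 is the A of the ATG
#' initiation codon.
#'
#' @return a [transcript_model].
#' @examples
#' sod1_transcript()
#' @export
sod1_transcript <- function() {
  load_transcript(nmdscan_extdata("sod1_nm000454.json"), "json")
}

#' The catalogue of ALS-associated truncating SOD1 variants
#'
#' Sixteen disease-associated PTC-introducing variants (4 nonsense, 11
#' frameshift, 1 deep intronic splicing mutation whose spliced consequence
#' is given at protein level), with the reported protein consequence and
#' resulting PTC codon for each.
#'
#' @return data.frame with columns `label`, `hgvs_c`, `hgvs_p`,
#'   `ptc_printed`, `reported_class`.
#' @export
sod1_variants <- function() {
  df <- utils::read.delim(nmdscan_extdata("sod1_table1.tsv"),
                          stringsAsFactors = FALSE, colClasses = "character")
  df$ptc_printed <- as.integer(df$ptc_printed)
  df
}
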