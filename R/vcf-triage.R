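# NGS versus genotype-array triage of VCF inputs.
#
# A VCF written by a variant caller lists (almost) only sites that differ
# from the reference, with the alternate allele always stated. VCFs
# converted from genotyping-array downloads instead carry the full array
# content — mostly homozygous-reference rows — and often leave the ALT
# column blank because the array download never stated it.

#' Classify a VCF as NGS output or an array conversion
#'
#' Genotyping when strictly more than half of the rows are
#' homozygous-reference, or strictly more than half lack an alternate
#' allele; NGS otherwise. Files with fewer than `min_rows` rows are
#' `undetermined`.
#'
#' @param stats list with `n_rows`, `frac_homref`, `frac_missing_alt`
#'   (as attached by [parse_vcf_file()] under `$vcf_stats`)
#' @param min_rows minimum rows for a decision (default 1000)
#' @return one of `"genotyping"`, `"ngs"`, `"undetermined"`
#' @export
classify_vcf <- function(stats, min_rows = 1000L) {
  stopifnot(is.list(stats), !is.null(stats$n_rows))
  if (stats$n_rows < min_rows) return("undetermined")
  if (stats$frac_homref > 0.5 || stats$frac_missing_alt > 0.5) {
    "genotyping"
  } else {
    "ngs"
  }
}

#' Apply VCF triage to a parsed genome
#'
#' @param g a `dtc_genome` from [parse_vcf_file()]
#' @param min_rows see [classify_vcf()]
#' @return `g` with `data_kind` set (and a `vcf_small` flag when
#'   undetermined)
#' @export
triage_vcf_genome <- function(g, min_rows = 1000L) {
  stopifnot(is_genome(g))
  if (is.null(g$vcf_stats)) return(g)
  kind <- classify_vcf(g$vcf_stats, min_rows = min_rows)
  g$data_kind <- kind
  if (kind == "undetermined") g <- add_qc_flag(g, "vcf_small")
  g
}
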