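# Reverse-strand detection and repair.
#
# Some providers report genotypes on the reverse strand. At probe sites
# inside genes known to be coded on the reverse strand the forward-strand
# allele pair is known; a file whose calls match the complements instead
# is flagged and repaired by complementing every call, then re-checked.

#' Load the strand-probe table
#'
#' Each probe is a site with a known forward-strand allele pair that is
#' not its own complement (A/T and C/G pairs cannot distinguish strands
#' and are never probes). The packaged table is synthetic and shared
#' with the generator.
#'
#' @param path TSV with columns `chrom`, `pos`, `allele_a`, `allele_b`,
#'   `gene`; defaults to the packaged synthetic table
#' @return data.table of probes
#' @export
read_strand_probes <- function(path = NULL) {
  path <- path %||% system.file("extdata", "strand_probes_synthetic.tsv",
                                package = "dtcqc")
  pr <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("chrom", "allele_a", "allele_b", "gene")))
  stopifnot(all(c("chrom", "pos", "allele_a", "allele_b") %in% names(pr)))
  amb <- mapply(function(a, b) setequal(c(a, b), complement_alleles(c(a, b))),
                pr$allele_a, pr$allele_b)
  if (any(amb)) stop("strand probes must not be self-complementary pairs")
  pr
}

#' Score a genome for reverse-strand reporting
#'
#' A probe is informative when the observed alleles are consistent with
#' exactly one of the forward pair or its complement. `frac_flipped` is
#' the fraction of informative probes matching the complement.
#'
#' @param g a `dtc_genome`
#' @param probes probe table from [read_strand_probes()]
#' @param min_informative minimum informative probes for a score
#'   (default 10); below it a classed error
#'   (`dtcqc_insufficient_probes`) is raised
#' @return list with `n_informative` and `frac_flipped`
#' @export
strand_flip_score <- function(g, probes = read_strand_probes(),
                              min_informative = 10L) {
  rec <- g$records[(!nocall)]
  m <- merge(rec, probes, by = c("chrom", "pos"))
  n_informative <- 0L
  n_flipped <- 0L
  if (nrow(m) > 0) {
    a2 <- ifelse(is.na(m$allele2), m$allele1, m$allele2)
    fwd <- (m$allele1 == m$allele_a | m$allele1 == m$allele_b) &
      (a2 == m$allele_a | a2 == m$allele_b)
    ca <- complement_alleles(m$allele_a)
    cb <- complement_alleles(m$allele_b)
    rev <- (m$allele1 == ca | m$allele1 == cb) & (a2 == ca | a2 == cb)
    informative <- xor(fwd, rev)
    n_informative <- sum(informative)
    n_flipped <- sum(rev & informative)
  }
  if (n_informative < min_informative) {
    cond <- structure(
      class = c("dtcqc_insufficient_probes", "error", "condition"),
      list(message = sprintf(
        "only %d informative strand probes (need %d)",
        n_informative, min_informative), call = sys.call(-1))
    )
    stop(cond)
  }
  list(n_informative = n_informative,
       frac_flipped = n_flipped / n_informative)
}

#' Complement every call in a genome
#'
#' A to T and C to G (and back) on both alleles; no-call codes and the
#' insertion/deletion codes I/D are untouched. Applying it twice is the
#' identity.
#'
#' @param g a `dtc_genome`
#' @return the complemented genome, flagged `strand_fixed`
#' @export
fix_strand <- function(g) {
  rec <- data.table::copy(g$records)
  rec[!(nocall), allele1 := complement_alleles(allele1)]
  rec[!(nocall) & !is.na(allele2), allele2 := complement_alleles(allele2)]
  g$records <- rec
  add_qc_flag(g, "strand_fixed")
}

#' Detect, repair, and verify strand orientation
#'
#' Clean files (flip score at or below `flip_lo`) pass untouched. Files
#' scoring above `flip_hi` are globally complemented and re-scored; the
#' repair must bring the score to `flip_lo` or below, otherwise the file
#' is rejected. Intermediate scores indicate a mix of strands that no
#' global complement can repair, so the file is rejected. Genomes with
#' too few informative probes pass with flag `strand_unchecked`.
#'
#' @param g a `dtc_genome`
#' @param probes probe table from [read_strand_probes()]
#' @param cfg configuration list, see [qc_config()]
#' @return the (possibly repaired) genome, or a [rejection()]
#' @export
verify_or_reject <- function(g, probes = read_strand_probes(),
                             cfg = qc_config()) {
  score <- tryCatch(
    strand_flip_score(g, probes, cfg$strand_min_informative),
    dtcqc_insufficient_probes = function(e) NULL
  )
  if (is.null(score)) return(add_qc_flag(g, "strand_unchecked"))

  if (score$frac_flipped <= cfg$strand_flip_lo) return(g)
  if (score$frac_flipped > cfg$strand_flip_hi) {
    fixed <- fix_strand(g)
    rescore <- strand_flip_score(fixed, probes, cfg$strand_min_informative)
    if (rescore$frac_flipped <= cfg$strand_flip_lo) return(fixed)
    return(rejection("strand unresolvable", stage = "strand_check",
                     detail = sprintf("flip score %.2f after repair",
                                      rescore$frac_flipped)))
  }
  rejection("strand unresolvable", stage = "strand_check",
            detail = sprintf("mixed-strand flip score %.2f",
                             score$frac_flipped))
}
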