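# Genome-build detection and reference-genome similarity checks.

BUILDS <- c("GRCh36", "GRCh37", "GRCh38")

#' Load the signature-SNP table used for build detection
#'
#' Signature SNPs are markers whose coordinates differ between assembly
#' versions, so observing which coordinate a file reports votes for its
#' build. The packaged table is synthetic (invented rsids/positions used
#' consistently by the generator and the detector); supply your own
#' table for real data.
#'
#' @param path TSV with columns `rsid`, `chrom`, `pos_grch36`,
#'   `pos_grch37`, `pos_grch38`; defaults to the packaged synthetic table
#' @return data.table of signatures
#' @export
read_build_signatures <- function(path = NULL) {
  path <- path %||% system.file("extdata", "build_signatures_synthetic.tsv",
                                package = "dtcqc")
  sig <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("rsid", "chrom")))
  stopifnot(all(c("rsid", "chrom", "pos_grch36", "pos_grch37",
                  "pos_grch38") %in% names(sig)))
  sig
}

#' Detect the genome build of a parsed file
#'
#' A build declared in the vendor header wins outright. Otherwise
#' signature SNPs present in the file vote for the build whose
#' coordinate matches the file's reported position; the majority wins
#' when at least `min_votes` signatures are informative. Ties, too few
#' votes, or no information default to GRCh37.
#'
#' @param g a `dtc_genome`
#' @param sigs signature table from [read_build_signatures()]
#' @param min_votes minimum informative signatures needed to override
#'   the GRCh37 default (default 3)
#' @return one of `GRCh36`, `GRCh37`, `GRCh38`
#' @export
detect_build <- function(g, sigs = read_build_signatures(), min_votes = 3L) {
  hdr <- grep("^header_build=", g$qc_flags, value = TRUE)
  if (length(hdr) > 0) {
    b <- sub("^header_build=", "", hdr[1])
    if (b %in% BUILDS) return(b)
  }

  rec <- g$records[rsid %in% sigs$rsid, .(rsid, chrom, pos)]
  if (nrow(rec) == 0) return("GRCh37")
  m <- merge(rec, sigs, by = c("rsid", "chrom"))
  if (nrow(m) == 0) return("GRCh37")
  votes <- c(
    GRCh36 = sum(m$pos == m$pos_grch36),
    GRCh37 = sum(m$pos == m$pos_grch37),
    GRCh38 = sum(m$pos == m$pos_grch38)
  )
  if (sum(votes) < min_votes) return("GRCh37")
  top <- which(votes == max(votes))
  if (length(top) > 1) return("GRCh37")
  names(votes)[top]
}

#' Load a sparse reference-base lookup
#'
#' @param path TSV with columns `chrom`, `pos`, `base`
#' @return keyed data.table usable by [compare_to_reference()] and the
#'   VCF writer
#' @export
read_reference_lookup <- function(path) {
  ref <- data.table::fread(path, sep = "\t",
                           colClasses = list(character = "chrom"))
  stopifnot(all(c("chrom", "pos", "base") %in% names(ref)))
  make_reference_lookup(ref$chrom, ref$pos, ref$base)
}

#' @rdname read_reference_lookup
#' @param chrom,pos,base parallel vectors defining the lookup in memory
#' @export
make_reference_lookup <- function(chrom, pos, base) {
  ref <- data.table::data.table(key_ = encode_pos(chrom, pos),
                                base = toupper(base))
  ref <- unique(ref, by = "key_")
  data.table::setkey(ref, key_)
  ref
}

# Vectorized base lookup by encoded position key; NA when absent.
ref_base <- function(ref, keys) {
  ref[data.table::data.table(key_ = keys), on = "key_", base]
}

#' Compare a genome's calls to the reference genome
#'
#' Classifies every called biallelic site covered by the lookup as
#' homozygous-reference, heterozygous (exactly one allele matches the
#' reference base), homozygous-alternate (no allele matches the
#' reference but one matches it or its complement-free alternate), or
#' reference-mismatch (neither allele equals the reference base or its
#' complement — calls that no strand interpretation explains). The four
#' fractions sum to 1 over compared sites.
#'
#' @param g a `dtc_genome`
#' @param ref reference lookup from [read_reference_lookup()]
#' @param min_coverage flag threshold for the fraction of the genome's
#'   positions the lookup must cover (default 0.5)
#' @return list with `n_compared`, `frac_homref`, `frac_het`,
#'   `frac_homalt`, `frac_ref_mismatch`, `ref_coverage`, `flags`
#' @export
compare_to_reference <- function(g, ref, min_coverage = 0.5) {
  rec <- g$records[!nocall & allele1 %in% c("A", "C", "G", "T") &
                     !is.na(allele2) & allele2 %in% c("A", "C", "G", "T")]
  keys <- encode_pos(rec$chrom, rec$pos)
  bases <- ref_base(ref, keys)
  covered <- !is.na(bases)
  coverage <- if (length(keys) > 0) mean(covered) else 0

  a1 <- rec$allele1[covered]
  a2 <- rec$allele2[covered]
  r <- bases[covered]
  rc <- complement_alleles(r)

  n_ref <- (a1 == r) + (a2 == r)
  touches_comp <- a1 == rc | a2 == rc
  homref <- n_ref == 2L
  het <- n_ref == 1L
  mismatch <- n_ref == 0L & !touches_comp
  homalt <- n_ref == 0L & touches_comp
  n <- length(r)

  flags <- character()
  if (coverage < min_coverage) flags <- "insufficient_reference_coverage"

  list(
    n_compared = n,
    frac_homref = if (n > 0) mean(homref) else NA_real_,
    frac_het = if (n > 0) mean(het) else NA_real_,
    frac_homalt = if (n > 0) mean(homalt) else NA_real_,
    frac_ref_mismatch = if (n > 0) mean(mismatch) else NA_real_,
    ref_coverage = coverage,
    flags = flags
  )
}

#' Gate a genome on plausibility bounds
#'
#' Rejects genomes whose record count or reference-mismatch fraction
#' falls outside configured bounds. Rejection is a return value, so the
#' pipeline can record the reason; `"pass"` otherwise.
#'
#' @param g a `dtc_genome`
#' @param rc result of [compare_to_reference()]
#' @param cfg configuration list, see [qc_config()]
#' @return `"pass"` or a [rejection()]
#' @export
sanity_gate <- function(g, rc, cfg = qc_config()) {
  n <- nrow(g$records)
  if (n < cfg$min_records) {
    return(rejection("too few records", stage = "sanity_gate",
                     detail = sprintf("%d < %d", n, cfg$min_records)))
  }
  if (n > cfg$max_records) {
    return(rejection("too many records", stage = "sanity_gate",
                     detail = sprintf("%d > %d", n, cfg$max_records)))
  }
  mm <- rc$frac_ref_mismatch
  if (!is.na(mm) && mm > cfg$max_ref_mismatch) {
    return(rejection("implausible mismatch", stage = "sanity_gate",
                     detail = sprintf("%.3f > %.3f", mm, cfg$max_ref_mismatch)))
  }
  "pass"
}
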