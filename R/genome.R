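# The normalized genome container shared by every pipeline stage.

# Recognized no-call spellings across vendors (single- and two-character).
NOCALL_CODES <- c("--", "-", "__", "_", "00", "0", "")
VALID_ALLELES <- c("A", "C", "G", "T", "I", "D")

#' Construct a normalized genome object
#'
#' A `dtc_genome` holds one person's genotype calls plus provenance and
#' parse accounting. Records are sorted by (chrom, pos); duplicate
#' (chrom, pos) pairs keep the first occurrence, the rest are counted as
#' rejected records.
#'
#' @param records data.table/data.frame with columns `rsid`, `chrom`
#'   (normalized labels), `pos` (integer, 1-based), `allele1`, `allele2`
#'   (characters in `A,C,G,T,I,D` or a no-call code; `allele2` may be
#'   `NA` for haploid calls), `nocall` (logical)
#' @param source vendor tag (`t23andme`, `ancestry`, `ftdna`,
#'   `myheritage`, `decodeme`, `vcf`, `synthetic`, or `unknown`)
#' @param build genome assembly, one of `GRCh36`, `GRCh37`, `GRCh38`
#' @param data_kind `genotyping`, `ngs`, or `undetermined`
#' @param n_input_lines,n_parsed,n_nocall,n_rejected_records parse counts
#' @param qc_flags character vector of QC labels accumulated by the stages
#' @return object of class `dtc_genome`
#' @export
new_genome <- function(records,
                       source = "unknown",
                       build = "GRCh37",
                       data_kind = "undetermined",
                       n_input_lines = NA_integer_,
                       n_parsed = NA_integer_,
                       n_nocall = NA_integer_,
                       n_rejected_records = 0L,
                       qc_flags = character()) {
  rec <- data.table::as.data.table(records)
  needed <- c("rsid", "chrom", "pos", "allele1", "allele2", "nocall")
  missing <- setdiff(needed, names(rec))
  if (length(missing) > 0) {
    stop("genome records lack columns: ", paste(missing, collapse = ", "))
  }
  rec <- rec[, needed, with = FALSE]
  rec[, pos := as.integer(pos)]

  # sort by (chrom, pos) in canonical chromosome order, then dedup
  ord <- order(chrom_index(rec$chrom), rec$pos)
  rec <- rec[ord]
  dup <- duplicated(rec, by = c("chrom", "pos"))
  n_dup <- sum(dup)
  if (n_dup > 0) rec <- rec[!dup]

  if (is.na(n_nocall)) n_nocall <- sum(rec$nocall)
  # n_parsed counts retained records: dropped duplicates move to rejected
  n_parsed <- if (is.na(n_parsed)) nrow(rec) else n_parsed - n_dup

  structure(
    list(
      records = rec,
      source = source,
      build = build,
      data_kind = data_kind,
      n_input_lines = as.integer(n_input_lines),
      n_parsed = as.integer(n_parsed),
      n_nocall = as.integer(n_nocall),
      n_rejected_records = as.integer(n_rejected_records + n_dup),
      qc_flags = qc_flags
    ),
    class = "dtc_genome"
  )
}

#' @export
print.dtc_genome <- function(x, ...) {
  cat(sprintf(
    "<dtc_genome: %d records | source=%s build=%s kind=%s | no-calls=%d rejected=%d>\n",
    nrow(x$records), x$source, x$build, x$data_kind, x$n_nocall,
    x$n_rejected_records
  ))
  if (length(x$qc_flags) > 0) {
    cat("  flags:", paste(x$qc_flags, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
format.dtc_genome <- function(x, ...) {
  sprintf("dtc_genome(%d records, %s, %s)", nrow(x$records), x$source, x$build)
}

is_genome <- function(x) inherits(x, "dtc_genome")

#' Position fingerprint of a genome
#'
#' The set of (chrom, pos) sites a genome reports, encoded as sorted
#' numeric keys (see [encode_pos()]). This is the object the array
#' fingerprint distance and clustering operate on.
#'
#' @param g a `dtc_genome`, or a data.frame with `chrom` and `pos`
#' @return sorted numeric vector of unique position keys
#' @export
position_set <- function(g) {
  rec <- if (is_genome(g)) g$records else data.table::as.data.table(g)
  sort(unique(encode_pos(rec$chrom, rec$pos)))
}

add_qc_flag <- function(g, flag) {
  g$qc_flags <- union(g$qc_flags, flag)
  g
}

# Unordered genotype string per record ("AG" == "GA"); no-calls -> NA.
genotype_string <- function(records) {
  a1 <- records$allele1
  a2 <- records$allele2
  a2[is.na(a2)] <- ""
  lo <- pmin(a1, a2)
  hi <- pmax(a1, a2)
  out <- paste0(lo, hi)
  out[records$nocall] <- NA_character_
  out
}
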