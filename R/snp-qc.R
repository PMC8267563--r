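# Per-record sanity filtering and allele-frequency based blacklisting.
#
# The blacklist machinery compares, per array cluster, the cohort
# alternate-allele frequency at each site with an external reference
# panel (in real use the 1000 Genomes Phase 3 ALL and EUR panels) via a
# one-sample binomial-proportion z statistic, and lists sites that fail
# on both panels.

#' Basic per-record SNP filter
#'
#' Removes records with an invalid chromosome label, a position outside
#' the chromosome length, call characters outside `A,C,G,T,I,D`, and
#' no-calls. Every removal is tallied by reason and
#' kept + removed = input.
#'
#' @param g a `dtc_genome`
#' @param chrom_lengths named vector of chromosome lengths used for the
#'   range check (default: packaged GRCh37 lengths)
#' @return list with `genome` (filtered) and `counts` (named integer
#'   vector: `invalid_chrom`, `out_of_range`, `invalid_call`, `nocall`,
#'   `kept`, `input`)
#' @export
basic_snp_check <- function(g, chrom_lengths = CHROM_LENGTHS) {
  stopifnot(is_genome(g))
  rec <- g$records
  n_in <- nrow(rec)

  bad_chrom <- !(rec$chrom %in% CHROM_LABELS)
  len <- chrom_lengths[rec$chrom]
  out_range <- !bad_chrom & (is.na(len) | rec$pos < 1 | rec$pos > len)
  is_nocall <- !bad_chrom & !out_range & rec$nocall
  ok_char <- rec$allele1 %in% VALID_ALLELES &
    (is.na(rec$allele2) | rec$allele2 %in% VALID_ALLELES)
  bad_call <- !bad_chrom & !out_range & !is_nocall & !ok_char

  keep <- !(bad_chrom | out_range | is_nocall | bad_call)
  counts <- c(
    invalid_chrom = sum(bad_chrom),
    out_of_range = sum(out_range),
    nocall = sum(is_nocall),
    invalid_call = sum(bad_call),
    kept = sum(keep),
    input = n_in
  )

  g$records <- rec[keep]
  g <- add_qc_flag(g, "basic_snp_checked")
  list(genome = g, counts = counts)
}

#' Load a reference allele-frequency table
#'
#' @param path TSV with columns `chrom`, `pos`, `ref`, `alt`, `af_all`,
#'   `af_eur` — the columns extractable from 1000 Genomes site VCFs
#' @return keyed data.table (`key_` encodes chrom/pos)
#' @export
read_allele_freq_table <- function(path) {
  af <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("chrom", "ref", "alt")))
  stopifnot(all(c("chrom", "pos", "ref", "alt", "af_all", "af_eur")
                %in% names(af)))
  make_allele_freq_table(af)
}

#' @rdname read_allele_freq_table
#' @param af data.frame with the same columns, built in memory
#' @export
make_allele_freq_table <- function(af) {
  af <- data.table::as.data.table(af)
  af[, key_ := encode_pos(chrom, pos)]
  stopifnot(all(af$ref != af$alt),
            all(af$af_all >= 0 & af$af_all <= 1),
            all(af$af_eur >= 0 & af$af_eur <= 1))
  data.table::setkey(af, key_)
  af
}

#' Tally cohort allele counts against a frequency table
#'
#' For every site in `freqs`, counts the alternate alleles (`k`) among
#' the genomes that call the site and the number of calling diploid
#' genomes (`n`, so `2n` alleles). Genomes not reporting or not calling
#' a site contribute nothing there; alleles matching neither the panel
#' ref nor alt are tallied separately as off-panel and excluded from
#' `k` and `n`.
#'
#' @param genomes list of `dtc_genome` (one array cluster's cohort)
#' @param freqs allele-frequency table from [read_allele_freq_table()]
#' @return data.table with `key_`, `chrom`, `pos`, `k`, `n`,
#'   `n_offpanel`
#' @export
cohort_counts <- function(genomes, freqs) {
  stopifnot(length(genomes) > 0)
  acc <- data.table::data.table(
    key_ = freqs$key_, ref = freqs$ref, alt = freqs$alt,
    k = 0L, n = 0L, n_offpanel = 0L
  )
  data.table::setkey(acc, key_)
  for (g in genomes) {
    rec <- g$records[!nocall & !is.na(allele2)]
    keys <- encode_pos(rec$chrom, rec$pos)
    idx <- acc[data.table::data.table(key_ = keys), on = "key_", which = TRUE]
    hit <- !is.na(idx)
    if (!any(hit)) next
    i <- idx[hit]
    a1 <- rec$allele1[hit]
    a2 <- rec$allele2[hit]
    ref_a <- acc$ref[i]
    alt_a <- acc$alt[i]
    on_panel <- (a1 == ref_a | a1 == alt_a) & (a2 == ref_a | a2 == alt_a)
    kk <- (a1 == alt_a) + (a2 == alt_a)
    acc[i[on_panel], `:=`(k = k + kk[on_panel], n = n + 1L)]
    acc[i[!on_panel], n_offpanel := n_offpanel + 1L]
  }
  cbind(decode_pos(acc$key_),
        acc[, .(key_, k, n, n_offpanel)])
}

#' One-sample allele-frequency z statistic
#'
#' `z = (k/(2n) - p0) / sqrt(p0 (1 - p0) / (2n))` — the standardized
#' deviation of the cohort alternate-allele frequency from the panel
#' frequency `p0` under the binomial null. Sites with a monomorphic
#' panel frequency or fewer than `n_min` called genomes are untestable
#' and return `NA`.
#'
#' @param k observed alternate-allele count(s)
#' @param n called diploid genome count(s)
#' @param p0 panel alternate-allele frequency(ies)
#' @param n_min minimum called genomes for testability (default 30)
#' @return numeric z (NA where untestable)
#' @export
af_zscore <- function(k, n, p0, n_min = 30L) {
  z <- (k / (2 * n) - p0) / sqrt(p0 * (1 - p0) / (2 * n))
  z[n < n_min | p0 <= 0 | p0 >= 1] <- NA_real_
  z
}

#' Build a per-cluster bad-SNP blacklist
#'
#' A site is blacklisted when its cohort frequency fails the z test
#' against **both** panels (|z| above `z_crit` on ALL and on EUR), or
#' when more than `offpanel_max` of the cohort's calls at the site carry
#' alleles that belong to neither panel allele (a probe-failure signal;
#' this is also the only route by which a monomorphic panel site can be
#' listed). Untestable sites are never listed by z.
#'
#' @param genomes list of `dtc_genome` in one cluster
#' @param freqs allele-frequency table carrying `af_all` and `af_eur`
#' @param cluster_id id of the cluster the cohort belongs to
#' @param z_crit z threshold (default 4; roughly 600K sites are tested
#'   per cluster, so a conventional 1.96 would drown in false positives)
#' @param n_min minimum called genomes per site (default 30)
#' @param offpanel_max maximum tolerated off-panel call fraction
#'   (default 0.1)
#' @return object of class `dtc_blacklist`: list with `cluster_id`,
#'   `sites` (data.table chrom/pos/key_/reason), `params`
#' @export
build_blacklist <- function(genomes, freqs, cluster_id = NA_character_,
                            z_crit = 4, n_min = 30L, offpanel_max = 0.1) {
  if (length(genomes) < 100) {
    warning("blacklist built from fewer than 100 genomes; ",
            "allele-frequency estimates will be noisy")
  }
  cc <- cohort_counts(genomes, freqs)
  m <- freqs[cc, on = "key_"]
  z_all <- af_zscore(m$k, m$n, m$af_all, n_min = n_min)
  z_eur <- af_zscore(m$k, m$n, m$af_eur, n_min = n_min)

  fail_z <- !is.na(z_all) & !is.na(z_eur) &
    abs(z_all) > z_crit & abs(z_eur) > z_crit
  n_called_any <- m$n + m$n_offpanel
  fail_off <- n_called_any > 0 & m$n_offpanel / n_called_any > offpanel_max

  listed <- fail_z | fail_off
  sites <- data.table::data.table(
    chrom = m$chrom[listed], pos = m$pos[listed], key_ = m$key_[listed],
    reason = ifelse(fail_z[listed], "z_both_panels", "off_panel")
  )
  structure(
    list(cluster_id = cluster_id, sites = sites,
         params = list(z_crit = z_crit, n_min = n_min,
                       offpanel_max = offpanel_max,
                       panels = c("ALL", "EUR"),
                       cohort_size = length(genomes),
                       n_sites_tested = sum(!is.na(z_all) & !is.na(z_eur)))),
    class = "dtc_blacklist"
  )
}

#' @export
print.dtc_blacklist <- function(x, ...) {
  cat(sprintf("<dtc_blacklist cluster=%s: %d sites (z_crit=%g, cohort=%d)>\n",
              x$cluster_id, nrow(x$sites), x$params$z_crit,
              x$params$cohort_size))
  invisible(x)
}

#' Remove blacklisted positions from a genome
#'
#' @param g a `dtc_genome` assigned to the blacklist's cluster
#' @param bl a `dtc_blacklist`
#' @param cluster_id the cluster `g` was assigned to; must match the
#'   blacklist's cluster unless either is `NA`
#' @return list with `genome` (filtered) and `n_removed`
#' @export
apply_blacklist <- function(g, bl, cluster_id = bl$cluster_id) {
  stopifnot(is_genome(g), inherits(bl, "dtc_blacklist"))
  if (!is.na(cluster_id) && !is.na(bl$cluster_id) &&
      cluster_id != bl$cluster_id) {
    stop("cluster mismatch: genome assigned to '", cluster_id,
         "' but blacklist is for '", bl$cluster_id, "'")
  }
  n_in <- nrow(g$records)
  keys <- encode_pos(g$records$chrom, g$records$pos)
  drop <- keys %in% bl$sites$key_
  g$records <- g$records[!drop]
  g <- add_qc_flag(g, "blacklist_applied")
  list(genome = g, n_removed = n_in - nrow(g$records))
}

#' Serialize / load a blacklist as TSV with a parameter header
#'
#' @param bl a `dtc_blacklist`
#' @param path output path
#' @return `path` invisibly (`write_blacklist`); a `dtc_blacklist`
#'   (`read_blacklist`)
#' @export
write_blacklist <- function(bl, path) {
  hdr <- sprintf(
    "# dtcqc blacklist cluster=%s z_crit=%g n_min=%d offpanel_max=%g cohort_size=%d",
    bl$cluster_id, bl$params$z_crit, bl$params$n_min,
    bl$params$offpanel_max, bl$params$cohort_size
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, "chrom\tpos\treason"), con, sep = "\n")
  if (nrow(bl$sites) > 0) {
    writeLines(paste(bl$sites$chrom, bl$sites$pos, bl$sites$reason,
                     sep = "\t"), con, sep = "\n")
  }
  invisible(path)
}

#' @rdname write_blacklist
#' @export
read_blacklist <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  params <- as.list(stats::setNames(sub("^[a-z_]+=", "", kv),
                                    sub("=.*$", "", kv)))
  sites <- data.table::fread(path, skip = 1, sep = "\t",
                             colClasses = list(character = c("chrom", "reason")))
  sites[, key_ := encode_pos(chrom, pos)]
  structure(
    list(cluster_id = params$cluster %||% NA_character_,
         sites = sites,
         params = list(z_crit = as.numeric(params$z_crit),
                       n_min = as.integer(params$n_min),
                       offpanel_max = as.numeric(params$offpanel_max),
                       panels = c("ALL", "EUR"),
                       cohort_size = as.integer(params$cohort_size))),
    class = "dtc_blacklist"
  )
}
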