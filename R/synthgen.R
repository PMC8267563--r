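# Seeded synthetic-data generator: array designs with controlled
# pairwise overlap, Hardy-Weinberg genomes, Mendelian families,
# injected pathologies, and vendor-dialect fixture files.
#
# Everything is a pure function of (arguments, seed); corruption returns
# a manifest of exactly what was planted so tests assert against it.

# Evaluate expr under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Draw n distinct (chrom, pos) keys from a virtual genome of the 22
# autosomes plus X, area-weighted by chromosome length.
sample_positions <- function(n) {
  chroms <- c(as.character(1:22), "X")
  lens <- CHROM_LENGTHS[chroms]
  keys <- numeric(0)
  while (length(keys) < n) {
    m <- ceiling((n - length(keys)) * 1.05) + 10
    u <- sample(sum(lens), m, replace = TRUE)
    ci <- findInterval(u - 1, cumsum(c(0, lens))[seq_along(lens)],
                       rightmost.closed = FALSE)
    pos <- u - cumsum(c(0, lens))[ci]
    keys <- unique(c(keys, encode_pos(chroms[ci], pos)))
  }
  sort(keys[seq_len(n)])
}

site_table <- function(keys) {
  dp <- decode_pos(keys)
  n <- length(keys)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  # alternate allele: uniform over the three non-reference bases
  others <- t(vapply(bases, function(b) setdiff(bases, b), character(3)))
  alt <- others[cbind(match(ref, bases), sample.int(3, n, replace = TRUE))]
  data.table::data.table(
    key_ = keys, chrom = dp$chrom, pos = dp$pos,
    rsid = paste0("rs", format_key_id(keys)),
    ref = ref, alt = alt,
    maf = stats::runif(n, 0.05, 0.5)
  )
}

format_key_id <- function(keys) format(keys, scientific = FALSE, trim = TRUE)

#' Generate array designs with controlled pairwise overlap
#'
#' Designs are built from disjoint position blocks: one core block
#' shared by every design (the smallest requested overlap), one block
#' per design pair carrying its extra overlap, and a private remainder
#' per design. Realized pairwise shared fractions equal the requested
#' ones up to rounding. Per-site ref/alt alleles and minor-allele
#' frequencies (Uniform(0.05, 0.5), the common-variant range arrays
#' target) are shared between designs at shared positions.
#'
#' @param n_designs number of designs
#' @param size positions per design (all designs equal-sized)
#' @param overlap scalar, or `n_designs` x `n_designs` symmetric matrix
#'   of pairwise shared fractions (diagonal ignored)
#' @param seed RNG seed
#' @return list of design objects (`design_id`, `sites` data.table with
#'   key_/chrom/pos/rsid/ref/alt/maf)
#' @export
make_designs <- function(n_designs, size, overlap = 0.5, seed = 1L) {
  if (length(overlap) == 1) {
    overlap <- matrix(overlap, n_designs, n_designs)
  }
  stopifnot(nrow(overlap) == n_designs, ncol(overlap) == n_designs,
            isTRUE(all.equal(overlap, t(overlap))))
  diag(overlap) <- NA
  core_frac <- if (n_designs > 1) min(overlap, na.rm = TRUE) else 0
  extra <- overlap - core_frac
  load_per_design <- core_frac + rowSums(extra, na.rm = TRUE)
  if (any(load_per_design > 1 + 1e-9)) {
    stop("infeasible overlap spec: design block fractions exceed 1 (max ",
         round(max(load_per_design), 3), ")")
  }

  with_seed(seed, {
    core_n <- round(core_frac * size)
    pair_idx <- which(upper.tri(overlap), arr.ind = TRUE)
    pair_n <- round(extra[pair_idx] * size)
    priv_n <- vapply(seq_len(n_designs), function(i) {
      size - core_n - sum(pair_n[pair_idx[, 1] == i | pair_idx[, 2] == i])
    }, numeric(1))
    if (any(priv_n < 0)) {
      stop("infeasible overlap spec after rounding")
    }
    total <- core_n + sum(pair_n) + sum(priv_n)
    keys <- sample_positions(total)
    sites <- site_table(keys)

    # carve the shuffled site table into blocks
    shuffled <- sites[sample(.N)]
    take <- function(n) {
      if (n <= 0) return(shuffled[0])
      out <- shuffled[seq_len(n)]
      shuffled <<- shuffled[-seq_len(n)]
      out
    }
    core <- take(core_n)
    pair_blocks <- lapply(seq_len(nrow(pair_idx)), function(r) take(pair_n[r]))
    priv_blocks <- lapply(priv_n, take)

    lapply(seq_len(n_designs), function(i) {
      mine <- pair_idx[, 1] == i | pair_idx[, 2] == i
      tab <- data.table::rbindlist(c(list(core), pair_blocks[mine],
                                     priv_blocks[i]))
      data.table::setkey(tab, key_)
      list(design_id = paste0("design", i), sites = tab)
    })
  })
}

#' Sample a Hardy-Weinberg genome from an array design
#'
#' Per site, the alternate-allele dosage is Binomial(2, maf); dosage 0
#' is hom-ref, 1 het, 2 hom-alt, all reported on the forward strand.
#'
#' @param design a design from [make_designs()]
#' @param seed RNG seed
#' @param nocall_rate fraction of sites reported as `--` (default 0)
#' @return a `dtc_genome` (`source = "synthetic"`)
#' @export
sample_genome <- function(design, seed = 1L, nocall_rate = 0) {
  s <- design$sites
  with_seed(seed, {
    dosage <- stats::rbinom(nrow(s), 2, s$maf)
    a1 <- ifelse(dosage >= 1, s$alt, s$ref)
    a2 <- ifelse(dosage == 2, s$alt, s$ref)
    nc <- stats::runif(nrow(s)) < nocall_rate
    a1[nc] <- "-"
    a2[nc] <- "-"
    new_genome(
      data.table::data.table(rsid = s$rsid, chrom = s$chrom, pos = s$pos,
                             allele1 = a1, allele2 = a2, nocall = nc),
      source = "synthetic", build = "GRCh37", data_kind = "genotyping"
    )
  })
}

#' Sample a Mendelian child from two parents
#'
#' At every site one allele is drawn uniformly from each parent's
#' genotype. Parents must come from the same design (same position
#' set); sites where either parent is a no-call become no-calls.
#'
#' @param p1,p2 parent `dtc_genome` objects on the same design
#' @param seed RNG seed
#' @return a `dtc_genome`
#' @export
sample_child <- function(p1, p2, seed = 1L) {
  r1 <- p1$records
  r2 <- p2$records
  if (nrow(r1) != nrow(r2) ||
      !all(r1$chrom == r2$chrom & r1$pos == r2$pos)) {
    stop("design mismatch: parents report different position sets")
  }
  with_seed(seed, {
    pick1 <- stats::runif(nrow(r1)) < 0.5
    pick2 <- stats::runif(nrow(r2)) < 0.5
    a1 <- ifelse(pick1, r1$allele1, ifelse(is.na(r1$allele2), r1$allele1,
                                           r1$allele2))
    a2 <- ifelse(pick2, r2$allele1, ifelse(is.na(r2$allele2), r2$allele1,
                                           r2$allele2))
    nc <- r1$nocall | r2$nocall
    a1[nc] <- "-"
    a2[nc] <- "-"
    new_genome(
      data.table::data.table(rsid = r1$rsid, chrom = r1$chrom, pos = r1$pos,
                             allele1 = a1, allele2 = a2, nocall = nc),
      source = "synthetic", build = p1$build, data_kind = "genotyping"
    )
  })
}

#' Inject pathologies into a genome
#'
#' Applies, in order: per-site genotype errors (the first allele is
#' replaced by a different random base, guaranteeing a changed
#' unordered genotype), no-call conversion, global strand complement,
#' invalid-record injection (bad chromosome labels and call characters,
#' caught later by [basic_snp_check()]), and truncation. A manifest
#' records exactly which sites were touched.
#'
#' @param g a `dtc_genome`
#' @param genotype_error,nocall_rate per-site probabilities
#' @param strand_flip logical: complement every call
#' @param n_invalid number of invalid records appended
#' @param truncate_frac fraction of trailing records dropped
#' @param seed RNG seed
#' @return list with `genome` and `manifest` (list: `error_keys`,
#'   `nocall_keys`, `strand_flipped`, `invalid_rsids`, `n_truncated`)
#' @export
corrupt_genome <- function(g, genotype_error = 0, nocall_rate = 0,
                           strand_flip = FALSE, n_invalid = 0L,
                           truncate_frac = 0, seed = 1L) {
  stopifnot(is_genome(g))
  with_seed(seed, {
    rec <- data.table::copy(g$records)
    keys <- encode_pos(rec$chrom, rec$pos)

    err <- which(!rec$nocall & stats::runif(nrow(rec)) < genotype_error)
    if (length(err) > 0) {
      rec$allele1[err] <- vapply(rec$allele1[err], function(a) {
        sample(setdiff(c("A", "C", "G", "T"), a), 1)
      }, character(1))
    }

    nc <- which(!rec$nocall & stats::runif(nrow(rec)) < nocall_rate)
    if (length(nc) > 0) {
      rec$allele1[nc] <- "-"
      rec$allele2[nc] <- "-"
      rec$nocall[nc] <- TRUE
    }

    if (strand_flip) {
      live <- !rec$nocall
      rec$allele1[live] <- complement_alleles(rec$allele1[live])
      sel <- live & !is.na(rec$allele2)
      rec$allele2[sel] <- complement_alleles(rec$allele2[sel])
    }

    n_trunc <- floor(truncate_frac * nrow(rec))
    if (n_trunc > 0) rec <- rec[seq_len(nrow(rec) - n_trunc)]

    invalid_rsids <- character(0)
    if (n_invalid > 0) {
      invalid_rsids <- paste0("bad", seq_len(n_invalid))
      bad <- data.table::data.table(
        rsid = invalid_rsids,
        chrom = sample(c("27", "ZZ", "0"), n_invalid, replace = TRUE),
        pos = sample.int(1000, n_invalid),
        allele1 = sample(c("E", "Z", "X"), n_invalid, replace = TRUE),
        allele2 = sample(c("E", "Z", "X"), n_invalid, replace = TRUE),
        nocall = FALSE
      )
      rec <- rbind(rec, bad)
    }

    out <- new_genome(rec, source = g$source, build = g$build,
                      data_kind = g$data_kind, qc_flags = g$qc_flags)
    list(
      genome = out,
      manifest = list(
        error_keys = keys[err],
        nocall_keys = keys[nc],
        strand_flipped = isTRUE(strand_flip),
        invalid_rsids = invalid_rsids,
        n_truncated = n_trunc
      )
    )
  })
}

#' Inject strand-probe sites into a genome
#'
#' Adds one called record per probe, drawn from the probe's
#' forward-strand allele pair (Hardy-Weinberg at frequency 0.5), so the
#' strand checker has informative sites to score.
#'
#' @param g a `dtc_genome`
#' @param probes table from [read_strand_probes()]
#' @param seed RNG seed
#' @return a `dtc_genome` including the probe records
#' @export
inject_probe_sites <- function(g, probes = read_strand_probes(), seed = 1L) {
  with_seed(seed, {
    pick <- function(a, b) {
      d <- stats::rbinom(length(a), 2, 0.5)
      list(a1 = ifelse(d >= 1, b, a), a2 = ifelse(d == 2, b, a))
    }
    al <- pick(probes$allele_a, probes$allele_b)
    add <- data.table::data.table(
      rsid = paste0("probe", seq_len(nrow(probes))),
      chrom = probes$chrom, pos = probes$pos,
      allele1 = al$a1, allele2 = al$a2, nocall = FALSE
    )
    new_genome(rbind(g$records, add), source = g$source, build = g$build,
               data_kind = g$data_kind, qc_flags = g$qc_flags)
  })
}

#' Inject build-signature sites into a genome
#'
#' Adds the signature rsids at their coordinates for one assembly so
#' build detection can vote.
#'
#' @param g a `dtc_genome`
#' @param build one of `GRCh36`, `GRCh37`, `GRCh38`
#' @param sigs table from [read_build_signatures()]
#' @param seed RNG seed
#' @return a `dtc_genome` including the signature records
#' @export
inject_signature_sites <- function(g, build = "GRCh37",
                                   sigs = read_build_signatures(),
                                   seed = 1L) {
  poscol <- paste0("pos_", tolower(sub("GRCh", "grch", build)))
  stopifnot(poscol %in% names(sigs))
  with_seed(seed, {
    add <- data.table::data.table(
      rsid = sigs$rsid, chrom = sigs$chrom, pos = sigs[[poscol]],
      allele1 = sample(c("A", "G"), nrow(sigs), replace = TRUE),
      allele2 = sample(c("A", "G"), nrow(sigs), replace = TRUE),
      nocall = FALSE
    )
    new_genome(rbind(g$records, add), source = g$source, build = build,
               data_kind = g$data_kind, qc_flags = g$qc_flags)
  })
}

#' Reference allele-frequency table and reference lookup from a design
#'
#' The design's own alternate-allele frequencies become the ALL panel;
#' the EUR panel is an optionally perturbed copy (clamped to [0.01,
#' 0.99]) so dual-panel behaviour is controllable in tests.
#'
#' @param design a design from [make_designs()]
#' @param eur_shift additive perturbation applied to the EUR column
#' @return an allele-frequency table (see [make_allele_freq_table()])
#' @export
design_freq_table <- function(design, eur_shift = 0) {
  s <- design$sites
  make_allele_freq_table(data.table::data.table(
    chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
    af_all = s$maf,
    af_eur = pmin(pmax(s$maf + eur_shift, 0.01), 0.99)
  ))
}

#' @rdname design_freq_table
#' @export
design_reference_lookup <- function(design) {
  s <- design$sites
  make_reference_lookup(s$chrom, s$pos, s$ref)
}

#' Write a genome fixture file, optionally inside a container
#'
#' @param g a `dtc_genome`
#' @param path output path (extension not adjusted)
#' @param dialect a [write_genome()] dialect
#' @param container one of `none`, `gzip`, `bzip2`, `zip`
#' @param ref reference lookup for the `vcf` dialect
#' @param array_style VCF style switch, see [write_genome()]
#' @param n_invalid_lines malformed text lines appended to the body
#'   (exercises the parser's malformed-line accounting)
#' @return `path` invisibly
#' @export
write_fixture <- function(g, path, dialect = "t23andme", container = "none",
                          ref = NULL, array_style = TRUE,
                          n_invalid_lines = 0L) {
  flat <- if (container == "none") path else tempfile("dtcqc_flat")
  write_genome(g, flat, dialect = dialect, ref = ref,
               array_style = array_style)
  if (n_invalid_lines > 0) {
    con <- file(flat, "ab")
    writeLines(rep("this line is not a genotype record", n_invalid_lines),
               con, sep = "\n")
    close(con)
  }
  if (container == "none") return(invisible(path))

  payload <- readBin(flat, "raw", file.size(flat))
  if (container == "gzip") {
    con <- gzfile(path, "wb")
    writeBin(payload, con)
    close(con)
  } else if (container == "bzip2") {
    con <- bzfile(path, "wb")
    writeBin(payload, con)
    close(con)
  } else if (container == "zip") {
    write_zip(path, stats::setNames(list(payload), "genome.txt"))
  } else {
    stop("unknown container: ", container)
  }
  invisible(path)
}
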