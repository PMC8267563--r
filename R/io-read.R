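# Reading raw consumer downloads: container extraction, format triage,
# vendor-dialect parsing, and VCF parsing.

FORMAT_TAGS <- c("t23andme", "ancestry", "ftdna", "myheritage", "decodeme",
                 "vcf", "rejected")

# Fraction of malformed non-header lines above which a file is rejected
# outright instead of dropping the bad lines.
MALFORMED_ABORT_FRACTION <- 0.05

read_magic <- function(path, n = 8L) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n)
}

#' Extract a genotype file from a zip/gzip/bzip2 container
#'
#' Decompresses a container and returns the path of the single inner flat
#' file. Archives must contain exactly one candidate genome file; zip
#' archives that are really Office documents (docx carries
#' `[Content_Types].xml` and a `word/` tree) are rejected, as are
#' archives with zero or multiple candidate members. Plain files pass
#' through unchanged.
#'
#' @param path path to the raw download
#' @param exdir directory for extracted files (default a session tempdir)
#' @return path to the flat file, with attribute `container_kind` in
#'   `none`, `zip`, `gzip`, `bzip2`
#' @export
extract_container <- function(path, exdir = tempfile("dtcqc_extract")) {
  if (file.size(path) == 0) reject("empty file")
  magic <- read_magic(path)

  kind <- "none"
  if (length(magic) >= 4 &&
      magic[1] == 0x50 && magic[2] == 0x4b &&
      magic[3] %in% as.raw(c(0x03, 0x05, 0x07))) {
    kind <- "zip"
  } else if (length(magic) >= 2 && magic[1] == 0x1f && magic[2] == 0x8b) {
    kind <- "gzip"
  } else if (length(magic) >= 3 && rawToChar(magic[1:3]) == "BZh") {
    kind <- "bzip2"
  }

  out <- switch(kind,
    none = path,
    zip = extract_zip(path, exdir),
    gzip = decompress_stream(gzfile(path, "rb"), exdir, path),
    bzip2 = decompress_stream(bzfile(path, "rb"), exdir, path)
  )
  attr(out, "container_kind") <- kind
  out
}

extract_zip <- function(path, exdir) {
  members <- tryCatch(utils::unzip(path, list = TRUE),
                      error = function(e) reject("unreadable zip"))
  names_all <- members$Name
  if (any(grepl("\\[Content_Types\\]\\.xml$", names_all)) ||
      any(grepl("^word/", names_all))) {
    reject("binary document", "zip has Office document structure")
  }
  # drop directories and archiver metadata, keep candidate flat files
  cand <- names_all[!grepl("/$", names_all)]
  cand <- cand[!grepl("^__MACOSX/|(^|/)\\.", cand)]
  if (length(cand) == 0) reject("no genome member")
  if (length(cand) > 1) reject("multiple members")
  dir.create(exdir, recursive = TRUE, showWarnings = FALSE)
  utils::unzip(path, files = cand, exdir = exdir, junkpaths = TRUE)
  file.path(exdir, basename(cand))
}

decompress_stream <- function(con, exdir, orig_path) {
  dir.create(exdir, recursive = TRUE, showWarnings = FALSE)
  out <- file.path(exdir, paste0(sub("\\.(gz|bz2)$", "", basename(orig_path)),
                                 ".flat"))
  ok <- tryCatch({
    dst <- file(out, "wb")
    on.exit(close(dst), add = TRUE)
    repeat {
      chunk <- readBin(con, "raw", 1e6)
      if (length(chunk) == 0) break
      writeBin(chunk, dst)
    }
    TRUE
  }, error = function(e) FALSE, finally = close(con))
  if (!ok || file.size(out) == 0) reject("corrupt container")
  out
}

# Read the leading lines of a text payload, tolerating BOM and CRLF.
read_head_lines <- function(path, n = 250L) {
  lines <- tryCatch(
    suppressWarnings(readLines(path, n = n, encoding = "UTF-8")),
    error = function(e) character()
  )
  clean_lines(lines)
}

clean_lines <- function(lines) {
  if (length(lines) > 0) lines[1] <- sub("^﻿", "", lines[1])
  sub("\r$", "", lines)
}

#' Classify a flat file into a genotype dialect
#'
#' Inspects magic bytes and header/column signatures to decide which
#' parser applies. Rejection (PDF, binary, unrecognizable layout) is a
#' return value, never an error: the tag `"rejected"` carries the reason
#' in attribute `reason`.
#'
#' @param path path to a flattened (non-container) file
#' @return one of `t23andme`, `ancestry`, `ftdna`, `myheritage`,
#'   `decodeme`, `vcf`, `rejected`
#' @export
triage_file <- function(path) {
  if (file.size(path) == 0) return(tag_rejected("empty"))
  magic <- read_magic(path, 512L)
  if (length(magic) >= 4 && rawToChar(magic[1:4]) == "%PDF") {
    return(tag_rejected("pdf"))
  }
  if (length(magic) >= 2 && magic[1] == 0x50 && magic[2] == 0x4b) {
    return(tag_rejected("unextracted container"))
  }
  if (any(magic == as.raw(0))) return(tag_rejected("binary"))

  lines <- read_head_lines(path)
  if (length(lines) == 0) return(tag_rejected("empty"))
  if (any(grepl("^##fileformat=VCF", lines))) return("vcf")

  nonblank <- lines[nzchar(trimws(lines))]
  comments <- nonblank[startsWith(nonblank, "#")]
  body <- nonblank[!startsWith(nonblank, "#")]

  # column-signature matching on the first body line (the header row),
  # falling back to a 23andMe-shaped data line
  if (length(body) > 0) {
    hdr <- tolower(gsub("\"| ", "", body[1]))
    tabs <- strsplit(hdr, "\t", fixed = TRUE)[[1]]
    commas <- strsplit(hdr, ",", fixed = TRUE)[[1]]
    if (identical(tabs[seq_len(min(5, length(tabs)))],
                  c("rsid", "chromosome", "position", "allele1", "allele2")[seq_len(min(5, length(tabs)))]) &&
        length(tabs) >= 5) {
      return("ancestry")
    }
    if (length(commas) >= 4 &&
        identical(commas[1:4], c("rsid", "chromosome", "position", "result"))) {
      # MyHeritage quotes its header and leads with comment lines;
      # FamilyTreeDNA does not. Parsers are identical either way.
      quoted <- startsWith(gsub(" ", "", body[1]), "\"")
      return(if (quoted || length(comments) > 0) "myheritage" else "ftdna")
    }
    if (length(commas) >= 6 &&
        identical(commas[1:6], c("name", "variation", "chromosome",
                                 "position", "strand", "yourcode"))) {
      return("decodeme")
    }
  }
  # 23andMe: header row hides in the comments; recognize either it or a
  # 4-field tab data line whose genotype is a 1-2 symbol call
  if (any(grepl("rsid\tchromosome\tposition\tgenotype", tolower(comments)))) {
    return("t23andme")
  }
  for (ln in utils::head(body, 5)) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) == 4 && grepl("^[0-9]+$", f[3]) &&
        grepl("^[A-Za-z0_-]{1,2}$", f[4])) {
      return("t23andme")
    }
  }
  tag_rejected("unrecognized")
}

tag_rejected <- function(reason) {
  structure("rejected", reason = reason)
}

#' Parse a vendor genotype file into a normalized genome
#'
#' All structurally well-formed lines become genotype records with
#' normalized chromosome labels (vendor numeric codes 23/24/25/26 map to
#' X/Y/XY/MT). Malformed lines are dropped and counted; the file is
#' rejected only when more than 5\% of its non-header lines are
#' unparseable. Call-character validity (beyond basic shape) is left to
#' [basic_snp_check()] so that its exclusion counts stay meaningful.
#'
#' @param path path to a flattened text file
#' @param fmt dialect tag from [triage_file()] (not `vcf`/`rejected`)
#' @return a [new_genome()] object with parse accounting filled in
#' @export
parse_genotype_file <- function(path, fmt) {
  stopifnot(fmt %in% c("t23andme", "ancestry", "ftdna", "myheritage",
                       "decodeme"))
  lines <- clean_lines(suppressWarnings(readLines(path, encoding = "UTF-8")))
  n_input <- length(lines)

  blank <- !nzchar(trimws(lines))
  comment <- startsWith(lines, "#")
  body <- lines[!blank & !comment]
  n_header <- sum(blank | comment)

  qc_flags <- header_build_flag(lines[comment])

  sep <- if (fmt %in% c("t23andme", "ancestry")) "\t" else ","
  fields <- data.table::tstrsplit(body, sep, fixed = TRUE)
  nf <- length(fields)
  # per-line field count (trailing empty fields still count)
  cnt <- rowSums(!vapply(fields, is.na, logical(length(body))))

  spec <- dialect_spec(fmt)
  # drop the header row if present
  is_hdr <- logical(length(body))
  if (length(body) > 0) {
    first <- tolower(gsub("\"| ", "", body[1]))
    if (grepl(spec$header_regex, first)) is_hdr[1] <- TRUE
  }
  n_header <- n_header + sum(is_hdr)

  keep <- !is_hdr & cnt >= spec$min_fields & nf >= spec$min_fields
  if (nf < spec$min_fields) keep[] <- FALSE
  get_col <- function(i) {
    v <- if (i <= nf) fields[[i]][keep] else rep(NA_character_, sum(keep))
    gsub("\"", "", trimws(v))
  }

  rsid <- get_col(spec$col$rsid)
  chrom_raw <- get_col(spec$col$chrom)
  pos_raw <- get_col(spec$col$pos)
  if (!is.null(spec$col$genotype)) {
    geno <- get_col(spec$col$genotype)
    geno[is.na(geno)] <- ""
    a1 <- toupper(substr(geno, 1, 1))
    a2 <- toupper(substr(geno, 2, 2))
    a2[nchar(geno) < 2] <- NA_character_
    call_ok <- grepl("^[A-Za-z0_-]{0,2}$", geno)
  } else {
    a1 <- toupper(get_col(spec$col$allele1))
    a2 <- toupper(get_col(spec$col$allele2))
    a2[is.na(a2) | a2 == ""] <- NA_character_
    call_ok <- grepl("^[A-Za-z0_-]?$", a1) &
      (is.na(a2) | grepl("^[A-Za-z0_-]$", a2))
    a1[a1 == ""] <- "-"
  }

  pos <- suppressWarnings(as.integer(pos_raw))
  valid <- !is.na(pos) & pos >= 1 & nzchar(rsid) & !is.na(rsid) & call_ok

  n_body <- length(body) - sum(is_hdr)
  n_malformed <- sum(!keep & !is_hdr) + sum(!valid)
  if (n_body > 0 && n_malformed / n_body > MALFORMED_ABORT_FRACTION) {
    reject("unparseable",
           sprintf("%d of %d lines malformed", n_malformed, n_body))
  }

  chrom <- normalize_chrom(chrom_raw)
  chrom[is.na(chrom)] <- toupper(trimws(chrom_raw[is.na(chrom)]))

  geno_pair <- paste0(a1, ifelse(is.na(a2), "", a2))
  nocall <- geno_pair %in% NOCALL_CODES | a1 %in% c("-", "_", "0")

  rec <- data.table::data.table(
    rsid = rsid, chrom = chrom, pos = pos,
    allele1 = a1, allele2 = a2, nocall = nocall
  )[valid]

  new_genome(rec,
             source = fmt,
             n_input_lines = n_input,
             n_parsed = nrow(rec),
             n_rejected_records = n_malformed,
             qc_flags = qc_flags)
}

dialect_spec <- function(fmt) {
  switch(fmt,
    t23andme = list(
      header_regex = "^rsid\tchromosome\tposition\tgenotype",
      min_fields = 4L,
      col = list(rsid = 1L, chrom = 2L, pos = 3L, genotype = 4L)
    ),
    ancestry = list(
      header_regex = "^rsid\tchromosome\tposition\tallele1\tallele2",
      min_fields = 5L,
      col = list(rsid = 1L, chrom = 2L, pos = 3L, allele1 = 4L, allele2 = 5L)
    ),
    ftdna = ,
    myheritage = list(
      header_regex = "^rsid,chromosome,position,result",
      min_fields = 4L,
      col = list(rsid = 1L, chrom = 2L, pos = 3L, genotype = 4L)
    ),
    decodeme = list(
      header_regex = "^name,variation,chromosome,position,strand,yourcode",
      min_fields = 6L,
      col = list(rsid = 1L, chrom = 3L, pos = 4L, genotype = 6L)
    )
  )
}

# Pull an assembly declaration out of vendor header comments.
header_build_flag <- function(comment_lines) {
  if (length(comment_lines) == 0) return(character())
  txt <- tolower(paste(comment_lines, collapse = " "))
  m <- regmatches(txt, regexpr("(grch|build[^0-9]{0,10})3[678]", txt))
  if (length(m) == 0) return(character())
  num <- regmatches(m, regexpr("3[678]$", m))
  paste0("header_build=GRCh", num)
}

#' Parse a single-sample VCF into a normalized genome
#'
#' One record per VCF row; homozygous-reference genotypes are retained
#' because the NGS-versus-array triage depends on them. Multi-sample
#' VCFs are rejected (this is a single-genome tool). Multi-base REF/ALT
#' alleles are collapsed to the insertion/deletion codes `I`/`D` used by
#' array vendors. Per-file statistics needed by [classify_vcf()] are
#' attached as `$vcf_stats`.
#'
#' @param path path to a VCF file (plain or gzipped)
#' @return a [new_genome()] object with `source = "vcf"`,
#'   `data_kind = "undetermined"` and a `vcf_stats` element
#' @export
parse_vcf_file <- function(path) {
  v <- tryCatch(
    suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE)),
    error = function(e) reject("malformed vcf", conditionMessage(e))
  )
  fix <- v@fix
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2) reject("malformed vcf", "no sample column")
  if (ncol(gt) > 2) reject("multi-sample vcf")
  if (nrow(fix) == 0) reject("malformed vcf", "no data rows")

  chrom <- normalize_chrom(fix[, "CHROM"])
  chrom[is.na(chrom)] <- toupper(fix[is.na(chrom), "CHROM"])
  pos <- as.integer(fix[, "POS"])
  id <- fix[, "ID"]
  id[is.na(id) | id == "."] <- paste0("pos", pos[is.na(id) | id == "."])
  ref_al <- toupper(fix[, "REF"])
  alt_al <- toupper(fix[, "ALT"])
  alt_missing <- is.na(alt_al) | alt_al %in% c(".", "")

  gt_field <- sub(":.*$", "", gt[, 2])
  parts <- data.table::tstrsplit(gt_field, "[/|]")
  i1 <- suppressWarnings(as.integer(parts[[1]]))
  i2 <- if (length(parts) >= 2) suppressWarnings(as.integer(parts[[2]])) else rep(NA_integer_, length(i1))

  alt_split <- strsplit(ifelse(alt_missing, "", alt_al), ",", fixed = TRUE)
  allele_of <- function(idx) {
    out <- rep(NA_character_, length(idx))
    is_ref <- !is.na(idx) & idx == 0L
    out[is_ref] <- ref_al[is_ref]
    sel <- which(!is.na(idx) & idx >= 1L)
    out[sel] <- vapply(sel, function(r) {
      a <- alt_split[[r]]
      if (idx[r] <= length(a)) a[idx[r]] else NA_character_
    }, character(1))
    out
  }
  a1 <- allele_of(i1)
  a2 <- allele_of(i2)

  squash <- function(x) {
    long <- !is.na(x) & nchar(x) > 1
    x[long] <- "I"
    x[!is.na(x) & x == "*"] <- "D"
    x
  }
  a1 <- squash(a1)
  a2 <- squash(a2)

  nocall <- is.na(a1) & is.na(a2)
  a1[nocall] <- "-"
  a2[nocall] <- "-"

  homref <- !nocall & !is.na(i1) & i1 == 0L & (!is.na(i2) & i2 == 0L)
  stats <- list(
    n_rows = nrow(fix),
    frac_homref = mean(homref),
    frac_missing_alt = mean(alt_missing)
  )

  g <- new_genome(
    data.table::data.table(rsid = id, chrom = chrom, pos = pos,
                           allele1 = a1, allele2 = a2, nocall = nocall),
    source = "vcf",
    data_kind = "undetermined",
    n_input_lines = nrow(fix),
    n_parsed = nrow(fix),
    n_rejected_records = 0L
  )
  g$vcf_stats <- stats
  g
}
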