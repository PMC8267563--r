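# Deterministic serialization of normalized genomes back to vendor
# dialects and a VCF-like form; the parsers round-trip these exactly.

#' Write a genome in a vendor dialect or VCF form
#'
#' Serialization is deterministic and round-trips: parsing the written
#' file reproduces the genome's records (alleles and no-call flags)
#' exactly. The `vcf` dialect needs the per-position reference base to
#' emit REF/ALT columns; rows without a reference base are written with
#' the call alleles as REF/ALT placeholders only when `ref` is `NULL`.
#'
#' @param g a `dtc_genome`
#' @param path output file path
#' @param dialect one of `t23andme`, `ancestry`, `ftdna`, `myheritage`,
#'   `decodeme`, `vcf`
#' @param ref optional reference lookup (see [read_reference_lookup()])
#'   used by the `vcf` dialect
#' @param array_style logical; for the `vcf` dialect, write
#'   genotype-array style rows (hom-ref rows kept, ALT left `.` when the
#'   call carries no non-reference allele) instead of NGS style
#'   (variant rows only, ALT always stated)
#' @return `path`, invisibly
#' @export
write_genome <- function(g, path, dialect = "t23andme", ref = NULL,
                         array_style = TRUE) {
  stopifnot(is_genome(g))
  rec <- g$records
  con <- file(path, "wb")  # binary: fixed "\n" endings for determinism
  on.exit(close(con))

  emit <- function(lines) writeLines(lines, con, sep = "\n")
  pair <- function() paste0(rec$allele1, ifelse(is.na(rec$allele2), "", rec$allele2))

  if (dialect == "t23andme") {
    emit(c(paste0("# This data file generated by dtcqc (source=", g$source,
                  ", build=", g$build, ")"),
           "# rsid\tchromosome\tposition\tgenotype"))
    if (nrow(rec) > 0) {
      emit(paste(rec$rsid, rec$chrom, rec$pos, pair(), sep = "\t"))
    }
  } else if (dialect == "ancestry") {
    emit(c(paste0("#AncestryDNA-style raw data (dtcqc, build=", g$build, ")"),
           "rsid\tchromosome\tposition\tallele1\tallele2"))
    if (nrow(rec) > 0) {
      chrom_num <- vendor_numeric_chrom(rec$chrom)
      a2 <- ifelse(is.na(rec$allele2), "", rec$allele2)
      emit(paste(rec$rsid, chrom_num, rec$pos, rec$allele1, a2, sep = "\t"))
    }
  } else if (dialect %in% c("ftdna", "myheritage")) {
    # FamilyTreeDNA writes bare CSV; MyHeritage quotes fields and leads
    # with a comment line — that difference is what triage keys on
    q <- if (dialect == "myheritage") {
      function(x) paste0("\"", x, "\"")
    } else identity
    if (dialect == "myheritage") {
      emit(paste0("# MyHeritage-style raw data (dtcqc, build=", g$build, ")"))
    }
    emit(paste(q("RSID"), q("CHROMOSOME"), q("POSITION"), q("RESULT"),
               sep = ","))
    if (nrow(rec) > 0) {
      emit(paste(q(rec$rsid), q(rec$chrom), q(rec$pos), q(pair()), sep = ","))
    }
  } else if (dialect == "decodeme") {
    emit("Name,Variation,Chromosome,Position,Strand,YourCode")
    if (nrow(rec) > 0) {
      a2 <- ifelse(is.na(rec$allele2), rec$allele1, rec$allele2)
      variation <- ifelse(rec$nocall, "?/?", paste0(rec$allele1, "/", a2))
      emit(paste(rec$rsid, variation, rec$chrom, rec$pos, "+", pair(),
                 sep = ","))
    }
  } else if (dialect == "vcf") {
    write_vcf_body(g, emit, ref, array_style)
  } else {
    stop("unknown output dialect: ", dialect)
  }
  invisible(path)
}

# AncestryDNA numeric chromosome codes on output.
vendor_numeric_chrom <- function(chrom) {
  out <- chrom
  out[chrom == "X"] <- "23"
  out[chrom == "Y"] <- "24"
  out[chrom == "XY"] <- "25"
  out[chrom == "MT"] <- "26"
  out
}

write_vcf_body <- function(g, emit, ref, array_style) {
  rec <- data.table::copy(g$records)
  emit(c("##fileformat=VCFv4.2",
         paste0("##source=dtcqc"),
         paste0("##reference=", g$build),
         "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
         "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tSAMPLE1"))
  if (nrow(rec) == 0) return(invisible())

  if (!is.null(ref)) {
    rec[, key_ := encode_pos(chrom, pos)]
    rec[, ref := ref_base(ref, key_)]
  } else {
    rec[, ref := ifelse(nocall, NA_character_, allele1)]
  }
  ok_call <- rec$nocall |
    (rec$allele1 %in% c("A", "C", "G", "T") &
       (is.na(rec$allele2) | rec$allele2 %in% c("A", "C", "G", "T")))
  rec <- rec[!is.na(ref) & ok_call]
  if (nrow(rec) == 0) return(invisible())

  a1 <- rec$allele1
  a2 <- rec$allele2
  # first non-reference allele becomes ALT; biallelic contract
  alt <- rep(".", nrow(rec))
  nc <- rec$nocall
  cand1 <- !nc & a1 != rec$ref
  alt[cand1] <- a1[cand1]
  cand2 <- !nc & alt == "." & !is.na(a2) & a2 != rec$ref
  alt[cand2] <- a2[cand2]

  idx <- function(a) ifelse(a == rec$ref, "0", "1")
  gt <- ifelse(nc, ifelse(is.na(a2), ".", "./."),
               ifelse(is.na(a2), idx(a1), paste0(idx(a1), "/", idx(a2))))

  keep <- rep(TRUE, nrow(rec))
  if (!array_style) keep <- !nc & alt != "."  # NGS style: variants only
  emit(paste(rec$chrom[keep], rec$pos[keep], rec$rsid[keep], rec$ref[keep],
             alt[keep], ".", "PASS", ".", "GT", gt[keep], sep = "\t"))
  invisible()
}
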