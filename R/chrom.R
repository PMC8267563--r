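# Chromosome label normalization and position encoding.
#
# All parsed data use labels in {1..22, X, Y, XY, MT}. Vendors differ:
# AncestryDNA emits numeric codes 23-26 for X/Y/pseudoautosomal/mito,
# VCFs may carry a "chr" prefix, and mitochondria appears as M, MT or 26.

CHROM_LABELS <- c(as.character(1:22), "X", "Y", "XY", "MT")

#' Normalize chromosome labels
#'
#' Maps vendor and VCF chromosome spellings onto the canonical label set
#' `{1..22, X, Y, XY, MT}`. Recognized inputs: optional `chr` prefix,
#' numeric codes 23/24/25/26 (X, Y, pseudoautosomal XY, mitochondrial),
#' `M`/`MT` and lower-case variants. Unrecognized labels map to `NA`.
#' The mapping is idempotent.
#'
#' @param x character vector of raw chromosome labels
#' @return character vector over `{1..22, X, Y, XY, MT}` with `NA` for
#'   invalid labels
#' @export
#' @examples
#' normalize_chrom(c("chr1", "23", "M", "x", "27"))
normalize_chrom <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- sub("^CHR", "", x)
  x[x == "23"] <- "X"
  x[x == "24"] <- "Y"
  x[x == "25"] <- "XY"
  x[x %in% c("26", "M")] <- "MT"
  x[!(x %in% CHROM_LABELS)] <- NA_character_
  x
}

# Integer index 1..26 used for sorting and position encoding.
chrom_index <- function(chrom) {
  match(chrom, CHROM_LABELS)
}

# GRCh37 chromosome lengths; the pseudoautosomal "XY" label shares the X
# coordinate system. Used for out-of-range checks and the synthetic genome.
CHROM_LENGTHS <- c(
  `1` = 249250621, `2` = 243199373, `3` = 198022430, `4` = 191154276,
  `5` = 180915260, `6` = 171115067, `7` = 159138663, `8` = 146364022,
  `9` = 141213431, `10` = 135534747, `11` = 135006516, `12` = 133851895,
  `13` = 115169878, `14` = 107349540, `15` = 102531392, `16` = 90354753,
  `17` = 81195210, `18` = 78077248, `19` = 59128983, `20` = 63025520,
  `21` = 48129895, `22` = 51304566, X = 155270560, Y = 59373566,
  XY = 155270560, MT = 16569
)

#' Encode (chrom, pos) pairs as sortable numeric keys
#'
#' One double per site: `chrom_index * 2^28 + pos`. Positions fit in 28
#' bits (longest chromosome < 2.5e8) and the product stays well inside
#' the exactly-representable double range, so keys are unique and order
#' by (chrom, pos).
#'
#' @param chrom normalized chromosome labels
#' @param pos 1-based positions
#' @return numeric vector of keys
#' @export
encode_pos <- function(chrom, pos) {
  chrom_index(chrom) * 2^28 + as.numeric(pos)
}

#' @rdname encode_pos
#' @param key numeric keys from `encode_pos`
#' @return `decode_pos`: a data.table with columns `chrom`, `pos`
#' @export
decode_pos <- function(key) {
  idx <- key %/% 2^28
  data.table::data.table(chrom = CHROM_LABELS[idx], pos = as.integer(key %% 2^28))
}

# Complement map for strand fixing; no-call and indel codes are fixed points.
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                I = "I", D = "D", `-` = "-", `0` = "0", `_` = "_")

complement_alleles <- function(x) {
  out <- COMPLEMENT[x]
  out[is.na(out)] <- x[is.na(out)]
  unname(out)
}
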