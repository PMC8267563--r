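# Minimal stored (uncompressed) zip archive writer, used by the fixture
# generator to wrap genome files the way consumers upload them. Writing
# only; reading goes through utils::unzip.

u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
u32 <- function(x) {
  # two 16-bit halves: R integers cannot hold unsigned 32-bit values
  lo <- x %% 65536
  hi <- x %/% 65536
  c(u16(lo), u16(hi))
}

#' Write a stored zip archive
#'
#' @param path output archive path
#' @param members named list: member name -> raw vector or text
#'   (character vectors are joined with `\n` and terminated)
#' @return `path` invisibly
#' @export
write_zip <- function(path, members) {
  stopifnot(length(members) > 0, !is.null(names(members)))
  con <- file(path, "wb")
  on.exit(close(con))

  offsets <- integer(0)
  central <- list()
  written <- 0L

  for (nm in names(members)) {
    data <- members[[nm]]
    if (is.character(data)) {
      data <- charToRaw(paste0(paste(data, collapse = "\n"), "\n"))
    }
    crc <- .crc32(data)
    name_raw <- charToRaw(nm)
    local_hdr <- c(
      as.raw(c(0x50, 0x4b, 0x03, 0x04)),
      u16(20), u16(0), u16(0),        # version, flags, method=stored
      u16(0), u16(0),                  # mod time/date
      u32(crc), u32(length(data)), u32(length(data)),
      u16(length(name_raw)), u16(0)
    )
    offsets <- c(offsets, written)
    writeBin(c(local_hdr, name_raw, data), con)
    written <- written + length(local_hdr) + length(name_raw) + length(data)
    central[[nm]] <- c(
      as.raw(c(0x50, 0x4b, 0x01, 0x02)),
      u16(20), u16(20), u16(0), u16(0),
      u16(0), u16(0),
      u32(crc), u32(length(data)), u32(length(data)),
      u16(length(name_raw)), u16(0), u16(0),
      u16(0), u16(0), u32(0),
      u32(offsets[length(offsets)]),
      name_raw
    )
  }

  cd_start <- written
  for (entry in central) {
    writeBin(entry, con)
    written <- written + length(entry)
  }
  eocd <- c(
    as.raw(c(0x50, 0x4b, 0x05, 0x06)),
    u16(0), u16(0),
    u16(length(central)), u16(length(central)),
    u32(written - cd_start), u32(cd_start),
    u16(0)
  )
  writeBin(eocd, con)
  invisible(path)
}
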