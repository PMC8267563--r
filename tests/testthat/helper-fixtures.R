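# Shared fixture builders. Everything is generated in code under fixed
# seeds; nothing is stored on disk.

# A small pair of half-overlapping designs reused across files.
fixture_designs <- function(seed = 101, size = 2000, n = 2, overlap = 0.5) {
  make_designs(n, size, overlap = overlap, seed = seed)
}

# One clean genotyping genome on design 1 of the pair.
fixture_genome <- function(seed = 11, nocall_rate = 0.02, size = 2000) {
  d <- fixture_designs(size = size)[[1]]
  sample_genome(d, seed = seed, nocall_rate = nocall_rate)
}

# Hand-built genome from explicit records (bypasses the generator).
manual_genome <- function(rsid, chrom, pos, a1, a2 = NULL, nocall = NULL,
                          ...) {
  if (is.null(a2)) a2 <- rep(NA_character_, length(a1))
  pairstr <- paste0(a1, ifelse(is.na(a2), "", a2))
  if (is.null(nocall)) nocall <- pairstr %in% c("--", "-", "__", "_", "00", "0", "")
  new_genome(data.table::data.table(
    rsid = rsid, chrom = chrom, pos = pos,
    allele1 = a1, allele2 = a2, nocall = nocall
  ), ...)
}

# Small config so generator-scale genomes pass the record-count gate.
test_config <- function(...) {
  qc_config(min_records = 100, ...)
}
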