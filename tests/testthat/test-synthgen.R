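# The synthetic-data generator itself: determinism, overlap realization,
# HWE sampling, Mendelian transmission, corruption manifests.

test_that("the generator is deterministic per seed", {
  d1 <- make_designs(2, 1000, overlap = 0.4, seed = 5)
  d2 <- make_designs(2, 1000, overlap = 0.4, seed = 5)
  expect_identical(d1[[1]]$sites, d2[[1]]$sites)
  expect_identical(d1[[2]]$sites, d2[[2]]$sites)
  d3 <- make_designs(2, 1000, overlap = 0.4, seed = 6)
  expect_false(identical(d1[[1]]$sites$key_, d3[[1]]$sites$key_))

  g1 <- sample_genome(d1[[1]], seed = 9, nocall_rate = 0.05)
  g2 <- sample_genome(d1[[1]], seed = 9, nocall_rate = 0.05)
  expect_identical(g1$records, g2$records)

  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fixture(g1, f1, dialect = "ancestry")
  write_fixture(g1, f2, dialect = "ancestry")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("pairwise overlap fractions are realized within 1%", {
  size <- 10000
  d <- make_designs(2, size, overlap = 0.5, seed = 15)
  shared <- (2 * size - delta_n(d[[1]]$sites$key_, d[[2]]$sites$key_)) / 2
  expect_gte(shared / size, 0.49)
  expect_lte(shared / size, 0.51)

  ident <- make_designs(2, 2000, overlap = 1, seed = 16)
  expect_identical(ident[[1]]$sites$key_, ident[[2]]$sites$key_)

  ov <- matrix(0.2, 3, 3); diag(ov) <- 1
  ov[1, 2] <- ov[2, 1] <- 0.7
  d3 <- make_designs(3, size, overlap = ov, seed = 17)
  sh <- function(i, j) {
    (2 * size - delta_n(d3[[i]]$sites$key_, d3[[j]]$sites$key_)) / (2 * size)
  }
  expect_lt(abs(sh(1, 2) - 0.7), 0.01)
  expect_lt(abs(sh(1, 3) - 0.2), 0.01)
  expect_lt(abs(sh(2, 3) - 0.2), 0.01)

  # two 90% overlaps with a 10% third pair cannot fit in one design
  bad <- matrix(0.1, 3, 3); diag(bad) <- 1
  bad[1, 2] <- bad[2, 1] <- 0.9
  bad[1, 3] <- bad[3, 1] <- 0.9
  expect_error(make_designs(3, 1000, overlap = bad, seed = 1), "infeasible")
})

test_that("designs draw valid unique positions and MAFs in range", {
  d <- make_designs(1, 5000, seed = 25)[[1]]
  s <- d$sites
  expect_equal(anyDuplicated(s$key_), 0)
  expect_true(all(s$maf >= 0.05 & s$maf <= 0.5))
  expect_true(all(s$ref != s$alt))
  expect_true(all(s$pos >= 1))
  expect_true(all(s$pos <= CHROM_LENGTHS[s$chrom]))
})

test_that("HWE sampling matches its closed-form genotype frequencies", {
  d <- make_designs(1, 20000, seed = 35)[[1]]
  d$sites$maf <- 0
  g0 <- sample_genome(d, seed = 36)
  expect_true(all(g0$records$allele1 == d$sites$ref &
                    g0$records$allele2 == d$sites$ref))

  d$sites$maf <- 0.5
  g <- sample_genome(d, seed = 37)
  homref <- mean(g$records$allele1 == d$sites$ref &
                   g$records$allele2 == d$sites$ref)
  se <- sqrt(0.25 * 0.75 / 20000)
  expect_lt(abs(homref - 0.25), 3 * se)
})

test_that("children are Mendelian-consistent at every site", {
  d <- make_designs(1, 5000, seed = 45)[[1]]
  p1 <- sample_genome(d, seed = 46)
  p2 <- sample_genome(d, seed = 47)
  ch <- sample_child(p1, p2, seed = 48)
  ok <- mapply(function(c1, c2, a1, a2, b1, b2) {
    (c1 %in% c(a1, a2) & c2 %in% c(b1, b2)) |
      (c2 %in% c(a1, a2) & c1 %in% c(b1, b2))
  }, ch$records$allele1, ch$records$allele2,
     p1$records$allele1, p1$records$allele2,
     p2$records$allele1, p2$records$allele2)
  expect_true(all(ok))

  aa <- manual_genome("r1", "1", 10L, "A", "A")
  gg <- manual_genome("r1", "1", 10L, "G", "G")
  expect_equal(sort(unlist(sample_child(aa, gg, seed = 1)$records[, .(allele1, allele2)])),
               c(allele1 = "A", allele2 = "G"))
  expect_error(sample_child(p1, manual_genome("x", "1", 1L, "A", "A"), 1),
               "design mismatch")
})

test_that("corruption rates match their manifests and zero rates are identity", {
  d <- make_designs(1, 10000, seed = 55)[[1]]
  g <- sample_genome(d, seed = 56)

  out <- corrupt_genome(g, nocall_rate = 0.1, seed = 57)
  n_nc <- length(out$manifest$nocall_keys)
  expect_lt(abs(n_nc - 1000), 3 * sqrt(10000 * 0.1 * 0.9))
  expect_equal(sum(out$genome$records$nocall), n_nc)

  err <- corrupt_genome(g, genotype_error = 0.02, seed = 58)
  changed <- encode_pos(g$records$chrom, g$records$pos)[
    g$records$allele1 != err$genome$records$allele1]
  expect_equal(sort(changed), sort(err$manifest$error_keys))

  idgen <- corrupt_genome(g, seed = 59)
  expect_identical(idgen$genome$records, g$records)
  expect_equal(length(idgen$manifest$error_keys), 0)
  expect_false(idgen$manifest$strand_flipped)

  tr <- corrupt_genome(g, truncate_frac = 0.25, seed = 60)
  expect_equal(nrow(tr$genome$records), 7500)
  expect_equal(tr$manifest$n_truncated, 2500)
})

test_that("array-converted VCF fixtures are mostly hom-ref by construction", {
  d <- make_designs(1, 3000, seed = 65)[[1]]
  g <- sample_genome(d, seed = 66)
  f <- withr::local_tempfile()
  write_fixture(g, f, dialect = "vcf", ref = design_reference_lookup(d),
                array_style = TRUE)
  st <- parse_vcf_file(f)$vcf_stats
  expect_gt(st$frac_homref, 0.5)
  expect_gt(st$frac_missing_alt, 0.5)
})
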