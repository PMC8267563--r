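# Basic SNP filtering and allele-frequency blacklisting.

test_that("basic SNP check excludes by reason and conserves counts", {
  g <- manual_genome(
    rsid = c("ok1", "ok2", "badchrom", "badpos", "badcall", "nc"),
    chrom = c("1", "X", "27", "1", "2", "3"),
    pos = c(100L, 200L, 300L, 999999999L, 400L, 500L),
    a1 = c("A", "I", "A", "A", "E", "-"),
    a2 = c("G", "D", "A", "A", "E", "-")
  )
  out <- basic_snp_check(g)
  expect_equal(unname(out$counts["invalid_chrom"]), 1)
  expect_equal(unname(out$counts["out_of_range"]), 1)
  expect_equal(unname(out$counts["invalid_call"]), 1)
  expect_equal(unname(out$counts["nocall"]), 1)
  expect_equal(unname(out$counts["kept"]), 2)
  expect_equal(sum(out$counts[c("invalid_chrom", "out_of_range",
                                "invalid_call", "nocall", "kept")]),
               unname(out$counts["input"]))
  expect_equal(sort(out$genome$records$rsid), c("ok1", "ok2"))
})

test_that("cohort counts match hand-tallied genotypes and skip no-calls", {
  freqs <- make_allele_freq_table(data.frame(
    chrom = c("1", "1"), pos = c(100L, 200L), ref = c("A", "C"),
    alt = c("G", "T"), af_all = c(0.3, 0.2), af_eur = c(0.3, 0.2)))
  g1 <- manual_genome("r1", "1", 100L, "A", "A")
  g2 <- manual_genome("r1", "1", 100L, "A", "G")
  g3 <- manual_genome(c("r1", "r2"), c("1", "1"), c(100L, 200L),
                      c("G", "-"), c("G", "-"))
  cc <- cohort_counts(list(g1, g2, g3), freqs)
  site1 <- cc[pos == 100L]
  expect_equal(site1$k, 3L)
  expect_equal(site1$n, 3L)
  # no-call at site 2: nobody contributes
  expect_equal(cc[pos == 200L, n], 0L)

  # off-panel alleles counted separately, excluded from k and n
  g4 <- manual_genome("r1", "1", 100L, "C", "C")
  cc2 <- cohort_counts(list(g1, g4), freqs)
  expect_equal(cc2[pos == 100L, .(k, n, n_offpanel)],
               data.table::data.table(k = 0L, n = 1L, n_offpanel = 1L))
})

test_that("z statistic matches the closed form and its null calibration", {
  expect_equal(af_zscore(30, 50, 0.3, n_min = 10), 0)
  expect_equal(af_zscore(60, 50, 0.5, n_min = 10), 2.0)
  expect_true(is.na(af_zscore(5, 50, 0, n_min = 10)))   # monomorphic panel
  expect_true(is.na(af_zscore(5, 5, 0.3, n_min = 30)))  # below n_min

  # under the null, |z| > crit fires at about the normal two-sided rate
  set.seed(12021)
  n <- 60; p0 <- 0.35; zc <- 2
  k <- rbinom(1e5, 2 * n, p0)
  rate <- mean(abs(af_zscore(k, n, p0, n_min = 10)) > zc)
  expected <- 2 * pnorm(-zc)
  expect_lt(abs(rate - expected), 4 * sqrt(expected * (1 - expected) / 1e5))
})

test_that("blacklist requires failure on both panels", {
  d <- make_designs(1, 400, seed = 71)[[1]]
  cohort <- lapply(1:40, function(i) sample_genome(d, seed = 700 + i))

  # ALL panel frequencies grossly wrong, EUR panel correct:
  # single-panel failure must not blacklist
  s <- d$sites
  freqs_all_wrong <- make_allele_freq_table(data.frame(
    chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
    af_all = pmin(s$maf + 0.45, 0.97), af_eur = s$maf))
  bl1 <- suppressWarnings(build_blacklist(cohort, freqs_all_wrong, "c1",
                                          z_crit = 4, n_min = 10))
  # nearly every site fails ALL, but almost none also fails the correct
  # EUR panel, so the dual-panel rule keeps the list near-empty
  expect_lt(nrow(bl1$sites), 0.05 * nrow(s))

  # both panels wrong: essentially every site fails
  freqs_both_wrong <- make_allele_freq_table(data.frame(
    chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
    af_all = pmin(s$maf + 0.45, 0.97), af_eur = pmin(s$maf + 0.45, 0.97)))
  bl2 <- suppressWarnings(build_blacklist(cohort, freqs_both_wrong, "c1",
                                          z_crit = 4, n_min = 10))
  expect_gt(nrow(bl2$sites), 0.9 * nrow(s))

  # dual-panel blacklist is a subset of each single-panel blacklist
  cc <- cohort_counts(cohort, freqs_both_wrong)
  m <- freqs_both_wrong[cc, on = "key_"]
  fail_all <- abs(af_zscore(m$k, m$n, m$af_all, n_min = 10)) > 4
  fail_eur <- abs(af_zscore(m$k, m$n, m$af_eur, n_min = 10)) > 4
  z_listed <- bl2$sites[reason == "z_both_panels", key_]
  expect_true(all(z_listed %in% m$key_[which(fail_all)]))
  expect_true(all(z_listed %in% m$key_[which(fail_eur)]))
})

test_that("off-panel probe failures are blacklisted independently", {
  d <- make_designs(1, 200, seed = 81)[[1]]
  s <- d$sites
  freqs <- design_freq_table(d)
  cohort <- lapply(1:40, function(i) sample_genome(d, seed = 800 + i))
  # corrupt one site in every genome to an allele outside {ref, alt}
  bad_site <- 7L
  bad_allele <- setdiff(c("A", "C", "G", "T"),
                        c(s$ref[bad_site], s$alt[bad_site]))[1]
  cohort <- lapply(cohort, function(g) {
    rec <- data.table::copy(g$records)
    i <- which(rec$chrom == s$chrom[bad_site] & rec$pos == s$pos[bad_site])
    rec$allele1[i] <- bad_allele
    rec$allele2[i] <- bad_allele
    new_genome(rec, source = g$source)
  })
  bl <- suppressWarnings(build_blacklist(cohort, freqs, "c1",
                                         z_crit = 4, n_min = 10))
  expect_true(encode_pos(s$chrom[bad_site], s$pos[bad_site]) %in%
                bl$sites[reason == "off_panel", key_])
})

test_that("applying a blacklist removes exactly the listed sites", {
  g <- fixture_genome(seed = 91, nocall_rate = 0)
  empty <- structure(list(cluster_id = "c1",
                          sites = data.table::data.table(
                            chrom = character(0), pos = integer(0),
                            key_ = numeric(0), reason = character(0)),
                          params = list()), class = "dtc_blacklist")
  out <- apply_blacklist(g, empty, cluster_id = "c1")
  expect_equal(out$n_removed, 0L)
  expect_identical(out$genome$records, g$records)

  all_sites <- structure(list(cluster_id = "c1",
                              sites = data.table::data.table(
                                chrom = g$records$chrom, pos = g$records$pos,
                                key_ = position_set(g),
                                reason = "z_both_panels"),
                              params = list()), class = "dtc_blacklist")
  out2 <- apply_blacklist(g, all_sites, cluster_id = "c1")
  expect_equal(nrow(out2$genome$records), 0L)
  expect_equal(out2$n_removed, nrow(g$records))

  some <- structure(list(cluster_id = "c1",
                         sites = all_sites$sites[1:100],
                         params = list()), class = "dtc_blacklist")
  out3 <- apply_blacklist(g, some, cluster_id = "c1")
  expect_equal(out3$n_removed, 100L)
  expect_equal(out3$n_removed + nrow(out3$genome$records), nrow(g$records))

  expect_error(apply_blacklist(g, some, cluster_id = "c9"),
               "cluster mismatch")
})

test_that("blacklists round-trip through their TSV serialization", {
  d <- make_designs(1, 300, seed = 95)[[1]]
  cohort <- lapply(1:35, function(i) sample_genome(d, seed = 900 + i))
  freqs <- design_freq_table(d, eur_shift = 0.4)
  bl <- suppressWarnings(build_blacklist(cohort, freqs, "c2", z_crit = 3,
                                         n_min = 10))
  f <- withr::local_tempfile()
  write_blacklist(bl, f)
  back <- read_blacklist(f)
  expect_equal(back$cluster_id, "c2")
  expect_equal(back$params$z_crit, 3)
  expect_equal(sort(back$sites$key_), sort(bl$sites$key_))
})
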