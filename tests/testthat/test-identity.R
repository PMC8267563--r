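# Genotype concordance, relationship classification, origin grouping.

test_that("identical genomes score concordance 1 and similarity is symmetric", {
  g <- fixture_genome(seed = 201)
  s <- pairwise_similarity(g, g, min_shared = 100)
  expect_equal(s$concordance, 1.0)
  expect_equal(s$relationship, "duplicate")

  other <- sample_genome(fixture_designs()[[1]], seed = 202)
  s_ab <- pairwise_similarity(g, other, min_shared = 100)
  s_ba <- pairwise_similarity(other, g, min_shared = 100)
  expect_equal(s_ab$concordance, s_ba$concordance)
  expect_equal(s_ab$n_shared_called, s_ba$n_shared_called)
})

test_that("a duplicate with 1% genotype error scores about 0.99", {
  d <- make_designs(1, 10000, seed = 211)[[1]]
  g <- sample_genome(d, seed = 212)
  dup <- corrupt_genome(g, genotype_error = 0.01, seed = 213)$genome
  s <- pairwise_similarity(g, dup, min_shared = 1000, screen_n = Inf)
  se <- sqrt(0.99 * 0.01 / 10000)
  expect_lt(abs(s$concordance - 0.99), 4 * se)
  expect_equal(s$relationship, "duplicate")
})

test_that("relationship cutoffs follow the 97.5% / 80% bands", {
  expect_equal(classify_relationship(0.99), "duplicate")
  expect_equal(classify_relationship(0.975), "close_relative")  # boundary
  expect_equal(classify_relationship(0.85), "close_relative")
  expect_equal(classify_relationship(0.80), "close_relative")   # inclusive
  expect_equal(classify_relationship(0.799), "unrelated")
  expect_equal(classify_relationship(0.50), "unrelated")
})

test_that("unrelated concordance matches the HWE closed form", {
  d <- make_designs(1, 20000, seed = 221)[[1]]
  a <- sample_genome(d, seed = 222)
  b <- sample_genome(d, seed = 223)
  s <- pairwise_similarity(a, b, min_shared = 1000, screen_n = Inf)
  expected <- mean(hwe_match_prob(d$sites$maf))
  se <- sqrt(expected * (1 - expected) / 20000)
  expect_lt(abs(s$concordance - expected), 4 * se)
  expect_equal(s$relationship, "unrelated")
})

test_that("parent-child concordance sits between unrelated and duplicate", {
  d <- make_designs(1, 20000, seed = 231)[[1]]
  p1 <- sample_genome(d, seed = 232)
  p2 <- sample_genome(d, seed = 233)
  child <- sample_child(p1, p2, seed = 234)
  s_pc <- pairwise_similarity(p1, child, min_shared = 1000, screen_n = Inf)

  pc_band <- mc_relative_concordance(d$sites$maf, n_rep = 20, seed = 9,
                                     relation = "parent_child")
  un_band <- mc_relative_concordance(d$sites$maf, n_rep = 20, seed = 10,
                                     relation = "unrelated")
  expect_gt(s_pc$concordance, max(un_band))
  expect_lt(s_pc$concordance, 0.975)
  expect_gt(s_pc$concordance, min(pc_band) - 0.02)
  expect_lt(s_pc$concordance, max(pc_band) + 0.02)
})

test_that("origin grouping finds planted multi-upload groups", {
  d <- make_designs(1, 12000, seed = 241)[[1]]
  genomes <- list()
  for (i in 1:10) {
    genomes[[paste0("person", i)]] <- sample_genome(d, seed = 2400 + i)
  }
  # persons 1-3 uploaded twice (second copy with small error)
  for (i in 1:3) {
    genomes[[paste0("person", i, "_again")]] <-
      corrupt_genome(genomes[[paste0("person", i)]], genotype_error = 0.01,
                     seed = 2500 + i)$genome
  }
  res <- distinct_origins(genomes, min_shared = 1000)
  expect_equal(res$n_origins, 10)
  org <- res$origins
  for (i in 1:3) {
    expect_equal(org[file == paste0("person", i), origin],
                 org[file == paste0("person", i, "_again"), origin])
  }
  multi <- table(org$origin)
  expect_equal(sum(multi > 1), 3)

  # invariant under corpus order
  perm <- sample(length(genomes))
  res2 <- distinct_origins(genomes[perm], min_shared = 1000)
  expect_equal(res2$n_origins, 10)
})

test_that("small overlaps yield insufficient_overlap and screening never flips verdicts", {
  g <- fixture_genome(seed = 251)
  s <- pairwise_similarity(g, g, min_shared = 1e6)
  expect_equal(s$relationship, "insufficient_overlap")

  d <- make_designs(1, 30000, seed = 252)[[1]]
  a <- sample_genome(d, seed = 253)
  dup <- corrupt_genome(a, genotype_error = 0.01, seed = 254)$genome
  unrel <- sample_genome(d, seed = 255)
  for (pair in list(list(a, dup), list(a, unrel))) {
    full <- pairwise_similarity(pair[[1]], pair[[2]], min_shared = 1000,
                                screen_n = Inf)
    screened <- pairwise_similarity(pair[[1]], pair[[2]], min_shared = 1000,
                                    screen_n = 10000, screen_min = 0.6)
    expect_equal(screened$relationship, full$relationship)
  }
})
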