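# Fingerprint distance, corpus clustering, profiling, assignment.

test_that("distance matches hand counts and the set-operation oracle", {
  a <- encode_pos(c("1", "1", "1"), c(1L, 2L, 3L))
  b <- encode_pos(c("1", "1", "1"), c(2L, 3L, 4L))
  expect_equal(delta_n(a, b), 2)
  expect_equal(delta_n(a, a), 0)

  set.seed(2024)
  for (i in 1:200) {
    x <- sort(sample(500, sample(5:80, 1)))
    y <- sort(sample(500, sample(5:80, 1)))
    expect_equal(delta_n(x, y), oracle_symdiff(x, y))
  }
})

test_that("the distance is a metric on position sets", {
  set.seed(99)
  for (i in 1:1000) {
    x <- sort(sample(300, 40))
    y <- sort(sample(300, 40))
    z <- sort(sample(300, 40))
    dxy <- delta_n(x, y); dyx <- delta_n(y, x)
    expect_equal(dxy, dyx)
    expect_equal(delta_n(x, x), 0)
    expect_lte(dxy, delta_n(x, z) + delta_n(z, y))
  }
})

test_that("distance matrix is symmetric, zero-diagonal, and permutes with the corpus", {
  d <- fixture_designs()
  sets <- c(lapply(1:3, function(i) position_set(sample_genome(d[[1]], seed = i))),
            lapply(1:3, function(i) position_set(sample_genome(d[[2]], seed = 5 + i))))
  m <- distance_matrix(sets)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 6))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(m[i, j], delta_n(sets[[i]], sets[[j]]))
  }
  perm <- c(4, 2, 6, 1, 3, 5)
  expect_equal(distance_matrix(sets[perm]), m[perm, perm])
})

test_that("clustering equals threshold-graph components and handles singletons", {
  d <- fixture_designs()
  # random dropout makes every member's position set distinct
  sets <- unlist(lapply(1:2, function(di) {
    lapply(1:4, function(i) {
      set.seed(di * 50 + i)
      ks <- d[[di]]$sites$key_
      sort(ks[runif(length(ks)) > 0.02])
    })
  }), recursive = FALSE)
  m <- distance_matrix(sets)
  lab <- cluster_corpus(m, cutoff = 500)
  oracle <- oracle_threshold_components(m, 500)
  expect_equal(unname(lab), match(oracle, unique(oracle)))
  expect_equal(length(unique(lab)), 2)

  # cutoff below every pairwise distance: all singletons
  lab1 <- cluster_corpus(m, cutoff = min(m[upper.tri(m)]) - 1)
  expect_equal(length(unique(lab1)), 8)
})

test_that("planted designs are recovered across seeds", {
  for (seed in 1:5) {
    ds <- make_designs(3, 5000, overlap = 0.3, seed = seed)
    sets <- unlist(lapply(ds, function(d) {
      lapply(1:6, function(i) {
        ps <- d$sites$key_
        set.seed(seed * 100 + i)
        sort(ps[runif(length(ps)) > 0.02])
      })
    }), recursive = FALSE)
    truth <- rep(1:3, each = 6)
    m <- distance_matrix(sets)
    lab <- cluster_corpus(m, cutoff = 2000)
    expect_equal(unname(lab), truth)
  }
})

test_that("cluster profiles expose prevalence, core set, and dropout", {
  one <- list(encode_pos(rep("1", 4), 1:4))
  mod1 <- profile_cluster(one, "c1")
  expect_equal(mod1$positions$prevalence, rep(1, 4))
  expect_equal(sort(mod1$core), sort(one[[1]]))

  # a position in 19 of 20 members has prevalence 0.95 and is not core
  base <- encode_pos(rep("1", 50), 1:50)
  members <- c(list(base[-1]), lapply(2:20, function(i) base))
  mod <- profile_cluster(members, "c2")
  expect_equal(mod$positions[key_ == base[1], prevalence], 19 / 20)
  expect_false(base[1] %in% mod$core)
  expect_true(base[2] %in% mod$core)

  # mean prevalence tracks the generative dropout rate
  d <- make_designs(1, 5000, seed = 31)[[1]]
  drop <- lapply(1:20, function(i) {
    set.seed(300 + i)
    ks <- d$sites$key_
    sort(ks[runif(length(ks)) > 0.05])
  })
  m <- profile_cluster(drop, "c3")
  expect_lt(abs(mean(m$positions$prevalence) - 0.95), 0.01)

  # the prevalence floor drops file-private positions
  private <- c(list(c(base, encode_pos("2", 999L))), lapply(2:30, function(i) base))
  mp <- profile_cluster(private, "c4", floor = 0.05)
  expect_false(encode_pos("2", 999L) %in% mp$positions$key_)
})

test_that("assignment uses inclusive 80% coverage and max-coverage wins", {
  m_pos <- encode_pos(rep("1", 1000), 1:1000)
  model <- profile_cluster(list(m_pos), "c1")
  outside <- encode_pos(rep("2", 250), 1:250)

  g80 <- sort(c(m_pos[1:800], outside[1:200]))
  g79 <- sort(c(m_pos[1:790], outside[1:210]))
  expect_equal(assign_cluster(g80, list(model))$cluster_id, "c1")
  expect_equal(assign_cluster(g79, list(model))$cluster_id, "unassigned")

  # two eligible models at coverage 0.95 and 0.85: the 0.95 one wins
  model_hi <- profile_cluster(list(sort(c(m_pos[1:800], outside[1:150]))), "chi")
  model_lo <- profile_cluster(list(sort(c(m_pos[1:800], outside[1:50]))), "clo")
  res <- assign_cluster(g80, list(model_lo, model_hi))
  expect_equal(res$coverage[["chi"]], 0.95)
  expect_equal(res$coverage[["clo"]], 0.85)
  expect_equal(res$cluster_id, "chi")

  # monotone: adding model positions never unassigns
  bigger <- profile_cluster(list(sort(c(m_pos, outside))), "c1")
  expect_equal(assign_cluster(g80, list(bigger))$cluster_id, "c1")
})

test_that("cluster models round-trip through serialization", {
  d <- fixture_designs()[[1]]
  members <- lapply(1:5, function(i) position_set(sample_genome(d, seed = i)))
  mod <- profile_cluster(members, "c7")
  f <- withr::local_tempfile()
  write_cluster_model(mod, f)
  back <- read_cluster_model(f)
  expect_equal(back$cluster_id, "c7")
  expect_equal(back$n_members, 5L)
  expect_equal(back$positions$key_, mod$positions$key_)
  expect_equal(back$positions$prevalence, mod$positions$prevalence)
  expect_equal(sort(back$core), sort(mod$core))
})
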