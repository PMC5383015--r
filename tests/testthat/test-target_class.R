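test_that("build_class produces the folded class with canonical members", {
  cls <- default_class()
  expect_equal(nrow(cls$members), 8L)
  expect_equal(cls$layout$N, 16L)

  one <- build_class(1, 1, b_subpatterns = list(c(1L)))
  expect_equal(nrow(one$members), 1L)
  expect_equal(unname(one$members[1, ]), 1L)

  two <- tiny_class()
  expect_equal(nrow(two$members), 2L)
  keys <- apply(two$members, 1L, pattern_key)
  neg_keys <- apply(-two$members, 1L, pattern_key)
  expect_length(intersect(keys, neg_keys), 0L)
})

test_that("class members and their negations tile all module combinations", {
  for (nm in 2:4) {
    cls <- build_class(nm, 3, seed = nm)
    # brute-force oracle: enumerate every A/B combination directly
    combos <- as.matrix(expand.grid(rep(list(c(1L, -1L)), nm)))
    all_patterns <- apply(combos, 1L, function(st) {
      pattern_key(unlist(lapply(seq_len(nm), function(m) {
        st[m] * cls$layout$b_subpatterns[[m]]
      })))
    })
    got <- c(apply(cls$members, 1L, pattern_key),
             apply(-cls$members, 1L, pattern_key))
    expect_setequal(got, all_patterns)
    expect_equal(anyDuplicated(got), 0L)
    # canonical representative rule and lexicographic order
    expect_true(all(cls$members[, 1L] == 1L))
    ord <- apply(cls$members, 1L, function(s) paste(s > 0, collapse = ""))
    expect_equal(order(ord, decreasing = TRUE), seq_len(nrow(cls$members)))
  }
})

test_that("build_class validates input", {
  expect_error(build_class(0, 4), "positive")
  expect_error(build_class(2, 2, b_subpatterns = list(c(1, -1))), "entry")
  expect_error(build_class(2, 2, b_subpatterns = list(c(1, 0), c(1, 1))),
               "-1 and \\+1")
  expect_error(module_layout(2, 0), "positive")
})

test_that("training_split selects members and tests on the full class", {
  cls <- default_class()
  sp <- training_split(cls, 1:3)
  expect_equal(nrow(sp$train), 3L)
  expect_equal(nrow(sp$test), 8L)
  expect_identical(sp$test, cls$members)

  full <- training_split(cls, 1:8)
  expect_identical(full$train, full$test)

  expect_error(training_split(cls, integer(0)), "non-empty")
  expect_error(training_split(cls, c(1, 1, 2)), "distinct")
  expect_error(training_split(cls, c(1, 9)), "1\\.\\.8")
})

test_that("default_train_indices picks a fully varying triple", {
  cls <- default_class()
  tri <- default_train_indices(cls)
  expect_length(tri, 3L)
  sig <- grnevolve:::module_signature(cls)[tri, -1L]
  expect_true(all(apply(sig, 2L, function(x) length(unique(x)) > 1L)))
  prods <- combn(ncol(sig), 2L, function(p) sig[, p[1L]] * sig[, p[2L]])
  expect_true(all(apply(prods, 2L, function(x) length(unique(x)) > 1L)))
  # no earlier triple qualifies (spot-check lexicographic minimality)
  expect_identical(tri, c(1L, 4L, 6L))
})

test_that("cyclic schedules assign block-constant targets in order", {
  cls <- build_class(2, 2, b_subpatterns = list(c(1L, -1L), c(1L, 1L)))
  tg <- rbind(a = c(1L, -1L, 1L, 1L), b = c(1L, 1L, -1L, -1L),
              c = c(1L, -1L, -1L, -1L))
  sch <- environment_schedule(tg, K = 2, total_generations = 12)
  got <- t(vapply(0:6, function(g) target_at(sch, g), integer(4)))
  expect_equal(got, tg[c(1, 1, 2, 2, 3, 3, 1), ], ignore_attr = TRUE)
  expect_error(target_at(sch, 12), "generation")
  expect_error(target_at(sch, -1), "generation")
  # every training target visited exactly once per epoch
  blocks <- sch$block_targets[1:3]
  expect_setequal(blocks, 1:3)
})

test_that("uniform_random schedules are block-constant and reproducible", {
  sch <- environment_schedule(rbind(c(1L, -1L), c(1L, 1L), c(-1L, -1L)),
                              K = 5, total_generations = 100,
                              order_policy = "uniform_random", seed = 42)
  expect_identical(target_at(sch, 10), target_at(sch, 14))
  sch2 <- environment_schedule(sch$targets, K = 5, total_generations = 100,
                               order_policy = "uniform_random", seed = 42)
  expect_identical(sch$block_targets, sch2$block_targets)
  # all three targets appear over 20 blocks with overwhelming probability
  expect_setequal(unique(sch$block_targets), 1:3)
})

test_that("noisy_target adds calibrated Gaussian noise", {
  S <- default_class()$members[1, ]
  expect_identical(noisy_target(S, 0), as.numeric(S))
  expect_error(noisy_target(S, -1), "nonnegative")

  kappa <- 35e-4
  set.seed(7)
  dev <- replicate(1e5, noisy_target(S[1:2], kappa)[1L] - S[1L])
  expect_equal(sd(dev), kappa, tolerance = 0.02)
  # mean converges to the target within 3 standard errors
  expect_lt(abs(mean(dev)), 3 * kappa / sqrt(1e5))

  set.seed(11)
  a <- noisy_target(S, 1)
  set.seed(11)
  b <- noisy_target(S, 1)
  expect_identical(a, b)
})

test_that("class config and pattern CSV round-trip", {
  cls <- default_class()
  path <- withr::local_tempfile(fileext = ".json")
  write_class_config(cls, path, train_indices = c(1, 4, 6), K = 2000)
  back <- read_class_config(path)
  expect_identical(back$class$members, cls$members)
  expect_equal(back$train_indices, c(1L, 4L, 6L))
  expect_equal(back$K, 2000)

  csv <- withr::local_tempfile(fileext = ".csv")
  export_patterns_csv(cls, csv)
  df <- read.csv(csv)
  expect_equal(nrow(df), 8L)
  expect_equal(as.integer(as.matrix(df[, -(1:2)])), as.integer(cls$members))

  shipped <- read_class_config(
    system.file("extdata", "example_layout_synthetic.json",
                package = "grnevolve"))
  expect_equal(shipped$class$layout$b_subpatterns[[2]],
               c(1L, 1L, -1L, -1L))
  expect_equal(nrow(shipped$class$members), 8L)
})
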