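test_that("fold_pattern identifies complement pairs", {
  expect_identical(fold_pattern(c(1L, -1L, -1L)), c(1L, -1L, -1L))
  expect_identical(fold_pattern(c(-1L, 1L, 1L)), c(1L, -1L, -1L))
  set.seed(12)
  for (rep in 1:30) {
    p <- sample(c(-1L, 1L), 6, replace = TRUE)
    expect_identical(fold_pattern(p), fold_pattern(-p))
    expect_equal(fold_pattern(p)[1L], 1L)
    expect_identical(fold_pattern(fold_pattern(p)), fold_pattern(p))
  }
})

test_that("sobol points reproduce the reference sequence", {
  # first points of the unscrambled Sobol sequence in 6 dimensions,
  # frozen from an independent reference implementation (scipy.stats.qmc)
  ref <- matrix(c(
    0, 0, 0, 0, 0, 0,
    0.5, 0.5, 0.5, 0.5, 0.5, 0.5,
    0.75, 0.25, 0.25, 0.25, 0.75, 0.75,
    0.25, 0.75, 0.75, 0.75, 0.25, 0.25,
    0.375, 0.375, 0.625, 0.875, 0.375, 0.125,
    0.875, 0.875, 0.125, 0.375, 0.875, 0.625,
    0.625, 0.125, 0.875, 0.625, 0.625, 0.875,
    0.125, 0.625, 0.375, 0.125, 0.125, 0.375,
    0.1875, 0.3125, 0.9375, 0.4375, 0.5625, 0.3125,
    0.6875, 0.8125, 0.4375, 0.9375, 0.0625, 0.8125), ncol = 6,
    byrow = TRUE)
  expect_equal(sobol_points(10, 6, "sobol"), ref, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("scrambled sobol is reproducible, uniform and leaves RNG alone", {
  a <- sobol_points(256, 3, "sobol_scrambled", seed = 5)
  b <- sobol_points(256, 3, "sobol_scrambled", seed = 5)
  expect_identical(a, b)
  c2 <- sobol_points(256, 3, "sobol_scrambled", seed = 6)
  expect_false(identical(a, c2))
  expect_true(all(a >= 0 & a < 1))
  # equidistribution: every dyadic 1/16 bin of each coordinate gets 16 points
  for (d in 1:3) {
    expect_true(all(tabulate(ceiling(a[, d] * 16), 16) == 16))
  }
  set.seed(1234)
  before <- .Random.seed
  invisible(sobol_points(64, 2, "sobol_scrambled", seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("chi-squared error matches hand-computed cases", {
  cls <- default_class()
  train <- cls$members[c(1, 4, 6), ]
  # O = (1/3, 1/3, 1/3) on the training set: zero error
  d0 <- dist_from_freqs(train, rep(1 / 3, 3), n_samples = 3000)
  expect_equal(chi_squared_error(d0, train), 0)
  # O = (0.5, 0.5, 0) -> 2*(1/6)^2/(1/3) + (1/3)^2/(1/3) = 1/2
  d1 <- dist_from_freqs(train, c(0.5, 0.5, 0))
  expect_equal(chi_squared_error(d1, train), 0.5)
  # uniform over the full folded class: perfect generalisation
  d2 <- dist_from_freqs(cls$members, rep(1 / 8, 8), n_samples = 4000)
  expect_equal(chi_squared_error(d2, cls$members), 0)
  expect_error(chi_squared_error(d2, cls$members[0, ]), "non-empty")
  # patterns are folded before lookup
  expect_equal(chi_squared_error(d2, -cls$members), 0)
})

test_that("entropy follows the plug-in formula", {
  one <- phenotype_distribution(setNames(100L, "+-+-"))
  expect_equal(entropy_bits(one), 0)
  cls <- default_class()
  keys16 <- c(apply(cls$members, 1, pattern_key),
              apply(-cls$members, 1, pattern_key))
  unif16 <- phenotype_distribution(setNames(rep(10L, 16), keys16))
  expect_equal(entropy_bits(unif16), 4)
  # uniform over all 2^N unfolded patterns at N = 3: maximum entropy
  keys8 <- apply(as.matrix(expand.grid(rep(list(c(1L, -1L)), 3))), 1,
                 pattern_key)
  expect_equal(entropy_bits(phenotype_distribution(setNames(rep(5L, 8),
                                                            keys8))), 3)
  # folding can only lose entropy
  d <- estimate_distribution(matrix(rnorm(16, sd = 0.3), 4), dev_default,
                             n_samples = 2000, seed = 3)
  f <- d$counts / d$n_samples
  folded_H <- -sum(f * log2(f))
  expect_lte(folded_H, entropy_bits(d) + 1e-12)
  expect_lte(length(d$counts), length(d$unfolded_counts))
})

test_that("class coverage applies the frequency threshold", {
  cls <- default_class()
  d <- dist_from_freqs(cls$members[1:3, ], c(0.5, 0.489, 0.009),
                       n_samples = 1000)
  cov <- class_coverage(d, cls, 0.01)
  expect_equal(cov$count, 2L)
  expect_setequal(cov$members, c("P1", "P2"))
  empty <- dist_from_freqs(matrix(c(1L, -1L, 1L, 1L, -1L, 1L, 1L, 1L,
                                    1L, -1L, 1L, 1L, -1L, 1L, 1L, -1L),
                                  nrow = 1), 1)
  expect_equal(class_coverage(empty, cls)$count, 0L)
})

test_that("B = 0 folded distribution is uniform under both samplers", {
  d_unif <- estimate_distribution(matrix(0, 4, 4), dev_default,
                                  n_samples = 1e5, sampler = "uniform",
                                  seed = 31)
  f <- d_unif$counts / d_unif$n_samples
  expect_length(f, 8L)
  expect_true(all(abs(f - 0.125) < 0.005))

  d_sob <- estimate_distribution(matrix(0, 4, 4), dev_default,
                                 n_samples = 5000, seed = 31)
  fs <- d_sob$counts / d_sob$n_samples
  expect_true(all(abs(fs[names(f)] - f) < 0.02))

  one <- estimate_distribution(matrix(0, 3, 3), dev_default,
                               n_samples = 1, seed = 2)
  expect_equal(sum(one$counts > 0), 1L)
})

test_that("sampled distributions agree with a dense grid oracle", {
  # oracle: map a 41-per-axis grid of embryonic states through development
  # and tally folded sign patterns; compare by total variation distance
  set.seed(77)
  for (B in list(matrix(0, 3, 3), matrix(rnorm(9, sd = 0.4), 3))) {
    ax <- seq(-1, 1, length.out = 41)
    grid <- as.matrix(expand.grid(ax, ax, ax))
    P <- develop_batch(grid, B, dev_default)
    codes <- grnevolve:::cpp_sign_codes(P)
    keys <- grnevolve:::code_to_key(sort(unique(codes)), 3L)
    tab <- table(factor(codes, levels = sort(unique(codes))))
    oracle <- phenotype_distribution(setNames(as.integer(tab), keys))
    of <- oracle$counts / oracle$n_samples

    est <- estimate_distribution(B, dev_default, n_samples = 2e5,
                                 sampler = "uniform", seed = 13)
    ef <- est$counts / est$n_samples
    all_keys <- union(names(of), names(ef))
    tv <- 0.5 * sum(abs(ifelse(is.na(of[all_keys]), 0, of[all_keys]) -
                        ifelse(is.na(ef[all_keys]), 0, ef[all_keys])))
    expect_lt(tv, 0.01)
  }
})

test_that("estimation is side-effect free for the caller's RNG", {
  set.seed(555)
  before <- .Random.seed
  invisible(estimate_distribution(matrix(0.1, 4, 4), dev_default,
                                  n_samples = 1000, seed = 8))
  expect_identical(.Random.seed, before)
})

test_that("distribution CSV export is faithful", {
  d <- estimate_distribution(matrix(0, 3, 3), dev_default,
                             n_samples = 500, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  export_distribution_csv(d, path)
  df <- read.csv(path, colClasses = c(pattern = "character",
                                      folded = "character"))
  expect_equal(sum(df$count), 500L)
  expect_equal(sort(df$pattern), sort(names(d$unfolded_counts)))
  expect_true(all(df$frequency == df$count / 500))
})
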