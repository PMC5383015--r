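#' Quasi-random and pseudo-random points for Classify-and-Count sampling
#'
#' Generates `n` points in `[0, 1)^dim`, either from a Sobol low-discrepancy
#' sequence with Matousek linear scrambling plus a random digital shift
#' (default; scramble drawn reproducibly from `seed`), an unscrambled Sobol
#' sequence, or plain iid uniforms.
#'
#' @param n number of points.
#' @param dim dimension (at most 36).
#' @param type `"sobol_scrambled"`, `"sobol"` or `"uniform"`.
#' @param seed integer seed controlling the scramble / uniform draws; the
#'   caller's RNG state is left untouched.
#' @return an `n x dim` numeric matrix.
#' @export
sobol_points <- function(n, dim,
                         type = c("sobol_scrambled", "sobol", "uniform"),
                         seed = 1L) {
  type <- match.arg(type)
  with_seed(seed, switch(
    type,
    sobol_scrambled = cpp_sobol(n, dim, TRUE),
    sobol = cpp_sobol(n, dim, FALSE),
    uniform = matrix(runif(n * dim), nrow = n)
  ))
}

# embryonic sample in the hypercube [-1, 1]^N
sample_embryos <- function(n, N, sampler = "sobol_scrambled", seed = 1L) {
  type <- if (sampler == "uniform") "uniform" else "sobol_scrambled"
  2 * sobol_points(n, N, type, seed) - 1
}

#' Construct a phenotype distribution from unfolded pattern counts
#'
#' Low-level constructor used by [estimate_distribution()] and by tests.
#' Folded counts are derived by identifying each pattern with its
#' elementwise complement (canonical representative: first trait `+1`).
#'
#' @param unfolded_counts named integer vector; names are pattern keys
#'   (see [pattern_key()]) and values are nonnegative counts.
#' @return an object of class `phenotype_distribution` with fields
#'   `counts` (folded), `unfolded_counts`, `n_samples` and `N`.
#' @export
phenotype_distribution <- function(unfolded_counts) {
  stopifnot(length(unfolded_counts) > 0, !is.null(names(unfolded_counts)))
  keys <- names(unfolded_counts)
  N <- nchar(keys[1L])
  folded_keys <- vapply(keys, function(k) {
    pattern_key(fold_pattern(key_to_pattern(k)))
  }, character(1))
  counts <- tapply(as.integer(unfolded_counts), folded_keys, sum)
  counts <- setNames(as.integer(counts), names(counts))
  structure(
    list(counts = counts,
         unfolded_counts = setNames(as.integer(unfolded_counts), keys),
         n_samples = sum(unfolded_counts), N = N),
    class = "phenotype_distribution"
  )
}

#' @export
print.phenotype_distribution <- function(x, ...) {
  cat(sprintf(
    "Phenotype distribution: %d samples, %d folded / %d unfolded patterns\n",
    x$n_samples, length(x$counts), length(x$unfolded_counts)))
  top <- sort(x$counts, decreasing = TRUE)
  top <- top[seq_len(min(10L, length(top)))]
  for (k in seq_along(top)) {
    cat(sprintf("  %s  %.4f\n", names(top)[k], top[k] / x$n_samples))
  }
  invisible(x)
}

#' Estimate the phenotype distribution induced by a regulatory matrix
#'
#' Classify-and-Count: `n_samples` embryonic states are drawn uniformly in
#' the hypercube `[-1, 1]^N` (scrambled Sobol by default), each is developed
#' under the fixed `B`, and the discretised adult sign patterns are
#' tallied, both raw (unfolded) and with complements identified (folded).
#' The estimation runs on its own seeded stream and leaves the caller's RNG
#' state untouched, so measuring a genotype never perturbs an evolution
#' run.
#'
#' @param B numeric `N x N` regulatory matrix.
#' @param dev a [development_params()] object (tanh activation).
#' @param n_samples number of embryonic samples (default 5000).
#' @param sampler `"sobol_scrambled"` (default) or `"uniform"`.
#' @param seed seed for the sampling stream.
#' @return a [phenotype_distribution()] object.
#' @export
#' @examples
#' d <- estimate_distribution(matrix(0, 4, 4), development_params(),
#'                            n_samples = 2000, seed = 1)
#' entropy_bits(d)
estimate_distribution <- function(B, dev = development_params(),
                                  n_samples = 5000L,
                                  sampler = c("sobol_scrambled", "uniform"),
                                  seed = 1L) {
  sampler <- match.arg(sampler)
  stopifnot(n_samples >= 1)
  N <- nrow(B)
  G <- sample_embryos(n_samples, N, sampler, seed)
  P <- develop_batch(G, B, dev)
  codes <- cpp_sign_codes(P)
  tab <- table(codes)
  keys <- code_to_key(as.integer(names(tab)), N)
  phenotype_distribution(setNames(as.integer(tab), keys))
}

#' Fold a sign pattern onto its canonical representative
#'
#' A pattern and its elementwise complement encode the same module states
#' up to global negation and are treated as one phenotype. The canonical
#' representative is the member of the pair whose first trait is `+1`.
#'
#' @param pattern integer vector of `-1`/`+1`.
#' @return the canonical pattern of the complement pair.
#' @export
#' @examples
#' fold_pattern(c(-1, 1, 1))  # +1 -1 -1
fold_pattern <- function(pattern) {
  assert_sign_vector(pattern)
  if (pattern[1L] > 0) pattern else -pattern
}

#' Chi-squared error of a distribution against a target set
#'
#' Compares the folded empirical frequencies `O(s_i)` with uniform expected
#' frequencies `E(s_i) = 1/k` over the `k` patterns of the set:
#' `sum_i (O_i - E_i)^2 / E_i`. Observed frequencies are looked up after
#' folding and are not renormalised over the set, so probability mass on
#' patterns outside the set depresses `O` and inflates the error. The
#' training error uses the training targets as the set; the test
#' (generalisation) error uses the full class.
#'
#' @param dist a [phenotype_distribution()].
#' @param pattern_set matrix of target patterns (rows), or a list of sign
#'   vectors.
#' @return nonnegative chi-squared error; zero iff the folded distribution
#'   is exactly uniform over the set with no outside mass.
#' @export
chi_squared_error <- function(dist, pattern_set) {
  stopifnot(inherits(dist, "phenotype_distribution"))
  if (is.list(pattern_set)) pattern_set <- do.call(rbind, pattern_set)
  pattern_set <- rbind(pattern_set)
  k <- nrow(pattern_set)
  if (k == 0L) stop("pattern_set must be non-empty", call. = FALSE)
  keys <- apply(pattern_set, 1L, function(s) pattern_key(fold_pattern(s)))
  if (anyDuplicated(keys)) {
    stop("pattern_set contains complement-duplicate patterns",
         call. = FALSE)
  }
  O <- unname(dist$counts[keys]) / dist$n_samples
  O[is.na(O)] <- 0
  E <- 1 / k
  sum((O - E)^2 / E)
}

#' Shannon entropy of the unfolded phenotype distribution
#'
#' Plug-in entropy in bits over the raw (unfolded) empirical pattern
#' frequencies, with `0 log 0 = 0`. A system representing all `2^N` sign
#' patterns uniformly scores `N` bits; perfect generalisation to a class
#' built from 4 independently varying modules scores 4 bits; canalisation
#' below the class structure scores less.
#'
#' @param dist a [phenotype_distribution()].
#' @return nonnegative entropy in bits.
#' @export
entropy_bits <- function(dist) {
  stopifnot(inherits(dist, "phenotype_distribution"))
  f <- dist$unfolded_counts / dist$n_samples
  f <- f[f > 0]
  -sum(f * log2(f))
}

#' Class members expressed by a phenotype distribution
#'
#' Counts class members whose folded empirical frequency reaches
#' `threshold` (default 0.01, the conventional cut-off below which a
#' phenotype is treated as unexpressed).
#'
#' @param dist a [phenotype_distribution()].
#' @param class a [build_class()] object.
#' @param threshold frequency cut-off in `[0, 1]`.
#' @return list with `count` and the character vector `members` of covered
#'   member labels.
#' @export
class_coverage <- function(dist, class, threshold = 0.01) {
  stopifnot(inherits(dist, "phenotype_distribution"),
            inherits(class, "phenotype_class"),
            threshold >= 0, threshold <= 1)
  keys <- apply(class$members, 1L, function(s) pattern_key(fold_pattern(s)))
  freq <- unname(dist$counts[keys]) / dist$n_samples
  freq[is.na(freq)] <- 0
  covered <- rownames(class$members)[freq >= threshold]
  list(count = length(covered), members = covered)
}

#' Export a phenotype distribution as CSV
#'
#' One row per observed pattern with its folded representative, count and
#' frequency.
#'
#' @param dist a [phenotype_distribution()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_distribution_csv <- function(dist, path) {
  stopifnot(inherits(dist, "phenotype_distribution"))
  keys <- names(dist$unfolded_counts)
  folded <- vapply(keys, function(k) {
    pattern_key(fold_pattern(key_to_pattern(k)))
  }, character(1))
  df <- data.frame(
    pattern = keys,
    folded = unname(folded),
    is_canonical = keys == folded,
    count = unname(dist$unfolded_counts),
    frequency = unname(dist$unfolded_counts) / dist$n_samples
  )
  df <- df[order(-df$count), ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Full error report for an evolved regulatory matrix
#'
#' Convenience wrapper estimating the induced distribution and collecting
#' training error, test error, entropy and class coverage in one list.
#'
#' @param B regulatory matrix.
#' @param class a [build_class()] object.
#' @param train_indices 1-based class rows of the training set.
#' @inheritParams estimate_distribution
#' @param threshold coverage frequency cut-off.
#' @return list of class `error_report`.
#' @export
error_report <- function(B, class, train_indices,
                         dev = development_params(), n_samples = 5000L,
                         sampler = "sobol_scrambled", seed = 1L,
                         threshold = 0.01) {
  dist <- estimate_distribution(B, dev, n_samples, sampler, seed)
  cov <- class_coverage(dist, class, threshold)
  structure(
    list(training_error = chi_squared_error(
           dist, class$members[train_indices, , drop = FALSE]),
         test_error = chi_squared_error(dist, class$members),
         entropy_bits = entropy_bits(dist),
         coverage_count = cov$count,
         covered_members = cov$members),
    class = "error_report"
  )
}
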