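# shared fixtures: tiny classes and parameter sets used across test files

tiny_class <- function(seed = 1L, n_modules = 2L, module_width = 2L) {
  build_class(n_modules, module_width, seed = seed)
}

default_class <- function(seed = 1L) build_class(4L, 4L, seed = seed)

dev_default <- development_params()

# straight-line reference development loop, written independently of the
# package implementation (no shared code path); used as a numeric oracle
oracle_develop <- function(G, B, tau1 = 1, tau2 = 0.2, steps = 10) {
  P <- G
  for (t in seq_len(steps)) P <- (1 - tau2) * P + tau1 * tanh(B %*% P)
  list(raw = as.numeric(P), normalized = as.numeric(P) * tau2 / tau1)
}

# distribution object with prescribed folded frequencies over given
# patterns (patterns must be canonical); remainder of the mass, if any,
# goes to an unrelated filler pattern
dist_from_freqs <- function(patterns, freqs, n_samples = 5000L,
                            filler = NULL) {
  counts <- as.integer(round(freqs * n_samples))
  keys <- apply(rbind(patterns), 1L, pattern_key)
  rest <- n_samples - sum(counts)
  stopifnot(rest >= 0)
  uc <- setNames(counts, keys)
  if (rest > 0) {
    if (is.null(filler)) {
      filler <- rep(c(1L, -1L), length.out = ncol(rbind(patterns)))
      filler[2L] <- -1L
    }
    fk <- pattern_key(filler)
    stopifnot(!fk %in% keys)
    uc <- c(uc, setNames(rest, fk))
  }
  phenotype_distribution(uc[uc > 0])
}
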