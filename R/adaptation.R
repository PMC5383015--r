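#' Generations for the direct effects to reach a target phenotype
#'
#' Rate-of-adaptation primitive: the regulatory matrix `B` is frozen and
#' only the direct effects `G` evolve, by single-gene hill climbing on the
#' benefit alone (with `B` fixed the connection cost is constant and cannot
#' affect acceptance; targets are noiseless). `G` starts uniformly at
#' random in `[-1, 1]^N` unless `G0` is supplied. The run stops at the
#' first generation whose developed sign pattern equals `S` (the initial
#' state counts as generation 1); if the target is never produced within
#' `max_gen` generations, `max_gen` is returned (a censored run).
#'
#' @param B frozen regulatory matrix.
#' @param S target sign pattern.
#' @param dev a [development_params()] object.
#' @param mp a [mutation_params()] object (only `g_step` is used).
#' @param max_gen generation cap (default 2500).
#' @param G0 optional initial direct effects (for tests); `NULL` = random.
#' @param criterion success test: `"sign"` (default; exact sign-pattern
#'   match, the discrete event the assay counts) or `"benefit"` (continuous
#'   benefit reaching `1 - epsilon`, for saturating dynamics where an
#'   exact-match notion of "maximum fitness" is wanted instead).
#' @param epsilon slack for the `"benefit"` criterion (default 0.05).
#' @return integer in `[1, max_gen]`.
#' @export
time_to_target <- function(B, S, dev = development_params(),
                           mp = mutation_params(length(S)),
                           max_gen = 2500L, G0 = NULL,
                           criterion = c("sign", "benefit"),
                           epsilon = 0.05) {
  criterion <- match.arg(criterion)
  N <- length(S)
  assert_sign_vector(S, "target")
  if (nrow(B) != N || ncol(B) != N) {
    stop_dim("B must be %d x %d to match the target", N, N)
  }
  stopifnot(max_gen >= 1)
  cpp_time_to_target(B, as.integer(S), dev$tau1, dev$tau2, dev$n_steps,
                     mp$g_step, as.integer(max_gen),
                     if (is.null(G0)) numeric(0) else as.numeric(G0),
                     if (criterion == "benefit") 1 - epsilon else 0)
}

#' Rate-of-adaptation assay over a phenotype class
#'
#' Runs [time_to_target()] for every class member and `n_runs` independent
#' replicates, each from its own sub-seed, with the developmental
#' architecture `B` held fixed throughout. Censored runs (target never
#' reached) carry the value `max_gen`.
#'
#' @param B frozen regulatory matrix.
#' @param class a [build_class()] object.
#' @param n_runs replicates per class member (default 1000).
#' @param dev,mp parameter objects.
#' @param max_gen generation cap (default 2500).
#' @param seed integer seed; the assay is deterministic given it.
#' @return object of class `adaptation_result`: list with `generations`
#'   (members x runs integer matrix), logical `censored` of the same
#'   shape, and `max_gen`.
#' @export
adaptation_assay <- function(B, class, n_runs = 1000L,
                             dev = development_params(), mp = NULL,
                             max_gen = 2500L, seed = 1L) {
  stopifnot(inherits(class, "phenotype_class"), n_runs >= 1)
  N <- class$layout$N
  if (is.null(mp)) mp <- mutation_params(N)
  members <- class$members
  gens <- matrix(NA_integer_, nrow(members), n_runs,
                 dimnames = list(rownames(members), NULL))
  for (k in seq_len(nrow(members))) {
    S <- members[k, ]
    for (r in seq_len(n_runs)) {
      gens[k, r] <- with_seed(
        seed + 10007L * k + r,
        time_to_target(B, S, dev, mp, max_gen)
      )
    }
  }
  structure(list(generations = gens, censored = gens == max_gen,
                 max_gen = as.integer(max_gen)),
            class = "adaptation_result")
}

#' @export
print.adaptation_result <- function(x, ...) {
  cat(sprintf(
    "Adaptation assay: %d targets x %d runs (cap %d generations)\n",
    nrow(x$generations), ncol(x$generations), x$max_gen))
  med <- apply(x$generations, 1L, median)
  cen <- rowSums(x$censored)
  for (k in seq_len(nrow(x$generations))) {
    cat(sprintf("  %s: median %g generations, %d censored\n",
                rownames(x$generations)[k], med[k], cen[k]))
  }
  invisible(x)
}

#' Long-format data frame of an adaptation assay
#'
#' @param x an `adaptation_result`.
#' @return data frame with columns `member`, `replicate`, `generations`,
#'   `censored`, suitable for box-plot summaries or CSV export.
#' @export
adaptation_to_df <- function(x) {
  stopifnot(inherits(x, "adaptation_result"))
  data.frame(
    member = rep(rownames(x$generations), times = ncol(x$generations)),
    replicate = rep(seq_len(ncol(x$generations)),
                    each = nrow(x$generations)),
    generations = as.vector(x$generations),
    censored = as.vector(x$censored)
  )
}
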