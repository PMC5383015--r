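#' Fitness parameters: benefit minus connection cost
#'
#' Fitness of an adult phenotype against a selective environment is
#' `benefit - lambda * cost`, where the benefit measures closeness to the
#' target pattern and the cost penalises regulatory connectivity (`"L1"`,
#' favouring sparse connections; `"L2"`, favouring weak ones; or `"none"`).
#' `kappa` scales iid Gaussian noise added to the target each generation,
#' modelling extrinsic environmental noise.
#'
#' @param lambda nonnegative cost weight.
#' @param cost_norm `"none"`, `"L1"` or `"L2"`.
#' @param kappa nonnegative environmental noise scale.
#' @return an object of class `fitness_params`.
#' @export
fitness_params <- function(lambda = 0, cost_norm = c("none", "L1", "L2"),
                           kappa = 0) {
  cost_norm <- match.arg(cost_norm)
  if (lambda < 0) stop("lambda must be nonnegative", call. = FALSE)
  if (kappa < 0) stop("kappa must be nonnegative", call. = FALSE)
  structure(list(lambda = lambda, cost_norm = cost_norm, kappa = kappa),
            class = "fitness_params")
}

#' Mutation parameters for the hill climber
#'
#' Each reproduction event perturbs a single uniformly chosen direct effect
#' by `Uniform[-g_step, g_step]` (clamped to `[-1, 1]`); with probability
#' `b_prob` every regulatory coefficient is additionally perturbed by
#' `Uniform[-b_step, b_step]` (unclamped). The tiny default
#' `b_step = 0.1/(15 N^2)` keeps regulatory evolution much slower than the
#' phenotypic variation it shapes. The default `b_prob = 1/2` (matrix
#' mutated in half the reproduction events) is the rate under which the
#' four headline scenarios separate within 150 epochs at K = 20000; the
#' alternative published rate 1/15 produces the same qualitative
#' trajectory stretched roughly sevenfold and is available via this knob
#' (see the methods vignette).
#'
#' @param N number of traits (used for the default `b_step`).
#' @param g_step half-range of the single-gene step (default 0.1).
#' @param b_prob per-generation probability of a matrix mutation
#'   (default 1/2).
#' @param b_step half-range of per-element matrix steps
#'   (default `0.1 / (15 * N^2)`).
#' @return an object of class `mutation_params`.
#' @export
mutation_params <- function(N = 16L, g_step = 0.1, b_prob = 0.5,
                            b_step = 0.1 / (15 * N^2)) {
  stopifnot(g_step > 0, b_step > 0, b_prob > 0, b_prob <= 1)
  structure(list(g_step = g_step, b_prob = b_prob, b_step = b_step),
            class = "mutation_params")
}

#' Selective benefit of an adult phenotype
#'
#' `benefit = (1 + P . S / N) / 2`: the normalised inner product between
#' the (normalised) adult phenotype and the target pattern, mapped to
#' `[0, 1]` when `S` is a sign pattern. `S` may be real-valued (a noisy
#' target), in which case the value can leave `[0, 1]`.
#'
#' @param P_norm normalised adult phenotype, entries in `[-1, 1]`.
#' @param S target vector of the same length.
#' @return a single numeric value.
#' @export
benefit <- function(P_norm, S) {
  if (length(P_norm) != length(S)) {
    stop_dim("phenotype and target lengths differ (%d vs %d)",
             length(P_norm), length(S))
  }
  0.5 * (1 + sum(P_norm * S) / length(S))
}

#' Connection cost of a regulatory matrix
#'
#' `"L1"`: mean absolute coefficient, `sum(|b_ij|) / N^2`; `"L2"`: mean
#' squared coefficient, `sum(b_ij^2) / N^2`; `"none"`: 0.
#'
#' @param B numeric square matrix.
#' @param cost_norm `"none"`, `"L1"` or `"L2"`.
#' @return nonnegative numeric value.
#' @export
connection_cost <- function(B, cost_norm = c("none", "L1", "L2")) {
  cost_norm <- match.arg(cost_norm)
  switch(cost_norm,
         none = 0,
         L1 = sum(abs(B)) / length(B),
         L2 = sum(B^2) / length(B))
}

#' Benefit-minus-cost fitness
#'
#' @inheritParams benefit
#' @param B regulatory matrix whose connection cost is charged.
#' @param fp a [fitness_params()] object.
#' @return numeric fitness value (at most 1).
#' @export
grn_fitness <- function(P_norm, S, B, fp = fitness_params()) {
  benefit(P_norm, S) - fp$lambda * connection_cost(B, fp$cost_norm)
}

#' Point mutation of the direct effects
#'
#' Adds `Uniform[-g_step, g_step]` to one uniformly chosen gene and clamps
#' the result to `[-1, 1]`; all other entries are untouched.
#'
#' @param G numeric vector of direct effects.
#' @param mp a [mutation_params()] object.
#' @return the mutated vector.
#' @export
mutate_G <- function(G, mp = mutation_params(length(G))) {
  i <- sample.int(length(G), 1L)
  u <- runif(1L, -mp$g_step, mp$g_step)
  G[i] <- min(max(G[i] + u, -1), 1)
  G
}

#' Mutation of the regulatory matrix
#'
#' With probability `b_prob` every element independently receives a
#' `Uniform[-b_step, b_step]` increment (no clamping); otherwise the matrix
#' is returned unchanged.
#'
#' @param B numeric square matrix.
#' @param mp a [mutation_params()] object.
#' @return the (possibly) mutated matrix.
#' @export
mutate_B <- function(B, mp = mutation_params(nrow(B))) {
  if (runif(1L) < mp$b_prob) {
    B <- B + matrix(runif(length(B), -mp$b_step, mp$b_step), nrow(B))
  }
  B
}

#' One generation of strong-selection/weak-mutation hill climbing
#'
#' Proposes a mutant `[G', B']`, develops parent and mutant, and accepts
#' the mutant iff its fitness strictly exceeds the parent's. Ties are
#' rejected. Under environmental noise (`kappa > 0`) parent and mutant are
#' by default evaluated against independent noisy realisations of the
#' current target (each selection event sees its own environmental state);
#' `noise_mode = "shared"` evaluates both against one realisation, which
#' nearly cancels the noise out of the selection differential. This
#' reference implementation mirrors the compiled loop inside
#' [run_evolution()] and is used for property-level validation.
#'
#' @param state list with elements `G`, `B` and `generation`.
#' @param S the active (noiseless) target pattern.
#' @param fp,mp,dev fitness, mutation and development parameter objects.
#' @param noise_mode `"independent"` (default) or `"shared"` noisy-target
#'   realisations for parent and mutant.
#' @return the updated state list, with `current_fitness` and `accepted`
#'   fields describing the outcome.
#' @export
hill_climb_step <- function(state, S, fp = fitness_params(),
                            mp = mutation_params(length(state$G)),
                            dev = development_params(),
                            noise_mode = c("independent", "shared")) {
  noise_mode <- match.arg(noise_mode)
  S_eff <- noisy_target(S, fp$kappa)
  S_eff2 <- if (noise_mode == "independent" && fp$kappa > 0) {
    noisy_target(S, fp$kappa)
  } else {
    S_eff
  }
  G2 <- mutate_G(state$G, mp)
  B2 <- mutate_B(state$B, mp)
  P_par <- develop(state$G, state$B, dev)$normalized
  P_mut <- develop(G2, B2, dev)$normalized
  f_par <- grn_fitness(P_par, S_eff, state$B, fp)
  f_mut <- grn_fitness(P_mut, S_eff2, B2, fp)
  accepted <- f_mut > f_par
  if (accepted) {
    state$G <- G2
    state$B <- B2
  }
  state$generation <- (state$generation %||% 0L) + 1L
  state$current_fitness <- if (accepted) f_mut else f_par
  state$accepted <- accepted
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evolve a genotype under a schedule of selective environments
#'
#' Runs the hill climber for `schedule$total_generations` generations,
#' starting from `G ~ Uniform[-1, 1]^N` and `B = 0` (a developmental
#' organisation representing all sign patterns equally). At every
#' `record_cadence` epochs the induced phenotype distribution is measured
#' by Classify-and-Count on a fixed embryonic sample (noiseless targets,
#' independent of the evolution stream) and the chi-squared training/test
#' errors, unfolded entropy, class coverage and mean parent benefit are
#' recorded.
#'
#' @param schedule an [environment_schedule()] built from the training
#'   targets.
#' @param class the [build_class()] object (test set = all members).
#' @param fp,mp,dev parameter objects; `mp` defaults to
#'   [mutation_params()] for the class trait count.
#' @param seed integer seed; the full run is reproducible from it.
#' @param train_indices 1-based class rows forming the training set, used
#'   for the training-error measurement. Defaults to matching schedule
#'   targets against class members.
#' @param record_cadence measurement interval in epochs (default 1).
#' @param n_meas embryonic sample size for measurement (default 5000).
#' @param sampler `"sobol_scrambled"` (default) or `"uniform"` for the
#'   measurement sample.
#' @param coverage_threshold folded frequency below which a class member
#'   counts as unexpressed (default 0.01).
#' @param snapshot_every optional cadence (in recorded epochs) at which to
#'   keep copies of `B`; 0 disables snapshots.
#' @param noise_mode `"independent"` (default) or `"shared"` noisy-target
#'   realisations for parent and mutant (see [hill_climb_step()]).
#' @return an object of class `evolution_result`: list with the `trace`
#'   data frame (one row per recorded epoch), the final `genotype`
#'   (`G`, `B`), any `snapshots`, and the call parameters.
#' @export
run_evolution <- function(schedule, class, fp = fitness_params(),
                          mp = NULL, dev = development_params(),
                          seed = 1L, train_indices = NULL,
                          record_cadence = 1L, n_meas = 5000L,
                          sampler = c("sobol_scrambled", "uniform"),
                          coverage_threshold = 0.01,
                          snapshot_every = 0L,
                          noise_mode = c("independent", "shared")) {
  noise_mode <- match.arg(noise_mode)
  stopifnot(inherits(schedule, "environment_schedule"),
            inherits(class, "phenotype_class"),
            inherits(fp, "fitness_params"),
            inherits(dev, "development_params"))
  sampler <- match.arg(sampler)
  N <- class$layout$N
  if (ncol(schedule$targets) != N) {
    stop_dim("schedule targets have %d traits but the class has %d",
             ncol(schedule$targets), N)
  }
  if (is.null(mp)) mp <- mutation_params(N)
  if (is.null(train_indices)) {
    keys <- apply(class$members, 1L, pattern_key)
    train_indices <- match(apply(schedule$targets, 1L, pattern_key), keys)
    if (anyNA(train_indices)) {
      stop("schedule targets not found among class members; pass ",
           "train_indices explicitly", call. = FALSE)
    }
  }
  epoch_gens <- schedule$n_targets * schedule$K
  cadence_gens <- as.numeric(record_cadence) * epoch_gens
  # measurement sample: fixed for the whole run, separate stream from the
  # evolution RNG (offset-derived seed)
  meas_G <- sample_embryos(n_meas, N, sampler, seed = seed + 500009L)

  set.seed(seed)
  G0 <- runif(N, -1, 1)
  B0 <- matrix(0, N, N)
  res <- cpp_run_evolution(
    G0, B0, schedule$targets, schedule$block_targets - 1L,
    as.integer(schedule$K), schedule$total_generations,
    fp$lambda, match(fp$cost_norm, c("none", "L1", "L2")) - 1L,
    fp$kappa, mp$g_step, mp$b_prob, mp$b_step,
    dev$tau1, dev$tau2, dev$n_steps,
    meas_G, class$members, train_indices - 1L,
    coverage_threshold, as.integer(cadence_gens),
    as.integer(snapshot_every),
    as.integer(noise_mode == "independent")
  )
  trace <- data.frame(
    epoch = seq_along(res$generation) * record_cadence,
    generation = res$generation,
    training_error = res$training_error,
    test_error = res$test_error,
    entropy_bits = res$entropy_bits,
    class_coverage = res$class_coverage,
    mean_benefit = res$mean_benefit
  )
  structure(
    list(trace = trace,
         genotype = list(G = res$G, B = res$B),
         snapshots = res$snapshots,
         accepted_b_mutations = res$accepted_b_mutations,
         params = list(fp = fp, mp = mp, dev = dev, seed = seed,
                       K = schedule$K, order_policy = schedule$order_policy,
                       total_generations = schedule$total_generations,
                       train_indices = train_indices, n_meas = n_meas,
                       sampler = sampler,
                       coverage_threshold = coverage_threshold,
                       noise_mode = noise_mode)),
    class = "evolution_result"
  )
}

#' @export
print.evolution_result <- function(x, ...) {
  tr <- x$trace
  cat(sprintf(
    "GRN evolution run: %g generations (K = %g), %d recorded epochs\n",
    x$params$total_generations, x$params$K, nrow(tr)))
  if (nrow(tr)) {
    last <- tr[nrow(tr), ]
    cat(sprintf(
      "  final: training error %.3f, test error %.3f, entropy %.2f bits, coverage %d\n",
      last$training_error, last$test_error, last$entropy_bits,
      last$class_coverage))
  }
  invisible(x)
}

#' Plot training/test error traces of an evolution run
#'
#' @param x an `evolution_result`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.evolution_result <- function(x, ...) {
  tr <- x$trace
  graphics::matplot(tr$epoch, cbind(tr$training_error, tr$test_error),
                    type = "l", lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "chi-squared error", ...)
  graphics::legend("topright", c("training", "test"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}
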