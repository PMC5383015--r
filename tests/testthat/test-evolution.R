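test_that("benefit matches its analytic values and bounds", {
  S <- c(1L, -1L, 1L, -1L)
  expect_equal(benefit(as.numeric(S), S), 1)
  expect_equal(benefit(-as.numeric(S), S), 0)
  expect_equal(benefit(c(1, 1, -1, -1), S), 0.5)  # orthogonal
  expect_error(benefit(c(1, 1), S), "lengths differ")
  set.seed(2)
  for (rep in 1:50) {
    P <- runif(4, -1, 1)
    expect_true(benefit(P, S) >= 0 && benefit(P, S) <= 1)
  }
})

test_that("connection cost matches hand-computed values and homogeneity", {
  B <- matrix(0.5, 2, 2)
  expect_equal(connection_cost(B, "L1"), 0.5)   # 4 * 0.5 / 4
  expect_equal(connection_cost(B, "L2"), 0.25)  # 4 * 0.25 / 4
  expect_equal(connection_cost(B, "none"), 0)
  expect_equal(connection_cost(matrix(0, 3, 3), "L1"), 0)
  expect_error(connection_cost(B, "L3"))
  set.seed(4)
  M <- matrix(rnorm(16), 4)
  for (a in c(-2, 0.3, 7)) {
    expect_equal(connection_cost(a * M, "L1"),
                 abs(a) * connection_cost(M, "L1"))
    expect_equal(connection_cost(a * M, "L2"),
                 a^2 * connection_cost(M, "L2"))
  }
})

test_that("fitness composes benefit and cost", {
  S <- c(1L, -1L)
  B <- matrix(0.5, 2, 2)
  expect_equal(grn_fitness(as.numeric(S), S, B,
                           fitness_params(0.22, "L1")),
               1 - 0.22 * 0.5)  # = 0.89
  expect_equal(grn_fitness(as.numeric(S), S, B, fitness_params(0, "none")),
               1)
  expect_equal(grn_fitness(as.numeric(S), S, matrix(0, 2, 2),
                           fitness_params(5, "L1")), 1)
  set.seed(1)
  for (rep in 1:20) {
    P <- runif(2, -1, 1)
    expect_lte(grn_fitness(P, S, B, fitness_params(runif(1), "L2")), 1)
  }
})

test_that("G mutation is single-gene, clamped, symmetric", {
  mp <- mutation_params(4)
  set.seed(6)
  G <- runif(4, -1, 1)
  deltas <- numeric(0)
  for (rep in 1:2000) {
    G2 <- mutate_G(G, mp)
    changed <- which(G2 != G)
    expect_lte(length(changed), 1L)
    if (length(changed)) deltas <- c(deltas, G2[changed] - G[changed])
    expect_true(all(abs(G2) <= 1))
  }
  expect_lt(abs(mean(deltas)),
            3 * (mp$g_step / sqrt(3)) / sqrt(length(deltas)))
  # upward mutations of a saturated gene clamp exactly at 1
  up <- replicate(200, mutate_G(rep(1, 1), mutation_params(1)))
  expect_true(all(up <= 1))
  expect_true(any(up == 1))
})

test_that("B mutation hits at its configured rate and step bound", {
  mp <- mutation_params(16)
  expect_equal(mp$b_step, 0.1 / (15 * 256))
  set.seed(8)
  B <- matrix(0, 4, 4)
  mp4 <- mutation_params(4, b_prob = 1 / 15)
  hits <- 0L
  for (rep in 1:20000) {
    B2 <- mutate_B(B, mp4)
    if (!identical(B2, B)) {
      hits <- hits + 1L
      expect_true(all(abs(B2 - B) <= mp4$b_step))
      expect_true(all(B2 != B))  # every element perturbed
    }
  }
  p_hat <- hits / 20000
  se <- sqrt((1 / 15) * (14 / 15) / 20000)
  expect_lt(abs(p_hat - 1 / 15), 3 * se)
})

test_that("hill climbing rejects deleterious and tied mutants", {
  cls <- tiny_class()
  S <- cls$members[1, ]
  dev <- dev_default
  # zero-size mutations give exact fitness ties: genotype must not move
  mp0 <- mutation_params(4, g_step = 1e-300, b_step = 1e-300,
                         b_prob = 1e-12)
  state <- list(G = runif(4, -1, 1), B = matrix(0, 4, 4), generation = 0L)
  st2 <- hill_climb_step(state, S, fitness_params(), mp0, dev)
  expect_false(st2$accepted)
  expect_identical(st2$G, state$G)
  expect_identical(st2$B, state$B)
  expect_equal(st2$generation, 1L)

  # with kappa = 0 and lambda = 0, accepted-lineage fitness never decreases
  set.seed(33)
  mp <- mutation_params(4)
  state <- list(G = runif(4, -1, 1), B = matrix(0, 4, 4), generation = 0L)
  f_prev <- -Inf
  for (g in 1:300) {
    state <- hill_climb_step(state, S, fitness_params(), mp, dev)
    expect_gte(state$current_fitness, f_prev)
    f_prev <- state$current_fitness
  }
  expect_gt(f_prev, 0.5)  # direct effects adapt towards the target
})

test_that("run_evolution is reproducible and well-formed", {
  cls <- tiny_class()
  sch <- environment_schedule(cls$members, K = 50, total_generations = 2000)
  args <- list(schedule = sch, class = cls, fp = fitness_params(),
               dev = dev_default, seed = 99, n_meas = 500)
  r1 <- do.call(run_evolution, args)
  r2 <- do.call(run_evolution, args)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$genotype, r2$genotype)
  expect_equal(nrow(r1$trace), 20L)  # 2000 / (2 * 50)
  expect_true(all(r1$trace$test_error >= 0))
  expect_true(all(r1$trace$entropy_bits >= 0))
  expect_true(all(r1$trace$class_coverage %in% 0:2))

  # dimension mismatch between class and schedule is rejected
  big <- default_class()
  expect_error(run_evolution(sch, big, fitness_params(), seed = 1),
               "traits")
})

test_that("compiled hill climber agrees with the R reference on G-only runs", {
  # with b_prob effectively 0 and kappa = 0 the climber is a deterministic
  # function of the proposal stream; both implementations must land on a
  # genotype with the same developed sign pattern and similar benefit
  cls <- tiny_class()
  S <- cls$members[1, ]
  sch <- environment_schedule(cls$members[1, , drop = FALSE], K = 1500,
                              total_generations = 1500)
  res <- run_evolution(sch, cls, fitness_params(),
                       mutation_params(4, b_prob = 1e-12), dev_default,
                       seed = 5, n_meas = 200)
  set.seed(170)
  state <- list(G = runif(4, -1, 1), B = matrix(0, 4, 4), generation = 0L)
  for (g in 1:1500) {
    state <- hill_climb_step(state, S, fitness_params(),
                             mutation_params(4, b_prob = 1e-12),
                             dev_default)
  }
  expect_identical(
    sign_pattern(develop(res$genotype$G, res$genotype$B, dev_default)),
    sign_pattern(develop(state$G, state$B, dev_default)))
  expect_identical(sign_pattern(develop(state$G, state$B, dev_default)),
                   unname(S))
})
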