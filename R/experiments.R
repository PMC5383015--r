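#' Configuration of a named evolutionary scenario
#'
#' Bundles every parameter of a simulation campaign. Presets follow the
#' four headline scenarios: `control` (moderate switching, no noise, no
#' cost), `noise` (kappa = 35e-4), `weak_L2` (L2 cost, lambda = 38),
#' `sparse_L1` (L1 cost, lambda = 0.22), plus the switching-rate sweep
#' (fixed total of 24e6 generations over a grid of K) and lambda/kappa
#' sensitivity sweeps. `scale_factor` multiplies `K` (and hence the total
#' generation count, epochs being held fixed) for scaled-down runs; the
#' exposure per environment relative to the mutation step sizes is the
#' quantity that matters, and intermediate switching works over a wide
#' range of K.
#'
#' @param scenario one of `"control"`, `"noise"`, `"weak_L2"`,
#'   `"sparse_L1"`, `"switching_sweep"`, `"sensitivity_lambda"`,
#'   `"sensitivity_kappa"`, `"adaptation"`.
#' @param n_modules,module_width,class_seed,b_subpatterns class layout
#'   settings (see [build_class()]).
#' @param train_indices training-set member rows; `NULL` (default) picks
#'   the representative triple of [default_train_indices()].
#' @param K generations per environment (default 20000).
#' @param epochs number of epochs, each `N_T * K` generations
#'   (default 150).
#' @param order_policy environment visiting order (default `"cyclic"`).
#' @param lambda,cost_norm,kappa fitness settings; `NULL` means "use the
#'   scenario preset".
#' @param g_step,b_prob,b_step mutation settings (`b_step = NULL` gives the
#'   `0.1/(15 N^2)` default).
#' @param tau1,tau2,n_steps development settings.
#' @param n_meas,sampler,coverage_threshold measurement settings.
#' @param seeds integer vector of replicate seeds (default `1:3`).
#' @param record_cadence trace cadence in epochs.
#' @param scale_factor positive multiplier applied to `K` (default 1;
#'   use 0.1 for the scaled-down presets).
#' @param K_grid switching-sweep grid of K values.
#' @param lambda_grid,kappa_grid sensitivity grids.
#' @param total_generations fixed total for the switching sweep
#'   (default 24e6).
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(
    scenario = c("control", "noise", "weak_L2", "sparse_L1",
                 "switching_sweep", "sensitivity_lambda",
                 "sensitivity_kappa", "adaptation"),
    n_modules = 4L, module_width = 4L, class_seed = 1L,
    b_subpatterns = NULL, train_indices = NULL,
    K = 20000, epochs = 150L, order_policy = "cyclic",
    lambda = NULL, cost_norm = NULL, kappa = NULL,
    g_step = 0.1, b_prob = 0.5, b_step = NULL,
    tau1 = 1, tau2 = 0.2, n_steps = 10L,
    n_meas = 5000L, sampler = "sobol_scrambled",
    coverage_threshold = 0.01,
    seeds = 1:3, record_cadence = 1L, scale_factor = 1,
    K_grid = c(2, 4e4, 2e6, 4e6),
    lambda_grid = NULL, kappa_grid = NULL,
    total_generations = 24e6) {
  scenario <- match.arg(scenario)
  if (scale_factor <= 0) stop("scale_factor must be positive", call. = FALSE)
  preset <- switch(scenario,
    control = list(lambda = 0, cost_norm = "none", kappa = 0),
    noise = list(lambda = 0, cost_norm = "none", kappa = 35e-4),
    weak_L2 = list(lambda = 38, cost_norm = "L2", kappa = 0),
    sparse_L1 = list(lambda = 0.22, cost_norm = "L1", kappa = 0),
    list(lambda = 0, cost_norm = "none", kappa = 0)
  )
  if (is.null(lambda)) lambda <- preset$lambda
  if (is.null(cost_norm)) cost_norm <- preset$cost_norm
  if (is.null(kappa)) kappa <- preset$kappa
  if (is.null(lambda_grid)) {
    # log-spaced grids spanning the over-fitting, effective and
    # under-fitting regimes of each cost norm, with the headline optima
    # (L1 0.22, L2 38) interior
    lambda_grid <- if (identical(cost_norm, "L2")) {
      c(0.1, 10, 38, 200, 1000)
    } else {
      c(1e-4, 1e-2, 0.22, 1, 30)
    }
  }
  if (is.null(kappa_grid)) kappa_grid <- c(0, 1e-3, 35e-4, 1e-2, 5e-2)
  if (is.null(train_indices)) {
    train_indices <- default_train_indices(
      build_class(n_modules, module_width, b_subpatterns, seed = class_seed))
  }
  cfg <- list(
    scenario = scenario, n_modules = as.integer(n_modules),
    module_width = as.integer(module_width),
    class_seed = as.integer(class_seed), b_subpatterns = b_subpatterns,
    train_indices = as.integer(train_indices),
    K = K * scale_factor, epochs = as.integer(epochs),
    order_policy = order_policy,
    lambda = lambda, cost_norm = cost_norm, kappa = kappa,
    g_step = g_step, b_prob = b_prob, b_step = b_step,
    tau1 = tau1, tau2 = tau2, n_steps = as.integer(n_steps),
    n_meas = as.integer(n_meas), sampler = sampler,
    coverage_threshold = coverage_threshold,
    seeds = as.integer(seeds), record_cadence = as.integer(record_cadence),
    scale_factor = scale_factor,
    K_grid = K_grid * scale_factor,
    lambda_grid = lambda_grid, kappa_grid = kappa_grid,
    total_generations = total_generations * scale_factor
  )
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario_config <- function(cfg) {
  N <- cfg$n_modules * cfg$module_width
  if (cfg$K < 1) stop("K must be at least 1", call. = FALSE)
  if (cfg$epochs < 1) stop("epochs must be at least 1", call. = FALSE)
  if (cfg$lambda < 0 || cfg$kappa < 0) {
    stop("lambda and kappa must be nonnegative", call. = FALSE)
  }
  if (!cfg$cost_norm %in% c("none", "L1", "L2")) {
    stop("cost_norm must be one of none, L1, L2", call. = FALSE)
  }
  if (!cfg$sampler %in% c("sobol_scrambled", "uniform")) {
    stop("unknown sampler", call. = FALSE)
  }
  n_members <- 2^(cfg$n_modules - 1L)
  if (any(cfg$train_indices < 1L | cfg$train_indices > n_members)) {
    stop(sprintf("train_indices must lie in 1..%d", n_members),
         call. = FALSE)
  }
  if (length(cfg$seeds) < 1L) stop("at least one seed", call. = FALSE)
  invisible(cfg)
}

# shared plumbing: build class/split/params from a config
config_components <- function(cfg) {
  class <- build_class(cfg$n_modules, cfg$module_width, cfg$b_subpatterns,
                       seed = cfg$class_seed)
  split <- training_split(class, cfg$train_indices)
  N <- class$layout$N
  mp <- mutation_params(
    N, g_step = cfg$g_step, b_prob = cfg$b_prob,
    b_step = if (is.null(cfg$b_step)) 0.1 / (15 * N^2) else cfg$b_step
  )
  list(
    class = class, split = split,
    fp = fitness_params(cfg$lambda, cfg$cost_norm, cfg$kappa),
    mp = mp,
    dev = development_params(cfg$tau1, cfg$tau2, cfg$n_steps)
  )
}

run_one_evolution <- function(cfg, seed, K = cfg$K, comp = NULL) {
  if (is.null(comp)) comp <- config_components(cfg)
  n_t <- length(cfg$train_indices)
  total <- if (cfg$scenario == "switching_sweep") {
    cfg$total_generations
  } else {
    cfg$epochs * n_t * K
  }
  sch <- environment_schedule(comp$split$train, K, total,
                              cfg$order_policy, seed = seed)
  run_evolution(sch, comp$class, comp$fp, comp$mp, comp$dev, seed = seed,
                train_indices = cfg$train_indices,
                record_cadence = cfg$record_cadence,
                n_meas = cfg$n_meas, sampler = cfg$sampler,
                coverage_threshold = cfg$coverage_threshold)
}

#' Execute a scenario and write its artefacts to a run directory
#'
#' Runs one replicate per seed, writing per-seed trace CSVs, the final
#' induced phenotype distribution, an error report, a JSON manifest (the
#' full configuration, for exact reproduction) and a plain-text log.
#'
#' @param cfg a [scenario_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `dir`, the per-seed `results`
#'   (`evolution_result` objects) and `reports`.
#' @export
run_scenario <- function(cfg, out_dir = tempfile("grnrun")) {
  stopifnot(inherits(cfg, "scenario_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  comp <- config_components(cfg)
  log_path <- file.path(out_dir, "log.txt")
  log_line <- function(...) {
    cat(sprintf(...), "\n", file = log_path, append = TRUE, sep = "")
  }
  log_line("scenario %s | K = %g | epochs = %d | lambda = %g (%s) | kappa = %g",
           cfg$scenario, cfg$K, cfg$epochs, cfg$lambda, cfg$cost_norm,
           cfg$kappa)
  log_line("order %s | %d training environments | one switch per K-block",
           cfg$order_policy, length(cfg$train_indices))
  results <- list()
  reports <- list()
  # the switching-rate sweep runs once per K-grid point; all other
  # scenarios run at the single configured K
  grid <- if (cfg$scenario == "switching_sweep") cfg$K_grid else cfg$K
  for (Kv in grid) for (seed in cfg$seeds) {
    res <- run_one_evolution(cfg, seed, K = Kv, comp = comp)
    tag <- if (cfg$scenario == "switching_sweep") {
      sprintf("K%g_seed%d", Kv, seed)
    } else {
      sprintf("seed%d", seed)
    }
    write.csv(res$trace, file.path(out_dir, sprintf("trace_%s.csv", tag)),
              row.names = FALSE)
    dist <- estimate_distribution(
      res$genotype$B, comp$dev, cfg$n_meas, cfg$sampler,
      seed = seed + 500009L)
    export_distribution_csv(
      dist, file.path(out_dir, sprintf("distribution_%s.csv", tag)))
    write_b_matrix(res$genotype$B,
                   file.path(out_dir, sprintf("B_%s.csv", tag)))
    cov <- class_coverage(dist, comp$class, cfg$coverage_threshold)
    rep <- list(
      seed = seed,
      K = Kv,
      training_error = chi_squared_error(dist, comp$split$train),
      test_error = chi_squared_error(dist, comp$split$test),
      entropy_bits = entropy_bits(dist),
      coverage_count = cov$count,
      covered_members = cov$members,
      min_test_error = min(res$trace$test_error),
      final_training_error = res$trace$training_error[nrow(res$trace)],
      final_test_error = res$trace$test_error[nrow(res$trace)],
      accepted_b_mutations = res$accepted_b_mutations
    )
    log_line("seed %d: final train %.3f test %.3f entropy %.2f coverage %d (accepted B mutations %g)",
             seed, rep$final_training_error, rep$final_test_error,
             rep$entropy_bits, rep$coverage_count,
             res$accepted_b_mutations)
    results[[tag]] <- res
    reports[[tag]] <- rep
  }
  manifest <- list(
    package = "grnevolve",
    version = as.character(utils::packageVersion("grnevolve")),
    config = unclass(cfg),
    created = format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  jsonlite::write_json(reports, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(dir = out_dir, results = results, reports = reports))
}

#' Rebuild a scenario configuration from a run manifest
#'
#' @param dir a run directory written by [run_scenario()].
#' @return the stored [scenario_config()].
#' @export
read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) {
    stop(sprintf("no manifest.json in %s", dir), call. = FALSE)
  }
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- m$config
  # scale_factor is already baked into the stored K / grids
  scenario_config(
    scenario = cfg$scenario, n_modules = cfg$n_modules,
    module_width = cfg$module_width, class_seed = cfg$class_seed,
    b_subpatterns = cfg$b_subpatterns, train_indices = cfg$train_indices,
    K = cfg$K, epochs = cfg$epochs, order_policy = cfg$order_policy,
    lambda = cfg$lambda, cost_norm = cfg$cost_norm, kappa = cfg$kappa,
    g_step = cfg$g_step, b_prob = cfg$b_prob, b_step = cfg$b_step,
    tau1 = cfg$tau1, tau2 = cfg$tau2, n_steps = cfg$n_steps,
    n_meas = cfg$n_meas, sampler = cfg$sampler,
    coverage_threshold = cfg$coverage_threshold,
    seeds = cfg$seeds, record_cadence = cfg$record_cadence,
    scale_factor = 1,
    K_grid = cfg$K_grid, lambda_grid = cfg$lambda_grid,
    kappa_grid = cfg$kappa_grid,
    total_generations = cfg$total_generations
  )
}

#' Sweep a sensitivity parameter over a grid
#'
#' Runs the configured scenario once per grid value and seed and records
#' the final training and test errors, exposing the characteristic
#' U-shape: over-fitting at low regularisation/noise, under-fitting at
#' high values (where the errors return to the no-model baseline).
#'
#' @param cfg a [scenario_config()]; `lambda`/`kappa` presets supply the
#'   non-swept parameters.
#' @param parameter `"lambda"` or `"kappa"`.
#' @param grid numeric vector of parameter values; defaults to the grid
#'   stored in `cfg`.
#' @param out_csv optional path for a tidy CSV of the table.
#' @return data frame with columns `parameter`, `value`, `seed`,
#'   `final_training_error`, `final_test_error`, `min_test_error`,
#'   `coverage`.
#' @export
sensitivity_sweep <- function(cfg, parameter = c("lambda", "kappa"),
                              grid = NULL, out_csv = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  parameter <- match.arg(parameter)
  if (is.null(grid)) {
    grid <- if (parameter == "lambda") cfg$lambda_grid else cfg$kappa_grid
  }
  if (length(grid) == 0L) stop("grid must be non-empty", call. = FALSE)
  if (any(grid < 0)) stop("grid values must be nonnegative", call. = FALSE)
  rows <- list()
  for (v in grid) {
    cfg_v <- cfg
    if (parameter == "lambda") {
      cfg_v$lambda <- v
      if (v > 0 && cfg_v$cost_norm == "none") {
        stop("lambda sweep requires cost_norm L1 or L2", call. = FALSE)
      }
      if (v == 0) cfg_v$cost_norm <- "none"
    } else {
      cfg_v$kappa <- v
    }
    for (seed in cfg$seeds) {
      res <- run_one_evolution(cfg_v, seed)
      tr <- res$trace
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = parameter, value = v, seed = seed,
        final_training_error = tr$training_error[nrow(tr)],
        final_test_error = tr$test_error[nrow(tr)],
        min_test_error = min(tr$test_error),
        coverage = tr$class_coverage[nrow(tr)]
      )
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Summarise completed run directories into one table
#'
#' Aggregates the stored reports of one or more [run_scenario()] output
#' directories without recomputation.
#'
#' @param dirs character vector of run directories.
#' @param out_csv optional CSV path for the summary.
#' @return data frame, one row per run directory.
#' @export
compare_runs <- function(dirs, out_csv = NULL) {
  stopifnot(length(dirs) >= 1)
  rows <- lapply(dirs, function(d) {
    mpath <- file.path(d, "manifest.json")
    rpath <- file.path(d, "report.json")
    if (!file.exists(mpath) || !file.exists(rpath)) {
      stop(sprintf("run directory %s is missing manifest or report", d),
           call. = FALSE)
    }
    m <- jsonlite::read_json(mpath, simplifyVector = TRUE)
    reps <- jsonlite::read_json(rpath, simplifyVector = FALSE)
    num <- function(field) {
      vapply(reps, function(r) as.numeric(r[[field]]), numeric(1))
    }
    adapt_path <- file.path(d, "adaptation.csv")
    adapt_median <- if (file.exists(adapt_path)) {
      median(read.csv(adapt_path)$generations)
    } else {
      NA_real_
    }
    data.frame(
      dir = d, scenario = m$config$scenario,
      lambda = m$config$lambda, cost_norm = m$config$cost_norm,
      kappa = m$config$kappa, n_seeds = length(reps),
      median_final_training_error = median(num("final_training_error")),
      median_final_test_error = median(num("final_test_error")),
      median_min_test_error = median(num("min_test_error")),
      median_entropy_bits = median(num("entropy_bits")),
      modal_coverage = modal_value(num("coverage_count")),
      median_adaptation_generations = adapt_median
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) write.csv(out, out_csv, row.names = FALSE)
  out
}

modal_value <- function(x) {
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])
}
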