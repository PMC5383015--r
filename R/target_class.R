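#' Modular layout of the phenotype class
#'
#' A phenotype is a vector of `N = n_modules * module_width` signed traits,
#' partitioned into modules. Each module has two complementary sub-patterns:
#' state B (stored here) and state A, its elementwise negation. Selective
#' targets are concatenations of one state per module, so the class of
#' targets shares intra-module regularities while module combinations vary
#' freely between environments.
#'
#' @param n_modules number of modules (default 4).
#' @param module_width traits per module (default 4).
#' @param b_subpatterns optional list of `n_modules` sign vectors (entries
#'   in `{-1, +1}`) of length `module_width`, the B state of each module.
#'   When omitted, sub-patterns are drawn reproducibly from `seed`.
#' @param seed integer seed used only when `b_subpatterns` is `NULL`.
#' @return an object of class `module_layout` with fields `n_modules`,
#'   `module_width`, `N` and `b_subpatterns`.
#' @export
#' @examples
#' layout <- module_layout(4, 4, seed = 1)
#' layout$N
module_layout <- function(n_modules = 4L, module_width = 4L,
                          b_subpatterns = NULL, seed = 1L) {
  n_modules <- as.integer(n_modules)
  module_width <- as.integer(module_width)
  if (is.na(n_modules) || n_modules < 1L) {
    stop_dim("n_modules must be a positive integer")
  }
  if (is.na(module_width) || module_width < 1L) {
    stop_dim("module_width must be a positive integer")
  }
  if (is.null(b_subpatterns)) {
    b_subpatterns <- with_seed(seed, lapply(seq_len(n_modules), function(m) {
      sample(c(-1L, 1L), module_width, replace = TRUE)
    }))
  } else {
    if (length(b_subpatterns) != n_modules) {
      stop_dim("b_subpatterns must have one entry per module")
    }
    b_subpatterns <- lapply(b_subpatterns, function(p) {
      if (length(p) != module_width) {
        stop_dim("each sub-pattern must have module_width entries")
      }
      assert_sign_vector(p, "sub-pattern")
      as.integer(p)
    })
  }
  structure(
    list(n_modules = n_modules, module_width = module_width,
         N = n_modules * module_width, b_subpatterns = b_subpatterns),
    class = "module_layout"
  )
}

#' @export
print.module_layout <- function(x, ...) {
  cat(sprintf("Module layout: %d modules x %d traits (N = %d)\n",
              x$n_modules, x$module_width, x$N))
  for (m in seq_len(x$n_modules)) {
    cat(sprintf("  module %d: B = %s, A = %s\n", m,
                pattern_key(x$b_subpatterns[[m]]),
                pattern_key(-x$b_subpatterns[[m]])))
  }
  invisible(x)
}

#' Build the modular phenotype class
#'
#' Enumerates all `2^n_modules` combinations of per-module A/B states and
#' folds each pattern with its elementwise complement, keeping as canonical
#' representative the member of each pair whose first trait is `+1`. The
#' result is the class of `2^(n_modules - 1)` distinct target phenotypes
#' (8 under the default 4 x 4 layout), ordered lexicographically
#' (`+1` sorting before `-1`).
#'
#' @inheritParams module_layout
#' @param layout optionally, a prebuilt [module_layout()]; overrides the
#'   other layout arguments.
#' @return an object of class `phenotype_class`: a list with the `layout`
#'   and `members`, an `n_members x N` integer matrix of `-1`/`+1` with row
#'   labels `"P1"`, `"P2"`, ...
#' @export
#' @examples
#' cls <- build_class(4, 4, seed = 1)
#' nrow(cls$members)  # 8
build_class <- function(n_modules = 4L, module_width = 4L,
                        b_subpatterns = NULL, seed = 1L, layout = NULL) {
  if (is.null(layout)) {
    layout <- module_layout(n_modules, module_width, b_subpatterns, seed)
  }
  stopifnot(inherits(layout, "module_layout"))
  nm <- layout$n_modules
  combos <- as.matrix(expand.grid(rep(list(c(1L, -1L)), nm)))
  patterns <- matrix(0L, nrow(combos), layout$N)
  for (r in seq_len(nrow(combos))) {
    patterns[r, ] <- unlist(lapply(seq_len(nm), function(m) {
      combos[r, m] * layout$b_subpatterns[[m]]
    }))
  }
  # fold complements: keep the representative whose first trait is +1
  canonical <- patterns[patterns[, 1L] == 1L, , drop = FALSE]
  # lexicographic order, +1 before -1
  ord <- do.call(order, as.data.frame(-canonical))
  members <- canonical[ord, , drop = FALSE]
  dimnames(members) <- list(paste0("P", seq_len(nrow(members))), NULL)
  structure(list(layout = layout, members = members),
            class = "phenotype_class")
}

#' @export
print.phenotype_class <- function(x, ...) {
  cat(sprintf("Phenotype class: %d members, N = %d traits\n",
              nrow(x$members), x$layout$N))
  for (k in seq_len(nrow(x$members))) {
    cat(sprintf("  %s: %s\n", rownames(x$members)[k],
                pattern_key(x$members[k, ])))
  }
  invisible(x)
}

#' Module-state signature of class members
#'
#' For each member and module, `+1` if the module expresses the layout's B
#' sub-pattern and `-1` for its complement (state A).
#'
#' @param class a [build_class()] object.
#' @return integer matrix, members x modules.
#' @keywords internal
module_signature <- function(class) {
  stopifnot(inherits(class, "phenotype_class"))
  lay <- class$layout
  sig <- vapply(seq_len(lay$n_modules), function(m) {
    idx <- ((m - 1L) * lay$module_width + 1L):(m * lay$module_width)
    apply(class$members[, idx, drop = FALSE], 1L, function(tr) {
      if (all(tr == lay$b_subpatterns[[m]])) 1L else -1L
    })
  }, integer(nrow(class$members)))
  rownames(sig) <- rownames(class$members)
  sig
}

#' Default training triple: a representative sample of class variation
#'
#' Returns the lexicographically first triple of member indices in which
#' every module state varies across the three members and every
#' module-pair product varies as well (no module, and no pair of modules,
#' is accidentally constant or locked over the whole training set). A
#' training sample chosen this way carries the class's combinatorial
#' structure; degenerate samples (e.g. three members sharing a module
#' state throughout) instead plant spurious inter-module correlations that
#' no evolutionary condition can unlearn. Module 1's state is fixed by the
#' complement-folding convention and is excluded from the variation
#' requirement.
#'
#' @param class a [build_class()] object with at least 2 modules and 3
#'   members.
#' @return integer vector of three member indices.
#' @export
default_train_indices <- function(class) {
  sig <- module_signature(class)
  n <- nrow(sig)
  if (n < 3L) return(seq_len(min(n, 3L)))
  vary_cols <- seq_len(ncol(sig))[-1L]  # module 1 fixed by folding
  for (i in 1:(n - 2L)) for (j in (i + 1L):(n - 1L)) for (k in (j + 1L):n) {
    s <- sig[c(i, j, k), vary_cols, drop = FALSE]
    if (!all(apply(s, 2L, function(x) length(unique(x)) > 1L))) next
    if (ncol(s) >= 2L) {
      pr <- utils::combn(ncol(s), 2L, function(p) {
        length(unique(s[, p[1L]] * s[, p[2L]])) > 1L
      })
      if (!all(pr)) next
    }
    return(c(i, j, k))
  }
  1:3  # no fully varying triple exists; fall back to the first members
}

#' Split the class into training and test sets
#'
#' The training set is the subset of class members used as selective
#' environments during evolution. The test set is always the full class
#' (it includes the trained targets), so zero test error corresponds to a
#' phenotype distribution uniform over all class members.
#'
#' @param class a [build_class()] object.
#' @param train_indices distinct 1-based member indices; defaults to the
#'   representative triple chosen by [default_train_indices()].
#' @return list with integer matrices `train` and `test` (rows = patterns)
#'   and the `train_indices`.
#' @export
training_split <- function(class, train_indices = default_train_indices(class)) {
  stopifnot(inherits(class, "phenotype_class"))
  n <- nrow(class$members)
  train_indices <- as.integer(train_indices)
  if (length(train_indices) == 0L) {
    stop("train_indices must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(train_indices)) {
    stop("train_indices must be distinct", call. = FALSE)
  }
  if (any(train_indices < 1L | train_indices > n)) {
    stop(sprintf("train_indices must lie in 1..%d", n), call. = FALSE)
  }
  list(train = class$members[train_indices, , drop = FALSE],
       test = class$members,
       train_indices = train_indices)
}

#' Schedule of switching selective environments
#'
#' The active target phenotype is constant within each block of `K`
#' generations and switches between blocks, either cycling through the
#' training targets in order (`"cyclic"`, the default) or drawing one target
#' uniformly at random per block (`"uniform_random"`, reproducible from
#' `seed`). One epoch is `N_T * K` generations, a full pass over the `N_T`
#' training environments.
#'
#' @param targets integer matrix of training targets (rows = patterns).
#' @param K generations per environment block.
#' @param total_generations total length of the run.
#' @param order_policy `"cyclic"` or `"uniform_random"`.
#' @param seed seed for the `"uniform_random"` block draws.
#' @return an object of class `environment_schedule`.
#' @export
environment_schedule <- function(targets, K, total_generations,
                                 order_policy = c("cyclic", "uniform_random"),
                                 seed = 1L) {
  order_policy <- match.arg(order_policy)
  targets <- rbind(targets)
  apply(targets, 1L, assert_sign_vector, what = "target")
  K <- as.numeric(K)
  total_generations <- as.numeric(total_generations)
  stopifnot(K >= 1, total_generations >= 1)
  n_blocks <- ceiling(total_generations / K)
  n_t <- nrow(targets)
  block_targets <- if (order_policy == "cyclic") {
    rep_len(seq_len(n_t), n_blocks)
  } else {
    with_seed(seed, sample.int(n_t, n_blocks, replace = TRUE))
  }
  structure(
    list(targets = targets, K = K, total_generations = total_generations,
         order_policy = order_policy, seed = as.integer(seed),
         n_targets = n_t, block_targets = block_targets),
    class = "environment_schedule"
  )
}

#' Active target at a given generation
#'
#' @param schedule an [environment_schedule()].
#' @param generation 0-based generation index in
#'   `[0, total_generations - 1]`.
#' @return the active target pattern (integer vector of `-1`/`+1`).
#' @export
#' @examples
#' cls <- build_class(2, 2, seed = 1)
#' sch <- environment_schedule(cls$members[1:2, ], K = 2,
#'                             total_generations = 8)
#' target_at(sch, 0)
target_at <- function(schedule, generation) {
  stopifnot(inherits(schedule, "environment_schedule"))
  if (generation < 0 || generation >= schedule$total_generations) {
    stop(sprintf("generation must lie in [0, %d)",
                 schedule$total_generations), call. = FALSE)
  }
  block <- floor(generation / schedule$K)
  schedule$targets[schedule$block_targets[block + 1L], ]
}

#' Add environmental noise to a target phenotype
#'
#' Returns `S + kappa * n` with `n` a fresh vector of iid standard normal
#' deviates, modelling extrinsic noise in the selective environment. The
#' result is real-valued and unbounded; with `kappa = 0` the target is
#' returned unchanged.
#'
#' @param S target pattern (`-1`/`+1` vector).
#' @param kappa nonnegative noise scale.
#' @return numeric vector of length `length(S)`.
#' @export
noisy_target <- function(S, kappa) {
  assert_sign_vector(S, "target")
  if (kappa < 0) stop("kappa must be nonnegative", call. = FALSE)
  if (kappa == 0) return(as.numeric(S))
  S + kappa * rnorm(length(S))
}

#' Serialise a phenotype class and schedule settings to JSON
#'
#' @param class a [build_class()] object.
#' @param path output file path.
#' @param train_indices,K,total_generations,order_policy,seed optional
#'   schedule settings stored alongside the layout.
#' @return `path`, invisibly.
#' @export
write_class_config <- function(class, path, train_indices = 1:3,
                               K = 20000, total_generations = NULL,
                               order_policy = "cyclic", seed = 1L) {
  stopifnot(inherits(class, "phenotype_class"))
  cfg <- list(
    n_modules = class$layout$n_modules,
    module_width = class$layout$module_width,
    b_subpatterns = vapply(class$layout$b_subpatterns, pattern_key,
                           character(1)),
    train_indices = as.integer(train_indices),
    K = K, total_generations = total_generations,
    order_policy = order_policy, seed = as.integer(seed)
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a class configuration written by [write_class_config()]
#'
#' @param path JSON file path.
#' @return list with the rebuilt `class` and the stored schedule settings.
#' @export
read_class_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  subs <- lapply(cfg$b_subpatterns, key_to_pattern)
  layout <- module_layout(cfg$n_modules, cfg$module_width, subs)
  list(class = build_class(layout = layout),
       train_indices = as.integer(cfg$train_indices),
       K = cfg$K, total_generations = cfg$total_generations,
       order_policy = cfg$order_policy, seed = cfg$seed)
}

#' Export class members as a CSV of signed traits
#'
#' One row per member: label, pattern key and the individual trait values.
#'
#' @param class a [build_class()] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_patterns_csv <- function(class, path) {
  stopifnot(inherits(class, "phenotype_class"))
  m <- class$members
  df <- data.frame(
    label = rownames(m),
    key = apply(m, 1L, pattern_key),
    m, check.names = FALSE
  )
  colnames(df)[-(1:2)] <- paste0("t", seq_len(ncol(m)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
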