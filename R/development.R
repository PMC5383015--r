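#' Parameters of the recurrent developmental map
#'
#' Development iterates `P(t+1) = (1 - tau2) * P(t) + tau1 * f(B %*% P(t))`
#' for `n_steps` steps from the embryonic state `P(0) = G`, where `f` is an
#' odd, bounded, monotone activation (hyperbolic tangent by default). With
#' `tau2` in (0, 1) trait magnitudes stay bounded by `tau1/tau2`, which is
#' also the normalisation constant mapping adult phenotypes into
#' `[-1, 1]^N`.
#'
#' @param tau1 activation gain (default 1).
#' @param tau2 decay rate in (0, 1) (default 0.2).
#' @param n_steps number of developmental iterations (default 10).
#' @param activation `"tanh"` (fast compiled path) or an odd bounded R
#'   function used by the reference R implementation.
#' @return an object of class `development_params`.
#' @export
development_params <- function(tau1 = 1, tau2 = 0.2, n_steps = 10L,
                               activation = "tanh") {
  stopifnot(tau1 > 0, tau2 > 0, tau2 < 1, n_steps >= 1)
  if (!(identical(activation, "tanh") || is.function(activation))) {
    stop("activation must be \"tanh\" or a function", call. = FALSE)
  }
  structure(list(tau1 = tau1, tau2 = tau2, n_steps = as.integer(n_steps),
                 activation = activation),
            class = "development_params")
}

#' Develop an embryonic phenotype into an adult phenotype
#'
#' Runs the recurrent GRN dynamics from `P(0) = G` under the regulatory
#' matrix `B` and returns both the raw final state `P(T)` and its
#' normalised version `P(T) * tau2 / tau1`, which lies in `[-1, 1]^N`
#' whenever `|G| <= tau1/tau2` entrywise. The map is deterministic and odd:
#' `develop(-G, B)` is the negation of `develop(G, B)`.
#'
#' @param G numeric vector of direct effects, entries in `[-1, 1]`.
#' @param B numeric `N x N` regulatory matrix (row = regulated gene,
#'   column = regulator).
#' @param params a [development_params()] object.
#' @return object of class `adult_phenotype`: list with `raw` and
#'   `normalized` numeric vectors.
#' @export
#' @examples
#' p <- development_params()
#' develop(runif(4, -1, 1), matrix(0, 4, 4), p)$normalized
develop <- function(G, B, params = development_params()) {
  stopifnot(inherits(params, "development_params"))
  N <- length(G)
  if (!is.matrix(B) || nrow(B) != N || ncol(B) != N) {
    stop_dim("B must be a %d x %d matrix to match G", N, N)
  }
  if (!all(is.finite(G)) || !all(is.finite(B))) {
    stop("G and B must be finite", call. = FALSE)
  }
  if (identical(params$activation, "tanh")) {
    norm <- cpp_develop_batch(matrix(as.numeric(G), nrow = 1L), B,
                              params$tau1, params$tau2, params$n_steps)[1L, ]
    raw <- norm * params$tau1 / params$tau2
  } else {
    f <- params$activation
    P <- as.numeric(G)
    for (t in seq_len(params$n_steps)) {
      P <- (1 - params$tau2) * P + params$tau1 * f(as.numeric(B %*% P))
    }
    raw <- P
    norm <- P * params$tau2 / params$tau1
  }
  structure(list(raw = raw, normalized = norm), class = "adult_phenotype")
}

#' Develop a batch of embryonic phenotypes
#'
#' Vectorised form of [develop()] over the rows of `G_matrix`; used by the
#' Classify-and-Count distribution estimator. Only the `"tanh"` activation
#' is supported on this path.
#'
#' @param G_matrix numeric matrix, one embryonic state per row.
#' @inheritParams develop
#' @return numeric matrix of normalised adult phenotypes (same shape).
#' @export
develop_batch <- function(G_matrix, B, params = development_params()) {
  stopifnot(inherits(params, "development_params"),
            identical(params$activation, "tanh"))
  N <- ncol(G_matrix)
  if (!is.matrix(B) || nrow(B) != N || ncol(B) != N) {
    stop_dim("B must be a %d x %d matrix", N, N)
  }
  cpp_develop_batch(G_matrix, B, params$tau1, params$tau2, params$n_steps)
}

#' Discretise an adult phenotype into a sign pattern
#'
#' Entrywise sign of the normalised phenotype; an entry exactly zero maps to
#' `+1` (deterministic tie rule, a measure-zero event under the continuous
#' dynamics).
#'
#' @param P an `adult_phenotype` from [develop()], or a numeric vector of
#'   normalised trait values.
#' @return integer vector of `-1`/`+1`.
#' @export
sign_pattern <- function(P) {
  x <- if (inherits(P, "adult_phenotype")) P$normalized else as.numeric(P)
  ifelse(x >= 0, 1L, -1L)
}

#' Write/read a regulatory matrix as dense CSV
#'
#' Row `i`, column `j` holds the coefficient `b_ij` of regulator `j` acting
#' on gene `i`.
#'
#' @param B numeric square matrix.
#' @param path file path.
#' @return `path` (write) or the matrix (read).
#' @export
write_b_matrix <- function(B, path) {
  utils::write.table(B, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_b_matrix
#' @export
read_b_matrix <- function(path) {
  unname(as.matrix(utils::read.table(path, sep = ",")))
}
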