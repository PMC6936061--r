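#' Configuration for a driver-prioritization run
#'
#' Collects every tunable parameter of the pipeline in one validated object.
#' The two damping weights are tied: `lambda_v` is always `1 - lambda_u`, so
#' the three mixing coefficients of the propagation update,
#' `(1 - lambda_u)`, `lambda_u * (1 - lambda_v)` and `lambda_u * lambda_v`,
#' sum to one for any admissible `lambda_u`.
#'
#' @param lambda_u Damping weight in `[0, 1]` given to the network terms of the
#'   propagation update; the remainder `1 - lambda_u` stays on the patient's own
#'   standardized expression. Default 0.9, placing most weight on the
#'   mutation-to-expression term.
#' @param epsilon Convergence threshold on the between-iteration change of the
#'   score vector. Default `1e-4`.
#' @param max_iter Iteration cap for the propagation. Default 100.
#' @param delta Condorcet penalty in `[0, 1]` applied to the normalized score of
#'   a gene that is *not* mutated in a given patient during pairwise
#'   comparison. Default 0.85.
#' @param top_k Number of top-ranked genes reported as candidate drivers.
#'   Default 100.
#' @param init Initialization of the propagation iterate: `"dx"` (differential
#'   expression, the default), `"x0"` (standardized expression) or `"zeros"`.
#' @param sym_norm Logical; if `TRUE` use symmetric degree normalization
#'   (`d_i^{-1/2} w_ij d_j^{-1/2}`) instead of the default one-sided source
#'   normalization (`w_ij d_j^{-1/2}`).
#' @param self_edges Logical; if `TRUE`, a gene present on both sides of a
#'   patient's bipartite graph gets an edge between its mutation node and its
#'   own expression node. Default `FALSE`: a mutated gene influences only its
#'   interaction partners.
#' @param candidate_pool Per-patient candidate cap for the aggregation: each
#'   patient contributes at most its `candidate_pool` best-ranked genes to the
#'   candidate set. Use `Inf` for no restriction. Default 1000.
#' @param missing_score Damage probability contributed by a mutation whose
#'   label passes a damage filter but whose numeric score is missing.
#'   Default 1.
#' @param convergence_norm Norm for the convergence test: `"max"` (default,
#'   per-gene maximum absolute change) or `"l2"`.
#' @param standardize_reference Cohort against which expression is z-scored:
#'   `"tumor"` (default) or `"normal"`.
#'
#' @return An object of class `mecorank_config` (a validated list).
#' @examples
#' cfg <- mecorank_config(lambda_u = 0.9)
#' cfg$lambda_v  # 0.1, always 1 - lambda_u
#' @export
mecorank_config <- function(lambda_u = 0.9,
                            epsilon = 1e-4,
                            max_iter = 100L,
                            delta = 0.85,
                            top_k = 100L,
                            init = c("dx", "x0", "zeros"),
                            sym_norm = FALSE,
                            self_edges = FALSE,
                            candidate_pool = 1000L,
                            missing_score = 1,
                            convergence_norm = c("max", "l2"),
                            standardize_reference = c("tumor", "normal")) {
  init <- match.arg(init)
  convergence_norm <- match.arg(convergence_norm)
  standardize_reference <- match.arg(standardize_reference)
  if (!is.numeric(lambda_u) || length(lambda_u) != 1L ||
      lambda_u < 0 || lambda_u > 1) {
    stop("`lambda_u` must be a single number in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    stop("`epsilon` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(max_iter) || length(max_iter) != 1L || max_iter < 1) {
    stop("`max_iter` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0 || delta > 1) {
    stop("`delta` must be a single number in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(top_k) || length(top_k) != 1L || top_k < 1) {
    stop("`top_k` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(candidate_pool) || length(candidate_pool) != 1L ||
      candidate_pool < 1) {
    stop("`candidate_pool` must be a positive integer or Inf", call. = FALSE)
  }
  if (!is.numeric(missing_score) || length(missing_score) != 1L ||
      missing_score < 0 || missing_score > 1) {
    stop("`missing_score` must be a single number in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      lambda_u = as.numeric(lambda_u),
      lambda_v = 1 - as.numeric(lambda_u),
      epsilon = as.numeric(epsilon),
      max_iter = as.integer(max_iter),
      delta = as.numeric(delta),
      top_k = as.integer(top_k),
      init = init,
      sym_norm = isTRUE(sym_norm),
      self_edges = isTRUE(self_edges),
      candidate_pool = candidate_pool,
      missing_score = as.numeric(missing_score),
      convergence_norm = convergence_norm,
      standardize_reference = standardize_reference
    ),
    class = "mecorank_config"
  )
}

#' @export
print.mecorank_config <- function(x, ...) {
  cat("Driver-prioritization configuration\n")
  cat(sprintf("  lambda_u = %g, lambda_v = %g\n", x$lambda_u, x$lambda_v))
  cat(sprintf("  epsilon = %g (%s norm), max_iter = %d\n",
              x$epsilon, x$convergence_norm, x$max_iter))
  cat(sprintf("  delta = %g, top_k = %d, candidate_pool = %s\n",
              x$delta, x$top_k, format(x$candidate_pool)))
  cat(sprintf("  init = %s, sym_norm = %s, self_edges = %s\n",
              x$init, x$sym_norm, x$self_edges))
  invisible(x)
}

# locale-independent lexicographic sort used for all gene/sample orderings
sort_genes <- function(x) sort(unique(x), method = "radix")
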