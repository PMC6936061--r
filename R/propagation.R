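# Shared pieces of the damped propagation update
#
#   x_i = (1 - lu) x0_i
#       + lu (1 - lv) sum_k w_ik^{vu} d_k^{-1/2} y_k
#       + lu lv       sum_j w_ij^{uu} d_j^{-1/2} x_j
#
# The first two terms are constant in x; the third is a sparse linear map.
# With the default one-sided normalization the d^{-1/2} factor always attaches
# to the source vertex (k in V, j in U); `sym_norm` adds the target-side factor
# as well. U-genes isolated in W_uu have d_j = 0 but never appear as a source
# of a nonzero term, so their 0^{-1/2} is defined as 0.
propagation_parts <- function(graph, config) {
  lu <- config$lambda_u
  lv <- config$lambda_v
  c0 <- (1 - lu) * graph$x0
  if (length(graph$V)) {
    if (any(graph$d_v <= 0)) {
      stop("graph has zero-degree mutation vertices; run prune_zero_vertices()",
           call. = FALSE)
    }
    t2 <- as.numeric(graph$W_vu %*% (graph$y / sqrt(graph$d_v)))
    if (config$sym_norm) {
      r <- Matrix::rowSums(graph$W_vu)
      t2 <- ifelse(r > 0, 1 / sqrt(r), 0) * t2
    }
    c0 <- c0 + lu * (1 - lv) * t2
  }
  s_u <- ifelse(graph$d_u > 0, 1 / sqrt(graph$d_u), 0)
  linmap <- if (config$sym_norm) {
    function(x) lu * lv * s_u * as.numeric(graph$W_uu %*% (s_u * x))
  } else {
    function(x) lu * lv * as.numeric(graph$W_uu %*% (s_u * x))
  }
  list(c0 = c0, linmap = linmap, s_u = s_u, lu = lu, lv = lv)
}

#' Propagate mutation and expression signal on a patient's bipartite graph
#'
#' Iterates the damped, degree-normalized update until the change in the score
#' vector falls below `epsilon` or `max_iter` is reached. The mutation-side
#' coefficients `y` are held fixed; the expression-side iterate is initialized
#' to the differential-expression vector by default (`config$init`). When the
#' linear part vanishes (`lambda_u * lambda_v == 0`, or no expression-side
#' edges) the fixed point is written down directly in one step.
#'
#' @param graph A pruned `patient_bipartite` (all `d_v > 0`).
#' @param config A [mecorank_config()].
#' @return An object of class `patient_ranking`: a list with `sample`, `genes`
#'   (the U partition), `scores` (converged vector over U),
#'   `iterations_used`, `converged`, `mutated` (genes with >= 1 somatic SNV in
#'   this sample) and `n_pruned`.
#' @export
propagate <- function(graph, config = mecorank_config()) {
  parts <- propagation_parts(graph, config)
  m <- length(graph$U)
  no_linear <- parts$lu * parts$lv == 0 || length(graph$W_uu@x) == 0L
  if (no_linear) {
    x <- parts$c0
    iterations <- 1L
    converged <- TRUE
  } else {
    x <- switch(config$init,
                dx = graph$dx,
                x0 = graph$x0,
                zeros = numeric(m))
    converged <- FALSE
    iterations <- config$max_iter
    prev_res <- Inf
    inc_run <- 0L
    for (t in seq_len(config$max_iter)) {
      x_new <- parts$c0 + parts$linmap(x)
      if (any(!is.finite(x_new))) {
        stop("non-finite scores during propagation for sample ",
             graph$sample, call. = FALSE)
      }
      res <- if (config$convergence_norm == "max") {
        max(abs(x_new - x))
      } else {
        sqrt(sum((x_new - x)^2))
      }
      x <- x_new
      if (res < config$epsilon) {
        converged <- TRUE
        iterations <- t
        break
      }
      inc_run <- if (res > prev_res) inc_run + 1L else 0L
      if (inc_run >= 10L) {
        stop(sprintf(
          "propagation diverging for sample %s (residual rose for 10 iterations, last %g); the degree-normalized update is not a contraction on this graph",
          graph$sample, res), call. = FALSE)
      }
      prev_res <- res
    }
  }
  structure(
    list(sample = graph$sample,
         genes = graph$U,
         scores = x,
         iterations_used = iterations,
         converged = converged,
         mutated = graph$mutated_genes,
         n_pruned = graph$n_pruned),
    class = "patient_ranking"
  )
}

#' Exact fixed point of the propagation by dense linear solve
#'
#' The update is affine in the score vector, so its fixed point solves
#' `(I - L) x = c0` where `L` is the damped, degree-normalized
#' expression-side map and `c0` collects the expression and mutation terms.
#' Intended as an independent cross-check of [propagate()] on small graphs.
#'
#' @param graph A pruned `patient_bipartite` with `|U| <= 2000`.
#' @param config A [mecorank_config()].
#' @return Numeric score vector over U.
#' @export
fixed_point_oracle <- function(graph, config = mecorank_config()) {
  m <- length(graph$U)
  if (m > 2000L) {
    stop("dense oracle restricted to |U| <= 2000", call. = FALSE)
  }
  parts <- propagation_parts(graph, config)
  lu <- parts$lu
  lv <- parts$lv
  if (lu * lv == 0 || length(graph$W_uu@x) == 0L) {
    return(parts$c0)
  }
  A <- as.matrix(graph$W_uu)
  A <- sweep(A, 2L, parts$s_u, `*`)
  if (config$sym_norm) {
    A <- sweep(A, 1L, parts$s_u, `*`)
  }
  sys <- diag(m) - lu * lv * A
  x <- tryCatch(solve(sys, parts$c0), error = function(e) {
    stop("singular propagation system (spectral radius of the damped map >= 1): ",
         conditionMessage(e), call. = FALSE)
  })
  as.numeric(x)
}

#' Order and normalize a patient's converged scores
#'
#' Sorts genes by score (descending, ties broken lexicographically) and
#' rescales scores affinely to `[0, 1]` so that the best gene gets exactly 1
#' and the worst 0. The normalized score is the `Rank(.)` quantity used in
#' pairwise Condorcet comparisons.
#'
#' @param ranking A `patient_ranking` from [propagate()].
#' @return A data frame with columns `gene`, `score`, `rank_score`
#'   (normalized), sorted best-first, with the sample ID as attribute
#'   `"sample"`.
#' @export
rank_patient <- function(ranking) {
  stopifnot(inherits(ranking, "patient_ranking"))
  sc <- ranking$scores
  rng <- range(sc)
  if (length(sc) == 1L || rng[1] == rng[2]) {
    if (length(sc) > 1L) {
      warning("all scores equal for sample ", ranking$sample,
              "; normalized scores set to 1, order lexicographic",
              call. = FALSE)
    }
    norm <- rep(1, length(sc))
  } else {
    norm <- (sc - rng[1]) / (rng[2] - rng[1])
  }
  ord <- order(-sc, ranking$genes, method = "radix")
  out <- data.frame(gene = ranking$genes[ord],
                    score = sc[ord],
                    rank_score = norm[ord],
                    stringsAsFactors = FALSE)
  attr(out, "sample") <- ranking$sample
  out
}

#' @export
print.patient_ranking <- function(x, ...) {
  cat(sprintf(
    "Patient ranking %s: %d genes, %d mutated, %s in %d iteration(s)\n",
    x$sample, length(x$genes), length(x$mutated),
    if (x$converged) "converged" else "NOT converged", x$iterations_used))
  top <- utils::head(rank_patient(x), 5L)
  cat("  top genes:", paste(top$gene, collapse = ", "), "\n")
  invisible(x)
}
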