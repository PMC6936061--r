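#' Build a patient's bipartite graph over the PPI network
#'
#' The left partition U holds the patient's expression genes that are present
#' in the PPI network (unfiltered); the right partition V holds the patient's
#' mutated genes present in the PPI. An edge between an expression node and a
#' mutation node is drawn exactly when the two genes interact in the PPI;
#' edges within U come from the same network. Both partitions are ordered
#' lexicographically for reproducibility. Weight matrices are binary and
#' stored sparse.
#'
#' @param profile A `patient_profile` from [build_profiles()].
#' @param ppi A `ppi_network`.
#' @param config A [mecorank_config()]; `self_edges = TRUE` additionally links
#'   a gene's mutation node to its own expression node when the gene sits on
#'   both sides.
#' @return An object of class `patient_bipartite`: a list with `sample`, `U`,
#'   `V` (gene vectors), `W_vu` (|U| x |V| sparse binary matrix), `W_uu`
#'   (|U| x |U| sparse symmetric binary matrix, zero diagonal), degree vectors
#'   `d_v` (column sums of `W_vu`) and `d_u` (row sums of `W_uu`), score
#'   vectors `x0`, `dx` (over U) and `y` (over V), the full set
#'   `mutated_genes` for this sample, and `n_pruned` (0 until pruning).
#' @export
build_bipartite <- function(profile, ppi, config = mecorank_config()) {
  U <- sort(intersect(names(profile$x0), ppi$genes), method = "radix")
  if (!length(U)) {
    stop("no expression genes overlap the PPI network for sample ",
         profile$sample, call. = FALSE)
  }
  mut_names <- names(profile$mutated)
  if (is.null(mut_names)) mut_names <- character(0)
  V <- sort(intersect(mut_names, ppi$genes), method = "radix")
  m <- length(U)
  n <- length(V)
  ea <- ppi$edges$from
  eb <- ppi$edges$to
  ua <- match(ea, U)
  ub <- match(eb, U)
  va <- match(ea, V)
  vb <- match(eb, V)

  both_u <- !is.na(ua) & !is.na(ub)
  W_uu <- Matrix::sparseMatrix(
    i = c(ua[both_u], ub[both_u]),
    j = c(ub[both_u], ua[both_u]),
    x = 1, dims = c(m, m), dimnames = list(U, U)
  )

  a_uv <- !is.na(ua) & !is.na(vb)   # from in U, to in V
  b_uv <- !is.na(ub) & !is.na(va)   # to in U, from in V
  vi <- c(ua[a_uv], ub[b_uv])
  vj <- c(vb[a_uv], va[b_uv])
  if (config$self_edges && n > 0L) {
    shared <- match(V, U)
    keep <- !is.na(shared)
    vi <- c(vi, shared[keep])
    vj <- c(vj, which(keep))
  }
  W_vu <- Matrix::sparseMatrix(i = vi, j = vj, x = 1, dims = c(m, n),
                               dimnames = list(U, V))

  structure(
    list(sample = profile$sample,
         U = U, V = V,
         W_vu = W_vu, W_uu = W_uu,
         d_v = Matrix::colSums(W_vu),
         d_u = Matrix::rowSums(W_uu),
         x0 = unname(profile$x0[U]),
         dx = unname(profile$dx[U]),
         y = unname(profile$mutated[V]),
         mutated_genes = sort(mut_names, method = "radix"),
         n_pruned = 0L),
    class = "patient_bipartite"
  )
}

#' Remove mutation-side vertices with no edges into the expression side
#'
#' A mutation node with degree zero cannot influence any expression node and
#' would make the inverse-square-root degree factor undefined, so such
#' vertices are removed. The expression side is never pruned. The operation is
#' idempotent.
#'
#' @param graph A `patient_bipartite`.
#' @return The graph with zero-degree V vertices (and the matching columns of
#'   `W_vu` and entries of `y`, `d_v`) removed; `n_pruned` accumulates the
#'   number dropped.
#' @export
prune_zero_vertices <- function(graph) {
  keep <- graph$d_v > 0
  if (all(keep)) {
    return(graph)
  }
  graph$W_vu <- graph$W_vu[, keep, drop = FALSE]
  graph$V <- graph$V[keep]
  graph$y <- graph$y[keep]
  graph$d_v <- graph$d_v[keep]
  graph$n_pruned <- graph$n_pruned + sum(!keep)
  graph
}

#' @export
print.patient_bipartite <- function(x, ...) {
  cat(sprintf(
    "Bipartite graph %s: |U| = %d, |V| = %d, |E(vu)| = %d, |E(uu)| = %d%s\n",
    x$sample, length(x$U), length(x$V),
    as.integer(sum(x$W_vu)), as.integer(sum(x$W_uu) / 2),
    if (x$n_pruned > 0L) sprintf(" (%d V pruned)", x$n_pruned) else ""))
  invisible(x)
}
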