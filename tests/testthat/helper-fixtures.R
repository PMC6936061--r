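# In-code fixtures and independent oracles shared across tests.

# small path PPI a-b-c, the worked toy of the graph/propagation tests
path_ppi <- function() {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "b\tc"), f)
  suppressMessages(read_ppi(f))
}

make_mutation_table <- function(sample, gene,
                                polyphen_label = "", polyphen_score = NA_real_,
                                sift_label = "", sift_score = NA_real_) {
  tab <- data.frame(sample = sample, gene = gene,
                    polyphen_label = polyphen_label,
                    polyphen_score = polyphen_score,
                    sift_label = sift_label, sift_score = sift_score,
                    stringsAsFactors = FALSE)
  class(tab) <- c("mutation_table", "data.frame")
  tab
}

make_expression <- function(values, condition) {
  mecorank:::new_expression_matrix(values, condition)
}

make_profile <- function(sample, x0, dx = x0, mutated = numeric(0)) {
  structure(list(sample = sample, x0 = x0, dx = dx, mutated = mutated),
            class = "patient_profile")
}

# build a patient_ranking directly from scores, bypassing propagation
make_ranking <- function(sample, genes, scores, mutated = character(0)) {
  structure(
    list(sample = sample, genes = genes, scores = scores,
         iterations_used = 1L, converged = TRUE,
         mutated = mutated, n_pruned = 0L),
    class = "patient_ranking"
  )
}

# random pruned bipartite graph for propagation property tests
random_graph <- function(m_max = 50L, n_max = 20L) {
  m <- sample(2:m_max, 1L)
  n <- sample(0:n_max, 1L)
  U <- sprintf("u%03d", seq_len(m))
  W_uu <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(m, m), dimnames = list(U, U))
  n_e <- sample(0:(2L * m), 1L)
  if (n_e > 0L) {
    i <- sample(m, n_e, replace = TRUE)
    j <- sample(m, n_e, replace = TRUE)
    keep <- i != j
    if (any(keep)) {
      W_uu <- Matrix::sparseMatrix(i = c(i[keep], j[keep]),
                                   j = c(j[keep], i[keep]),
                                   x = 1, dims = c(m, m),
                                   dimnames = list(U, U))
      W_uu@x[] <- 1  # collapse duplicate edge draws to binary
    }
  }
  V <- character(0)
  W_vu <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(m, 0L))
  y <- numeric(0)
  if (n > 0L) {
    V <- sprintf("v%03d", seq_len(n))
    # ensure each V column has >= 1 edge (pruned by construction)
    i <- c(sample(m, n, replace = TRUE),
           sample(m, sample(0:(2L * n), 1L), replace = TRUE))
    j <- c(seq_len(n), sample(n, length(i) - n, replace = TRUE))
    W_vu <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(m, n),
                                 dimnames = list(U, V))
    W_vu@x[] <- 1
    y <- 1 + round(stats::runif(n, 0, 2), 3)
  }
  structure(
    list(sample = "rnd", U = U, V = V, W_vu = W_vu, W_uu = W_uu,
         d_v = Matrix::colSums(W_vu), d_u = Matrix::rowSums(W_uu),
         x0 = round(stats::rnorm(m), 3), dx = round(stats::rnorm(m), 3),
         y = y, mutated_genes = V, n_pruned = 0L),
    class = "patient_bipartite"
  )
}

# independent dense fixed-point solve, written from the update rule itself
dense_solve_oracle <- function(graph, config) {
  lu <- config$lambda_u
  lv <- config$lambda_v
  m <- length(graph$U)
  c0 <- (1 - lu) * graph$x0
  if (length(graph$V)) {
    c0 <- c0 + lu * (1 - lv) *
      as.numeric(as.matrix(graph$W_vu) %*% (graph$y / sqrt(graph$d_v)))
  }
  s <- ifelse(graph$d_u > 0, 1 / sqrt(graph$d_u), 0)
  A <- as.matrix(graph$W_uu) %*% diag(s, nrow = m)
  solve(diag(m) - lu * lv * A, c0)
}

# exhaustive Condorcet/Copeland tabulation, independent of the package path:
# re-normalizes each voter's scores itself and loops over all pairs x voters
brute_condorcet <- function(score_list, mutated_list, delta) {
  cand <- sort(unique(unlist(lapply(score_list, names))), method = "radix")
  G <- length(cand)
  nv <- length(score_list)
  norm1 <- function(s) {
    if (length(s) == 1L || max(s) == min(s)) return(stats::setNames(rep(1, length(s)), names(s)))
    (s - min(s)) / (max(s) - min(s))
  }
  normed <- lapply(score_list, norm1)
  wins <- stats::setNames(integer(G), cand)
  losses <- stats::setNames(integer(G), cand)
  rank_sum <- stats::setNames(numeric(G), cand)
  for (v in seq_len(nv)) {
    r <- normed[[v]][cand]
    r[is.na(r)] <- 0
    rank_sum <- rank_sum + r
  }
  if (G > 1L) {
    for (a in 1:(G - 1L)) {
      for (b in (a + 1L):G) {
        va <- 0L
        for (v in seq_len(nv)) {
          r <- normed[[v]]
          ra <- if (cand[a] %in% names(r)) r[[cand[a]]] else 0
          rb <- if (cand[b] %in% names(r)) r[[cand[b]]] else 0
          da <- if (cand[a] %in% mutated_list[[v]]) 1 else delta
          db <- if (cand[b] %in% mutated_list[[v]]) 1 else delta
          if (da * ra > db * rb) va <- va + 1L
        }
        vb <- nv - va
        if (va > vb) {
          wins[a] <- wins[a] + 1L
          losses[b] <- losses[b] + 1L
        } else if (vb > va) {
          wins[b] <- wins[b] + 1L
          losses[a] <- losses[a] + 1L
        }
      }
    }
  }
  copeland <- wins - losses
  ord <- order(-copeland, -rank_sum, cand, method = "radix")
  list(gene = cand[ord], copeland = as.integer(copeland[ord]))
}

# tiny cohort used by pipeline-level tests; fast but structured
small_cohort <- function(seed = 1L) {
  generate_cohort(params = cohort_params(n_genes = 60L, n_tumor = 8L,
                                         n_normal = 4L, n_drivers = 3L),
                  seed = seed)
}
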