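test_that("damping degeneracies give closed-form fixed points immediately", {
  ppi <- path_ppi()
  prof <- make_profile("S1", x0 = c(a = 1, b = 0, c = 1), mutated = c(b = 2))
  g <- build_bipartite(prof, ppi)

  r0 <- propagate(g, mecorank_config(lambda_u = 0))
  expect_equal(r0$scores, g$x0)
  expect_equal(r0$iterations_used, 1L)
  expect_true(r0$converged)

  # edgeless graph: only the expression term survives
  f <- tempfile()
  writeLines(c("a\tb", "x\ty"), f)
  ppi_iso <- read_ppi(f)
  prof_iso <- make_profile("S2", x0 = c(a = 2, x = -1))  # a, x not adjacent
  g_iso <- prune_zero_vertices(build_bipartite(prof_iso, ppi_iso))
  r_iso <- propagate(g_iso, mecorank_config())
  expect_equal(r_iso$scores, 0.1 * g_iso$x0)
  expect_true(r_iso$converged)
})

test_that("iterated scores match a hand-built dense solve on the 3-U/1-V toy", {
  ppi <- path_ppi()
  prof <- make_profile("S1", x0 = c(a = 1, b = 0, c = 1),
                       dx = c(a = 1, b = 0, c = 1), mutated = c(b = 2))
  g <- build_bipartite(prof, ppi)
  cfg <- mecorank_config(epsilon = 1e-10)
  r <- propagate(g, cfg)
  # independent oracle: write the linear system down from the update rule
  x_direct <- dense_solve_oracle(g, cfg)
  expect_lt(max(abs(r$scores - x_direct)), 1e-6)
  expect_true(r$converged)
  expect_equal(fixed_point_oracle(g, cfg), x_direct)
})

test_that("propagation agrees with the dense oracle on random graphs", {
  set.seed(20)
  cfg <- mecorank_config(epsilon = 1e-9)
  for (i in 1:25) {
    g <- random_graph(30, 12)
    r <- propagate(g, cfg)
    expect_true(r$converged)
    expect_lt(max(abs(r$scores - dense_solve_oracle(g, cfg))), 1e-6)
    # package oracle agrees with the test-local one
    expect_lt(max(abs(fixed_point_oracle(g, cfg) - dense_solve_oracle(g, cfg))),
              1e-10)
  }
})

test_that("the fixed point does not depend on the iterate's initialization", {
  set.seed(33)
  g <- random_graph(25, 8)
  xs <- lapply(c("dx", "x0", "zeros"), function(ini) {
    propagate(g, mecorank_config(init = ini, epsilon = 1e-10))$scores
  })
  expect_lt(max(abs(xs[[1]] - xs[[2]])), 1e-8)
  expect_lt(max(abs(xs[[1]] - xs[[3]])), 1e-8)
})

test_that("raising a mutation coefficient never lowers any score and raises neighbors", {
  set.seed(14)
  cfg <- mecorank_config(epsilon = 1e-10)
  for (i in 1:10) {
    g <- random_graph(20, 6)
    if (!length(g$V)) next
    base <- fixed_point_oracle(g, cfg)
    k <- sample(length(g$V), 1L)
    g2 <- g
    g2$y[k] <- g2$y[k] * 2
    bumped <- fixed_point_oracle(g2, cfg)
    expect_true(all(bumped - base >= -1e-12))
    nbrs <- which(as.numeric(g$W_vu[, k]) > 0)
    expect_true(all(bumped[nbrs] > base[nbrs]))
  }
})

test_that("relabeling genes permutes scores identically", {
  set.seed(9)
  ppi <- generate_ppi(30, 2, seed = 4)
  genes <- ppi$genes
  mut <- sample(genes, 5)
  x0 <- setNames(rnorm(30), genes)
  prof <- make_profile("S1", x0 = x0, dx = x0,
                       mutated = setNames(runif(5, 1, 2), mut))
  r <- propagate(prune_zero_vertices(build_bipartite(prof, ppi)),
                 mecorank_config(epsilon = 1e-10))
  # relabel: swap name prefixes; lexicographic order changes wholesale
  relab <- setNames(sprintf("Z%04d", rev(seq_along(genes))), genes)
  f <- tempfile()
  writeLines(paste(relab[ppi$edges$from], relab[ppi$edges$to], sep = "\t"), f)
  ppi2 <- read_ppi(f)
  prof2 <- make_profile("S1", x0 = setNames(x0, relab[names(x0)]),
                        dx = setNames(x0, relab[names(x0)]),
                        mutated = setNames(prof$mutated, relab[mut]))
  r2 <- propagate(prune_zero_vertices(build_bipartite(prof2, ppi2)),
                  mecorank_config(epsilon = 1e-10))
  expect_equal(setNames(r2$scores, r2$genes)[relab[r$genes]],
               setNames(r$scores, relab[r$genes]))
})

test_that("a non-contractive graph raises a divergence error", {
  m <- 140L
  U <- sprintf("u%03d", 1:m)
  W <- Matrix::sparseMatrix(i = rep(1:m, each = m), j = rep(1:m, times = m),
                            x = 1, dims = c(m, m))
  Matrix::diag(W) <- 0
  W <- Matrix::drop0(W)
  g <- structure(
    list(sample = "K140", U = U, V = character(0),
         W_vu = Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                     x = numeric(0), dims = c(m, 0L)),
         W_uu = W, d_v = numeric(0), d_u = Matrix::rowSums(W),
         x0 = rep(1, m), dx = rep(1, m), y = numeric(0),
         mutated_genes = character(0), n_pruned = 0L),
    class = "patient_bipartite")
  # complete graph: damped spectral radius 0.09 * sqrt(m - 1) > 1
  expect_error(propagate(g, mecorank_config()), "diverging")
})

test_that("per-patient ranking sorts, breaks ties lexicographically, normalizes", {
  r <- make_ranking("S1", c("g1", "g2", "g3"), c(3, 1, 2))
  rp <- rank_patient(r)
  expect_equal(rp$gene, c("g1", "g3", "g2"))
  expect_equal(rp$rank_score, c(1, 0.5, 0))

  single <- rank_patient(make_ranking("S1", "g1", 0.7))
  expect_equal(single$rank_score, 1)

  expect_warning(rp_eq <- rank_patient(make_ranking("S1", c("b", "a"), c(2, 2))),
                 "all scores equal")
  expect_equal(rp_eq$gene, c("a", "b"))
  expect_equal(rp_eq$rank_score, c(1, 1))
})
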